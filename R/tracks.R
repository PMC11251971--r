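# Windowed structural tracks: running means of per-position profiles
# (stacking energy, position preference, curvature) and direct base-count
# statistics (GC skew, AT/GC content). Default step is 1 bp — tracks stay
# resolution-independent and the renderer downsamples to pixels.

check_window_spec <- function(window, step) {
  if (!is.numeric(window) || length(window) != 1L || window < 1L) {
    abort("`window` must be a positive integer")
  }
  if (!is.numeric(step) || length(step) != 1L || step < 1L) {
    abort("`step` must be a positive integer >= 1")
  }
  list(window = as.integer(window), step = as.integer(step))
}

#' Running mean of a per-position profile
#'
#' Each output value is the mean of the non-`NaN` entries in its window; a
#' window with no valid entries yields `NaN` (so long `N` gaps do not blank
#' a whole lane).
#'
#' @param profile Numeric vector of per-position values (may contain `NaN`).
#' @param window Window size (in profile positions).
#' @param step Step between window starts.
#' @param name,units,seq_id,seq_length Track metadata.
#' @return An `atlas_track` tibble.
#' @export
windowed_mean <- function(profile, window, step = 1L, name = "track",
                          units = "", seq_id = "seq",
                          seq_length = length(profile)) {
  ws <- check_window_spec(window, step)
  rs <- running_sums(as.numeric(profile), ws$window, ws$step)
  vals <- ifelse(rs$n > 0L, rs$sum / rs$n, NaN)
  new_track(vals, name, ws$window, ws$step, units = units, seq_id = seq_id,
            seq_length = seq_length)
}

profile_track <- function(dna, scale, window, step, name) {
  rec <- as_seq_record(dna)
  prof <- lookup_profile(dna, scale)
  if (window > length(prof)) abort("window exceeds sequence")
  windowed_mean(prof, window, step, name = name, units = scale$units,
                seq_id = rec$id, seq_length = rec$length)
}

#' Base-stacking energy track
#'
#' Mean dinucleotide stacking energy (kcal/mol) per window. The smallest
#' (most negative) values mark the most stable, hardest-to-melt DNA; values
#' closest to zero mark DNA that melts most easily.
#'
#' @inheritParams lookup_profile
#' @param window Window size in bp.
#' @param step Step in bp (default 1).
#' @param scale The dinucleotide scale (defaults to the packaged one).
#' @return An `atlas_track`.
#' @export
stacking_energy_track <- function(dna, window = 101L, step = 1L,
                                  scale = load_builtin_scale("stacking_energy")) {
  profile_track(dna, scale, window, step, "stacking_energy")
}

#' Nucleosome position-preference track
#'
#' Mean trinucleotide position preference per window; low values indicate a
#' decreased preference for wrapping around nucleosomes — candidate open
#' chromatin.
#'
#' @inheritParams stacking_energy_track
#' @export
position_preference_track <- function(dna, window = 101L, step = 1L,
                                      scale = load_builtin_scale("position_preference")) {
  profile_track(dna, scale, window, step, "position_preference")
}

# Raw curvature profile at the model's own helical window: per dinucleotide
# step, a planar deflection vector of magnitude `wedge` at phase
# (cumulative twist + direction); curvature over a window of L steps is
# |sum of vectors| / L, in degrees per step. Steps involving N contribute a
# zero vector (and the mean twist keeps the phase advancing through gaps).
curvature_profile <- function(rec, model) {
  codes <- encode_dna(rec$seq)
  n_steps <- rec$length - 1L
  if (n_steps < 1L) abort("sequence too short for curvature")
  i1 <- codes[seq_len(n_steps)]
  i2 <- codes[seq_len(n_steps) + 1L]
  ok <- i1 >= 1L & i1 <= 4L & i2 >= 1L & i2 <= 4L
  step_idx <- ifelse(ok, (i1 - 1L) * 4L + i2, NA_integer_)
  tbl <- model$table[order(model$table$kmer), ]
  wedge <- ifelse(ok, tbl$wedge[step_idx], 0)
  direction <- ifelse(ok, tbl$direction[step_idx], 0)
  twist <- ifelse(ok, tbl$twist[step_idx], mean(tbl$twist))
  phase <- (cumsum(twist) - twist) * pi / 180  # twist accumulated before step i
  ang <- phase + direction * pi / 180
  vx <- wedge * cos(ang)
  vy <- wedge * sin(ang)
  L <- model$window_len - 1L  # window_len bp -> L dinucleotide steps
  if (L > n_steps) abort("curvature model window exceeds sequence")
  sx <- running_sums(vx, L, 1L)
  sy <- running_sums(vy, L, 1L)
  sqrt(sx$sum^2 + sy$sum^2) / L
}

#' Intrinsic DNA curvature track
#'
#' Curvature magnitude from a dinucleotide wedge model: wedge deflection
#' vectors are summed with helical phasing over the model's window
#' (`model$window_len`, default 21 bp, two helical turns), giving degrees of
#' axis deflection per bp step; the resulting profile is then smoothed with
#' the requested window. Phased A-tracts (repeating in ~10.5 bp helical
#' phase) sum coherently and score high; out-of-phase composition cancels.
#' Values are non-negative magnitudes.
#'
#' @inheritParams stacking_energy_track
#' @param model A `curvature_model` (defaults to the packaged wedge model).
#' @export
curvature_track <- function(dna, window = 101L, step = 1L,
                            model = load_builtin_scale("curvature")) {
  rec <- as_seq_record(dna)
  stopifnot(inherits(model, "curvature_model"))
  prof <- curvature_profile(rec, model)
  if (window > length(prof)) abort("window exceeds sequence")
  tr <- windowed_mean(prof, window, step, name = "curvature",
                      units = "degrees/bp", seq_id = rec$id,
                      seq_length = rec$length)
  # centre positions account for the model's own window
  tr$pos <- tr$pos + model$window_len %/% 2L
  tr
}

count_track <- function(rec, window, step, numer_codes, denom = c("window", "gc"),
                        signed_codes = NULL, name, units = "") {
  codes <- encode_dna(rec$seq)
  ws <- check_window_spec(window, step)
  if (ws$window > rec$length) abort("window exceeds sequence")
  x <- as.numeric(codes %in% numer_codes)
  rs <- running_sums(x, ws$window, ws$step)
  denom <- match.arg(denom)
  if (denom == "window") {
    vals <- rs$sum / ws$window
  } else {
    d <- running_sums(as.numeric(codes %in% signed_codes), ws$window, ws$step)
    vals <- ifelse(d$sum > 0, rs$sum / d$sum, NaN)
  }
  new_track(vals, name, ws$window, ws$step, units = units, seq_id = rec$id,
            seq_length = rec$length)
}

#' GC skew track
#'
#' Per window, `(#G - #C) / (#G + #C)` — the bias of G towards the plotted
#' strand. A window with no G or C yields `NaN`. Values lie in `[-1, 1]`,
#' and the skew of the reverse complement is the reversed negated skew.
#' `denominator = "window"` switches to window-length normalisation.
#'
#' @inheritParams stacking_energy_track
#' @param window Window size in bp (default 10,000).
#' @param denominator `"gc"` (default, the standard skew definition) or
#'   `"window"`.
#' @export
gc_skew_track <- function(dna, window = 10000L, step = 1L,
                          denominator = c("gc", "window")) {
  denominator <- rlang::arg_match(denominator)
  rec <- as_seq_record(dna)
  codes <- encode_dna(rec$seq)
  ws <- check_window_spec(window, step)
  if (ws$window > rec$length) abort("window exceeds sequence")
  g <- running_sums(as.numeric(codes == 3L), ws$window, ws$step)
  c_ <- running_sums(as.numeric(codes == 2L), ws$window, ws$step)
  vals <- if (denominator == "gc") {
    den <- g$sum + c_$sum
    ifelse(den > 0, (g$sum - c_$sum) / den, NaN)
  } else {
    (g$sum - c_$sum) / ws$window
  }
  new_track(vals, "gc_skew", ws$window, ws$step, units = "", seq_id = rec$id,
            seq_length = rec$length)
}

#' AT-content track
#'
#' Per window, `(#A + #T) / window`. `N` counts in the denominator, not the
#' numerator. The default window is 0.1% of the sequence (or plotted
#' region) length, with a floor of 1 bp, so zoom atlases automatically get
#' finer windows.
#'
#' @inheritParams stacking_energy_track
#' @param window Window size in bp; `NULL` uses `max(1, round(0.001 * length))`.
#' @export
at_content_track <- function(dna, window = NULL, step = 1L) {
  rec <- as_seq_record(dna)
  window <- window %||% max(1L, as.integer(round(0.001 * rec$length)))
  count_track(rec, window, step, numer_codes = c(1L, 4L), denom = "window",
              name = "at_content")
}

#' GC-content track
#'
#' Per window, `(#G + #C) / window`; the complement of [at_content_track()]
#' on N-free sequence.
#'
#' @inheritParams at_content_track
#' @export
gc_content_track <- function(dna, window = NULL, step = 1L) {
  rec <- as_seq_record(dna)
  window <- window %||% max(1L, as.integer(round(0.001 * rec$length)))
  count_track(rec, window, step, numer_codes = c(2L, 3L), denom = "window",
              name = "gc_content")
}
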