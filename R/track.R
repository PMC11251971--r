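# The Track container: a tibble of window-centred values plus metadata
# attributes. Kept deliberately thin so tracks chain through dplyr verbs;
# metadata lives in attributes and is preserved by the track verbs here.

#' Construct a track tibble
#'
#' A track is a tibble with columns `pos` (0-based bp coordinate of the
#' window centre, `start_offset + i * step`) and `value`, carrying the
#' window size, step, units and originating sequence as attributes.
#' Missing windows hold `NaN`.
#'
#' @param values Numeric vector of per-window values.
#' @param name Track name (e.g. `"gc_skew"`).
#' @param window Window size in bp.
#' @param step Step between window starts in bp.
#' @param units Unit string (`""` for dimensionless).
#' @param seq_id Identifier of the source sequence.
#' @param seq_length Length of the source sequence in bp.
#' @param start_offset bp coordinate of the first value; defaults to
#'   `floor(window / 2)` (window-centred convention).
#' @param extra Optional tibble/data.frame of extra columns (e.g. repeat
#'   match metadata), row-aligned with `values`.
#' @return A tibble of class `atlas_track`.
#' @export
new_track <- function(values, name, window, step, units = "", seq_id = "seq",
                      seq_length = NA_integer_, start_offset = NULL,
                      extra = NULL) {
  start_offset <- start_offset %||% (window %/% 2L)
  out <- tibble(
    pos = start_offset + step * (seq_along(values) - 1L),
    value = as.numeric(values)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(out, as_tibble(extra))
  structure(
    out,
    class = c("atlas_track", class(out)),
    track_name = name,
    window = as.integer(window),
    step = as.integer(step),
    units = units,
    seq_id = seq_id,
    seq_length = as.integer(seq_length)
  )
}

track_meta <- function(track) {
  list(
    name = attr(track, "track_name"),
    window = attr(track, "window"),
    step = attr(track, "step"),
    units = attr(track, "units"),
    seq_id = attr(track, "seq_id"),
    seq_length = attr(track, "seq_length")
  )
}

#' @export
print.atlas_track <- function(x, ...) {
  m <- track_meta(x)
  cat(sprintf(
    "# Track \"%s\" on %s: window %d bp, step %d bp%s\n",
    m$name, m$seq_id, m$window, m$step,
    if (nzchar(m$units)) paste0(", units ", m$units) else ""
  ))
  NextMethod()
}

#' Summarise a track
#'
#' @param x An `atlas_track`.
#' @param ... Unused.
#' @return A one-row tibble with the track name, window, step, number of
#'   values, mean and SD over non-missing values.
#' @method glance atlas_track
#' @export
glance.atlas_track <- function(x, ...) {
  m <- track_meta(x)
  v <- x$value[is.finite(x$value)]
  tibble(
    track = m$name, seq_id = m$seq_id, window = m$window, step = m$step,
    units = m$units, n = nrow(x), n_missing = sum(!is.finite(x$value)),
    mean = if (length(v)) mean(v) else NaN,
    sd = if (length(v) > 1L) sd(v) else NaN
  )
}

#' Plot a track as a line along the sequence
#'
#' @param object An `atlas_track`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot atlas_track
#' @export
autoplot.atlas_track <- function(object, ...) {
  m <- track_meta(object)
  ggplot(object, aes(x = .data$pos, y = .data$value)) +
    ggplot2::geom_line(na.rm = TRUE, colour = "#2C6FBB") +
    labs(
      x = "position (bp)",
      y = if (nzchar(m$units)) sprintf("%s (%s)", m$name, m$units) else m$name,
      title = sprintf("%s — %s (window %d bp)", m$seq_id, m$name, m$window)
    ) +
    theme_minimal()
}
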