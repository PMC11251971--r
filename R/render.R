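# Atlas rendering: downsample tracks to a fixed pixel width, colour lanes by
# mean +/- k SD (or a fixed range for repeat bins), stack them with a
# strand-separated gene lane, and write PNG/SVG plus a sidecar JSON of lane
# statistics. All lane geometry is drawn in bp coordinates; one tile per
# pixel column.

#' bp-per-pixel resolution of an atlas
#'
#' @param region_length Length of the plotted region in bp.
#' @param width_px Plot width in pixels.
#' @return `region_length / width_px`.
#' @export
#' @examples
#' resolution(4930000, 2500) # 1972 bp/pixel
resolution <- function(region_length, width_px) {
  if (region_length < 1 || width_px < 1) abort("region_length and width_px must be >= 1")
  region_length / width_px
}

#' Describe one atlas lane
#'
#' @param track Name of the track the lane displays.
#' @param low,mid,high Colours of the lane's diverging map (value below /
#'   at / above centre).
#' @param scaling `"mean_sd"` (centre at the track mean, saturate at
#'   `mean +/- saturation_k * SD`) or `"fixed"` (use `fixed_min`/`fixed_max`).
#' @param saturation_k SDs at which the colour saturates (default 3).
#' @param invert Flip the colour axis (for lanes where low values are "hot").
#' @param fixed_min,fixed_max Range for `scaling = "fixed"`.
#' @return A one-row lanes tibble.
#' @export
lane_spec <- function(track, low, mid, high, scaling = c("mean_sd", "fixed"),
                      saturation_k = 3, invert = FALSE,
                      fixed_min = NA_real_, fixed_max = NA_real_) {
  scaling <- rlang::arg_match(scaling)
  if (!is.na(saturation_k) && saturation_k <= 0) abort("saturation_k must be > 0")
  tibble(track = track, low = low, mid = mid, high = high, scaling = scaling,
         saturation_k = saturation_k, invert = invert,
         fixed_min = fixed_min, fixed_max = fixed_max)
}

gene_lane_spec <- function() {
  tibble(track = "genes", low = NA_character_, mid = NA_character_,
         high = NA_character_, scaling = "none", saturation_k = NA_real_,
         invert = FALSE, fixed_min = NA_real_, fixed_max = NA_real_)
}

#' Default whole-locus lane set
#'
#' Stacking energy (red = melts easily), position preference (green = open
#' chromatin), strand-separated gene lane, direct repeats (blue), inverted
#' repeats (red), GC skew (magenta-turquoise) and AT content (red = AT
#' rich), in atlas order.
#'
#' @return A lanes tibble for [atlas_spec()].
#' @export
default_lanes <- function() {
  bind_rows(
    lane_spec("stacking_energy", "#B03A2E", "#F7F4F0", "#2E5FA3"),
    lane_spec("position_preference", "#1E8449", "#F7F4F0", "#5D5D5D"),
    gene_lane_spec(),
    lane_spec("direct_repeats", "#FFFFFF", "#9DBFE8", "#1A468F",
              scaling = "fixed", fixed_min = 0, fixed_max = 9),
    lane_spec("inverted_repeats", "#FFFFFF", "#EFA49B", "#A61B1B",
              scaling = "fixed", fixed_min = 0, fixed_max = 9),
    lane_spec("gc_skew", "#C71585", "#F7F4F0", "#17A2A2"),
    lane_spec("at_content", "#2E5FA3", "#F7F4F0", "#B03A2E")
  )
}

#' Zoom lane set
#'
#' The whole-locus set minus GC skew (a global property, uninformative in a
#' zoom) plus a DNA curvature lane on top, matching the per-gene atlas
#' layout.
#'
#' @return A lanes tibble for [atlas_spec()].
#' @export
zoom_lanes <- function() {
  bind_rows(
    lane_spec("curvature", "#F7F4F0", "#8FA8D8", "#1A468F"),
    lane_spec("stacking_energy", "#B03A2E", "#F7F4F0", "#2E5FA3"),
    lane_spec("position_preference", "#1E8449", "#F7F4F0", "#5D5D5D"),
    gene_lane_spec(),
    lane_spec("direct_repeats", "#FFFFFF", "#9DBFE8", "#1A468F",
              scaling = "fixed", fixed_min = 0, fixed_max = 9),
    lane_spec("inverted_repeats", "#FFFFFF", "#EFA49B", "#A61B1B",
              scaling = "fixed", fixed_min = 0, fixed_max = 9),
    lane_spec("at_content", "#2E5FA3", "#F7F4F0", "#B03A2E")
  )
}

#' Declarative atlas description
#'
#' @param lanes Lanes tibble ([default_lanes()] or [zoom_lanes()] or custom).
#' @param width_px Plot width in pixels (default 2500).
#' @param region Optional `c(start, end)` 0-based half-open plotted region;
#'   `NULL` plots the whole sequence.
#' @param title Optional title.
#' @return An `atlas_spec` list.
#' @export
atlas_spec <- function(lanes = default_lanes(), width_px = 2500L,
                       region = NULL, title = NULL) {
  if (width_px < 1L) abort("width_px must be >= 1")
  structure(list(lanes = lanes, width_px = as.integer(width_px),
                 region = region, title = title),
            class = "atlas_spec")
}

#' Downsample a track to pixel columns
#'
#' Pixel `j` (0-based) spans
#' `[region_start + j * res, region_start + (j + 1) * res)` bp; its value is
#' the mean of the non-`NaN` track values whose centre positions fall in
#' that span, or `NaN` if the pixel is empty.
#'
#' @param track An `atlas_track`.
#' @param region `c(start, end)`, 0-based half-open.
#' @param width_px Number of pixels.
#' @return Numeric vector of length `width_px`.
#' @export
downsample <- function(track, region, width_px) {
  res <- resolution(region[[2]] - region[[1]], width_px)
  keep <- track$pos >= region[[1]] & track$pos < region[[2]] & is.finite(track$value)
  px <- pmin(floor((track$pos[keep] - region[[1]]) / res), width_px - 1L)
  out <- rep(NaN, width_px)
  if (any(keep)) {
    sums <- rowsum(track$value[keep], px, reorder = TRUE)
    cnts <- rowsum(rep(1, sum(keep)), px, reorder = TRUE)
    out[as.integer(rownames(sums)) + 1L] <- sums[, 1] / cnts[, 1]
  }
  out
}

#' Normalise pixel values to [0, 1] for colouring
#'
#' `mean_sd` scaling maps the track mean to 0.5 and clamps at
#' `mean +/- saturation_k * SD`; `fixed` scaling uses the lane's stated
#' range (repeat bins use 0-9). A zero SD maps every pixel to 0.5.
#'
#' @param pixels Numeric pixel values (may contain `NaN`).
#' @param lane One row of a lanes tibble ([lane_spec()]).
#' @param mu,sigma Track mean and SD (used for `mean_sd` scaling).
#' @return Values in `[0, 1]` (`NaN` preserved).
#' @export
color_scale <- function(pixels, lane, mu = NA_real_, sigma = NA_real_) {
  if (lane$scaling == "fixed") {
    rng <- lane$fixed_max - lane$fixed_min
    norm <- if (rng == 0) rep(0.5, length(pixels)) else (pixels - lane$fixed_min) / rng
  } else {
    if (!is.finite(sigma) || sigma == 0) {
      norm <- ifelse(is.finite(pixels), 0.5, NaN)
    } else {
      norm <- 0.5 + (pixels - mu) / (2 * lane$saturation_k * sigma)
    }
  }
  norm <- pmin(pmax(norm, 0), 1)
  if (isTRUE(lane$invert)) norm <- 1 - norm
  norm
}

lane_palette <- function(lane, n = 256L) {
  grDevices::colorRampPalette(c(lane$low, lane$mid, lane$high))(n)
}

norm_to_colors <- function(norm, lane, background = "#FFFFFF") {
  pal <- lane_palette(lane)
  out <- rep(background, length(norm))
  ok <- is.finite(norm)
  out[ok] <- pal[pmin(pmax(floor(norm[ok] * 255) + 1L, 1L), 256L)]
  out
}

track_windows_for <- function(name, region_len, windows) {
  defaults <- list(
    stacking_energy = list(window = 101L, step = 1L),
    position_preference = list(window = 101L, step = 1L),
    curvature = list(window = 101L, step = 1L),
    gc_skew = list(window = min(10000L, region_len), step = 1L),
    at_content = list(window = max(1L, as.integer(round(0.001 * region_len))), step = 1L),
    gc_content = list(window = max(1L, as.integer(round(0.001 * region_len))), step = 1L),
    direct_repeats = list(window = 100L, step = 100L),
    inverted_repeats = list(window = 100L, step = 100L)
  )
  d <- defaults[[name]] %||% list(window = 101L, step = 1L)
  ov <- windows[[name]]
  if (!is.null(ov)) d <- modifyList(d, as.list(ov))
  d
}

compute_lane_tracks <- function(dna, lane_names, region, windows = list()) {
  rec <- as_seq_record(dna)
  r0 <- region[[1]]; r1 <- region[[2]]
  region_len <- r1 - r0
  sub <- tibble(id = rec$id, seq = substr(rec$seq, r0 + 1L, r1),
                length = region_len)
  shift_pos <- function(tr) { tr$pos <- tr$pos + r0; tr }
  out <- list()
  for (nm in setdiff(unique(lane_names), "genes")) {
    ws <- track_windows_for(nm, region_len, windows)
    out[[nm]] <- switch(nm,
      stacking_energy = shift_pos(stacking_energy_track(sub, ws$window, ws$step)),
      position_preference = shift_pos(position_preference_track(sub, ws$window, ws$step)),
      curvature = shift_pos(curvature_track(sub, ws$window, ws$step)),
      gc_skew = shift_pos(gc_skew_track(sub, ws$window, ws$step)),
      at_content = shift_pos(at_content_track(sub, ws$window, ws$step)),
      gc_content = shift_pos(gc_content_track(sub, ws$window, ws$step)),
      direct_repeats = repeat_track(dna, ws$window, ws$step, "direct", region = region),
      inverted_repeats = repeat_track(dna, ws$window, ws$step, "inverted", region = region),
      abort(sprintf("no track computer for lane '%s'", nm))
    )
  }
  out
}

#' Build a structural atlas object
#'
#' Computes every track the spec's lanes need over the plotted region and
#' bundles tracks, annotations, per-lane statistics and the bp/pixel
#' resolution into a `dna_atlas` object; [render_atlas()] or [autoplot()]
#' turn it into an image.
#'
#' @inheritParams stacking_energy_track
#' @param annotations Optional gene features tibble ([read_annotations()]).
#' @param spec An [atlas_spec()].
#' @param windows Named list of per-track `list(window =, step =)` overrides.
#' @param tracks Optional named list of precomputed `atlas_track`s; lanes
#'   without an entry are computed.
#' @return A `dna_atlas` object.
#' @export
build_atlas <- function(dna, annotations = NULL, spec = atlas_spec(),
                        windows = list(), tracks = NULL) {
  rec <- as_seq_record(dna)
  region <- spec$region %||% c(0L, rec$length)
  if (region[[1]] < 0L || region[[2]] > rec$length || region[[2]] <= region[[1]]) {
    abort("region must lie within the sequence")
  }
  lane_names <- spec$lanes$track
  need <- setdiff(setdiff(unique(lane_names), "genes"), names(tracks %||% list()))
  computed <- compute_lane_tracks(dna, need, region, windows)
  tracks <- c(tracks %||% list(), computed)
  stats <- bind_rows(lapply(setdiff(unique(lane_names), "genes"), function(nm) {
    glance(tracks[[nm]])
  }))
  structure(
    list(
      seq_id = rec$id, seq_length = rec$length, region = region,
      spec = spec, tracks = tracks,
      annotations = annotations,
      stats = stats,
      resolution = resolution(region[[2]] - region[[1]], spec$width_px),
      zoom = FALSE
    ),
    class = "dna_atlas"
  )
}

#' @export
print.dna_atlas <- function(x, ...) {
  cat(sprintf(
    "<dna_atlas> %s [%d, %d) — %d lanes, %d px, %.6g bp/pixel\n",
    x$seq_id, x$region[[1]], x$region[[2]], nrow(x$spec$lanes),
    x$spec$width_px, x$resolution
  ))
  invisible(x)
}

#' @describeIn build_atlas per-lane statistics (mean, SD, window, step).
#' @param x,object A `dna_atlas`.
#' @param ... Unused.
#' @method tidy dna_atlas
#' @export
tidy.dna_atlas <- function(x, ...) x$stats

#' @describeIn build_atlas one-row summary (region, resolution, lane count).
#' @method glance dna_atlas
#' @export
glance.dna_atlas <- function(x, ...) {
  tibble(
    seq_id = x$seq_id, region_start = x$region[[1]], region_end = x$region[[2]],
    n_lanes = nrow(x$spec$lanes), width_px = x$spec$width_px,
    resolution_bp_per_px = x$resolution
  )
}

atlas_pixels <- function(atlas) {
  lanes <- atlas$spec$lanes
  w <- atlas$spec$width_px
  out <- list()
  for (i in seq_len(nrow(lanes))) {
    lane <- lanes[i, ]
    if (lane$track == "genes") next
    tr <- atlas$tracks[[lane$track]]
    if (is.null(tr)) abort(sprintf("missing track for lane '%s'", lane$track))
    st <- glance(tr)
    px <- downsample(tr, atlas$region, w)
    norm <- color_scale(px, lane, st$mean, st$sd)
    out[[lane$track]] <- list(pixels = px, norm = norm,
                              colors = norm_to_colors(norm, lane))
  }
  out
}

draw_gene_lane <- function(atlas, y0, height) {
  ann <- atlas$annotations
  layers <- list(
    annotate("segment", x = atlas$region[[1]], xend = atlas$region[[2]],
             y = y0, yend = y0, colour = "grey70", linewidth = 0.3)
  )
  if (is.null(ann) || !nrow(ann)) return(layers)
  ann <- ann[ann$end > atlas$region[[1]] & ann$start < atlas$region[[2]], , drop = FALSE]
  strand_col <- c("+" = "#1F618D", "-" = "#B9770E")
  h2 <- height / 2
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    ymin <- if (g$strand == "+") y0 else y0 - h2
    ymax <- if (g$strand == "+") y0 + h2 else y0
    col <- strand_col[[g$strand]]
    if (isTRUE(atlas$zoom)) {
      # intron/exon shading: light gene body underneath, solid exons on top
      layers <- c(layers, list(
        annotate("rect", xmin = g$start, xmax = g$end, ymin = ymin, ymax = ymax,
                 fill = col, alpha = 0.3)
      ))
      ex <- g$exons[[1]]
      layers <- c(layers, list(
        annotate("rect", xmin = ex$start, xmax = ex$end, ymin = rep(ymin, nrow(ex)),
                 ymax = rep(ymax, nrow(ex)), fill = col)
      ))
    } else {
      layers <- c(layers, list(
        annotate("rect", xmin = g$start, xmax = g$end, ymin = ymin, ymax = ymax,
                 fill = col)
      ))
    }
  }
  layers
}

lane_label <- function(track) {
  c(stacking_energy = "Stacking energy",
    position_preference = "Position preference",
    curvature = "Curvature",
    genes = "Genes (+/-)",
    direct_repeats = "Direct repeats",
    inverted_repeats = "Inverted repeats",
    gc_skew = "GC skew",
    at_content = "AT content")[[track]] %||% track
}

#' Plot a structural atlas
#'
#' One coloured band per lane in spec order (top to bottom), a
#' strand-separated gene lane, a bp axis, and a legend strip giving each
#' lane's colour range.
#'
#' @param object A `dna_atlas` from [build_atlas()] or [render_zoom()].
#' @param ... Unused.
#' @return A patchwork of ggplots.
#' @method autoplot dna_atlas
#' @export
autoplot.dna_atlas <- function(object, ...) {
  lanes <- object$spec$lanes
  n <- nrow(lanes)
  w <- object$spec$width_px
  r0 <- object$region[[1]]; r1 <- object$region[[2]]
  res <- object$resolution
  pix <- atlas_pixels(object)
  tile_x <- r0 + (seq_len(w) - 0.5) * res
  tiles <- list(); gene_layers <- list()
  for (i in seq_len(n)) {
    lane <- lanes[i, ]
    y <- n - i + 1
    if (lane$track == "genes") {
      gene_layers <- draw_gene_lane(object, y, 0.8)
    } else {
      tiles[[lane$track]] <- tibble(x = tile_x, y = y,
                                    fill = pix[[lane$track]]$colors)
    }
  }
  tiles <- bind_rows(tiles)
  main <- ggplot(tiles, aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    geom_tile(width = res, height = 0.8) +
    scale_fill_identity() +
    scale_y_continuous(
      breaks = n:1,
      labels = vapply(lanes$track, lane_label, character(1)),
      limits = c(0.4, n + 0.6), expand = c(0, 0)
    ) +
    scale_x_continuous(
      labels = function(x) format(x, big.mark = ",", scientific = FALSE),
      limits = c(r0, r1), expand = c(0, 0), name = "position (bp)"
    ) +
    labs(
      title = object$spec$title %||% sprintf("Structural atlas — %s", object$seq_id),
      subtitle = sprintf("Resolution: %.6g bp/pixel (%s bp at %d px)",
                         res, format(r1 - r0, big.mark = ","), w)
    ) +
    theme_minimal(base_size = 9) +
    theme(panel.grid = element_blank(),
          plot.title = element_text(face = "bold"))
  main <- Reduce(`+`, gene_layers, init = main)
  legend <- atlas_legend(object)
  patchwork::wrap_plots(main, legend, ncol = 1, heights = c(max(n, 3), 1.6))
}

atlas_legend <- function(atlas) {
  lanes <- atlas$spec$lanes
  rows <- list()
  k <- 0
  for (i in seq_len(nrow(lanes))) {
    lane <- lanes[i, ]
    if (lane$track == "genes") next
    k <- k + 1
    st <- atlas$stats[atlas$stats$track == lane$track, ]
    if (lane$scaling == "fixed") {
      lo <- lane$fixed_min; hi <- lane$fixed_max
    } else {
      lo <- st$mean - lane$saturation_k * st$sd
      hi <- st$mean + lane$saturation_k * st$sd
    }
    grad <- seq(0, 1, length.out = 64)
    if (isTRUE(lane$invert)) grad <- rev(grad)
    rows[[lane$track]] <- tibble(
      x = seq_along(grad), y = k, fill = norm_to_colors(grad, lane),
      track = lane$track, lo = lo, hi = hi,
      units = if (nrow(st)) st$units else ""
    )
  }
  d <- bind_rows(rows)
  labs_d <- d |> dplyr::distinct(.data$track, .data$y, .data$lo, .data$hi, .data$units)
  nk <- max(d$y)
  ggplot(d, aes(x = .data$x, y = .data$y, fill = .data$fill)) +
    geom_tile(height = 0.55) +
    scale_fill_identity() +
    ggplot2::geom_text(data = labs_d, inherit.aes = FALSE, size = 2.4, hjust = 1,
                       aes(x = -1, y = .data$y,
                           label = sprintf("%s [%.3g, %.3g] %s",
                                           vapply(.data$track, lane_label, character(1)),
                                           .data$lo, .data$hi, .data$units))) +
    coord_cartesian(xlim = c(-70, 70)) +
    scale_y_continuous(limits = c(0.4, nk + 0.6)) +
    theme_void()
}

atlas_sidecar <- function(atlas) {
  lanes <- stats::setNames(
    lapply(atlas$stats$track, function(nm) {
      st <- atlas$stats[atlas$stats$track == nm, ]
      list(mean = st$mean, sd = st$sd, window = st$window, step = st$step,
           units = st$units)
    }),
    atlas$stats$track
  )
  list(
    seq_id = atlas$seq_id,
    region = c(atlas$region[[1]], atlas$region[[2]]),
    width_px = atlas$spec$width_px,
    resolution_bp_per_px = atlas$resolution,
    lanes = lanes
  )
}

#' Render an atlas to an image file with a sidecar JSON
#'
#' Writes PNG (ragg device; byte-deterministic for identical inputs) or SVG
#' (cairo) at exactly `width_px` pixels wide, plus `<path>.json` recording
#' per-lane mean/SD/window/step and the bp/pixel resolution.
#'
#' @param atlas A `dna_atlas`.
#' @param path Output image path ending in `.png` or `.svg`.
#' @param sidecar Write the JSON sidecar (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
render_atlas <- function(atlas, path, sidecar = TRUE) {
  stopifnot(inherits(atlas, "dna_atlas"))
  for (nm in setdiff(atlas$spec$lanes$track, "genes")) {
    if (is.null(atlas$tracks[[nm]])) abort(sprintf("missing track for lane '%s'", nm))
  }
  p <- autoplot(atlas)
  n <- nrow(atlas$spec$lanes)
  w <- atlas$spec$width_px
  h <- as.integer(48 * n + 220)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    ragg::agg_png(path, width = w, height = h, units = "px", background = "white")
  } else if (ext == "svg") {
    grDevices::svg(path, width = w / 96, height = h / 96, bg = "white")
  } else {
    abort(sprintf("unsupported image format '.%s' (use .png or .svg)", ext))
  }
  print(p)
  grDevices::dev.off()
  written <- path
  if (sidecar) {
    jpath <- paste0(tools::file_path_sans_ext(path), ".json")
    jsonlite::write_json(atlas_sidecar(atlas), jpath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, jpath)
  }
  invisible(written)
}

flip_track <- function(tr, region_len) {
  m <- track_meta(tr)
  pos_new <- region_len - tr$pos
  ord <- order(pos_new)
  new_track(tr$value[ord], m$name, m$window, m$step, units = m$units,
            seq_id = m$seq_id, seq_length = region_len,
            start_offset = pos_new[ord][[1]],
            extra = tr[ord, setdiff(names(tr), c("pos", "value")), drop = FALSE])
}

#' Build (and optionally render) a per-gene zoom atlas
#'
#' Extracts the gene plus flanks; a `-`-strand gene's region is
#' reverse-complemented before track computation so the gene reads 5'-to-3'
#' left to right. The lane set defaults to [zoom_lanes()] (no GC skew,
#' curvature added); the AT-content window is 0.1% of the zoom length;
#' exons are drawn solid and introns light-shaded. Repeat lanes are still
#' searched against the whole sequence (repeats are global). Flanks are
#' truncated at sequence ends with a note.
#'
#' @inheritParams build_atlas
#' @param gene A `gene_id` present in `annotations`.
#' @param flank Flank on each side of the gene, bp (default 5000).
#' @param path Optional image path; when given, [render_atlas()] is called.
#' @return A `dna_atlas` (invisibly when `path` is given).
#' @export
render_zoom <- function(dna, gene, annotations, flank = 5000L,
                        spec = atlas_spec(lanes = zoom_lanes()),
                        windows = list(), path = NULL) {
  rec <- as_seq_record(dna)
  if (!gene %in% annotations$gene_id) {
    abort(sprintf("gene '%s' not in annotations; available: %s", gene,
                  paste(annotations$gene_id, collapse = ", ")))
  }
  g <- annotations[annotations$gene_id == gene, ][1, ]
  r0 <- g$start - flank
  r1 <- g$end + flank
  if (r0 < 0L || r1 > rec$length) {
    inform(sprintf("flank truncated at sequence end for gene '%s'", gene))
    r0 <- max(r0, 0L); r1 <- min(r1, rec$length)
  }
  region <- c(as.integer(r0), as.integer(r1))
  region_len <- region[[2]] - region[[1]]
  flipped <- g$strand == "-"
  zseq <- substr(rec$seq, region[[1]] + 1L, region[[2]])
  if (flipped) zseq <- revcomp(zseq)
  zrec <- tibble(id = sprintf("%s|%s", rec$id, gene), seq = zseq,
                 length = region_len)
  # local annotation frame (all genes overlapping the region)
  ann <- annotations[annotations$end > region[[1]] & annotations$start < region[[2]], , drop = FALSE]
  to_local <- function(s, e) {
    if (flipped) c(region_len - (e - region[[1]]), region_len - (s - region[[1]]))
    else c(s - region[[1]], e - region[[1]])
  }
  ann_local <- ann
  for (i in seq_len(nrow(ann))) {
    sp <- to_local(ann$start[[i]], ann$end[[i]])
    ann_local$start[[i]] <- sp[[1]]; ann_local$end[[i]] <- sp[[2]]
    ex <- ann$exons[[i]]
    exl <- bind_rows(lapply(seq_len(nrow(ex)), function(j) {
      s <- to_local(ex$start[[j]], ex$end[[j]])
      tibble(start = s[[1]], end = s[[2]])
    })) |> arrange(.data$start)
    ann_local$exons[[i]] <- exl
    if (flipped) {
      ann_local$strand[[i]] <- if (ann$strand[[i]] == "+") "-" else "+"
    }
  }
  lane_names <- setdiff(unique(spec$lanes$track), "genes")
  local_names <- setdiff(lane_names, c("direct_repeats", "inverted_repeats"))
  tracks <- compute_lane_tracks(zrec, local_names, c(0L, region_len), windows)
  for (strand in c("direct", "inverted")) {
    nm <- paste0(strand, "_repeats")
    if (!nm %in% lane_names) next
    ws <- track_windows_for(nm, region_len, windows)
    tr <- repeat_track(dna, ws$window, ws$step, strand, region = region)
    tr$pos <- tr$pos - region[[1]]
    attr(tr, "seq_length") <- region_len
    if (flipped) tr <- flip_track(tr, region_len)
    tracks[[nm]] <- tr
  }
  zspec <- spec
  zspec$region <- NULL
  zspec$title <- zspec$title %||%
    sprintf("Zoom atlas — %s (%s strand, 5'→3')", gene, g$strand)
  atlas <- build_atlas(zrec, annotations = ann_local, spec = zspec,
                       tracks = tracks)
  atlas$zoom <- TRUE
  atlas$source_region <- region
  atlas$gene <- gene
  if (!is.null(path)) {
    render_atlas(atlas, path)
    return(invisible(atlas))
  }
  atlas
}
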