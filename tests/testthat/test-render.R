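test_that("resolution is region length over pixel width", {
  expect_equal(resolution(4930000, 2500), 1972)
  expect_equal(resolution(2500, 2500), 1)
  expect_equal(resolution(15000, 2500), 6)
  expect_error(resolution(0, 100), ">= 1")
})

test_that("downsampling means track values per pixel and marks empty pixels", {
  tr <- new_track(rep(2.5, 200), "c", window = 1L, step = 1L,
                  seq_id = "s", seq_length = 200L)
  expect_equal(downsample(tr, c(0, 200), 50), rep(2.5, 50))
  # width equal to value count with aligned step: identity
  v <- runif(64)
  tr2 <- new_track(v, "i", window = 1L, step = 1L, seq_id = "s",
                   seq_length = 64L)
  expect_equal(downsample(tr2, c(0, 64), 64), v)
  # brute-force per-pixel mean oracle
  structatlas:::with_seed(64, {
    vals <- runif(500)
    tr3 <- new_track(vals, "r", window = 9L, step = 3L, seq_id = "s",
                     seq_length = 1500L)
    region <- c(0, 1500)
    width <- 37
    res <- 1500 / width
    oracle <- vapply(seq_len(width) - 1L, function(j) {
      inpix <- tr3$value[tr3$pos >= j * res & tr3$pos < (j + 1) * res]
      if (length(inpix)) mean(inpix) else NaN
    }, numeric(1))
    expect_equal(downsample(tr3, region, width), oracle, tolerance = 1e-9)
  })
  # values outside the region are ignored; empty pixels are NaN
  expect_true(all(is.nan(downsample(tr2, c(100, 200), 10))))
})

test_that("colour scaling centres at the mean and saturates at k SDs", {
  lane <- lane_spec("x", "#000000", "#888888", "#FFFFFF", saturation_k = 3)
  expect_equal(color_scale(5, lane, mu = 5, sigma = 2), 0.5)
  expect_equal(color_scale(5 + 3 * 2, lane, mu = 5, sigma = 2), 1)
  expect_equal(color_scale(5 - 3 * 2, lane, mu = 5, sigma = 2), 0)
  expect_equal(color_scale(100, lane, mu = 5, sigma = 2), 1) # clamped
  expect_equal(color_scale(c(1, 7, 9), lane, mu = 5, sigma = 0),
               c(0.5, 0.5, 0.5))
  fixed <- lane_spec("bins", "#FFFFFF", "#8888FF", "#0000FF",
                     scaling = "fixed", fixed_min = 0, fixed_max = 9)
  expect_equal(color_scale(9, fixed), 1)
  expect_equal(color_scale(0, fixed), 0)
  inv <- lane_spec("x", "#000000", "#888888", "#FFFFFF", invert = TRUE)
  expect_equal(color_scale(5 + 6, inv, mu = 5, sigma = 2), 0)
})

test_that("atlas images have the requested pixel width and all lanes", {
  skip_if_not_installed("png")
  dna <- make_sequence(fixture_recipe(6000, seed = 41, id = "r6k"))
  ann <- make_annotation(tibble::tibble(
    gene_id = "g1", strand = "+", start = 1000L, end = 2000L))
  spec <- atlas_spec(width_px = 600)
  atlas <- build_atlas(dna, annotations = ann, spec = spec,
                       windows = list(gc_skew = list(window = 1000L)))
  expect_equal(nrow(atlas$spec$lanes), 7L)  # 6 structural + gene lane
  p <- withr::local_tempfile(fileext = ".png")
  paths <- render_atlas(atlas, p)
  img <- png::readPNG(p)
  expect_equal(dim(img)[[2]], 600L)
  side <- jsonlite::read_json(paths[[2]])
  expect_equal(side$resolution_bp_per_px, 6000 / 600)
  expect_setequal(names(side$lanes), setdiff(atlas$spec$lanes$track, "genes"))
  expect_true(all(c("mean", "sd", "window", "step") %in%
                    names(side$lanes$stacking_energy)))
})

test_that("rendering is deterministic: identical input gives identical bytes", {
  dna <- make_sequence(fixture_recipe(4000, seed = 10, id = "det"))
  spec <- atlas_spec(width_px = 400)
  win <- list(gc_skew = list(window = 500L))
  p1 <- withr::local_tempfile(fileext = ".png")
  p2 <- withr::local_tempfile(fileext = ".png")
  render_atlas(build_atlas(dna, spec = spec, windows = win), p1)
  render_atlas(build_atlas(dna, spec = spec, windows = win), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("missing lane tracks are reported by name", {
  dna <- make_sequence(fixture_recipe(3000, seed = 2))
  atlas <- build_atlas(dna, spec = atlas_spec(
    lanes = lane_spec("at_content", "#FFFFFF", "#888888", "#000000"),
    width_px = 100))
  atlas$tracks$at_content <- NULL
  expect_error(render_atlas(atlas, withr::local_tempfile(fileext = ".png")),
               "at_content")
})

test_that("zoom atlases swap GC skew for curvature and scale the AT window", {
  dna <- make_sequence(fixture_recipe(12000, seed = 19, id = "z12k"))
  ann <- make_annotation(tibble::tibble(
    gene_id = c("plus", "minus"), strand = c("+", "-"),
    start = c(3000L, 7000L), end = c(5000L, 9500L),
    exons = list(tibble::tibble(start = c(3000L, 4200L), end = c(3600L, 5000L)),
                 tibble::tibble(start = c(7000L, 8400L), end = c(7900L, 9500L)))))
  z <- render_zoom(dna, "plus", ann, flank = 1500,
                   spec = atlas_spec(lanes = zoom_lanes(), width_px = 500))
  whole <- default_lanes()$track
  expect_setequal(z$spec$lanes$track,
                  c(setdiff(whole, "gc_skew"), "curvature"))
  zoom_len <- z$region[[2]] - z$region[[1]]
  expect_equal(attr(z$tracks$at_content, "window"),
               max(1L, as.integer(round(0.001 * zoom_len))))
  expect_equal(zoom_len, 5000L)
})

test_that("minus-strand zooms read 5'-to-3': exon order is reversed genomic order", {
  dna <- make_sequence(fixture_recipe(12000, seed = 19, id = "z12k"))
  exons_genomic <- tibble::tibble(start = c(7000L, 8400L), end = c(7900L, 9500L))
  ann <- make_annotation(tibble::tibble(
    gene_id = "minus", strand = "-", start = 7000L, end = 9500L,
    exons = list(exons_genomic)))
  z <- render_zoom(dna, "minus", ann, flank = 500,
                   spec = atlas_spec(lanes = zoom_lanes(), width_px = 400))
  # region [6500, 10000); local frame flipped: genomic exon [8400,9500)
  # (the 3' one on the genome) becomes the first local exon
  loc <- z$annotations[z$annotations$gene_id == "minus", ]
  expect_equal(loc$strand, "+")  # reads left to right after flipping
  ex <- loc$exons[[1]]
  rlen <- 10000L - 6500L
  expect_equal(ex$start[[1]], rlen - (9500L - 6500L))
  expect_equal(ex$end[[2]], rlen - (7000L - 6500L))
  # zoomed sequence is the reverse complement of the genomic region
  expect_equal(as_tibble(z$tracks$at_content)$value[1:5],
               at_content_track(tibble::tibble(
                 id = "m", seq = revcomp(substr(dna$seq, 6501, 10000)),
                 length = rlen), window = attr(z$tracks$at_content, "window"))$value[1:5])
})

test_that("flanks truncate at sequence ends with a note", {
  dna <- make_sequence(fixture_recipe(3000, seed = 29))
  ann <- make_annotation(tibble::tibble(
    gene_id = "edge", strand = "+", start = 100L, end = 600L))
  expect_message(
    z <- render_zoom(dna, "edge", ann, flank = 1000,
                     spec = atlas_spec(lanes = zoom_lanes(), width_px = 200)),
    "truncated"
  )
  expect_equal(z$region, c(0L, 1600L))
})

test_that("a planted extreme block stays put through downsampling", {
  # single AT-rich block: the hottest pixel of the AT lane must sit within
  # one pixel of the full-resolution argmax
  recipe <- fixture_recipe(10000, seed = 37, blocks = list(
    block("at_rich", start = 6200, len = 400, p = 1)
  ))
  dna <- make_sequence(recipe)
  tr <- at_content_track(dna, 100)
  width <- 125
  px <- downsample(tr, c(0, 10000), width)
  res <- 10000 / width
  argmax_px <- which.max(px) - 1L
  argmax_full <- tr$pos[which.max(tr$value)]
  expect_lte(abs(argmax_px - floor(argmax_full / res)), 1L)
})
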