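test_that("windowed mean averages valid positions and flags empty windows", {
  expect_equal(windowed_mean(c(1, 1, 1, 1), 2)$value, c(1, 1, 1))
  expect_equal(windowed_mean(c(0, 2), 2)$value, 1)
  expect_equal(windowed_mean(c(1, NaN, 3), 3)$value, 2)
  expect_true(is.nan(windowed_mean(c(NaN, NaN), 2)$value))
  expect_error(windowed_mean(c(1, 2), 5), "window exceeds sequence")
})

test_that("track geometry obeys the window-centred coordinate convention", {
  for (window in c(1L, 2L, 7L, 50L)) {
    for (step in c(1L, 3L, 10L)) {
      tr <- windowed_mean(runif(100), window, step)
      expect_equal(tr$pos[[1]], window %/% 2L)
      expect_equal(nrow(tr), (100L - window) %/% step + 1L)
      expect_equal(diff(tr$pos), rep(step, nrow(tr) - 1L))
    }
  }
})

test_that("property tracks match a brute-force oracle on random sequence", {
  dna <- random_dna(1000, seed = 101)
  st <- load_builtin_scale("stacking_energy")
  pp <- load_builtin_scale("position_preference")
  for (spec in list(c(100L, 1L), c(33L, 7L), c(250L, 50L))) {
    tr <- stacking_energy_track(dna, spec[[1]], spec[[2]])
    expect_equal(tr$value,
                 oracle_window_mean(lookup_profile(dna, st), spec[[1]], spec[[2]]),
                 tolerance = 1e-9)
    tr2 <- position_preference_track(dna, spec[[1]], spec[[2]])
    expect_equal(tr2$value,
                 oracle_window_mean(lookup_profile(dna, pp), spec[[1]], spec[[2]]),
                 tolerance = 1e-9)
  }
})

test_that("homopolymers give constant tracks equal to the homotypic entry", {
  polyA <- tibble::tibble(id = "pA", seq = strrep("A", 300), length = 300L)
  st <- stacking_energy_track(polyA, 50)
  expect_equal(st$value,
               rep(load_builtin_scale("stacking_energy")$values[["AA"]], nrow(st)))
  pp <- position_preference_track(polyA, 50)
  expect_equal(pp$value,
               rep(load_builtin_scale("position_preference")$values[["AAA"]], nrow(pp)))
})

test_that("strand-symmetric tracks reverse under reverse complement", {
  dna <- random_dna(600, seed = 55)
  rc <- tibble::tibble(id = "rc", seq = revcomp(dna$seq), length = 600L)
  expect_equal(stacking_energy_track(rc, 75)$value,
               rev(stacking_energy_track(dna, 75)$value))
})

test_that("all-N windows yield NaN without poisoning neighbours", {
  s <- paste0(strrep("A", 50), strrep("N", 60), strrep("A", 50))
  dna <- tibble::tibble(id = "n", seq = s, length = nchar(s))
  tr <- position_preference_track(dna, 20)
  expect_true(any(is.nan(tr$value)))
  expect_true(any(is.finite(tr$value)))
  aa <- load_builtin_scale("position_preference")$values[["AAA"]]
  fin <- tr$value[is.finite(tr$value)]
  expect_equal(fin, rep(aa, length(fin)))
})

test_that("GC skew follows its definition, bounds and antisymmetry", {
  g <- tibble::tibble(id = "g", seq = strrep("G", 50), length = 50L)
  expect_equal(gc_skew_track(g, 10)$value, rep(1, 41))
  gccc <- tibble::tibble(id = "x", seq = strrep("GGCC", 25), length = 100L)
  expect_equal(gc_skew_track(gccc, 4, step = 4)$value, rep(0, 25))
  at <- tibble::tibble(id = "at", seq = strrep("AT", 30), length = 60L)
  expect_true(all(is.nan(gc_skew_track(at, 10)$value)))
  # window-length normalisation is available as an option
  expect_equal(gc_skew_track(gccc, 4, step = 4, denominator = "window")$value,
               rep(0, 25))
})

test_that("gc_skew and at_content identities hold over many random draws", {
  structatlas:::with_seed(424, {
    for (i in 1:1000) {
      n <- sample(30:120, 1)
      w <- sample(5:25, 1)
      dna <- random_dna(n)
      sk <- gc_skew_track(dna, w)$value
      expect_true(all(is.nan(sk) | (sk >= -1 & sk <= 1)))
      rc <- tibble::tibble(id = "rc", seq = revcomp(dna$seq), length = n)
      expect_equal(gc_skew_track(rc, w)$value, -rev(sk))
      expect_equal(at_content_track(dna, w)$value + gc_content_track(dna, w)$value,
                   rep(1, n - w + 1))
    }
  })
})

test_that("AT content handles pure, mixed and N-containing input", {
  atat <- tibble::tibble(id = "a", seq = strrep("AT", 50), length = 100L)
  expect_equal(at_content_track(atat, 10)$value, rep(1, 91))
  gcgc <- tibble::tibble(id = "g", seq = strrep("GC", 50), length = 100L)
  expect_equal(at_content_track(gcgc, 10)$value, rep(0, 91))
  # N counts in the denominator, not the numerator
  wn <- tibble::tibble(id = "n", seq = "AANN", length = 4L)
  expect_equal(at_content_track(wn, 4)$value, 0.5)
  # default window is 0.1% of the sequence length
  long <- random_dna(20000, seed = 9)
  expect_equal(attr(at_content_track(long), "window"), 20L)
})

test_that("curvature is zero for a straight model and invariant to translation", {
  model <- load_builtin_scale("curvature")
  straight <- model
  straight$table$wedge <- 0
  dna <- random_dna(400, seed = 77)
  cv0 <- curvature_track(dna, 50, model = straight)$value
  expect_equal(cv0, rep(0, length(cv0)))
  # profile spans the wedge window, then the smoothing window
  expect_length(cv0, 400 - 21 - 50 + 2)
  polyA <- tibble::tibble(id = "pA", seq = strrep("A", 200), length = 200L)
  cv <- curvature_track(polyA, 30)$value
  expect_true(all(abs(cv - cv[[1]]) < 1e-9))
  expect_true(all(curvature_track(dna, 50)$value >= 0))
})

test_that("in-phase A-tracts are more curved than a shuffled control", {
  recipe <- fixture_recipe(420, seed = 5, blocks = list(
    block("phased_a_tract", start = 0, len = 420)
  ))
  phased <- make_sequence(recipe)
  shuffled <- structatlas:::with_seed(6, {
    ch <- sample(strsplit(phased$seq, "")[[1]])
    tibble::tibble(id = "shuf", seq = paste(ch, collapse = ""), length = 420L)
  })
  c_phased <- mean(curvature_track(phased, 50)$value)
  c_shuf <- mean(curvature_track(shuffled, 50)$value)
  expect_gt(c_phased, c_shuf)
})
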