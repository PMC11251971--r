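# Independent oracles and tiny generators used across the suite. The
# oracles deliberately use different code paths from the package: plain
# loops for window means, Biostrings' C mismatch counter for repeat
# identities.

random_dna <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  draw <- function() paste(sample(alphabet, n, replace = TRUE), collapse = "")
  s <- if (is.null(seed)) draw() else structatlas:::with_seed(seed, draw())
  tibble::tibble(id = "rand", seq = s, length = n)
}

# brute-force running mean ignoring NaN, O(n * w)
oracle_window_mean <- function(profile, window, step = 1) {
  starts <- seq(1, length(profile) - window + 1, by = step)
  vapply(starts, function(s) {
    v <- profile[s:(s + window - 1)]
    v <- v[!is.na(v)]
    if (length(v)) mean(v) else NaN
  }, numeric(1))
}

# brute-force best ungapped identity via Biostrings mismatch counts;
# excludes candidates overlapping [qstart, qstart + w) in original
# coordinates. N-free sequences only (Biostrings lets N match N).
oracle_best_identity <- function(seq, qstart, w, strand = "direct",
                                 min_offset = 0) {
  n <- nchar(seq)
  subject <- if (strand == "inverted") {
    Biostrings::reverseComplement(Biostrings::DNAString(seq))
  } else {
    Biostrings::DNAString(seq)
  }
  pat <- Biostrings::DNAString(substr(seq, qstart + 1, qstart + w))
  np <- n - w + 1
  ed <- Biostrings::neditStartingAt(pat, subject, starting.at = 1:np,
                                    with.indels = FALSE)
  p <- 0:(np - 1)
  orig <- if (strand == "inverted") n - p - w else p
  ed[abs(orig - qstart) < (w + min_offset)] <- NA
  if (all(is.na(ed))) return(0)
  (w - min(ed, na.rm = TRUE)) / w
}

# pure-R identity oracle that treats N as matching nothing (for N cases)
oracle_best_identity_n <- function(seq, qstart, w, strand = "direct") {
  n <- nchar(seq)
  space <- if (strand == "inverted") structatlas::revcomp(seq) else seq
  q <- strsplit(substr(seq, qstart + 1, qstart + w), "")[[1]]
  sv <- strsplit(space, "")[[1]]
  best <- 0
  for (p in 0:(n - w)) {
    orig <- if (strand == "inverted") n - p - w else p
    if (abs(orig - qstart) < w) next
    cand <- sv[(p + 1):(p + w)]
    hits <- sum(q == cand & q != "N" & cand != "N")
    best <- max(best, hits)
  }
  best / w
}

oracle_repeat_track <- function(seq, w = 100, step = 100, strand = "direct") {
  n <- nchar(seq)
  qs <- seq(0, n - w, by = step)
  vapply(qs, function(q) oracle_best_identity(seq, q, w, strand), numeric(1))
}

toy_annotation <- function(path = NULL) {
  make_annotation(tibble::tibble(
    gene_id = c("gA", "gB"), strand = c("+", "-"),
    start = c(1000L, 6000L), end = c(3000L, 9000L),
    exons = list(
      tibble::tibble(start = c(1000L, 2200L), end = c(1600L, 3000L)),
      tibble::tibble(start = c(6000L, 7500L), end = c(6800L, 9000L))
    )
  ), path = path, seq_id = "rand")
}
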