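# Internal helpers shared across modules. All coordinates inside the package
# are 0-based half-open; 1-based coordinates exist only at file boundaries.

DNA_BASES <- c("A", "C", "G", "T")

# Integer encoding of a DNA string: A=1 C=2 G=3 T=4, N=5, anything else 0.
# Used by the profile lookup and the repeat scanner.
encode_dna <- function(seq) {
  lut <- integer(128L)
  lut[utf8ToInt("A")] <- 1L
  lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L
  lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  codes <- utf8ToInt(seq)
  codes[codes > 128L] <- 1L  # defensive: non-ASCII never occurs post-ingest
  lut[codes]
}

decode_dna <- function(x) {
  intToUtf8(utf8ToInt("ACGTN")[x])
}

#' Reverse complement of a DNA string
#'
#' Complements over the `{A,C,G,T,N}` alphabet (`N` maps to `N`) and reverses.
#'
#' @param seq A character scalar DNA sequence.
#' @return A character scalar.
#' @export
#' @examples
#' revcomp("AACGT")
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  intToUtf8(rev(utf8ToInt(chartr("ACGTNacgtn", "TGCANtgcan", seq))))
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Accept either a one-row sequence tibble (id, seq, length) or a plain
# character scalar; return a list(id, seq, length).
as_seq_record <- function(dna, arg = "dna") {
  if (is.character(dna) && length(dna) == 1L) {
    return(list(id = "seq", seq = toupper(dna), length = nchar(dna)))
  }
  if (is.data.frame(dna)) {
    if (!all(c("id", "seq") %in% names(dna))) {
      abort(sprintf("`%s` must have columns `id` and `seq`", arg))
    }
    if (nrow(dna) != 1L) {
      abort(sprintf(
        "`%s` must be a single sequence record (got %d rows); atlases are per-record",
        arg, nrow(dna)
      ))
    }
    return(list(id = dna$id[[1]], seq = dna$seq[[1]], length = nchar(dna$seq[[1]])))
  }
  abort(sprintf("`%s` must be a one-row sequence tibble or a character scalar", arg))
}

# Running windowed sums over x, ignoring NA/NaN: returns list(sum, n) per
# window, windows starting at offsets seq(0, len - window, by = step).
running_sums <- function(x, window, step = 1L) {
  len <- length(x)
  if (window > len) abort("window exceeds sequence")
  valid <- !is.na(x)
  x0 <- ifelse(valid, x, 0)
  cs <- c(0, cumsum(x0))
  cn <- c(0L, cumsum(as.integer(valid)))
  starts <- seq.int(1L, len - window + 1L, by = step)
  list(
    sum = cs[starts + window] - cs[starts],
    n = cn[starts + window] - cn[starts],
    starts0 = starts - 1L
  )
}

fmt_num <- function(x) sprintf("%.10g", x)
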