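# Global direct / inverted repeat lanes. For each query window the best
# ungapped (Hamming) identity against every other same-length window of the
# sequence (direct) or of its reverse complement (inverted) is found,
# excluding candidates that overlap the query in original coordinates, and
# binned to 0-9. The search is k-mer seeded with an exhaustive vectorised
# fallback, so reported identities are exact (see `approximate`).

#' Bin a repeat identity into the 0-9 atlas scale
#'
#' `bin = min(floor(identity * 10), 9)`: 9 means more than 90% identity,
#' 0 less than 10%.
#'
#' @param identity Numeric vector of identities in `[0, 1]`.
#' @return Integer vector of bins in `0:9`.
#' @export
#' @examples
#' bin_identity(c(0.05, 0.95, 1))
bin_identity <- function(identity) {
  if (any(!is.finite(identity)) || any(identity < 0) || any(identity > 1)) {
    abort("identity must lie in [0, 1]")
  }
  pmin(as.integer(floor(identity * 10)), 9L)
}

# match counts of query (codes qv, length w) against every window of subject
# codes sv, via w vectorised comparisons. N never matches (query N -> -1).
match_counts <- function(sv, qv) {
  n <- length(sv)
  w <- length(qv)
  np <- n - w + 1L
  if (np < 1L) return(integer(0))
  qv[qv == 5L | qv == 0L] <- -1L
  m <- integer(np)
  base <- seq_len(np)
  for (j in seq_len(w)) m <- m + (sv[base + j - 1L] == qv[[j]])
  m
}

# candidate window starts (0-based, in *search-space* coordinates) that must
# be excluded for a query at qstart (original coordinates). For the inverted
# strand the search space is revcomp(seq): search start p maps to original
# start n - p - w.
overlapping_candidates <- function(np, qstart, w, n, inverted, min_offset = 0L) {
  p <- seq_len(np) - 1L
  orig <- if (inverted) n - p - w else p
  abs(orig - qstart) < (w + min_offset)
}

repeat_search_space <- function(rec, strand) {
  if (strand == "inverted") encode_dna(revcomp(rec$seq)) else encode_dna(rec$seq)
}

# exact best match for one query against precomputed search-space codes
best_match_impl <- function(sv, qv, qstart, w, n, inverted, min_offset,
                            seed_index = NULL, seed_len = 12L,
                            approximate = FALSE) {
  np <- n - w + 1L
  excl <- overlapping_candidates(np, qstart, w, n, inverted, min_offset)
  if (all(excl)) {
    return(list(identity = 0, match_start = NA_integer_, note = "no non-overlapping placement exists"))
  }
  use_seeds <- !is.null(seed_index) && w > seed_len
  best <- -1L
  best_p <- NA_integer_
  if (use_seeds) {
    cand <- seeded_candidates(seed_index, qv, w, seed_len, np)
    cand <- cand[!excl[cand + 1L]]
    if (length(cand)) {
      counts <- vapply(cand, function(p) {
        sum(sv[p + seq_len(w)] == qv)
      }, integer(1))
      best <- max(counts)
      best_p <- cand[[which.max(counts)]]
    }
    # pigeonhole guarantee: any alignment with <= floor((w - s)/(s + 1))
    # mismatches contains an exact seed; below that identity the seeds may
    # miss the optimum, so fall through to the exhaustive scan.
    guaranteed_mm <- (w - seed_len) %/% (seed_len + 1L)
    if (best >= w - guaranteed_mm || approximate) {
      id <- max(best, 0L) / w
      return(list(identity = id, match_start = finalize_start(best_p, n, w, inverted), note = NA_character_))
    }
  }
  m <- match_counts(sv, qv)
  m[excl] <- -1L
  best_p <- which.max(m) - 1L
  best <- m[[best_p + 1L]]
  list(identity = max(best, 0L) / w,
       match_start = finalize_start(best_p, n, w, inverted),
       note = NA_character_)
}

finalize_start <- function(p, n, w, inverted) {
  if (is.na(p)) return(NA_integer_)
  as.integer(if (inverted) n - p - w else p)
}

# seed index: positions (0-based) of every seed_len-mer of the search space;
# seeds longer than 15 bp would overflow the 32-bit 4^k key (and give no
# speedup), so the search falls back to the exhaustive scan instead
build_seed_index <- function(sv, seed_len) {
  n <- length(sv)
  if (n < seed_len || seed_len > 15L) return(NULL)
  np <- n - seed_len + 1L
  ok <- rep(TRUE, np)
  key <- integer(np)
  for (j in seq_len(seed_len)) {
    cj <- sv[seq_len(np) + j - 1L]
    ok <- ok & cj >= 1L & cj <= 4L
    key <- key * 4L + (cj - 1L)
  }
  # 4^12 keys overflow 32-bit? 4^12 = 16.7M, fits; accumulate as double to be safe
  split(which(ok) - 1L, key[ok])
}

seeded_candidates <- function(seed_index, qv, w, seed_len, np) {
  nq <- w - seed_len + 1L
  ok <- rep(TRUE, nq)
  key <- integer(nq)
  for (j in seq_len(seed_len)) {
    cj <- qv[seq_len(nq) + j - 1L]
    ok <- ok & cj >= 1L & cj <= 4L
    key <- key * 4L + (cj - 1L)
  }
  offs <- which(ok) - 1L
  keys <- as.character(key[ok])
  hits <- seed_index[keys]
  cand <- unlist(purrr::map2(hits, offs, function(h, o) if (is.null(h)) integer(0) else h - o),
                 use.names = FALSE)
  cand <- unique(cand)
  cand[cand >= 0L & cand < np]
}

#' Best repeat match for one query window
#'
#' Scans a length-`window` query against every same-length window of the
#' whole sequence (`strand = "direct"`) or of its reverse complement
#' (`strand = "inverted"`), excluding candidates that overlap the query in
#' original coordinates. Identity is ungapped: matching positions divided
#' by `window`; `N` matches nothing.
#'
#' @inheritParams stacking_energy_track
#' @param query_start 0-based start of the query window.
#' @param window Query window length in bp (default 100).
#' @param strand `"direct"` or `"inverted"`.
#' @param min_offset Minimum extra gap (bp) required between query and
#'   candidate beyond non-overlap (default 0).
#' @param seed_len Seed length for the indexed search (default 12).
#' @param approximate If `TRUE`, skip the exhaustive fallback and report the
#'   best seeded hit (low bins may then be underestimated).
#' @return A one-row tibble: `query_start`, `query_center`, `best_identity`,
#'   `bin`, `match_start`, `match_strand`.
#' @export
best_match <- function(dna, query_start, window = 100L,
                       strand = c("direct", "inverted"), min_offset = 0L,
                       seed_len = 12L, approximate = FALSE) {
  strand <- rlang::arg_match(strand)
  rec <- as_seq_record(dna)
  w <- as.integer(window)
  if (query_start < 0L || query_start + w > rec$length) {
    abort("query window outside sequence")
  }
  if (rec$length < 2L * w) {
    inform(sprintf(
      "sequence %s is shorter than twice the window (%d < %d); identity reported as 0",
      rec$id, rec$length, 2L * w
    ))
  }
  sv <- repeat_search_space(rec, strand)
  qv <- encode_dna(rec$seq)[query_start + seq_len(w)]
  idx <- build_seed_index(sv, seed_len)
  hit <- best_match_impl(sv, qv, query_start, w, rec$length,
                         strand == "inverted", as.integer(min_offset),
                         seed_index = idx, seed_len = seed_len,
                         approximate = approximate)
  tibble(
    query_start = as.integer(query_start),
    query_center = as.integer(query_start + w %/% 2L),
    best_identity = hit$identity,
    bin = bin_identity(hit$identity),
    match_start = hit$match_start,
    match_strand = strand
  )
}

#' Direct or inverted repeat track
#'
#' One binned best-match identity per query window of size `window`
#' (default 100 bp), windows starting every `step` bp (default
#' `step = window`, non-overlapping). Values are plotted at window centres:
#' the first at `floor(window / 2)` bp (50 bp for the default window) and
#' the last within `window / 2 + step` bp of the sequence end. With a
#' `region`, only queries inside the region are computed but the search
#' space remains the whole sequence (repeats are global).
#'
#' @inheritParams best_match
#' @param step Step between query starts (default `window`).
#' @param region Optional `c(start, end)` 0-based half-open restriction of
#'   query windows.
#' @return An `atlas_track` of integer bins (0-9) with extra columns
#'   `best_identity` and `match_start`.
#' @export
repeat_track <- function(dna, window = 100L, step = window,
                         strand = c("direct", "inverted"), min_offset = 0L,
                         seed_len = 12L, approximate = FALSE, region = NULL) {
  strand <- rlang::arg_match(strand)
  rec <- as_seq_record(dna)
  w <- as.integer(window)
  step <- as.integer(step)
  if (w > rec$length) abort("window exceeds sequence")
  region <- region %||% c(0L, rec$length)
  q0 <- as.integer(region[[1]])
  q1 <- min(as.integer(region[[2]]), rec$length) - w
  if (q1 < q0) abort("region shorter than window")
  qstarts <- seq.int(q0, q1, by = step)
  if (rec$length < 2L * w) {
    inform(sprintf(
      "sequence %s is shorter than twice the window (%d < %d); identities reported as 0",
      rec$id, rec$length, 2L * w
    ))
  }
  sv <- repeat_search_space(rec, strand)
  codes <- encode_dna(rec$seq)
  idx <- build_seed_index(sv, seed_len)
  hits <- lapply(qstarts, function(q) {
    best_match_impl(sv, codes[q + seq_len(w)], q, w, rec$length,
                    strand == "inverted", as.integer(min_offset),
                    seed_index = idx, seed_len = seed_len,
                    approximate = approximate)
  })
  ids <- vapply(hits, `[[`, numeric(1), "identity")
  new_track(
    as.numeric(bin_identity(ids)),
    name = paste0(strand, "_repeats"), window = w, step = step, units = "bin",
    seq_id = rec$id, seq_length = rec$length,
    start_offset = q0 + w %/% 2L,
    extra = tibble(
      best_identity = ids,
      match_start = vapply(hits, `[[`, integer(1), "match_start")
    )
  )
}
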