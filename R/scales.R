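# Published k-mer parameter sets, stored as plain-text data assets under
# inst/extdata/scales/ (header comments carry name/k/units/citation; body is
# KMER<TAB>value...). Stored as text so completeness and strand symmetry are
# test-assertable without touching code.

BUILTIN_SCALES <- c("stacking_energy", "position_preference", "curvature")

all_kmers <- function(k) {
  g <- do.call(expand.grid, rep(list(DNA_BASES), k))
  sort(apply(g[, rev(seq_len(k)), drop = FALSE], 1, paste, collapse = ""))
}

parse_scale_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  meta_of <- function(key, default = NA_character_) {
    m <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (length(m)) sub(paste0("^#", key, " "), "", m[[1]]) else default
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  kmers <- vapply(fields, `[[`, character(1), 1L)
  k <- as.integer(meta_of("k"))
  name <- meta_of("name")
  citation <- meta_of("citation")
  units <- meta_of("units", "")
  sym <- tolower(meta_of("strand_symmetric", "false")) == "true"
  if (name == "curvature" || length(fields[[1]]) > 2L) {
    tbl <- tibble(
      kmer = kmers,
      wedge = as.numeric(vapply(fields, `[[`, character(1), 2L)),
      direction = as.numeric(vapply(fields, `[[`, character(1), 3L)),
      twist = as.numeric(vapply(fields, `[[`, character(1), 4L))
    )
    structure(
      list(name = name, k = k, table = tbl,
           window_len = as.integer(meta_of("window_len", "21")),
           units = units, citation = citation),
      class = "curvature_model"
    )
  } else {
    values <- stats::setNames(
      as.numeric(vapply(fields, `[[`, character(1), 2L)), kmers
    )
    new_property_scale(name, k, values, units, citation, sym)
  }
}

#' Construct a property scale
#'
#' A property scale maps every k-mer over `{A,C,G,T}` (k = 2 or 3) to a real
#' number. Completeness is enforced at construction.
#'
#' @param name Scale name.
#' @param k k-mer size (2 or 3).
#' @param values Named numeric vector over all `4^k` k-mers.
#' @param units Unit string.
#' @param citation Literature source of the values.
#' @param strand_symmetric Whether `values[kmer] == values[revcomp(kmer)]`.
#' @return An object of class `property_scale`.
#' @export
new_property_scale <- function(name, k, values, units = "", citation = "",
                               strand_symmetric = FALSE) {
  km <- all_kmers(k)
  if (!setequal(names(values), km) || length(values) != 4^k) {
    abort(sprintf("scale '%s' must map exactly the %d %d-mers over ACGT",
                  name, 4^k, k))
  }
  if (any(!is.finite(values))) abort(sprintf("scale '%s' has non-finite values", name))
  structure(
    list(name = name, k = as.integer(k), values = values[km], units = units,
         citation = citation, strand_symmetric = isTRUE(strand_symmetric)),
    class = "property_scale"
  )
}

#' @export
print.property_scale <- function(x, ...) {
  cat(sprintf("<property_scale> %s: k=%d, %d values, units=%s%s\n  source: %s\n",
              x$name, x$k, length(x$values), x$units,
              if (x$strand_symmetric) ", strand-symmetric" else "", x$citation))
  invisible(x)
}

#' @export
print.curvature_model <- function(x, ...) {
  cat(sprintf("<curvature_model> %s: wedge/direction/twist over %d dinucleotides, window %d bp\n  source: %s\n",
              x$name, nrow(x$table), x$window_len, x$citation))
  invisible(x)
}

#' Load a packaged structural parameter set
#'
#' Three scales ship with the package: `"stacking_energy"` (dinucleotide
#' base-stacking energies, kcal/mol), `"position_preference"` (trinucleotide
#' nucleosome position preference) and `"curvature"` (a dinucleotide
#' wedge-angle model with helical twist). Each carries its literature
#' citation in metadata.
#'
#' @param name One of `"stacking_energy"`, `"position_preference"`,
#'   `"curvature"`.
#' @return A `property_scale`, or a `curvature_model` for `"curvature"`.
#' @export
#' @examples
#' load_builtin_scale("stacking_energy")
load_builtin_scale <- function(name) {
  if (!is.character(name) || length(name) != 1L || !name %in% BUILTIN_SCALES) {
    abort(sprintf("unknown scale '%s'; available scales: %s",
                  paste(name, collapse = ","),
                  paste(BUILTIN_SCALES, collapse = ", ")))
  }
  path <- system.file("extdata", "scales", paste0(name, ".tsv"),
                      package = "structatlas", mustWork = TRUE)
  parse_scale_file(path)
}

#' List the packaged scales
#'
#' @return A character vector of scale names accepted by
#'   [load_builtin_scale()].
#' @export
list_builtin_scales <- function() BUILTIN_SCALES

#' Per-position profile of a property scale along a sequence
#'
#' Position `i` (0-based) holds the scale value of the k-mer starting at
#' `i`; the profile has `length - k + 1` entries. Any k-mer containing `N`
#' yields `NaN`.
#'
#' @param dna A one-row sequence tibble (from [read_fasta()] or
#'   [make_sequence()]) or a character scalar.
#' @param scale A `property_scale`.
#' @return A numeric vector of length `seq length - k + 1`.
#' @export
lookup_profile <- function(dna, scale) {
  rec <- as_seq_record(dna)
  stopifnot(inherits(scale, "property_scale"))
  k <- scale$k
  if (k > rec$length) abort("scale k exceeds sequence length")
  codes <- encode_dna(rec$seq)
  codes[codes > 4L | codes == 0L] <- NA_integer_
  n <- rec$length - k + 1L
  idx <- codes[seq_len(n)] - 1L
  if (k >= 2L) for (j in 2L:k) idx <- idx * 4L + (codes[seq_len(n) + j - 1L] - 1L)
  vals <- unname(scale$values[all_kmers(k)])[idx + 1L]
  vals[is.na(vals)] <- NaN
  vals
}
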