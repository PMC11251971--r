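# Synthetic sequence and annotation generators. Every fixture is
# reproducible from (recipe, seed); planted repeat blocks are exact copies
# (direct) or exact reverse complements (inverted) of their source spans.

#' Describe a block of a synthetic sequence
#'
#' @param kind One of `"random"`, `"at_rich"`, `"gc_rich"`, `"g_run"`,
#'   `"planted_direct_repeat"`, `"planted_inverted_repeat"`,
#'   `"phased_a_tract"`.
#' @param start 0-based start of the block.
#' @param len Block length in bp.
#' @param ... Kind-specific parameters: `p` (probability of the enriched
#'   bases, default 1 for `at_rich`/`gc_rich`), `src_start` (source span
#'   start for planted repeats), `tract_len` and `period` for
#'   `phased_a_tract` (defaults 6 and 10.5 bp).
#' @return A block list for [fixture_recipe()].
#' @export
block <- function(kind = c("random", "at_rich", "gc_rich", "g_run",
                           "planted_direct_repeat", "planted_inverted_repeat",
                           "phased_a_tract"),
                  start, len, ...) {
  kind <- rlang::arg_match(kind)
  c(list(kind = kind, start = as.integer(start), len = as.integer(len)),
    list(...))
}

#' Recipe for a synthetic sequence
#'
#' @param length Sequence length in bp.
#' @param seed Integer RNG seed; the sequence is deterministic given the
#'   recipe and seed.
#' @param blocks List of [block()]s applied, in order, on top of a uniform
#'   random background.
#' @param id Record id.
#' @return A `fixture_recipe` list.
#' @export
fixture_recipe <- function(length, seed = 1L, blocks = list(), id = "synthetic") {
  length <- as.integer(length)
  planted_spans <- list()
  for (b in blocks) {
    if (b$start < 0L || b$start + b$len > length) {
      abort(sprintf("block [%d, %d) outside sequence of length %d",
                    b$start, b$start + b$len, length))
    }
    if (startsWith(b$kind, "planted_")) {
      if (is.null(b$src_start)) abort(sprintf("%s needs `src_start`", b$kind))
      if (b$src_start < 0L || b$src_start + b$len > length) {
        abort("planted repeat source span outside sequence")
      }
      for (sp in planted_spans) {
        if (b$start < sp[[2]] && sp[[1]] < b$start + b$len) {
          abort("overlapping planted blocks")
        }
      }
      planted_spans <- c(planted_spans, list(c(b$start, b$start + b$len)))
    }
  }
  structure(list(length = length, seed = as.integer(seed), blocks = blocks,
                 id = id),
            class = "fixture_recipe")
}

sample_bases <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sample(DNA_BASES, n, replace = TRUE, prob = probs[DNA_BASES])
}

#' Generate a synthetic sequence from a recipe
#'
#' @param recipe A [fixture_recipe()].
#' @return A one-row sequence tibble (`id`, `seq`, `length`), as from
#'   [read_fasta()].
#' @export
make_sequence <- function(recipe) {
  stopifnot(inherits(recipe, "fixture_recipe"))
  with_seed(recipe$seed, {
    chars <- sample_bases(recipe$length)
    for (b in recipe$blocks) {
      span <- b$start + seq_len(b$len)
      chars[span] <- switch(b$kind,
        random = sample_bases(b$len),
        at_rich = {
          p <- b$p %||% 1
          sample(DNA_BASES, b$len, replace = TRUE,
                 prob = c(p / 2, (1 - p) / 2, (1 - p) / 2, p / 2))
        },
        gc_rich = {
          p <- b$p %||% 1
          sample(DNA_BASES, b$len, replace = TRUE,
                 prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2))
        },
        g_run = rep("G", b$len),
        planted_direct_repeat = chars[b$src_start + seq_len(b$len)],
        planted_inverted_repeat = {
          src <- chars[b$src_start + seq_len(b$len)]
          rev(chartr("ACGT", "TGCA", src))
        },
        phased_a_tract = {
          out <- chars[span]
          period <- b$period %||% 10.5
          tract_len <- b$tract_len %||% 6L
          starts <- unique(as.integer(round(seq(0, b$len - tract_len, by = period))))
          for (s in starts) out[s + seq_len(tract_len)] <- "A"
          out
        }
      )
    }
    tibble(id = recipe$id, seq = paste(chars, collapse = ""),
           length = recipe$length)
  })
}

#' Serialise / restore a fixture recipe as YAML
#'
#' @param recipe A `fixture_recipe`.
#' @param path YAML file path.
#' @return `path` invisibly; `recipe_from_yaml()` returns the recipe.
#' @export
recipe_to_yaml <- function(recipe, path) {
  yaml::write_yaml(unclass(recipe), path)
  invisible(path)
}

#' @rdname recipe_to_yaml
#' @export
recipe_from_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  blocks <- lapply(x$blocks, function(b) do.call(block, b))
  fixture_recipe(x$length, x$seed, blocks, id = x$id %||% "synthetic")
}

#' Generate a toy gene annotation (features + GFF3)
#'
#' @param layout A tibble with columns `gene_id`, `strand`, `start`, `end`
#'   (0-based half-open) and optionally a list-column `exons` of tibbles
#'   with `start`/`end`; genes without exons get one exon spanning the
#'   gene.
#' @param path Optional GFF3 output path; when given the file is written
#'   (1-based inclusive coordinates, `gene` rows with `ID=`, `exon` rows
#'   with `Parent=`).
#' @param seq_id Sequence name used in the GFF3 `seqid` column.
#' @return The features tibble in [read_annotations()] form.
#' @export
make_annotation <- function(layout, path = NULL, seq_id = "synthetic") {
  layout <- as_tibble(layout)
  if (!"exons" %in% names(layout)) layout$exons <- vector("list", nrow(layout))
  feats <- layout
  for (i in seq_len(nrow(feats))) {
    if (is.null(feats$exons[[i]])) {
      feats$exons[[i]] <- tibble(start = feats$start[[i]], end = feats$end[[i]])
    } else {
      feats$exons[[i]] <- as_tibble(feats$exons[[i]]) |> arrange(.data$start)
    }
  }
  feats <- validate_features(feats)
  if (!is.null(path)) {
    lines <- "##gff-version 3"
    for (i in seq_len(nrow(feats))) {
      g <- feats[i, ]
      lines <- c(lines, sprintf(
        "%s\tstructatlas\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
        seq_id, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id
      ))
      ex <- g$exons[[1]]
      lines <- c(lines, sprintf(
        "%s\tstructatlas\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        seq_id, ex$start + 1L, ex$end, g$strand, g$gene_id,
        seq_len(nrow(ex)), g$gene_id
      ))
    }
    writeLines(lines, path)
  }
  feats
}
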