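# Sequence and annotation I/O, plus track export in genome-browser formats.
# FASTA parsing is delegated to Biostrings; GFF3 to rtracklayer. The GenBank
# flat-file feature-table reader is minimal and covers gene/CDS/exon keys
# with join()/complement() locations, which is all an atlas needs.

#' Read DNA sequences from a FASTA file
#'
#' Sequences are upper-cased on ingest. Any IUPAC ambiguity code other than
#' `N` (and any other non-`ACGT` character) is mapped to `N` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(sprintf("failed to parse FASTA %s: %s", path, conditionMessage(e)))
  )
  if (length(set) == 0L) abort("no sequences")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  total <- sum(nchar(seqs))
  if (total == 0L) abort("no sequences")
  n_acgtn <- sum(vapply(seqs, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1]] %in% c(DNA_BASES, "N"))
  }, integer(1)))
  if (n_acgtn / total < 0.5) abort("not DNA")
  cleaned <- gsub("[^ACGTN]", "N", seqs)
  changed <- cleaned != seqs
  if (any(changed)) {
    warn(sprintf(
      "%d record(s) contained non-ACGTN characters; mapped to N",
      sum(changed)
    ))
  }
  tibble(id = unname(ids), seq = unname(cleaned), length = unname(nchar(cleaned)))
}

#' Write sequences to a FASTA file
#'
#' @param dna A sequence tibble (`id`, `seq`).
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dna, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(dna))) {
    writeLines(paste0(">", dna$id[[i]]), con)
    s <- dna$seq[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

validate_features <- function(feats) {
  for (i in seq_len(nrow(feats))) {
    ex <- feats$exons[[i]]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(ex$start < feats$start[[i]]) || any(ex$end > feats$end[[i]])) {
      abort(sprintf("exon outside gene span for feature '%s'", feats$gene_id[[i]]))
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      abort(sprintf("overlapping exons in feature '%s'", feats$gene_id[[i]]))
    }
    feats$exons[[i]] <- as_tibble(ex)
  }
  feats
}

#' Read gene annotations
#'
#' Coordinates in GFF3 and GenBank files are 1-based inclusive; they are
#' converted to the package's 0-based half-open convention on ingest.
#' Features without exon/CDS sub-features get a single exon spanning the
#' gene. Introns are the gaps between consecutive exons.
#'
#' @param path Path to the annotation file.
#' @param format `"gff3"` or `"genbank"`.
#' @return A tibble with columns `gene_id`, `strand` (`"+"`/`"-"`), `start`,
#'   `end` (0-based half-open) and a list-column `exons` of tibbles with
#'   `start`/`end`.
#' @export
read_annotations <- function(path, format = c("gff3", "genbank")) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  feats <- if (format == "gff3") read_gff3_features(path) else read_genbank_features(path)
  validate_features(feats)
}

read_gff3_features <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  types <- tolower(as.character(df$type))
  is_gene <- types == "gene"
  if (!any(is_gene)) {
    # fall back: treat every top-level feature as a gene
    is_gene <- !types %in% c("exon", "cds")
  }
  genes <- df[is_gene, , drop = FALSE]
  kids <- df[types %in% c("exon", "cds"), , drop = FALSE]
  get_id <- function(d) {
    id <- if ("ID" %in% names(d)) as.character(d$ID) else rep(NA_character_, nrow(d))
    if ("Name" %in% names(d)) id <- dplyr::coalesce(id, as.character(d$Name))
    dplyr::coalesce(id, paste0("feature_", seq_len(nrow(d))))
  }
  gene_ids <- get_id(genes)
  parents <- if ("Parent" %in% names(kids)) {
    vapply(kids$Parent, function(p) if (length(p)) as.character(p)[[1]] else NA_character_, character(1))
  } else {
    rep(NA_character_, nrow(kids))
  }
  exons <- lapply(seq_len(nrow(genes)), function(i) {
    sel <- !is.na(parents) & parents == gene_ids[[i]]
    if (!any(sel)) {
      return(tibble(start = genes$start[[i]] - 1L, end = genes$end[[i]]))
    }
    k <- kids[sel, , drop = FALSE]
    # prefer exon rows over CDS rows when both are present
    ktypes <- tolower(as.character(k$type))
    if (any(ktypes == "exon")) k <- k[ktypes == "exon", , drop = FALSE]
    tibble(start = as.integer(k$start) - 1L, end = as.integer(k$end)) |>
      arrange(.data$start)
  })
  tibble(
    gene_id = gene_ids,
    strand = ifelse(as.character(genes$strand) == "-", "-", "+"),
    start = as.integer(genes$start) - 1L,
    end = as.integer(genes$end),
    exons = exons
  )
}

# Parse a GenBank location string: "123..456", "complement(...)",
# "join(1..3,7..10)" and nesting thereof. Returns list(strand, spans) with
# spans as a 1-based inclusive start/end tibble.
parse_gb_location <- function(loc) {
  strand <- "+"
  loc <- gsub("[<>]", "", gsub("\\s", "", loc))
  while (TRUE) {
    if (grepl("^complement\\(", loc)) {
      strand <- if (strand == "+") "-" else "+"
      loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    } else if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
      loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    } else {
      break
    }
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  spans <- lapply(parts, function(p) {
    p <- gsub("complement\\(|\\)", "", p)
    nums <- as.integer(strsplit(p, "\\.\\.")[[1]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    tibble(start = nums[[1]], end = nums[[2]])
  })
  list(strand = strand, spans = bind_rows(spans))
}

read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (!length(fstart)) abort(sprintf("no FEATURES table in %s", path))
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[[1]]]) - 1L else length(lines)
  block <- lines[(fstart[[1]] + 1L):fend]
  # a feature line has a key in columns 6-20; continuation lines are blank there
  is_key <- grepl("^ {5}\\S", block)
  idx <- cumsum(is_key)
  feats <- split(block, idx)
  feats <- feats[names(feats) != "0"]
  parsed <- lapply(feats, function(fl) {
    key <- sub("^ {5}(\\S+).*$", "\\1", fl[[1]])
    rest <- sub("^ {5}\\S+\\s*", "", fl[[1]])
    quals_at <- grepl("^\\s*/", fl)
    loc <- paste0(c(rest, trimws(fl[-1][!quals_at[-1]])), collapse = "")
    quals <- trimws(fl[quals_at])
    gene <- sub('^/gene="?([^"]*)"?$', "\\1", grep("^/gene=", quals, value = TRUE))
    locus <- sub('^/locus_tag="?([^"]*)"?$', "\\1", grep("^/locus_tag=", quals, value = TRUE))
    list(key = tolower(key), loc = loc,
         name = if (length(gene)) gene[[1]] else if (length(locus)) locus[[1]] else NA_character_)
  })
  keys <- vapply(parsed, `[[`, character(1), "key")
  genes <- parsed[keys == "gene"]
  subs <- parsed[keys %in% c("cds", "exon", "mrna")]
  if (!length(genes)) abort(sprintf("no gene features in %s", path))
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    gl <- parse_gb_location(g$loc)
    gspan <- c(min(gl$spans$start), max(gl$spans$end))
    gid <- g$name %||% NA_character_
    if (is.na(gid)) gid <- paste0("gene_", i)
    # sub-features matched by /gene name, else by containment
    ex <- NULL
    for (s in subs) {
      if (s$key == "mrna") next
      sl <- parse_gb_location(s$loc)
      same_name <- !is.na(s$name) && !is.na(g$name) && s$name == g$name
      contained <- min(sl$spans$start) >= gspan[[1]] && max(sl$spans$end) <= gspan[[2]]
      if (same_name || (is.na(s$name) && contained)) {
        ex <- sl$spans
        break
      }
    }
    if (is.null(ex)) ex <- tibble(start = gspan[[1]], end = gspan[[2]])
    tibble(
      gene_id = gid, strand = gl$strand,
      start = gspan[[1]] - 1L, end = gspan[[2]],
      exons = list(tibble(start = ex$start - 1L, end = ex$end) |> arrange(.data$start))
    )
  })
  bind_rows(rows)
}

# ---- track export -----------------------------------------------------------

track_header_comments <- function(track) {
  m <- track_meta(track)
  c(
    "# structatlas track",
    sprintf("# name=%s", m$name),
    sprintf("# window=%d", m$window),
    sprintf("# step=%d", m$step),
    sprintf("# units=%s", m$units),
    sprintf("# seq_id=%s", m$seq_id),
    sprintf("# seq_length=%d", m$seq_length)
  )
}

parse_header_comments <- function(lines) {
  kv <- grep("^# [a-z_]+=", lines, value = TRUE)
  keys <- sub("^# ([a-z_]+)=.*$", "\\1", kv)
  vals <- sub("^# [a-z_]+=", "", kv)
  stats::setNames(as.list(vals), keys)
}

# Map value index -> exported interval [i*step, i*step + step) (anchored at
# the window start, so a full-coverage step-1 track spans [0, n_values)).
track_intervals <- function(track) {
  m <- track_meta(track)
  starts <- (seq_len(nrow(track)) - 1L) * m$step
  tibble(start = starts, end = starts + m$step, value = track$value)
}

#' Export a track to a genome-browser format
#'
#' `bedgraph` writes 0-based half-open intervals with runs of equal values
#' merged; `wig` writes 1-based fixedStep blocks; `bed` writes one scored
#' interval per window (for integer repeat-bin tracks). `NaN` values become
#' gaps (omitted intervals / block breaks), never literal `NaN` text.
#' Metadata needed for a lossless re-read is written as `# key=value`
#' comments, which browsers ignore.
#'
#' @param track An `atlas_track`.
#' @param path Output path.
#' @param format `"bedgraph"`, `"wig"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wig", "bed")) {
  format <- rlang::arg_match(format)
  m <- track_meta(track)
  iv <- track_intervals(track)
  keep <- is.finite(iv$value)
  out <- track_header_comments(track)
  if (format == "bedgraph") {
    out <- c(out, sprintf('track type=bedGraph name="%s"', m$name))
    ivk <- iv[keep, , drop = FALSE]
    if (nrow(ivk)) {
      new_run <- c(TRUE, ivk$value[-1L] != ivk$value[-nrow(ivk)] |
        ivk$start[-1L] != ivk$end[-nrow(ivk)])
      run <- cumsum(new_run)
      merged <- ivk |>
        group_by(run = run) |>
        summarise(start = min(.data$start), end = max(.data$end),
                  value = .data$value[[1L]], .groups = "drop")
      out <- c(out, sprintf("%s\t%d\t%d\t%s", m$seq_id, merged$start,
                            merged$end, fmt_num(merged$value)))
    }
  } else if (format == "wig") {
    out <- c(out, sprintf('track type=wiggle_0 name="%s"', m$name))
    if (any(keep)) {
      block <- cumsum(c(TRUE, diff(which(keep)) != 1L))
      ks <- split(which(keep), block)
      for (b in ks) {
        out <- c(out, sprintf("fixedStep chrom=%s start=%d step=%d span=%d",
                              m$seq_id, iv$start[b[[1]]] + 1L, m$step, m$step))
        out <- c(out, fmt_num(iv$value[b]))
      }
    }
  } else { # bed
    ivk <- iv[keep, , drop = FALSE]
    if (nrow(ivk)) {
      out <- c(out, sprintf("%s\t%d\t%d\t%s_%d\t%d\t.", m$seq_id, ivk$start,
                            ivk$end, m$name, seq_len(nrow(ivk)),
                            as.integer(round(ivk$value))))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Re-read a track written by [write_track()]
#'
#' Reconstructs the track (including `NaN` gaps) from the data lines and the
#' `# key=value` metadata comments.
#'
#' @inheritParams write_track
#' @return An `atlas_track`.
#' @export
read_track <- function(path, format = c("bedgraph", "wig", "bed")) {
  format <- rlang::arg_match(format)
  lines <- readLines(path, warn = FALSE)
  meta <- parse_header_comments(lines)
  window <- as.integer(meta$window)
  step <- as.integer(meta$step)
  seq_length <- as.integer(meta$seq_length)
  n_values <- if (!is.na(seq_length) && !is.na(window) && window <= seq_length) {
    (seq_length - window) %/% step + 1L
  } else {
    NA_integer_
  }
  data <- lines[!grepl("^#", lines) & !grepl("^track ", lines) & nzchar(lines)]
  fill <- function(idx, vals, n) {
    n <- if (is.na(n)) max(idx) else n
    v <- rep(NaN, n)
    v[idx] <- vals
    v
  }
  if (format == "bedgraph") {
    f <- strsplit(data, "\t", fixed = TRUE)
    starts <- as.integer(vapply(f, `[[`, character(1), 2L))
    ends <- as.integer(vapply(f, `[[`, character(1), 3L))
    vals <- as.numeric(vapply(f, `[[`, character(1), 4L))
    idx <- integer(0); vv <- numeric(0)
    for (i in seq_along(starts)) {
      ii <- seq.int(starts[[i]] %/% step, (ends[[i]] - 1L) %/% step) + 1L
      idx <- c(idx, ii); vv <- c(vv, rep(vals[[i]], length(ii)))
    }
    values <- fill(idx, vv, n_values)
  } else if (format == "wig") {
    idx <- integer(0); vv <- numeric(0)
    cur <- NA_integer_
    for (ln in data) {
      if (grepl("^fixedStep", ln)) {
        cur <- (as.integer(sub(".*start=(\\d+).*", "\\1", ln)) - 1L) %/% step + 1L
      } else {
        idx <- c(idx, cur); vv <- c(vv, as.numeric(ln)); cur <- cur + 1L
      }
    }
    values <- fill(idx, vv, n_values)
  } else {
    f <- strsplit(data, "\t", fixed = TRUE)
    starts <- as.integer(vapply(f, `[[`, character(1), 2L))
    vals <- as.numeric(vapply(f, `[[`, character(1), 5L))
    values <- fill(starts %/% step + 1L, vals, n_values)
  }
  new_track(values, meta$name, window, step, units = meta$units %||% "",
            seq_id = meta$seq_id %||% "seq", seq_length = seq_length)
}
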