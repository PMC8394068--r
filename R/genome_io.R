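## Annotated-genome input and LUR extraction. Internal coordinates are
## 0-based half-open; on circular records an interval with end > length
## wraps the origin. Written reports are 1-based inclusive.

feature_kinds <- c("protein_coding", "rRNA", "tRNA", "orf_uncertain", "other")

new_genome_record <- function(id, sequence, circular, features,
                              mitotype = "unknown") {
  stopifnot(nchar(sequence) > 0L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    stopifnot(all(features$kind %in% feature_kinds),
              all(features$start >= 0L),
              all(features$start < nchar(sequence)),
              all(features$end > features$start))
  }
  structure(list(id = id, sequence = toupper(sequence),
                 circular = isTRUE(circular), features = features,
                 mitotype = mitotype),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %s, %d features, mitotype %s\n",
              x$id, nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              nrow(x$features), x$mitotype))
  invisible(x)
}

empty_features <- function() {
  data.frame(kind = character(), name = character(), strand = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

## Map a GenBank feature key to the internal classification. CDS (oxidative
## phosphorylation and ORF proteins) and rRNA bound LURs; everything else,
## including misc_feature (e.g. an F-ORF annotated as a miscellaneous
## feature), does not.
classify_feature_key <- function(key) {
  switch(key,
         CDS = "protein_coding",
         rRNA = "rRNA",
         tRNA = "tRNA",
         "other")
}

infer_mitotype <- function(definition) {
  d <- tolower(definition)
  if (grepl("recently masculini[sz]ed|\\brm[- ]type", d)) return("RM")
  if (grepl("hermaphrodit", d)) return("H")
  if (grepl("\\bm[- ]type|male[- ]t(ype|ransmitted)|\\bmale\\b", d)) return("M")
  if (grepl("\\bf[- ]type|female[- ]t(ype|ransmitted)|\\bfemale\\b", d)) return("F")
  "unknown"
}

parse_gb_location <- function(loc, n) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    coords <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    first <- coords[[1]]; last <- coords[[length(coords)]]
    if (length(coords) == 2L && first[2] == n && last[1] == 1L) {
      # origin-spanning join on a circular record
      return(list(start = first[1] - 1L, end = n + last[2], strand = strand))
    }
    return(list(start = min(vapply(coords, min, integer(1))) - 1L,
                end = max(vapply(coords, max, integer(1))), strand = strand))
  }
  ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  if (length(ab) == 1L) ab <- c(ab, ab)
  list(start = ab[1] - 1L, end = ab[2], strand = strand)
}

#' Read a GenBank flat file
#'
#' Minimal reader for single-record GenBank flat files as produced by
#' [write_genbank()] and by standard annotation pipelines: LOCUS (length and
#' circular/linear topology), DEFINITION, FEATURES (key, location including
#' `complement()` and origin-spanning `join()`, `/gene` or `/product`
#' qualifiers) and ORIGIN sequence. Feature keys are classified as
#' `protein_coding` (CDS), `rRNA`, `tRNA` or `other`; an optional override
#' table reclassifies features (e.g. to `orf_uncertain` for inconsistently
#' annotated DUI ORFs, which then never bound LURs).
#'
#' @param path Path to a GenBank flat file.
#' @param overrides Optional data frame with columns `feature_index`
#'   (1-based, in file order) and `new_kind`.
#' @return A `genome_record`.
#' @export
read_genbank <- function(path, overrides = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(tolower(toks) == "circular")
  def_i <- grep("^DEFINITION", lines)
  definition <- if (length(def_i)) sub("^DEFINITION\\s+", "", lines[def_i[1]]) else ""

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank record ", id, " has no ORIGIN sequence")
  seq_lines <- lines[(ori[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record ", id, " has an empty sequence")
  n <- nchar(sequence)

  feats <- empty_features()
  fi <- grep("^FEATURES", lines)
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(ori[1] - 1L)]
    # a feature line has a key at column 6 and a location at column 22
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    rows <- list()
    for (j in seq_along(idx)) {
      ln <- block[idx[j]]
      key <- sub("^ {5}(\\S+).*$", "\\1", ln)
      loc <- trimws(sub("^ {5}\\S+\\s+", "", ln))
      # locations may continue on the following (qualifier-indented) lines
      nxt <- idx[j] + 1L
      while (nxt <= length(block) && grepl("^ {21}[^/]", block[nxt])) {
        loc <- paste0(loc, trimws(block[nxt]))
        nxt <- nxt + 1L
      }
      if (key == "source") next
      qual_end <- if (j < length(idx)) idx[j + 1L] - 1L else length(block)
      quals <- block[nxt:max(nxt, qual_end)]
      name <- NA_character_
      gm <- grep("/(gene|product)=", quals, value = TRUE)
      if (length(gm)) name <- gsub("^.*=\"?|\"$", "", gm[1])
      pl <- parse_gb_location(loc, n)
      if (pl$end > n && !circular) {
        stop("record ", id, ": feature wraps the origin of a linear sequence")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        kind = classify_feature_key(key), name = name, strand = pl$strand,
        start = pl$start, end = pl$end, stringsAsFactors = FALSE)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  if (!is.null(overrides) && nrow(feats)) {
    stopifnot(all(c("feature_index", "new_kind") %in% names(overrides)),
              all(overrides$new_kind %in% feature_kinds))
    feats$kind[overrides$feature_index] <- overrides$new_kind
  }
  new_genome_record(id, sequence, circular, feats,
                    mitotype = infer_mitotype(definition))
}

#' Read a genome with annotations
#'
#' Either a GenBank flat file, or a FASTA file accompanied by a feature
#' table (TSV with columns `kind`, `name`, `strand`, `start`, `end`;
#' 1-based inclusive coordinates, `end < start` denoting an origin wrap on
#' circular records).
#'
#' @param path Sequence file.
#' @param format `"genbank"` or `"fasta"`.
#' @param annotation Path to the feature TSV (required for FASTA input).
#' @param circular Topology flag for FASTA input.
#' @param overrides Optional reclassification table, see [read_genbank()].
#' @return A `genome_record`.
#' @export
read_genome <- function(path, format = c("genbank", "fasta"),
                        annotation = NULL, circular = TRUE, overrides = NULL) {
  format <- match.arg(format)
  if (format == "genbank") return(read_genbank(path, overrides = overrides))
  if (is.null(annotation)) stop("FASTA input requires an `annotation` table")
  dna <- Biostrings::readDNAStringSet(path)
  if (length(dna) == 0L) stop("no sequences in FASTA file: ", path)
  seq <- as.character(dna[[1]])
  n <- nchar(seq)
  tab <- read.delim(annotation, stringsAsFactors = FALSE)
  stopifnot(all(c("kind", "start", "end") %in% names(tab)))
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  if (!"name" %in% names(tab)) tab$name <- NA_character_
  start <- tab$start - 1L
  end <- ifelse(tab$end >= tab$start, tab$end, tab$end + n)
  feats <- data.frame(kind = tab$kind, name = tab$name, strand = tab$strand,
                      start = as.integer(start), end = as.integer(end),
                      stringsAsFactors = FALSE)
  if (!is.null(overrides) && nrow(feats)) {
    feats$kind[overrides$feature_index] <- overrides$new_kind
  }
  new_genome_record(sub("\\s.*$", "", names(dna)[1]), seq, circular, feats)
}

## 0/1 coverage of the genome circle by the given features.
feature_coverage <- function(genome, kinds) {
  n <- nchar(genome$sequence)
  cov <- logical(n)
  f <- genome$features
  f <- f[f$kind %in% kinds, , drop = FALSE]
  for (i in seq_len(nrow(f))) {
    pos <- seq.int(f$start[i], f$end[i] - 1L) %% n
    cov[pos + 1L] <- TRUE
  }
  cov
}

#' Extract large unassigned regions (LURs)
#'
#' Returns every maximal stretch of the genome not covered by a
#' protein-coding or rRNA feature. tRNAs, `orf_uncertain` and `other`
#' features neither break nor mask an interval, so a gap containing tRNAs
#' is one contiguous LUR. On circular genomes the interval may wrap the
#' origin (then `end > genome length`). Intervals shorter than `min_length`
#' are dropped, except that the single longest interval is always reported.
#'
#' @param genome A `genome_record` with at least one protein-coding or rRNA
#'   feature.
#' @param min_length Minimum reported length in bp (default 100).
#' @return Data frame sorted by decreasing length: `genome_id`, 0-based
#'   half-open `start`/`end`, `length`, base frequencies `piT..piA`
#'   (ambiguous bases excluded) and the forward-strand `sequence`.
#' @export
extract_lurs <- function(genome, min_length = 100L) {
  stopifnot(inherits(genome, "genome_record"))
  cov <- feature_coverage(genome, c("protein_coding", "rRNA"))
  if (!any(cov)) {
    stop("cannot define LURs: genome ", genome$id,
         " has no protein-coding or rRNA boundary features")
  }
  n <- length(cov)
  free <- which(!cov)
  if (length(free) == 0L) {
    return(data.frame(genome_id = character(), start = integer(),
                      end = integer(), length = integer(),
                      piT = numeric(), piC = numeric(), piG = numeric(),
                      piA = numeric(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  # runs of uncovered positions, 0-based half-open
  brk <- which(diff(free) > 1L)
  runs <- data.frame(start = free[c(1L, brk + 1L)] - 1L,
                     end = free[c(brk, length(free))])
  # circular: a run ending at the origin joins the one starting at 0
  if (genome$circular && nrow(runs) > 1L &&
      runs$start[1] == 0L && runs$end[nrow(runs)] == n) {
    runs$end[nrow(runs)] <- n + runs$end[1]
    runs <- runs[-1, , drop = FALSE]
  }
  runs$length <- runs$end - runs$start
  keep <- runs$length >= min_length
  keep[which.max(runs$length)] <- TRUE
  runs <- runs[keep, , drop = FALSE]
  runs <- runs[order(-runs$length, runs$start), , drop = FALSE]
  seqs <- vapply(seq_len(nrow(runs)), function(i) {
    extract_region(genome, runs$start[i], runs$end[i])
  }, character(1))
  freqs <- t(vapply(seqs, base_frequencies, numeric(4)))
  out <- data.frame(genome_id = genome$id, start = runs$start, end = runs$end,
                    length = runs$length,
                    piT = freqs[, 1], piC = freqs[, 2],
                    piG = freqs[, 3], piA = freqs[, 4],
                    sequence = seqs, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

#' Write LUR tables and FASTA
#'
#' The summary TSV reports 1-based inclusive coordinates; FASTA headers are
#' `genome_id|start-end|strand`.
#'
#' @param lurs Data frame from [extract_lurs()].
#' @param tsv,fasta Output paths (either may be `NULL`).
#' @return Invisibly, the LUR table.
#' @export
write_lurs <- function(lurs, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    out <- data.frame(genome_id = lurs$genome_id, start = lurs$start + 1L,
                      end = lurs$end, length = lurs$length,
                      piT = round(lurs$piT, 3), piC = round(lurs$piC, 3),
                      piG = round(lurs$piG, 3), piA = round(lurs$piA, 3))
    write.table(out, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(fasta)) {
    headers <- sprintf("%s|%d-%d|+", lurs$genome_id, lurs$start + 1L, lurs$end)
    writeLines(paste0(">", headers, "\n", lurs$sequence), fasta)
  }
  invisible(lurs)
}
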