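## End-to-end orchestration: genomes -> LURs -> LUR scan -> conditional
## genome-wide rescan -> similarity/flank report, with deterministic TSV
## outputs and a run manifest.

#' Annotate hits with their genomic context
#'
#' Labels each hit `in_LUR` when it overlaps a LUR interval, otherwise
#' `in_feature:<name-or-kind>` for the feature with the largest overlap
#' (suffixed `,antisense` when hit and feature strands differ), otherwise
#' `intergenic`. Overlap is computed on the circle for circular records.
#'
#' @param genome A `genome_record`.
#' @param hits Hit data frame from [scan_genome()] (genome coordinates).
#' @param lurs Optional LUR table from [extract_lurs()]; extracted on the
#'   fly when `NULL` and the genome has boundary features.
#' @return `hits` with a `context` column.
#' @export
annotate_hits <- function(genome, hits, lurs = NULL) {
  n <- nchar(genome$sequence)
  if (is.null(lurs)) {
    lurs <- tryCatch(extract_lurs(genome), error = function(e) NULL)
  }
  circle_pos <- function(start, end) seq.int(start, end - 1L) %% n
  in_lur <- function(s, e) {
    if (is.null(lurs) || nrow(lurs) == 0L) return(FALSE)
    hp <- circle_pos(s, e)
    any(vapply(seq_len(nrow(lurs)), function(i) {
      any(hp %in% circle_pos(lurs$start[i], lurs$end[i]))
    }, logical(1)))
  }
  context <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (in_lur(s, e)) {
      context[i] <- "in_LUR"
      next
    }
    f <- genome$features
    overlaps <- vapply(seq_len(nrow(f)), function(j) {
      length(intersect(circle_pos(s, e), circle_pos(f$start[j], f$end[j])))
    }, integer(1))
    if (length(overlaps) && any(overlaps > 0L)) {
      j <- which.max(overlaps)
      lab <- if (!is.na(f$name[j])) f$name[j] else f$kind[j]
      anti <- if (f$strand[j] != hits$strand[i]) ",antisense" else ""
      context[i] <- paste0("in_feature:", lab, anti)
    } else {
      context[i] <- "intergenic"
    }
  }
  hits$context <- context
  hits
}

#' Run the full STE screening pipeline
#'
#' For each genome: extract LURs, scan them for the motif; any genome with
#' at least one LUR hit is re-screened across its entire circular sequence
#' (the two-pass rule), and LUR hits get a similarity/flank report. Genomes
#' without boundary features are skipped with a warning and listed in the
#' manifest. Outputs, when `out_dir` is given, are plain TSVs with 1-based
#' coordinates; re-running with the same inputs is byte-identical (all
#' stages deterministic).
#'
#' @param genomes List of `genome_record` objects and/or GenBank file paths.
#' @param motif An [ste_motif()].
#' @param scheme A [scoring_scheme()].
#' @param min_lur_length Minimum LUR length passed to [extract_lurs()].
#' @param strand_mode Strand mode for the LUR scan.
#' @param out_dir Optional output directory (created if needed).
#' @return A manifest list: parameters, per-genome LUR/hit counts, the
#'   combined `lurs`, `lur_hits`, `genome_hits` and `similarity` tables,
#'   skipped genome ids, and md5 checksums of written files.
#' @export
run_pipeline <- function(genomes, motif = ste_motif(),
                         scheme = scoring_scheme(), min_lur_length = 100L,
                         strand_mode = "both", out_dir = NULL) {
  if (length(genomes) == 0L) stop("no genomes supplied")
  genomes <- lapply(genomes, function(g) {
    if (inherits(g, "genome_record")) g else read_genbank(g)
  })
  lur_tabs <- list(); lur_hit_tabs <- list(); genome_hit_tabs <- list()
  sim_tabs <- list(); skipped <- character(0); rescreened <- character(0)
  for (g in genomes) {
    lurs <- tryCatch(extract_lurs(g, min_length = min_lur_length),
                     error = function(e) {
                       warning("skipping ", g$id, ": ", conditionMessage(e))
                       NULL
                     })
    if (is.null(lurs)) {
      skipped <- c(skipped, g$id)
      next
    }
    lur_tabs[[g$id]] <- lurs
    hits <- do.call(rbind, lapply(seq_len(nrow(lurs)), function(i) {
      h <- scan_sequence(lurs$sequence[i], motif, scheme,
                         strand_mode = strand_mode, target_id = g$id)
      if (nrow(h)) {
        # lift LUR-local coordinates to genome coordinates
        h$lur_start <- lurs$start[i]
        h$start <- h$start + lurs$start[i]
        h$end <- h$end + lurs$start[i]
      }
      h
    }))
    if (!is.null(hits) && nrow(hits)) {
      lur_hit_tabs[[g$id]] <- hits
      sim_tabs[[g$id]] <- do.call(rbind, lapply(seq_len(nrow(lurs)), function(i) {
        local_hits <- scan_sequence(lurs$sequence[i], motif, scheme,
                                    strand_mode = strand_mode,
                                    target_id = g$id)
        if (nrow(local_hits) == 0L) return(NULL)
        similarity_report(lurs$sequence[i], local_hits, motif)
      }))
      # two-pass rule: a LUR hit triggers a whole-genome rescan
      rescreened <- c(rescreened, g$id)
      genome_hit_tabs[[g$id]] <- scan_genome(g, motif, scheme, lurs = lurs)
    }
  }
  bind <- function(tabs) if (length(tabs)) do.call(rbind, unname(tabs)) else NULL
  manifest <- list(
    parameters = list(motif = motif$sequence, match = scheme$match,
                      mismatch = scheme$mismatch, ts = scheme$ts,
                      min_lur_length = min_lur_length,
                      strand_mode = strand_mode),
    n_genomes = length(genomes),
    skipped = skipped,
    rescreened = rescreened,
    lurs = bind(lur_tabs),
    lur_hits = bind(lur_hit_tabs),
    genome_hits = bind(genome_hit_tabs),
    similarity = bind(sim_tabs)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(lurs = "lurs.tsv", lur_hits = "lur_hits.tsv",
               genome_hits = "genome_hits.tsv", similarity = "similarity.tsv")
    for (key in names(files)) {
      tab <- manifest[[key]]
      if (is.null(tab)) next
      out <- tab
      if ("start" %in% names(out)) out$start <- out$start + 1L  # 1-based
      if ("sequence" %in% names(out)) out$sequence <- NULL
      write.table(out, file.path(out_dir, files[[key]]), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    written <- file.path(out_dir, files[names(files) %in%
                                         names(Filter(Negate(is.null), manifest[names(files)]))])
    manifest$checksums <- tools::md5sum(written[file.exists(written)])
  }
  manifest
}
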