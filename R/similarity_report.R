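## Similarity of candidate motifs to the query and inspection of the 30 bp
## upstream flank (adenine content), the descriptive companions to the scan.

#' Ungapped percent identity between equal-length strings
#'
#' @param a,b Nucleotide strings of equal length; ambiguous bases never
#'   match.
#' @return Percent identity `100 * matches / length`.
#' @examples
#' ungapped_identity("CCAT", "CCAA")
#' @export
ungapped_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    stop("ungapped identity needs equal lengths (", nchar(a), " vs ",
         nchar(b), ")")
  }
  ca <- dna_codes(a)
  cb <- dna_codes(b)
  eq <- ca == cb
  100 * sum(!is.na(eq) & eq) / nchar(a)
}

#' Global pairwise similarity with gaps
#'
#' Needleman-Wunsch global alignment under the scan's match/mismatch scores
#' and affine gap penalties; similarity is reported over the full alignment
#' length, so gap columns count against it (a 24-column alignment with 15
#' matches scores 62.5%).
#'
#' @param a,b Non-empty nucleotide strings.
#' @param match,mismatch Substitution scores (defaults +5/-4).
#' @param gap_open,gap_extend Gap penalties as positive costs (defaults
#'   10 and 0.5).
#' @return List with `aligned_length` (columns incl. gaps), `matches`,
#'   `pct = 100 * matches / aligned_length`, the alignment `score` and the
#'   two aligned strings.
#' @export
gapped_similarity <- function(a, b, match = 5, mismatch = -4,
                              gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  letters4 <- c("A", "C", "G", "T", "N")
  mat <- matrix(mismatch, 5, 5, dimnames = list(letters4, letters4))
  diag(mat) <- match
  mat["N", ] <- mismatch
  mat[, "N"] <- mismatch          # no ambiguous matches, N vs N included
  aln <- Biostrings::pairwiseAlignment(
    toupper(a), toupper(b), type = "global", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1]]
  cb <- strsplit(pb, "")[[1]]
  matches <- sum(ca == cb & ca %in% c("A", "C", "G", "T"))
  list(aligned_length = length(ca), matches = matches,
       pct = 100 * matches / length(ca),
       score = Biostrings::score(aln), aligned_a = pa, aligned_b = pb)
}

#' Retrieve and summarise the upstream flank of a hit
#'
#' Takes up to `flank` bp 5' of the hit on the hit's strand (for a minus
#' strand hit: downstream on the forward axis, reverse-complemented) and
#' reports adenine statistics. The flank is truncated at the sequence
#' boundary on linear regions and wraps on circular ones.
#'
#' @param region Nucleotide string containing the hit.
#' @param hit One-row hit data frame (fields `start`, `end`, `strand`) with
#'   coordinates relative to `region`.
#' @param flank Flank length in bp (default 30).
#' @param circular Wrap around the region boundary?
#' @return List with `flank30` (string, possibly shorter than `flank`),
#'   `flank_A_fraction` (0 with `truncated = TRUE` flag when empty),
#'   `flank_longest_A_run` and `truncated`.
#' @export
upstream_flank <- function(region, hit, flank = 30L, circular = FALSE) {
  n <- nchar(region)
  start <- hit$start[1]
  end <- hit$end[1]
  strand <- hit$strand[1]
  stopifnot(start >= 0, start < end)
  if (strand == "+") {
    from <- start - flank
    if (circular) {
      idx <- (seq.int(from, start - 1L) %% n)
      fl <- paste(strsplit(region, "")[[1]][idx + 1L], collapse = "")
    } else {
      fl <- if (start == 0L) "" else substr(region, max(1L, from + 1L), start)
    }
  } else {
    to <- end + flank
    if (circular) {
      idx <- (seq.int(end, to - 1L) %% n)
      fl <- paste(strsplit(region, "")[[1]][idx + 1L], collapse = "")
    } else {
      fl <- if (end >= n) "" else substr(region, end + 1L, min(n, to))
    }
    fl <- reverse_complement(fl)
  }
  truncated <- nchar(fl) < flank
  if (nchar(fl) == 0L) {
    return(list(flank30 = "", flank_A_fraction = 0,
                flank_longest_A_run = 0L, truncated = TRUE))
  }
  is_a <- strsplit(fl, "")[[1]] == "A"
  runs <- rle(is_a)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  list(flank30 = fl, flank_A_fraction = mean(is_a),
       flank_longest_A_run = as.integer(longest), truncated = truncated)
}

#' Similarity and flank report for a set of hits
#'
#' For each hit in a region: ungapped identity of the hit window to the
#' motif, gapped global similarity, and the 30 bp upstream flank with
#' adenine statistics.
#'
#' @param region Nucleotide string the hits were found in.
#' @param hits Hit data frame from [scan_sequence()] (coordinates relative
#'   to `region`).
#' @param motif An [ste_motif()].
#' @param circular Wrap flanks around the region boundary?
#' @return Data frame with one row per hit.
#' @export
similarity_report <- function(region, hits, motif = ste_motif(),
                              circular = FALSE) {
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, , drop = FALSE]
    win <- extract_region(region, h$start, h$end, strand = h$strand,
                          circular = circular)
    gs <- gapped_similarity(win, motif$sequence)
    fl <- upstream_flank(region, h, circular = circular)
    data.frame(
      target_id = h$target_id, start = h$start, end = h$end,
      strand = h$strand,
      pct_ungapped = round(ungapped_identity(win, motif$sequence), 1),
      aligned_length = gs$aligned_length, matches = gs$matches,
      pct_gapped = round(gs$pct, 1),
      flank30 = fl$flank30, flank_A_fraction = round(fl$flank_A_fraction, 3),
      flank_longest_A_run = fl$flank_longest_A_run,
      flank_truncated = fl$truncated,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(target_id = character(), start = integer(), end = integer(),
               strand = character(), pct_ungapped = numeric(),
               aligned_length = integer(), matches = integer(),
               pct_gapped = numeric(), flank30 = character(),
               flank_A_fraction = numeric(), flank_longest_A_run = integer(),
               flank_truncated = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
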