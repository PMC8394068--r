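## The calibrated sliding-window scan: score every motif-length window of a
## target with an exact match/mismatch scheme, accept windows at or above the
## threshold Ts, and merge overlapping accepted windows into hits.

#' Construct a query motif
#'
#' The default is the functionally characterised 22 bp sperm transmission
#' element from the *Mytilus galloprovincialis* recently-masculinized
#' control region. The window length `W` of every scan equals the motif
#' length.
#'
#' @param sequence Motif nucleotide string over `A, C, G, T`.
#' @param name Display name.
#' @return An object of class `ste_motif` with fields `name`, `sequence`,
#'   `W` and the precomputed integer base codes.
#' @examples
#' ste_motif()
#' @export
ste_motif <- function(sequence = STE_MGALLO, name = "STE-Mgallo") {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L || grepl("[^ACGT]", sequence)) {
    stop("motif must be a non-empty string over A, C, G, T")
  }
  structure(
    list(name = name, sequence = sequence, W = nchar(sequence),
         codes = dna_codes(sequence)),
    class = "ste_motif"
  )
}

#' @export
print.ste_motif <- function(x, ...) {
  cat("<ste_motif>", x$name, ":", x$sequence, sprintf("(W = %d)\n", x$W))
  invisible(x)
}

#' Construct a window scoring scheme
#'
#' Exact scoring with no ambiguous matches: each identical unambiguous base
#' contributes `match`, every other column `mismatch`. The acceptance
#' threshold `ts` is the calibrated value at which a window is reported; the
#' default `ts = 56` with `(+5, -4)` scoring accepts 22 bp windows with at
#' least 16/22 identities.
#'
#' @param match Positive match score (default +5).
#' @param mismatch Negative mismatch score (default -4).
#' @param ts Acceptance threshold on the window score.
#' @return An object of class `ste_scoring`.
#' @export
scoring_scheme <- function(match = 5L, mismatch = -4L, ts = 56L) {
  if (!(match > 0 && mismatch < 0)) stop("need match > 0 > mismatch")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 ts = as.numeric(ts)),
            class = "ste_scoring")
}

#' Score one window against the motif
#'
#' @param window A string of exactly `motif$W` bases.
#' @param motif An [ste_motif()].
#' @param scheme A [scoring_scheme()].
#' @return List with `m` (identity count; ambiguous bases never match) and
#'   `S = m * match + (W - m) * mismatch`.
#' @examples
#' m <- ste_motif()
#' window_score(m$sequence, m, scoring_scheme())
#' @export
window_score <- function(window, motif, scheme = scoring_scheme()) {
  if (nchar(window) != motif$W) {
    stop("window length ", nchar(window), " != motif length ", motif$W)
  }
  codes <- dna_codes(window)
  eq <- codes == motif$codes
  m <- sum(!is.na(eq) & eq)
  list(m = m, S = m * scheme$match + (motif$W - m) * scheme$mismatch)
}

#' Minimum identities needed to reach a percent similarity
#'
#' Smallest integer `k` with `100 * k / W >= pct - 0.05`; the 0.05 tolerance
#' absorbs one-decimal rounding of reported percentages (e.g. 72.7% of a
#' 22 bp window maps to 16 identities).
#'
#' @param pct Percent similarity in `[0, 100]`.
#' @param W Window length.
#' @return Integer identity threshold `k`.
#' @examples
#' min_matches_for_percent(72.7, 22)
#' @export
min_matches_for_percent <- function(pct, W = 22L) {
  stopifnot(pct >= 0, pct <= 100)
  k <- ceiling((pct - 0.05) * W / 100)
  as.integer(max(0L, min(W, k)))
}

## Identity threshold implied by a score threshold: smallest m with
## m*match + (W-m)*mismatch >= ts.
min_identities_for_score <- function(scheme, W) {
  k <- ceiling((scheme$ts - W * scheme$mismatch) / (scheme$match - scheme$mismatch))
  as.integer(max(0L, k))
}

hit_frame <- function(target_id = character(), start = integer(),
                      strand = character(), m = integer(), W = integer(),
                      scheme = NULL) {
  score <- if (length(m)) m * scheme$match + (W - m) * scheme$mismatch else numeric()
  data.frame(
    target_id = target_id,
    start = as.integer(start),
    end = as.integer(start) + as.integer(W),
    strand = strand,
    m = as.integer(m),
    score = score,
    pct = if (length(m)) round(100 * m / W, 1) else numeric(),
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence for motif windows at or above the threshold
#'
#' Slides a window of the motif length along the target and reports every
#' window whose score reaches `scheme$ts`. The minus strand is scanned on the
#' reverse complement and coordinates are mapped back to the forward axis.
#' Overlapping accepted windows are merged into distinct hits by
#' [merge_hits()] unless `merge = FALSE`.
#'
#' @param target Target nucleotide string.
#' @param motif An [ste_motif()].
#' @param scheme A [scoring_scheme()].
#' @param strand_mode `"both"` (default) or `"forward"`.
#' @param target_id Identifier used in the result.
#' @param merge Merge overlapping same-strand windows (default `TRUE`).
#' @return Data frame of hits with 0-based half-open `start`/`end` on the
#'   forward axis, `strand`, identity count `m`, `score` and percent
#'   identity `pct`.
#' @export
scan_sequence <- function(target, motif, scheme = scoring_scheme(),
                          strand_mode = c("both", "forward"),
                          target_id = "target", merge = TRUE) {
  strand_mode <- match.arg(strand_mode)
  W <- motif$W
  k <- min_identities_for_score(scheme, W)
  n <- nchar(target)
  scan_one <- function(seq, strand) {
    counts <- window_identity_counts(dna_codes(seq), motif$codes)
    acc <- which(counts >= k)
    if (length(acc) == 0L) return(hit_frame(scheme = scheme))
    start <- acc - 1L
    if (strand == "-") start <- n - start - W
    hit_frame(rep(target_id, length(acc)), start, rep(strand, length(acc)),
              counts[acc], W, scheme)
  }
  out <- scan_one(target, "+")
  if (strand_mode == "both") {
    out <- rbind(out, scan_one(reverse_complement(target), "-"))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (merge) merge_hits(out) else out
}

#' Merge overlapping accepted windows into distinct hits
#'
#' Runs of mutually overlapping windows on the same strand collapse to a
#' single hit represented by the maximum-score window (ties broken to the
#' leftmost). Non-overlapping windows remain distinct, so the hit count is
#' the number of separate motif copies.
#'
#' @param hits Data frame of raw windows from [scan_sequence()].
#' @return Data frame with one row per merged hit.
#' @export
merge_hits <- function(hits) {
  if (nrow(hits) <= 1L) return(hits)
  parts <- split(hits, list(hits$target_id, hits$strand), drop = TRUE)
  merged <- lapply(parts, function(h) {
    h <- h[order(h$start), , drop = FALSE]
    # new cluster whenever a window starts at/after the running interval end
    cluster <- cumsum(c(1L, as.integer(h$start[-1] >= cummax(h$end[-nrow(h)]))))
    do.call(rbind, lapply(split(h, cluster), function(g) {
      g[which.max(g$score), , drop = FALSE]   # which.max: leftmost on ties
    }))
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$target_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan an entire (possibly circular) genome on both strands
#'
#' On circular records the first `W - 1` bases are appended so windows
#' spanning the origin are scored; such hits keep a wrapped interval
#' (`end > genome length`). Each hit is annotated with its genomic context
#' (inside which feature, inside a LUR, or intergenic) via [annotate_hits()].
#'
#' @param genome A `genome_record`.
#' @param motif An [ste_motif()].
#' @param scheme A [scoring_scheme()].
#' @param lurs Optional LUR table from [extract_lurs()] used for context
#'   labels; extracted on the fly when `NULL` and the genome has boundary
#'   features.
#' @return Data frame of merged hits with a `context` column.
#' @export
scan_genome <- function(genome, motif, scheme = scoring_scheme(), lurs = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  n <- nchar(genome$sequence)
  W <- motif$W
  target <- genome$sequence
  if (genome$circular && n >= W) {
    target <- paste0(target, substr(genome$sequence, 1L, W - 1L))
  }
  n_ext <- nchar(target)
  k <- min_identities_for_score(scheme, W)
  scan_one <- function(seq, strand) {
    counts <- window_identity_counts(dna_codes(seq), motif$codes)
    acc <- which(counts >= k)
    if (length(acc) == 0L) return(hit_frame(scheme = scheme))
    start <- acc - 1L
    if (strand == "-") start <- n_ext - start - W
    hit_frame(rep(genome$id, length(acc)), start, rep(strand, length(acc)),
              counts[acc], W, scheme)
  }
  hits <- rbind(scan_one(target, "+"), scan_one(reverse_complement(target), "-"))
  # windows are enumerated once per forward-axis start in [0, n)
  hits <- hits[hits$start < n, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits <- merge_hits(hits)
  annotate_hits(genome, hits, lurs = lurs)
}

#' Calibrate the acceptance threshold from labeled references
#'
#' Evaluates the merged-hit count of every reference sequence at every
#' integer threshold `T` from `W * mismatch` to `W * match` and returns the
#' largest `T` at which each reference yields exactly its expected hit count
#' (the conservative choice: the highest stringency still detecting all
#' known copies). The full threshold-to-count table (the calibration curve)
#' is returned alongside.
#'
#' @param motif An [ste_motif()].
#' @param references List of `list(sequence =, expected =)` entries: a
#'   sequence with a known number of true motif copies.
#' @param match,mismatch Scoring values.
#' @param strand_mode Passed to [scan_sequence()].
#' @return List with `ts` (selected threshold) and `curve` (data frame of
#'   per-reference merged-hit counts at every threshold).
#' @export
calibrate_threshold <- function(motif, references, match = 5L, mismatch = -4L,
                                strand_mode = "both") {
  if (length(references) < 1L) stop("need at least one reference")
  W <- motif$W
  ts_grid <- seq.int(W * mismatch, W * match)
  counts <- vapply(seq_along(references), function(i) {
    ref <- references[[i]]
    # counting at threshold T only depends on the implied identity cutoff;
    # compute merged counts once per k and index into them
    per_k <- vapply(0:W, function(k) {
      sch <- scoring_scheme(match, mismatch,
                            ts = k * match + (W - k) * mismatch)
      nrow(scan_sequence(ref$sequence, motif, sch, strand_mode = strand_mode,
                         merge = TRUE))
    }, integer(1))
    k_of_ts <- pmin(W, pmax(0L, ceiling((ts_grid - W * mismatch) / (match - mismatch))))
    per_k[k_of_ts + 1L]
  }, integer(length(ts_grid)))
  counts <- matrix(counts, nrow = length(ts_grid))
  expected <- vapply(references, `[[`, numeric(1), "expected")
  feasible <- apply(counts, 1L, function(row) all(row == expected))
  curve <- data.frame(ts = ts_grid, counts)
  names(curve)[-1] <- paste0("ref", seq_along(references))
  if (!any(feasible)) {
    ranges <- vapply(seq_along(references), function(i) {
      ok <- ts_grid[counts[, i] == expected[i]]
      if (length(ok) == 0L) "none" else paste0("[", min(ok), ", ", max(ok), "]")
    }, character(1))
    stop("no threshold satisfies all references; feasible ranges: ",
         paste(sprintf("ref%d %s", seq_along(ranges), ranges), collapse = "; "))
  }
  list(ts = max(ts_grid[feasible]), curve = curve)
}
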