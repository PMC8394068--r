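## Monte-Carlo significance of motif matches against composition-matched
## random sequence, with an exact Poisson-binomial analytic oracle. Under an
## i.i.d. base model the identity count of one window is a sum of W
## independent Bernoulli draws whose success probability at position i is
## the background frequency of the motif base at i.

#' Count qualifying windows in one sequence
#'
#' Number of window start positions whose ungapped identity count to the
#' motif (forward orientation, no merging) is at least `k`. Overlapping
#' qualifying windows are all counted, so a single tandem-like stretch can
#' contribute several matches.
#'
#' @param seq Target nucleotide string.
#' @param motif An [ste_motif()].
#' @param k Minimum identities per window, `0 <= k <= W`.
#' @return Integer count; 0 (with a warning) when the sequence is shorter
#'   than the window.
#' @export
count_qualifying_windows <- function(seq, motif, k) {
  stopifnot(k >= 0, k <= motif$W)
  if (nchar(seq) < motif$W) {
    warning("sequence shorter than the scan window; no windows to count")
    return(0L)
  }
  counts <- window_identity_counts(dna_codes(seq), motif$codes)
  sum(counts >= k)
}

#' Exact per-window match probability under the i.i.d. base model
#'
#' Probability that a single window of i.i.d. bases has at least `k`
#' identities to the motif. The identity count is Poisson-binomial with
#' per-position success probabilities equal to the background frequency of
#' the motif base at that position; the tail is computed by exact dynamic
#' programming over the `W` positions.
#'
#' @param motif An [ste_motif()].
#' @param freqs Base frequencies in `(T, C, G, A)` order.
#' @param k Minimum identities.
#' @return `P(identities >= k)`, exact to floating precision.
#' @examples
#' window_match_prob_exact(ste_motif(), rep(0.25, 4), 22)  # 0.25^22
#' @export
window_match_prob_exact <- function(motif, freqs, k) {
  freqs <- normalize_freqs(freqs)
  stopifnot(k >= 0, k <= motif$W)
  W <- motif$W
  p <- freqs[motif$codes]
  dp <- c(1, numeric(W))          # dp[j+1] = P(j identities so far)
  for (i in seq_len(W)) {
    dp <- dp * (1 - p[i]) + c(0, head(dp, -1L)) * p[i]
  }
  sum(dp[(k + 1L):(W + 1L)])
}

#' Expected total qualifying windows across replicates
#'
#' By linearity of expectation (exact despite window overlap):
#' `n_reps * (L - W + 1) * P(one window qualifies)`.
#'
#' @param L Replicate sequence length.
#' @param freqs Base frequencies `(T, C, G, A)`.
#' @param motif An [ste_motif()].
#' @param k Minimum identities per window.
#' @param n_reps Number of replicate sequences.
#' @return Expected total count of qualifying windows.
#' @export
expected_total_hits <- function(L, freqs, motif, k, n_reps = 1000L) {
  stopifnot(L >= motif$W)
  n_reps * (L - motif$W + 1L) * window_match_prob_exact(motif, freqs, k)
}

#' Monte-Carlo null test for motif matches in random sequence
#'
#' Generates `n_reps` random sequences of length `L` with the given base
#' composition, counts qualifying windows (at least `k` of `W` identities,
#' forward orientation) in each, and reports the total hit count, the number
#' of replicate sequences with at least one hit, and the pseudo p-value
#' (that proportion). A replicate-level seed stream derived from `seed`
#' makes the run reproducible. The exact analytic expectation of the total
#' is attached for cross-checking.
#'
#' @param L Replicate length in bp (`>= W`).
#' @param freqs Base frequencies `(T, C, G, A)`; ignored (forced to 0.25
#'   each) when `freq_mode = "uniform"`.
#' @param k Minimum identities per window.
#' @param motif An [ste_motif()].
#' @param n_reps Number of replicates (default 1000).
#' @param seed Master seed (mandatory).
#' @param freq_mode `"empirical"` (use `freqs`) or `"uniform"`.
#' @param alpha Significance level on the pseudo p-value (default 0.05,
#'   no multiple-testing correction).
#' @return An object of class `ste_null`: list with `total_hits`,
#'   `seqs_with_hit`, `pseudo_p`, `analytic_expected_total`, `significant`,
#'   the per-replicate `counts`, and the call parameters.
#' @export
mc_null_test <- function(L, freqs, k, motif = ste_motif(), n_reps = 1000L,
                         seed, freq_mode = c("empirical", "uniform"),
                         alpha = 0.05) {
  freq_mode <- match.arg(freq_mode)
  if (freq_mode == "uniform") freqs <- rep(0.25, 4)
  freqs <- normalize_freqs(freqs)
  stopifnot(L >= motif$W, k >= 0, k <= motif$W, n_reps >= 1)
  if (missing(seed)) stop("`seed` is mandatory for the null test")
  # replicate seeds drawn from a stream keyed by the master seed, so each
  # replicate is regenerable in isolation
  rep_seeds <- withr_seed(seed, sample.int(.Machine$integer.max, n_reps))
  W <- motif$W
  mc <- motif$codes
  counts <- vapply(rep_seeds, function(s) {
    codes <- withr_seed(s, sample.int(4L, L, replace = TRUE, prob = freqs))
    sum(window_identity_counts(codes, mc) >= k)
  }, integer(1))
  res <- list(
    total_hits = sum(counts),
    seqs_with_hit = sum(counts > 0L),
    pseudo_p = sum(counts > 0L) / n_reps,
    analytic_expected_total = expected_total_hits(L, freqs, motif, k, n_reps),
    significant = (sum(counts > 0L) / n_reps) <= alpha,
    counts = counts,
    L = L, freqs = freqs, k = k, n_reps = n_reps, seed = seed,
    freq_mode = freq_mode, alpha = alpha
  )
  class(res) <- "ste_null"
  res
}

#' @export
print.ste_null <- function(x, ...) {
  cat(sprintf(
    "<ste_null> L=%d, k=%d/%d, %s frequencies, %d replicates\n", x$L, x$k,
    nchar(STE_MGALLO), x$freq_mode, x$n_reps))
  cat(sprintf("  total hits: %d   seqs with >=1 hit: %d   pseudo p: %.3f%s\n",
              x$total_hits, x$seqs_with_hit, x$pseudo_p,
              if (x$significant) " *" else ""))
  cat(sprintf("  analytic expected total: %.4g\n", x$analytic_expected_total))
  invisible(x)
}

#' Reference LUR screening table
#'
#' The 19 published LURs in which STE-like signatures were reported, with
#' their map codes, strand basis of the frequencies, taxon, observed percent
#' similarity of the putative STE to the 22 bp query, LUR length and base
#' composition, plus the published randomization results (total hits,
#' replicates with >= 1 hit, and pseudo p) under both the empirical and the
#' uniform base composition, for cross-checking re-runs. The 77.3% entry is
#' screened at 17/22 identities (its motif is likely 23 bp; the 22 bp window
#' match was 17/22).
#'
#' @return Data frame with one row per LUR.
#' @export
ste_reference_lurs <- function() {
  cols <- c("map_code", "strand", "order", "taxon", "pct", "L",
            "piT", "piC", "piG", "piA",
            "ref_hits_emp", "ref_seqs_emp", "ref_p_emp",
            "ref_hits_uni", "ref_seqs_uni", "ref_p_uni")
  rows <- list(
    list("1",  "F", "Mytiloida", "Mytilus galloprovincialis RM", 72.7, 3590, .282, .158, .209, .350,  85,  81, 0.081, 14, 14, 0.014),
    list("6",  "F", "Mytiloida", "Mytilus galloprovincialis M",  77.3, 1529, .301, .152, .189, .358,   7,   7, 0.007,  0,  0, 0.000),
    list("C",  "F", "Mytiloida", "Mytilus galloprovincialis F",  72.7, 1225, .280, .146, .255, .319,  11,  11, 0.011,  3,  3, 0.003),
    list("9",  "F", "Mytiloida", "Mytilus trossulus RM",        100.0, 1070, .279, .153, .195, .373,   0,   0, 0.000,  0,  0, 0.000),
    list("12", "F", "Mytiloida", "Mytilus edulis M",             95.5,  993, .289, .157, .194, .359,   0,   0, 0.000,  0,  0, 0.000),
    list("D",  "F", "Mytiloida", "Mytilus edulis F",             72.7, 1226, .281, .143, .251, .325,  17,  17, 0.017,  4,  4, 0.004),
    list("14", "F", "Venerida",  "Sinonovacula constricta",      72.7, 1602, .331, .084, .247, .338,  36,  35, 0.035,  6,  6, 0.006),
    list("16", "F", "Venerida",  "Paphia textile",               72.7, 1986, .268, .119, .254, .359,  53,  51, 0.051,  9,  9, 0.009),
    list("17", "R", "Venerida",  "Coelomactra antiquata",        72.7, 1285, .314, .276, .133, .276,   7,   7, 0.007,  4,  4, 0.004),
    list("19", "F", "Venerida",  "Fulvia mutica",                72.7, 4368, .307, .123, .221, .349, 108, 106, 0.106,  9,  9, 0.009),
    list("21", "F", "Venerida",  "Meretrix lyrata",              72.7, 4620, .415, .058, .208, .319, 142, 137, 0.137, 12, 12, 0.012),
    list("23", "F", "Venerida",  "Limecola balthica",            81.8, 3968, .358, .106, .209, .327,   0,   0, 0.000,  0,  0, 0.000),
    list("A",  "F", "Venerida",  "Hippopus hippopus",            77.3, 3027, .334, .121, .257, .288,   4,   4, 0.004,  1,  1, 0.001),
    list("B",  "F", "Venerida",  "Arctica islandica",            72.7, 1497, .374, .102, .174, .350,  52,  52, 0.052,  6,  6, 0.006),
    list("24", "R", "Unionida",  "Leptodea leptodon",            72.7,  830, .375, .084, .265, .276,  16,  15, 0.015,  3,  3, 0.003),
    list("25", "R", "Unionida",  "Lampsilis siliquoidea",        72.7,  575, .348, .111, .238, .303,  10,  10, 0.010,  4,  4, 0.004),
    list("26", "R", "Unionida",  "Toxolasma parvus",             72.7,  647, .320, .108, .258, .314,  13,  13, 0.013,  0,  0, 0.000),
    list("27", "R", "Unionida",  "Pyganodon grandis",            72.7,  575, .337, .117, .198, .348,   9,   9, 0.009,  2,  2, 0.002),
    list("29", "R", "Unionida",  "Unio crassus",                 72.7,  557, .312, .135, .203, .350,  12,  12, 0.012,  0,  0, 0.000)
  )
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(setNames(r, cols), stringsAsFactors = FALSE)
  }))
  # identity threshold implied by each observed percent (footnoted row
  # included: 77.3 -> 17)
  out$k <- vapply(out$pct, min_matches_for_percent, integer(1), W = 22L)
  out
}

#' Run the full randomization table over a set of LURs
#'
#' For each row runs [mc_null_test()] under the empirical composition and
#' under uniform frequencies, with `k` derived from the row's observed
#' percent similarity via [min_matches_for_percent()].
#'
#' @param rows Data frame with columns `taxon` (or `label`), `L`, `piT`,
#'   `piC`, `piG`, `piA` and `pct` (or a precomputed `k`); defaults to
#'   [ste_reference_lurs()].
#' @param motif An [ste_motif()].
#' @param n_reps Replicates per run (default 1000).
#' @param seed Master seed; row/mode seeds are derived from it.
#' @param alpha Significance level for the flag (raw pseudo p, no
#'   correction); a Bonferroni-adjusted flag over `2 * nrow` runs is emitted
#'   alongside for transparency.
#' @return Data frame with, per row and frequency mode, total hits, number
#'   of replicates with a hit, pseudo p, the exact analytic expectation and
#'   significance flags.
#' @export
run_table1 <- function(rows = ste_reference_lurs(), motif = ste_motif(),
                       n_reps = 1000L, seed = 1L, alpha = 0.05) {
  if (nrow(rows) == 0L) {
    return(data.frame(label = character(), freq_mode = character(),
                      k = integer(), total_hits = integer(),
                      seqs_with_hit = integer(), pseudo_p = numeric(),
                      analytic_expected_total = numeric(),
                      significant = logical(), significant_bonferroni = logical()))
  }
  label <- if ("taxon" %in% names(rows)) rows$taxon else rows$label
  if (!"k" %in% names(rows)) {
    rows$k <- vapply(rows$pct, min_matches_for_percent, integer(1), W = motif$W)
  }
  n_runs <- 2L * nrow(rows)
  run_seeds <- withr_seed(seed, sample.int(.Machine$integer.max, n_runs))
  res <- vector("list", n_runs)
  for (i in seq_len(nrow(rows))) {
    freqs <- as.numeric(rows[i, c("piT", "piC", "piG", "piA")])
    freqs <- freqs / sum(freqs)     # printed frequencies are rounded to 3 dp
    for (j in 1:2) {
      mode <- c("empirical", "uniform")[j]
      r <- mc_null_test(rows$L[i], freqs, rows$k[i], motif, n_reps,
                        seed = run_seeds[2L * (i - 1L) + j], freq_mode = mode,
                        alpha = alpha)
      res[[2L * (i - 1L) + j]] <- data.frame(
        label = label[i], freq_mode = mode, k = rows$k[i], L = rows$L[i],
        total_hits = r$total_hits, seqs_with_hit = r$seqs_with_hit,
        pseudo_p = r$pseudo_p,
        analytic_expected_total = r$analytic_expected_total,
        significant = r$significant,
        significant_bonferroni = r$pseudo_p <= alpha / n_runs,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
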