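motif <- ste_motif()
scheme <- scoring_scheme()   # +5/-4, Ts = 56

test_that("window scores follow the exact match/mismatch scheme", {
  self <- window_score(motif$sequence, motif, scheme)
  expect_identical(self$m, 22L)
  expect_identical(self$S, 110L)
  allN <- window_score(strrep("N", 22), motif, scheme)
  expect_identical(allN$m, 0L)
  expect_identical(allN$S, -88L)
  w16 <- plant_motif_copy(strrep("A", 22), motif, m = 16, offset = 0, seed = 1)
  s16 <- window_score(substr(w16, 1, 22), motif, scheme)
  expect_identical(s16$S, 56L)
  expect_error(window_score("ACGT", motif, scheme), "length")
})

test_that("percent-to-identity conversion matches reported percentages", {
  expect_identical(min_matches_for_percent(72.7, 22), 16L)
  expect_identical(min_matches_for_percent(77.3, 22), 17L)
  expect_identical(min_matches_for_percent(81.8, 22), 18L)
  expect_identical(min_matches_for_percent(95.5, 22), 21L)
  expect_identical(min_matches_for_percent(100, 22), 22L)
  expect_identical(min_matches_for_percent(0, 22), 0L)
})

test_that("scanning agrees with a brute-force oracle and handles strands", {
  target <- random_dna(1000, 31)
  raw <- scan_sequence(target, motif, scoring_scheme(ts = 22 * -4 + 9 * 8),
                       strand_mode = "forward", merge = FALSE)
  # low threshold: compare against every window's brute-force count
  bf <- brute_force_counts(target, motif$sequence)
  k <- ceiling((22 * -4 + 72 + 88) / 9)
  expect_identical(raw$start, which(bf >= k) - 1L)
  expect_identical(raw$m, bf[bf >= k])

  # short target
  expect_identical(nrow(scan_sequence("ACGT", motif, scheme)), 0L)

  # strand symmetry: forward hits of the reverse complement equal mapped
  # minus-strand hits of the target
  t2 <- plant_motif_copy(random_dna(300, 32), motif, m = 20, strand = "-",
                         offset = 120, seed = 33)
  fwd_rc <- scan_sequence(reverse_complement(t2), motif, scheme,
                          strand_mode = "forward", merge = FALSE)
  minus <- scan_sequence(t2, motif, scheme, strand_mode = "both",
                         merge = FALSE)
  minus <- minus[minus$strand == "-", ]
  expect_equal(sort(300 - fwd_rc$start - 22), sort(minus$start))
  expect_identical(sort(fwd_rc$m), sort(minus$m))
})

test_that("overlapping windows merge into one hit per motif copy", {
  W <- 22L
  mk <- function(starts, ms) {
    data.frame(target_id = "t", start = starts, end = starts + W,
               strand = "+", m = ms, score = ms * 5 + (W - ms) * -4,
               pct = round(100 * ms / W, 1), stringsAsFactors = FALSE)
  }
  expect_identical(nrow(merge_hits(mk(c(0L, 1L), c(16L, 17L)))), 1L)
  expect_identical(merge_hits(mk(c(0L, 1L), c(16L, 17L)))$start, 1L)
  expect_identical(nrow(merge_hits(mk(c(0L, 50L), c(16L, 16L)))), 2L)
  # tie on score -> leftmost window represents the run
  expect_identical(merge_hits(mk(c(5L, 6L), c(16L, 16L)))$start, 5L)

  planted <- data.frame(m = c(22, 21, 16), strand = "+",
                        offset = c(100, 400, 700))
  g <- tiny_genome(seed = 41, lur_length = 1000, planted = planted)
  lur <- extract_lurs(g$genome)$sequence[1]
  expect_identical(nrow(scan_sequence(lur, motif, scheme)), 3L)
})

test_that("accepted-window counts never increase with the threshold", {
  planted <- data.frame(m = c(22, 19, 17, 16), strand = "+",
                        offset = c(50, 300, 550, 800))
  g <- tiny_genome(seed = 42, lur_length = 1100, planted = planted)
  lur <- extract_lurs(g$genome)$sequence[1]
  raw <- vapply(seq(-88, 110), function(ts) {
    nrow(scan_sequence(lur, motif, scoring_scheme(ts = ts), merge = FALSE))
  }, integer(1))
  expect_true(all(diff(raw) <= 0))
  # merged counts step down exactly at the planted identity boundaries
  merged_at <- function(k) {
    nrow(scan_sequence(lur, motif, scoring_scheme(ts = 9 * k - 88)))
  }
  expect_identical(vapply(c(16, 17, 18, 20, 22), merged_at, integer(1)),
                   c(4L, 3L, 2L, 1L, 1L))
})

test_that("threshold calibration recovers the conservative Ts", {
  mk_ref <- function(seed, ms, L = 1200) {
    planted <- data.frame(m = ms, strand = "+",
                          offset = seq(50, by = 250, length.out = length(ms)))
    g <- tiny_genome(seed = seed, lur_length = L, planted = planted)
    list(sequence = extract_lurs(g$genome)$sequence[1], expected = length(ms))
  }
  refs <- list(mk_ref(51, c(22, 21, 16)), mk_ref(52, 17), mk_ref(53, 16))
  cal <- calibrate_threshold(motif, refs)
  expect_identical(cal$ts, 56L)
  # every reference shows its expected copy number at the selected Ts and
  # loses a detection just above it (the conservative-maximum property)
  at56 <- cal$curve[cal$curve$ts == 56L, -1]
  at57 <- cal$curve[cal$curve$ts == 57L, -1]
  expect_equal(unlist(at56, use.names = FALSE), c(3, 1, 1))
  expect_false(all(unlist(at57) == c(3, 1, 1)))

  # a single exact copy supports the maximal threshold
  one <- mk_ref(54, 22)
  expect_identical(calibrate_threshold(motif, list(one))$ts, 110L)

  # expecting two copies when one is planted is infeasible
  expect_error(
    calibrate_threshold(motif,
                        list(list(sequence = motif$sequence, expected = 2)),
                        strand_mode = "forward"),
    "feasible")
})

test_that("genome-wide scans annotate context and wrap the origin", {
  g <- tiny_genome(seed = 61, lur_length = 600)
  gr <- g$genome
  # plant an antisense copy inside the rRNA gene
  rr <- gr$features[gr$features$kind == "rRNA", ]
  gr$sequence <- plant_motif_copy(gr$sequence, motif, m = 22, strand = "-",
                                  offset = rr$start + 100L, seed = 62)
  hits <- scan_genome(gr, motif, scheme)
  inside <- hits[hits$start == rr$start + 100L, ]
  expect_identical(nrow(inside), 1L)
  expect_identical(inside$strand, "-")
  expect_identical(inside$context, "in_feature:rrnL,antisense")

  # hit spanning the origin of a circular record
  n0 <- nchar(tiny_genome(seed = 63, lur_length = 600)$genome$sequence)
  # rotation putting the planted copy (absolute position n0 - 300 before
  # rotation) 11 bp before the origin; negative rotations wrap
  gw <- tiny_genome(seed = 63, lur_length = 600,
                    planted = data.frame(m = 22, strand = "+", offset = 300),
                    rotate = (n0 - 300L) - (n0 - 11L))
  # planted copy now starts 11 bp before the origin
  wh <- scan_genome(gw$genome, motif, scheme)
  wrapped <- wh[wh$m == 22L, ]
  expect_identical(nrow(wrapped), 1L)
  expect_identical(wrapped$start, nchar(gw$genome$sequence) - 11L)
  expect_gt(wrapped$end, nchar(gw$genome$sequence))
  expect_identical(wrapped$context, "in_LUR")

  # maximal threshold on a copy-free genome: no hits
  g0 <- tiny_genome(seed = 64, lur_length = 3000)
  expect_identical(nrow(scan_genome(g0$genome, motif, scoring_scheme(ts = 110))), 0L)
})
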