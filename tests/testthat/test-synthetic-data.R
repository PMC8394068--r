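motif <- ste_motif()

test_that("planted copies carry exactly the requested identity", {
  bg <- random_dna(200, 1)
  exact <- plant_motif_copy(bg, motif, m = 22, strand = "+", offset = 50,
                            seed = 1)
  expect_identical(substr(exact, 51, 72), motif$sequence)
  # only the window changed
  expect_identical(substr(exact, 1, 50), substr(bg, 1, 50))
  expect_identical(substr(exact, 73, 200), substr(bg, 73, 200))

  for (m in c(0, 10, 16, 21)) {
    p <- plant_motif_copy(bg, motif, m = m, strand = "+", offset = 50,
                          seed = m + 2)
    expect_equal(ungapped_identity(substr(p, 51, 72), motif$sequence),
                 100 * m / 22, tolerance = 1e-9)
  }
  # 16/22 is the 72.7% boundary reported for 22 bp windows
  p16 <- plant_motif_copy(bg, motif, m = 16, strand = "+", offset = 50, seed = 3)
  expect_equal(round(ungapped_identity(substr(p16, 51, 72), motif$sequence), 1),
               72.7)

  # minus strand: the reverse complement of the window matches
  pm <- plant_motif_copy(bg, motif, m = 18, strand = "-", offset = 50, seed = 4)
  expect_equal(ungapped_identity(reverse_complement(substr(pm, 51, 72)),
                                 motif$sequence),
               100 * 18 / 22, tolerance = 1e-9)

  expect_error(plant_motif_copy(bg, motif, m = 23, offset = 0, seed = 1),
               "\\[0, 22\\]")
  expect_error(plant_motif_copy(bg, motif, m = 22, offset = 190, seed = 1),
               "out of range")
})

test_that("scan threshold separates planted copies at the identity boundary", {
  scheme <- scoring_scheme(ts = 56)   # accepts m >= 16
  bg <- generate_background(500, c(0.282, 0.158, 0.209, 0.351), seed = 9)
  p15 <- plant_motif_copy(bg, motif, m = 15, strand = "+", offset = 200, seed = 5)
  p16 <- plant_motif_copy(bg, motif, m = 16, strand = "+", offset = 200, seed = 5)
  h15 <- scan_sequence(p15, motif, scheme)
  h16 <- scan_sequence(p16, motif, scheme)
  expect_false(200 %in% h15$start)
  expect_true(200 %in% h16$start)
})

test_that("synthetic genomes round-trip through LUR extraction", {
  # no planted copies -> empty truth
  g0 <- tiny_genome(seed = 2, planted = NULL)
  expect_identical(nrow(g0$truth$planted), 0L)

  # LUR interval recovered exactly as the longest unannotated stretch
  g <- tiny_genome(seed = 3, lur_length = 700)
  lurs <- extract_lurs(g$genome)
  expect_identical(lurs$start[1], g$truth$lur_start)
  expect_identical(lurs$end[1], g$truth$lur_end)
  expect_identical(lurs$length[1], 700L)
  # coordinates round-trip
  expect_identical(extract_region(g$genome, lurs$start[1], lurs$end[1]),
                   lurs$sequence[1])

  # full default bivalve template too
  gd <- generate_annotated_genome(synth_spec(seed = 4, lur_length = 3590))
  ld <- extract_lurs(gd$genome)
  expect_identical(ld$start[1], gd$truth$lur_start)
  expect_identical(ld$length[1], 3590L)
})

test_that("a LUR straddling the origin is returned as one wrapped interval", {
  n_nowrap <- nchar(tiny_genome(seed = 5, lur_length = 700)$genome$sequence)
  # rotate so the origin lands inside the LUR
  g <- tiny_genome(seed = 5, lur_length = 700, rotate = n_nowrap - 350L)
  lurs <- extract_lurs(g$genome)
  expect_identical(nrow(lurs[lurs$length == 700L, ]), 1L)
  expect_identical(lurs$start[1], g$truth$lur_start)
  expect_identical(lurs$end[1], g$truth$lur_end)
  expect_gt(lurs$end[1], nchar(g$genome$sequence))  # wrapped
  expect_identical(nchar(lurs$sequence[1]), 700L)
})

test_that("planted truth is recovered by the scan", {
  planted <- data.frame(m = c(22, 21, 16), strand = c("+", "+", "-"),
                        offset = c(50, 250, 450))
  g <- tiny_genome(seed = 6, lur_length = 700, planted = planted)
  lurs <- extract_lurs(g$genome)
  hits <- scan_sequence(lurs$sequence[1], motif, scoring_scheme(ts = 56))
  expect_identical(nrow(hits), 3L)
  expect_setequal(hits$start, planted$offset)
  expect_setequal(hits$m, planted$m)
})

test_that("generated LUR composition matches the requested frequencies", {
  freqs <- c(0.358, 0.106, 0.209, 0.327)
  for (seed in 1:3) {
    s <- generate_background(10000, freqs / sum(freqs), seed = seed)
    counts <- table(factor(strsplit(s, "")[[1]], levels = c("T", "C", "G", "A")))
    p <- stats::chisq.test(counts, p = freqs / sum(freqs))$p.value
    expect_gt(p, 0.001)
  }
})

test_that("template and spec invariants are enforced", {
  expect_error(synth_spec(planted = data.frame(m = c(22, 22),
                                               strand = c("+", "+"),
                                               offset = c(0, 10))),
               "overlap")
  bad_tpl <- data.frame(name = c("t", "g"), kind = c("tRNA", "protein_coding"),
                        length = c(68L, 500L), strand = "+")
  expect_error(generate_annotated_genome(synth_spec(gene_template = bad_tpl)),
               "start and end with")
  expect_error(
    generate_annotated_genome(
      synth_spec(gene_template = tiny_template(), lur_length = 100,
                 genome_length = 500)),
    "longer than genome")
})

test_that("GenBank and truth files round-trip the synthetic genome", {
  planted <- data.frame(m = 22, strand = "+", offset = 100)
  g <- tiny_genome(seed = 7, lur_length = 400, planted = planted, rotate = 900)
  gb <- tempfile(fileext = ".gb")
  write_genbank(g$genome, gb)
  back <- read_genbank(gb)
  expect_identical(back$sequence, g$genome$sequence)
  expect_true(back$circular)
  expect_identical(nrow(back$features), nrow(g$genome$features))
  expect_identical(back$features$start, g$genome$features$start)
  expect_identical(back$features$end, g$genome$features$end)
  expect_identical(back$features$kind, g$genome$features$kind)

  tsv <- tempfile(fileext = ".tsv")
  write_truth_tsv(g$genome, g$truth, tsv)
  truth <- read.delim(tsv)
  expect_identical(truth$lur_start[1], g$truth$lur_start)
  expect_identical(truth$hit_pos[1], g$truth$planted$pos[1])
})
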