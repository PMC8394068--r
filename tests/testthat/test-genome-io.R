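motif <- ste_motif()

minimal_gb <- function(seq, features, circular = TRUE, id = "TEST0001") {
  c(sprintf("LOCUS       %s %d bp    DNA     %s   INV", id, nchar(seq),
            if (circular) "circular" else "linear"),
    sprintf("DEFINITION  %s test record.", id),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(seq)),
    features,
    "ORIGIN",
    sprintf("%9d %s", 1, tolower(seq)),
    "//")
}

test_that("a minimal GenBank record with one CDS parses", {
  seq <- random_dna(120, 1)
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, "     CDS             11..70"), gb)
  g <- read_genbank(gb)
  expect_s3_class(g, "genome_record")
  expect_identical(nrow(g$features), 1L)
  expect_identical(g$features$kind, "protein_coding")
  expect_identical(g$features$start, 10L)
  expect_identical(g$features$end, 70L)
  expect_identical(g$sequence, seq)
})

test_that("misc_feature is classified as other and never bounds a LUR", {
  seq <- random_dna(1000, 2)
  feats <- c("     CDS             1..200",
             "     misc_feature    401..500",
             "     CDS             801..1000")
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, feats, circular = FALSE), gb)
  g <- read_genbank(gb)
  expect_identical(g$features$kind[2], "other")
  lurs <- extract_lurs(g, min_length = 100)
  # single gap [200, 800) spanning the misc_feature
  expect_identical(nrow(lurs), 1L)
  expect_identical(lurs$start, 200L)
  expect_identical(lurs$end, 800L)
})

test_that("feature overrides reclassify to orf_uncertain", {
  seq <- random_dna(600, 3)
  feats <- c("     CDS             1..100",
             "     CDS             301..400",
             "     CDS             501..600")
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, feats, circular = FALSE), gb)
  ov <- data.frame(feature_index = 2L, new_kind = "orf_uncertain")
  g <- read_genbank(gb, overrides = ov)
  expect_identical(g$features$kind[2], "orf_uncertain")
  lurs <- extract_lurs(g, min_length = 50)
  # the uncertain ORF no longer splits the [100, 500) gap
  expect_identical(lurs$start[1], 100L)
  expect_identical(lurs$end[1], 500L)
})

test_that("tRNAs neither break nor mask a LUR", {
  seq <- random_dna(1200, 4)
  feats <- c("     CDS             1..300",
             "     tRNA            401..468",
             "     tRNA            501..568",
             "     CDS             1001..1200")
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, feats, circular = FALSE), gb)
  g <- read_genbank(gb)
  lurs <- extract_lurs(g, min_length = 100)
  expect_identical(nrow(lurs), 1L)
  expect_identical(c(lurs$start, lurs$end), c(300L, 1000L))
  # sequence over the tRNAs is kept, not masked
  expect_identical(lurs$sequence, substr(seq, 301, 1000))
})

test_that("a genome fully tiled except one 1070 bp gap yields that LUR", {
  seq <- random_dna(3000, 5)
  feats <- c("     CDS             1..1000",
             "     rRNA            1001..1430",
             "     CDS             2501..3000")
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, feats, circular = TRUE), gb)
  g <- read_genbank(gb)
  lurs <- extract_lurs(g)
  expect_identical(lurs$length[1], 1070L)
  expect_identical(c(lurs$start[1], lurs$end[1]), c(1430L, 2500L))
})

test_that("genomes without boundary features are rejected", {
  seq <- random_dna(300, 6)
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, "     tRNA            1..68"), gb)
  g <- read_genbank(gb)
  expect_error(extract_lurs(g), "cannot define LURs")
})

test_that("complement and origin-spanning join locations parse", {
  seq <- random_dna(500, 7)
  feats <- c("     CDS             complement(101..200)",
             "     rRNA            join(451..500,1..50)")
  gb <- tempfile(fileext = ".gb")
  writeLines(minimal_gb(seq, feats, circular = TRUE), gb)
  g <- read_genbank(gb)
  expect_identical(g$features$strand, c("-", "+"))
  expect_identical(g$features$start[2], 450L)
  expect_identical(g$features$end[2], 550L)   # wraps
})

test_that("FASTA plus annotation table reads equivalently", {
  seq <- random_dna(800, 8)
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">FASTA01 test", seq), fa)
  ann <- tempfile(fileext = ".tsv")
  write.table(data.frame(kind = c("protein_coding", "rRNA"),
                         name = c("cox1", "rrnS"), strand = c("+", "-"),
                         start = c(1, 601), end = c(200, 800)),
              ann, sep = "\t", quote = FALSE, row.names = FALSE)
  g <- read_genome(fa, format = "fasta", annotation = ann, circular = TRUE)
  expect_identical(g$id, "FASTA01")
  expect_identical(g$features$start, c(0L, 600L))
  lurs <- extract_lurs(g)
  expect_identical(c(lurs$start, lurs$end), c(200L, 600L))
})

test_that("synthetic LUR frequencies sit within sampling error of the target", {
  # composition and length of the most promising clam LUR
  freqs <- c(0.358, 0.106, 0.209, 0.327)
  s <- generate_background(3968, freqs / sum(freqs), seed = 21)
  est <- base_frequencies(s)
  expect_true(all(abs(est - freqs / sum(freqs)) < 0.025))
})
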