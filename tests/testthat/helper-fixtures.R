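# Small fixtures shared across tests; everything is generated in code.

# A compact annotated-genome template: 3 boundary genes and 2 tRNAs,
# bounded on both sides so the LUR interval is unambiguous.
tiny_template <- function() {
  data.frame(
    name = c("cox1", "trn1", "rrnL", "trn2", "cob"),
    kind = c("protein_coding", "tRNA", "rRNA", "tRNA", "protein_coding"),
    length = c(600L, 68L, 400L, 68L, 500L),
    strand = "+",
    stringsAsFactors = FALSE
  )
}

tiny_genome <- function(seed = 1L, lur_length = 600L, planted = NULL,
                        rotate = 0L,
                        lur_freqs = c(0.282, 0.158, 0.209, 0.350)) {
  generate_annotated_genome(
    synth_spec(seed = seed, gene_template = tiny_template(),
               lur_length = lur_length, lur_freqs = lur_freqs,
               planted = planted, rotate = rotate)
  )
}

# Independent brute-force window scorer: identity counts by direct string
# comparison, no shared code with the scanner.
brute_force_counts <- function(target, motif_seq) {
  W <- nchar(motif_seq)
  n <- nchar(target)
  if (n < W) return(integer(0))
  ms <- strsplit(motif_seq, "")[[1]]
  vapply(seq_len(n - W + 1L), function(i) {
    w <- strsplit(substr(target, i, i + W - 1L), "")[[1]]
    sum(w == ms & w %in% c("A", "C", "G", "T"))
  }, integer(1))
}

# Independent affine-gap global aligner (Gotoh), scores only; used as the
# oracle for gapped_similarity on short strings.
gotoh_score <- function(a, b, match = 5, mismatch = -4, gap_open = 10,
                        gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (A aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_extend * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      # a gap may open right after a gap in the other sequence
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     Y[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     X[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
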