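## Low-level nucleotide utilities shared by the scanner, the null model and
## the synthetic generator. Sequences are plain uppercase character strings;
## frequency vectors are always in <T, C, G, A> order.

#' Encode a DNA string as integer base codes
#'
#' Bases are coded 1..4 in `T, C, G, A` order; any other character
#' (ambiguity codes, gaps) becomes `NA` and never matches in a scan.
#'
#' @param seq A nucleotide string.
#' @return Integer vector, one code per base.
#' @keywords internal
dna_codes <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], STE_BASES)
}

decode_dna <- function(codes) {
  paste(STE_BASES[codes], collapse = "")
}

check_freqs <- function(freqs) {
  if (!is.numeric(freqs) || length(freqs) != 4L) {
    stop("`freqs` must be a numeric 4-vector in (T, C, G, A) order")
  }
  if (any(freqs < 0)) stop("`freqs` must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("`freqs` must sum to 1 (got ", format(sum(freqs)), ")")
  }
  invisible(freqs)
}

## Published compositions are printed to 3 significant digits and may sum to
## e.g. 0.999; renormalize when within `tol` of 1, error otherwise.
normalize_freqs <- function(freqs, tol = 0.005) {
  if (!is.numeric(freqs) || length(freqs) != 4L || any(freqs < 0)) {
    stop("`freqs` must be a non-negative numeric 4-vector in (T, C, G, A) order")
  }
  if (abs(sum(freqs) - 1) > tol) {
    stop("`freqs` must sum to 1 (got ", format(sum(freqs)), ")")
  }
  freqs / sum(freqs)
}

#' Generate a random background sequence of fixed base composition
#'
#' Draws bases i.i.d. from the supplied frequencies, the null model used for
#' the randomization test: random sequence matched in length and composition
#' to an observed LUR.
#'
#' @param length Sequence length in bp.
#' @param freqs Numeric 4-vector of base probabilities in `(T, C, G, A)`
#'   order, summing to 1.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A nucleotide string of exactly `length` characters.
#' @examples
#' generate_background(10, c(0.25, 0.25, 0.25, 0.25), seed = 1)
#' @export
generate_background <- function(length, freqs, seed) {
  if (!is.numeric(length) || length < 0) stop("`length` must be >= 0")
  check_freqs(freqs)
  if (length == 0) return("")
  codes <- withr_seed(seed, sample.int(4L, length, replace = TRUE, prob = freqs))
  decode_dna(codes)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user streams.
withr_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Reverse-complement a nucleotide string
#'
#' @param seq A nucleotide string (IUPAC codes allowed).
#' @return The reverse complement, an involution of the input.
#' @examples
#' reverse_complement("CCAT")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Base frequencies of a sequence
#'
#' Proportions of the four unambiguous bases in `(T, C, G, A)` order,
#' computed over unambiguous positions only (N and other ambiguity codes are
#' ignored in the denominator).
#'
#' @param seq A nucleotide string.
#' @return Named numeric 4-vector summing to 1.
#' @examples
#' base_frequencies("TCGA")
#' @export
base_frequencies <- function(seq) {
  codes <- dna_codes(seq)
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) {
    stop("cannot compute base frequencies: no unambiguous bases in sequence")
  }
  counts <- tabulate(codes, nbins = 4L)
  setNames(counts / sum(counts), STE_BASES)
}

#' Extract a (possibly wrapped) region from a genome
#'
#' Coordinates are 0-based half-open on the forward strand. On circular
#' genomes `end` may exceed the genome length, in which case the region wraps
#' the origin and the tail and head are concatenated. With `strand = "-"` the
#' reverse complement of the slice is returned.
#'
#' @param genome A `genome_record` (see [read_genome()]) or a plain string
#'   (then `circular` controls wrapping).
#' @param start,end 0-based half-open interval; `end > length(genome)`
#'   denotes a wrap.
#' @param strand `"+"` or `"-"`.
#' @param circular Only used when `genome` is a bare string.
#' @return The extracted nucleotide string.
#' @export
extract_region <- function(genome, start, end, strand = "+", circular = NULL) {
  if (inherits(genome, "genome_record")) {
    seq <- genome$sequence
    circ <- genome$circular
  } else {
    seq <- genome
    circ <- isTRUE(circular)
  }
  n <- nchar(seq)
  if (start < 0 || end < start) stop("invalid interval [", start, ", ", end, ")")
  if (end > n) {
    if (!circ) stop("interval wraps the origin but the record is linear")
    if (end - start > n) stop("interval longer than the genome")
    out <- paste0(substr(seq, start + 1L, n), substr(seq, 1L, end - n))
  } else {
    out <- substr(seq, start + 1L, end)
  }
  if (strand == "-") out <- reverse_complement(out)
  out
}

## Sliding-window identity counts: number of identities between the motif and
## every window of the target. NA codes (ambiguous bases) never match.
window_identity_counts <- function(codes, motif_codes) {
  n <- length(codes)
  W <- length(motif_codes)
  nw <- n - W + 1L
  if (nw < 1L) return(integer(0))
  acc <- integer(nw)
  idx <- seq_len(nw)
  if (anyNA(codes)) {
    for (j in seq_len(W)) {
      eq <- codes[idx + (j - 1L)] == motif_codes[j]
      acc <- acc + as.integer(!is.na(eq) & eq)
    }
  } else {
    for (j in seq_len(W)) {
      acc <- acc + (codes[idx + (j - 1L)] == motif_codes[j])
    }
  }
  acc
}
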