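## Synthetic annotated circular mitogenomes with a single long unannotated
## region of controlled length/composition and planted motif copies at
## controlled identity, so every downstream stage has known truth.

#' Plant a diverged motif copy into a background sequence
#'
#' Replaces the window `[offset, offset + W)` of `background` with a copy of
#' the motif carrying exactly `W - m` mismatches. Mismatch positions are
#' drawn uniformly without replacement; each substituted base is drawn
#' uniformly from the three bases different from the motif base at that
#' position. With `strand = "-"` the mutated copy is reverse-complemented
#' before insertion, so the planted window has exactly `m` identities to the
#' motif after reverse complementation.
#'
#' @param background Nucleotide string.
#' @param motif An [ste_motif()].
#' @param m Identity count of the planted copy, `0 <= m <= W`.
#' @param strand `"+"` or `"-"`.
#' @param offset 0-based insertion offset; `offset + W <= nchar(background)`.
#' @param seed Integer seed for the mismatch draw.
#' @return The modified background string.
#' @export
plant_motif_copy <- function(background, motif, m, strand = "+", offset = 0L,
                             seed = 1L) {
  W <- motif$W
  if (m < 0 || m > W) stop("`m` must be in [0, ", W, "]")
  if (offset < 0 || offset + W > nchar(background)) {
    stop("offset ", offset, " out of range for a ", W, " bp window in a ",
         nchar(background), " bp background")
  }
  codes <- motif$codes
  n_mut <- W - m
  if (n_mut > 0L) {
    mut <- withr_seed(seed, {
      pos <- sample.int(W, n_mut)
      subs <- vapply(pos, function(p) {
        sample(setdiff(1:4, codes[p]), 1L)
      }, integer(1))
      list(pos = pos, subs = subs)
    })
    codes[mut$pos] <- mut$subs
  }
  copy <- decode_dna(codes)
  if (strand == "-") copy <- reverse_complement(copy)
  paste0(substr(background, 1L, offset),
         copy,
         substr(background, offset + W + 1L, nchar(background)))
}

#' Specify a synthetic annotated mitogenome
#'
#' The genome is laid out as the gene features in template order, each
#' followed by a 20 bp fixed low-complexity spacer, with the LUR occupying
#' the single remaining stretch — so the LUR is unambiguously the longest
#' unannotated region and truth is unique. `rotate` shifts the origin so
#' that features and/or the LUR can wrap it.
#'
#' @param seed Master seed for background generation and mismatch draws.
#' @param gene_template Data frame with columns `kind`
#'   (`protein_coding`/`rRNA`/`tRNA`/`orf_uncertain`), `length` (bp) and
#'   `strand`; defaults to a typical bivalve complement of 13 protein-coding
#'   genes, 2 rRNAs and 22 tRNAs via [default_gene_template()].
#' @param lur_length LUR length `L` in bp.
#' @param lur_freqs LUR base frequencies `(T, C, G, A)`.
#' @param planted Data frame with columns `m`, `strand`, `offset` (0-based
#'   offset within the LUR); copies must not overlap. `NULL` for none.
#' @param rotate Rotation of the final genome in bp (0 = LUR at the end of
#'   the sequence, not wrapping).
#' @param genome_length Optional expected total length; an error is raised
#'   when the template plus spacers plus LUR does not fit it exactly.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, gene_template = default_gene_template(),
                       lur_length = 1000L,
                       lur_freqs = c(0.282, 0.158, 0.209, 0.350),
                       planted = NULL, rotate = 0L, genome_length = NULL) {
  lur_freqs <- normalize_freqs(lur_freqs)
  stopifnot(is.data.frame(gene_template),
            all(c("kind", "length", "strand") %in% names(gene_template)),
            all(gene_template$kind %in% feature_kinds),
            all(gene_template$length >= 1L),
            lur_length >= 0L)
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(all(c("m", "strand", "offset") %in% names(planted)))
    o <- planted[order(planted$offset), , drop = FALSE]
    if (nrow(o) > 1L && any(o$offset[-1] < head(o$offset, -1) + 22L)) {
      stop("planted copies must not overlap")
    }
  }
  structure(list(seed = seed, gene_template = gene_template,
                 lur_length = as.integer(lur_length), lur_freqs = lur_freqs,
                 planted = planted, rotate = as.integer(rotate),
                 genome_length = genome_length),
            class = "synth_spec")
}

#' Default bivalve-like gene template
#'
#' 13 protein-coding genes, 2 ribosomal RNAs and 22 transfer RNAs with
#' representative mitochondrial gene lengths. tRNAs are interleaved between
#' the boundary (protein-coding/rRNA) genes — as in real mitogenomes — so
#' that no long tRNA-only stretch competes with the LUR, and the template
#' starts and ends with a boundary gene so the LUR is flanked by features
#' that bound it. The scan does not depend on gene order, only on which
#' feature kinds bound the LUR.
#'
#' @return Data frame usable as `gene_template` in [synth_spec()].
#' @export
default_gene_template <- function() {
  pc <- c(cox1 = 1539, cox2 = 690, cox3 = 780, cob = 1140, nad1 = 930,
          nad2 = 1020, nad3 = 351, nad4 = 1350, nad4l = 282, nad5 = 1680,
          nad6 = 480, atp6 = 699, atp8 = 165)
  rr <- c(rrnL = 1250, rrnS = 840)
  boundary <- data.frame(
    name = c(names(pc), names(rr)),
    kind = c(rep("protein_coding", length(pc)), rep("rRNA", length(rr))),
    length = as.integer(c(pc, rr)),
    stringsAsFactors = FALSE
  )
  # distribute the 22 tRNAs round-robin into the 14 gaps between the 15
  # boundary genes (none after the last, which abuts the LUR)
  slots <- rep(seq_len(nrow(boundary) - 1L), length.out = 22L)
  rows <- list()
  t_i <- 0L
  for (i in seq_len(nrow(boundary))) {
    rows[[length(rows) + 1L]] <- boundary[i, ]
    for (s in which(sort(slots) == i)) {
      t_i <- t_i + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste0("trn", t_i), kind = "tRNA", length = 68L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$strand <- "+"
  rownames(out) <- NULL
  out
}

## fixed low-complexity intergenic spacer (20 bp)
SPACER <- "ACACACACACACACACACAC"

#' Generate a synthetic annotated circular genome with known truth
#'
#' Builds the genome described by a [synth_spec()]: gene features (filled
#' with random uniform-composition sequence), 20 bp spacers, and one LUR of
#' the requested length and composition carrying the planted motif copies.
#' Deterministic given the spec seed.
#'
#' @param spec A [synth_spec()].
#' @param motif An [ste_motif()] used for planting.
#' @param id Genome identifier.
#' @return List with `genome` (a `genome_record`) and `truth`: the 0-based
#'   half-open LUR interval (`end > length` when it wraps the origin) and a
#'   data frame of planted hits (`pos` = genome position of the window
#'   start, possibly `>= length` when the copy itself wraps, `strand`, `m`).
#' @export
generate_annotated_genome <- function(spec, motif = ste_motif(),
                                      id = "SYNTH0001") {
  tpl <- spec$gene_template
  boundary_kinds <- c("protein_coding", "rRNA")
  if (!(tpl$kind[1] %in% boundary_kinds &&
        tpl$kind[nrow(tpl)] %in% boundary_kinds)) {
    stop("gene template must start and end with a protein_coding or rRNA ",
         "feature so the LUR interval is bounded")
  }
  sp_len <- nchar(SPACER)
  # spacer after every feature except the last, which abuts the LUR
  gene_block_len <- sum(tpl$length) + (nrow(tpl) - 1L) * sp_len
  n <- gene_block_len + spec$lur_length
  if (!is.null(spec$genome_length)) {
    if (spec$genome_length < n) stop("gene template longer than genome")
    if (spec$genome_length > n) {
      stop("genome_length must equal template + spacers + LUR (", n, " bp)")
    }
  }

  # LUR background with planted copies
  lur <- generate_background(spec$lur_length, spec$lur_freqs, seed = spec$seed)
  planted <- spec$planted
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      if (planted$offset[i] + motif$W > spec$lur_length) {
        stop("planted copy ", i, " exceeds the LUR")
      }
      lur <- plant_motif_copy(lur, motif, planted$m[i], planted$strand[i],
                              planted$offset[i], seed = spec$seed + i)
    }
  }

  # gene blocks: random uniform sequence per feature, spacer after each
  gene_seqs <- withr_seed(spec$seed + 10000L, lapply(tpl$length, function(l) {
    decode_dna(sample.int(4L, l, replace = TRUE))
  }))
  pieces <- character(0)
  feats <- list()
  pos <- 0L
  for (i in seq_len(nrow(tpl))) {
    feats[[i]] <- data.frame(
      kind = tpl$kind[i],
      name = if ("name" %in% names(tpl)) tpl$name[i] else paste0("g", i),
      strand = tpl$strand[i], start = pos, end = pos + tpl$length[i],
      stringsAsFactors = FALSE)
    last <- i == nrow(tpl)
    pieces <- c(pieces, gene_seqs[[i]], if (!last) SPACER)
    pos <- pos + tpl$length[i] + if (!last) sp_len else 0L
  }
  sequence <- paste0(paste(pieces, collapse = ""), lur)
  lur_start <- gene_block_len
  lur_end <- n
  feats <- do.call(rbind, feats)

  # rotate so intervals may wrap the origin: new coord = (old - r) mod n
  r <- spec$rotate %% n
  if (r > 0L) {
    sequence <- paste0(substr(sequence, r + 1L, n), substr(sequence, 1L, r))
    shift <- function(s) (s - r) %% n
    feats$start <- shift(feats$start)
    feats$end <- feats$start + tpl$length
    lur_start <- shift(lur_start)
    lur_end <- lur_start + spec$lur_length
  }

  truth_hits <- if (!is.null(planted) && nrow(planted)) {
    data.frame(pos = as.integer((lur_start + planted$offset) %% n),
               strand = planted$strand, m = as.integer(planted$m),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(), strand = character(), m = integer(),
               stringsAsFactors = FALSE)
  }

  genome <- new_genome_record(id, sequence, circular = TRUE, features = feats)
  list(genome = genome,
       truth = list(lur_start = lur_start, lur_end = lur_end,
                    planted = truth_hits))
}

#' Write a genome record as a GenBank flat file
#'
#' Emits LOCUS (with the circular topology flag), DEFINITION, FEATURES
#' (CDS/rRNA/tRNA/misc_feature with `complement()` and origin-spanning
#' `join()` locations) and ORIGIN blocks, round-trippable by
#' [read_genbank()].
#'
#' @param genome A `genome_record`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genbank <- function(genome, path) {
  n <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   INV",
                     genome$id, n,
                     if (genome$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s synthetic mitochondrion, complete genome.",
                     genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  key_of <- c(protein_coding = "CDS", rRNA = "rRNA", tRNA = "tRNA",
              orf_uncertain = "misc_feature", other = "misc_feature")
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    s <- f$start[i] + 1L
    e <- f$end[i]
    loc <- if (e > n) sprintf("join(%d..%d,1..%d)", s, n, e - n)
           else sprintf("%d..%d", s, e)
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", key_of[[f$kind[i]]], loc), con)
    nm <- f$name[i]
    if (!is.na(nm)) writeLines(sprintf("                     /gene=\"%s\"", nm), con)
  }
  writeLines("ORIGIN", con)
  seq <- tolower(genome$sequence)
  starts <- seq.int(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write the truth table of a synthetic genome
#'
#' TSV with 0-based half-open coordinates: `genome_id`, `lur_start`,
#' `lur_end`, then one row per planted hit (`hit_pos`, `strand`,
#' `identities`); a genome without planted copies yields a single row with
#' empty hit columns.
#'
#' @param genome A `genome_record`.
#' @param truth Truth list from [generate_annotated_genome()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth_tsv <- function(genome, truth, path) {
  ph <- truth$planted
  if (nrow(ph) == 0L) {
    out <- data.frame(genome_id = genome$id, lur_start = truth$lur_start,
                      lur_end = truth$lur_end, hit_pos = NA_integer_,
                      strand = NA_character_, identities = NA_integer_)
  } else {
    out <- data.frame(genome_id = genome$id, lur_start = truth$lur_start,
                      lur_end = truth$lur_end, hit_pos = ph$pos,
                      strand = ph$strand, identities = ph$m)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
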