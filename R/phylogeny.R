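## Overview phylogeny: p-distances with pairwise deletion over an aligned
## co1 set, neighbor-joining reconstruction, nonparametric bootstrap.

as_char_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment), length(alignment) >= 2L)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("aligned sequences must all have the same length")
  }
  labs <- names(alignment) %||% paste0("seq", seq_along(alignment))
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- labs
  mat
}

#' p-distance matrix with pairwise deletion
#'
#' For every pair of aligned sequences, sites where either sequence carries
#' a gap or an ambiguity code are excluded; the distance is the proportion
#' of differing sites among the remaining comparable sites.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences, or a character matrix (rows = taxa).
#' @return List of class `ste_dist` with `d` (symmetric distance matrix),
#'   `comparable` (per-pair comparable-site counts) and `labels`.
#' @examples
#' p_distance_matrix(c(a = "ACGTACGTAC", b = "ACGTACGTAT", c = "ACGAACGTAT"))
#' @export
p_distance_matrix <- function(alignment) {
  mat <- as_char_matrix(alignment)
  nt <- nrow(mat)
  if (nt < 2L) stop("need at least two sequences")
  ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nt)
  d <- matrix(0, nt, nt, dimnames = list(rownames(mat), rownames(mat)))
  comp <- matrix(ncol(mat), nt, nt, dimnames = dimnames(d))
  for (i in seq_len(nt - 1L)) {
    for (j in (i + 1L):nt) {
      use <- ok[i, ] & ok[j, ]
      nc <- sum(use)
      if (nc == 0L) {
        stop("no comparable sites between ", rownames(mat)[i], " and ",
             rownames(mat)[j])
      }
      dij <- sum(mat[i, use] != mat[j, use]) / nc
      d[i, j] <- d[j, i] <- dij
      comp[i, j] <- comp[j, i] <- nc
    }
  }
  structure(list(d = d, comparable = comp, labels = rownames(mat)),
            class = "ste_dist")
}

## Zero out negative NJ branch lengths, transferring the deficit to the
## sibling edge at the same node (standard display convention).
clamp_negative_edges <- function(tree) {
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1L]
    sibs <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sibs)) {
      s <- sibs[1L]
      tree$edge.length[s] <- tree$edge.length[s] + tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor-joining (successive Q-criterion joins with the
#' standard branch-length formulas); negative branch lengths are clamped to
#' zero with the deficit moved to the sibling edge.
#'
#' @param dm An `ste_dist` from [p_distance_matrix()] or a symmetric
#'   numeric matrix with row/column names.
#' @return An unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dm) {
  d <- if (inherits(dm, "ste_dist")) dm$d else as.matrix(dm)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least 3 taxa")
  # lexicographic taxon order makes tie-breaks deterministic
  ord <- order(rownames(d))
  d <- d[ord, ord, drop = FALSE]
  clamp_negative_edges(ape::nj(stats::as.dist(d)))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' p-distance/neighbor-joining tree for each replicate, and reports for
#' every internal edge of the original tree the percentage of replicate
#' trees containing the same bipartition (stored in `node.label`).
#'
#' @param alignment As in [p_distance_matrix()].
#' @param n_boot Number of bootstrap replicates (default 1000); `0` returns
#'   the tree without support annotations.
#' @param seed Integer seed for the resampling.
#' @return A `phylo` tree; with `n_boot > 0`, `node.label` holds integer
#'   support percentages for internal nodes.
#' @export
bootstrap_support <- function(alignment, n_boot = 1000L, seed = 1L) {
  mat <- as_char_matrix(alignment)
  tree <- neighbor_joining(p_distance_matrix(mat))
  if (n_boot == 0L) return(tree)
  nc <- ncol(mat)
  boot_trees <- withr_seed(seed, lapply(seq_len(n_boot), function(b) {
    cols <- sample.int(nc, nc, replace = TRUE)
    neighbor_joining(p_distance_matrix(mat[, cols, drop = FALSE]))
  }))
  class(boot_trees) <- "multiPhylo"
  counts <- ape::prop.clades(tree, boot_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / n_boot)
  tree$node.label <- as.character(support)
  # root node of an unrooted tree is not a bipartition; leave it blank
  tree$node.label[1L] <- ""
  tree
}

#' Write a tree with support labels as newick
#'
#' @param tree A `phylo` tree (e.g. from [bootstrap_support()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
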