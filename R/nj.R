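# Neighbor joining (Saitou & Nei agglomeration on the Q-matrix) with a fixed
# deterministic tie-break, plus column-resampling bootstrap support for the
# internal bipartitions of the resulting unrooted tree.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined. Ties are broken
#' deterministically by the lowest index pair (row-major order), so the
#' result is reproducible. Negative branch lengths are clamped to zero.
#'
#' @param d Symmetric numeric matrix with zero diagonal and at least three
#'   taxa; dimnames give the taxon labels.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop_format("d must be square")
  n <- nrow(d)
  if (n < 3) stop_format("neighbor joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-9 || any(abs(diag(d)) > 1e-12))
    stop_format("d must be symmetric with zero diagonal")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  # newick fragments for the active nodes
  frag <- labels
  D <- d
  fmt <- function(x) sprintf("%.10g", max(0, x))
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest-index pair among minimisers (i < j, ordered by i then j)
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      if (Q[i, j] < bestq) { bestq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- paste0("(", frag[i], ":", fmt(li), ",", frag[j], ":", fmt(lj), ")")
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- paste0("(", frag[1], ":", fmt(b1), ",", frag[2], ":", fmt(b2), ",",
                frag[3], ":", fmt(b3), ");")
  ape::read.tree(text = nwk)
}

#' Internal bipartitions of an unrooted tree
#'
#' Each internal edge splits the tips into two sets; the split is encoded as
#' the sorted tip set on the side not containing the alphabetically first
#' tip, joined with `|`. Trivial splits (a single tip on one side) are
#' omitted.
#'
#' @param tree An [ape::phylo] tree.
#' @return Character vector of canonical split encodings.
#' @export
tree_bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  out <- character()
  for (s in pp) {
    side <- labs[s]
    if (length(side) < 2 || length(side) > n - 2) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(sort(side), collapse = "|"))
  }
  unique(out)
}

# p-distance tolerant of incomparable pairs (used only inside the bootstrap,
# where column resampling can leave a pair with no shared columns; such a
# pair is set to the maximal p-distance 1)
pdistance_boot <- function(chars, labels) {
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- chars[i, ] != "-" & chars[j, ] != "-"
    d[i, j] <- d[j, i] <- if (any(both)) mean(chars[i, both] != chars[j, both]) else 1
  }
  d
}

#' Bootstrap support for neighbor-joining bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree from
#' the p-distance matrix of each replicate, and reports for every internal
#' bipartition of the original tree the fraction of replicates containing
#' it. A single seeded generator drives all replicates, so results are
#' reproducible. If the alignment is degenerate (all pairwise distances
#' zero) the tree is arbitrary and all supports are reported as 0, with a
#' warning.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @param n_replicates Number of bootstrap replicates (`>= 1`).
#' @param seed Integer RNG seed.
#' @return Named numeric vector of supports in `[0, 1]`, keyed by the
#'   canonical split encoding of [tree_bipartitions()]; the original tree is
#'   attached as attribute `"tree"`.
#' @export
bootstrap_support <- function(msa, n_replicates = 1000, seed = 1) {
  if (n_replicates < 1) stop_config("n_replicates must be >= 1")
  d0 <- pdistance_matrix(msa)
  tree <- neighbor_joining(d0)
  splits <- tree_bipartitions(tree)
  if (max(d0) == 0) {
    warning("degenerate alignment: all pairwise distances are zero; supports set to 0")
    out <- setNames(rep(0, length(splits)), splits)
    attr(out, "tree") <- tree
    return(out)
  }
  chars <- do.call(rbind, strsplit(msa, ""))
  rownames(chars) <- names(msa)
  ncol_aln <- ncol(chars)
  counts <- setNames(numeric(length(splits)), splits)
  with_seed(seed, {
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      db <- pdistance_boot(chars[, idx, drop = FALSE], names(msa))
      tb <- neighbor_joining(db)
      sb <- tree_bipartitions(tb)
      hit <- splits %in% sb
      counts[hit] <- counts[hit] + 1
    }
  })
  out <- counts / n_replicates
  attr(out, "tree") <- tree
  out
}
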