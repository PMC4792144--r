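# Independent brute-force oracles used to check the package's fast paths.
# These are written from the definitions (Gotoh three-state DP, grid-search
# root finding, direct counting loops) and share no code with the package
# implementations they check.

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# three-state affine-gap DP; a gap of length L costs open + L * extend
oracle_align_score <- function(a, b, type = c("global", "local"),
                               open = 11, ext = 1) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # a[i] aligned to b[j]
  X <- matrix(NEG, n + 1, m + 1)  # a[i] aligned to a gap
  Y <- matrix(NEG, n + 1, m + 1)  # b[j] aligned to a gap
  M[1, 1] <- 0
  best_local <- 0
  for (i in 0:n) for (j in 0:m) {
    ii <- i + 1; jj <- j + 1
    if (i > 0) {
      X[ii, jj] <- max(M[ii - 1, jj] - (open + ext), X[ii - 1, jj] - ext,
                       Y[ii - 1, jj] - (open + ext))
      if (type == "global" && j == 0 && i > 0) X[ii, jj] <- -(open + ext * i)
    }
    if (j > 0) {
      Y[ii, jj] <- max(M[ii, jj - 1] - (open + ext), Y[ii, jj - 1] - ext,
                       X[ii, jj - 1] - (open + ext))
      if (type == "global" && i == 0 && j > 0) Y[ii, jj] <- -(open + ext * j)
    }
    if (i > 0 && j > 0) {
      s <- oracle_blosum62[A[i], B[j]]
      prev <- max(M[ii - 1, jj - 1], X[ii - 1, jj - 1], Y[ii - 1, jj - 1])
      if (type == "local") prev <- max(prev, 0)
      M[ii, jj] <- s + prev
      best_local <- max(best_local, M[ii, jj])
    }
  }
  if (type == "global") max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  else best_local
}

# dense grid search for the isoelectric point: coarse pass at `step`,
# refinement pass at step/10 around the coarse minimum of |charge|
oracle_pi_grid <- function(sequence, step = 1e-3) {
  grid <- seq(0, 14, by = step)
  ch <- abs(wrkyfam::net_charge(sequence, grid))
  p0 <- grid[which.min(ch)]
  fine <- seq(max(0, p0 - 2 * step), min(14, p0 + 2 * step), by = step / 10)
  fine[which.min(abs(wrkyfam::net_charge(sequence, fine)))]
}

KD_ORACLE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
               E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
               M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
               Y = -1.3, V = 4.2)

oracle_gravy <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  tot <- 0; nres <- 0
  for (ch in chars) if (ch %in% names(KD_ORACLE)) {
    tot <- tot + KD_ORACLE[[ch]]; nres <- nres + 1
  }
  tot / nres
}

oracle_instability <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  if (L < 2) return(0)
  tot <- 0
  diwv <- wrkyfam:::DIWV
  for (i in seq_len(L - 1)) {
    a <- chars[i]; b <- chars[i + 1]
    if (a %in% rownames(diwv) && b %in% colnames(diwv))
      tot <- tot + diwv[a, b]
  }
  10 * tot / L
}

oracle_aliphatic <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  100 * (sum(chars == "A") + 2.9 * sum(chars == "V") +
           3.9 * (sum(chars == "I") + sum(chars == "L"))) / L
}

oracle_pdistance <- function(row_i, row_j) {
  ci <- strsplit(row_i, "")[[1]]; cj <- strsplit(row_j, "")[[1]]
  diff <- 0; comp <- 0
  for (k in seq_along(ci)) {
    if (ci[k] != "-" && cj[k] != "-") {
      comp <- comp + 1
      if (ci[k] != cj[k]) diff <- diff + 1
    }
  }
  if (comp == 0) NA_real_ else diff / comp
}

# exhaustive reciprocal-best-hit check straight from the definition
oracle_rbh <- function(scores, species_map, sa, sb) {
  ia <- names(species_map)[species_map == sa]
  ib <- names(species_map)[species_map == sb]
  out <- character()
  for (a in ia) for (b in ib) {
    if (scores[a, b] <= 0) next
    if (scores[a, b] == max(scores[a, ib]) &&
        scores[a, b] == max(scores[b, ia]))
      out <- c(out, paste(min(a, b), max(a, b), sep = "\r"))
  }
  unique(out)
}

# least-squares branch-length fit of a distance matrix on a fixed topology;
# returns the residual sum of squares (0 iff the matrix is additive on it)
oracle_topology_rss <- function(topology, d) {
  tips <- topology$tip.label
  topo <- topology
  topo$edge.length <- rep(1, nrow(topo$edge))
  n <- length(tips)
  pairs <- t(combn(n, 2))
  # indicator: does edge e lie on the path between tips i and j
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- topo$edge[topo$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  X <- matrix(0, nrow(pairs), nrow(topo$edge))
  for (e in seq_len(nrow(topo$edge))) {
    below <- tips_below(topo$edge[e, 2])
    side <- seq_len(n) %in% below
    for (p in seq_len(nrow(pairs))) {
      if (side[pairs[p, 1]] != side[pairs[p, 2]]) X[p, e] <- 1
    }
  }
  y <- d[pairs]
  fit <- lm.fit(X, y)
  sum(fit$residuals^2)
}

rand_peptide <- function(len, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
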