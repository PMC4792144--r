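# Homolog-group calling. All-vs-all Smith-Waterman scores are normalised by
# the larger self-score to give similarity weights in (0, 1]; the weighted
# graph is clustered by Markov clustering (MCL: alternating expansion and
# inflation of a column-stochastic flow matrix), and within each cluster
# pairs are typed: same-species pairs are paralogs, cross-species reciprocal
# best hits are orthologs, and the remaining cross-species pairs are
# coorthologs. Tallies are arranged as a species-by-species pair table.

#' All-vs-all local alignment score matrix
#'
#' @param records Data frame from [read_fasta()] (columns `id`, `sequence`).
#' @return Symmetric numeric matrix of Smith-Waterman scores (BLOSUM62,
#'   gap open 11 / extend 1), including self-scores on the diagonal.
#' @export
score_matrix <- function(records) {
  n <- nrow(records)
  s <- matrix(0, n, n, dimnames = list(records$id, records$id))
  seqs <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  for (j in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      seqs[seq_len(j)], seqs[[j]], substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1, type = "local", scoreOnly = TRUE)
    s[seq_len(j), j] <- s[j, seq_len(j)] <- pmax(0, sc)
  }
  s
}

#' Build a similarity graph from protein records
#'
#' Edge weight between a and b is `score(a, b) / max(score(a, a),
#' score(b, b))`, which lies in (0, 1]; edges below `cutoff` are dropped.
#'
#' @param records Data frame with `id`, `species`, `sequence`.
#' @param cutoff Minimum weight kept (default 0.3).
#' @param scores Optional precomputed [score_matrix()].
#' @return List with `nodes` (data frame `id`, `species`) and `edges`
#'   (data frame `from`, `to`, `weight`).
#' @export
build_similarity_graph <- function(records, cutoff = 0.3, scores = NULL) {
  s <- scores %||% score_matrix(records)
  n <- nrow(records)
  from <- character(); to <- character(); w <- numeric()
  for (i in seq_len(max(0, n - 1))) for (j in seq(i + 1, n)) {
    denom <- max(s[i, i], s[j, j])
    if (denom <= 0) next
    wt <- s[i, j] / denom
    if (wt >= cutoff && wt > 0) {
      from <- c(from, records$id[i]); to <- c(to, records$id[j])
      w <- c(w, wt)
    }
  }
  list(nodes = data.frame(id = records$id, species = records$species,
                          stringsAsFactors = FALSE),
       edges = data.frame(from = from, to = to, weight = w,
                          stringsAsFactors = FALSE))
}

# connected components over an adjacency indicator matrix (BFS)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Markov clustering of a similarity graph
#'
#' Runs the MCL process on the column-stochastic flow matrix of the graph
#' (self-loops of weight 1 added): expansion (matrix squaring) alternating
#' with inflation (elementwise power `inflation`, column renormalisation),
#' pruning entries below `prune_eps`, until idempotence
#' (`max |change| < 1e-6`) or `max_iter`. Clusters are the connected
#' components of the non-zero structure of the limit matrix; singletons are
#' allowed.
#'
#' @param graph A [build_similarity_graph()] result.
#' @param inflation Inflation exponent, `> 1` (default 1.5).
#' @param prune_eps Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap.
#' @return List of character vectors (cluster memberships, each sorted);
#'   clusters partition the node set. Empty graph gives an empty list.
#' @export
mcl <- function(graph, inflation = 1.5, prune_eps = 1e-5, max_iter = 100) {
  if (inflation <= 1) stop_config("inflation must be > 1")
  if (prune_eps < 0) stop_config("prune_eps must be >= 0")
  ids <- graph$nodes$id
  n <- length(ids)
  if (n == 0) return(list())
  M <- diag(n)
  dimnames(M) <- list(ids, ids)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$from[k]; j <- graph$edges$to[k]
    M[i, j] <- M[j, i] <- graph$edges$weight[k]
  }
  normalize <- function(m) sweep(m, 2, colSums(m), "/")
  M <- normalize(M)
  for (it in seq_len(max_iter)) {
    prev <- M
    M <- M %*% M                              # expansion
    M <- normalize(M^inflation)               # inflation
    M[M < prune_eps] <- 0                     # pruning
    M <- normalize(M)
    if (max(abs(M - prev)) < 1e-6) break
  }
  comp <- components_of(M > 1e-6 | t(M) > 1e-6)
  unname(lapply(split(ids, comp), function(x) sort(unname(x))))
}

#' Reciprocal best hits between two species
#'
#' A cross-species pair (a, b) qualifies when b attains the maximum of
#' `score(a, .)` over species B genes and a attains the maximum of
#' `score(b, .)` over species A genes. All tied best partners qualify.
#' Pairs with non-positive best scores are excluded.
#'
#' @param scores Symmetric score matrix ([score_matrix()]).
#' @param species_map Named character vector, gene id to species tag.
#' @param species_a,species_b The two species tags.
#' @return Data frame with columns `a`, `b` (ids from species A and B).
#' @export
reciprocal_best_hits <- function(scores, species_map, species_a, species_b) {
  ids_a <- names(species_map)[species_map == species_a]
  ids_b <- names(species_map)[species_map == species_b]
  ids_a <- intersect(ids_a, rownames(scores))
  ids_b <- intersect(ids_b, rownames(scores))
  out <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
  if (!length(ids_a) || !length(ids_b)) return(out)
  best_of <- function(id, pool) {
    sc <- scores[id, pool]
    mx <- max(sc)
    if (mx <= 0) return(character(0))
    pool[sc == mx]
  }
  for (a in ids_a) {
    for (b in best_of(a, ids_b)) {
      if (a %in% best_of(b, ids_a))
        out <- rbind(out, data.frame(a = a, b = b, stringsAsFactors = FALSE))
    }
  }
  out
}

rbh_all_pairs <- function(scores, species_map) {
  sps <- unique(species_map)
  keys <- character()
  if (length(sps) >= 2) {
    for (i in seq_len(length(sps) - 1)) for (j in seq(i + 1, length(sps))) {
      r <- reciprocal_best_hits(scores, species_map, sps[i], sps[j])
      if (nrow(r))
        keys <- c(keys, paste(pmin(r$a, r$b), pmax(r$a, r$b), sep = "\r"))
    }
  }
  unique(keys)
}

#' Type the gene pairs within homolog clusters
#'
#' Every unordered within-cluster pair receives exactly one type:
#' `paralog` for same-species pairs, `ortholog` for cross-species reciprocal
#' best hits, `coortholog` for the remaining cross-species pairs.
#'
#' @param clusters List of id vectors ([mcl()]).
#' @param species_map Named character vector, id to species.
#' @param rbh Either a data frame of RBH pairs (columns `a`, `b`) or the
#'   score matrix from which RBHs are computed for every species pair.
#' @return Data frame with columns `a`, `b`, `type` (one row per unordered
#'   pair, `a < b` lexicographically).
#' @export
call_pair_types <- function(clusters, species_map, rbh) {
  rbh_keys <- if (is.matrix(rbh)) rbh_all_pairs(rbh, species_map)
  else if (nrow(rbh)) unique(paste(pmin(rbh$a, rbh$b), pmax(rbh$a, rbh$b),
                                   sep = "\r"))
  else character(0)
  rows <- list()
  for (cl in clusters) {
    if (length(cl) < 2) next
    prs <- combn(sort(cl), 2)
    for (k in seq_len(ncol(prs))) {
      a <- prs[1, k]; b <- prs[2, k]
      type <- if (species_map[[a]] == species_map[[b]]) "paralog"
      else if (paste(a, b, sep = "\r") %in% rbh_keys) "ortholog"
      else "coortholog"
      rows[[length(rows) + 1L]] <- data.frame(a = a, b = b, type = type,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(a = character(), b = character(), type = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Species-by-species pair-count table
#'
#' Arranges typed pairs as a pair table: the diagonal holds per-species
#' paralog counts; each off-diagonal species pair holds its ortholog and
#' coortholog counts (stored as symmetric matrices).
#'
#' @param typed_pairs Data frame from [call_pair_types()].
#' @param species_map Named character vector, id to species.
#' @param species_order Species in display order.
#' @return A `pair_table`: list with `species`, `paralog` (named vector),
#'   `ortholog` and `coortholog` (symmetric matrices).
#' @export
pair_count_table <- function(typed_pairs, species_map, species_order) {
  n <- length(species_order)
  paralog <- setNames(numeric(n), species_order)
  ortho <- matrix(0, n, n, dimnames = list(species_order, species_order))
  co <- matrix(0, n, n, dimnames = list(species_order, species_order))
  for (k in seq_len(nrow(typed_pairs))) {
    sa <- species_map[[typed_pairs$a[k]]]
    sb <- species_map[[typed_pairs$b[k]]]
    switch(typed_pairs$type[k],
           paralog = { paralog[sa] <- paralog[sa] + 1 },
           ortholog = { ortho[sa, sb] <- ortho[sa, sb] + 1
                        if (sa != sb) ortho[sb, sa] <- ortho[sa, sb] },
           coortholog = { co[sa, sb] <- co[sa, sb] + 1
                          if (sa != sb) co[sb, sa] <- co[sa, sb] })
  }
  structure(list(species = species_order, paralog = paralog,
                 ortholog = ortho, coortholog = co),
            class = "pair_table")
}

#' Total paralog / ortholog / coortholog pair counts
#'
#' Sums a [pair_count_table()] (or the packaged fixture from
#' [load_table2()]): paralogs over the diagonal, orthologs and coorthologs
#' over the unordered off-diagonal species pairs.
#'
#' @param pt A `pair_table`.
#' @return Named numeric vector `paralog`, `ortholog`, `coortholog`.
#' @export
aggregate_pair_totals <- function(pt) {
  stopifnot(inherits(pt, "pair_table"))
  lower <- lower.tri(pt$ortholog)
  c(paralog = sum(pt$paralog),
    ortholog = sum(pt$ortholog[lower]),
    coortholog = sum(pt$coortholog[lower]))
}

#' @export
print.pair_table <- function(x, ...) {
  n <- length(x$species)
  m <- matrix("", n, n, dimnames = list(x$species, x$species))
  diag(m) <- as.character(x$paralog)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i > j)
    m[i, j] <- paste0(x$ortholog[i, j], "/", x$coortholog[i, j])
  print(m, quote = FALSE)
  invisible(x)
}

#' WRKY gene density per megabase
#'
#' @param count Number of WRKY genes.
#' @param genome_size_mb Genome size in Mb.
#' @return `count / genome_size_mb`, rounded to 4 decimals.
#' @export
wrky_density <- function(count, genome_size_mb) {
  if (genome_size_mb <= 0) stop_config("genome size must be positive")
  round(count / genome_size_mb, 4)
}
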