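# End-to-end orchestration. Each runner validates its configuration up
# front (unknown keys are rejected; missing inputs are config errors raised
# before any computation), logs the config hash and seed to stderr, writes
# data only to files under `outdir` (when given), and returns the results
# invisibly structured. The runners, together with the exported
# stage functions, are the package's operational interface.

validate_config <- function(config, required, optional) {
  if (!is.list(config)) stop_config("config must be a list")
  unknown <- setdiff(names(config), c(required, optional))
  if (length(unknown))
    stop_config("unknown config keys: ", paste(unknown, collapse = ", "))
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop_config("missing config keys: ", paste(missing, collapse = ", "))
  for (key in intersect(names(config), c("fasta", "counts", "lengths", "ct",
                                         "candidates", "species"))) {
    v <- config[[key]]
    if (is.character(v) && length(v) == 1 && !file.exists(v))
      stop_config("config key '", key, "': file not found: ", v)
  }
  invisible(config)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(md5sum(f))
}

log_run <- function(stage, config) {
  message(sprintf("[wrkyfam] %s: config %s seed %s", stage,
                  config_hash(config), config$seed %||% "none"))
}

ensure_outdir <- function(outdir) {
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  outdir
}

#' Run the identification and characterization stage
#'
#' Scans the input proteins for WRKY domains, classifies them into groups
#' and subgroups, computes physicochemical profiles and summarizes the
#' family.
#'
#' @param config List with keys `fasta` (path or a records data frame),
#'   `references` (a labeled reference data frame, e.g.
#'   [gen_reference_set()]), and optionally `profile`
#'   (`"default"`/`"strict"`), `variants`, `bootstrap`, `seed`, `outdir`.
#' @return List with `family` (the family table), `physchem`, `summary`
#'   and `report` (the JSON-ready report list). With `outdir` set, writes
#'   `family.tsv`, `physchem.tsv` and `report.json`.
#' @export
run_identify <- function(config) {
  validate_config(config, required = c("fasta", "references"),
                  optional = c("profile", "variants", "bootstrap", "seed",
                               "outdir"))
  log_run("identify", config)
  records <- if (is.character(config$fasta)) read_fasta(config$fasta)
  else config$fasta
  ps <- wrky_pattern_space(config$profile %||% "default")
  fam <- classify_family(records, config$references, pattern_space = ps,
                         variant_set = config$variants %||% wrky_variants(),
                         bootstrap = config$bootstrap %||% 0,
                         seed = config$seed %||% 1)
  phys <- if (nrow(records))
    cbind(gene_id = records$id,
          do.call(rbind, lapply(records$sequence, physchem_profile)))
  else data.frame()
  summ <- if (nrow(fam)) summarize_family(fam) else
    list(n = 0, group_counts = c(I = 0, II = 0, III = 0, unclassified = 0),
         subgroup_counts = numeric(0), variant_counts = numeric(0))
  report <- list(n_proteins = nrow(records),
                 group_counts = as.list(summ$group_counts),
                 subgroup_counts = as.list(summ$subgroup_counts),
                 variant_counts = as.list(summ$variant_counts),
                 length_stats = if (nrow(fam))
                   list(min = summ$length_min, max = summ$length_max,
                        mean = summ$length_mean) else NULL,
                 seed = config$seed %||% 1)
  outdir <- ensure_outdir(config$outdir)
  if (!is.null(outdir)) {
    write.table(fam, file.path(outdir, "family.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(records))
      write.table(phys, file.path(outdir, "physchem.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(family = fam, physchem = phys, summary = summ,
                 report = report))
}

#' Run the homology stage
#'
#' All-vs-all local alignment, similarity graph construction, Markov
#' clustering, reciprocal-best-hit orthology and typed pair tallies.
#'
#' @param config List with keys `fasta` (path or records data frame),
#'   `species` (path to a two-column id/species TSV, or a named vector;
#'   defaults to the records' `species` column), and optionally `inflation`,
#'   `cutoff`, `outdir`, `seed`.
#' @return List with `clusters`, `typed_pairs`, `pair_table`, `totals`.
#'   With `outdir` set, writes `clusters.tsv`, `pairs.tsv`,
#'   `pair_table.tsv`.
#' @export
run_homology <- function(config) {
  validate_config(config, required = "fasta",
                  optional = c("species", "inflation", "cutoff", "outdir",
                               "seed"))
  log_run("homology", config)
  records <- if (is.character(config$fasta)) read_fasta(config$fasta)
  else config$fasta
  species_map <- if (is.null(config$species)) {
    setNames(records$species, records$id)
  } else if (is.character(config$species) && length(config$species) == 1) {
    sm <- read.delim(config$species, stringsAsFactors = FALSE)
    setNames(sm[[2]], sm[[1]])
  } else config$species
  if (any(is.na(species_map[records$id])))
    stop_config("every record needs a species tag")
  records$species <- unname(species_map[records$id])
  scores <- score_matrix(records)
  graph <- build_similarity_graph(records, cutoff = config$cutoff %||% 0.3,
                                  scores = scores)
  clusters <- mcl(graph, inflation = config$inflation %||% 1.5)
  typed <- call_pair_types(clusters, species_map, scores)
  species_order <- unique(records$species)
  pt <- pair_count_table(typed, species_map, species_order)
  totals <- aggregate_pair_totals(pt)
  outdir <- ensure_outdir(config$outdir)
  if (!is.null(outdir)) {
    cl_df <- data.frame(
      cluster = rep(seq_along(clusters), lengths(clusters)),
      id = unlist(clusters))
    write.table(cl_df, file.path(outdir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(typed, file.path(outdir, "pairs.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    m <- matrix("", length(species_order), length(species_order),
                dimnames = list(species_order, species_order))
    diag(m) <- as.character(pt$paralog)
    for (i in seq_along(species_order)) for (j in seq_len(i - 1))
      m[i, j] <- paste0(pt$ortholog[i, j], "/", pt$coortholog[i, j])
    df <- data.frame(species = rownames(m), m, check.names = FALSE)
    write.table(df, file.path(outdir, "pair_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(clusters = clusters, typed_pairs = typed, pair_table = pt,
                 totals = totals))
}

#' Run the expression stage
#'
#' RPKM quantification, optional qPCR fold changes and optional signed
#' co-expression network over candidate edges.
#'
#' @param config List with keys `counts` (TSV path or counts matrix),
#'   `lengths` (two-column TSV path or named vector), and optionally
#'   `mapped_totals` (named vector), `ct` (TSV path or Ct data frame),
#'   `calibrator`, `candidates` (TSV path or data frame with columns
#'   `a`, `b`), `outdir`, `seed`.
#' @return List with `rpkm` ([rpkm_matrix()] output), `folds` (or NULL) and
#'   `network` (or NULL) plus `sign_counts`. With `outdir` set, writes
#'   `rpkm.tsv`, `rpkm_log2.tsv`, `folds.tsv`, `network.tsv`.
#' @export
run_expression <- function(config) {
  validate_config(config, required = c("counts", "lengths"),
                  optional = c("mapped_totals", "ct", "calibrator",
                               "candidates", "outdir", "seed"))
  log_run("expression", config)
  counts <- if (is.character(config$counts)) read_tsv_matrix(config$counts)
  else config$counts
  lens <- if (is.character(config$lengths)) {
    df <- read.delim(config$lengths, stringsAsFactors = FALSE)
    setNames(df[[2]], df[[1]])
  } else config$lengths
  em <- expression_matrix(counts, lens,
                          config$mapped_totals %||% colSums(counts))
  rp <- rpkm_matrix(em)
  folds <- NULL
  if (!is.null(config$ct)) {
    ct <- if (is.character(config$ct)) read.delim(config$ct,
                                                  stringsAsFactors = FALSE)
    else config$ct
    folds <- ddct_fold_change(ct, calibrator = config$calibrator %||% "control")
  }
  network <- NULL; sign_counts <- NULL
  if (!is.null(config$candidates)) {
    cand <- if (is.character(config$candidates))
      read.delim(config$candidates, stringsAsFactors = FALSE)
    else config$candidates
    network <- coexpression_network(rp$rpkm, cand)
    sign_counts <- attr(network, "sign_counts")
  }
  outdir <- ensure_outdir(config$outdir)
  if (!is.null(outdir)) {
    write_tsv_matrix(rp$rpkm, file.path(outdir, "rpkm.tsv"))
    write_tsv_matrix(rp$log2, file.path(outdir, "rpkm_log2.tsv"))
    if (!is.null(folds))
      write.table(folds, file.path(outdir, "folds.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(network))
      write.table(network, file.path(outdir, "network.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  invisible(list(rpkm = rp, folds = folds, network = network,
                 sign_counts = sign_counts))
}
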