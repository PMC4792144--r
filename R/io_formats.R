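#' Read protein records from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and returns a plain data frame of
#' protein records. The header line is split on whitespace: the first token
#' becomes the record id; a `species=TAG` token, if present, sets the species
#' tag (otherwise `NA`).
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id`, `species`, `sequence` (upper-case
#'   amino acids). One row per record, order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">p1 species=Dca", "WRKYGQK", ">p2", "MKV"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop_format("malformed FASTA in ", path,
                                                  ": ", conditionMessage(e)))
  if (length(set) == 0)
    return(data.frame(id = character(), species = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  headers <- names(set)
  toks <- strsplit(headers, "\\s+")
  ids <- vapply(toks, `[`, character(1), 1)
  species <- vapply(toks, function(tk) {
    sp <- grep("^species=", tk, value = TRUE)
    if (length(sp)) sub("^species=", "", sp[1]) else NA_character_
  }, character(1))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids)) || any(is.na(ids)))
    stop_format("malformed FASTA header in ", path)
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop_format("empty sequence for record '", ids[empty[1]], "' in ", path)
  if (anyDuplicated(ids))
    stop_format("duplicate record id '", ids[anyDuplicated(ids)], "' in ", path)
  data.frame(id = ids, species = species, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#'
#' @param records Data frame with `id`, `sequence` and optionally `species`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- records$id
  if (!is.null(records$species)) {
    has_sp <- !is.na(records$species)
    headers[has_sp] <- paste0(headers[has_sp], " species=", records$species[has_sp])
  }
  set <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read gene models (exon structures) from a GFF3 file
#'
#' Parses exon features with [rtracklayer::import()] and groups them by their
#' `Parent` attribute. Coordinates are GFF3 1-based inclusive, kept as written;
#' exons are sorted by start within each model.
#'
#' @param path Path to a GFF3 file containing `exon` features with `Parent`
#'   attributes.
#' @return A named list of gene models; each model is a list with `gene_id`,
#'   `strand` (`"+"` or `"-"`) and `exons`, a two-column matrix of
#'   (start, end) rows sorted ascending.
#' @export
read_gff3_gene_models <- function(path) {
  if (!file.exists(path)) stop_format("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop_format("malformed GFF3 in ", path,
                                                 ": ", conditionMessage(e)))
  ex <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(ex) == 0) return(list())
  parents <- ex$Parent
  np <- vapply(parents, length, integer(1))
  if (any(np == 0)) {
    i <- which(np == 0)[1]
    stop_format("exon without resolvable Parent at ", as.character(ex[i]))
  }
  parent1 <- vapply(parents, `[`, character(1), 1)
  out <- list()
  for (pid in unique(parent1)) {
    sub <- ex[parent1 == pid]
    o <- order(GenomicRanges::start(sub))
    starts <- GenomicRanges::start(sub)[o]
    ends <- GenomicRanges::end(sub)[o]
    strand <- unique(as.character(GenomicRanges::strand(sub)))
    if (length(strand) != 1 || !strand %in% c("+", "-"))
      stop_format("gene model '", pid, "' lacks a consistent +/- strand")
    if (any(starts > ends))
      stop_format("gene model '", pid, "' has an exon with start > end")
    if (length(starts) > 1 && any(starts[-1] <= ends[-length(ends)]))
      stop_format("gene model '", pid, "' has overlapping exons")
    out[[pid]] <- gene_model(pid, strand, cbind(start = starts, end = ends))
  }
  out
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix of 1-based inclusive (start, end) rows.
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (!strand %in% c("+", "-")) stop_format("strand must be '+' or '-'")
  if (nrow(exons) == 0) stop_format("gene model needs at least one exon")
  o <- order(exons[, "start"])
  exons <- exons[o, , drop = FALSE]
  if (any(exons[, "start"] > exons[, "end"]))
    stop_format("exon with start > end in '", gene_id, "'")
  if (nrow(exons) > 1 && any(exons[-1, "start"] <= exons[-nrow(exons), "end"]))
    stop_format("overlapping exons in '", gene_id, "'")
  structure(list(gene_id = gene_id, strand = strand, exons = exons),
            class = "gene_model")
}

#' Write gene models to GFF3
#'
#' Emits one `gene` feature and its `exon` children per model, suitable for
#' round-tripping through [read_gff3_gene_models()].
#'
#' @param models List of `gene_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_gene_models <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- range(m$exons)
    lines <- c(lines,
               paste("chr1", "wrkyfam", "gene", span[1], span[2], ".",
                     m$strand, ".", paste0("ID=", m$gene_id), sep = "\t"))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines,
                 paste("chr1", "wrkyfam", "exon",
                       m$exons[i, "start"], m$exons[i, "end"], ".",
                       m$strand, ".",
                       paste0("ID=", m$gene_id, ".e", i, ";Parent=", m$gene_id),
                       sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a phylogenetic tree to Newick
#'
#' @param tree An [ape::phylo] tree with finite branch lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop_format("tree must be a 'phylo' object")
  if (!is.null(tree$edge.length) && any(!is.finite(tree$edge.length)))
    stop_format("non-finite branch length; refusing to serialize")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write / read a weighted edge list as TSV
#'
#' @param edges Data frame with columns `from`, `to`, `weight`.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the edge data
#'   frame.
#' @export
write_edge_list <- function(edges, path) {
  if (nrow(edges) && any(!is.finite(edges$weight)))
    stop_format("non-finite edge weight; refusing to serialize")
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a numeric matrix as TSV with row and column names
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return For the writer, `path` invisibly; for the reader, the matrix.
#' @export
write_tsv_matrix <- function(m, path) {
  if (any(!is.finite(m))) stop_format("non-finite matrix value; refusing to serialize")
  df <- data.frame(row = rownames(m) %||% as.character(seq_len(nrow(m))),
                   m, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
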