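# Packaged transcriptions of the published carrot WRKY family table and of
# the nine-species homolog pair-count table. Values are stored exactly as
# printed, including internally inconsistent rows (e.g. group labels that
# contradict the printed zinc-finger pattern); no loader resolves those
# conflicts. Integrity is enforced by an md5 checksum of the shipped TSV.

TABLE1_MD5 <- "2fd3a3b21f18248fbb78d8e8e9590d3d"
TABLE2_MD5 <- "4423fab5466e970f78bbaa0286e7eead"

fixture_path <- function(fn) {
  p <- system.file("extdata", fn, package = "wrkyfam")
  if (!nzchar(p)) stop_format("packaged fixture '", fn, "' not found")
  p
}

check_fixture <- function(path, expected) {
  got <- unname(md5sum(path))
  if (!identical(got, expected))
    stop_format("fixture checksum mismatch for ", basename(path),
                " (got ", got, ", expected ", expected, ")")
}

#' Load the packaged carrot WRKY family table
#'
#' Returns the 95-gene family table (gene name, ORF length in amino acids,
#' group label, conserved heptapeptide, printed zinc-finger domain pattern,
#' best Arabidopsis hit and locus, stress annotation) exactly as transcribed
#' from print. Domain-pattern strings are stored verbatim and are interpreted
#' only by [parse_signature()].
#'
#' @return A data frame with 95 rows and columns `gene_name`, `orf_len_aa`,
#'   `group`, `conserved_motif`, `domain_pattern`, `best_hit_name`,
#'   `best_hit_locus`, `stress_response`.
#' @examples
#' t1 <- load_table1()
#' subset(t1, gene_name == "DcWRKY9")
#' @export
load_table1 <- function() {
  p <- fixture_path("table1_dcwrky.tsv")
  check_fixture(p, TABLE1_MD5)
  df <- read.delim(p, stringsAsFactors = FALSE)
  stopifnot(nrow(df) == 95,
            all(df$group %in% c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")))
  df
}

#' Load the packaged nine-species homolog pair-count table
#'
#' The lower-triangular table of paralogous (diagonal), orthologous and
#' coorthologous (off-diagonal, printed `ortholog/coortholog`) WRKY gene pair
#' counts across nine plant species, parsed into a [pair_table] object.
#'
#' @return A `pair_table` with species order Cre, Ppa, Smo, Pab, Ath, Dca,
#'   Vvi, Mdo, Osa; see [pair_count_table()] for the structure.
#' @examples
#' t2 <- load_table2()
#' aggregate_pair_totals(t2)
#' @export
load_table2 <- function() {
  p <- fixture_path("table2_homolog_pairs.tsv")
  check_fixture(p, TABLE2_MD5)
  raw <- read.delim(p, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = "character")
  species <- raw$species
  stopifnot(identical(colnames(raw)[-1], species))
  n <- length(species)
  paralog <- setNames(numeric(n), species)
  ortho <- matrix(0, n, n, dimnames = list(species, species))
  co <- matrix(0, n, n, dimnames = list(species, species))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    cell <- trimws(raw[i, j + 1])
    if (!nzchar(cell)) stop_format("empty lower-triangular cell (", i, ",", j, ")")
    if (i == j) {
      paralog[i] <- as.numeric(cell)
    } else {
      parts <- strsplit(cell, "/", fixed = TRUE)[[1]]
      if (length(parts) != 2)
        stop_format("cell '", cell, "' is not 'ortholog/coortholog'")
      ortho[i, j] <- as.numeric(parts[1]); ortho[j, i] <- ortho[i, j]
      co[i, j] <- as.numeric(parts[2]); co[j, i] <- co[i, j]
    }
  }
  if (any(paralog < 0) || any(ortho < 0) || any(co < 0))
    stop_format("negative pair count in fixture")
  structure(list(species = species, paralog = paralog,
                 ortholog = ortho, coortholog = co),
            class = "pair_table")
}
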