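# Pairwise alignment wrappers. All alignments use BLOSUM62 with affine gaps:
# a gap of length L costs open + L * extend (open 11, extend 1). Alignment
# itself is delegated to Biostrings; everything downstream (identity,
# center-star merging, p-distances) is computed here.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

align_pair <- function(a, b, type = "global", gap_open = 11, gap_extend = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, type = type)
  list(score = Biostrings::score(aln),
       a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Global alignment score
#'
#' Needleman-Wunsch score with BLOSUM62 and affine gaps (a gap of length L
#' costs `gap_open + L * gap_extend`).
#'
#' @param a,b Amino-acid strings.
#' @param gap_open,gap_extend Affine gap parameters (defaults 11 and 1).
#' @return Numeric score.
#' @export
global_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  check_protein_sequence(a); check_protein_sequence(b)
  align_pair(a, b, "global", gap_open, gap_extend)$score
}

#' Smith-Waterman local alignment score
#'
#' Local alignment score with BLOSUM62 and affine gaps; the empty alignment
#' scores 0, so the result is never negative. Symmetric in its arguments.
#'
#' @inheritParams global_align_score
#' @return Numeric score, `>= 0`.
#' @export
local_align_score <- function(a, b, gap_open = 11, gap_extend = 1) {
  check_protein_sequence(a); check_protein_sequence(b)
  max(0, align_pair(a, b, "local", gap_open, gap_extend)$score)
}

#' Pairwise sequence identity from global alignment
#'
#' Globally aligns the two sequences and returns the fraction of identical
#' residues over aligned columns in which both rows carry a residue. Columns
#' where either row is gapped are excluded from the denominator; the
#' ambiguity code `X` never counts as a match. Returns 0 when no column has
#' residues in both rows.
#'
#' @inheritParams global_align_score
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, gap_open = 11, gap_extend = 1) {
  check_protein_sequence(a); check_protein_sequence(b)
  aln <- align_pair(a, b, "global", gap_open, gap_extend)
  ca <- strsplit(aln$a, "")[[1]]
  cb <- strsplit(aln$b, "")[[1]]
  both <- ca != "-" & cb != "-"
  if (!any(both)) return(0)
  sum(ca[both] == cb[both] & ca[both] != "X") / sum(both)
}

# decompose a pairwise alignment of seq against the anchor into, per anchor
# position, the residue aligned to it plus the insertion that follows it
# (slot 0 = insertion before the first anchor residue)
anchor_decompose <- function(aln_anchor, aln_seq) {
  ca <- strsplit(aln_anchor, "")[[1]]
  cs <- strsplit(aln_seq, "")[[1]]
  n_anchor <- sum(ca != "-")
  residue <- character(n_anchor)
  ins <- character(n_anchor + 1)
  ins[] <- ""
  k <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == "-") {
      ins[k + 1L] <- paste0(ins[k + 1L], cs[i])
    } else {
      k <- k + 1L
      residue[k] <- cs[i]
    }
  }
  list(residue = residue, ins = ins)
}

#' Center-star multiple alignment
#'
#' Builds a multiple alignment by aligning every sequence to a designated
#' anchor and merging the pairwise alignments on anchor coordinates:
#' insertions relative to the anchor open gap columns in all other rows.
#' This is the classical center-star construction; all rows have equal
#' length, at least the anchor's.
#'
#' @param sequences Named character vector of amino-acid strings.
#' @param anchor_id Name of the anchor sequence; must be present.
#' @return Named character vector of equal-length aligned rows (gap `"-"`),
#'   in the input order.
#' @export
center_star_msa <- function(sequences, anchor_id) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop_config("sequences must be uniquely named")
  if (!anchor_id %in% names(sequences))
    stop_config("anchor '", anchor_id, "' not in sequence set")
  anchor <- sequences[[anchor_id]]
  n_anchor <- nchar(anchor)
  others <- setdiff(names(sequences), anchor_id)
  dec <- lapply(others, function(id) {
    aln <- align_pair(anchor, sequences[[id]], "global")
    anchor_decompose(aln$a, aln$b)
  })
  names(dec) <- others
  max_ins <- rep(0L, n_anchor + 1)
  for (d in dec) max_ins <- pmax(max_ins, nchar(d$ins))
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  build_row <- function(residue, ins) {
    pieces <- character(2 * n_anchor + 1)
    pieces[1] <- pad(ins[1], max_ins[1])
    for (k in seq_len(n_anchor)) {
      pieces[2 * k] <- residue[k]
      pieces[2 * k + 1] <- pad(ins[k + 1], max_ins[k + 1])
    }
    paste(pieces, collapse = "")
  }
  out <- setNames(character(length(sequences)), names(sequences))
  out[anchor_id] <- build_row(strsplit(anchor, "")[[1]],
                              rep("", n_anchor + 1))
  for (id in others) out[id] <- build_row(dec[[id]]$residue, dec[[id]]$ins)
  out[names(sequences)]
}

#' p-distance matrix from a multiple alignment
#'
#' `d(i, j)` is the fraction of differing residues over columns where both
#' rows are ungapped (the p-distance). A pair with zero comparable columns is
#' an error.
#'
#' @param msa Named character vector of equal-length aligned rows.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pdistance_matrix <- function(msa) {
  if (length(unique(nchar(msa))) != 1) stop_format("MSA rows differ in length")
  chars <- do.call(rbind, strsplit(msa, ""))
  n <- length(msa)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    both <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(both))
      stop_format("rows '", names(msa)[i], "' and '", names(msa)[j],
                  "' share no comparable columns")
    d[i, j] <- d[j, i] <- mean(chars[i, both] != chars[j, both])
  }
  d
}
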