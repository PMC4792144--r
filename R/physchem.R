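# Physicochemical descriptors re-derived from their published closed forms:
# isoelectric point by bisection on the Henderson-Hasselbalch net charge,
# GRAVY as the mean Kyte-Doolittle hydropathy, the instability index as the
# length-normalised sum of dipeptide instability weights, and the aliphatic
# index from the mole percentages of A, V, I and L. Residues outside the
# 20-letter alphabet (e.g. X) carry no weight in any descriptor.

# Kyte & Doolittle (1982) hydropathy scale
KD_SCALE <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2)

# Bjellqvist pKa set: side chains plus free termini
PKA_POS <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
PKA_NEG <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)

# dipeptide instability weight values (Guruprasad et al. 1990);
# rows = first residue of the pair, columns = second residue
INSTAB_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
DIWV <- matrix(c(
  1, 44.94, -7.49, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 1,
  1, 1, 20.26, 1, 1, 1, 33.6, 1, 1, 20.26, 33.6, 1, 20.26, -6.54, 1, 1, 33.6, -6.54, 24.68, 1,
  1, 1, 1, 1, -6.54, 1, 1, 1, -7.49, 1, 1, 1, 1, 1, -6.54, 20.26, -14.03, 1, 1, 1,
  1, 44.94, 20.26, 33.6, 1, 1, -6.54, 20.26, 1, 1, 1, 1, 20.26, 20.26, 1, 20.26, 1, 1, -14.03, 1,
  1, 1, 13.34, 1, 1, 1, 1, 1, -14.03, 1, 1, 1, 20.26, 1, 1, 1, 1, 1, 1, 33.601,
  -7.49, 1, 1, -6.54, 1, 13.34, 1, -7.49, -7.49, 1, 1, -7.49, 1, 1, 1, 1, -7.49, 1, 13.34, -7.49,
  1, 1, 1, 1, -9.37, -9.37, 1, 44.94, 24.68, 1, 1, 24.68, -1.88, 1, 1, 1, -6.54, 1, -1.88, 44.94,
  1, 1, 1, 44.94, 1, 1, 13.34, 1, -7.49, 20.26, 1, 1, -1.88, 1, 1, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, -7.49, 1, -7.49, 1, -7.49, 33.6, 1, -6.54, 24.64, 33.6, 1, 1, -7.49, 1, 1,
  1, 1, 1, 1, 1, 1, 1, 1, -7.49, 1, 1, 1, 20.26, 33.6, 20.26, 1, 1, 1, 24.68, 1,
  13.34, 1, 1, 1, 1, 1, 58.28, 1, 1, 1, -1.88, 1, 44.94, -6.54, -6.54, 44.94, -1.88, 1, 1, 24.68,
  1, -1.88, 1, 1, -14.03, -14.03, 1, 44.94, 24.68, 1, 1, 1, -1.88, -6.54, 1, 1, -7.49, 1, -9.37, 1,
  20.26, -6.54, -6.54, 18.38, 20.26, 1, 1, 1, 1, 1, -6.54, 1, 20.26, 20.26, -6.54, 20.26, 1, 20.26, -1.88, 1,
  1, -6.54, 20.26, 20.26, -6.54, 1, 1, 1, 1, 1, 1, 1, 20.26, 20.26, 1, 44.94, 1, -6.54, 1, -6.54,
  1, 1, 1, 1, 1, -7.49, 20.26, 1, 1, 1, 1, 13.34, 20.26, 20.26, 58.28, 44.94, 1, 1, 58.28, -6.54,
  1, 33.6, 1, 20.26, 1, 1, 1, 1, 1, 1, 1, 1, 44.94, 20.26, 20.26, 20.26, 1, 1, 1, 1,
  1, 1, 1, 20.26, 13.34, -7.49, 1, 1, 1, 1, 1, -14.03, 1, -6.54, 1, 1, 1, 1, -14.03, 1,
  1, 1, -14.03, 1, 1, -7.49, 1, 1, -1.88, 1, 1, 1, 20.26, 1, 1, 1, -7.49, 1, 1, -6.54,
  -14.03, 1, 1, 1, 1, -9.37, 24.68, 1, 1, 13.34, 24.68, 13.34, 1, 1, 1, 1, -14.03, -7.49, 1, 1,
  24.68, 1, 24.68, -6.54, 1, -7.49, 13.34, 1, 1, 1, 44.94, 1, 13.34, 1, -15.91, 1, -7.49, 1, -9.37, 13.34
), nrow = 20, byrow = TRUE, dimnames = list(INSTAB_AA, INSTAB_AA))

aa_counts <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  vapply(AA20, function(a) sum(chars == a), 0)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: the free termini plus
#' K, R, H (basic) and D, E, C, Y (acidic), using the bundled Bjellqvist pKa
#' set (`wrkyfam:::PKA_POS`, `wrkyfam:::PKA_NEG`).
#'
#' @param sequence Amino-acid string.
#' @param pH pH value (may be a vector).
#' @return Net charge (same length as `pH`).
#' @export
net_charge <- function(sequence, pH) {
  check_protein_sequence(sequence)
  cnt <- aa_counts(sequence)
  npos <- c(Nterm = 1, cnt[c("K", "R", "H")])
  nneg <- c(Cterm = 1, cnt[c("D", "E", "C", "Y")])
  pos_pka <- PKA_POS[names(npos)]
  neg_pka <- PKA_NEG[names(nneg)]
  vapply(pH, function(p) {
    sum(npos / (1 + 10^(p - pos_pka))) - sum(nneg / (1 + 10^(neg_pka - p)))
  }, 0)
}

#' Theoretical isoelectric point
#'
#' The pH at which [net_charge()] crosses zero, found by bisection on
#' `[0, 14]` to an interval width below `tol`. The net charge is strictly
#' decreasing in pH and is positive at pH 0 and negative at pH 14 for any
#' peptide (the termini always ionize), so the root exists and is unique.
#'
#' @param sequence Amino-acid string.
#' @param tol Bisection tolerance on pH (default `1e-6`, well below the
#'   `1e-3` the descriptor is quoted at).
#' @return The pI, in (0, 14).
#' @export
isoelectric_point <- function(sequence, tol = 1e-6) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues that carry a scale value.
#'
#' @param sequence Amino-acid string.
#' @return Mean hydropathy.
#' @export
gravy <- function(sequence) {
  check_protein_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  vals <- KD_SCALE[chars]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop_format("no residues with a hydropathy value")
  mean(vals)
}

#' Instability index
#'
#' `(10 / L) * sum` of the dipeptide instability weights over all adjacent
#' residue pairs, where `L` is the sequence length. Values below 40 classify
#' the protein as stable. A length-1 sequence has no dipeptides and scores 0.
#'
#' @param sequence Amino-acid string.
#' @return List with `value` and `stable` (`value < 40`).
#' @export
instability_index <- function(sequence) {
  check_protein_sequence(sequence)
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  if (L < 2) return(list(value = 0, stable = TRUE))
  a <- chars[-L]; b <- chars[-1]
  ok <- a %in% INSTAB_AA & b %in% INSTAB_AA
  val <- 10 / L * sum(DIWV[cbind(a[ok], b[ok])])
  list(value = val, stable = val < 40)
}

#' Aliphatic index
#'
#' `X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` where `X(aa)` is the mole
#' percentage of the residue over the whole sequence length.
#'
#' @param sequence Amino-acid string.
#' @return Aliphatic index (poly-A scores 100, poly-V 290).
#' @export
aliphatic_index <- function(sequence) {
  check_protein_sequence(sequence)
  cnt <- aa_counts(sequence)
  molepct <- cnt / nchar(sequence) * 100
  unname(molepct["A"] + 2.9 * molepct["V"] + 3.9 * (molepct["I"] + molepct["L"]))
}

#' Residue class percentages
#'
#' Percentages (of total length) of positively charged (K, R, H), negatively
#' charged (D, E), aliphatic (A, V, I, L, optionally G) and aromatic
#' (F, W, Y) residues.
#'
#' @param sequence Amino-acid string.
#' @param aliphatic_includes_glycine Whether G counts as aliphatic for the
#'   composition statistic (default FALSE; the aliphatic *index* always uses
#'   A, V, I, L).
#' @return Named numeric vector `positive`, `negative`, `aliphatic`,
#'   `aromatic`, each in `[0, 100]`.
#' @export
residue_class_percentages <- function(sequence, aliphatic_includes_glycine = FALSE) {
  check_protein_sequence(sequence)
  cnt <- aa_counts(sequence)
  L <- nchar(sequence)
  ali <- c("A", "V", "I", "L", if (aliphatic_includes_glycine) "G")
  c(positive = sum(cnt[c("K", "R", "H")]),
    negative = sum(cnt[c("D", "E")]),
    aliphatic = sum(cnt[ali]),
    aromatic = sum(cnt[c("F", "W", "Y")])) / L * 100
}

#' Full physicochemical profile
#'
#' @param sequence Amino-acid string.
#' @return One-row data frame with `length`, `pI`, `gravy`,
#'   `instability_index`, `stable`, `aliphatic_index` and the four residue
#'   class percentages.
#' @export
physchem_profile <- function(sequence) {
  ii <- instability_index(sequence)
  pc <- residue_class_percentages(sequence)
  data.frame(length = nchar(sequence),
             pI = isoelectric_point(sequence),
             gravy = gravy(sequence),
             instability_index = ii$value, stable = ii$stable,
             aliphatic_index = aliphatic_index(sequence),
             pct_positive = pc[["positive"]], pct_negative = pc[["negative"]],
             pct_aliphatic = pc[["aliphatic"]], pct_aromatic = pc[["aromatic"]])
}

#' Intron count of a gene model
#'
#' @param model A [gene_model()].
#' @return `exon count - 1`.
#' @export
count_introns <- function(model) {
  nrow(model$exons) - 1L
}

#' Histogram of intron counts over gene models
#'
#' @param models List of [gene_model()] objects.
#' @return Named integer vector mapping intron count to number of genes
#'   (empty for empty input); values sum to `length(models)`.
#' @export
exon_intron_summary <- function(models) {
  if (!length(models)) return(setNames(integer(0), character(0)))
  counts <- vapply(models, count_introns, 0L)
  tab <- table(counts)
  setNames(as.integer(tab), names(tab))
}
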