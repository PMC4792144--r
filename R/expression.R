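# Expression analytics: RPKM quantification of read counts, qPCR relative
# expression by the 2^-ddCt method, and signed Pearson co-expression
# networks over externally supplied candidate interaction edges.

#' Construct an expression matrix container
#'
#' @param counts Numeric genes x samples matrix of read counts (dimnames
#'   required; counts `>= 0`).
#' @param gene_length Named numeric vector of exon-model lengths in bp
#'   (`> 0`), one per gene.
#' @param mapped_total Named numeric vector of mapped-read totals per sample
#'   (`> 0`); defaults to the column sums of `counts`.
#' @return An `expression_matrix` list.
#' @export
expression_matrix <- function(counts, gene_length, mapped_total = colSums(counts)) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_config("counts must have gene and sample dimnames")
  if (any(counts < 0)) stop_config("counts must be non-negative")
  gene_length <- gene_length[rownames(counts)]
  if (any(is.na(gene_length)) || any(gene_length <= 0))
    stop_config("every gene needs a positive exon-model length")
  if (length(mapped_total) != ncol(counts) || any(mapped_total <= 0))
    stop_config("mapped totals must be positive, one per sample")
  structure(list(counts = counts, gene_length = gene_length,
                 mapped_total = mapped_total),
            class = "expression_matrix")
}

#' Reads per kilobase of exon model per million mapped reads
#'
#' `rpkm = 1e9 * count / (mapped_total * length_bp)`.
#'
#' @param count Read count(s) for the gene.
#' @param exon_model_length_bp Exon-model length in bp.
#' @param mapped_total Total mapped reads in the library.
#' @return RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, exon_model_length_bp, mapped_total) {
  if (any(exon_model_length_bp <= 0)) stop_config("gene length must be positive")
  if (any(mapped_total <= 0)) stop_config("mapped total must be positive")
  1e9 * count / (mapped_total * exon_model_length_bp)
}

#' RPKM matrix and heatmap export
#'
#' Applies [rpkm()] per cell of an [expression_matrix()]; the heatmap export
#' is `log2(rpkm + 1)`.
#'
#' @param em An `expression_matrix`.
#' @param heatmap_path Optional TSV path for the `log2(rpkm + 1)` matrix.
#' @return List with `rpkm` and `log2` matrices.
#' @export
rpkm_matrix <- function(em, heatmap_path = NULL) {
  stopifnot(inherits(em, "expression_matrix"))
  r <- 1e9 * sweep(sweep(em$counts, 2, em$mapped_total, "/"),
                   1, em$gene_length, "/")
  l2 <- log2(r + 1)
  if (!is.null(heatmap_path)) write_tsv_matrix(l2, heatmap_path)
  list(rpkm = r, log2 = l2)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per row, `dCt = Ct_target - Ct_reference`; technical replicates (rows
#' sharing gene and condition) are averaged on the dCt scale. Then
#' `ddCt = dCt(condition) - dCt(calibrator)` and the fold change is
#' `2^-ddCt`; the calibrator condition's fold is exactly 1.
#'
#' @param ct_table Data frame with columns `gene`, `condition`, `ct_target`,
#'   `ct_reference` (one row per reaction).
#' @param calibrator Name of the calibrator condition (default
#'   `"control"`); required for every gene.
#' @return Data frame `gene`, `condition`, `dct`, `ddct`, `fold`.
#' @export
ddct_fold_change <- function(ct_table, calibrator = "control") {
  need <- c("gene", "condition", "ct_target", "ct_reference")
  if (!all(need %in% names(ct_table)))
    stop_format("ct_table must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(ct_table$ct_target)) || any(!is.finite(ct_table$ct_reference)))
    stop_format("Ct values must be finite")
  dct_rows <- ct_table$ct_target - ct_table$ct_reference
  agg <- stats::aggregate(dct_rows,
                          by = list(gene = ct_table$gene,
                                    condition = ct_table$condition),
                          FUN = mean)
  names(agg)[3] <- "dct"
  out <- list()
  for (g in unique(agg$gene)) {
    sub <- agg[agg$gene == g, ]
    cal <- sub$dct[sub$condition == calibrator]
    if (!length(cal))
      stop_format("missing calibrator condition '", calibrator,
                  "' for gene '", g, "'")
    sub$ddct <- sub$dct - cal
    sub$fold <- 2^(-sub$ddct)
    sub$fold[sub$condition == calibrator] <- 1
    out[[g]] <- sub
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pearson correlation with a not-calculable policy
#'
#' Standard Pearson r; returns `NA` when either vector is constant (zero
#' variance), mirroring expression profiles whose correlation cannot be
#' calculated.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Correlation in `[-1, 1]`, or `NA_real_`.
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y)) stop_config("x and y must have equal length")
  if (length(x) < 3) stop_config("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Signed co-expression network over candidate edges
#'
#' Annotates each externally supplied candidate interaction edge with the
#' Pearson correlation of the two genes' expression profiles and its sign.
#' Candidates with a gene absent from the expression matrix get sign `"na"`
#' (reason `"missing"`, with a warning); zero-variance profiles get sign
#' `"na"` (reason `"zero_variance"`).
#'
#' @param expr Numeric genes x samples abundance matrix (e.g.
#'   `rpkm_matrix(em)$rpkm`).
#' @param candidate_edges Data frame with columns `a`, `b` (gene ids).
#' @return Data frame `a`, `b`, `pcc`, `sign` (`"positive"`, `"negative"`,
#'   `"na"`), `na_reason`; the positive/negative/na counts are attached as
#'   attribute `"sign_counts"` and always sum to the candidate count.
#' @export
coexpression_network <- function(expr, candidate_edges) {
  n <- nrow(candidate_edges)
  out <- data.frame(a = candidate_edges$a, b = candidate_edges$b,
                    pcc = rep(NA_real_, n), sign = rep("na", n),
                    na_reason = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    a <- out$a[k]; b <- out$b[k]
    if (!a %in% rownames(expr) || !b %in% rownames(expr)) {
      out$na_reason[k] <- "missing"
      warning("candidate gene absent from expression matrix: ",
              if (a %in% rownames(expr)) b else a)
      next
    }
    r <- pcc(expr[a, ], expr[b, ])
    if (is.na(r)) {
      out$na_reason[k] <- "zero_variance"
    } else {
      out$pcc[k] <- r
      out$sign[k] <- if (r > 0) "positive" else if (r < 0) "negative" else "na"
      if (r == 0) out$na_reason[k] <- "zero_correlation"
    }
  }
  attr(out, "sign_counts") <- c(positive = sum(out$sign == "positive"),
                                negative = sum(out$sign == "negative"),
                                na = sum(out$sign == "na"))
  out
}
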