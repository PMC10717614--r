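# qPCR relative quantification (2^-ddCt against a reference gene and a
# calibrator condition), per-gene z-score matrices for heatmaps, and RNA
# purity bookkeeping.

#' Relative gene expression by the 2^-ddCt method
#'
#' For each sample, technical-replicate Ct values are averaged
#' arithmetically, then `dCt = Ct_gene - Ct_ref`. Sample dCt values are
#' averaged within condition, `ddCt = dCt_condition - dCt_calibrator`, and
#' the fold change is `2^-ddCt`. The calibrator condition's fold is exactly 1
#' for every gene, and the result is invariant to adding a constant to all
#' Ct values of a sample (the shift cancels in dCt).
#'
#' @param ct_table Long data frame with columns `sample`, `condition`,
#'   `gene`, `ct` (finite, positive) and optionally `replicate`.
#' @param ref_gene Reference gene symbol (default `"ACTB"`, beta-actin).
#' @param calibrator Calibrator condition label (default `"Xpan"`,
#'   expansion medium).
#' @return Data frame with one row per gene x condition: `gene`, `condition`,
#'   `delta_ct`, `delta_delta_ct`, `fold`.
#' @examples
#' tab <- simulate_ct_table(c(ALPL = 2.3), seed = 1)
#' delta_delta_ct(tab)
#' @export
delta_delta_ct <- function(ct_table, ref_gene = "ACTB", calibrator = "Xpan") {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns sample, condition, gene, ct",
         call. = FALSE)
  }
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    stop("Ct values must be finite and positive", call. = FALSE)
  }
  if (!calibrator %in% ct_table$condition) {
    stop(sprintf("calibrator condition '%s' not present", calibrator),
         call. = FALSE)
  }
  # replicate-average within sample x gene
  agg <- stats::aggregate(ct ~ sample + condition + gene, ct_table, mean)
  genes <- setdiff(unique(agg$gene), ref_gene)
  if (length(genes) == 0) stop("no target genes in table", call. = FALSE)
  ref <- agg[agg$gene == ref_gene, c("sample", "ct")]
  if (nrow(ref) == 0) {
    stop(sprintf("reference gene '%s' not present", ref_gene), call. = FALSE)
  }
  names(ref)[2] <- "ct_ref"
  tgt <- merge(agg[agg$gene != ref_gene, ], ref, by = "sample")
  if (nrow(tgt) < sum(agg$gene != ref_gene)) {
    stop("some samples are missing a reference-gene Ct", call. = FALSE)
  }
  tgt$delta_ct <- tgt$ct - tgt$ct_ref
  cond_dct <- stats::aggregate(delta_ct ~ condition + gene, tgt, mean)
  cal <- cond_dct[cond_dct$condition == calibrator, c("gene", "delta_ct")]
  names(cal)[2] <- "delta_ct_cal"
  out <- merge(cond_dct, cal, by = "gene")
  out$delta_delta_ct <- out$delta_ct - out$delta_ct_cal
  out$fold <- 2^(-out$delta_delta_ct)
  out$delta_ct_cal <- NULL
  out[order(out$gene, out$condition), ]
}

#' Per-gene z-score matrix for expression heatmaps
#'
#' Scales each gene (row) across samples: `z = (x - mu) / sigma` with the
#' sample (n - 1) standard deviation. Every scaled row has mean zero;
#' constant rows (sigma = 0) are returned as all zeros and flagged through
#' the `"degenerate"` attribute instead of producing NaN. Scaling is joint
#' across all samples/conditions; the orientation (genes in rows) is
#' recorded so transposed input is caught early.
#'
#' @param values Numeric matrix, genes in rows, samples in columns (>= 2
#'   columns).
#' @return Matrix of z-scores with attributes `"degenerate"` (logical per
#'   gene) and `"orientation"` (`"genes_by_samples"`).
#' @examples
#' zscore_matrix(rbind(g1 = c(1, 2, 3)))  # -1 0 1
#' @export
zscore_matrix <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) {
    stop("z-scores need at least 2 samples per gene", call. = FALSE)
  }
  mu <- rowMeans(values)
  sigma <- apply(values, 1, stats::sd)
  degenerate <- sigma == 0
  z <- (values - mu) / ifelse(degenerate, 1, sigma)
  z[degenerate, ] <- 0
  structure(z, degenerate = degenerate, orientation = "genes_by_samples")
}

#' RNA purity check from absorbance ratios
#'
#' Computes A260/A280 and A260/A230 and passes the sample when both ratios
#' fall within a tolerance band around the nominal 1.8 expected for pure
#' RNA.
#'
#' @param a260,a280,a230 Positive absorbance readings.
#' @param target Nominal ratio (default 1.8).
#' @param tol Acceptance half-width (default 0.2, i.e. ratios in
#'   `[1.6, 2.0]` pass).
#' @return An object of class `rna_qc`: `ratio_260_280`, `ratio_260_230`,
#'   `pass`.
#' @export
rna_qc <- function(a260, a280, a230, target = 1.8, tol = 0.2) {
  if (any(c(a260, a280, a230) <= 0)) {
    stop("absorbances must be positive", call. = FALSE)
  }
  r1 <- a260 / a280
  r2 <- a260 / a230
  structure(
    list(ratio_260_280 = r1, ratio_260_230 = r2,
         pass = abs(r1 - target) <= tol & abs(r2 - target) <= tol),
    class = "rna_qc"
  )
}

#' @export
print.rna_qc <- function(x, ...) {
  cat(sprintf("RNA QC: A260/A280 = %.2f, A260/A230 = %.2f -> %s\n",
              x$ratio_260_280, x$ratio_260_230,
              if (x$pass) "pass" else "fail"))
  invisible(x)
}
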