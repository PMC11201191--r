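# Gene-environment correlation (rGE) screen: the moderated-regression
# framework treats the environment as exogenous, so any SNP whose dosage
# correlates with the environment is excluded before interaction testing.

#' Pearson gene-environment correlation test
#'
#' Two-sided Pearson correlation between a genetic variable (SNP dosage or
#' CGS) and the environment, with the usual t transform
#' `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param g genetic vector (dosage or CGS).
#' @param pe environment vector.
#' @param alpha exclusion level (default 0.05).
#' @param label name recorded in the result.
#' @return one-row data.frame: `label`, `r`, `p`, `n`, `excluded`
#'   (`p < alpha`).
#' @export
pearson_rge <- function(g, pe, alpha = 0.05, label = "G") {
  if (length(g) != length(pe)) stop_input("vectors differ in length")
  keep <- !is.na(g) & !is.na(pe)
  g <- g[keep]; pe <- pe[keep]
  if (length(g) < 3) stop_input("need at least 3 complete pairs")
  if (stats::var(g) == 0 || stats::var(pe) == 0)
    stop_input(label, ": correlation undefined for a constant vector")
  ct <- stats::cor.test(g, pe, method = "pearson")
  data.frame(label = label, r = unname(ct$estimate), p = ct$p.value,
             n = length(g), excluded = ct$p.value < alpha,
             stringsAsFactors = FALSE)
}

#' Screen a SNP panel for gene-environment correlation
#'
#' Runs [pearson_rge()] for every SNP and for the CGS, excludes SNPs whose
#' correlation with the environment is significant at `alpha`, and
#' recomputes the CGS on the retained panel (dosages themselves are never
#' modified).
#'
#' @param cohort a [gxe_cohort()].
#' @param alpha exclusion level (default 0.05).
#' @return list with `results` (per-SNP rows plus a CGS row), `retained`
#'   (SNP ids kept) and `cgs_retained` (CGS recomputed on the retained
#'   panel).
#' @export
screen_panel <- function(cohort, alpha = 0.05) {
  snps <- colnames(cohort$dosages)
  if (!length(snps)) stop_input("empty SNP panel")
  pe <- cohort$pheno$pe
  rows <- lapply(snps, function(s)
    pearson_rge(cohort$dosages[, s], pe, alpha = alpha, label = s))
  rows <- do.call(rbind, rows)
  cgs_row <- pearson_rge(cohort$cgs, pe, alpha = alpha, label = "CGS")
  retained <- rows$label[!rows$excluded]
  list(results = rbind(rows, cgs_row), retained = retained,
       cgs_retained = rowSums(cohort$dosages[, retained, drop = FALSE]))
}
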