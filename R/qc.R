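#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' Chi-square goodness-of-fit of observed genotype counts against the
#' Hardy-Weinberg proportions \eqn{(q^2, 2pq, p^2)}, with the risk-allele
#' frequency \eqn{p} estimated from the counts.
#'
#' The statistically standard biallelic test has one degree of freedom
#' (three categories, one estimated allele frequency). `df = 2` treats the
#' statistic as a plain three-category goodness-of-fit test without charging
#' the estimated frequency; some published panel tables use this convention,
#' so it is available for replication.
#'
#' @param counts integer vector of length 3: genotype counts ordered as
#'   (hom other allele, het, hom risk allele).
#' @param df degrees of freedom for the reference chi-square distribution,
#'   1 (default) or 2.
#' @return An object of class `hwe_result`: list with `chi2`, `df`, `p`,
#'   `observed`, `expected`, `allele_freq` (risk-allele frequency) and `n`.
#' @examples
#' hwe_test(c(545, 687, 245), df = 2)
#' @export
hwe_test <- function(counts, df = 1) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0))
    stop_input("counts must be three nonnegative genotype counts")
  n <- sum(counts)
  if (n <= 0) stop_input("all genotype counts are zero")
  if (!df %in% c(1, 2)) stop_input("df must be 1 or 2")
  p <- (2 * counts[3] + counts[2]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  # A fixed allele (p = 0 or 1) gives expected zeros in unobserved classes;
  # those classes contribute 0 by convention (obs = exp = 0).
  contrib <- ifelse(expected > 0, (counts - expected)^2 / expected, 0)
  chi2 <- sum(contrib)
  structure(
    list(chi2 = chi2, df = df,
         p = stats::pchisq(chi2, df = df, lower.tail = FALSE),
         observed = counts, expected = expected, allele_freq = p, n = n),
    class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("HWE goodness-of-fit: chi2 = ", format(x$chi2, digits = 4),
      " (df = ", x$df, "), p = ", format(x$p, digits = 3), "\n", sep = "")
  cat("  risk-allele frequency:", format(x$allele_freq, digits = 4), "\n")
  invisible(x)
}

#' Genotype counts from a dosage vector
#'
#' @param dosage risk-allele dosage vector in \{0,1,2\}; NA ignored.
#' @return integer vector (hom other, het, hom risk).
#' @export
genotype_counts <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  c(sum(dosage == 0), sum(dosage == 1), sum(dosage == 2))
}

#' Variant-level quality control
#'
#' Flags each SNP against call-rate, minor-allele-frequency and
#' Hardy-Weinberg thresholds. Filtering is flag-based and non-destructive;
#' use [drop_failed_variants()] to subset.
#'
#' @param dosages dosage matrix (individuals x SNPs), NA = missing call.
#' @param thresholds list with `call_rate` (default 0.95), `maf` (0.02) and
#'   `hwe_p` (1e-5): a SNP fails when call rate < `call_rate`, MAF < `maf`,
#'   or HWE p-value < `hwe_p`.
#' @param hwe_df degrees of freedom for [hwe_test()].
#' @return An object of class `qc_report`: list with `variants` (per-SNP
#'   data.frame of metrics and pass flags), `sample_missingness` (per-row
#'   fraction of missing calls) and the thresholds used.
#' @export
variant_qc <- function(dosages,
                       thresholds = list(call_rate = 0.95, maf = 0.02,
                                         hwe_p = 1e-5),
                       hwe_df = 1) {
  dosages <- as.matrix(dosages)
  if (!nrow(dosages) || !ncol(dosages)) stop_input("empty dosage table")
  thr <- utils::modifyList(list(call_rate = 0.95, maf = 0.02, hwe_p = 1e-5),
                           thresholds)
  res <- lapply(seq_len(ncol(dosages)), function(j) {
    d <- dosages[, j]
    call_rate <- mean(!is.na(d))
    cnt <- genotype_counts(d)
    if (sum(cnt) > 0) {
      hwe <- hwe_test(cnt, df = hwe_df)
      maf <- min(hwe$allele_freq, 1 - hwe$allele_freq)
      hwe_chi2 <- hwe$chi2; hwe_p <- hwe$p
    } else {
      maf <- NA_real_; hwe_chi2 <- NA_real_; hwe_p <- NA_real_
    }
    data.frame(snp_id = colnames(dosages)[j], call_rate = call_rate,
               maf = maf, hwe_chi2 = hwe_chi2, hwe_p = hwe_p,
               pass_call_rate = call_rate >= thr$call_rate,
               pass_maf = !is.na(maf) && maf >= thr$maf,
               pass_hwe = !is.na(hwe_p) && hwe_p >= thr$hwe_p,
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, res)
  variants$pass <- variants$pass_call_rate & variants$pass_maf & variants$pass_hwe
  structure(
    list(variants = variants,
         sample_missingness = rowMeans(is.na(dosages)),
         thresholds = thr, hwe_df = hwe_df),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Variant QC (call rate >= ", x$thresholds$call_rate,
      ", MAF >= ", x$thresholds$maf, ", HWE p >= ", x$thresholds$hwe_p,
      ", df = ", x$hwe_df, ")\n", sep = "")
  print(x$variants, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Drop SNPs that failed QC
#'
#' @param dosages dosage matrix.
#' @param report [variant_qc()] report on the same matrix.
#' @return the dosage matrix restricted to passing SNPs.
#' @export
drop_failed_variants <- function(dosages, report) {
  keep <- report$variants$snp_id[report$variants$pass]
  as.matrix(dosages)[, keep, drop = FALSE]
}

#' Code genotype calls as risk-allele dosages
#'
#' Converts two-allele genotype strings (e.g. `"CT"`, `"C/T"`, `"T|T"`) into
#' the count of risk-allele copies: 0, 1 or 2. For rs281238 with risk allele
#' T, the genotypes CC, CT and TT code to 0, 1 and 2.
#'
#' @param calls character vector of genotype calls; NA allowed.
#' @param risk_allele the risk (counted) allele.
#' @param other_allele the alternative allele.
#' @param snp_id identifier used in error messages.
#' @param ids optional sample identifiers for error messages.
#' @return numeric dosage vector in \{0,1,2\} with NA preserved.
#' @export
code_risk_dosage <- function(calls, risk_allele, other_allele,
                             snp_id = "SNP", ids = NULL) {
  if (is.na(risk_allele) || is.na(other_allele) || risk_allele == other_allele)
    stop_input(snp_id, ": risk and other allele must be distinct and declared")
  clean <- gsub("[/|]", "", as.character(calls))
  out <- rep(NA_real_, length(calls))
  for (i in seq_along(clean)) {
    if (is.na(clean[i]) || clean[i] == "" || clean[i] == "..") next
    al <- strsplit(clean[i], "")[[1]]
    if (length(al) != 2 || !all(al %in% c(risk_allele, other_allele))) {
      who <- if (!is.null(ids)) paste0(" (sample ", ids[i], ")") else ""
      stop_input(snp_id, ": call '", calls[i], "'", who,
                 " uses an undeclared allele")
    }
    out[i] <- sum(al == risk_allele)
  }
  out
}

#' Cumulative genetic score
#'
#' Unweighted per-individual sum of risk-allele dosages across the panel;
#' with `m` SNPs the score ranges over \[0, 2m\]. Source-study effect sizes
#' are metadata only and do not weight the score.
#'
#' @param dosages dosage matrix (individuals x SNPs); must be complete.
#' @return integer-valued CGS vector.
#' @export
compute_cgs <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages))
    stop_input("missing dosages: compute the CGS on complete cases only")
  rowSums(dosages)
}
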