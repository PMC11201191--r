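#' Assemble a cohort object for G\eqn{\times}E analysis
#'
#' A `gxe_cohort` bundles the per-individual phenotype, environment and
#' covariates with the SNP dosage matrix and the cumulative genetic score
#' (CGS). All downstream stages (QC, rGE screen, exploratory and
#' confirmatory regressions) take this container.
#'
#' @param pheno data.frame with columns `id`, `score` (the quantitative
#'   outcome, e.g. a character-recognition score), `pe` (environment:
#'   parental education, mean of two 1-8 integer levels), `age` (months) and
#'   `sex` (0/1). Optional `pe_father`/`pe_mother` columns carry the raw
#'   parent levels.
#' @param dosages numeric matrix (individuals x SNPs) of risk-allele counts
#'   in \{0,1,2\}; column names are SNP identifiers. `NA` entries are allowed
#'   at assembly and handled by [complete_cases()] / [variant_qc()].
#' @param snp_info optional data.frame of SNP metadata (see
#'   [read_snp_info()]).
#'
#' @return An object of class `gxe_cohort`: a list with elements `pheno`,
#'   `dosages`, `cgs` (row sum of dosages; `NA` where any dosage is missing)
#'   and `snp_info`.
#' @export
gxe_cohort <- function(pheno, dosages, snp_info = NULL) {
  required <- c("id", "score", "pe", "age", "sex")
  missing_cols <- setdiff(required, names(pheno))
  if (length(missing_cols))
    stop_input("phenotype table lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(pheno))
    stop_input("dosage matrix has ", nrow(dosages), " rows but phenotype table has ",
               nrow(pheno))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad))
    stop_input("dosages must be risk-allele counts in {0, 1, 2}")
  ok_pe <- is.na(pheno$pe) | (pheno$pe >= 1 & pheno$pe <= 8)
  if (!all(ok_pe))
    stop_input("pe values must lie in [1, 8]")
  structure(
    list(pheno = as.data.frame(pheno), dosages = dosages,
         cgs = rowSums(dosages), snp_info = snp_info),
    class = "gxe_cohort")
}

#' @export
print.gxe_cohort <- function(x, ...) {
  cat("gxe_cohort: ", nrow(x$pheno), " individuals, ",
      ncol(x$dosages), " SNPs\n", sep = "")
  cat("  phenotype: mean ", round(mean(x$pheno$score, na.rm = TRUE), 2),
      ", sd ", round(stats::sd(x$pheno$score, na.rm = TRUE), 2), "\n", sep = "")
  cat("  environment (pe): mean ", round(mean(x$pheno$pe, na.rm = TRUE), 2),
      ", range [", min(x$pheno$pe, na.rm = TRUE), ", ",
      max(x$pheno$pe, na.rm = TRUE), "]\n", sep = "")
  cat("  CGS range: [", min(x$cgs, na.rm = TRUE), ", ",
      max(x$cgs, na.rm = TRUE), "]\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort a [gxe_cohort()] object.
#' @return integer count.
#' @export
n_individuals <- function(cohort) nrow(cohort$pheno)

#' Restrict a cohort to complete cases
#'
#' Drops individuals with any missing phenotype, environment, covariate or
#' dosage value, mirroring the complete-data analysis subset a cohort study
#' would report.
#'
#' @param cohort a [gxe_cohort()] object.
#' @return a `gxe_cohort` with only complete rows; the CGS is recomputed.
#' @export
complete_cases <- function(cohort) {
  ph <- cohort$pheno
  keep <- stats::complete.cases(ph[, c("id", "score", "pe", "age", "sex")]) &
    stats::complete.cases(cohort$dosages)
  gxe_cohort(ph[keep, , drop = FALSE],
             cohort$dosages[keep, , drop = FALSE],
             snp_info = cohort$snp_info)
}

#' Read SNP metadata
#'
#' Reads a CSV of panel metadata with at least `snp_id` and `risk_allele`
#' columns; optional columns include `other_allele`, `beta` (effect size in
#' the source association study, metadata only -- the CGS is unweighted),
#' `trait`, `gene` and `base_pair`.
#'
#' @param path CSV file path.
#' @return data.frame of SNP metadata.
#' @export
read_snp_info <- function(path) {
  info <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "risk_allele") %in% names(info)))
    stop_input("snp info file needs columns snp_id and risk_allele: ", path)
  if (anyDuplicated(info$snp_id))
    stop_input("duplicate snp_id in ", path)
  info
}

#' Read an additive dosage table (PLINK .raw style)
#'
#' Parses a whitespace-delimited dosage table with header `FID IID` followed
#' by one column per SNP named `<snp_id>_<counted allele>`. The standard
#' PLINK pedigree columns (`PAT`, `MAT`, `SEX`, `PHENOTYPE`) are dropped if
#' present. Values must be 0/1/2 or NA.
#'
#' @param path file path.
#' @return list with `ids` (IID character vector), `dosages` (matrix with
#'   SNP-id column names) and `counted_alleles` (named character vector).
#' @export
read_dosage_raw <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!all(c("FID", "IID") %in% names(tab)))
    stop_input("dosage table lacks FID/IID header: ", path)
  drop <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(tab))
  snp_cols <- setdiff(names(tab), drop)
  if (!length(snp_cols)) stop_input("dosage table has no SNP columns: ", path)
  dos <- as.matrix(tab[, snp_cols, drop = FALSE])
  # "<snp>_<allele>" -> snp id + counted allele
  m <- regmatches(snp_cols, regexec("^(.*)_([A-Za-z]+)$", snp_cols))
  ids <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3) m[[i]][2] else snp_cols[i], character(1))
  alleles <- vapply(seq_along(m), function(i)
    if (length(m[[i]]) == 3) m[[i]][3] else NA_character_, character(1))
  colnames(dos) <- ids
  names(alleles) <- ids
  list(ids = as.character(tab$IID), dosages = dos, counted_alleles = alleles)
}

#' Write an additive dosage table (PLINK .raw style)
#'
#' @param dosages matrix of risk-allele dosages with SNP-id column names.
#' @param ids individual identifiers.
#' @param path output file.
#' @param counted_alleles optional named character vector of counted (risk)
#'   alleles; appended to column names as `<snp>_<allele>`.
#' @return the path, invisibly.
#' @export
write_dosage_raw <- function(dosages, ids, path, counted_alleles = NULL) {
  cn <- colnames(dosages)
  if (!is.null(counted_alleles)) {
    al <- counted_alleles[cn]
    cn <- ifelse(is.na(al), cn, paste0(cn, "_", al))
  }
  out <- data.frame(FID = ids, IID = ids, check.names = FALSE)
  out[cn] <- as.data.frame(dosages)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate CSV
#'
#' Expects columns `id`, `score`, `age_months`, `sex`, `pe_father`,
#' `pe_mother`; the environment `pe` is computed as the mean of the two
#' parent levels.
#'
#' @param path CSV file path.
#' @return data.frame ready for [gxe_cohort()].
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "score", "age_months", "sex", "pe_father", "pe_mother")
  missing_cols <- setdiff(need, names(ph))
  if (length(missing_cols))
    stop_input("phenotype file lacks column(s): ",
               paste(missing_cols, collapse = ", "))
  data.frame(id = as.character(ph$id), score = ph$score,
             pe = (ph$pe_father + ph$pe_mother) / 2,
             age = ph$age_months, sex = ph$sex,
             pe_father = ph$pe_father, pe_mother = ph$pe_mother,
             stringsAsFactors = FALSE)
}

#' Write a phenotype/covariate CSV
#'
#' @param pheno phenotype data.frame (as in a [gxe_cohort()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  out <- data.frame(id = pheno$id, score = pheno$score,
                    age_months = pheno$age, sex = pheno$sex,
                    pe_father = pheno$pe_father %||% pheno$pe,
                    pe_mother = pheno$pe_mother %||% pheno$pe)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract risk-allele dosages from a VCF
#'
#' Reads the GT field of a VCF and converts each call to a risk-allele count
#' using the panel metadata: REF/ALT at each site are matched against the
#' declared `risk_allele`/`other_allele`, and the dosage is the number of
#' risk-allele copies. Requires the `vcfR` package.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param snp_info SNP metadata with `snp_id`, `risk_allele` and
#'   `other_allele` columns.
#' @return list with `ids` and `dosages` as in [read_dosage_raw()].
#' @export
read_genotypes_vcf <- function(path, snp_info) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- colnames(gt)
  keep <- fix[, "ID"] %in% snp_info$snp_id
  if (!any(keep)) stop_input("no panel SNPs found in ", path)
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dos <- matrix(NA_real_, nrow = length(ids), ncol = nrow(fix),
                dimnames = list(ids, fix[, "ID"]))
  for (i in seq_len(nrow(fix))) {
    snp <- fix[i, "ID"]
    meta <- snp_info[snp_info$snp_id == snp, ]
    alleles <- c(fix[i, "REF"], fix[i, "ALT"])
    declared <- c(meta$risk_allele, meta$other_allele)
    if (!all(alleles %in% declared))
      stop_input("VCF alleles ", paste(alleles, collapse = "/"),
                 " at ", snp, " do not match declared panel alleles")
    for (j in seq_along(ids)) {
      call <- gt[i, j]
      if (is.na(call) || call %in% c(".", "./.", ".|.")) next
      idx <- as.integer(strsplit(call, "[/|]")[[1]]) + 1L
      dos[j, i] <- sum(alleles[idx] == meta$risk_allele)
    }
  }
  list(ids = ids, dosages = dos)
}
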