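# End-to-end orchestration: QC -> rGE screen -> exploratory scan ->
# confirmatory crossover modelling, from files or from a simulated cohort.

#' Build and validate a pipeline configuration
#'
#' Exactly one of `paths` (input files) or `simulate` (a [sim_config()])
#' must be supplied.
#'
#' @param paths list with `genotypes` (PLINK-.raw-style dosage table or
#'   VCF), `phenotypes` (CSV) and `snp_info` (CSV); or `NULL`.
#' @param simulate a [sim_config()]; or `NULL`.
#' @param alpha_rge,alpha_scan,alpha_confirm significance levels for the
#'   rGE screen, the Bonferroni scan and the confirmatory nested tests.
#' @param hwe_df degrees of freedom for the HWE test (1 standard, 2 for
#'   three-category replication mode).
#' @param bonferroni_m optional override of the Bonferroni denominator
#'   (default: number of retained SNPs).
#' @param fixed_c_rule crossover rule for the diathesis-stress models.
#' @param out_dir optional output directory for stage TSVs and the JSON
#'   summary.
#' @param seed integer seed (simulation mode).
#' @return An object of class `run_config`.
#' @export
run_config <- function(paths = NULL, simulate = NULL,
                       alpha_rge = 0.05, alpha_scan = 0.05,
                       alpha_confirm = 0.05, hwe_df = 1,
                       bonferroni_m = NULL,
                       fixed_c_rule = "mean_plus_3sd",
                       out_dir = NULL, seed = NULL) {
  if (is.null(paths) == is.null(simulate))
    stop_input("supply exactly one of `paths` or `simulate`")
  for (a in c(alpha_rge, alpha_scan, alpha_confirm))
    if (a <= 0 || a >= 1) stop_input("alpha levels must lie in (0, 1)")
  if (!is.null(simulate) && !inherits(simulate, "sim_config"))
    stop_input("`simulate` must be a sim_config object")
  if (!is.null(paths)) {
    need <- c("genotypes", "phenotypes", "snp_info")
    if (!all(need %in% names(paths)))
      stop_input("`paths` needs entries: ", paste(need, collapse = ", "))
  }
  structure(
    list(paths = paths, simulate = simulate, alpha_rge = alpha_rge,
         alpha_scan = alpha_scan, alpha_confirm = alpha_confirm,
         hwe_df = hwe_df, bonferroni_m = bonferroni_m,
         fixed_c_rule = fixed_c_rule, out_dir = out_dir, seed = seed),
    class = "run_config")
}

load_cohort_from_paths <- function(paths) {
  snp_info <- read_snp_info(paths$snp_info)
  ph <- read_phenotypes(paths$phenotypes)
  geno <- if (grepl("\\.vcf(\\.gz)?$", paths$genotypes))
    read_genotypes_vcf(paths$genotypes, snp_info)
  else read_dosage_raw(paths$genotypes)
  idx <- match(ph$id, geno$ids)
  if (anyNA(idx))
    stop_input("phenotype ids missing from genotype table: ",
               paste(utils::head(ph$id[is.na(idx)]), collapse = ", "))
  gxe_cohort(ph, geno$dosages[idx, , drop = FALSE], snp_info = snp_info)
}

#' Run the full G\eqn{\times}E analysis pipeline
#'
#' Executes, in order: cohort assembly (from files or simulation),
#' complete-case filtering, variant QC, the gene-environment correlation
#' screen, the exploratory per-SNP scan with Bonferroni control, the
#' exploratory CGS interaction (the confirmatory gate), and -- for the top
#' scan SNP and for the CGS -- the confirmatory crossover model family with
#' classification. Identical config and seed give identical output.
#'
#' @param config a [run_config()].
#' @return An object of class `gxe_run`: list with `cohort`, `qc`,
#'   `screen`, `scan`, `cgs` (exploratory fits + gate), `focal_snp`,
#'   `confirmatory` (fits `3a`-`3d` and classification), and
#'   `confirmatory_cgs` (fits `3e`/`3f` and classification). When
#'   `config$out_dir` is set, stage TSVs and `summary.json` are written
#'   there.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop_input("config must be a run_config")
  cohort <- if (!is.null(config$simulate)) {
    cfg <- config$simulate
    if (!is.null(config$seed)) cfg$seed <- config$seed
    gen_cohort(cfg)
  } else load_cohort_from_paths(config$paths)
  cohort <- complete_cases(cohort)

  qc <- variant_qc(cohort$dosages, hwe_df = config$hwe_df)
  passing <- qc$variants$snp_id[qc$variants$pass]
  cohort_qc <- gxe_cohort(cohort$pheno,
                          cohort$dosages[, passing, drop = FALSE],
                          snp_info = cohort$snp_info)

  screen <- screen_panel(cohort_qc, alpha = config$alpha_rge)
  retained <- screen$retained
  cohort_scr <- gxe_cohort(cohort_qc$pheno,
                           cohort_qc$dosages[, retained, drop = FALSE],
                           snp_info = cohort$snp_info)

  scan <- run_snp_scan(cohort_scr, alpha = config$alpha_scan)
  if (!is.null(config$bonferroni_m)) {
    scan$threshold <- config$alpha_scan / config$bonferroni_m
    scan$significant <- scan$p < scan$threshold
  }
  cgs_stage <- fit_cgs_interaction(cohort_scr)

  pe_range <- range(cohort_scr$pheno$pe)
  focal <- scan$snp_id[which.min(scan$p)]
  snp_gate <- nested_f_test(fit_ols(cohort_scr, focal, interaction = FALSE),
                            fit_ols(cohort_scr, focal, interaction = TRUE))
  fits_g <- fit_crossover_family(cohort_scr, focal,
                                 fixed_c_rule = config$fixed_c_rule)
  cls_g <- compare_models(fits_g, gate_passed = snp_gate$f > 1.0,
                          pe_range = pe_range, alpha = config$alpha_confirm)
  fits_c <- fit_crossover_family_cgs(cohort_scr,
                                     fixed_c_rule = config$fixed_c_rule)
  cls_c <- compare_models(fits_c, gate_passed = cgs_stage$gate_passed,
                          pe_range = pe_range, alpha = config$alpha_confirm)

  run <- structure(
    list(cohort = cohort_scr, qc = qc, screen = screen, scan = scan,
         cgs = cgs_stage, focal_snp = focal, snp_gate = snp_gate,
         confirmatory = list(fits = fits_g, classification = cls_g),
         confirmatory_cgs = list(fits = fits_c, classification = cls_c),
         config = config),
    class = "gxe_run")
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$qc$variants, "qc_variants.tsv")
  wt(run$screen$results, "rge_screen.tsv")
  wt(run$scan, "snp_scan.tsv")
  wt(reparam_table(run$confirmatory$fits), "confirmatory_groups.tsv")
  wt(reparam_table(run$confirmatory_cgs$fits), "confirmatory_cgs.tsv")
  summary <- list(
    n = n_individuals(run$cohort),
    retained_snps = run$screen$retained,
    focal_snp = run$focal_snp,
    scan_significant = run$scan$snp_id[run$scan$significant],
    cgs_gate_f = run$cgs$comparison$f,
    snp = classification_record(run$confirmatory$classification),
    cgs = classification_record(run$confirmatory_cgs$classification),
    seed = run$config$seed,
    schema_version = "1.0")
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

classification_record <- function(cls) {
  list(selected_model = cls$selected_model, family = cls$family,
       strength = cls$strength, shape = cls$shape,
       gate_passed = cls$gate_passed)
}

#' Machine-readable table of a fitted crossover model family
#'
#' Stacks the parameter estimates, standard errors and fit statistics of a
#' list of `reparam_fit`s into one long data.frame (one row per parameter
#' per model), the layout the stage TSVs use.
#'
#' @param fits named list of `reparam_fit`s, e.g. from
#'   [fit_crossover_family()].
#' @return data.frame with columns `model`, `parameter`, `estimate`, `se`.
#' @export
reparam_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    par_rows <- rbind(
      data.frame(parameter = "C", estimate = f$c_hat,
                 se = if (f$c_fixed) NA_real_ else f$c_se),
      data.frame(parameter = "A0", estimate = f$a0, se = f$a0_se),
      data.frame(parameter = f$group_slopes$term,
                 estimate = f$group_slopes$estimate, se = f$group_slopes$se),
      data.frame(parameter = c("Age", "Sex"),
                 estimate = c(f$age_slope, f$sex_slope),
                 se = c(f$age_se, f$sex_se)),
      data.frame(parameter = c("R2", "F", "AIC", "BIC"),
                 estimate = c(f$r2, f$f_overall, f$aic, f$bic),
                 se = NA_real_))
    cbind(model = id, par_rows)
  })
  do.call(rbind, rows)
}

#' Render human-readable model tables
#'
#' Formats the confirmatory model families in the journal convention:
#' one column per model, estimates with standard errors in parentheses,
#' fixed parameters shown as `(--)`.
#'
#' @param run a [run_pipeline()] result.
#' @return character vector of report lines, invisibly printed.
#' @export
render_tables <- function(run) {
  lines <- character(0)
  emit <- function(...) lines <<- c(lines, paste0(...))
  fmt <- function(est, se) {
    if (is.na(est)) return("--")
    if (is.na(se)) sprintf("%.2f (--)", est)
    else sprintf("%.2f (%.2f)", est, se)
  }
  render_family <- function(fits, title) {
    emit("== ", title, " ==")
    params <- unique(unlist(lapply(fits, function(f)
      c("C", "A0", f$group_slopes$term, "Age", "Sex"))))
    header <- c(sprintf("%-6s", "Param"),
                sprintf("%-18s", paste0("Model ", names(fits))))
    emit(paste(header, collapse = ""))
    for (p in params) {
      cells <- vapply(fits, function(f) {
        val <- switch(p,
          C = fmt(f$c_hat, if (f$c_fixed) NA_real_ else f$c_se),
          A0 = fmt(f$a0, f$a0_se),
          Age = fmt(f$age_slope, f$age_se),
          Sex = fmt(f$sex_slope, f$sex_se),
          {
            i <- match(p, f$group_slopes$term)
            if (is.na(i)) "--"
            else fmt(f$group_slopes$estimate[i], f$group_slopes$se[i])
          })
        val
      }, character(1))
      emit(paste(c(sprintf("%-6s", p), sprintf("%-18s", cells)), collapse = ""))
    }
    for (stat in c("r2", "f_overall", "aic", "bic")) {
      cells <- vapply(fits, function(f)
        sprintf("%-18s", sprintf("%.4f", f[[stat]])), character(1))
      emit(paste(c(sprintf("%-6s", toupper(sub("_overall", "", stat))), cells),
                 collapse = ""))
    }
  }
  if (!run$confirmatory$classification$gate_passed &&
      !run$confirmatory_cgs$classification$gate_passed) {
    emit("Confirmatory stage not run: exploratory interaction F ratio <= 1.0 ",
         "for both the focal SNP and the CGS.")
    return(invisible(lines))
  }
  render_family(run$confirmatory$fits,
                paste0("Re-parameterized models, SNP ", run$focal_snp))
  emit("Classification: ",
       run$confirmatory$classification$family, " / ",
       run$confirmatory$classification$strength, " (",
       run$confirmatory$classification$shape %||% "NA", ")")
  emit("")
  render_family(run$confirmatory_cgs$fits, "Re-parameterized models, CGS")
  emit("Classification: ",
       run$confirmatory_cgs$classification$family, " (",
       run$confirmatory_cgs$classification$shape %||% "NA", ")")
  invisible(lines)
}
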