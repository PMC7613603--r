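#' @name cli_pipeline
#' @title End-to-end analysis pipeline
#'
#' @description
#' `run_pipeline()` chains the whole analysis — simulate (or read), exclude
#' unattributable records, multiply impute, fit all pairwise models per
#' completed dataset (and once under complete-case deletion), combine with
#' the weight matrix and sandwich covariance, pool by Rubin's rules, run the
#' joint Wald tests, and assemble the random-intercept covariance with its
#' correlation and PCA summaries — writing every artifact to a run directory
#' with seeds and content hashes logged. Completed stages are detected by
#' their output files and skipped on re-run, so a run can be resumed. The
#' numbered scripts under `analysis/` are thin drivers over this function
#' and the stage functions it calls.
NULL

#' Pipeline configuration
#'
#' @param out_dir run directory (created if absent)
#' @param params [trial_params()] for simulation, or NULL with `input_csv`
#' @param input_csv optional existing dataset (skips simulation)
#' @param impute an [impute_spec()] or NULL for complete-case only
#' @param engine sandwich engine, `"empirical"` (default) or `"printed"`
#' @param nq quadrature nodes per dimension for the pairwise fits
#' @param wald_terms term labels for the joint Wald table
#' @param seed master seed; stage seeds are derived from it
#' @param scale `"desk"` (enforces p <= 3, M <= 5, <= 100 clinicians
#'   expected) or `"study"`
#' @return validated list of class `pipeline_config`
#' @export
pipeline_config <- function(out_dir,
                            params = NULL,
                            input_csv = NULL,
                            impute = NULL,
                            engine = c("empirical", "printed"),
                            nq = 7,
                            wald_terms = NULL,
                            seed = 1L,
                            scale = c("desk", "study")) {
  engine <- match.arg(engine)
  scale <- match.arg(scale)
  if (is.null(params) && is.null(input_csv)) {
    params <- if (scale == "desk") desk_params(seed = seed) else
      trial_params(seed = seed)
  }
  if (!is.null(params) && scale == "desk") {
    exp_cl <- params$n_hospitals * params$clinicians_per_hospital$mean
    if (params$p_outcomes > 3 || exp_cl > 100) {
      stop("desk scale requires p <= 3 outcomes and at most ~100 clinicians")
    }
  }
  if (!is.null(impute) && scale == "desk" && impute$M > 5) {
    stop("desk scale caps imputations at M = 5")
  }
  structure(list(out_dir = out_dir, params = params, input_csv = input_csv,
                 impute = impute, engine = engine, nq = nq,
                 wald_terms = wald_terms, seed = as.integer(seed),
                 scale = scale),
            class = "pipeline_config")
}

#' Desk-scale generator preset
#'
#' A bounded-runtime version of the trial generator: 6 hospitals, ~10
#' clinicians each, ~6 patients per clinician, 3 outcomes, no unattributable
#' records. Fixed effects and D are the corresponding sub-blocks of the
#' study-scale defaults.
#'
#' Fixed effects and D follow the moderate-prevalence indicators of the
#' study-scale defaults (oxygen saturation, correct diagnosis, correct
#' prescription) so that desk-sized datasets keep both outcome classes well
#' populated in every cluster.
#'
#' @param p_outcomes number of outcomes (<= 3)
#' @param seed RNG seed
#' @param n_hospitals,clinicians_per_hospital,patients_per_clinician
#'   hierarchy sizes (desk-sized defaults)
#' @param ... further overrides passed to [trial_params()]
#' @return `trial_params`
#' @export
desk_params <- function(p_outcomes = 3, seed = 1L, n_hospitals = 6,
                        clinicians_per_hospital = list(mean = 10, size = 8),
                        patients_per_clinician = list(mean = 6, size = 2,
                                                      min = 3, max = 20),
                        ...) {
  rows <- c(4, 7, 8)[seq_len(p_outcomes)]
  trial_params(p_outcomes = p_outcomes, n_hospitals = n_hospitals,
               clinicians_per_hospital = clinicians_per_hospital,
               patients_per_clinician = patients_per_clinician,
               beta = default_beta()[rows, , drop = FALSE],
               D_true = psd_clip(read_varcorr("mi")$D)[rows, rows, drop = FALSE],
               covariates = list(p_age_infant = 0.425, p_pat_male = 0.551,
                                 p_comorbid = c(0.468, 0.298, 0.179, 0.055),
                                 p_cadre_co = 0.644, p_clin_female = 0.432,
                                 n_malaria_high = max(1, round(n_hospitals * 5 / 12)),
                                 workload_prop = 0.5),
               unassigned_rate = 0, seed = seed, ...)
}

log_line <- function(log_path, ...) {
  cat(paste0(..., "\n"), file = log_path, append = TRUE)
}

log_outputs <- function(log_path, stage, files) {
  for (f in files[file.exists(files)]) {
    log_line(log_path, sprintf("stage=%s out=%s md5=%s", stage, basename(f),
                               unname(tools::md5sum(f))))
  }
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()]
#' @return the run directory, invisibly; artifacts: `data.csv`,
#'   `data_analysis.csv`, `exclusion.json`, `imp/data_imp_###.csv`,
#'   `fits/fit_<set>_<r>_<s>.json`, `combined_<set>.csv`, `pooled.csv`,
#'   `wald.csv`, `dmatrix_cc.csv` / `dmatrix_mi.csv`, `pca.csv`,
#'   `or_table.csv`, `run.log`
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out, "imp"), showWarnings = FALSE)
  dir.create(file.path(out, "fits"), showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  log_line(log_path, sprintf("run_pipeline seed=%d engine=%s scale=%s",
                             config$seed, config$engine, config$scale))

  # --- stage: data ------------------------------------------------------
  data_csv <- file.path(out, "data.csv")
  if (!file.exists(data_csv)) {
    if (!is.null(config$input_csv)) {
      file.copy(config$input_csv, data_csv)
      log_line(log_path, "stage=data source=input_csv")
    } else {
      dat <- simulate_trial(config$params)
      write_trial_csv(dat, data_csv, audit = TRUE)
      log_line(log_path, sprintf("stage=data seed=%d", config$params$seed))
    }
    log_outputs(log_path, "data", data_csv)
  } else log_line(log_path, "stage=data skipped (exists)")
  dat <- read_trial_csv(data_csv)
  p <- sum(grepl("^y[0-9]+$", names(dat)))
  k <- 13L
  idx <- enumerate_pairs(p)

  # --- stage: exclude ---------------------------------------------------
  excl_json <- file.path(out, "exclusion.json")
  ana_csv <- file.path(out, "data_analysis.csv")
  if (!file.exists(ana_csv)) {
    ex <- exclude_missing_cluster(dat)
    write_trial_csv(ex$data, ana_csv)
    jsonlite::write_json(ex$report, excl_json, auto_unbox = TRUE, digits = NA)
    log_line(log_path, sprintf("stage=exclude %s", ex$report$label))
    log_outputs(log_path, "exclude", c(ana_csv, excl_json))
  } else log_line(log_path, "stage=exclude skipped (exists)")
  ana <- read_trial_csv(ana_csv)

  # --- stage: impute ----------------------------------------------------
  datasets <- list(CC = ana)
  if (!is.null(config$impute)) {
    M <- config$impute$M
    imp_files <- file.path(out, "imp", sprintf("data_imp_%03d.csv", seq_len(M)))
    if (!all(file.exists(imp_files))) {
      stk <- run_imputation(ana, config$impute)
      for (m in seq_len(M)) write_trial_csv(stk$datasets[[m]], imp_files[m])
      convergence_report(stk, path = file.path(out, "imp", "trace_summary.csv"),
                         series_path = file.path(out, "imp", "trace.csv"))
      log_line(log_path, sprintf("stage=impute M=%d burn_in=%d between=%d seed=%d",
                                 M, config$impute$burn_in, config$impute$between,
                                 config$impute$seed))
      log_outputs(log_path, "impute", imp_files)
    } else log_line(log_path, "stage=impute skipped (exists)")
    for (m in seq_len(M)) {
      datasets[[sprintf("imp%03d", m)]] <- read_trial_csv(imp_files[m])
    }
  }

  # --- stage: pairwise fits --------------------------------------------
  fit_path <- function(set, rs) {
    file.path(out, "fits", sprintf("fit_%s_%d_%d.json", set, rs[1], rs[2]))
  }
  all_fits <- list()
  warm <- vector("list", idx$Q)
  for (set in names(datasets)) {
    fits <- vector("list", idx$Q)
    for (q in seq_len(idx$Q)) {
      rs <- idx$pairs[q, ]
      fp <- fit_path(set, rs)
      if (file.exists(fp)) {
        fits[[q]] <- read_fit(fp)
      } else {
        f <- fit_bivariate(datasets[[set]], rs, nq = config$nq,
                           start = warm[[q]])
        if (!f$converged) {
          warning(sprintf("pair (%d,%d) [%s] flagged: max|score|/J = %.2e",
                          rs[1], rs[2], set, f$grad_norm), call. = FALSE)
        }
        write_fit(f, fp)
        # downstream stages always consume the serialized fit so that fresh
        # and resumed runs produce bit-identical artifacts
        fits[[q]] <- read_fit(fp)
        log_line(log_path, sprintf("stage=fit set=%s pair=%d,%d loglik=%.4f conv=%s",
                                   set, rs[1], rs[2], f$loglik, f$converged))
      }
      if (is.null(warm[[q]])) warm[[q]] <- fits[[q]]$theta
    }
    all_fits[[set]] <- fits
  }

  # --- stage: combine ---------------------------------------------------
  A <- build_weight_matrix(p, k)
  combined <- list()
  for (set in names(all_fits)) {
    st <- stack_fits(all_fits[[set]], idx, k)
    sw <- if (config$engine == "printed") {
      suppressWarnings(sandwich_printed_recipe(st))
    } else sandwich_empirical(st, singular = "pseudo")
    cmb <- combine_estimates(A, st, sw, m = set)
    combined[[set]] <- cmb
    cf <- file.path(out, sprintf("combined_%s.csv", set))
    write.csv(data.frame(coefficient = names(cmb$beta_star),
                         estimate = cmb$beta_star, se = cmb$se),
              cf, row.names = FALSE)
  }
  log_outputs(log_path, "combine",
              file.path(out, sprintf("combined_%s.csv", names(combined))))

  # --- stage: pool ------------------------------------------------------
  pooled <- NULL
  if (!is.null(config$impute)) {
    pooled <- rubin_pool(combined[names(combined) != "CC"])
    write.csv(data.frame(coefficient = names(combined$CC$beta_star),
                         estimate = pooled$beta_bar, se = pooled$se,
                         W = diag(pooled$W), B = diag(pooled$B),
                         V = diag(pooled$V)),
              file.path(out, "pooled.csv"), row.names = FALSE)
    log_outputs(log_path, "pool", file.path(out, "pooled.csv"))
  }

  # --- stage: wald ------------------------------------------------------
  wald_terms <- config$wald_terms
  if (is.null(wald_terms)) wald_terms <- setdiff(trial_seq_terms(k), "(Intercept)")
  wtab <- do.call(rbind, lapply(wald_terms, function(tm) {
    ws <- build_L(tm, p, k)
    cc <- wald_joint_test(ws, combined$CC$beta_star, combined$CC$sigma_star)
    row <- data.frame(term = tm, df = cc$df, stat_cc = cc$statistic,
                      p_cc = cc$p_value, stat_mi = NA_real_, p_mi = NA_real_)
    if (!is.null(pooled)) {
      mi <- wald_joint_test(ws, pooled$beta_bar, pooled$V)
      row$stat_mi <- mi$statistic
      row$p_mi <- mi$p_value
    }
    row
  }))
  write.csv(wtab, file.path(out, "wald.csv"), row.names = FALSE)
  log_outputs(log_path, "wald", file.path(out, "wald.csv"))

  # --- stage: associate -------------------------------------------------
  labels <- if (p == 9) outcome_labels() else paste0("y", seq_len(p))
  D_cc <- assemble_D(all_fits$CC, idx)
  vc_cc <- corr_from_D(D_cc, labels)
  write.csv(vc_cc$table, file.path(out, "dmatrix_cc.csv"))
  pca_rows <- pca_to_df(pca_correlation(fill_na_corr(vc_cc$corr)), "CC")
  if (!is.null(config$impute)) {
    D_mi <- average_over_imputations(
      lapply(all_fits[names(all_fits) != "CC"], assemble_D, index = idx))
    vc_mi <- corr_from_D(D_mi, labels)
    write.csv(vc_mi$table, file.path(out, "dmatrix_mi.csv"))
    pca_rows <- rbind(pca_rows,
                      pca_to_df(pca_correlation(fill_na_corr(vc_mi$corr)), "MI"))
  }
  write.csv(pca_rows, file.path(out, "pca.csv"), row.names = FALSE)
  log_outputs(log_path, "associate",
              file.path(out, c("dmatrix_cc.csv", "dmatrix_mi.csv", "pca.csv")))

  # --- stage: report ----------------------------------------------------
  rep <- pipeline_report(combined, pooled, wtab)
  write.csv(rep$or_table, file.path(out, "or_table.csv"), row.names = FALSE)
  log_outputs(log_path, "report", file.path(out, "or_table.csv"))
  log_line(log_path, "run complete")
  invisible(out)
}

fill_na_corr <- function(C) {
  C[is.na(C)] <- 0
  C
}

pca_to_df <- function(pc, which) {
  data.frame(analysis = which,
             component = seq_along(pc$eigenvalues),
             eigenvalue = pc$eigenvalues,
             proportion = pc$proportion,
             cumulative = pc$cumulative)
}

#' Odds-ratio and Wald summary tables for a completed run
#'
#' Per-coefficient odds ratios exp(beta) with 95% CIs exp(beta +/- 1.96 se),
#' complete-case and pooled-imputation side by side, plus the joint Wald
#' table. Degenerate intervals (se = 0) are flagged rather than dropped.
#'
#' @param combined named list of `combined_estimates` incl. `CC`
#' @param pooled `pooled_estimates` or NULL
#' @param wald_table data frame as written by [run_pipeline()]
#' @return list with `or_table` and `wald_table`
#' @export
pipeline_report <- function(combined, pooled = NULL, wald_table = NULL) {
  cc <- combined$CC
  or_row <- function(est, se) {
    data.frame(or = exp(est), lo = exp(est - 1.96 * se),
               hi = exp(est + 1.96 * se), degenerate = se == 0)
  }
  tab <- cbind(data.frame(coefficient = names(cc$beta_star)),
               setNames(or_row(cc$beta_star, cc$se),
                        c("or_cc", "lo_cc", "hi_cc", "degenerate_cc")))
  if (!is.null(pooled)) {
    tab <- cbind(tab, setNames(or_row(pooled$beta_bar, pooled$se),
                               c("or_mi", "lo_mi", "hi_mi", "degenerate_mi")))
  }
  list(or_table = tab, wald_table = wald_table)
}

#' Summarize a completed run directory
#'
#' @param run_dir directory produced by [run_pipeline()]
#' @return list of the run's tables (read back from the artifacts)
#' @export
report <- function(run_dir) {
  need <- c("combined_CC.csv", "wald.csv", "or_table.csv", "pca.csv")
  have <- file.exists(file.path(run_dir, need))
  if (!all(have)) {
    stop("incomplete run; missing stages for: ",
         paste(need[!have], collapse = ", "))
  }
  out <- list(
    combined_cc = read.csv(file.path(run_dir, "combined_CC.csv")),
    wald = read.csv(file.path(run_dir, "wald.csv")),
    or_table = read.csv(file.path(run_dir, "or_table.csv")),
    pca = read.csv(file.path(run_dir, "pca.csv"))
  )
  if (file.exists(file.path(run_dir, "pooled.csv"))) {
    out$pooled <- read.csv(file.path(run_dir, "pooled.csv"))
  }
  out
}
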