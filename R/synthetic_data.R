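#' @name synthetic_data
#' @title Synthetic three-level trial data with correlated binary outcomes
#'
#' @description
#' The quality-of-care study this package emulates is a cluster-randomized
#' audit-and-feedback trial: 12 hospitals (6 per arm), roughly 378 admitting
#' clinicians, and about 2127 analyzable pediatric pneumonia admissions, with
#' nine binary care indicators per admission driven by clinician-level
#' correlated random intercepts. Its raw data are not public, so the
#' generator here reproduces the printed structure: hierarchy sizes, covariate
#' marginals, outcome prevalences, the random-intercept covariance (seeded
#' from the published variance-correlation matrix), the missingness rates in
#' patient sex (~0.7%), clinician sex (~21.9%) and clinician cadre (~21.7%)
#' with near-coincident missingness of the two clinician variables, and the
#' ~7.5% of records lacking an admitting-clinician identifier that the
#' analysis excludes.
NULL

# run expr under a given seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

rmvnorm_chol <- function(n, D) {
  p <- ncol(D)
  L <- t(chol(D + diag(1e-12, p)))
  matrix(rnorm(n * p), n, p) %*% t(L)
}

#' Outcome labels of the nine care indicators
#' @return character vector of length 9 (assessment, diagnosis, treatment order)
#' @export
outcome_labels <- function() {
  c("cough", "difficult_breathing", "resp_rate", "oxygen_sat", "avpu",
    "indrawing", "diagnosis", "treatment", "dose")
}

#' Read a published variance-correlation matrix
#'
#' Reads one of the two variance-correlation matrices of clinician random
#' intercepts shipped with the package (complete-case and after multiple
#' imputation): variances on the diagonal, correlations below it.
#'
#' @param which `"cca"` or `"mi"`
#' @param path optional explicit CSV path with the same layout
#' @return list with `variances`, `corr` (symmetric, unit diagonal) and the
#'   implied covariance `D`
#' @export
read_varcorr <- function(which = c("cca", "mi"), path = NULL) {
  if (is.null(path)) {
    which <- match.arg(which)
    path <- system.file("extdata", paste0("varcorr_", which, ".csv"),
                        package = "pairjmm", mustWork = TRUE)
  }
  M <- as.matrix(read.csv(path, row.names = 1))
  stopifnot(nrow(M) == ncol(M))
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  v <- diag(M)
  C <- M
  diag(C) <- 1
  list(variances = v, corr = C, D = C * sqrt(outer(v, v)))
}

# nearest-PSD by eigenvalue clipping; assembled published matrices can be
# slightly indefinite and the generator needs a valid covariance
psd_clip <- function(D, eps = 1e-6) {
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, eps), nrow(D)) %*% t(e$vectors)
}

#' Default fixed-effect matrix of the generator
#'
#' 9 x 13 log-odds matrix on the trial design ([trial_terms()]). Intercepts
#' are calibrated so that, under the default covariate marginals and
#' random-intercept variances, marginal outcome prevalences match the
#' documentation/adherence rates of the emulated study (e.g. respiratory
#' rate 88.8%, oxygen saturation 60.9%, correct diagnosis 69.3%, correct
#' prescription 48.7%, correct dose 24.6%). Covariate effects are modest
#' common values; the arm-by-time interaction is positive (0.15 per month)
#' for the six indicators the study found to improve under enhanced audit
#' and feedback, and zero for cough, difficult breathing and AVPU.
#'
#' @return 9 x 13 matrix with outcome and term dimnames
#' @export
default_beta <- function() {
  intercepts <- c(3.7205, 3.0256, 2.3682, 0.0895, 2.0095, 1.3261,
                  0.6014, -0.6101, -1.8775)
  common <- c(age_grp = -0.15, pat_sex = 0.05, comorb0 = 0.10,
              comorb1 = 0.05, comorb2 = 0.0, cadre = 0.15, clin_sex = 0.10,
              workload = -0.25, malaria = 0.20, time = 0.02, arm = 0.10)
  time_arm <- c(0, 0, 0.15, 0.15, 0, 0.15, 0.15, 0.15, 0.15)
  beta <- cbind(intercepts, matrix(common, 9, 11, byrow = TRUE), time_arm)
  dimnames(beta) <- list(outcome_labels(), trial_terms())
  beta
}

#' Generator parameters
#'
#' Assembles and validates the parameter set of the synthetic trial
#' generator. Defaults emulate the study: 12 hospitals half in the
#' intervention arm, clinicians per hospital from a shifted negative
#' binomial with mean 32, patients per clinician from a shifted negative
#' binomial with mean 5.63 bounded to \[3, 46\], the printed covariate
#' marginals, the published (PSD-projected) random-intercept covariance,
#' follow-up uniform over 0-8 months, MCAR missingness at the printed rates
#' with 95% gender/cadre co-missingness coupling, and a 172/2299 share of
#' records lacking a clinician identifier.
#'
#' @param p_outcomes number of outcomes to generate (<= 9; defaults subset)
#' @param n_hospitals number of hospitals
#' @param arm_prop proportion of hospitals in the intervention arm
#' @param clinicians_per_hospital list(mean, size): shifted negative binomial
#'   (minimum 1)
#' @param patients_per_clinician list(mean, size, min, max)
#' @param beta fixed-effect matrix, p_outcomes x 13 (log-odds)
#' @param D_true p_outcomes x p_outcomes random-intercept covariance
#'   (log-odds squared); must be symmetric positive semidefinite
#' @param covariates list of category probabilities (see defaults)
#' @param missingness per-variable spec: each of `pat_sex`, `clin_sex`,
#'   `cadre` is list(rate, mechanism = "MCAR"|"MAR", predictors, slopes);
#'   `couple` is P(clinician sex missing | cadre missing)
#' @param unassigned_rate share of records lacking a clinician identifier
#' @param follow_up_months length-2 range of calendar time
#' @param seed integer RNG seed
#' @return validated list of class `trial_params`
#' @export
trial_params <- function(p_outcomes = 9,
                         n_hospitals = 12,
                         arm_prop = 0.5,
                         clinicians_per_hospital = list(mean = 32, size = 8),
                         patients_per_clinician = list(mean = 5.63, size = 1.5,
                                                       min = 3, max = 46),
                         beta = NULL,
                         D_true = NULL,
                         covariates = list(p_age_infant = 0.425,
                                           p_pat_male = 0.551,
                                           p_comorbid = c(0.468, 0.298, 0.179, 0.055),
                                           p_cadre_co = 0.644,
                                           p_clin_female = 0.432,
                                           n_malaria_high = 5,
                                           workload_prop = 0.5),
                         missingness = list(
                           pat_sex = list(rate = 17 / 2127, mechanism = "MCAR"),
                           clin_sex = list(rate = 83 / 378, mechanism = "MCAR"),
                           cadre = list(rate = 82 / 378, mechanism = "MCAR"),
                           couple = 0.95),
                         unassigned_rate = 172 / 2299,
                         follow_up_months = c(0, 8),
                         seed = 1L) {
  p <- as.integer(p_outcomes)
  stopifnot(p >= 1, p <= 9)
  if (is.null(beta)) beta <- default_beta()[seq_len(p), , drop = FALSE]
  if (is.null(D_true)) {
    D_true <- psd_clip(read_varcorr("mi")$D)[seq_len(p), seq_len(p), drop = FALSE]
  }
  beta <- as.matrix(beta)
  if (nrow(beta) != p || ncol(beta) != 13) {
    stop("beta must be ", p, " x 13 (one row per outcome, terms of trial_terms())")
  }
  D_true <- as.matrix(D_true)
  stopifnot(nrow(D_true) == p, ncol(D_true) == p)
  if (max(abs(D_true - t(D_true))) > 1e-8) stop("D_true must be symmetric")
  ev <- eigen((D_true + t(D_true)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(sprintf("D_true is not positive semidefinite (smallest eigenvalue %.6g)",
                 min(ev)))
  }
  rates <- c(missingness$pat_sex$rate, missingness$clin_sex$rate,
             missingness$cadre$rate, unassigned_rate)
  if (any(rates < 0 | rates > 1)) stop("all missingness rates must lie in [0, 1]")
  stopifnot(arm_prop >= 0, arm_prop <= 1,
            length(follow_up_months) == 2,
            follow_up_months[1] <= follow_up_months[2],
            abs(sum(covariates$p_comorbid) - 1) < 1e-8)
  structure(list(
    p_outcomes = p, n_hospitals = as.integer(n_hospitals), arm_prop = arm_prop,
    clinicians_per_hospital = clinicians_per_hospital,
    patients_per_clinician = patients_per_clinician,
    beta = beta, D_true = D_true, covariates = covariates,
    missingness = missingness, unassigned_rate = unassigned_rate,
    follow_up_months = follow_up_months, seed = as.integer(seed)
  ), class = "trial_params")
}

#' Generate a synthetic trial dataset
#'
#' Draws the three-level hierarchy (hospitals with arm/malaria/workload
#' labels, clinicians with cadre and sex, patients with age group, sex,
#' comorbidity count and admission time), one p-vector of correlated
#' clinician random intercepts b_j ~ MVN(0, D_true) shared by all of a
#' clinician's patients, and Bernoulli outcomes with
#' P(y_ir = 1) = logit^-1(x_i' beta_r + b_jr). Records lacking a clinician
#' identifier are appended at `unassigned_rate` (drawn with their own
#' independent intercepts); covariate missingness is imposed afterwards via
#' [impose_missingness()]. Bit-for-bit reproducible given the seed.
#'
#' @param params a [trial_params()] object
#' @param missingness impose the configured covariate missingness? (default
#'   TRUE; the underlying complete values are returned as attribute
#'   `complete` for calibration studies)
#' @return data frame in the trial schema with attributes `b` (the drawn
#'   random intercepts, clinicians x p), `params`, `complete`
#' @export
simulate_trial <- function(params = trial_params(), missingness = TRUE) {
  stopifnot(inherits(params, "trial_params"))
  with_seed(params$seed, {
    p <- params$p_outcomes
    L <- params$n_hospitals
    cv <- params$covariates

    # hospital-level labels; with few hospitals the three binary labels can
    # coincide by chance and break the analysis design's rank, so redraw
    for (attempt in 1:100) {
      arm <- integer(L)
      arm[sample.int(L, round(L * params$arm_prop))] <- 1L
      malaria <- integer(L)
      malaria[sample.int(L, min(cv$n_malaria_high, L))] <- 1L
      workload <- integer(L)
      workload[sample.int(L, round(L * cv$workload_prop))] <- 1L
      if (L < 4 || qr(cbind(1, arm, malaria, workload))$rank == 4) break
    }

    cph <- params$clinicians_per_hospital
    ncl <- 1L + rnbinom(L, mu = cph$mean - 1, size = cph$size)
    J <- sum(ncl)
    clin_hosp <- rep(seq_len(L), ncl)
    cadre <- rbinom(J, 1, cv$p_cadre_co)
    clin_sex <- rbinom(J, 1, cv$p_clin_female)

    ppc <- params$patients_per_clinician
    npat <- pmin(ppc$min + rnbinom(J, mu = ppc$mean - ppc$min, size = ppc$size),
                 ppc$max)
    N <- sum(npat)
    pat_clin <- rep(seq_len(J), npat)

    b <- rmvnorm_chol(J, params$D_true)

    dat <- data.frame(
      hospital_id = clin_hosp[pat_clin],
      clinician_id = pat_clin,
      patient_id = seq_len(N),
      time_months = round(runif(N, params$follow_up_months[1],
                                params$follow_up_months[2]), 3),
      arm = arm[clin_hosp[pat_clin]],
      malaria = malaria[clin_hosp[pat_clin]],
      workload = workload[clin_hosp[pat_clin]],
      cadre = cadre[pat_clin],
      clin_sex = clin_sex[pat_clin],
      age_group = rbinom(N, 1, cv$p_age_infant),
      pat_sex = rbinom(N, 1, cv$p_pat_male),
      comorbid = sample(0:3, N, TRUE, cv$p_comorbid)
    )
    eta <- trial_design(dat) %*% t(params$beta) + b[pat_clin, , drop = FALSE]
    Y <- matrix(rbinom(N * p, 1, plogis(eta)), N, p)
    colnames(Y) <- paste0("y", seq_len(p))
    dat <- cbind(dat, Y)

    u <- params$unassigned_rate
    n_un <- if (u > 0) rbinom(1, N, u / (1 - u)) else 0L
    if (n_un > 0) {
      un <- data.frame(
        hospital_id = sample.int(L, n_un, TRUE),
        clinician_id = NA_integer_,
        patient_id = N + seq_len(n_un),
        time_months = round(runif(n_un, params$follow_up_months[1],
                                  params$follow_up_months[2]), 3),
        arm = NA_integer_, malaria = NA_integer_, workload = NA_integer_,
        cadre = rbinom(n_un, 1, cv$p_cadre_co),
        clin_sex = rbinom(n_un, 1, cv$p_clin_female),
        age_group = rbinom(n_un, 1, cv$p_age_infant),
        pat_sex = rbinom(n_un, 1, cv$p_pat_male),
        comorbid = sample(0:3, n_un, TRUE, cv$p_comorbid)
      )
      un$arm <- arm[un$hospital_id]
      un$malaria <- malaria[un$hospital_id]
      un$workload <- workload[un$hospital_id]
      bu <- rmvnorm_chol(n_un, params$D_true)
      eu <- trial_design(un) %*% t(params$beta) + bu
      Yu <- matrix(rbinom(n_un * p, 1, plogis(eu)), n_un, p)
      colnames(Yu) <- paste0("y", seq_len(p))
      dat <- rbind(dat, cbind(un, Yu))
    }
    rownames(dat) <- NULL
    for (cc2 in setdiff(trial_schema(p), "time_months")) {
      dat[[cc2]] <- as.integer(dat[[cc2]])
    }
    complete <- dat
    if (missingness) {
      dat <- impose_missingness(dat, params$missingness,
                                seed = params$seed + 1000L)
    }
    attr(dat, "b") <- b
    attr(dat, "params") <- params
    attr(dat, "complete") <- complete
    dat
  })
}

#' Impose covariate missingness
#'
#' Blanks entries of `pat_sex` (patient level) and `clin_sex` / `cadre`
#' (clinician level: all of a clinician's rows are blanked together).
#' Under MCAR each unit is missing with the configured rate; under MAR the
#' missingness probability is logistic in the stated fully observed
#' covariates with the given slopes, with the intercept calibrated so the
#' marginal rate matches the configured rate. Clinician sex missingness is
#' coupled to cadre missingness: P(sex missing | cadre missing) equals
#' `couple` (default 0.95), with the sex rate preserved marginally.
#'
#' @param data trial data frame (complete in the target variables)
#' @param spec missingness spec as in [trial_params()]
#' @param seed RNG seed
#' @return data frame with NA entries in the targets; attribute
#'   `miss_pattern` records the indicator columns
#' @export
impose_missingness <- function(data, spec, seed = 1L) {
  with_seed(seed, {
    prob_of <- function(sp, df, unit_rows) {
      n <- length(unit_rows)
      if (sp$rate == 0) return(rep(0, n))
      if (identical(sp$mechanism, "MAR")) {
        stopifnot(!is.null(sp$predictors), !is.null(sp$slopes))
        Z <- as.matrix(df[unit_rows, sp$predictors, drop = FALSE])
        if (anyNA(Z)) {
          stop("MAR predictors must be fully observed (missingness would be MNAR): ",
               paste(sp$predictors, collapse = ", "))
        }
        s <- as.vector(Z %*% sp$slopes)
        a <- uniroot(function(a) mean(plogis(a + s)) - sp$rate, c(-30, 30),
                     tol = 1e-10)$root
        plogis(a + s)
      } else {
        rep(sp$rate, n)
      }
    }

    out <- data
    # patient sex
    if (!is.null(spec$pat_sex) && spec$pat_sex$rate > 0) {
      pr <- prob_of(spec$pat_sex, data, seq_len(nrow(data)))
      out$pat_sex[runif(nrow(data)) < pr] <- NA_integer_
    }
    # clinician-level: one draw per clinician
    cl <- data$clinician_id
    has_cl <- !is.na(cl)
    clin <- unique(cl[has_cl])
    first_row <- match(clin, cl)
    miss_cadre <- rep(FALSE, length(clin))
    if (!is.null(spec$cadre) && spec$cadre$rate > 0) {
      prc <- prob_of(spec$cadre, data, first_row)
      miss_cadre <- runif(length(clin)) < prc
    }
    miss_sex <- rep(FALSE, length(clin))
    if (!is.null(spec$clin_sex) && spec$clin_sex$rate > 0) {
      couple <- if (is.null(spec$couple)) 0.95 else spec$couple
      rs <- spec$clin_sex$rate
      rc <- mean(miss_cadre)
      if (identical(spec$clin_sex$mechanism, "MAR") || rc == 0) {
        prs <- prob_of(spec$clin_sex, data, first_row)
        miss_sex <- runif(length(clin)) < prs
      } else {
        # conditional rates preserving the marginal and the coupling
        p_giv_miss <- min(couple, 1)
        p_giv_obs <- max(0, min(1, (rs - p_giv_miss * rc) / (1 - rc)))
        pr <- ifelse(miss_cadre, p_giv_miss, p_giv_obs)
        miss_sex <- runif(length(clin)) < pr
      }
    }
    idx_cadre <- has_cl & cl %in% clin[miss_cadre]
    idx_sex <- has_cl & cl %in% clin[miss_sex]
    out$cadre[idx_cadre] <- NA_integer_
    out$clin_sex[idx_sex] <- NA_integer_
    attr(out, "miss_pattern") <- data.frame(
      pat_sex = is.na(out$pat_sex), clin_sex = is.na(out$clin_sex),
      cadre = is.na(out$cadre))
    out
  })
}

#' Exclude records lacking a clinician identifier
#'
#' The analysis dataset keeps only records that can be attributed to an
#' admitting clinician; the rest are excluded and reported.
#'
#' @param data trial data frame
#' @return list with `data` (retained rows) and `report`
#'   (excluded, total, pct to one decimal, and a formatted label such as
#'   "172/2299 (7.5%)")
#' @export
exclude_missing_cluster <- function(data) {
  miss <- is.na(data$clinician_id)
  total <- nrow(data)
  excluded <- sum(miss)
  pct <- round(100 * excluded / total, 1)
  kept <- data[!miss, , drop = FALSE]
  rownames(kept) <- NULL
  for (a in c("b", "params")) attr(kept, a) <- attr(data, a)
  list(data = kept,
       report = list(excluded = excluded, total = total, pct = pct,
                     label = sprintf("%d/%d (%.1f%%)", excluded, total, pct)))
}

trial_schema <- function(p = 9) {
  c("hospital_id", "clinician_id", "patient_id", "time_months", "arm",
    "malaria", "workload", "cadre", "clin_sex", "age_group", "pat_sex",
    "comorbid", paste0("y", seq_len(p)))
}

#' Counts of the three hierarchy levels
#' @param data trial data frame
#' @return list with `n_patients`, `n_clinicians`, `n_hospitals`
#' @export
trial_counts <- function(data) {
  list(n_patients = nrow(data),
       n_clinicians = length(unique(data$clinician_id[!is.na(data$clinician_id)])),
       n_hospitals = length(unique(data$hospital_id[!is.na(data$hospital_id)])))
}

#' Write a trial dataset to CSV
#'
#' Fixed 21-column header (hierarchy ids, covariates, y1..y9; fewer outcome
#' columns for desk-scale data), UTF-8, comma separated, empty field as the
#' missing-value sentinel. With `audit = TRUE` a sidecar
#' `<stem>_missing.csv` of boolean missingness indicators is also written.
#'
#' @param data trial data frame
#' @param path output path
#' @param audit also write the missingness-indicator sidecar?
#' @return `path`, invisibly
#' @export
write_trial_csv <- function(data, path, audit = FALSE) {
  p <- sum(grepl("^y[0-9]+$", names(data)))
  cols <- trial_schema(p)
  stopifnot(all(cols %in% names(data)))
  write.csv(data[, cols], path, row.names = FALSE, na = "", quote = FALSE)
  if (audit) {
    ind <- data.frame(patient_id = data$patient_id,
                      pat_sex_missing = is.na(data$pat_sex),
                      clin_sex_missing = is.na(data$clin_sex),
                      cadre_missing = is.na(data$cadre),
                      clinician_missing = is.na(data$clinician_id))
    write.csv(ind, sub("\\.csv$", "_missing.csv", path),
              row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a trial dataset from CSV
#'
#' Validates the schema: exact header, 0/1 outcomes with no missing values,
#' consistent clinician-to-hospital mapping. Rows with an empty clinician
#' identifier are admitted and left for [exclude_missing_cluster()].
#'
#' @param path CSV path written by [write_trial_csv()]
#' @return trial data frame
#' @export
read_trial_csv <- function(path) {
  hdr <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  p <- sum(grepl("^y[0-9]+$", hdr))
  want <- trial_schema(p)
  if (!identical(hdr, want)) {
    stop("schema error: header must be exactly: ", paste(want, collapse = ","))
  }
  dat <- read.csv(path, colClasses = c(rep("integer", 3), "numeric",
                                       rep("integer", 8 + p)),
                  na.strings = "")
  ycols <- paste0("y", seq_len(p))
  for (yc in ycols) {
    bad <- which(is.na(dat[[yc]]) | !(dat[[yc]] %in% c(0L, 1L)))
    if (length(bad)) {
      stop("schema error: non-binary or missing outcome ", yc, " in rows ",
           paste(head(bad, 10), collapse = ", "))
    }
  }
  ok <- !is.na(dat$clinician_id)
  map <- unique(dat[ok, c("clinician_id", "hospital_id")])
  dup <- map$clinician_id[duplicated(map$clinician_id)]
  if (length(dup)) {
    stop("schema error: clinician id(s) mapped to multiple hospitals: ",
         paste(head(dup, 10), collapse = ", "))
  }
  if (anyNA(dat$hospital_id[ok])) {
    stop("schema error: rows with clinician id but no hospital id: ",
         paste(head(which(ok & is.na(dat$hospital_id)), 10), collapse = ", "))
  }
  dat
}
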