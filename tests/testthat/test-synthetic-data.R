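test_that("generation is seed-deterministic down to the CSV bytes", {
  pp <- desk_params(seed = 7)
  d1 <- simulate_trial(pp)
  d2 <- simulate_trial(pp)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_csv(d1, f1); write_trial_csv(d2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("zero fixed effects and zero D give prevalence 1/2", {
  pp <- trial_params(p_outcomes = 2, n_hospitals = 10,
                     clinicians_per_hospital = list(mean = 40, size = 10),
                     patients_per_clinician = list(mean = 26, size = 5,
                                                   min = 3, max = 60),
                     beta = matrix(0, 2, 13), D_true = matrix(0, 2, 2),
                     unassigned_rate = 0, seed = 11)
  d <- simulate_trial(pp, missingness = FALSE)
  expect_gt(nrow(d), 8000)
  for (yc in c("y1", "y2")) {
    ph <- mean(d[[yc]])
    se <- sqrt(0.25 / nrow(d))
    expect_lt(abs(ph - 0.5), 4 * se)
  }
})

test_that("a non-PSD D_true is rejected with the offending eigenvalue", {
  Dbad <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(trial_params(p_outcomes = 2, beta = matrix(0, 2, 13),
                            D_true = Dbad),
               "positive semidefinite.*-1", ignore.case = TRUE)
})

test_that("drawn random intercepts recover D_true and drive cluster-level association", {
  Dt <- matrix(c(1, 0.8, 0.8, 1), 2)
  pp <- trial_params(p_outcomes = 2, n_hospitals = 50,
                     clinicians_per_hospital = list(mean = 40, size = 50),
                     patients_per_clinician = list(mean = 50, size = 20,
                                                   min = 40, max = 60),
                     beta = matrix(0, 2, 13), D_true = Dt,
                     unassigned_rate = 0, seed = 5)
  d <- simulate_trial(pp, missingness = FALSE)
  b <- attr(d, "b")
  expect_gte(nrow(b), 1500)
  # entrywise covariance recovery within 3 Monte-Carlo standard errors
  S <- cov(b)
  J <- nrow(b)
  for (i in 1:2) for (j in 1:2) {
    mc_se <- sqrt((Dt[i, j]^2 + Dt[i, i] * Dt[j, j]) / J)
    expect_lt(abs(S[i, j] - Dt[i, j]), 3 * mc_se)
  }
  # cluster-level empirical logits of the two outcomes co-vary
  el <- function(yc) {
    m <- tapply(d[[yc]], d$clinician_id, mean)
    qlogis(pmin(pmax(m, 0.02), 0.98))
  }
  r_high <- cor(el("y1"), el("y2"))
  expect_gt(r_high, 0.4)
  pp_lo <- trial_params(p_outcomes = 2, n_hospitals = 50,
                        clinicians_per_hospital = list(mean = 40, size = 50),
                        patients_per_clinician = list(mean = 50, size = 20,
                                                      min = 40, max = 60),
                        beta = matrix(0, 2, 13),
                        D_true = matrix(c(1, 0.2, 0.2, 1), 2),
                        unassigned_rate = 0, seed = 5)
  d_lo <- simulate_trial(pp_lo, missingness = FALSE)
  el2 <- function(yc) {
    m <- tapply(d_lo[[yc]], d_lo$clinician_id, mean)
    qlogis(pmin(pmax(m, 0.02), 0.98))
  }
  expect_gt(r_high, cor(el2("y1"), el2("y2")))
})

test_that("realized missingness matches the spec and couples gender to cadre", {
  d <- simulate_trial(trial_params(seed = 31))
  ana <- exclude_missing_cluster(d)$data
  cm <- ana[!duplicated(ana$clinician_id), ]
  J <- nrow(cm)
  for (chk in list(list(r = mean(is.na(cm$clin_sex)), t = 83 / 378, n = J),
                   list(r = mean(is.na(cm$cadre)), t = 82 / 378, n = J),
                   list(r = mean(is.na(ana$pat_sex)), t = 17 / 2127,
                        n = nrow(ana)))) {
    se <- sqrt(chk$t * (1 - chk$t) / chk$n)
    expect_lt(abs(chk$r - chk$t), 3 * se)
  }
  expect_gte(mean(is.na(cm$clin_sex[is.na(cm$cadre)])), 0.85)
})

test_that("rate-zero missingness is the identity and MAR tracks its driver", {
  d <- desk_trial_data(seed = 3)
  comp <- attr(d, "complete")
  d0 <- impose_missingness(comp, list(pat_sex = list(rate = 0, mechanism = "MCAR"),
                                      clin_sex = list(rate = 0, mechanism = "MCAR"),
                                      cadre = list(rate = 0, mechanism = "MCAR")),
                           seed = 1)
  expect_identical(as.data.frame(d0)[names(comp)], as.data.frame(comp))

  spec <- list(clin_sex = list(rate = 0.3, mechanism = "MAR",
                               predictors = "workload", slopes = 1.0),
               cadre = list(rate = 0, mechanism = "MCAR"),
               pat_sex = list(rate = 0, mechanism = "MCAR"))
  dm <- impose_missingness(comp, spec, seed = 9)
  cm <- dm[!duplicated(dm$clinician_id), ]
  r_hi <- mean(is.na(cm$clin_sex[cm$workload == 1]))
  r_lo <- mean(is.na(cm$clin_sex[cm$workload == 0]))
  expect_gt(r_hi, r_lo)
  # marginal rate calibrated
  expect_lt(abs(mean(is.na(cm$clin_sex)) - 0.3),
            3 * sqrt(0.3 * 0.7 / nrow(cm)))

  # MAR on a partially observed driver would be MNAR
  bad <- list(pat_sex = list(rate = 0.1, mechanism = "MAR",
                             predictors = "clin_sex", slopes = 1),
              clin_sex = list(rate = 0, mechanism = "MCAR"),
              cadre = list(rate = 0, mechanism = "MCAR"))
  dmiss <- d
  expect_error(impose_missingness(dmiss, bad, seed = 1), "MNAR|fully observed")
})

test_that("exclusion reporting reproduces count/denominator arithmetic", {
  base <- desk_trial_data(seed = 12)
  n_extra <- 2299 - nrow(base)
  d <- base[c(seq_len(nrow(base)), rep(1, max(n_extra, 0))), ]
  d <- d[seq_len(2299), ]
  d$clinician_id[seq_len(172)] <- NA
  ex <- exclude_missing_cluster(d)
  expect_identical(ex$report$label, "172/2299 (7.5%)")
  expect_equal(nrow(ex$data), 2127)

  ex0 <- exclude_missing_cluster(base)
  expect_identical(nrow(ex0$data), nrow(base))
  expect_equal(ex0$report$excluded, 0)

  d100 <- base[seq_len(100), ]
  d100$clinician_id[seq_len(10)] <- NA
  ex10 <- exclude_missing_cluster(d100)
  expect_equal(ex10$report$pct, 10.0)
  expect_equal(nrow(ex10$data), 90)
})

test_that("CSV round trip is the identity and schema violations are caught", {
  d <- desk_trial_data(seed = 8)
  f <- tempfile(fileext = ".csv")
  write_trial_csv(d, f)
  rd <- read_trial_csv(f)
  expect_identical(as.data.frame(d)[, names(rd)], rd)

  # hierarchy referential integrity survives the round trip
  map <- unique(rd[, c("clinician_id", "hospital_id")])
  expect_false(anyDuplicated(map$clinician_id) > 0)

  bad <- readLines(f)
  bad[2] <- sub("([01]),([01]),([01])$", "2,\\2,\\3", bad[2])
  fb <- tempfile(fileext = ".csv")
  writeLines(bad, fb)
  expect_error(read_trial_csv(fb), "schema error.*y1")

  # rows without clinician id are admitted and flagged for exclusion
  d2 <- d
  d2$clinician_id[1:3] <- NA
  f2 <- tempfile(fileext = ".csv")
  write_trial_csv(d2, f2)
  rd2 <- read_trial_csv(f2)
  expect_equal(sum(is.na(rd2$clinician_id)), 3)
  expect_equal(exclude_missing_cluster(rd2)$report$excluded, 3)
})
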