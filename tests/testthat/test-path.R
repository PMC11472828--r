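test_that("path specs validate edges and reject cycles", {
  expect_error(path_spec(list(c("a", "a"))), "distinct")
  expect_error(path_spec(list()), "non-empty")
  expect_error(path_spec(list(c("a", "b"), c("b", "c"), c("c", "a"))),
               "cyclic")
  expect_error(path_spec(list(c("a", "b"), c("a", "b"))), "duplicate")
  sp <- path_spec(list(c("a", "b"), c("b", "c")))
  expect_equal(sp$order, c("a", "b", "c"))
})

test_that("a deterministic chain is recovered exactly, with exact path tracing", {
  a <- seq(-2, 2, length.out = 40)
  tab <- data.frame(A = a, B = 0.7 * a, C = 0.5 * 0.7 * a)
  sp <- path_spec(list(c("A", "B"), c("B", "C")), covariates = character(0),
                  bootstrap_n = 50, seed = 1)
  fit <- fit_path_model(tab, sp, stratum = "toy")
  expect_equal(unname(fit$coefficients["A->B"]), 0.7, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["B->C"]), 0.5, tolerance = 1e-12)
  expect_equal(fit$indirect_effects$estimate, 0.35, tolerance = 1e-12)
  expect_equal(
    fit$total_effects$estimate[fit$total_effects$pair == "A->C"], 0.35,
    tolerance = 1e-12
  )
})

test_that("total effects equal direct plus the sum of indirect paths exactly", {
  set.seed(14)
  n <- 400
  a <- rnorm(n); b <- 0.6 * a + rnorm(n)
  c_ <- 0.4 * a + 0.5 * b + rnorm(n)
  tab <- data.frame(A = a, B = b, C = c_)
  sp <- path_spec(list(c("A", "B"), c("A", "C"), c("B", "C")),
                  covariates = character(0), bootstrap_n = 50, seed = 2)
  fit <- fit_path_model(tab, sp)
  direct <- unname(fit$coefficients["A->C"])
  indirect <- sum(fit$indirect_effects$estimate[
    fit$indirect_effects$source == "A" & fit$indirect_effects$target == "C"
  ])
  total <- fit$total_effects$estimate[fit$total_effects$pair == "A->C"]
  expect_equal(total, direct + indirect, tolerance = 1e-12)

  # each indirect effect is the exact product of its edge coefficients
  expect_equal(
    fit$indirect_effects$estimate[fit$indirect_effects$path == "A->B->C"],
    unname(fit$coefficients["A->B"] * fit$coefficients["B->C"]),
    tolerance = 1e-12
  )
})

test_that("per-equation least squares agrees with a joint-likelihood optimisation", {
  tab <- make_chain_data(n = 300, b_ab = 0.7, b_bc = 0.5, seed = 23)
  sp <- path_spec(list(c("A", "B"), c("B", "C")), covariates = character(0),
                  bootstrap_n = 50, seed = 3)
  fit <- fit_path_model(tab, sp)

  # independent FIML: maximise the joint Gaussian likelihood of the
  # recursive system over intercepts, slopes and residual SDs
  negll <- function(th) {
    -sum(dnorm(tab$B, th[1] + th[2] * tab$A, exp(th[3]), log = TRUE)) -
      sum(dnorm(tab$C, th[4] + th[5] * tab$B, exp(th[6]), log = TRUE))
  }
  start <- c(0, 0, log(sd(tab$B)), 0, 0, log(sd(tab$C)))
  opt <- optim(start, negll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(unname(fit$coefficients["A->B"]) - opt$par[2]), 1e-6)
  expect_lt(abs(unname(fit$coefficients["B->C"]) - opt$par[5]), 1e-6)
})

test_that("a null system produces small coefficients with CIs covering zero", {
  set.seed(9)
  n <- 500
  tab <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n))
  sp <- path_spec(list(c("A", "B"), c("A", "C"), c("B", "C")),
                  covariates = character(0), bootstrap_n = 400, seed = 4)
  fit <- fit_path_model(tab, sp)
  expect_true(all(abs(fit$coefficients) < 0.15))
  # no estimate more than 4 SEs from the generating zero
  expect_true(all(abs(fit$coefficients) / fit$std_errors < 4))
})

test_that("generating cascade coefficients are recovered within bootstrap CIs at n = 2000", {
  tab <- residualize_age(make_cohort(ageless_cascade_spec(n = 2000, seed = 7)))
  sp <- path_spec(default_cascade_edges(), bootstrap_n = 500, seed = 11)
  fit <- fit_path_model(tab, sp)
  truth <- c("wmh_cc->gfap" = 12, "wmh_cc->ptau217" = 0.015,
             "gfap->ptau217" = 0.001, "ptau217->nfl_age_resid" = 18,
             "wmh_cc->nfl_age_resid" = 1.2, "gfap->nfl_age_resid" = 0.04)
  # all edges close to truth; at least five of six simultaneous 95% CIs cover
  z <- abs(fit$coefficients[names(truth)] - truth) /
    fit$std_errors[names(truth)]
  expect_true(all(z < 4))
  in_ci <- vapply(names(truth), function(e) {
    fit$direct_ci[e, "ci_low"] <= truth[e] &&
      truth[e] <= fit$direct_ci[e, "ci_high"]
  }, logical(1))
  expect_gte(sum(in_ci), 5)
  # standardised coefficients are reported alongside
  expect_length(fit$coefficients_std, length(fit$coefficients))
})

test_that("bootstrap CIs are deterministic under a fixed seed", {
  tab <- make_chain_data(n = 200, b_ab = 0.7, b_bc = 0.5, seed = 31)
  sp <- path_spec(list(c("A", "B"), c("B", "C")), covariates = character(0),
                  bootstrap_n = 200, seed = 17)
  f1 <- fit_path_model(tab, sp)
  f2 <- fit_path_model(tab, sp)
  expect_identical(f1$indirect_effects, f2$indirect_effects)
  expect_identical(f1$total_effects, f2$total_effects)
})

test_that("bootstrap indirect-effect CIs cover the truth at close to the nominal rate", {
  sp <- path_spec(list(c("A", "B"), c("B", "C")), covariates = character(0),
                  bootstrap_n = 500, seed = 1)
  covered <- logical(200)
  for (i in seq_len(200)) {
    tab <- make_chain_data(n = 400, b_ab = 0.7, b_bc = 0.5, seed = 2000 + i)
    sp$seed <- 3000L + i
    fit <- fit_path_model(tab, sp, stratum = "toy")
    ie <- fit$indirect_effects
    covered[i] <- ie$ci_low[1] <= 0.35 && 0.35 <= ie$ci_high[1]
  }
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("stratified fits split the sample as the study design requires", {
  tab <- residualize_age(make_cohort(cohort_spec(n = 600, seed = 19)))
  sp <- path_spec(default_cascade_edges(), bootstrap_n = 100, seed = 5,
                  stratify_by = "diagnosis")
  fits <- fit_stratified(tab, sp)

  # combined sample keeps the undetermined subjects
  expect_equal(fits$combined$n, nrow(tab))
  expect_false("undetermined" %in% names(fits)[-1])
  expect_equal(
    sum(vapply(fits[-1], function(f) f$n, 0)),
    sum(tab$diagnosis != "undetermined")
  )

  # identical strata produce identical fits
  half <- make_cohort(cohort_spec(n = 120, seed = 23))
  dup <- rbind(half, half)
  dup$diagnosis <- factor(rep(c("MCI", "DS_AD"), each = 120),
                          levels = diagnosis_levels())
  dup$subject_id <- sprintf("S%04d", seq_len(240))
  dup <- residualize_age(dup)
  # residuals differ only through the shared fit; strata rows are identical
  fits2 <- fit_stratified(dup, sp)
  expect_equal(fits2$MCI$coefficients, fits2$DS_AD$coefficients,
               tolerance = 1e-12)

  # a stratum too small to fit is flagged, not an error
  tiny <- tab[1:30, ]
  tiny$diagnosis <- factor(c(rep("cognitively_stable", 27), rep("MCI", 3)),
                           levels = diagnosis_levels())
  tiny <- residualize_age(tiny)
  fits3 <- fit_stratified(tiny, sp)
  expect_true(fits3$MCI$skipped)
  expect_false(fits3$combined$skipped)
})

test_that("regime differences between strata are recovered", {
  # direct WMH -> NfL edge present only in the MCI stratum
  base <- c(age_wmh = 0, wmh_gfap = 12, wmh_ptau = 0.015, gfap_ptau = 0.001,
            ptau_nfl = 18, wmh_nfl = 0, gfap_nfl = 0.04)
  cs <- cohort_spec(
    n = 3000, seed = 41, coefficients = base,
    strata = list(
      proportions = c(cognitively_stable = 0.5, MCI = 0.5),
      overrides = list(MCI = c(wmh_nfl = 2.5))
    )
  )
  tab <- residualize_age(make_cohort(cs))
  sp <- path_spec(default_cascade_edges(), bootstrap_n = 300, seed = 6,
                  stratify_by = "diagnosis")
  fits <- fit_stratified(tab, sp)
  e <- "wmh_cc->nfl_age_resid"
  expect_gt(fits$MCI$direct_ci[e, "ci_low"], 0)
  ci_cs <- fits$cognitively_stable$direct_ci[e, ]
  expect_true(ci_cs["ci_low"] <= 0 && ci_cs["ci_high"] >= 0)
})

test_that("the age-driver variant roots the cascade in age and uses raw NfL", {
  tab <- residualize_age(make_cohort(cohort_spec(n = 2000, seed = 29)))
  sp <- path_spec(default_cascade_edges(), bootstrap_n = 300, seed = 8)
  fit <- fit_age_driver_model(tab, sp)
  expect_true("age->wmh_cc" %in% names(fit$coefficients))
  expect_true(all(grepl("nfl$|gfap$|ptau217$|wmh_cc$",
                        names(fit$coefficients))))
  expect_false(any(grepl("nfl_age_resid", names(fit$coefficients))))
  ci <- fit$direct_ci["age->wmh_cc", ]
  expect_true(ci["ci_low"] <= 0.15 && 0.15 <= ci["ci_high"])

  # constant age is a degenerate regression
  tab2 <- tab; tab2$age <- 45
  expect_error(fit_age_driver_model(tab2, sp), "constant")

  # nesting: on age-free data the downstream coefficients match the base fit
  tab3 <- residualize_age(make_cohort(ageless_cascade_spec(n = 3000, seed = 3)))
  base_fit <- fit_path_model(tab3, sp)
  age_fit <- fit_age_driver_model(tab3, sp)
  for (e in c("wmh_cc->gfap", "wmh_cc->ptau217", "gfap->ptau217")) {
    expect_equal(unname(age_fit$coefficients[e]),
                 unname(base_fit$coefficients[e]), tolerance = 1e-8)
  }
  expect_equal(unname(age_fit$coefficients["ptau217->nfl"]),
               unname(base_fit$coefficients["ptau217->nfl_age_resid"]),
               tolerance = 0.05)
})

test_that("DOT export writes the fitted graph", {
  tab <- make_chain_data(n = 100, b_ab = 0.7, b_bc = 0.5, seed = 2)
  sp <- path_spec(list(c("A", "B"), c("B", "C")), covariates = character(0),
                  bootstrap_n = 50, seed = 1)
  fit <- fit_path_model(tab, sp)
  p <- tempfile(fileext = ".dot")
  export_path_dot(fit, p)
  txt <- readLines(p)
  expect_true(any(grepl('"A" -> "B"', txt)))
  expect_true(any(grepl("digraph", txt)))
  unlink(p)
})
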