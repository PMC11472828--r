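#' Specification of a single mediation model
#'
#' @param treatment,mediator,outcome distinct column names of the cohort
#'   table.
#' @param covariates covariate columns (default `"site"`, entered as
#'   reference-coded indicators).
#' @param n_sims number of quasi-Bayesian Monte-Carlo draws (>= 100,
#'   default 1000).
#' @param seed RNG seed; results are deterministic given the seed.
#' @param ci_level percentile confidence level (default 0.95).
#' @return A `mediation_spec` list.
#' @export
mediation_spec <- function(treatment, mediator, outcome,
                           covariates = "site", n_sims = 1000, seed = 1,
                           ci_level = 0.95) {
  vars <- c(treatment, mediator, outcome)
  if (anyDuplicated(vars)) {
    stop("treatment, mediator and outcome must be distinct columns",
         call. = FALSE)
  }
  if (n_sims < 100) stop("`n_sims` must be at least 100", call. = FALSE)
  structure(
    list(treatment = treatment, mediator = mediator, outcome = outcome,
         covariates = covariates, n_sims = as.integer(n_sims),
         seed = as.integer(seed), ci_level = ci_level),
    class = "mediation_spec"
  )
}

# design matrix: intercept + columns (factors reference-coded)
mediation_design <- function(table, columns) {
  if (length(columns) == 0L) {
    return(matrix(1, nrow(table), 1, dimnames = list(NULL, "(Intercept)")))
  }
  dat <- table[, columns, drop = FALSE]
  for (cn in columns) if (is.character(dat[[cn]])) dat[[cn]] <- factor(dat[[cn]])
  stats::model.matrix(~ ., data = dat)
}

#' Estimate a causal mediation effect (quasi-Bayesian Monte Carlo)
#'
#' Decomposes the effect of a treatment on an outcome into the average
#' causal mediation effect (ACME) transmitted through the mediator and the
#' average direct effect (ADE). Two linear models are fitted by ordinary
#' least squares — mediator `M ~ T + covariates` and outcome
#' `Y ~ T + M + covariates` (no treatment-mediator interaction) — and
#' `n_sims` coefficient vectors are drawn from each model's asymptotic
#' multivariate normal sampling distribution. Per draw, ACME is the product
#' of the treatment-to-mediator and mediator-to-outcome coefficients and ADE
#' the direct treatment coefficient, so per draw ACME + ADE equals the total
#' effect exactly. Point estimates are means of draws, intervals are
#' percentile intervals, and p-values are doubled tail proportions of draws
#' crossing zero (floored at `2 / n_sims`). Effects are per 1-unit treatment
#' contrast on the analysis scale.
#'
#' @param table cohort `data.frame`.
#' @param spec a [mediation_spec()].
#' @return A `mediation_result` with `acme`, `acme_ci`, `acme_p`, `ade`,
#'   `ade_ci`, `ade_p`, `total`, `total_ci`, `total_p`, `prop_mediated`,
#'   `n`, `spec`, plus the fitted-coefficient products in `point_products`
#'   (`a_hat`, `b_hat`, `d_hat` from the two OLS fits).
#' @examples
#' tab <- make_cohort(cohort_spec(n = 200, seed = 5))
#' sp <- mediation_spec("wmh_cc", "gfap", "ptau217", n_sims = 200, seed = 9)
#' estimate_mediation(tab, sp)
#' @export
estimate_mediation <- function(table, spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  cols <- c(spec$treatment, spec$mediator, spec$outcome, spec$covariates)
  ok <- stats::complete.cases(table[, cols, drop = FALSE])
  if (sum(ok) < 10L) {
    stop("need at least 10 complete cases for mediation", call. = FALSE)
  }
  dat <- table[ok, , drop = FALSE]

  Xm <- mediation_design(dat, c(spec$treatment, spec$covariates))
  Xy <- mediation_design(dat, c(spec$treatment, spec$mediator,
                                spec$covariates))
  check_full_rank(Xm, "mediator model")
  check_full_rank(Xy, "outcome model")

  m_fit <- stats::lm.fit(Xm, dat[[spec$mediator]])
  y_fit <- stats::lm.fit(Xy, dat[[spec$outcome]])
  vc <- function(fit, X) {
    rdf <- length(fit$residuals) - fit$rank
    s2 <- sum(fit$residuals^2) / rdf
    V <- s2 * solve(crossprod(X))
    dimnames(V) <- list(colnames(X), colnames(X))
    V
  }
  Vm <- vc(m_fit, Xm); Vy <- vc(y_fit, Xy)

  a_hat <- m_fit$coefficients[[spec$treatment]]
  b_hat <- y_fit$coefficients[[spec$mediator]]
  d_hat <- y_fit$coefficients[[spec$treatment]]

  set.seed(spec$seed)
  dm <- MASS::mvrnorm(spec$n_sims, m_fit$coefficients, Vm)
  dy <- MASS::mvrnorm(spec$n_sims, y_fit$coefficients, Vy)
  i_t_m <- match(spec$treatment, colnames(Xm))
  i_m_y <- match(spec$mediator, colnames(Xy))
  i_t_y <- match(spec$treatment, colnames(Xy))

  acme_d <- dm[, i_t_m] * dy[, i_m_y]
  ade_d <- dy[, i_t_y]
  total_d <- acme_d + ade_d

  summarise <- function(d) {
    alpha <- 1 - spec$ci_level
    ci <- unname(stats::quantile(d, c(alpha / 2, 1 - alpha / 2), type = 7))
    p <- 2 * min(mean(d <= 0), mean(d >= 0))
    list(point = mean(d), ci = ci,
         p = min(1, max(p, 2 / spec$n_sims)), se = stats::sd(d))
  }
  s_acme <- summarise(acme_d); s_ade <- summarise(ade_d)
  s_tot <- summarise(total_d)

  structure(
    list(
      acme = s_acme$point, acme_ci = s_acme$ci, acme_p = s_acme$p,
      acme_se = s_acme$se,
      ade = s_ade$point, ade_ci = s_ade$ci, ade_p = s_ade$p,
      total = s_tot$point, total_ci = s_tot$ci, total_p = s_tot$p,
      prop_mediated = s_acme$point / s_tot$point,
      point_products = c(a_hat = a_hat, b_hat = b_hat, d_hat = d_hat),
      n = nrow(dat), spec = spec, reversed = FALSE
    ),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  dir <- if (isTRUE(x$reversed)) " (reversed)" else ""
  cat(sprintf(
    "<mediation_result>%s %s -> [%s] -> %s  (n = %d)\n",
    dir, x$spec$treatment, x$spec$mediator, x$spec$outcome, x$n
  ))
  cat(sprintf("  ACME  %.4g (%.4g, %.4g), P = %.3g\n",
              x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p))
  cat(sprintf("  ADE   %.4g (%.4g, %.4g), P = %.3g\n",
              x$ade, x$ade_ci[1], x$ade_ci[2], x$ade_p))
  cat(sprintf("  Total %.4g; proportion mediated %.3g\n",
              x$total, x$prop_mediated))
  invisible(x)
}

#' Mediation with treatment and mediator roles switched
#'
#' Directionality probe: identical machinery with the hypothesised predictor
#' and mediator exchanged. Reversing twice reproduces the forward
#' specification.
#'
#' @param table cohort `data.frame`.
#' @param spec a [mediation_spec()]; the swapped spec keeps the seed and
#'   settings.
#' @return A `mediation_result` with `reversed = TRUE`.
#' @export
reverse_mediation <- function(table, spec) {
  rspec <- reverse_spec(spec)
  res <- estimate_mediation(table, rspec)
  res$reversed <- TRUE
  res
}

#' @rdname reverse_mediation
#' @export
reverse_spec <- function(spec) {
  mediation_spec(
    treatment = spec$mediator, mediator = spec$treatment,
    outcome = spec$outcome, covariates = spec$covariates,
    n_sims = spec$n_sims, seed = spec$seed, ci_level = spec$ci_level
  )
}

#' The six-model mediation suite
#'
#' The three hypothesised models — (i) GFAP mediates WMH -> p-tau217,
#' (ii) p-tau217 mediates WMH -> age-residualised NfL, (iii) p-tau217
#' mediates GFAP -> age-residualised NfL — each in the forward and the
#' role-switched (reversed) direction, all adjusted for research site.
#'
#' @param table cohort `data.frame`; `nfl_age_resid` is computed if absent.
#' @param n_sims Monte-Carlo draws per model.
#' @param seed base seed; model `k` uses `seed + k - 1`.
#' @param covariates covariate columns (default `"site"`).
#' @return Named list of six `mediation_result`s
#'   (`wmh_gfap_ptau`, `wmh_ptau_nfl`, `gfap_ptau_nfl`, each also as
#'   `*_rev`).
#' @export
run_mediation_suite <- function(table, n_sims = 1000, seed = 1,
                                covariates = "site") {
  if (!"nfl_age_resid" %in% names(table)) {
    table <- residualize_age(table)
  }
  models <- list(
    wmh_gfap_ptau = c("wmh_cc", "gfap", "ptau217"),
    wmh_ptau_nfl = c("wmh_cc", "ptau217", "nfl_age_resid"),
    gfap_ptau_nfl = c("gfap", "ptau217", "nfl_age_resid")
  )
  out <- list()
  for (k in seq_along(models)) {
    v <- models[[k]]
    sp <- mediation_spec(v[1], v[2], v[3], covariates = covariates,
                         n_sims = n_sims, seed = seed + k - 1L)
    out[[names(models)[k]]] <- estimate_mediation(table, sp)
    out[[paste0(names(models)[k], "_rev")]] <- reverse_mediation(table, sp)
  }
  out
}

#' Summarise a mediation suite as a data frame
#'
#' @param suite result of [run_mediation_suite()].
#' @return A `data.frame` with one row per model.
#' @export
mediation_summary <- function(suite) {
  do.call(rbind, lapply(names(suite), function(nm) {
    x <- suite[[nm]]
    data.frame(
      model = nm, treatment = x$spec$treatment, mediator = x$spec$mediator,
      outcome = x$spec$outcome, reversed = isTRUE(x$reversed), n = x$n,
      acme = x$acme, acme_ci_low = x$acme_ci[1], acme_ci_high = x$acme_ci[2],
      acme_p = x$acme_p, ade = x$ade, total = x$total,
      prop_mediated = x$prop_mediated, stringsAsFactors = FALSE
    )
  }))
}
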