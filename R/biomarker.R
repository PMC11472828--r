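#' Read a cohort biomarker table from CSV
#'
#' Expects the shared schema (`subject_id`, `age`, `sex`, `site`,
#' `diagnosis`, `wmh_cc`, `abeta42`, `abeta40`, `ptau217`, `gfap`, `nfl`) and
#' computes the amyloid ratio `abeta42_40 = abeta42 / abeta40`, the plasma
#' amyloid pathology marker. Diagnosis values must come from the four-level
#' clinical vocabulary ([diagnosis_levels()]).
#'
#' @param path CSV file path.
#' @return A validated `data.frame` with an `abeta42_40` column.
#' @export
read_biomarker_table <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age", "sex", "site", "diagnosis", "wmh_cc",
                "abeta42", "abeta40", "ptau217", "gfap", "nfl")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop("cohort CSV is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(tab$diagnosis), diagnosis_levels())
  if (length(bad)) {
    stop("unknown diagnosis values: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab$diagnosis <- factor(tab$diagnosis, levels = diagnosis_levels())
  if (!"abeta42_40" %in% names(tab)) {
    tab$abeta42_40 <- tab$abeta42 / tab$abeta40
  }
  if (any(tab$age <= 0, na.rm = TRUE)) {
    stop("ages must be positive", call. = FALSE)
  }
  tab
}

#' Age-residualised NfL
#'
#' The pathophysiological progression of Alzheimer's disease in Down
#' syndrome is strongly age-dependent, so raw NfL mixes disease signal with
#' age. Residualising NfL on age (ordinary least squares, `nfl ~ age`)
#' yields a neurodegeneration measure orthogonal to age without removing the
#' age-driven variance from the upstream predictors.
#'
#' @param table cohort `data.frame` with `age` and `nfl` columns.
#' @return The table with an `nfl_age_resid` column (NA where `age` or
#'   `nfl` is missing); residuals have zero mean and are orthogonal to age.
#' @examples
#' tab <- make_cohort(cohort_spec(n = 50, seed = 2))
#' tab <- residualize_age(tab)
#' abs(mean(tab$nfl_age_resid)) < 1e-10
#' @export
residualize_age <- function(table) {
  ok <- stats::complete.cases(table[, c("age", "nfl")])
  if (sum(ok) < 3L) {
    stop("degenerate regression: need at least 3 complete (age, nfl) pairs",
         call. = FALSE)
  }
  if (stats::var(table$age[ok]) == 0) {
    stop("degenerate regression: age is constant", call. = FALSE)
  }
  fit <- stats::lm(nfl ~ age, data = table[ok, ])
  table$nfl_age_resid <- NA_real_
  table$nfl_age_resid[ok] <- stats::residuals(fit)
  table
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample Pearson correlation with the classical inferential pair: a
#' confidence interval from the Fisher z-transform,
#' `tanh(atanh(r) +/- z_{1-alpha/2} / sqrt(n - 3))`, and a two-sided p-value
#' from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Incomplete pairs are dropped (complete-case analysis).
#'
#' @param x,y numeric vectors of equal length.
#' @param conf_level confidence level (default 0.95).
#' @return List of class `correlation_record`: `r`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `conf_level`.
#' @examples
#' pearson_with_ci(1:10, (1:10) * 2 + rnorm(10, 0, 0.1))
#' @export
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) {
    stop("need at least 4 complete pairs for a Pearson correlation with CI",
         call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: constant input", call. = FALSE)
  }
  r <- stats::cor(x, y)
  z <- atanh(r)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- tanh(z + c(-1, 1) * zc / sqrt(n - 3))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  structure(
    list(r = r, ci_low = ci[1], ci_high = ci[2], p_value = p, n = n,
         conf_level = conf_level),
    class = "correlation_record"
  )
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf("r = %.3f (%.3f, %.3f), P = %.3g, n = %d\n",
              x$r, x$ci_low, x$ci_high, x$p_value, x$n))
  invisible(x)
}

#' Bivariate association table of biomarkers with neurodegeneration
#'
#' One Pearson correlation (with Fisher-z CI and t-test p-value) of each
#' predictor with the outcome, in the whole sample and, when `stratify` is
#' `TRUE`, within each clinical diagnosis group. Subjects with an
#' undetermined diagnosis contribute to the whole-sample rows but are
#' excluded from every stratified row. Strata with fewer than `min_n`
#' complete pairs (or constant inputs) are flagged `insufficient` rather
#' than silently dropped.
#'
#' @param table cohort `data.frame` (run [residualize_age()] first if the
#'   outcome is `nfl_age_resid`).
#' @param predictors character vector of predictor columns.
#' @param outcome outcome column (default `"nfl_age_resid"`).
#' @param stratify add per-diagnosis rows (default `TRUE`).
#' @param conf_level confidence level for the CIs.
#' @param min_n minimum complete pairs per record (default 4).
#' @return A `data.frame` with columns `stratum`, `predictor`, `n`, `r`,
#'   `ci_low`, `ci_high`, `p_value`, `insufficient`.
#' @export
correlation_table <- function(table,
                              predictors = c("wmh_cc", "abeta42_40",
                                             "ptau217", "gfap"),
                              outcome = "nfl_age_resid", stratify = TRUE,
                              conf_level = 0.95, min_n = 4L) {
  if (!outcome %in% names(table)) {
    stop(sprintf("outcome column '%s' not in table", outcome), call. = FALSE)
  }
  one <- function(rows, stratum, predictor) {
    x <- table[[predictor]][rows]
    y <- table[[outcome]][rows]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_n || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      return(data.frame(stratum = stratum, predictor = predictor,
                        n = sum(ok), r = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        insufficient = TRUE, stringsAsFactors = FALSE))
    }
    rec <- pearson_with_ci(x[ok], y[ok], conf_level)
    data.frame(stratum = stratum, predictor = predictor, n = rec$n,
               r = rec$r, ci_low = rec$ci_low, ci_high = rec$ci_high,
               p_value = rec$p_value, insufficient = FALSE,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(predictors, function(p) {
    one(rep(TRUE, nrow(table)), "whole_sample", p)
  }))
  if (stratify) {
    for (dg in setdiff(diagnosis_levels(), "undetermined")) {
      rows <- !is.na(table$diagnosis) & table$diagnosis == dg
      out <- rbind(out, do.call(rbind, lapply(predictors, function(p) {
        one(rows, dg, p)
      })))
    }
  }
  rownames(out) <- NULL
  out
}

# model-matrix rank guard shared by the regression layers; names offenders
check_full_rank <- function(X, context) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop(sprintf("collinearity in %s: rank-deficient design (columns: %s)",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' WMH-by-GFAP interaction model on p-tau217
#'
#' Probes the synergy between cerebrovascular disease and astrocytosis:
#' ordinary least squares `ptau217 ~ wmh_cc * gfap + site`, followed by
#' model-implied conditional slopes — the slope of each focal predictor on
#' p-tau217 evaluated at the mean of the moderator within moderator quantile
#' bins (tertiles by default). A positive interaction shows as a GFAP slope
#' that grows across WMH bins and vice versa.
#'
#' @param table cohort `data.frame` with complete `wmh_cc`, `gfap`,
#'   `ptau217`, `site`.
#' @param n_bins number of moderator quantile bins (default 3, tertiles).
#' @return List with `model` (the `lm` fit), `coefficients`, and
#'   `conditional_slopes`: a `data.frame` with `focal`, `moderator`, `bin`,
#'   `moderator_mean`, `slope`, `se`.
#' @export
fit_interaction_model <- function(table, n_bins = 3L) {
  need <- c("wmh_cc", "gfap", "ptau217", "site")
  ok <- stats::complete.cases(table[, need])
  dat <- table[ok, ]
  dat$site <- factor(dat$site)
  fml <- ptau217 ~ wmh_cc * gfap + site
  X <- stats::model.matrix(fml, dat)
  check_full_rank(X, "interaction model")
  fit <- stats::lm(fml, data = dat)
  cf <- stats::coef(fit)
  # analytic covariance without summary.lm's perfect-fit warning path
  s2 <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  V <- s2 * solve(crossprod(X))
  dimnames(V) <- list(colnames(X), colnames(X))

  slope_rows <- function(focal, moderator) {
    b_f <- cf[[focal]]
    b_i <- cf[["wmh_cc:gfap"]]
    mv <- dat[[moderator]]
    qs <- stats::quantile(mv, probs = seq(0, 1, length.out = n_bins + 1L),
                          type = 7)
    bin <- cut(mv, breaks = unique(qs), include.lowest = TRUE,
               labels = FALSE)
    do.call(rbind, lapply(sort(unique(bin)), function(b) {
      m_mean <- mean(mv[bin == b])
      slope <- b_f + b_i * m_mean
      v <- V[focal, focal] + m_mean^2 * V["wmh_cc:gfap", "wmh_cc:gfap"] +
        2 * m_mean * V[focal, "wmh_cc:gfap"]
      data.frame(focal = focal, moderator = moderator, bin = b,
                 moderator_mean = m_mean, slope = slope, se = sqrt(v),
                 stringsAsFactors = FALSE)
    }))
  }
  slopes <- rbind(slope_rows("gfap", "wmh_cc"), slope_rows("wmh_cc", "gfap"))
  rownames(slopes) <- NULL
  list(model = fit, coefficients = cf, conditional_slopes = slopes,
       n = nrow(dat))
}
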