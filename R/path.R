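#' Specification of a recursive path model
#'
#' A directed acyclic edge set over cohort columns. Each endogenous node
#' (one with at least one parent) is regressed on its parents plus the
#' covariates; direct effects are the regression coefficients, indirect
#' effects are products of coefficients along directed paths, and total
#' effects are sums over all directed paths. For a recursive system with
#' uncorrelated errors this per-equation least-squares estimator coincides
#' with full-information maximum likelihood.
#'
#' @param edges list of `c(source, target)` pairs (or a 2-column matrix).
#' @param covariates covariate columns added to every equation (default
#'   `"site"`).
#' @param stratify_by optional category column for [fit_stratified()].
#' @param bootstrap_n nonparametric bootstrap resamples for indirect/total
#'   effect CIs (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @param ci_level percentile CI level (default 0.95).
#' @return A `path_spec` list with the topological node order.
#' @export
path_spec <- function(edges, covariates = "site", stratify_by = NULL,
                      bootstrap_n = 2000, seed = 1, ci_level = 0.95) {
  if (is.matrix(edges)) edges <- asplit(edges, 1)
  edges <- lapply(edges, function(e) {
    e <- as.character(unlist(e))
    if (length(e) != 2L || e[1] == e[2]) {
      stop("each edge must be a (source, target) pair of distinct columns",
           call. = FALSE)
    }
    e
  })
  if (length(edges) == 0L) stop("edge set must be non-empty", call. = FALSE)
  em <- do.call(rbind, edges)
  if (anyDuplicated(paste(em[, 1], em[, 2]))) {
    stop("duplicate edges in path specification", call. = FALSE)
  }
  nodes <- unique(c(em[, 1], em[, 2]))
  order <- topo_sort(nodes, em)  # errors on cycles
  structure(
    list(edges = em, nodes = nodes, order = order, covariates = covariates,
         stratify_by = stratify_by, bootstrap_n = as.integer(bootstrap_n),
         seed = as.integer(seed), ci_level = ci_level),
    class = "path_spec"
  )
}

# Kahn's algorithm; error on cyclic graphs
topo_sort <- function(nodes, em) {
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (i in seq_len(nrow(em))) indeg[em[i, 2]] <- indeg[em[i, 2]] + 1L
  order <- character(0)
  ready <- names(indeg)[indeg == 0L]
  while (length(ready)) {
    nd <- ready[1]; ready <- ready[-1]
    order <- c(order, nd)
    ch <- em[em[, 1] == nd, 2]
    for (c2 in ch) {
      indeg[c2] <- indeg[c2] - 1L
      if (indeg[c2] == 0L) ready <- c(ready, c2)
    }
  }
  if (length(order) != length(nodes)) {
    stop("invalid path specification: edge graph is cyclic", call. = FALSE)
  }
  order
}

# all directed paths between every connected ordered node pair
enumerate_paths <- function(nodes, em) {
  adj <- lapply(stats::setNames(nodes, nodes), function(nd) em[em[, 1] == nd, 2])
  paths <- list()
  walk <- function(current, trail) {
    for (nxt in adj[[current]]) {
      p <- c(trail, nxt)
      paths[[length(paths) + 1L]] <<- p
      walk(nxt, p)
    }
  }
  for (nd in nodes) walk(nd, nd)
  paths
}

#' The default cascade edge set
#'
#' The hypothesised cerebrovascular cascade: WMH -> GFAP -> p-tau217 ->
#' age-residualised NfL, plus the direct edges WMH -> p-tau217, WMH -> NfL
#' and GFAP -> NfL (the full upper-triangular recursive system over the four
#' markers).
#'
#' @return List of `c(source, target)` edges.
#' @export
default_cascade_edges <- function() {
  list(
    c("wmh_cc", "gfap"), c("wmh_cc", "ptau217"), c("gfap", "ptau217"),
    c("ptau217", "nfl_age_resid"), c("wmh_cc", "nfl_age_resid"),
    c("gfap", "nfl_age_resid")
  )
}

# one set of per-equation OLS fits; returns named edge coefficient vector
# (and optionally standard errors) given precomputed design matrices
fit_equations <- function(designs, idx = NULL, with_se = FALSE) {
  coefs <- c(); ses <- c()
  for (eq in designs) {
    X <- eq$X; y <- eq$y
    if (!is.null(idx)) { X <- X[idx, , drop = FALSE]; y <- y[idx] }
    fit <- stats::lm.fit(X, y)
    cf <- fit$coefficients[eq$parents]
    names(cf) <- paste(eq$parents, eq$node, sep = "->")
    coefs <- c(coefs, cf)
    if (with_se) {
      rdf <- length(y) - fit$rank
      s2 <- sum(fit$residuals^2) / rdf
      V <- s2 * solve(crossprod(X))
      se <- sqrt(diag(V))[match(eq$parents, colnames(X))]
      names(se) <- paste(eq$parents, eq$node, sep = "->")
      ses <- c(ses, se)
    }
  }
  if (with_se) list(coefficients = coefs, std_errors = ses) else coefs
}

path_products <- function(paths, coefs) {
  vapply(paths, function(p) {
    e <- paste(p[-length(p)], p[-1], sep = "->")
    prod(coefs[e])
  }, numeric(1))
}

#' Fit a recursive path model
#'
#' Per-equation ordinary least squares over the acyclic edge set of `spec`
#' (each endogenous node on its parents plus covariates), followed by path
#' tracing: every indirect effect is the product of its edge coefficients,
#' and the total effect between two nodes is the sum over all directed
#' paths (direct edge included). Standard errors of direct effects are
#' analytic; indirect and total effects get percentile CIs from a
#' seed-fixed nonparametric bootstrap. Both unstandardised and standardised
#' (all model variables z-scored) coefficients are reported.
#'
#' @param table cohort `data.frame`.
#' @param spec a [path_spec()].
#' @param stratum label stored on the fit (default "combined").
#' @return A `path_fit`: `coefficients`, `std_errors`, `coefficients_std`,
#'   `direct_ci`, `indirect_effects` (per directed path of length >= 2),
#'   `total_effects` (per connected ordered pair), `stratum`, `n`, `spec`.
#' @examples
#' tab <- residualize_age(make_cohort(cohort_spec(n = 150, seed = 4)))
#' sp <- path_spec(default_cascade_edges(), bootstrap_n = 100, seed = 2)
#' fit_path_model(tab, sp)
#' @export
fit_path_model <- function(table, spec, stratum = "combined") {
  stopifnot(inherits(spec, "path_spec"))
  need <- unique(c(spec$nodes, spec$covariates))
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("table lacks path-model columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ok <- stats::complete.cases(table[, need, drop = FALSE])
  dat <- table[ok, , drop = FALSE]
  em <- spec$edges
  endo <- unique(em[, 2])

  build_designs <- function(d) {
    lapply(stats::setNames(endo, endo), function(nd) {
      parents <- em[em[, 2] == nd, 1]
      X <- mediation_design(d, c(parents, spec$covariates))
      list(node = nd, parents = parents, X = X, y = d[[nd]])
    })
  }
  designs <- build_designs(dat)
  max_p <- 0L
  for (eq in designs) {
    if (stats::var(eq$y) == 0) {
      stop(sprintf("degenerate regression: '%s' is constant", eq$node),
           call. = FALSE)
    }
    for (pv in eq$parents) {
      if (stats::var(dat[[pv]]) == 0) {
        stop(sprintf("degenerate regression: '%s' is constant", pv),
             call. = FALSE)
      }
    }
    check_full_rank(eq$X, sprintf("equation for '%s'", eq$node))
    max_p <- max(max_p, ncol(eq$X))
  }
  if (nrow(dat) < max_p + 2L) {
    stop(sprintf("too few complete cases (%d) for the path model", nrow(dat)),
         call. = FALSE)
  }

  point <- fit_equations(designs, with_se = TRUE)
  coefs <- point$coefficients

  # standardised variant: z-score every model node
  dat_z <- dat
  for (nd in spec$nodes) dat_z[[nd]] <- as.numeric(scale(dat_z[[nd]]))
  coefs_std <- fit_equations(build_designs(dat_z))

  paths <- enumerate_paths(spec$nodes, em)
  path_id <- vapply(paths, paste, "", collapse = "->")
  est <- path_products(paths, coefs)
  pair <- t(vapply(paths, function(p) c(p[1], p[length(p)]), character(2)))
  pair_id <- paste(pair[, 1], pair[, 2], sep = "->")
  tot <- tapply(est, pair_id, sum)

  # bootstrap for edge, indirect and total CIs
  B <- spec$bootstrap_n
  alpha <- 1 - spec$ci_level
  set.seed(spec$seed)
  n <- nrow(dat)
  boot_edges <- matrix(NA_real_, B, length(coefs),
                       dimnames = list(NULL, names(coefs)))
  boot_paths <- matrix(NA_real_, B, length(paths))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    cb <- tryCatch(fit_equations(designs, idx = idx), error = function(e) NULL)
    if (is.null(cb)) next
    boot_edges[b, ] <- cb
    boot_paths[b, ] <- path_products(paths, cb)
  }
  qr2 <- function(v) unname(stats::quantile(v, c(alpha / 2, 1 - alpha / 2),
                                            na.rm = TRUE, type = 7))
  direct_ci <- t(apply(boot_edges, 2, qr2))
  colnames(direct_ci) <- c("ci_low", "ci_high")

  indirect <- data.frame(
    source = pair[, 1], target = pair[, 2], path = path_id,
    estimate = est, stringsAsFactors = FALSE
  )
  pci <- t(apply(boot_paths, 2, qr2))
  indirect$ci_low <- pci[, 1]; indirect$ci_high <- pci[, 2]
  indirect <- indirect[vapply(paths, length, 1L) > 2L, , drop = FALSE]
  rownames(indirect) <- NULL

  boot_tot <- sapply(sort(unique(pair_id)), function(pid) {
    rowSums(boot_paths[, pair_id == pid, drop = FALSE])
  })
  tot_ids <- sort(unique(pair_id))
  tci <- t(apply(boot_tot, 2, qr2))
  total <- data.frame(
    pair = tot_ids,
    estimate = as.numeric(tot[tot_ids]),
    ci_low = tci[, 1], ci_high = tci[, 2], stringsAsFactors = FALSE
  )
  rownames(total) <- NULL

  structure(
    list(coefficients = coefs, std_errors = point$std_errors,
         coefficients_std = coefs_std, direct_ci = direct_ci,
         indirect_effects = indirect, total_effects = total,
         stratum = stratum, n = n, spec = spec, skipped = FALSE),
    class = "path_fit"
  )
}

#' @export
print.path_fit <- function(x, ...) {
  cat(sprintf("<path_fit> stratum '%s', n = %d\n", x$stratum, x$n))
  if (isTRUE(x$skipped)) {
    cat("  fit skipped:", x$reason, "\n")
    return(invisible(x))
  }
  for (e in names(x$coefficients)) {
    cat(sprintf("  %-28s %8.4g (SE %.3g)\n", e, x$coefficients[e],
                x$std_errors[e]))
  }
  invisible(x)
}

#' Combined and diagnosis-stratified path fits
#'
#' One fit on the combined sample (undetermined-diagnosis subjects
#' included — the combined analysis does not consider diagnosis) and one per
#' diagnosis stratum (undetermined excluded). Strata with too few complete
#' cases are returned as flagged, skipped entries rather than errors.
#'
#' @param table cohort `data.frame`.
#' @param spec a [path_spec()] with `stratify_by` set (default
#'   `"diagnosis"` if `NULL`).
#' @return Named list of `path_fit` objects (`combined` plus one per
#'   stratum).
#' @export
fit_stratified <- function(table, spec) {
  by <- spec$stratify_by
  if (is.null(by)) by <- "diagnosis"
  out <- list(combined = fit_path_model(table, spec, stratum = "combined"))
  levels_ <- setdiff(unique(as.character(table[[by]])), "undetermined")
  for (lv in sort(levels_)) {
    sub <- table[!is.na(table[[by]]) & table[[by]] == lv, , drop = FALSE]
    out[[lv]] <- tryCatch(
      fit_path_model(sub, spec, stratum = lv),
      error = function(e) {
        structure(
          list(stratum = lv, n = nrow(sub), skipped = TRUE,
               reason = conditionMessage(e), spec = spec),
          class = "path_fit"
        )
      }
    )
  }
  out
}

#' Age-driver variant of the path model
#'
#' Re-expresses the cascade with chronological age as the exogenous root:
#' adds an age -> WMH edge and uses raw NfL (not age-residualised) as the
#' terminal outcome, since age itself is now modelled.
#'
#' @param table cohort `data.frame`.
#' @param spec a [path_spec()]; its edges are rewritten by substituting
#'   `nfl_age_resid` with `nfl` and prepending the `age -> wmh_cc` edge.
#' @param wmh_col name of the WMH column age feeds into.
#' @return A `path_fit` for the extended model.
#' @export
fit_age_driver_model <- function(table, spec, wmh_col = "wmh_cc") {
  em <- spec$edges
  em[em == "nfl_age_resid"] <- "nfl"
  edges <- c(list(c("age", wmh_col)), asplit(em, 1))
  spec2 <- path_spec(edges, covariates = spec$covariates,
                     stratify_by = spec$stratify_by,
                     bootstrap_n = spec$bootstrap_n, seed = spec$seed,
                     ci_level = spec$ci_level)
  fit_path_model(table, spec2, stratum = "combined_age_driver")
}

#' Export a fitted path graph as DOT
#'
#' Writes a Graphviz DOT file with edge weights (unstandardised
#' coefficients) for diagram rendering.
#'
#' @param fit a `path_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_path_dot <- function(fit, path) {
  lines <- c("digraph path_model {", "  rankdir=LR;")
  for (e in names(fit$coefficients)) {
    ends <- strsplit(e, "->", fixed = TRUE)[[1]]
    lines <- c(lines, sprintf('  "%s" -> "%s" [label="%.3g"];',
                              ends[1], ends[2], fit$coefficients[e]))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
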