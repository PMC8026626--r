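#' Pool event proportions across groups
#'
#' @param counts list of `c(events, n)` pairs (or a 2-column matrix).
#' @return pooled proportion `sum(events) / sum(n)`.
#' @export
pooled_proportion <- function(counts) {
  if (is.list(counts)) counts <- do.call(rbind, counts)
  stopifnot(ncol(counts) == 2L, all(counts[, 1L] <= counts[, 2L]),
            all(counts >= 0))
  n <- sum(counts[, 2L])
  if (n == 0) stop("total group size is zero")
  sum(counts[, 1L]) / n
}

#' Pool group means and standard deviations
#'
#' Weighted mean, with the pooled SD from the within + between variance
#' decomposition: `var = (sum((n_i - 1) s_i^2 + n_i (m_i - M)^2)) / (N - 1)`.
#'
#' @param groups data frame (or list of lists) with columns/fields `n`,
#'   `mean`, `sd`.
#' @return list `n`, `mean`, `sd`.
#' @export
pooled_mean_sd <- function(groups) {
  if (!is.data.frame(groups)) {
    groups <- do.call(rbind, lapply(groups, as.data.frame))
  }
  stopifnot(all(c("n", "mean") %in% names(groups)), all(groups$n > 0))
  if (is.null(groups$sd)) groups$sd <- 0
  N <- sum(groups$n)
  M <- sum(groups$n * groups$mean) / N
  if (N <= 1) return(list(n = N, mean = M, sd = NA_real_))
  ss <- sum((groups$n - 1) * groups$sd^2 + groups$n * (groups$mean - M)^2)
  list(n = N, mean = M, sd = sqrt(ss / (N - 1)))
}

#' Pearson chi-squared test of independence
#'
#' Pearson statistic without continuity correction,
#' `df = (r - 1)(c - 1)`, p from the upper chi-squared tail.
#'
#' @param table matrix of non-negative counts.
#' @return list `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("contingency table has a zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Two-sample t test from summary statistics
#'
#' @param a,b lists `n`, `mean`, `sd` describing the two groups.
#' @param mode `"pooled"` (Student, default) or `"welch"`.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(a, b, mode = c("pooled", "welch")) {
  mode <- match.arg(mode)
  stopifnot(a$n >= 2, b$n >= 2)
  diff <- a$mean - b$mean
  if (mode == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  t <- if (se == 0) 0 else diff / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way analysis of variance
#'
#' @param groups named list of numeric vectors (each `n >= 2`).
#' @return list `F`, `df`, `p`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 0L) >= 2L))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(fit$statistic),
       df = unname(c(fit$parameter[1L], fit$parameter[2L])),
       p = unname(fit$p.value))
}

#' Kruskal-Wallis rank test (with tie correction)
#'
#' @param groups named list of numeric vectors.
#' @return list `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(vapply(groups, length, 0L) >= 1L))
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  fit <- stats::kruskal.test(values, g)
  list(H = unname(fit$statistic), df = unname(fit$parameter),
       p = unname(fit$p.value))
}

#' Logistic regression with Wald confidence intervals
#'
#' Maximum-likelihood fit (IRLS via [stats::glm()]) of a binary outcome on
#' numeric predictors, reporting odds ratios with Wald 95% intervals.
#' When the fit does not converge or a coefficient diverges (as under
#' perfect separation) the result is flagged and no estimates are
#' returned.
#'
#' @param outcome binary (0/1 or logical) response.
#' @param predictors data frame of numeric predictors (an ordinal edema
#'   type can be encoded 1-5 in progression order).
#' @param level confidence level (default 0.95).
#' @return list `coefficients` (data frame: term, estimate, se, z, p, or,
#'   ci_low, ci_high), `converged`, `separated`.
#' @export
logistic_regression <- function(outcome, predictors, level = 0.95) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)), is.data.frame(predictors),
            nrow(predictors) == length(outcome))
  if (length(outcome) < 10L) stop("need at least 10 observations")
  dat <- cbind(data.frame(.y = outcome), predictors)
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()))
  # under (near-)perfect separation the linear predictor diverges
  eta <- stats::predict(fit)
  separated <- !fit$converged || max(abs(eta)) > 15
  if (separated) {
    return(list(coefficients = NULL, converged = fit$converged,
                separated = TRUE))
  }
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  co <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                   z = sm[, 3L], p = sm[, 4L],
                   or = exp(sm[, 1L]),
                   ci_low = exp(sm[, 1L] - z * sm[, 2L]),
                   ci_high = exp(sm[, 1L] + z * sm[, 2L]),
                   row.names = NULL)
  list(coefficients = co, converged = TRUE, separated = FALSE)
}

# per-type cohort parameters of the reference population: group sizes,
# means +/- SD of the continuous variables and event counts of the binary
# ones, ordered FC/NF, PC/NF, PC/DF, DF/DF, DF/DF + SF
reference_cohort_params <- function() {
  data.frame(
    type = observed_types(),
    n = c(24, 25, 16, 37, 26),
    age_mean = c(64.4, 62.3, 70.3, 63.9, 60.2),
    age_sd = c(12.2, 11.5, 8.3, 8.8, 11.6),
    female = c(6, 12, 8, 16, 8),
    hba1c_mean = c(7.2, 6.9, 7.3, 8.2, 8.1),
    hba1c_sd = c(1.4, 1.0, 1.6, 1.9, 2.1),
    bcva_logmar_mean = c(0.17, 0.27, 0.47, 0.46, 0.50),
    bcva_logmar_sd = c(0.20, 0.26, 0.40, 0.30, 0.35),
    pvd = c(10, 8, 7, 16, 17),
    ez = c(0, 5, 5, 25, 25),
    cst_mean = c(304.4, 385.2, 420.8, 407.9, 493.5),
    cst_sd = c(42.7, 80.4, 82.4, 129.0, 106.0),
    erm = c(9, 12, 8, 19, 12),
    mdrf_mean = c(49.7, 41.4, 57.9, 54.3, 57.2),
    mdrf_sd = c(33.8, 26.0, 16.0, 44.2, 46.5))
}

#' Simulate a table-level cohort
#'
#' Draws per-eye records from per-type distributions (normal for the
#' continuous variables, truncated at plausible floors; binomial for the
#' binary ones) whose defaults are the reference population parameters.
#' Useful for exercising [table2_report()] and the regression analyses on
#' data with a known generating process.
#'
#' @param n_per_type integer vector of group sizes in the order of
#'   [observed_types()]; default the reference group sizes.
#' @param seed RNG seed.
#' @param params parameter table in the format of the default.
#' @return a `cohort_table` data frame.
#' @export
simulate_cohort <- function(n_per_type = NULL, seed = 1L, params = NULL) {
  if (is.null(params)) params <- reference_cohort_params()
  if (is.null(n_per_type)) n_per_type <- params$n
  stopifnot(length(n_per_type) == nrow(params))
  with_local_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      n <- n_per_type[i]
      if (n == 0L) return(NULL)
      erm <- stats::runif(n) < p$erm / p$n
      mdrf <- ifelse(erm,
                     pmax(stats::rnorm(n, p$mdrf_mean, p$mdrf_sd), 0),
                     NA_real_)
      logmar <- pmax(stats::rnorm(n, p$bcva_logmar_mean, p$bcva_logmar_sd),
                     -0.3)
      data.frame(
        eye_id = sprintf("%s-%02d", gsub("[ /+]", "", p$type), seq_len(n)),
        age = round(pmax(stats::rnorm(n, p$age_mean, p$age_sd), 30)),
        sex = ifelse(stats::runif(n) < p$female / p$n, "F", "M"),
        hba1c = pmax(stats::rnorm(n, p$hba1c_mean, p$hba1c_sd), 4.5),
        bcva_decimal = 10^(-logmar),
        dme_type = p$type,
        cst_um = pmax(stats::rnorm(n, p$cst_mean, p$cst_sd), 150),
        ez_disrupted = stats::runif(n) < p$ez / p$n,
        erm_present = erm,
        mdrf_um = mdrf,
        pvd_incomplete = stats::runif(n) < p$pvd / p$n)
    })
    as_cohort_table(do.call(rbind, rows))
  })
}

#' Per-type and pooled cohort comparison report
#'
#' Reproduces the standard comparison layout for a labelled cohort: one
#' column per observed type with n (%), mean +/- SD or count (%) for each
#' variable, the across-type test for each row (chi-squared for counts,
#' one-way ANOVA for age/HbA1c/CST/MDRF, Kruskal-Wallis for BCVA), and a
#' pooled two-group block comparing eyes with vs without diffuse
#' Segment-2 fluid (Student's t for BCVA and CST, chi-squared for EZ
#' disruption and ERM incidence).
#'
#' @param cohort a `cohort_table` (see [read_cohort()]).
#' @return list `per_type` (data frame of group summaries), `tests`
#'   (named list of test results), `pooled` (two-group block), `n_total`.
#' @export
table2_report <- function(cohort) {
  stopifnot(inherits(cohort, "data.frame"))
  types <- intersect(observed_types(), unique(cohort$dme_type))
  groups <- lapply(types, function(t) cohort[cohort$dme_type == t, ])
  names(groups) <- types
  n <- vapply(groups, nrow, 0L)
  N <- nrow(cohort)

  msd <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  per_type <- data.frame(
    type = types, n = n, pct = 100 * n / N,
    age_mean = vapply(groups, function(g) mean(g$age), 0),
    age_sd = vapply(groups, function(g) stats::sd(g$age), 0),
    female = vapply(groups, function(g) sum(g$sex == "F"), 0L),
    hba1c_mean = vapply(groups, function(g) mean(g$hba1c), 0),
    hba1c_sd = vapply(groups, function(g) stats::sd(g$hba1c), 0),
    bcva_logmar_mean = vapply(groups, function(g) mean(g$bcva_logmar), 0),
    bcva_logmar_sd = vapply(groups, function(g) stats::sd(g$bcva_logmar), 0),
    pvd_incomplete = vapply(groups, function(g) sum(g$pvd_incomplete), 0L),
    ez_disrupted = vapply(groups, function(g) sum(g$ez_disrupted), 0L),
    cst_mean = vapply(groups, function(g) mean(g$cst_um), 0),
    cst_sd = vapply(groups, function(g) stats::sd(g$cst_um), 0),
    erm_present = vapply(groups, function(g) sum(g$erm_present), 0L),
    mdrf_mean = vapply(groups, function(g) mean(g$mdrf_um, na.rm = TRUE), 0),
    mdrf_sd = vapply(groups, function(g) stats::sd(g$mdrf_um, na.rm = TRUE), 0),
    row.names = NULL)

  tests <- list()
  can_test <- length(types) >= 2L && all(n >= 2L)
  if (can_test) {
    bin_tab <- function(count) rbind(count, n - count)
    tests <- list(
      n = list(p = stats::chisq.test(n)$p.value),
      age = anova_oneway(lapply(groups, function(g) g$age)),
      sex = chi_square_independence(bin_tab(per_type$female)),
      hba1c = anova_oneway(lapply(groups, function(g) g$hba1c)),
      bcva = kruskal_wallis(lapply(groups, function(g) g$bcva_logmar)),
      pvd = chi_square_independence(bin_tab(per_type$pvd_incomplete)),
      ez = chi_square_independence(bin_tab(per_type$ez_disrupted)),
      cst = anova_oneway(lapply(groups, function(g) g$cst_um)),
      erm = chi_square_independence(bin_tab(per_type$erm_present)))
    mdrf_groups <- lapply(groups, function(g) g$mdrf_um[!is.na(g$mdrf_um)])
    mdrf_groups <- mdrf_groups[vapply(mdrf_groups, length, 0L) >= 2L]
    if (length(mdrf_groups) >= 2L) {
      tests$mdrf <- anova_oneway(mdrf_groups)
    }
  }

  pooled <- NULL
  wet <- cohort[cohort$segment2_fluid, ]
  dry <- cohort[!cohort$segment2_fluid, ]
  if (nrow(wet) >= 2L && nrow(dry) >= 2L) {
    sumstat <- function(v) list(n = sum(!is.na(v)), mean = mean(v, na.rm = TRUE),
                                sd = stats::sd(v, na.rm = TRUE))
    pooled <- list(
      n = c(dry = nrow(dry), wet = nrow(wet)),
      ez_proportion = c(dry = mean(dry$ez_disrupted),
                        wet = mean(wet$ez_disrupted)),
      cst = list(dry = sumstat(dry$cst_um), wet = sumstat(wet$cst_um)),
      bcva = list(dry = sumstat(dry$bcva_logmar),
                  wet = sumstat(wet$bcva_logmar)),
      t_cst = two_sample_t(sumstat(dry$cst_um), sumstat(wet$cst_um)),
      t_bcva = two_sample_t(sumstat(dry$bcva_logmar),
                            sumstat(wet$bcva_logmar)),
      chi_ez = chi_square_independence(rbind(
        c(sum(dry$ez_disrupted), sum(!dry$ez_disrupted)),
        c(sum(wet$ez_disrupted), sum(!wet$ez_disrupted)))),
      chi_erm = chi_square_independence(rbind(
        c(sum(dry$erm_present), sum(!dry$erm_present)),
        c(sum(wet$erm_present), sum(!wet$erm_present)))))
  }
  list(per_type = per_type, tests = tests, pooled = pooled, n_total = N)
}
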