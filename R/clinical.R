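## Responder bookkeeping and the ROI-level frequentist / Bayesian statistics:
## covariate-adjusted group tests, JZS Bayes-factor t-tests, stretched-beta
## Bayes-factor correlations, bootstrap Pearson correlations, Tukey-corrected
## simple effects and Levene's variance test.

#' Average repeated baseline VAS measurements
#'
#' Baseline pain is measured up to three times over the pre-treatment window
#' (to damp regression to the mean) and the arithmetic mean is used as the
#' working baseline.
#'
#' @param repeats numeric vector of 1-3 finite VAS values in \[0, 10\].
#' @return the mean.
#' @export
average_baseline_vas <- function(repeats) {
  repeats <- as.numeric(repeats)
  if (!length(repeats)) stop("no baseline measurements", call. = FALSE)
  if (length(repeats) > 3L)
    stop("at most three baseline measurements expected", call. = FALSE)
  if (any(!is.finite(repeats)) || any(repeats < 0) || any(repeats > 10))
    stop("VAS values must be finite and in [0, 10]", call. = FALSE)
  mean(repeats)
}

#' Classify analgesic responders by percent VAS decrease
#'
#' Percent analgesia is `100 * (baseline - post) / baseline`; a subject is a
#' responder iff it reaches `threshold_pct` (default 20, i.e. at least a 20%
#' decrease in VAS pain from baseline). When repeat columns
#' `vas_baseline_1..3` are present the baseline is their mean, otherwise the
#' `vas_baseline` column is used directly.
#'
#' @param table data.frame with `subject_id`, `vas_post` and either
#'   `vas_baseline` or `vas_baseline_1..3`.
#' @param threshold_pct responder threshold in percent (default 20).
#' @return data.frame: `subject_id`, `pct_analgesia`, `responder`.
#' @export
classify_responders <- function(table, threshold_pct = 20) {
  stopifnot(is.data.frame(table), "vas_post" %in% names(table))
  rep_cols <- intersect(paste0("vas_baseline_", 1:3), names(table))
  baseline <- if (length(rep_cols)) {
    apply(as.matrix(table[rep_cols]), 1L, average_baseline_vas)
  } else if ("vas_baseline" %in% names(table)) {
    table$vas_baseline
  } else stop("no baseline VAS column found", call. = FALSE)
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline VAS must be positive (percent change undefined at 0)",
         call. = FALSE)
  pct <- 100 * (baseline - table$vas_post) / baseline
  data.frame(subject_id = table$subject_id, pct_analgesia = pct,
             responder = pct >= threshold_pct, stringsAsFactors = FALSE)
}

#' Covariate-adjusted two-group comparison of ROI values
#'
#' Linear model `value ~ group + age + gender`; reports the group
#' coefficient's t (and two-sided p), the omnibus model F with
#' `(p, n - p - 1)` degrees of freedom, and the single-df group contrast F
#' (`t^2`), since published tables quote either convention.
#'
#' @param values per-subject numeric outcome.
#' @param group two-level factor or binary vector.
#' @param age,gender nuisance covariates.
#' @return list: `estimate`, `t`, `df`, `p` (group, two-sided), `F_model`,
#'   `df_model`, `p_model`, `F_group`, `n`.
#' @export
adjusted_group_test <- function(values, group, age, gender) {
  g <- as.numeric(factor(group)) - 1
  df_dat <- data.frame(y = values, g = g, age = age, gender = gender)
  if (nrow(df_dat) <= 4L) stop("too few subjects", call. = FALSE)
  fit <- stats::lm(y ~ g + age + gender, data = df_dat)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design (collinear covariates)", call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients["g", ]
  fs <- sm$fstatistic
  list(
    estimate = unname(co["Estimate"]),
    t = unname(co["t value"]),
    df = fit$df.residual,
    p = unname(co["Pr(>|t|)"]),
    F_model = unname(fs["value"]),
    df_model = unname(c(fs["numdf"], fs["dendf"])),
    p_model = unname(stats::pf(fs["value"], fs["numdf"], fs["dendf"],
                               lower.tail = FALSE)),
    F_group = unname(co["t value"]^2),
    n = nrow(df_dat)
  )
}

#' JZS (Cauchy-prior) Bayes factor for a two-sample t-test
#'
#' BF01 for H0: delta = 0 against a Cauchy prior of scale `cauchy_scale`
#' (default 0.707, the conventional "default prior" of Bayesian statistics
#' software) on the standardized effect size, computed from the two-sample t
#' statistic by numerical integration of the Zellner-Siow g-prior mixture:
#' `BF10 = \[integral over g of (1+Ng)^{-1/2}
#' (1 + t^2 / ((1+Ng) nu))^{-(nu+1)/2} dInvGamma(g; 1/2, r^2/2)\] /
#' (1 + t^2/nu)^{-(nu+1)/2}` with `N = n1 n2 / (n1 + n2)`.
#'
#' @param x,y the two groups' values (each n >= 2), or `NULL` when `t`, `n1`,
#'   `n2` are given directly.
#' @param t,n1,n2 optional sufficient statistics overriding `x`/`y`.
#' @param cauchy_scale prior scale r (default `1/sqrt(2)`).
#' @return object of class `bayes_factor`: `bf01`, `bf10`, `t`, `df`,
#'   `prior`, `abs_error` (quadrature error estimate on BF10),
#'   `interpretation`.
#' @export
jzs_ttest_bf01 <- function(x = NULL, y = NULL, t = NULL, n1 = NULL, n2 = NULL,
                           cauchy_scale = 1 / sqrt(2)) {
  if (is.null(t)) {
    stopifnot(length(x) >= 2L, length(y) >= 2L)
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 <= 0) stop("zero pooled variance", call. = FALSE)
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  stopifnot(is.numeric(n1), is.numeric(n2), n1 >= 2, n2 >= 2)
  nu <- n1 + n2 - 2
  neff <- n1 * n2 / (n1 + n2)
  r <- cauchy_scale
  log_lik0 <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(neff * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + neff * g) * nu)) -
          log_lik0 +                         # fold the null likelihood in
          0.5 * log(r^2 / 2) - lgamma(0.5) - 1.5 * log(g) - r^2 / (2 * g))
  }
  quad <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-12,
                           abs.tol = 0, subdivisions = 500L)
  bf10 <- quad$value
  structure(
    list(bf01 = 1 / bf10, bf10 = bf10, t = t, df = nu,
         prior = sprintf("JZS Cauchy(0, %.4g) on effect size", r),
         method = "adaptive quadrature of the g-prior mixture",
         abs_error = quad$abs.error,
         interpretation = interpret_bf(1 / bf10)),
    class = "bayes_factor"
  )
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("<bayes_factor> BF01 = %.4g (BF10 = %.4g): %s\n  prior: %s\n",
              x$bf01, x$bf10, x$interpretation, x$prior))
  invisible(x)
}

#' Interpret a Bayes factor on the Lee-Wagenmakers evidence scale
#'
#' The conventional bands, regularized to the non-overlapping partition
#' (0, 1/10\], (1/10, 1/3\], (1/3, 1), \[1, 3), \[3, 10), \[10, Inf) of BF01:
#' strong / moderate / anecdotal evidence for an alternative hypothesis,
#' then anecdotal / moderate / strong evidence in favour of the null.
#'
#' @param bf01 positive Bayes factor for the null.
#' @return character label.
#' @export
interpret_bf <- function(bf01) {
  stop_if_not_scalar_number(bf01, "bf01")
  if (bf01 <= 0) stop("`bf01` must be > 0", call. = FALSE)
  if (bf01 <= 1 / 10) "strong evidence for an alternative hypothesis"
  else if (bf01 <= 1 / 3) "moderate evidence for an alternative hypothesis"
  else if (bf01 < 1) "anecdotal evidence for an alternative hypothesis"
  else if (bf01 < 3) "anecdotal evidence in favour of the null hypothesis"
  else if (bf01 < 10) "moderate evidence in favour of the null hypothesis"
  else "strong evidence in favour of the null hypothesis"
}

#' Pearson correlation with a percentile bootstrap confidence interval
#'
#' Frequentist Pearson r with its two-sided t-test p-value and a seeded
#' percentile bootstrap CI over `n_boot` resamples of subject pairs.
#'
#' @param x,y numeric vectors (n >= 4).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return list: `r`, `p`, `ci` (length 2), `n`, `n_boot`.
#' @export
pearson_with_bootstrap <- function(x, y, n_boot = 1000, conf = 0.95,
                                   seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y)
  n <- length(x)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    idx <- sample.int(n, replace = TRUE)
    xs <- x[idx]; ys <- y[idx]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) return(NA_real_)
    stats::cor(xs, ys)
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  list(r = unname(ct$estimate), p = ct$p.value, ci = ci, n = n,
       n_boot = n_boot)
}

#' Bayes factor for a Pearson correlation under a stretched-beta prior
#'
#' BF01 for H0: rho = 0 against a stretched Beta(1/kappa, 1/kappa) prior on
#' (-1, 1) (width `kappa = 1` is uniform, the conventional default),
#' integrating the exact sampling density of the observed correlation r:
#' `f(r | rho, n) proportional to (1 - rho^2)^{(n-1)/2}
#' (1 - rho r)^{-(n - 3/2)} 2F1(1/2, 1/2; n - 1/2; (1 + rho r)/2)`.
#' The Gauss hypergeometric factor is summed as a series.
#'
#' @param x,y numeric vectors (n >= 4), or `NULL` if `r` and `n` are given.
#' @param r,n optional sufficient statistics.
#' @param kappa prior width (default 1).
#' @return a `bayes_factor` object (`t`/`df` slots replaced by `r`/`n`).
#' @export
bayes_pearson_bf01 <- function(x = NULL, y = NULL, r = NULL, n = NULL,
                               kappa = 1) {
  if (is.null(r)) {
    stopifnot(length(x) == length(y), length(x) >= 4L)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("zero variance input", call. = FALSE)
    r <- stats::cor(x, y); n <- length(x)
  }
  stopifnot(n >= 4, abs(r) < 1)
  a <- 1 / kappa
  log_ratio <- function(rho) {
    (n - 1) / 2 * log1p(-rho^2) -
      (n - 1.5) * log1p(-rho * r) +
      log_hyp2f1(0.5, 0.5, n - 0.5, (1 + rho * r) / 2) -
      log_hyp2f1(0.5, 0.5, n - 0.5, 0.5)
  }
  prior <- function(rho)
    stats::dbeta((rho + 1) / 2, a, a) / 2
  quad <- stats::integrate(function(rho)
    exp(log_ratio(rho)) * prior(rho), -1, 1,
    rel.tol = 1e-10, subdivisions = 500L)
  bf10 <- quad$value
  structure(
    list(bf01 = 1 / bf10, bf10 = bf10, r = r, n = n,
         prior = sprintf("stretched Beta(%.3g, %.3g) on rho", a, a),
         method = "adaptive quadrature with series 2F1",
         abs_error = quad$abs.error,
         interpretation = interpret_bf(1 / bf10)),
    class = "bayes_factor"
  )
}

# log Gauss hypergeometric 2F1(a, b; c; z) by direct series, valid for
# 0 <= z < 1 (and z = 1 when c - a - b > 0). Vectorized over z.
log_hyp2f1 <- function(a, b, c, z) {
  vapply(z, function(zz) {
    term <- 1; s <- 1; k <- 0
    repeat {
      term <- term * (a + k) * (b + k) / ((c + k) * (k + 1)) * zz
      s <- s + term
      k <- k + 1
      if (abs(term) < 1e-16 * abs(s) || k > 100000L) break
    }
    log(s)
  }, numeric(1))
}

#' Post hoc simple effects of treatment response within each arm
#'
#' After a significant arm x response interaction: within each treatment arm,
#' the covariate-adjusted responder-vs-non-responder contrast from
#' `value ~ response + age + gender` fitted on that arm alone. The family of
#' simple effects is corrected with Tukey's studentized-range adjustment
#' treating the four arm x response cells as the compared means
#' (`p_tukey = P(q_{4, df} >= sqrt(2) |t|)`), so `p_tukey >= p` always.
#'
#' @param values per-subject outcome.
#' @param arm two-level factor (e.g. placebo / duloxetine).
#' @param response two-level factor (responder / non-responder); each
#'   arm x response cell needs n >= 2.
#' @param age,gender nuisance covariates.
#' @return data.frame: `arm`, `estimate`, `t`, `df`, `p`, `p_tukey`.
#' @export
posthoc_simple_effects <- function(values, arm, response, age, gender) {
  arm <- factor(arm); response <- factor(response)
  if (nlevels(arm) != 2L || nlevels(response) != 2L)
    stop("`arm` and `response` must each have two levels", call. = FALSE)
  if (any(table(arm, response) < 2L))
    stop("each arm x response cell needs at least 2 subjects", call. = FALSE)
  k_means <- 4L
  rows <- lapply(levels(arm), function(a) {
    sel <- arm == a
    dd <- data.frame(y = values[sel],
                     resp = as.numeric(response[sel]) - 1,
                     age = age[sel], gender = gender[sel])
    # drop covariates that are constant within the arm
    form <- y ~ resp
    if (stats::sd(dd$age) > 0) form <- stats::update(form, . ~ . + age)
    if (stats::sd(dd$gender) > 0) form <- stats::update(form, . ~ . + gender)
    fit <- stats::lm(form, data = dd)
    co <- summary(fit)$coefficients["resp", ]
    df <- fit$df.residual
    tval <- unname(co["t value"])
    if (!is.finite(tval)) tval <- 0
    data.frame(
      arm = a,
      estimate = unname(co["Estimate"]),
      t = tval,
      df = df,
      p = unname(co["Pr(>|t|)"]),
      p_tukey = stats::ptukey(sqrt(2) * abs(tval), k_means, df,
                              lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations from each group's centre (mean by
#' default; the Brown-Forsythe median variant is available). W is the ANOVA F
#' statistic with (k - 1, n - k) degrees of freedom.
#'
#' @param values numeric outcome.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @param center `"mean"` (classical) or `"median"`.
#' @return list: `W`, `df1`, `df2`, `p`, `center`.
#' @export
levene_test <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("each group needs at least 2 observations", call. = FALSE)
  centre_fun <- if (center == "mean") mean else stats::median
  d <- abs(values - stats::ave(values, g, FUN = centre_fun))
  k <- nlevels(g); n <- length(values)
  gm <- mean(d)
  ssb <- sum(tapply(d, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum((d - stats::ave(d, g, FUN = mean))^2)
  df1 <- k - 1L; df2 <- n - k
  w <- if (ssb <= 1e-300) 0 else (ssb / df1) / (ssw / df2)
  p <- if (w == 0) 1 else stats::pf(w, df1, df2, lower.tail = FALSE)
  list(W = w, df1 = df1, df2 = df2, p = p, center = center)
}
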