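# Surrogate fit evaluation: transformed linear models and their R-squared,
# quadratic-term checks, GLS with an exponential variance function for the
# heteroscedastic regularity dimension, and balanced-nested variance
# components of R-squared across the simulation design factors.

#' Fit a (transformed) linear surrogate model
#'
#' Ordinary least squares of a possibly transformed response on a clade
#' index. `sqrt` is the conventional transform for Faith's PD and `log`
#' (natural) for VPD. Rows with missing values are dropped listwise;
#' for `log`, nonpositive responses are also dropped, and for `sqrt`
#' negative ones - the counts are recorded. The quadratic flag adds an
#' `x^2` term and reports its Wald p-value.
#'
#' @param x predictor values (a clade index).
#' @param y response values (a phylogeny-based metric).
#' @param transform `"none"`, `"sqrt"` or `"log"` applied to `y`.
#' @param quadratic add an `x^2` term.
#' @return an object of class `cladiv_fit`: list with `model`, `transform`,
#'   `coefficients`, `r_squared`, `n`, `n_dropped`, and `quad_p` when
#'   `quadratic = TRUE`.
#' @export
#' @examples
#' f <- fit_linear(c(0, 1, 2), c(0, 1, 1))
#' f$coefficients # intercept 1/6, slope 1/2
#' f$r_squared    # 0.75
fit_linear <- function(x, y, transform = c("none", "sqrt", "log"),
                       quadratic = FALSE) {
  transform <- match.arg(transform)
  d <- complete_xy(x, y, transform)
  if (d$n < 3L)
    abort_cladiv(sprintf("need >= 3 complete pairs, got %d", d$n))
  check_nondegenerate(d$x, d$y)
  fit <- if (quadratic) stats::lm(y ~ x + I(x^2), data = d[c("x", "y")])
         else stats::lm(y ~ x, data = d[c("x", "y")])
  sm <- summary(fit)
  out <- list(model = if (quadratic) "ols+quadratic" else "ols",
              transform = transform,
              coefficients = stats::coef(fit),
              r_squared = sm$r.squared,
              n = d$n, n_dropped = d$n_dropped,
              fitted = stats::fitted(fit), residuals = stats::residuals(fit))
  if (quadratic) out$quad_p <- sm$coefficients["I(x^2)", "Pr(>|t|)"]
  structure(out, class = "cladiv_fit")
}

#' Fit a GLS surrogate model with exponential residual variance
#'
#' Linear mean model with residual variance
#' \eqn{Var(\epsilon_i) = \sigma^2 \exp(2\delta v_i)} (the `varExp` variance
#' class), estimated by maximum likelihood via [nlme::gls()]. Used for the
#' regularity dimension, where residual spread shrinks as the clade
#' regularity index grows. The variance covariate defaults to the predictor.
#' Since ordinary R-squared is not defined for GLS, the squared correlation
#' of fitted and observed values is reported as a pseudo-R-squared.
#'
#' @inheritParams fit_linear
#' @param v variance covariate; defaults to `x`.
#' @param fix_delta optional fixed value for the variance parameter
#'   \eqn{\delta} (0 reduces the fit to OLS).
#' @return a `cladiv_fit` with `delta`, `log_lik` and `pseudo_r_squared`.
#' @export
fit_gls_varexp <- function(x, y, v = x, transform = c("none", "sqrt", "log"),
                           fix_delta = NULL) {
  transform <- match.arg(transform)
  d <- complete_xy(x, y, transform, v = v)
  if (d$n < 10L)
    abort_cladiv(sprintf("GLS fit needs >= 10 complete pairs, got %d", d$n))
  check_nondegenerate(d$x, d$y)
  dat <- data.frame(x = d$x, y = d$y, v = d$v)
  vf <- if (is.null(fix_delta)) nlme::varExp(form = ~v)
        else nlme::varExp(form = ~v, fixed = fix_delta)
  fit <- tryCatch(
    nlme::gls(y ~ x, data = dat, weights = vf, method = "ML"),
    error = function(e) abort_cladiv(
      sprintf("GLS (varExp) did not converge: %s", conditionMessage(e))))
  delta <- if (is.null(fix_delta))
    unname(stats::coef(fit$modelStruct$varStruct, unconstrained = FALSE))
  else fix_delta
  fv <- as.numeric(stats::fitted(fit))
  structure(list(model = "gls-varexp", transform = transform,
                 coefficients = stats::coef(fit),
                 delta = delta,
                 log_lik = as.numeric(stats::logLik(fit)),
                 pseudo_r_squared = stats::cor(fv, d$y)^2,
                 r_squared = stats::cor(fv, d$y)^2,
                 n = d$n, n_dropped = d$n_dropped,
                 fitted = fv, residuals = d$y - fv),
            class = "cladiv_fit")
}

#' @export
print.cladiv_fit <- function(x, ...) {
  cat(sprintf("%s fit (response transform: %s), n = %d (%d dropped)\n",
              x$model, x$transform, x$n, x$n_dropped))
  print(round(x$coefficients, 6))
  if (!is.null(x$delta))
    cat(sprintf("variance parameter delta = %.4f, logLik = %.3f\n",
                x$delta, x$log_lik))
  if (!is.null(x$quad_p))
    cat(sprintf("quadratic term p = %.4g\n", x$quad_p))
  cat(sprintf("%sR-squared = %.4f\n",
              if (x$model == "gls-varexp") "pseudo-" else "", x$r_squared))
  invisible(x)
}

complete_xy <- function(x, y, transform, v = NULL) {
  stopifnot(length(x) == length(y))
  v <- v %||% x
  stopifnot(length(v) == length(x))
  ok <- stats::complete.cases(x, y, v)
  if (transform == "log") ok <- ok & !is.na(y) & y > 0
  if (transform == "sqrt") ok <- ok & !is.na(y) & y >= 0
  n_dropped <- sum(!ok)
  if (n_dropped)
    message(sprintf("dropping %d rows (missing values%s)", n_dropped,
                    switch(transform, log = " or nonpositive response",
                           sqrt = " or negative response", "")))
  yt <- switch(transform, none = y[ok], sqrt = sqrt(y[ok]), log = log(y[ok]))
  list(x = x[ok], y = yt, v = v[ok], n = sum(ok), n_dropped = n_dropped)
}

check_nondegenerate <- function(x, y) {
  if (stats::var(x) <= 0)
    abort_cladiv("degenerate fit: predictor has zero variance",
                 class = "cladiv_degenerate_fit")
  if (stats::var(y) <= 0)
    abort_cladiv("degenerate fit: response has zero variance",
                 class = "cladiv_degenerate_fit")
  invisible(TRUE)
}

#' Fit one diversity dimension from site tables
#'
#' Merges a [diversity_table()] and a [clade_index_table()] by site and fits
#' the conventional surrogate model of the chosen dimension:
#' `sqrt(PD) ~ clade richness index` (richness), `MPD ~ clade divergence
#' index` (divergence), `log(VPD) ~ clade regularity index` (regularity).
#'
#' @param div data.frame from [diversity_table()].
#' @param idx data.frame from [clade_index_table()].
#' @param dimension which diversity dimension to fit.
#' @param quadratic add a quadratic term (OLS only).
#' @param gls use [fit_gls_varexp()] instead of OLS (the usual choice for
#'   the regularity dimension when residual spread varies along the index).
#' @return a `cladiv_fit`.
#' @export
fit_dimension <- function(div, idx,
                          dimension = c("richness", "divergence", "regularity"),
                          quadratic = FALSE, gls = FALSE) {
  dimension <- match.arg(dimension)
  m <- merge(div, idx[, setdiff(colnames(idx), "S")], by = "site", sort = FALSE)
  spec <- switch(dimension,
                 richness = list(x = m$clade_richness_index, y = m$PD, tr = "sqrt"),
                 divergence = list(x = m$clade_divergence_index, y = m$MPD, tr = "none"),
                 regularity = list(x = m$clade_regularity_index, y = m$VPD, tr = "log"))
  if (gls) fit_gls_varexp(spec$x, spec$y, transform = spec$tr)
  else fit_linear(spec$x, spec$y, transform = spec$tr, quadratic = quadratic)
}

#' Nested variance components of fit accuracy
#'
#' Decomposes the variance of per-matrix R-squared values across the
#' hierarchically nested simulation design factors (phylogenetic scale /
#' species pool size / species richness range) plus residual, by the
#' balanced-design expected-mean-squares method of moments. Negative
#' estimates are truncated to zero and the components expressed as
#' percentages of their sum.
#'
#' @param results data.frame with the response column and the three factor
#'   columns.
#' @param response name of the response column (an R-squared column from
#'   [run_factorial()] results).
#' @param factors names of the nesting factors, outermost first.
#' @param balance `"error"` (default) rejects unbalanced designs (including
#'   designs made unbalanced by missing responses); `"drop"` trims every
#'   innermost cell to the smallest complete replicate count first.
#' @return an object of class `cladiv_varcomp`: data.frame with columns
#'   `factor`, `variance`, `percent` (summing to 100).
#' @export
#' @examples
#' d <- expand.grid(scale = c("a", "b"), pool_size = 1, richness_range = 1,
#'                  replicate = 1:4)
#' d$r2 <- ifelse(d$scale == "a", 1, 3)
#' variance_components(d, "r2")
variance_components <- function(results, response = "r2_richness",
                                factors = c("scale", "pool_size",
                                            "richness_range"),
                                balance = c("error", "drop")) {
  balance <- match.arg(balance)
  miss <- setdiff(c(response, factors), colnames(results))
  if (length(miss))
    abort_cladiv(sprintf("missing columns: %s", paste(miss, collapse = ", ")))
  y <- results[[response]]
  sep <- "\r" # composite-key separator no sane factor label contains
  A <- factor(results[[factors[1L]]])
  B <- factor(paste(A, results[[factors[2L]]], sep = sep))
  C <- factor(paste(B, results[[factors[3L]]], sep = sep))
  keep <- !is.na(y)
  if (!all(keep)) {
    if (balance == "error")
      abort_cladiv(sprintf(
        "%d missing responses make the design unbalanced; use balance = \"drop\"",
        sum(!keep)))
    y <- y[keep]; A <- droplevels(A[keep]); B <- droplevels(B[keep]); C <- droplevels(C[keep])
  }
  counts <- table(C)
  n <- min(counts)
  if (max(counts) != n) {
    if (balance == "error")
      abort_cladiv("unequal replicate counts per innermost cell; use balance = \"drop\"")
    idx <- unlist(lapply(split(seq_along(y), C), function(ii) ii[seq_len(n)]),
                  use.names = FALSE)
    y <- y[idx]; A <- A[idx]; B <- B[idx]; C <- C[idx]
  }
  b_per_a <- tapply(B, A, function(z) length(unique(z)))
  c_per_b <- tapply(C, B, function(z) length(unique(z)))
  if (length(unique(b_per_a)) != 1L || length(unique(c_per_b)) != 1L)
    abort_cladiv("nesting structure is unbalanced (unequal level counts)")
  a <- nlevels(A); b <- unname(b_per_a[1L]); cc <- unname(c_per_b[1L])
  if (n < 2L)
    abort_cladiv("need >= 2 replicates per innermost cell to separate the residual")
  if (stats::var(y) == 0)
    abort_cladiv("all responses identical: zero total variance")

  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean); mC <- tapply(y, C, mean)
  ss_a <- b * cc * n * sum((mA - grand)^2)
  # means are keyed by composite level labels; strip one key piece to find
  # each level's parent mean
  parent_b <- sub(paste0(sep, "[^", sep, "]*$"), "", names(mB))
  ss_b <- cc * n * sum((mB - mA[parent_b])^2)
  parent_c <- sub(paste0(sep, "[^", sep, "]*$"), "", names(mC))
  ss_c <- n * sum((mC - mB[parent_c])^2)
  ss_e <- sum((y - mC[C])^2)

  df <- c(a - 1, a * (b - 1), a * b * (cc - 1), a * b * cc * (n - 1))
  ms <- c(ss_a, ss_b, ss_c, ss_e) / ifelse(df > 0, df, NA)
  # EMS chain: E[MS_A] = s2e + n s2C + cn s2B + bcn s2A, etc. A stratum with
  # zero df (a single nested level) contributes no variance; its MS slot is
  # bridged by the next estimable stratum below.
  next_ms <- function(k) {
    for (j in (k + 1):4) if (!is.na(ms[j])) return(ms[j])
    NA_real_
  }
  s2e <- ms[4L]
  if (is.na(s2e)) abort_cladiv("no residual degrees of freedom")
  s2c <- if (is.na(ms[3L])) 0 else (ms[3L] - next_ms(3L)) / n
  s2b <- if (is.na(ms[2L])) 0 else (ms[2L] - next_ms(2L)) / (cc * n)
  s2a <- if (is.na(ms[1L])) 0 else (ms[1L] - next_ms(1L)) / (b * cc * n)
  comp <- pmax(c(s2a, s2b, s2c, s2e), 0)
  if (sum(comp) == 0) abort_cladiv("all variance components are zero")
  structure(data.frame(factor = c(factors, "residual"),
                       variance = comp,
                       percent = 100 * comp / sum(comp),
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("cladiv_varcomp", "data.frame"))
}

#' Variance components for all three diversity dimensions
#'
#' Convenience wrapper over [variance_components()] for the three R-squared
#' columns of a [run_factorial()] results table; output mirrors a
#' factors-by-dimensions percentage table.
#'
#' @param results results data.frame of a `cladiv_sim`.
#' @param balance passed to [variance_components()].
#' @return data.frame: rows = scale / pool size / richness range / residual,
#'   columns `richness`, `divergence`, `regularity` (percent).
#' @export
varcomp_all <- function(results, balance = "drop") {
  cols <- c(richness = "r2_richness", divergence = "r2_divergence",
            regularity = "r2_regularity")
  out <- lapply(cols, function(cl)
    variance_components(results, response = cl, balance = balance)$percent)
  data.frame(factor = c("scale", "pool_size", "richness_range", "residual"),
             as.data.frame(out), stringsAsFactors = FALSE)
}
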