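#' Fit the three mediation path regressions
#'
#' OLS with intercepts: `a` from `m ~ x`, `c` from `y ~ x`, and
#' `(c_prime, b)` from `y ~ x + m`. The OLS identity
#' `c = c_prime + a * b` holds exactly on a common sample.
#'
#' @param x Independent variable (e.g. striatal D1R availability).
#' @param m Mediator (e.g. MP-induced FPN+ dwell-time change).
#' @param y Outcome (e.g. MP-induced 2-ball response-time change).
#' @return A list: `a`, `b`, `c`, `c_prime`, `indirect` (= a*b), `n`.
#' @export
fit_paths <- function(x, m, y) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 5, "mediation needs at least 5 complete cases")
  assert_that(sd(x) > 0 && sd(m) > 0, "x and m must be nonconstant")
  kappa_xm <- kappa(cbind(1, scale(x), scale(m)), exact = TRUE)
  if (!is.finite(kappa_xm) || kappa_xm > 1e8) {
    abort(sprintf("x and m are (nearly) collinear: condition number %.3g",
                  kappa_xm))
  }
  a <- unname(coef(lm(m ~ x))[2])
  cc <- unname(coef(lm(y ~ x))[2])
  fit2 <- coef(lm(y ~ x + m))
  list(a = a, b = unname(fit2[3]), c = cc, c_prime = unname(fit2[2]),
       indirect = a * unname(fit2[3]), n = n)
}

# Closed-form a and b for a batch of bootstrap resamples.
# xs, ms, ys are n x B matrices (one resample per column).
boot_ab <- function(xs, ms, ys) {
  n <- nrow(xs)
  cx <- sweep(xs, 2, colMeans(xs))
  cm <- sweep(ms, 2, colMeans(ms))
  cy <- sweep(ys, 2, colMeans(ys))
  sxx <- colSums(cx^2)
  smm <- colSums(cm^2)
  sxm <- colSums(cx * cm)
  sxy <- colSums(cx * cy)
  smy <- colSums(cm * cy)
  a <- sxm / sxx
  det <- sxx * smm - sxm^2
  b <- (sxx * smy - sxm * sxy) / det
  list(a = a, b = b, bad = !(sxx > 0 & det > 0))
}

#' Bootstrap inference on the indirect effect
#'
#' Resamples subjects (rows of x, m, y jointly) with replacement `n_boot`
#' times, refits paths a and b on each resample, and summarizes the
#' distribution of `a * b` with a percentile 95% CI and the two-sided
#' bootstrap p-value `2 * min(#\{ab <= 0\}, #\{ab >= 0\}) / n_boot`, floored
#' at `2 / n_boot`. Degenerate resamples (constant x or m) are redrawn and
#' counted in `n_redrawn`.
#'
#' @param x,m,y Subject-level vectors (see [fit_paths()]).
#' @param n_boot Bootstrap iterations.
#' @param seed Integer seed; the run is bit-reproducible under a fixed seed.
#' @param conf_level CI coverage level.
#' @return A list of class `mediation_result`: the [fit_paths()] point
#'   estimates plus `ci_low`, `ci_high`, `p_indirect`, `boot_indirect`
#'   (the n_boot draws), `n_boot`, `n_redrawn`, `seed`.
#' @export
bootstrap_indirect <- function(x, m, y, n_boot = 1000, seed = NULL,
                               conf_level = 0.95) {
  ok <- complete.cases(x, m, y)
  x <- x[ok]; m <- m[ok]; y <- y[ok]
  pt_est <- fit_paths(x, m, y)
  n <- pt_est$n

  draws <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    ab <- boot_ab(matrix(x[idx], n), matrix(m[idx], n), matrix(y[idx], n))
    redrawn <- 0L
    while (any(ab$bad)) {
      nb <- sum(ab$bad)
      redrawn <- redrawn + nb
      idx2 <- matrix(sample.int(n, n * nb, replace = TRUE), n, nb)
      ab2 <- boot_ab(matrix(x[idx2], n), matrix(m[idx2], n),
                     matrix(y[idx2], n))
      ab$a[ab$bad] <- ab2$a
      ab$b[ab$bad] <- ab2$b
      ab$bad[ab$bad] <- ab2$bad
    }
    list(ab = ab$a * ab$b, redrawn = redrawn)
  })
  boot_ind <- draws$ab
  ci <- unname(quantile(boot_ind, c((1 - conf_level) / 2,
                                    1 - (1 - conf_level) / 2), type = 7))
  p_ind <- max(2 * min(mean(boot_ind <= 0), mean(boot_ind >= 0)),
               2 / n_boot)
  structure(c(pt_est, list(
    ci_low = ci[1], ci_high = ci[2], p_indirect = p_ind,
    boot_indirect = boot_ind, n_boot = as.integer(n_boot),
    n_redrawn = draws$redrawn, conf_level = conf_level, seed = seed
  )), class = "mediation_result")
}

#' Mediation analysis on a subject table
#'
#' Tidy front-end: picks the `x`, `m`, `y` columns from a data frame,
#' optionally residualizes all three on a covariate (e.g. IQ) first, and
#' runs [bootstrap_indirect()].
#'
#' @param data A data frame of subject-level variables.
#' @param x,m,y Column names (strings) of the independent variable, mediator
#'   and outcome.
#' @param covariate Optional column name to residualize all three variables
#'   on before fitting.
#' @param n_boot,seed,conf_level Passed to [bootstrap_indirect()].
#' @return A `mediation_result`.
#' @export
mediate <- function(data, x, m, y, covariate = NULL, n_boot = 1000,
                    seed = NULL, conf_level = 0.95) {
  xv <- data[[x]]; mv <- data[[m]]; yv <- data[[y]]
  assert_that(!is.null(xv) && !is.null(mv) && !is.null(yv),
              "x, m and y must name columns of `data`")
  if (!is.null(covariate)) {
    cv <- data[[covariate]]
    assert_that(!is.null(cv), "covariate must name a column of `data`")
    ok <- complete.cases(xv, mv, yv, cv)
    Z <- cbind(1, cv[ok])
    res <- function(v) as.numeric(v[ok] - Z %*% qr.solve(Z, v[ok]))
    xv <- res(xv); mv <- res(mv); yv <- res(yv)
  }
  bootstrap_indirect(xv, mv, yv, n_boot = n_boot, seed = seed,
                     conf_level = conf_level)
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("<mediation_result> n = ", x$n, ", boot = ", x$n_boot, "\n",
      sprintf("  a = %.4g, b = %.4g, c = %.4g, c' = %.4g\n",
              x$a, x$b, x$c, x$c_prime),
      sprintf("  indirect (a*b) = %.4g, %d%% CI [%.4g, %.4g], p = %.4g\n",
              x$indirect, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$p_indirect), sep = "")
  invisible(x)
}

#' Tidy a mediation result into one row per path
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `conf.low`,
#'   `conf.high`, `p.value` (CI and p only for the indirect effect).
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("a", "b", "c", "c_prime", "indirect"),
    estimate = c(x$a, x$b, x$c, x$c_prime, x$indirect),
    conf.low = c(NA, NA, NA, NA, x$ci_low),
    conf.high = c(NA, NA, NA, NA, x$ci_high),
    p.value = c(NA, NA, NA, NA, x$p_indirect)
  )
}

#' One-row summary of a mediation result
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `n_boot`, `indirect`, `ci_low`, `ci_high`,
#'   `p_indirect`, `n_redrawn`.
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(n = x$n, n_boot = x$n_boot, indirect = x$indirect,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 p_indirect = x$p_indirect, n_redrawn = x$n_redrawn)
}
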