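#' Cumulative component-size distribution
#'
#' `P(s)` = fraction of components with size at least `s`, evaluated at
#' every observed size.
#'
#' @param sizes Integer vector of component sizes (or a
#'   [metrics_table()] data.frame, whose `size` column is used).
#' @return data.frame `s`, `P` with `P` non-increasing and `P(min) = 1`.
#' @export
cumulative_size_distribution <- function(sizes) {
  if (is.data.frame(sizes)) sizes <- sizes$size
  if (!length(sizes)) stop_invalid("no components supplied")
  s <- sort(unique(sizes))
  P <- vapply(s, function(si) mean(sizes >= si), 1)
  data.frame(s = s, P = P)
}

#' Fit the size-distribution slope
#'
#' Fits `P(s) = a * k^s` to the cumulative size distribution by
#' Levenberg-Marquardt nonlinear least squares, after trimming the
#' lowest and highest `trim_fraction` of the distinct observed sizes to
#' focus on the central part of the curve. The 68% confidence half-width
#' of `k` is taken from the estimator's covariance (one standard error
#' times the 68% normal quantile). A strict power law
#' `P(s) = a * s^(-gamma)` is available behind `model = "power"` for
#' sensitivity checks; its exponent is reported in the same `k` slot.
#'
#' @param dist Output of [cumulative_size_distribution()], or a raw size
#'   vector (converted automatically).
#' @param trim_fraction Fraction of distinct sizes dropped at each tail.
#' @param model `"exponential"` (the default decay `a k^s`) or
#'   `"power"`.
#' @param ci_method How the 68% CI of `k` is obtained. `"bootstrap"`
#'   (component resampling; requires raw sizes) reflects the sampling
#'   variability of the whole curve; `"covariance"` uses the LM fit's
#'   asymptotic covariance, which treats the cumulative points as
#'   independent and badly understates the CI on sampled cohorts (the
#'   points share the same components). `"auto"` picks bootstrap when
#'   raw sizes are supplied, covariance otherwise.
#' @param n_boot Bootstrap replicates.
#' @return Object of class `size_fit`: `k`, `a`, `ci68_halfwidth`,
#'   `support` (trimmed size range), `n_points`, `n_components`,
#'   `model`, `ci_method`, and the `fit` object.
#' @export
fit_slope <- function(dist, trim_fraction = 0.10,
                      model = c("exponential", "power"),
                      ci_method = c("auto", "bootstrap", "covariance"),
                      n_boot = 100) {
  model <- match.arg(model)
  ci_method <- match.arg(ci_method)
  n_components <- NA_integer_
  sizes <- NULL
  if (!is.data.frame(dist)) {
    sizes <- dist
    n_components <- length(sizes)
    dist <- cumulative_size_distribution(sizes)
  }
  if (ci_method == "auto")
    ci_method <- if (is.null(sizes)) "covariance" else "bootstrap"
  if (ci_method == "bootstrap" && is.null(sizes))
    stop_invalid("bootstrap CI requires raw component sizes")
  fit <- .fit_decay_curve(dist, trim_fraction, model)
  est <- coef(fit$fit)
  if (ci_method == "covariance") {
    se_k <- sqrt(vcov(fit$fit)["k", "k"])
    ci68 <- qnorm(1 - (1 - 0.68) / 2) * se_k
  } else {
    kstar <- vapply(seq_len(n_boot), function(b) {
      d <- cumulative_size_distribution(sample(sizes, replace = TRUE))
      unname(coef(.fit_decay_curve(d, trim_fraction, model)$fit)["k"])
    }, 1)
    ci68 <- sd(kstar)
  }
  structure(list(k = unname(est["k"]), a = unname(est["a"]),
                 ci68_halfwidth = ci68,
                 support = range(fit$s), n_points = length(fit$s),
                 n_components = n_components, model = model,
                 ci_method = ci_method, fit = fit$fit),
            class = "size_fit")
}

.fit_decay_curve <- function(dist, trim_fraction, model) {
  ns <- nrow(dist)
  drop <- floor(trim_fraction * ns)
  keep <- dist[seq.int(drop + 1, ns - drop), , drop = FALSE]
  if (nrow(keep) < 4)
    stop_invalid("fewer than 4 distinct sizes remain after trimming")
  s <- keep$s; P <- keep$P
  if (model == "exponential") {
    # log-linear start values
    lmfit <- stats::lm(log(P) ~ s)
    start <- list(a = unname(exp(coef(lmfit)[1])),
                  k = unname(min(0.999, exp(coef(lmfit)[2]))))
    fit <- minpack.lm::nlsLM(P ~ a * k^s, start = start,
                             lower = c(a = 1e-12, k = 1e-6),
                             upper = c(a = Inf, k = 1 - 1e-9),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    lmfit <- stats::lm(log(P) ~ log(s))
    start <- list(a = unname(exp(coef(lmfit)[1])),
                  k = unname(-coef(lmfit)[2]))
    fit <- minpack.lm::nlsLM(P ~ a * s^(-k), start = start,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  list(fit = fit, s = s)
}

#' @export
print.size_fit <- function(x, ...) {
  cat(sprintf("<size_fit %s: k = %.4f +/- %.4f (68%% CI), a = %.3g, s in [%d, %d]>\n",
              x$model, x$k, x$ci68_halfwidth, x$a,
              x$support[1], x$support[2]))
  invisible(x)
}

#' Test whether two fitted slopes differ
#'
#' Represents each slope as a normal random variable centred on its
#' estimate with SD equal to the 68% confidence half-width, and converts
#' the probability that their difference is zero into a two-sided
#' p-value: `z = (k1 - k2) / sqrt(sd1^2 + sd2^2)`. Setting
#' `sd_rule = "full"` doubles both SDs (the full-width reading of the
#' 68% interval).
#'
#' @param fit1,fit2 [fit_slope()] results.
#' @param sd_rule `"half"` (default) or `"full"` width of the 68% CI.
#' @return Object of class `slope_test`: `k1`, `k2`, `sd1`, `sd2`,
#'   `z_stat`, `p_value`.
#' @export
compare_slopes <- function(fit1, fit2, sd_rule = c("half", "full")) {
  sd_rule <- match.arg(sd_rule)
  if (!inherits(fit1, "size_fit") || !inherits(fit2, "size_fit"))
    stop_invalid("both arguments must be size_fit objects")
  mult <- if (sd_rule == "half") 1 else 2
  sd1 <- mult * fit1$ci68_halfwidth
  sd2 <- mult * fit2$ci68_halfwidth
  z <- (fit1$k - fit2$k) / sqrt(sd1^2 + sd2^2)
  structure(list(k1 = fit1$k, k2 = fit2$k, sd1 = sd1, sd2 = sd2,
                 z_stat = z, p_value = 2 * pnorm(-abs(z))),
            class = "slope_test")
}

#' @export
print.slope_test <- function(x, ...) {
  cat(sprintf("<slope_test: k1 = %.4f, k2 = %.4f, z = %.3f, p = %.3g>\n",
              x$k1, x$k2, x$z_stat, x$p_value))
  invisible(x)
}
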