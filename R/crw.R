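#' Closed-form MSD of a correlated random walk
#'
#' Mean squared displacement after `n` steps of size `lambda` with
#' per-step direction correlation `gamma` (the mean cosine of the turn
#' angle):
#' `lambda^2 * (n * (1 + gamma) / (1 - gamma) - 2 * gamma * (1 - gamma^n) / (1 - gamma)^2)`.
#' `gamma = 0` gives the Brownian limit `n * lambda^2`; `gamma = 1` is
#' handled as the ballistic branch `(n * lambda)^2`.
#'
#' @param n Step count(s), >= 0.
#' @param lambda Step size, micrometres (> 0).
#' @param gamma Correlation factor, `|gamma| < 1` (or exactly 1 for the
#'   ballistic branch).
#' @return MSD in um^2, same length as `n`.
#' @examples
#' crw_msd(5, 2, 0)    # 20
#' crw_msd(2, 1, 0.5)  # 3
#' @export
crw_msd <- function(n, lambda, gamma) {
  if (any(n < 0)) stop_domain("'n' must be >= 0")
  check_scalar(lambda, "lambda")
  if (lambda <= 0) stop_domain("'lambda' must be > 0")
  check_scalar(gamma, "gamma", -Inf, Inf)
  if (gamma == 1) return((n * lambda)^2)
  if (abs(gamma) >= 1) stop_domain("'gamma' must satisfy |gamma| < 1 (gamma = 1 ballistic branch excepted)")
  lambda^2 * (n * (1 + gamma) / (1 - gamma) -
                2 * gamma * (1 - gamma^n) / (1 - gamma)^2)
}

#' Mean cosine of observed turn angles
#'
#' The direct (per-step) estimator of the correlation factor: the
#' arithmetic mean of the cosines of the turn angles.
#'
#' @param turn_angles Turn angles in degrees (>= 1 value).
#' @return Estimate of `gamma`.
#' @export
mean_cos_turns <- function(turn_angles) {
  turn_angles <- turn_angles[!is.na(turn_angles)]
  if (!length(turn_angles)) stop_domain("'turn_angles' must contain at least one angle")
  mean(cos(deg2rad(turn_angles)))
}

#' Fit the correlated-random-walk MSD model
#'
#' Least-squares fit of the closed-form CRW mean squared displacement to
#' an observed MSD curve, with the step size `lambda` held fixed (it is
#' identified separately as `lambda_p * cos(phi/2)`) and the correlation
#' factor `gamma` as the single free parameter.  All supplied lags enter
#' unweighted.
#'
#' When `lambda = NULL` both parameters are estimated: the model is
#' linear in `lambda^2` at fixed `gamma`, so `lambda` is profiled out
#' analytically and only `gamma` is searched.  This is the variant used
#' when analysing simulated ensembles, where the effective step size is
#' itself of interest (it converges to `lambda_p * cos(phi/2)` for
#' split-dominated walks and to `lambda_p` for the Brownian `s = 0`
#' limit).
#'
#' @param curve An `msd_curve` data frame (columns `lag`, `msd`) from
#'   [ensemble_msd()], or anything coercible; >= 3 lags, non-negative
#'   and non-decreasing MSD.
#' @param lambda Fixed step size, micrometres, or `NULL` to estimate it.
#' @param gamma_range Search interval for `gamma` (kept inside
#'   `(-1, 1)`).
#' @return Object of class `crw_fit` with components `gamma`, `lambda`,
#'   `lambda_fixed`, `n_points`, `rss`, `lags`, `msd`, `fitted` and
#'   `out_of_range` (`TRUE` when the unclamped estimate falls outside
#'   `[0, 1)`).
#' @examples
#' curve <- data.frame(lag = 1:30, msd = crw_msd(1:30, 4.61, 0.65))
#' fit_crw(curve, lambda = 4.61)
#' @export
fit_crw <- function(curve, lambda = NULL, gamma_range = c(-0.99, 0.9995)) {
  if (!is.data.frame(curve) || !all(c("lag", "msd") %in% names(curve))) {
    stop_domain("'curve' must be a data frame with columns 'lag' and 'msd'")
  }
  lags <- curve$lag
  msd <- curve$msd
  if (length(lags) < 3L) stop_domain("need at least 3 MSD lags")
  if (any(msd < 0)) stop_domain("MSD values must be non-negative")
  if (is.unsorted(lags)) stop_domain("'lag' must be increasing")
  if (any(diff(msd) < 0)) stop_domain("MSD must be non-decreasing in lag")
  fixed <- !is.null(lambda)
  if (fixed) {
    check_scalar(lambda, "lambda")
    rss <- function(g) sum((msd - crw_msd(lags, lambda, g))^2)
  } else {
    # profile lambda^2 out: msd = lambda^2 * shape(lag, gamma)
    rss <- function(g) {
      shape <- crw_msd(lags, 1, g)
      l2 <- max(sum(msd * shape) / sum(shape^2), 0)
      sum((msd - l2 * shape)^2)
    }
  }
  opt <- stats::optimize(rss, interval = gamma_range, tol = 1e-12)
  gamma <- opt$minimum
  if (!fixed) {
    shape <- crw_msd(lags, 1, gamma)
    lambda <- sqrt(max(sum(msd * shape) / sum(shape^2), 0))
  }
  structure(list(gamma = gamma, lambda = lambda, lambda_fixed = fixed,
                 n_points = length(lags), rss = opt$objective,
                 lags = lags, msd = msd,
                 fitted = crw_msd(lags, lambda, gamma),
                 out_of_range = gamma < 0 || gamma >= 1),
            class = "crw_fit")
}

#' @export
print.crw_fit <- function(x, ...) {
  cat("Correlated-random-walk MSD fit\n")
  cat(sprintf("  gamma  = %.4f%s\n", x$gamma,
              if (x$out_of_range) "  [outside [0, 1)]" else ""))
  cat(sprintf("  lambda = %.3f um (%s)\n", x$lambda,
              if (isTRUE(x$lambda_fixed)) "fixed" else "fitted"))
  cat(sprintf("  turn angle = %.1f deg; %d lags, RSS = %.4g\n",
              turn_angle(max(min(x$gamma, 1), -1)), x$n_points, x$rss))
  invisible(x)
}

#' @export
summary.crw_fit <- function(object, ...) {
  out <- c(coef(object),
           turn_angle = turn_angle(max(min(object$gamma, 1), -1)),
           n_points = object$n_points, rss = object$rss)
  class(out) <- "summary.crw_fit"
  out
}

#' @export
print.summary.crw_fit <- function(x, ...) {
  print(unclass(x), ...)
  invisible(x)
}

#' @export
coef.crw_fit <- function(object, ...) {
  c(gamma = object$gamma, lambda = object$lambda)
}

#' @export
predict.crw_fit <- function(object, newdata = NULL, ...) {
  lags <- if (is.null(newdata)) object$lags
  else if (is.data.frame(newdata)) newdata$lag else newdata
  crw_msd(lags, object$lambda, min(object$gamma, 0.999999))
}

#' @export
residuals.crw_fit <- function(object, ...) object$msd - object$fitted

#' @export
plot.crw_fit <- function(x, ...) {
  graphics::plot(x$lags, x$msd, xlab = "steps", ylab = "MSD (um^2)",
                 pch = 1, ...)
  graphics::lines(x$lags, x$fitted, col = 2)
  graphics::legend("topleft", c("ensemble MSD", "CRW fit"),
                   pch = c(1, NA), lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

split_weight <- function(a, phi) {
  w <- a + (1 - a) * cos(deg2rad(2 * phi))
  if (w < 0) {
    stop_domain("a + (1 - a) * cos(2 * phi) < 0: no real per-step reduction ",
                "(phi near 90 degrees with small a)")
  }
  w
}

#' Per-step correlation factor from pseudopod parameters
#'
#' Closed form `gamma = s * cos(sigma_phi) * sqrt(a + (1 - a) * cos(2 * phi))`:
#' the product of the splitting fraction, a small-noise term, and the
#' right/left alternation term.  The cosine noise surrogate is the
#' default; the exact von Mises (`I1/I0` at `kappa = 1/sigma^2`) and
#' wrapped normal (`exp(-sigma^2/2)`) expectations are available for
#' comparison at large `sigma_phi`.
#'
#' @param params A [pseudopod_model()] (or coercible list).
#' @param noise_term `"cosine"` (default), `"von_mises"` or
#'   `"wrapped_normal"`.
#' @return The per-step correlation factor.
#' @examples
#' gamma_step(pseudopod_model(5.2, 0.86, 0.77, 55, 27.8))  # ~0.63
#' @export
gamma_step <- function(params, noise_term = c("cosine", "von_mises",
                                              "wrapped_normal")) {
  p <- as_pseudopod_model(params)
  noise_term <- match.arg(noise_term)
  noise <- switch(noise_term,
                  cosine = cos_sigma_approx(p$sigma_phi),
                  von_mises = expected_cos_vmd(kappa_from_sigma(p$sigma_phi)),
                  wrapped_normal = expected_cos_wrapped_normal(p$sigma_phi))
  p$s * noise * sqrt(split_weight(p$a, p$phi))
}

#' Pair correlation factor from pseudopod parameters
#'
#' Correlation factor of the displacement over pseudopod pairs: the
#' RL/LR pairs (weight `a`) have net turn 0 and the RR/LL pairs (weight
#' `1 - a`) net turn `2 * phi`; the three pair types involving a de
#' novo pseudopod average to zero.  Angular noise enters through the
#' expectation of the cosine of the summed noise of the two steps:
#' by default the exact expectation for two independent von Mises
#' noises, `(I1/I0(kappa))^2` with `kappa = 1/sigma_phi^2`
#' (`noise_model = "von_mises"`); `"single_vmd"` instead approximates
#' the summed noise by one von Mises of doubled variance
#' (`kappa = 1/(2*sigma_phi^2)`), and `"wrapped_normal"` uses
#' `exp(-sigma_phi^2)`.  The per-step factor is the square root of the
#' pair factor, so `gamma_pairs` ~ `gamma_step()^2` for
#' `sigma_phi` below ~30 degrees.
#'
#' @inheritParams gamma_step
#' @param noise_model `"von_mises"` (default, exact two-step noise),
#'   `"single_vmd"` or `"wrapped_normal"`.
#' @return The pair correlation factor
#'   `s^2 * (a + (1 - a) * cos(2 * phi)) * E[cos(noise)]`.
#' @export
gamma_pairs <- function(params, noise_model = c("von_mises", "single_vmd",
                                                "wrapped_normal")) {
  p <- as_pseudopod_model(params)
  noise_model <- match.arg(noise_model)
  e <- switch(noise_model,
              von_mises = expected_cos_vmd(kappa_from_sigma(p$sigma_phi))^2,
              single_vmd = expected_cos_vmd(kappa_from_sigma(p$sigma_phi) / 2),
              wrapped_normal = exp(-deg2rad(p$sigma_phi)^2))
  p$s^2 * split_weight(p$a, p$phi) * e
}

#' Effective step size of the pair walk
#'
#' `lambda = lambda_p * cos(phi / 2)`: the displacement per pseudopod
#' of a perfect zig-zag at splitting angle `phi`.
#'
#' @param lambda_p Pseudopod size, micrometres.
#' @param phi Splitting angle, degrees.
#' @export
step_size <- function(lambda_p, phi) {
  if (any(lambda_p <= 0)) stop_domain("'lambda_p' must be > 0")
  if (any(phi < 0 | phi > 180)) stop_domain("'phi' must be in [0, 180]")
  lambda_p * cos(deg2rad(phi / 2))
}

#' Mean turn angle implied by a correlation factor
#'
#' `theta = acos(gamma)` in degrees.
#'
#' @param gamma Correlation factor(s) in `[-1, 1]`.
#' @export
turn_angle <- function(gamma) {
  if (any(is.na(gamma)) || any(abs(gamma) > 1)) {
    stop_domain("'gamma' must be in [-1, 1]")
  }
  rad2deg(acos(gamma))
}

#' Expected directional displacement
#'
#' Expected displacement after `n` steps projected on the direction of
#' the first step: `lambda * (1 - gamma^n) / (1 - gamma)`, a geometric
#' series that saturates at `lambda / (1 - gamma)` (pass `n = Inf` for
#' the asymptote).  Relevant for drift under directional cues.
#'
#' @param n Step count(s) >= 1, `Inf` allowed.
#' @param lambda Step size, micrometres.
#' @param gamma Correlation factor, `|gamma| < 1`.
#' @export
directional_displacement <- function(n, lambda, gamma) {
  if (any(n < 1)) stop_domain("'n' must be >= 1")
  check_scalar(lambda, "lambda")
  check_scalar(gamma, "gamma")
  if (abs(gamma) >= 1) stop_domain("'gamma' must satisfy |gamma| < 1")
  if (gamma == 0) return(rep(lambda, length(n)))
  out <- lambda * (1 - gamma^n) / (1 - gamma)
  out[is.infinite(n)] <- lambda / (1 - gamma)
  out
}

#' Regress the correlation factor on the splitting fraction
#'
#' Ordinary least squares of observed `gamma` on the splitting fraction
#' `s` across strains/conditions, the empirical summary of how
#' persistence scales with splitting.
#'
#' @param s Splitting fractions (or a data frame with columns `s` and
#'   `gamma`).
#' @param gamma Observed correlation factors (ignored when `s` is a
#'   data frame).
#' @return List with `slope`, `intercept`, `r_squared` and the
#'   underlying `lm` fit.
#' @examples
#' tab <- table1_strains()[1:7, ]
#' regress_gamma_vs_s(tab$s, tab$gamma_obs)
#' @export
regress_gamma_vs_s <- function(s, gamma = NULL) {
  if (is.data.frame(s)) {
    if (!all(c("s", "gamma") %in% names(s))) {
      stop_domain("data frame input needs columns 's' and 'gamma'")
    }
    gamma <- s$gamma
    s <- s$s
  }
  if (length(s) < 3L) stop_domain("need at least 3 (s, gamma) points")
  if (diff(range(s)) < 1e-12) stop_domain("singular design: all 's' values equal")
  fit <- stats::lm(gamma ~ s)
  tss <- sum((gamma - mean(gamma))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, fit = fit)
}

#' Quadrature composition of angular variances
#'
#' Predicted SD of the pseudopod angle when the tangent orientation and
#' the pseudopod-to-tangent angle vary independently:
#' `sqrt(sigma_t^2 + sigma_beta^2)` degrees.
#'
#' @param sigma_t SD of the tangent angle, degrees (>= 0).
#' @param sigma_beta SD of the pseudopod angle to the tangent, degrees.
#' @examples
#' variance_composition(24.9, 13.3)  # 28.2
#' @export
variance_composition <- function(sigma_t, sigma_beta) {
  if (any(sigma_t < 0) || any(sigma_beta < 0)) stop_domain("SDs must be >= 0")
  sqrt(sigma_t^2 + sigma_beta^2)
}
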