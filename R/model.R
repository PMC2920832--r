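#' Five-parameter pseudopod model of amoeboid movement
#'
#' Constructs the parameter set describing how one strain or condition
#' extends pseudopodia: each step is either a split of the current
#' pseudopod (probability `s`), extended at `phi` degrees to the right
#' or left of it (alternating sides with probability `a`), or a de novo
#' pseudopod in a uniformly random direction; the realised direction is
#' then perturbed by angular noise of SD `sigma_phi`.
#'
#' @param lambda_p Pseudopod size, micrometres (> 0).
#' @param s Splitting fraction in `[0, 1]`.
#' @param a Right/left alternation bias in `[0, 1]`.
#' @param phi Splitting angle, degrees, in `[0, 180]`.
#' @param sigma_phi SD of the pseudopod angle, degrees (>= 0).
#' @param name Optional strain/condition label.
#' @return Object of class `pseudopod_model`.
#' @examples
#' wt <- pseudopod_model(5.2, 0.86, 0.77, 55, 27.8, name = "WT 5h")
#' wt
#' coef(wt)
#' @seealso [simulate.pseudopod_model()], [gamma_step()], [step_size()]
#' @export
pseudopod_model <- function(lambda_p, s, a, phi, sigma_phi, name = NULL) {
  check_scalar(lambda_p, "lambda_p")
  if (lambda_p <= 0) stop_domain("'lambda_p' must be > 0")
  check_scalar(s, "s", 0, 1)
  check_scalar(a, "a", 0, 1)
  check_scalar(phi, "phi", 0, 180)
  check_scalar(sigma_phi, "sigma_phi", 0, Inf)
  structure(list(lambda_p = lambda_p, s = s, a = a, phi = phi,
                 sigma_phi = sigma_phi, name = name),
            class = "pseudopod_model")
}

as_pseudopod_model <- function(x) {
  if (inherits(x, "pseudopod_model")) return(x)
  if (is.list(x) || is.data.frame(x)) {
    need <- c("lambda_p", "s", "a", "phi", "sigma_phi")
    if (all(need %in% names(x))) {
      return(pseudopod_model(x$lambda_p[1], x$s[1], x$a[1], x$phi[1],
                             x$sigma_phi[1],
                             name = if ("strain" %in% names(x)) as.character(x$strain[1]) else NULL))
    }
  }
  stop_domain("cannot interpret 'params' as a pseudopod model")
}

#' @export
print.pseudopod_model <- function(x, ...) {
  cat("Pseudopod model", if (!is.null(x$name)) paste0("(", x$name, ")"), "\n")
  cat(sprintf("  lambda_p  = %.2f um   (pseudopod size)\n", x$lambda_p))
  cat(sprintf("  s         = %.2f      (splitting fraction)\n", x$s))
  cat(sprintf("  a         = %.2f      (R/L alternation bias)\n", x$a))
  cat(sprintf("  phi       = %.1f deg  (splitting angle)\n", x$phi))
  cat(sprintf("  sigma_phi = %.1f deg  (angular noise SD)\n", x$sigma_phi))
  cat(sprintf("  derived: step size lambda = %.3f um, gamma_step = %.3f, turn angle = %.1f deg\n",
              step_size(x$lambda_p, x$phi), gamma_step(x),
              turn_angle(gamma_step(x))))
  invisible(x)
}

#' @export
coef.pseudopod_model <- function(object, ...) {
  c(lambda_p = object$lambda_p, s = object$s, a = object$a,
    phi = object$phi, sigma_phi = object$sigma_phi)
}

#' Published strain parameter table
#'
#' Observed pseudopod parameters for wild-type cells at four starvation
#' times and four signalling/cytoskeleton mutants, together with the
#' reference correlation factors (observed from centroid dispersion,
#' from the original Monte Carlo runs, and from the per-step closed
#' form) used by [run_table1_reproduction()].
#'
#' @return A data frame with columns `strain`, `lambda_p`, `s`, `a`,
#'   `phi`, `sigma_phi`, `gamma_obs`, `gamma_mc_ref`, `gamma_step_ref`.
#' @export
table1_strains <- function() {
  data.frame(
    strain = c("WT 1h", "WT 3h", "WT 5h", "WT 7h",
               "gc-null", "pla2-null", "sgc/pla2-null", "ddia2-null"),
    lambda_p = c(5.0, 5.3, 5.2, 4.7, 4.6, 7.7, 5.3, 5.6),
    s = c(0.55, 0.60, 0.86, 0.89, 0.71, 0.67, 0.41, 0.82),
    a = c(0.74, 0.74, 0.77, 0.82, 0.67, 0.68, 0.75, 0.75),
    phi = c(62, 58, 55, 55, 54, 50, 54, 54),
    sigma_phi = c(26.1, 29.7, 27.8, 27.5, 26.9, 28.5, 27.5, 46.5),
    gamma_obs = c(0.46, 0.52, 0.74, 0.81, 0.58, 0.55, 0.35, 0.53),
    gamma_mc_ref = c(0.40, 0.46, 0.65, 0.70, 0.53, 0.51, 0.35, 0.46),
    gamma_step_ref = c(0.40, 0.42, 0.64, 0.69, 0.50, 0.48, 0.31, 0.43),
    stringsAsFactors = FALSE
  )
}
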