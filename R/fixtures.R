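#' Generate a synthetic cell outline
#'
#' Seeded generators for the polygonal outlines consumed by
#' [shape_psi()]: an exact sampled ellipse, a star (sinusoidal radial
#' modulation of the ellipse, emulating irregular star-like mutants), or
#' an ellipse with smooth random radial perturbations.
#'
#' @param kind `"ellipse"`, `"star"` or `"noisy_ellipse"`.
#' @param semi_axes Semi-axes in micrometres (default 7 x 4.5, a
#'   typical amoeboid cell).
#' @param n_nodes Number of outline nodes (>= 16; default 150).
#' @param spike_count Number of star arms.
#' @param spike_amplitude Radial modulation as a fraction of the local
#'   radius, in `[0, 1)`; 0 reduces the star to the ellipse.
#' @param noise_amplitude RMS radial perturbation for
#'   `"noisy_ellipse"`.
#' @param center,orientation Placement of the outline.
#' @param seed Optional integer seed (only `"noisy_ellipse"` is
#'   stochastic).
#' @return A [cell_outline()].
#' @examples
#' plot(make_outline("star", spike_amplitude = 0.3))
#' @export
make_outline <- function(kind = c("ellipse", "star", "noisy_ellipse"),
                         semi_axes = c(7, 4.5), n_nodes = 150,
                         spike_count = 7, spike_amplitude = 0.25,
                         noise_amplitude = 0.08,
                         center = c(0, 0), orientation = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (n_nodes < 16) stop_domain("'n_nodes' must be >= 16")
  if (spike_amplitude < 0 || spike_amplitude >= 1) {
    stop_domain("'spike_amplitude' must be in [0, 1)")
  }
  if (any(semi_axes <= 0)) stop_domain("'semi_axes' must be positive")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, 2 * pi, length.out = n_nodes + 1)[-(n_nodes + 1)]
  mod <- switch(kind,
                ellipse = rep(1, n_nodes),
                star = 1 + spike_amplitude * sin(spike_count * t),
                noisy_ellipse = {
                  harm <- 2:6
                  eps <- stats::rnorm(length(harm)) * noise_amplitude / sqrt(length(harm))
                  ph <- stats::runif(length(harm), 0, 2 * pi)
                  m <- 1 + colSums(eps * sin(outer(harm, t) + ph))
                  pmax(m, 0.2)
                })
  u <- semi_axes[1] * cos(t) * mod
  v <- semi_axes[2] * sin(t) * mod
  th <- deg2rad(orientation)
  cell_outline(center[1] + u * cos(th) - v * sin(th),
               center[2] + u * sin(th) + v * cos(th))
}

#' Angular noise implied by cell shape
#'
#' Empirical coupling between shape irregularity and the SD of the
#' pseudopod angle, `sigma_phi = 37.6 * psi + 22.8` degrees, used to
#' give synthetic strains a shape-consistent noise level.
#'
#' @param psi Shape statistic in `[0, 2)`.
#' @return `sigma_phi` in degrees.
#' @export
sigma_from_psi <- function(psi) {
  if (any(psi < 0 | psi >= 2)) stop_domain("'psi' must be in [0, 2)")
  37.6 * psi + 22.8
}

#' Generate a synthetic pseudopod event table
#'
#' Wraps the trajectory simulator to emit tracker-style event records.
#' With `tangent = TRUE` (default) the angular noise of split events is
#' decomposed into two independent wrapped-normal components — the
#' tangent orientation at the emergence site (`alpha_t`, SD `sigma_t`)
#' and the pseudopod-to-tangent angle (`beta`, SD `sigma_beta`) — so
#' the event table carries tangent columns whose statistics match the
#' supplied values and whose quadrature sum sets the total angular SD
#' (overriding `params$sigma_phi`; the defaults give
#' `sqrt(24.9^2 + 13.3^2) = 28.2` degrees).
#'
#' @param params A [pseudopod_model()] (or coercible list).
#' @param n_cells,n_steps Positive counts.
#' @param seed Optional integer seed.
#' @param tangent Record the tangent decomposition?
#' @param alpha_t_mean,sigma_t Tangent angle relative to the previous
#'   pseudopod: mean magnitude and SD, degrees.
#' @param beta_mean,sigma_beta Pseudopod angle relative to the tangent:
#'   mean and SD, degrees.
#' @return Data frame in the events schema (`cell_id`, `index`, `kind`,
#'   `side`, `alpha_deg`, start/end coordinates and times), plus
#'   `alpha_t_deg` and `beta_deg` when `tangent = TRUE` (NA for de novo
#'   events).
#' @export
make_event_table <- function(params, n_cells = 10, n_steps = 30, seed = NULL,
                             tangent = TRUE,
                             alpha_t_mean = 34.5, sigma_t = 24.9,
                             beta_mean = 89.1, sigma_beta = 13.3) {
  model <- as_pseudopod_model(params)
  if (n_cells < 1 || n_steps < 1) stop_domain("counts must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (!tangent) {
    w <- simulate(model, nsim = n_cells, n_steps = n_steps, events = TRUE)
    return(w$events)
  }
  n_cells <- as.integer(n_cells); n_steps <- as.integer(n_steps)
  # simulate with noise decomposed into tangent + perpendicularity parts
  x <- matrix(0, n_steps + 1L, n_cells)
  y <- matrix(0, n_steps + 1L, n_cells)
  alpha <- norm_angle(stats::runif(n_cells, -180, 180))
  side <- integer(n_cells)
  ev <- vector("list", n_steps)
  for (k in seq_len(n_steps)) {
    a_t <- rep(NA_real_, n_cells)
    beta <- rep(NA_real_, n_cells)
    if (k > 1L) {
      r1 <- stats::runif(n_cells); r2 <- stats::runif(n_cells)
      r3 <- stats::runif(n_cells); r4 <- stats::runif(n_cells)
      split <- r1 < model$s
      coin <- ifelse(r3 < 0.5, -1L, 1L)
      alt <- ifelse(r2 < model$a, -side, side)
      new_side <- ifelse(side == 0L, coin, alt)
      new_side[!split] <- 0L
      e_t <- stats::rnorm(n_cells, 0, sigma_t)
      e_b <- stats::rnorm(n_cells, 0, sigma_beta)
      mean_ang <- ifelse(split, alpha + new_side * model$phi, r4 * 360 - 180)
      alpha <- norm_angle(mean_ang + e_t + e_b)
      a_t[split] <- (new_side * alpha_t_mean + e_t)[split]
      beta[split] <- (beta_mean + e_b)[split]
      kind <- ifelse(split, "split", "de_novo")
      side <- new_side
    } else {
      kind <- rep("first", n_cells)
    }
    ar <- deg2rad(alpha)
    x[k + 1L, ] <- x[k, ] + model$lambda_p * cos(ar)
    y[k + 1L, ] <- y[k, ] + model$lambda_p * sin(ar)
    ev[[k]] <- data.frame(cell_id = seq_len(n_cells), index = k, kind = kind,
                          side = side_label(side), alpha_deg = alpha,
                          x_start = x[k, ], y_start = y[k, ],
                          t_start = (k - 1) * 30,
                          x_end = x[k + 1L, ], y_end = y[k + 1L, ],
                          t_end = (k - 1) * 30 + 13,
                          alpha_t_deg = a_t, beta_deg = beta,
                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$cell_id, out$index), ]
  out$cell_id <- sprintf("cell_%03d", out$cell_id)
  rownames(out) <- NULL
  out
}
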