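# Vectorised one-step update of the pseudopod decision tree.
# prev_alpha: degrees; prev_side: integer (+1 = L, -1 = R, 0 = none);
# always consumes four uniform deviates per trajectory (R1..R4) plus the
# angular-noise draws, so the stream layout is fixed.
sim_step <- function(prev_alpha, prev_side, model) {
  n <- length(prev_alpha)
  r1 <- stats::runif(n)
  r2 <- stats::runif(n)
  r3 <- stats::runif(n)
  r4 <- stats::runif(n)
  split <- r1 < model$s
  coin_side <- ifelse(r3 < 0.5, -1L, 1L)              # split after de novo
  alt_side <- ifelse(r2 < model$a, -prev_side, prev_side)
  side <- ifelse(prev_side == 0L, coin_side, alt_side)
  side[!split] <- 0L
  mean_ang <- ifelse(split, prev_alpha + side * model$phi, r4 * 360 - 180)
  kappa <- kappa_from_sigma(model$sigma_phi)
  noise <- if (model$sigma_phi == 0) numeric(n) else rad2deg(rvm_rad(n, kappa))
  list(alpha = norm_angle(mean_ang + noise),
       kind = ifelse(split, "split", "de_novo"),
       side = side)
}

side_label <- function(side) c("R", "none", "L")[side + 2L]
side_code <- function(side) {
  s <- match(side, c("R", "none", "L"))
  if (anyNA(s)) stop_domain("'side' must be one of \"R\", \"L\", \"none\"")
  as.integer(s - 2L)
}

#' Draw the next pseudopod of the decision tree
#'
#' One stochastic update: with probability `s` the next pseudopod splits
#' off the current one at `phi` degrees (alternating right/left with
#' probability `a`; a fair coin sets the side when the previous event
#' was de novo), otherwise a de novo pseudopod is extended in a uniform
#' random direction; von Mises angular noise of SD `sigma_phi` is then
#' applied.  Right is clockwise, i.e. a negative angular increment.
#'
#' @param prev_alpha Direction of the previous pseudopod, degrees.
#' @param prev_side `"R"`, `"L"` or `"none"` (previous event de novo).
#' @param params A [pseudopod_model()] (or coercible list).
#' @param seed Optional integer seed.
#' @return List with `alpha` (degrees), `kind` (`"split"`/`"de_novo"`)
#'   and `side` (`"R"`/`"L"`/`"none"`).
#' @export
next_pseudopod_angle <- function(prev_alpha, prev_side = "none", params,
                                 seed = NULL) {
  model <- as_pseudopod_model(params)
  check_scalar(prev_alpha, "prev_alpha")
  if (!is.null(seed)) set.seed(seed)
  st <- sim_step(prev_alpha, side_code(prev_side), model)
  list(alpha = st$alpha, kind = st$kind, side = side_label(st$side))
}

#' Simulate pseudopod trajectories
#'
#' Monte Carlo simulation of `nsim` independent cells.  The first
#' pseudopod direction is uniform; every subsequent direction follows
#' the split/de-novo decision tree of the model; each pseudopod
#' displaces the tip by exactly `lambda_p` micrometres.  Trajectories
#' start at the origin.  All trajectories are advanced together from a
#' single seeded stream, so a fixed `(seed, nsim, n_steps)` triple is
#' exactly reproducible.
#'
#' @param object A [pseudopod_model()].
#' @param nsim Number of trajectories (>= 1).
#' @param seed Optional integer seed.
#' @param n_steps Pseudopodia per trajectory (default 30, the typical
#'   count over a 15-minute recording).
#' @param events If `TRUE`, also return the per-step event table
#'   (kind, side, direction, start/end coordinates, synthetic clock).
#' @param ... Unused.
#' @return Object of class `pseudopod_walk`: list with position
#'   matrices `x`, `y` (`n_steps + 1` rows, `nsim` columns), the event
#'   data frame (or `NULL`), and the generating model.
#' @examples
#' wt <- pseudopod_model(5.2, 0.86, 0.77, 55, 27.8)
#' w <- simulate(wt, nsim = 50, seed = 1)
#' plot(w)
#' @export
simulate.pseudopod_model <- function(object, nsim = 1, seed = NULL,
                                     n_steps = 30, events = FALSE, ...) {
  if (!is.numeric(nsim) || nsim < 1) stop_domain("'nsim' must be >= 1")
  if (!is.numeric(n_steps) || n_steps < 1) stop_domain("'n_steps' must be >= 1")
  nsim <- as.integer(nsim); n_steps <- as.integer(n_steps)
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(0, n_steps + 1L, nsim)
  y <- matrix(0, n_steps + 1L, nsim)
  alpha <- norm_angle(stats::runif(nsim, -180, 180))
  side <- integer(nsim)
  ev <- if (events) vector("list", n_steps) else NULL
  for (k in seq_len(n_steps)) {
    if (k > 1L) {
      st <- sim_step(alpha, side, object)
      alpha <- st$alpha
      side <- st$side
      kind <- st$kind
    } else {
      kind <- rep("first", nsim)
    }
    ar <- deg2rad(alpha)
    x[k + 1L, ] <- x[k, ] + object$lambda_p * cos(ar)
    y[k + 1L, ] <- y[k, ] + object$lambda_p * sin(ar)
    if (events) {
      ev[[k]] <- data.frame(cell_id = seq_len(nsim), index = k, kind = kind,
                            side = side_label(side), alpha_deg = alpha,
                            x_start = x[k, ], y_start = y[k, ],
                            t_start = (k - 1) * 30,
                            x_end = x[k + 1L, ], y_end = y[k + 1L, ],
                            t_end = (k - 1) * 30 + 13,
                            stringsAsFactors = FALSE)
    }
  }
  events_df <- NULL
  if (events) {
    events_df <- do.call(rbind, ev)
    events_df <- events_df[order(events_df$cell_id, events_df$index), ]
    events_df$cell_id <- sprintf("cell_%03d", events_df$cell_id)
    rownames(events_df) <- NULL
  }
  structure(list(x = x, y = y, events = events_df, model = object,
                 n_steps = n_steps, nsim = nsim, seed = seed),
            class = "pseudopod_walk")
}

#' Simulate a single trajectory with its event list
#'
#' Convenience wrapper around [simulate.pseudopod_model()] for one cell,
#' returning both the tip trajectory and the annotated event table.
#'
#' @param params A [pseudopod_model()] (or coercible list).
#' @param n_steps Number of pseudopodia (>= 1).
#' @param seed Optional integer seed.
#' @return List with `trajectory` (data frame `step`, `x`, `y`) and
#'   `events` (data frame in the events schema).
#' @export
simulate_trajectory <- function(params, n_steps = 30, seed = NULL) {
  w <- simulate(as_pseudopod_model(params), nsim = 1, seed = seed,
                n_steps = n_steps, events = TRUE)
  list(trajectory = data.frame(step = 0:w$n_steps, x = w$x[, 1], y = w$y[, 1]),
       events = w$events)
}

#' Simulate an ensemble of trajectories
#'
#' Alias for [simulate.pseudopod_model()] with positional ensemble
#' arguments, matching the dispersion-analysis workflow (typically
#' 100,000 trajectories of 30 steps).
#'
#' @inheritParams simulate_trajectory
#' @param n_traj Number of trajectories (>= 1).
#' @export
simulate_ensemble <- function(params, n_traj, n_steps = 30, seed = NULL) {
  simulate(as_pseudopod_model(params), nsim = n_traj, seed = seed,
           n_steps = n_steps, events = FALSE)
}

#' @export
print.pseudopod_walk <- function(x, ...) {
  cat(sprintf("Pseudopod walk: %d trajectories x %d steps (lambda_p = %.2f um)\n",
              x$nsim, x$n_steps, x$model$lambda_p))
  d <- sqrt(x$x[x$n_steps + 1L, ]^2 + x$y[x$n_steps + 1L, ]^2)
  cat(sprintf("  mean end-to-end displacement: %.2f um\n", mean(d)))
  if (!is.null(x$events)) cat(sprintf("  events recorded: %d\n", nrow(x$events)))
  invisible(x)
}

#' @export
plot.pseudopod_walk <- function(x, max_traj = 25, ...) {
  k <- seq_len(min(x$nsim, max_traj))
  graphics::matplot(x$x[, k], x$y[, k], type = "l", lty = 1,
                    xlab = "x (um)", ylab = "y (um)", asp = 1, ...)
  graphics::points(0, 0, pch = 3)
  invisible(x)
}

#' Ensemble mean squared displacement
#'
#' Squared displacement from the origin at each step count, averaged
#' over trajectories (ensemble MSD, not time-averaged).
#'
#' @param walk A `pseudopod_walk` from [simulate.pseudopod_model()].
#' @return Data frame of class `msd_curve` with columns `lag` (1..n
#'   steps), `msd` (um^2) and `n_traj`.
#' @export
ensemble_msd <- function(walk) {
  if (!inherits(walk, "pseudopod_walk")) stop_domain("'walk' must be a pseudopod_walk")
  lags <- seq_len(walk$n_steps)
  msd <- rowMeans(walk$x[-1L, , drop = FALSE]^2 +
                    walk$y[-1L, , drop = FALSE]^2)
  structure(data.frame(lag = lags, msd = msd, n_traj = walk$nsim),
            class = c("msd_curve", "data.frame"))
}

#' Turn angles of a trajectory ensemble
#'
#' Signed angular change of direction between consecutive steps of each
#' trajectory, degrees in `(-180, 180]`.
#'
#' @param walk A `pseudopod_walk`.
#' @return Matrix with `n_steps - 1` rows and one column per trajectory.
#' @export
walk_turn_angles <- function(walk) {
  if (!inherits(walk, "pseudopod_walk")) stop_domain("'walk' must be a pseudopod_walk")
  dx <- diff(walk$x)
  dy <- diff(walk$y)
  ang <- rad2deg(atan2(dy, dx))
  norm_angle(ang[-1L, , drop = FALSE] - ang[-nrow(ang), , drop = FALSE])
}
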