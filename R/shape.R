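#' Closed polygonal cell outline
#'
#' Validates and stores a simple closed polygon of outline nodes
#' (typically ~150, as produced by contour trackers).  The closing
#' vertex may be repeated or omitted; vertices are re-oriented
#' counter-clockwise.
#'
#' @param x,y Vertex coordinates in micrometres (or a 2-column matrix /
#'   data frame as `x`).
#' @return Object of class `cell_outline` with fields `x`, `y`, `n`.
#' @export
cell_outline <- function(x, y = NULL) {
  if (is.null(y)) {
    if (is.data.frame(x) || is.matrix(x)) {
      y <- x[, 2]
      x <- x[, 1]
    } else stop_domain("supply 'y' or a two-column matrix/data frame")
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop_domain("'x' and 'y' lengths differ")
  if (anyNA(x) || anyNA(y)) stop_domain("outline coordinates contain NA")
  n <- length(x)
  if (n > 2 && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  if (n < 8L) stop_domain("outline needs at least 8 vertices")
  if (any(diff(x) == 0 & diff(y) == 0)) stop_domain("outline has duplicate adjacent vertices")
  area <- signed_area(x, y)
  if (abs(area) < 1e-12) stop_domain("outline has zero enclosed area")
  if (area < 0) { x <- rev(x); y <- rev(y) }
  out <- structure(list(x = x, y = y, n = n), class = "cell_outline")
  if (has_self_intersection(x, y)) stop_domain("outline is self-intersecting")
  out
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("Cell outline: %d vertices, area %.2f um^2\n",
              x$n, signed_area(x$x, x$y)))
  invisible(x)
}

#' @export
plot.cell_outline <- function(x, ...) {
  graphics::plot(c(x$x, x$x[1]), c(x$y, x$y[1]), type = "l", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

signed_area <- function(x, y) {
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# O(n^2) segment-pair test over non-adjacent edges; fine at ~150 nodes
has_self_intersection <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  ax <- x; ay <- y; bx <- x[j]; by <- y[j]
  seg_int <- function(i, k) {
    d1 <- (bx[i] - ax[i]) * (ay[k] - ay[i]) - (by[i] - ay[i]) * (ax[k] - ax[i])
    d2 <- (bx[i] - ax[i]) * (by[k] - ay[i]) - (by[i] - ay[i]) * (bx[k] - ax[i])
    d3 <- (bx[k] - ax[k]) * (ay[i] - ay[k]) - (by[k] - ay[k]) * (ax[i] - ax[k])
    d4 <- (bx[k] - ax[k]) * (by[i] - ay[k]) - (by[k] - ay[k]) * (bx[i] - ax[k])
    d1 * d2 < 0 & d3 * d4 < 0
  }
  for (i in seq_len(n - 2L)) {
    ks <- (i + 2L):n
    ks <- ks[!(i == 1L & ks == n)]  # skip adjacent wrap pair
    if (length(ks) && any(seg_int(i, ks))) return(TRUE)
  }
  FALSE
}

#' Tangent and outward normal at an outline node
#'
#' The tangent is the direction of the chord through the two
#' neighbouring nodes; the outward normal is the tangent rotated by 90
#' degrees, oriented away from the outline centroid.
#'
#' @param outline A [cell_outline()].
#' @param node_index Vertex index in `1..n`.
#' @return List with `tangent` and `normal`, degrees in `(-180, 180]`.
#' @export
tangent_at_node <- function(outline, node_index) {
  if (!inherits(outline, "cell_outline")) stop_domain("'outline' must be a cell_outline")
  n <- outline$n
  i <- as.integer(node_index)
  if (is.na(i) || i < 1L || i > n) stop_domain("'node_index' out of range")
  ip <- if (i == 1L) n else i - 1L
  im <- if (i == n) 1L else i + 1L
  dx <- outline$x[im] - outline$x[ip]
  dy <- outline$y[im] - outline$y[ip]
  if (dx == 0 && dy == 0) stop_domain("degenerate geometry: neighbouring nodes coincide")
  tang <- rad2deg(atan2(dy, dx))
  nrm <- tang + 90
  cx <- mean(outline$x); cy <- mean(outline$y)
  vx <- outline$x[i] - cx; vy <- outline$y[i] - cy
  if (cos(deg2rad(nrm)) * vx + sin(deg2rad(nrm)) * vy < 0) nrm <- nrm - 180
  list(tangent = norm_angle(tang), normal = norm_angle(nrm))
}

#' Ellipse parameters
#'
#' @param center Numeric length-2 centre (um).
#' @param semi_major,semi_minor Semi-axes (um), `semi_major >= semi_minor > 0`.
#' @param orientation Major-axis orientation, degrees.
#' @return Object of class `ellipse_params`.
#' @export
ellipse_params <- function(center, semi_major, semi_minor, orientation = 0) {
  if (length(center) != 2L || anyNA(center)) stop_domain("'center' must be length-2")
  if (semi_minor <= 0 || semi_major < semi_minor) {
    stop_domain("need semi_major >= semi_minor > 0")
  }
  structure(list(center = as.numeric(center), semi_major = semi_major,
                 semi_minor = semi_minor,
                 orientation = norm_angle(orientation)),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf("Ellipse: center (%.2f, %.2f), semi-axes %.2f x %.2f um, orientation %.1f deg, area %.2f um^2\n",
              x$center[1], x$center[2], x$semi_major, x$semi_minor,
              x$orientation, ellipse_area(x)))
  invisible(x)
}

ellipse_area <- function(e) pi * e$semi_major * e$semi_minor

# boundary points, counter-clockwise
ellipse_polygon <- function(e, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  th <- deg2rad(e$orientation)
  u <- e$semi_major * cos(t)
  v <- e$semi_minor * sin(t)
  list(x = e$center[1] + u * cos(th) - v * sin(th),
       y = e$center[2] + u * sin(th) + v * cos(th))
}

# normalized elliptic radius of points (1 on the boundary)
ellipse_metric <- function(e, x, y) {
  th <- deg2rad(e$orientation)
  dx <- x - e$center[1]; dy <- y - e$center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  sqrt((u / e$semi_major)^2 + (v / e$semi_minor)^2)
}

# Direct least-squares conic fit (Halir & Flusser partitioning),
# followed by conversion to geometric parameters.
fit_base_ellipse <- function(outline) {
  mx <- mean(outline$x); my <- mean(outline$y)
  x <- outline$x - mx; y <- outline$y - my
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1); s2 <- crossprod(d1, d2); s3 <- crossprod(d2)
  tmat <- -solve(s3, t(s2))
  m <- s1 + s2 %*% tmat
  m <- rbind(m[3, ] / 2, -m[2, ], m[1, ] / 2)
  ev <- eigen(m)
  vec <- Re(ev$vectors)
  cond <- 4 * vec[1, ] * vec[3, ] - vec[2, ]^2
  idx <- which(cond > 0)
  if (!length(idx)) stop_domain("ellipse fit failed: no elliptical solution")
  a1 <- vec[, idx[1]]
  co <- c(a1, as.numeric(tmat %*% a1))  # A B C D E F
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; FF <- co[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop_domain("ellipse fit failed: degenerate conic")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  Fc <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + FF
  q <- eigen(matrix(c(A, B / 2, B / 2, C), 2))
  ax <- sqrt(-Fc / q$values)      # semi-axes along eigen directions
  if (any(!is.finite(ax)) || any(ax <= 0)) stop_domain("ellipse fit failed: non-positive axes")
  major <- which.max(ax)
  orient <- rad2deg(atan2(q$vectors[2, major], q$vectors[1, major]))
  ellipse_params(c(cx + mx, cy + my), max(ax), min(ax), orient)
}

#' Inscribed and circumscribed ellipses of an outline
#'
#' A base ellipse is fitted to the outline vertices by direct algebraic
#' least squares, then scaled about its centre: down by the largest
#' factor keeping it inside the polygon (checked against the outline
#' boundary subsampled along every edge) and up by the smallest factor
#' covering all vertices.  Containment is verified at 512 sampled
#' ellipse points (inner) and at every vertex (outer).
#'
#' @param outline A [cell_outline()].
#' @param subdivide Boundary subsamples per edge for the inner scaling.
#' @return List with `inner` and `outer` [ellipse_params()].
#' @export
inner_outer_ellipses <- function(outline, subdivide = 4) {
  if (!inherits(outline, "cell_outline")) stop_domain("'outline' must be a cell_outline")
  base <- fit_base_ellipse(outline)
  j <- c(2:outline$n, 1L)
  tfrac <- seq(0, 1, length.out = subdivide + 1)[-(subdivide + 1)]
  bx <- as.vector(outer(outline$x, rep(1, length(tfrac))) +
                    outer(outline$x[j] - outline$x, tfrac))
  by <- as.vector(outer(outline$y, rep(1, length(tfrac))) +
                    outer(outline$y[j] - outline$y, tfrac))
  m_boundary <- ellipse_metric(base, bx, by)
  m_vertex <- ellipse_metric(base, outline$x, outline$y)
  c_in <- min(m_boundary)
  c_out <- max(m_vertex)
  mk <- function(s) ellipse_params(base$center, base$semi_major * s,
                                   base$semi_minor * s, base$orientation)
  inner <- mk(c_in)
  outer_e <- mk(c_out)
  # verify inner containment; nudge down a little if boundary sampling
  # missed a concavity
  ok <- FALSE
  for (k in 0:25) {
    ip <- ellipse_polygon(inner, 512)
    if (all(pracma::inpolygon(ip$x, ip$y, outline$x, outline$y,
                              boundary = TRUE))) { ok <- TRUE; break }
    inner <- mk(c_in * 0.995^(k + 1))
  }
  if (!ok) {
    stop(structure(class = c("pseudowalk_ellipse_error", "error", "condition"),
                   list(message = "could not verify an inscribed ellipse for this outline",
                        call = sys.call(-1),
                        best_pair = list(inner = inner, outer = outer_e))))
  }
  if (any(ellipse_metric(outer_e, outline$x, outline$y) > 1 + 1e-9)) {
    stop_domain("outer ellipse fails to cover all vertices")
  }
  list(inner = inner, outer = outer_e)
}

#' Interpolate between two ellipses
#'
#' Parameter-wise linear interpolation of centre and semi-axes;
#' orientation follows the shortest angular path modulo 180 degrees.
#' `t = 0` returns `inner`, `t = 1` returns `outer`.
#'
#' @param inner,outer [ellipse_params()].
#' @param t Interpolation coordinate in `[0, 1]`.
#' @export
interpolated_ellipse <- function(inner, outer, t) {
  check_scalar(t, "t", 0, 1)
  dth <- ((outer$orientation - inner$orientation + 90) %% 180) - 90
  ellipse_params(inner$center + t * (outer$center - inner$center),
                 inner$semi_major + t * (outer$semi_major - inner$semi_major),
                 inner$semi_minor + t * (outer$semi_minor - inner$semi_minor),
                 inner$orientation + t * dth)
}

# Sutherland-Hodgman: clip an arbitrary simple polygon against a convex
# counter-clockwise clip polygon; vectorised over subject vertices.
clip_polygon <- function(sx, sy, cx, cy) {
  nc <- length(cx)
  jn <- c(2:nc, 1L)
  for (i in seq_len(nc)) {
    if (!length(sx)) break
    x1 <- cx[i]; y1 <- cy[i]; x2 <- cx[jn[i]]; y2 <- cy[jn[i]]
    cr <- (x2 - x1) * (sy - y1) - (y2 - y1) * (sx - x1)
    ins <- cr >= 0
    prev <- c(length(sx), seq_len(length(sx) - 1L))
    crp <- cr[prev]; insp <- ins[prev]
    denom <- crp - cr
    tpar <- ifelse(abs(denom) > 0, crp / denom, 0)
    ix <- sx[prev] + tpar * (sx - sx[prev])
    iy <- sy[prev] + tpar * (sy - sy[prev])
    keep <- as.vector(rbind(xor(ins, insp), ins))
    xs <- as.vector(rbind(ix, sx))
    ys <- as.vector(rbind(iy, sy))
    sx <- xs[keep]; sy <- ys[keep]
  }
  list(x = sx, y = sy)
}

#' Outline/ellipse mismatch areas
#'
#' Boolean areas between a cell outline and an ellipse discretised to
#' `n_ellipse` vertices: `O` is the cell area outside the ellipse, `I`
#' the ellipse area outside the cell, `T` the total cell area.
#'
#' @param outline A [cell_outline()].
#' @param ellipse An [ellipse_params()].
#' @param n_ellipse Ellipse discretisation (>= 256 recommended).
#' @return Named list `O`, `I`, `T` (um^2).
#' @export
overlap_areas <- function(outline, ellipse, n_ellipse = 256) {
  if (!inherits(outline, "cell_outline")) stop_domain("'outline' must be a cell_outline")
  if (!inherits(ellipse, "ellipse_params")) stop_domain("'ellipse' must be ellipse_params")
  ep <- ellipse_polygon(ellipse, n_ellipse)
  inter <- clip_polygon(outline$x, outline$y, ep$x, ep$y)
  a_int <- if (length(inter$x) >= 3) abs(signed_area(inter$x, inter$y)) else 0
  t_area <- abs(signed_area(outline$x, outline$y))
  e_area <- abs(signed_area(ep$x, ep$y))
  list(O = max(t_area - a_int, 0), I = max(e_area - a_int, 0), T = t_area)
}

#' Cell-shape irregularity statistic
#'
#' Constructs the inscribed and circumscribed ellipses of the outline,
#' finds by bisection the interpolated ellipse whose mismatch areas
#' balance (`O = I`, equivalently whose area equals the cell area), and
#' returns `psi = (O + I) / T`: 0 for a smooth ellipse, approaching 2
#' for extreme shapes.
#'
#' @param outline A [cell_outline()] (or coercible coordinates).
#' @param tol Balancing tolerance as a fraction of the cell area.
#' @param n_ellipse Ellipse discretisation for the boolean areas.
#' @param max_iter Bisection iteration cap.
#' @return Object of class `shape_psi`: `psi`, `O`, `I`, `T`,
#'   `t_interp`, ellipses `inner`, `outer`, `intermediate`, and
#'   `balanced` (`FALSE` with a warning when no `O = I` crossing exists
#'   and the minimiser of `|O - I|` is reported instead).
#' @examples
#' shape_psi(make_outline("ellipse"))$psi        # ~0
#' shape_psi(make_outline("star", spike_amplitude = 0.3))
#' @export
shape_psi <- function(outline, tol = 1e-3, n_ellipse = 256, max_iter = 60) {
  if (!inherits(outline, "cell_outline")) outline <- cell_outline(outline)
  eo <- inner_outer_ellipses(outline)
  resid <- function(t) {
    oa <- overlap_areas(outline, interpolated_ellipse(eo$inner, eo$outer, t),
                        n_ellipse)
    oa$diff <- oa$O - oa$I
    oa
  }
  lo <- 0; hi <- 1
  r_lo <- resid(lo); r_hi <- resid(hi)
  t_area <- r_lo$T
  balanced <- TRUE
  if (sign(r_lo$diff) == sign(r_hi$diff) &&
      abs(r_lo$diff) > tol * t_area && abs(r_hi$diff) > tol * t_area) {
    warning("no O = I crossing on [0, 1]; reporting the minimiser of |O - I|")
    balanced <- FALSE
    opt <- stats::optimize(function(t) abs(resid(t)$diff), c(0, 1), tol = 1e-8)
    t_star <- opt$minimum
    r <- resid(t_star)
  } else {
    mid <- (lo + hi) / 2
    for (k in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      r <- resid(mid)
      if (abs(r$diff) <= tol * t_area || (hi - lo) < 1e-12) break
      if (sign(r$diff) == sign(r_lo$diff)) {
        lo <- mid; r_lo <- r
      } else hi <- mid
    }
    t_star <- mid
  }
  structure(list(psi = (r$O + r$I) / r$T, O = r$O, I = r$I, T = r$T,
                 t_interp = t_star, inner = eo$inner, outer = eo$outer,
                 intermediate = interpolated_ellipse(eo$inner, eo$outer, t_star),
                 balanced = balanced),
            class = "shape_psi")
}

#' @export
print.shape_psi <- function(x, ...) {
  cat(sprintf("Cell shape statistic: psi = %.4f\n", x$psi))
  cat(sprintf("  O = %.3f, I = %.3f, T = %.3f um^2 (t = %.3f%s)\n",
              x$O, x$I, x$T, x$t_interp,
              if (x$balanced) "" else ", O = I not balanced"))
  invisible(x)
}

#' @export
plot.shape_psi <- function(x, outline = NULL, ...) {
  ip <- ellipse_polygon(x$intermediate, 256)
  if (!is.null(outline)) {
    plot(outline, ...)
  } else {
    graphics::plot(ip$x, ip$y, type = "n", asp = 1,
                   xlab = "x (um)", ylab = "y (um)", ...)
  }
  graphics::polygon(ip$x, ip$y, border = 2)
  for (e in list(x$inner, x$outer)) {
    p <- ellipse_polygon(e, 256)
    graphics::polygon(p$x, p$y, border = "grey60", lty = 2)
  }
  invisible(x)
}
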