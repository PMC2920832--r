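# Independent oracles used to freeze expected values.

# truncated power series for modified Bessel functions
i0_series <- function(x, terms = 40) {
  k <- 0:(terms - 1)
  sum(exp(2 * k * log(x / 2) - 2 * lfactorial(k)))
}
i1_series <- function(x, terms = 40) {
  k <- 0:(terms - 1)
  sum(exp((2 * k + 1) * log(x / 2) - lfactorial(k) - lfactorial(k + 1)))
}

# numeric quadrature of a circular density over one period (theta in deg,
# density per radian)
circle_integral <- function(pdf_deg) {
  stats::integrate(function(t) pdf_deg(t * 180 / pi), -pi, pi,
                   rel.tol = 1e-9)$value
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

# brute-force area of (cell \ ellipse) and (ellipse \ cell) on a grid
grid_overlap_oracle <- function(outline, ellipse, n = 500) {
  xs <- range(c(outline$x, ellipse$center[1] + c(-1, 1) * ellipse$semi_major))
  ys <- range(c(outline$y, ellipse$center[2] + c(-1, 1) * ellipse$semi_major))
  gx <- seq(xs[1], xs[2], length.out = n)
  gy <- seq(ys[1], ys[2], length.out = n)
  px <- rep(gx, times = n)
  py <- rep(gy, each = n)
  cell <- pracma::inpolygon(px, py, outline$x, outline$y)
  th <- rad(ellipse$orientation)
  dx <- px - ellipse$center[1]; dy <- py - ellipse$center[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  ell <- (u / ellipse$semi_major)^2 + (v / ellipse$semi_minor)^2 <= 1
  a_pix <- diff(gx)[1] * diff(gy)[1]
  list(O = sum(cell & !ell) * a_pix, I = sum(ell & !cell) * a_pix,
       T = sum(cell) * a_pix)
}

# per-cell signed turn angles from an event table
event_turns <- function(ev) {
  prev <- ave(ev$alpha_deg, ev$cell_id,
              FUN = function(a) c(NA, a[-length(a)]))
  t <- ev$alpha_deg - prev
  ((t + 180) %% 360) - 180
}

wt5h_model <- function() pseudopod_model(5.2, 0.86, 0.77, 55, 27.8, name = "WT 5h")
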