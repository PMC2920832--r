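# internal angle helpers; public interfaces use degrees, internals radians

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)

# map to (-180, 180]
norm_angle <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

stop_domain <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    stop_domain(sprintf("'%s' must be in [%s, %s], got %s",
                        name, format(lower), format(upper), format(x)))
  }
  invisible(x)
}
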