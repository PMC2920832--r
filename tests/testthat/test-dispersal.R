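test_that("closed-form CRW MSD has the Brownian, two-step, and ballistic limits", {
  expect_equal(crw_msd(5, 2, 0), 20)
  expect_equal(crw_msd(0:20, 3, 0), (0:20) * 9)
  # two-step oracle: 2 lambda^2 + 2 lambda^2 E[cos theta], E[cos theta] = gamma
  expect_equal(crw_msd(2, 1, 0.5), 2 + 2 * 0.5)
  expect_equal(crw_msd(1, 4.61, 0.73), 4.61^2)
  expect_equal(crw_msd(7, 2, 1), (7 * 2)^2)
  expect_error(crw_msd(3, 1, 1.2), "gamma")
  expect_error(crw_msd(3, 1, -1), "gamma")
  # strictly increasing in n and in gamma
  expect_true(all(diff(crw_msd(1:50, 1.3, 0.6)) > 0))
  gs <- seq(-0.5, 0.95, by = 0.05)
  expect_true(all(diff(sapply(gs, function(g) crw_msd(10, 1.3, g))) > 0))
})

test_that("mean_cos_turns implements the arithmetic-mean estimator", {
  expect_equal(mean_cos_turns(rep(0, 10)), 1)
  expect_equal(mean_cos_turns(rep(c(60, -60), 25)), 0.5)
  set.seed(1)
  expect_equal(mean_cos_turns(stats::runif(1e5, -180, 180)), 0,
               tolerance = 0.01)
  expect_error(mean_cos_turns(numeric(0)), "at least one")
})

test_that("fit_crw is the identity on noiseless closed-form curves", {
  curve <- data.frame(lag = 1:30, msd = crw_msd(1:30, 4.61, 0.65))
  f <- fit_crw(curve, lambda = 4.61)
  expect_equal(f$gamma, 0.65, tolerance = 1e-6)
  expect_lt(max(abs(residuals(f))), 1e-4)
  expect_equal(unname(coef(f)["gamma"]), 0.65, tolerance = 1e-6)
  # with lambda free both parameters are recovered
  f2 <- fit_crw(curve)
  expect_equal(f2$gamma, 0.65, tolerance = 1e-6)
  expect_equal(f2$lambda, 4.61, tolerance = 1e-5)
  expect_equal(predict(f2, newdata = 1:30), curve$msd, tolerance = 1e-5)
})

test_that("fit_crw validates its input curve", {
  expect_error(fit_crw(data.frame(lag = 1:2, msd = c(1, 2)), 1), "3")
  expect_error(fit_crw(data.frame(lag = 1:5, msd = c(1, 2, -1, 4, 5)), 1),
               "non-negative")
  expect_error(fit_crw(data.frame(lag = 1:5, msd = c(1, 3, 2, 4, 5)), 1),
               "non-decreasing")
})

test_that("per-step closed form reproduces the published per-strain values", {
  # WT 5h
  expect_equal(gamma_step(wt5h_model()), 0.64, tolerance = 0.01 / 0.64)
  # sgc/pla2-null
  expect_equal(gamma_step(pseudopod_model(5.3, 0.41, 0.75, 54, 27.5)), 0.31,
               tolerance = 0.02 / 0.31)
  expect_equal(gamma_step(pseudopod_model(1, 1, 1, 55, 0)), 1)
  expect_equal(gamma_step(pseudopod_model(1, 0, 1, 55, 28)), 0)
  expect_error(gamma_step(pseudopod_model(1, 1, 0, 90, 10)), "cos")
})

test_that("gamma_step is monotone in s and a, decreasing in sigma, flat in phi at a = 1", {
  g <- function(s = 0.8, a = 0.8, phi = 55, sig = 28) {
    gamma_step(pseudopod_model(1, s, a, phi, sig))
  }
  expect_true(all(diff(sapply(seq(0, 1, 0.1), function(s) g(s = s))) > 0))
  expect_true(all(diff(sapply(seq(0.5, 1, 0.05), function(a) g(a = a))) > 0))
  expect_true(all(diff(sapply(seq(0, 60, 5), function(s) g(sig = s))) < 0))
  dphi <- sapply(seq(30, 80, 5), function(p) g(a = 1, phi = p))
  expect_lt(max(abs(diff(dphi))), 1e-12)
})

test_that("pair and per-step closed forms agree in the low-noise regime", {
  expect_equal(gamma_pairs(pseudopod_model(1, 0, 0.8, 55, 28)), 0)
  expect_equal(gamma_pairs(pseudopod_model(1, 1, 1, 55, 0)), 1)
  p5 <- wt5h_model()
  expect_lt(abs(gamma_step(p5)^2 - gamma_pairs(p5)) / gamma_pairs(p5), 0.03)
  for (sig in seq(5, 30, by = 5)) {
    m <- pseudopod_model(1, 0.8, 0.8, 55, sig)
    expect_lt(abs(gamma_step(m)^2 - gamma_pairs(m)) / gamma_pairs(m), 0.05)
  }
  # the single doubled-variance von Mises variant deviates more at high noise
  m30 <- pseudopod_model(1, 0.8, 0.8, 55, 30)
  expect_gt(abs(gamma_step(m30)^2 - gamma_pairs(m30, "single_vmd")) /
              gamma_pairs(m30, "single_vmd"), 0.05)
})

test_that("step size follows lambda_p cos(phi/2)", {
  expect_equal(step_size(3.7, 0), 3.7)
  expect_equal(step_size(5.2, 180), 0, tolerance = 1e-12)
  expect_equal(round(step_size(5.2, 55), 3), 4.612)
  expect_equal(step_size(5.2, 55), 5.2 * cos(rad(27.5)))
  expect_error(step_size(-1, 55), "lambda_p")
  expect_error(step_size(1, 190), "phi")
})

test_that("turn angle is the arccosine of the correlation factor", {
  expect_equal(turn_angle(0), 90)
  expect_equal(turn_angle(1), 0)
  expect_equal(round(turn_angle(0.74)), 42)
  expect_error(turn_angle(1.2), "gamma")
})

test_that("directional displacement is geometric, monotone, and bounded", {
  expect_equal(directional_displacement(1, 4.61, 0.7), 4.61)
  expect_equal(directional_displacement(c(1, 5, 50), 2, 0), rep(2, 3))
  d <- directional_displacement(1:60, 4.61, 0.7)
  expect_true(all(diff(d) > 0))
  expect_true(all(d < 4.61 / 0.3 + 1e-12))
  expect_equal(directional_displacement(Inf, 4.61, 0.7), 4.61 / 0.3)
  expect_equal(round(directional_displacement(Inf, 4.61, 0.7), 1), 15.4)
  expect_error(directional_displacement(0, 1, 0.5), "n")
  expect_error(directional_displacement(3, 1, 1), "gamma")
})

test_that("gamma-on-s regression matches the published coefficients", {
  tab <- table1_strains()[1:7, ]
  r <- regress_gamma_vs_s(tab$s, tab$gamma_obs)
  expect_equal(round(r$slope, 3), 0.921)
  expect_equal(round(r$intercept, 3), -0.044)
  r2 <- regress_gamma_vs_s(c(0, 1, 0.5), c(0, 1, 0.5))
  expect_equal(r2$slope, 1)
  expect_equal(r2$intercept, 0, tolerance = 1e-12)
  s <- seq(0.1, 0.9, by = 0.1)
  r3 <- regress_gamma_vs_s(s, 0.9 * s)
  expect_equal(r3$slope, 0.9, tolerance = 1e-9)
  expect_error(regress_gamma_vs_s(c(1, 2), c(1, 2)), "3")
  expect_error(regress_gamma_vs_s(rep(0.5, 5), 1:5 / 5), "singular")
})

test_that("variance composition adds independent angular noises in quadrature", {
  expect_equal(round(variance_composition(24.9, 13.3), 1), 28.2)
  expect_equal(variance_composition(17, 0), 17)
  expect_equal(variance_composition(3, 4), 5)
  expect_error(variance_composition(-1, 2), ">= 0")
})

test_that("fitted ensemble correlation factors track the closed form for sigma below 30 deg", {
  tab <- table1_strains()
  tab <- tab[tab$sigma_phi < 30, ]
  for (i in seq_len(nrow(tab))) {
    m <- pseudopod_model(tab$lambda_p[i], tab$s[i], tab$a[i], tab$phi[i],
                         tab$sigma_phi[i])
    w <- simulate(m, nsim = 5e4, seed = 100 + i, n_steps = 30)
    f <- fit_crw(ensemble_msd(w))
    expect_lt(abs(f$gamma - gamma_step(m)), 0.03)
  }
})
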