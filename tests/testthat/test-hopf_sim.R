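test_that("frequency sampling is truncated-normal in rad/s", {
  expect_equal(sample_frequencies(0.04, 0, 5, seed = 1),
               rep(2 * pi * 0.04, 5))
  om <- sample_frequencies(0.04, 0.01, 1e4, seed = 2)
  expect_true(all(om > 0))
  f <- om / (2 * pi)
  expect_lt(abs(mean(f) - 0.04), 3 * 0.01 / sqrt(1e4))
  expect_lt(abs(sd(f) - 0.01), 3 * 0.01 / sqrt(2e4) + 2e-4)
  expect_error(sample_frequencies(-1, 0.1, 5), "positive")
  expect_error(sample_frequencies(0.04, -0.1, 5), "nonnegative")
})

test_that("config validation enforces the documented invariants", {
  expect_error(hopf_config(2, dt = 0), "dt")
  expect_error(hopf_config(2, duration = 5, transient = 10), "transient")
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(hopf_config(2, d = d), "symmetric")
  expect_error(hopf_config(2, d = matrix(c(0, -1, -1, 0), 2)), "nonnegative")
  expect_error(hopf_config(2, omega = c(-1, 1)), "omega")
})

test_that("uncoupled noise-free dynamics have the Stuart-Landau closed forms", {
  # limit cycle: radius sqrt(a), RMS(x) = sqrt(a/2), dominant frequency omega
  f0 <- 0.04
  cfg <- hopf_config(n_o = 1, a = 0.09, omega = 2 * pi * f0, g = 0, xi = 0,
                     duration = 360, transient = 60, seed = 4)
  tr <- simulate_hopf(cfg)
  keep <- tr$time > 60          # 300 s = 12 whole periods at 0.04 Hz
  x <- tr$x[1, keep]
  y <- tr$y[1, keep]
  expect_lt(abs(mean(sqrt(x^2 + y^2)) - 0.3), 0.003)
  expect_lt(abs(sqrt(mean(x^2)) - sqrt(0.09 / 2)) / sqrt(0.09 / 2), 0.01)
  spec <- Mod(fft(x))[2:(length(x) / 2)]
  freq <- (which.max(spec)) / (length(x) * cfg$dt)
  expect_equal(freq, f0, tolerance = 0.05 / length(x))

  # subthreshold: decay toward the low-activity fixed point
  cfg2 <- hopf_config(n_o = 1, a = -0.075, omega = 2 * pi * f0, g = 0,
                      xi = 0, duration = 120, transient = 20, seed = 4)
  tr2 <- simulate_hopf(cfg2)
  expect_lt(abs(tr2$x[1, ncol(tr2$x)]) + abs(tr2$y[1, ncol(tr2$y)]), 1e-2)
})

test_that("RMS is monotone in the bifurcation parameter", {
  rms <- vapply(c(0.02, 0.05, 0.1, 0.2), function(a) {
    cfg <- hopf_config(n_o = 1, a = a, omega = 2 * pi * 0.04, g = 0, xi = 0,
                       duration = 200, transient = 100, seed = 5)
    oscillator_rms(simulate_hopf(cfg))
  }, numeric(1))
  expect_true(all(diff(rms) > 0))
})

test_that("trajectories are reproducible under a fixed seed", {
  cfg <- hopf_config(n_o = 3, a = -0.075, g = 0.1,
                     d = matrix(0.2, 3, 3) - diag(0.2, 3),
                     duration = 30, transient = 10, seed = 12)
  t1 <- simulate_hopf(cfg)
  t2 <- simulate_hopf(cfg)
  expect_identical(t1$x, t2$x)
  expect_identical(t1$omega, t2$omega)
})

test_that("Kuramoto order parameter has its analytic values", {
  # identical signals: R(t) = 1
  t_axis <- seq(0, 100, by = 0.1)
  s <- sin(2 * pi * 0.04 * t_axis)
  expect_equal(kuramoto_order(rbind(s, s, s))$mean_r, 1, tolerance = 1e-9)

  # four equally spaced phases: R = 0
  ph <- c(0, pi / 2, pi, 3 * pi / 2)
  m4 <- t(vapply(ph, function(p) cos(2 * pi * 0.04 * t_axis + p),
                 numeric(length(t_axis))))
  expect_lt(kuramoto_order(m4)$mean_r, 0.02)

  # R in [0, 1] for arbitrary signals
  set.seed(6)
  noisy <- matrix(rnorm(5 * 400), 5)
  r <- kuramoto_order(noisy)
  expect_true(all(r$r_t >= 0 & r$r_t <= 1))
  expect_error(kuramoto_order(matrix(1, 2, 50)), "constant")
})

test_that("two detuned oscillators average R = 2/pi", {
  cfg <- hopf_config(n_o = 2, a = 0.09, omega = 2 * pi * c(0.04, 0.05),
                     g = 0, xi = 0, duration = 360, transient = 60, seed = 3)
  k <- kuramoto_order(simulate_hopf(cfg))
  expect_lt(abs(k$mean_r - 2 / pi), 0.01)
})

test_that("halving dt changes post-transient summaries by < 2%", {
  base <- build_grouped_config("4", config_args = list(
    duration = 120, transient = 20, seed = 21, xi = 0))
  fine <- base
  fine$dt <- 0.005
  om <- sample_frequencies(0.04, 0.01, 4, seed = 22)
  t1 <- simulate_hopf(base, omega = om)
  t2 <- simulate_hopf(fine, omega = om)
  r1 <- kuramoto_order(t1)$mean_r
  r2 <- kuramoto_order(t2)$mean_r
  expect_lt(abs(r1 - r2) / r1, 0.02)
  m1 <- mean(oscillator_rms(t1))
  m2 <- mean(oscillator_rms(t2))
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("grouped configs expand the coupling matrix consistently", {
  d4 <- motif_coupling_matrix()
  c4 <- build_grouped_config("4", d_group = d4)
  expect_equal(c4$n_o, 4L)
  expect_equal(unname(c4$d), unname(d4))

  c192 <- build_grouped_config("192", d_group = NULL)
  expect_equal(c192$n_o, 192L)
  expect_equal(lengths(c192$groups),
               c(`SN-A` = 30L, `SN-B` = 31L, DM = 79L, DA = 52L))
  # total inter-group coupling matches the group-level entry
  idx_a <- c192$groups[["SN-A"]]
  idx_dm <- c192$groups[["DM"]]
  expect_equal(sum(c192$d[idx_a, idx_dm]),
               motif_coupling_matrix()["SN-A", "DM"], tolerance = 1e-12)

  c400 <- build_grouped_config("400")
  expect_equal(c400$n_o, 400L)
  expect_equal(length(c400$groups$other), 208L)
  expect_error(build_grouped_config("123"), "preset")
  expect_error(build_grouped_config(c(a = 0L)), "at least 1")
})

test_that("ablation zeroes the coupling and nothing else", {
  cfg <- build_grouped_config("4", config_args = list(seed = 7))
  ab <- ablate_coupling(cfg)
  expect_true(all(ab$d == 0))
  expect_identical(ablate_coupling(ab)$d, ab$d)    # idempotent
  expect_identical(ab$a, cfg$a)
  expect_identical(ab$xi, cfg$xi)
  expect_identical(ab$g, cfg$g)
})

test_that("parameter sweep averages repetitions and flags the working point", {
  cfg <- build_grouped_config("4", config_args = list(
    duration = 60, transient = 20, seed = 30))
  sw <- parameter_sweep(c(-0.075, 0.09), c(0, 0.1), cfg, reps = 2)
  expect_equal(dim(sw$mean_r), c(2, 2))
  expect_true(all(sw$mean_r >= 0 & sw$mean_r <= 1))
  expect_true(all(is.finite(sw$mean_rms)))
  expect_true(sw$working_point_intermediate %in% c(TRUE, FALSE))
})

test_that("synchrony trends upward with global coupling", {
  cfg <- build_grouped_config("4", config_args = list(
    duration = 120, transient = 20, seed = 50))
  g_grid <- c(0, 0.05, 0.1, 0.3, 0.8, 2)
  sw <- parameter_sweep(-0.075, g_grid, cfg, reps = 2)
  ct <- suppressWarnings(
    stats::cor.test(g_grid, as.numeric(sw$mean_r), method = "spearman",
                    alternative = "greater"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("anticorrelation census has binomial behavior at D = 0", {
  cfg <- ablate_coupling(build_grouped_config("4", config_args = list(
    duration = 90, transient = 20, seed = 40)))
  cen1 <- anticorrelation_census(cfg, n_runs = 1, seed = 2)
  expect_true(cen1$count %in% c(0L, 1L))
  cen <- anticorrelation_census(cfg, n_runs = 100, seed = 3)
  # independence: sign of corr(SN-A, SN-B) is a fair coin
  expect_lt(abs(cen$count - 50), 3 * sqrt(100 * 0.25))
  expect_true(cen$p >= 0 && cen$p <= 1)
})
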