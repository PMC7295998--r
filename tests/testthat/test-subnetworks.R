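test_that("wsbm_loglik matches its exponent algebra and an edge-loop oracle", {
  # 2 nodes, 1 edge of weight w, mu = w, sigma2 = 1: exponent is exactly 0
  w <- 0.37
  cm <- matrix(c(0, w, w, 0), 2)
  expect_equal(wsbm_loglik(cm, c(1, 1), matrix(w), matrix(1)), 0)

  # any instance equals an independent per-edge loop, exponent and full forms
  set.seed(3)
  n <- 12
  cm <- matrix(rnorm(n * n), n)
  cm <- (cm + t(cm)) / 2
  diag(cm) <- 0
  z <- sample(1:3, n, replace = TRUE)
  mu <- matrix(rnorm(9), 3)
  mu <- (mu + t(mu)) / 2
  s2 <- matrix(runif(9, 0.5, 2), 3)
  s2 <- (s2 + t(s2)) / 2
  loop_ll <- function(full) {
    ll <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      m <- mu[z[i], z[j]]
      v <- s2[z[i], z[j]]
      ll <- ll + cm[i, j] * m / v - cm[i, j]^2 / (2 * v) - m^2 / (2 * v)
      if (full) ll <- ll - 0.5 * log(2 * pi * v)
    }
    ll
  }
  expect_equal(wsbm_loglik(cm, z, mu, s2), loop_ll(FALSE), tolerance = 1e-12)
  expect_equal(wsbm_loglik(cm, z, mu, s2, full = TRUE), loop_ll(TRUE),
               tolerance = 1e-12)

  # K = 1 reduces to the global-parameter formula
  expect_equal(wsbm_loglik(cm, rep(1, n), matrix(0.1), matrix(1.3)),
               loop_llk1 <- sum(apply(which(upper.tri(cm), arr.ind = TRUE), 1,
                 function(ij) {
                   w <- cm[ij[1], ij[2]]
                   w * 0.1 / 1.3 - w^2 / 2.6 - 0.01 / 2.6
                 })))

  # invariant to simultaneous relabeling of z, mu, sigma2
  perm <- c(2, 3, 1)
  zp <- perm[z]
  inv <- order(perm)
  expect_equal(wsbm_loglik(cm, zp, mu[inv, inv], s2[inv, inv]),
               wsbm_loglik(cm, z, mu, s2), tolerance = 1e-12)
  expect_error(wsbm_loglik(cm, z, mu, matrix(0, 3, 3)), "positive")
  expect_error(wsbm_loglik(cm, rep(4, n), mu, s2), "out of range")
})

test_that("fit_wsbm recovers planted blocks with monotone log-likelihood", {
  pl <- make_planted_wsbm(seed = 21)
  fit <- fit_wsbm(pl$m, 2, restarts = 10, seed = 1)
  agree <- max(mean(fit$z == pl$z), mean(fit$z == 3 - pl$z))
  expect_equal(agree, 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(fit$z[1], 1L)   # canonical labeling

  # K = 1: the global normal fit
  f1 <- fit_wsbm(pl$m, 1, restarts = 1, seed = 1)
  ut <- pl$m[upper.tri(pl$m)]
  mu <- mean(ut)
  v <- mean((ut - mu)^2)
  expect_equal(f1$loglik, sum(dnorm(ut, mu, sqrt(v), log = TRUE)),
               tolerance = 1e-10)
  expect_lt(f1$loglik, fit$loglik)
  expect_error(fit_wsbm(pl$m, 70, seed = 1), "exceeds")
})

test_that("recovery probability grows with block separation", {
  hits <- vapply(c(0.05, 0.15, 0.5), function(sep) {
    mean(vapply(1:6, function(s) {
      pl <- make_planted_wsbm(seed = 100 + s, n1 = 15, n2 = 16, win = sep,
                              btw = 0, s = 0.1)
      fit <- fit_wsbm(pl$m, 2, restarts = 8, seed = s)
      max(mean(fit$z == pl$z), mean(fit$z == 3 - pl$z)) == 1
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(hits) >= 0))
  expect_equal(hits[3], 1)
})

test_that("zrand is symmetric, centered under independence, and guarded", {
  set.seed(5)
  p1 <- sample(1:3, 60, replace = TRUE)
  p2 <- sample(1:4, 60, replace = TRUE)
  expect_equal(zrand(p1, p2), zrand(p2, p1), tolerance = 1e-12)
  expect_gt(zrand(p1, p1), 0)

  zs <- vapply(1:300, function(i) {
    zrand(sample(1:3, 40, replace = TRUE), sample(1:3, 40, replace = TRUE))
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 / sqrt(300))   # mean 0, unit-ish variance

  expect_error(zrand(1:4, 1:5), "length")
  expect_error(zrand(rep(1, 10), rep(1, 10)), "zero variance")
})

test_that("zrand matches a permutation oracle", {
  set.seed(8)
  p1 <- sample(1:3, 30, replace = TRUE)
  p2 <- sample(1:3, 30, replace = TRUE)
  w_of <- function(a, b) {
    nij <- table(a, b)
    sum(nij * (nij - 1) / 2)
  }
  perm_w <- vapply(1:4000, function(i) w_of(p1, sample(p2)), numeric(1))
  z_emp <- (w_of(p1, p2) - mean(perm_w)) / sd(perm_w)
  expect_equal(zrand(p1, p2), z_emp, tolerance = 0.15)
})

test_that("consensus partition picks the most central input", {
  base <- rep(1:2, each = 10)
  expect_equal(consensus_partition(rep(list(base), 4))$consensus, base)

  set.seed(2)
  scrambled <- sample(base)
  res <- consensus_partition(c(rep(list(base), 9), list(scrambled)))
  expect_true(res$index <= 9)
  expect_equal(res$consensus, base)

  # 3 partitions: argmax of mean pairwise z-Rand, verified by enumeration
  p <- list(rep(1:2, each = 10), c(rep(1, 9), 2, rep(2, 9), 1),
            sample(rep(1:2, each = 10)))
  res3 <- consensus_partition(p)
  ms <- vapply(1:3, function(i) {
    mean(vapply(setdiff(1:3, i), function(j) zrand(p[[i]], p[[j]]),
                numeric(1)))
  }, numeric(1))
  expect_equal(res3$index, which.max(ms))
  expect_error(consensus_partition(list()), "at least two")
})

test_that("permutation null separates planted from structureless cohorts", {
  cons <- rep(1:2, c(15, 16))
  planted <- lapply(1:6, function(s)
    make_planted_wsbm(seed = 300 + s, n1 = 15, n2 = 16)$m)
  res <- partition_permutation_null(planted, cons, seed = 2)
  expect_gt(mean(res$loglik_true - res$loglik_perm), 0)

  # identity permutation: difference exactly zero
  res_id <- partition_permutation_null(planted, cons, seed = 2,
                                       identity_perm = TRUE)
  expect_equal(res_id$loglik_true, res_id$loglik_perm)

  # structureless cohort: single-block generator, expected difference ~ 0
  flat <- lapply(1:10, function(s)
    make_planted_wsbm(seed = 400 + s, n1 = 15, n2 = 16, win = 0, btw = 0)$m)
  res0 <- partition_permutation_null(flat, cons, seed = 3)
  d <- res0$loglik_true - res0$loglik_perm
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)) + 1)
})

test_that("compare_k handles forced and degenerate cases", {
  # identical per-K log-likelihoods: all bootstrap differences are zero
  fits <- list("1" = c(5, 7, 9), "2" = c(5, 7, 9), "3" = c(5, 7, 9))
  res <- compare_k(list(), k_values = c(1, 3), n_boot = 50, seed = 1,
                   fits = fits)
  expect_true(all(res$distributions$k2_vs_k1 == 0))
  expect_true(all(res$distributions$k2_vs_k3 == 0))

  # single subject: distribution degenerate at that subject's difference
  fits1 <- list("1" = 4, "2" = 10)
  res1 <- compare_k(list(), k_values = 1, n_boot = 20, seed = 1, fits = fits1)
  expect_true(all(res1$distributions$k2_vs_k1 == 6))
  expect_error(compare_k(list(), n_boot = 0, fits = fits), "at least 1")
})
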