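test_that("cohort_spec validates targets and sizes", {
  expect_error(cohort_spec(n_timepoints = 5), "at least 10")
  expect_error(cohort_spec(coupling_targets = c(a_dm = 1.2, b_dm = -0.1,
                                                a_da = -0.1, b_da = 0.1)),
               "in \\(-1, 1\\)")
  expect_error(cohort_spec(structural_motif_means = c(a_dm = -1, b_dm = 1,
                                                      a_da = 1, b_da = 1)),
               "nonnegative")
  # planted-world sign convention on targets
  expect_error(cohort_spec(coupling_targets = c(a_dm = -0.04, b_dm = -0.08,
                                                a_da = -0.01, b_da = 0.12)),
               "sign")
  # zeroed effects are a valid (null) world
  expect_silent(cohort_spec(coupling_targets = c(a_dm = 0, b_dm = 0,
                                                 a_da = 0, b_da = 0)))
})

test_that("timeseries generation is deterministic under a fixed seed", {
  parc <- synthetic_parcellation("small")
  spec <- cohort_spec(n_subjects = 3, n_timepoints = 40, seed = 5)
  c1 <- generate_cohort_timeseries(spec, parc)
  c2 <- generate_cohort_timeseries(spec, parc)
  expect_identical(c1$amplitudes, c2$amplitudes)
  expect_identical(c1$timeseries[[5]]$mat, c2$timeseries[[5]]$mat)
})

test_that("noise-free unit-coefficient world gives perfect A-DM coupling", {
  parc <- synthetic_parcellation("small")
  spec <- cohort_spec(n_subjects = 2, n_timepoints = 50,
                      within_subnetwork_corr = 1, amplitude_sd = 0, seed = 2)
  coh <- generate_cohort_timeseries(
    spec, parc,
    coefficients = list(c1 = 1, c2 = 0, c3 = 0, c4 = 0,
                        sigma_a = 0, sigma_b = 1))
  ts <- coh$timeseries[[1]]
  ma <- colMeans(ts$mat[regions_of(parc, "frontoparietal", "A"), ])
  mdm <- colMeans(ts$mat[regions_of(parc, "default-mode"), ])
  expect_equal(cor(ma, mdm), 1)
})

test_that("cohort-average couplings hit the targets within 0.02", {
  # full stated world; both the subnetwork-mean and the region-pair
  # estimator must sit within the band. Monte-Carlo error of the cohort
  # average shrinks as 1/sqrt(n), so the calibration is checked at 150
  # subjects (~3x the default) with the same +/-0.02 band; block
  # correlations are computed directly to keep the test fast.
  parc <- synthetic_parcellation("full")
  spec <- cohort_spec(n_subjects = 150, seed = 11)
  coh <- generate_cohort_timeseries(spec, parc)
  idx <- list(a = regions_of(parc, "frontoparietal", "A"),
              b = regions_of(parc, "frontoparietal", "B"),
              dm = regions_of(parc, "default-mode"),
              da = regions_of(parc, "dorsal-attention"))
  est <- vapply(coh$timeseries, function(ts) {
    mn <- function(i) colMeans(ts$mat[i, ])
    blk <- function(i, j) mean(cor(t(ts$mat[i, ]), t(ts$mat[j, ])))
    c(cor(mn(idx$a), mn(idx$dm)), cor(mn(idx$b), mn(idx$dm)),
      cor(mn(idx$a), mn(idx$da)), cor(mn(idx$b), mn(idx$da)),
      blk(idx$a, idx$dm), blk(idx$b, idx$dm),
      blk(idx$a, idx$da), blk(idx$b, idx$da))
  }, numeric(8))
  targets <- c(0.042, -0.082, -0.014, 0.12)
  mm <- rowMeans(est)[1:4]        # subnetwork-mean vs system-mean
  pair <- rowMeans(est)[5:8]      # region-pair estimator
  expect_true(all(abs(mm - targets) < 0.02))
  expect_true(all(abs(pair - targets) < 0.02))
})

test_that("structural generator plants the block motif", {
  parc <- synthetic_parcellation("full")
  spec <- cohort_spec(n_subjects = 2, seed = 4)
  nets <- generate_structural_network(spec, parc)
  m <- nets[[1]]
  expect_true(isSymmetric(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0))
  g <- list(a = regions_of(parc, "frontoparietal", "A"),
            b = regions_of(parc, "frontoparietal", "B"),
            dm = regions_of(parc, "default-mode"),
            da = regions_of(parc, "dorsal-attention"))
  got <- c(mean(m[g$a, g$dm]), mean(m[g$b, g$dm]),
           mean(m[g$a, g$da]), mean(m[g$b, g$da]))
  want <- c(2.07, 0.676, 1.03, 1.54)
  expect_true(all(abs(got - want) / want < 0.05))
})

test_that("structural generator degenerate worlds behave", {
  parc <- synthetic_parcellation("small")
  # all motif means equal to background: block differences ~ 0
  spec <- cohort_spec(n_subjects = 1,
                      structural_motif_means = c(a_dm = 0.3, b_dm = 0.3,
                                                 a_da = 0.3, b_da = 0.3),
                      structural_background_mean = 0.3, seed = 8)
  m <- generate_structural_network(spec, parc)[[1]]
  g <- list(a = regions_of(parc, "frontoparietal", "A"),
            dm = regions_of(parc, "default-mode"))
  b <- regions_of(parc, "frontoparietal", "B")
  expect_lt(abs(mean(m[g$a, g$dm]) - mean(m[b, g$dm])), 0.05)
  # zero motif + zero background: all-zero matrix
  spec0 <- cohort_spec(n_subjects = 1,
                       structural_motif_means = c(a_dm = 0, b_dm = 0,
                                                  a_da = 0, b_da = 0),
                       structural_background_mean = 0, seed = 8)
  expect_true(all(generate_structural_network(spec0, parc)[[1]] == 0))
})

test_that("a cohort round-trips through its directory layout", {
  parc <- synthetic_parcellation("small")
  spec <- cohort_spec(n_subjects = 2, n_timepoints = 20, seed = 7)
  coh <- generate_cohort_timeseries(spec, parc)
  st <- generate_structural_network(spec, parc)
  dir <- withr::local_tempdir()
  write_cohort(coh, st, dir, spec = spec)
  back <- read_cohort(dir, tr = spec$tr)
  expect_length(back$timeseries, 4)
  expect_equal(back$timeseries[[1]]$mat, coh$timeseries[[1]]$mat,
               tolerance = 1e-6)
  expect_identical(back$structural[[2]], st[[2]])
  expect_equal(back$amplitudes$g_a, coh$amplitudes$g_a, tolerance = 1e-6)
})

test_that("behavior generator respects its construction", {
  spec <- cohort_spec(
    n_subjects = 4,
    behavior = list(intercept = 0.8, beta_a = 0, beta_b = 0, beta_fc = 0,
                    subject_sd = 0, noise_sd = 0), seed = 3)
  runs <- data.frame(subject = rep(1:4, each = 2), run = rep(1:2, 4),
                     g_a = rnorm(8, 1, 0.1), g_b = rnorm(8, 1, 0.1),
                     fc_fp_dm = rnorm(8, 0, 0.05))
  out <- generate_behavior(runs, spec)
  expect_true(all(out$score == 0.8))

  spec2 <- cohort_spec(
    n_subjects = 4,
    behavior = list(intercept = 0.8, beta_a = 0, beta_b = 0, beta_fc = 1,
                    subject_sd = 0, noise_sd = 1e-8), seed = 3)
  out2 <- generate_behavior(runs, spec2)
  expect_lt(cor(out2$score, runs$fc_fp_dm), -0.99)
  expect_true(all(out2$score >= 0 & out2$score <= 1))
  expect_error(generate_behavior(runs[, -3], spec2), "columns")
})

test_that("gene expression generator plants a margin-dependent effect", {
  parc <- synthetic_parcellation("small")
  spec <- cohort_spec(seed = 6)
  labels_of <- function(pr) attr(pr, "subnet_labels")
  ratio_at <- function(margin, seed) {
    sp <- cohort_spec(seed = seed)
    pr <- generate_gene_expression(sp, parc, n_genes = 400,
                                   probes_per_gene = 1, margin = margin)
    agg <- aggregate_probes(pr)
    lab <- labels_of(pr)[rownames(agg$expr)]
    fp <- !is.na(lab)
    r <- coexpression_matrix(agg$expr[fp, ])
    is_a <- lab[fp] == "A"
    wa <- mean(r[is_a, is_a][upper.tri(diag(sum(is_a)))])
    bt <- mean(r[is_a, !is_a])
    wa / bt
  }
  # no planted effect: ratio ~ 1; planted effect: ratio clearly > 1
  null_ratios <- vapply(1:5, function(s) ratio_at(0, s), numeric(1))
  expect_lt(abs(mean(null_ratios) - 1), 0.1)
  big_ratios <- vapply(1:5, function(s) ratio_at(0.5, s), numeric(1))
  expect_true(all(big_ratios > 1.2))
  expect_error(generate_gene_expression(spec, parc, n_genes = 1), "at least 2")
  expect_error(generate_gene_expression(spec, parc, probes_per_gene = 0),
               "at least 1")
})
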