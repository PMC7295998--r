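# shared fixture builders; everything is generated in code at test time

# planted two-block weighted network (within-mean win, between-mean btw)
make_planted_wsbm <- function(seed, n1 = 30, n2 = 31, win = 0.5, btw = 0,
                              s = 0.1) {
  set.seed(seed)
  n <- n1 + n2
  z <- rep(1:2, c(n1, n2))
  mu <- ifelse(outer(z, z, "=="), win, btw)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- rnorm(sum(ut), mu[ut], s)
  m <- m + t(m)
  list(m = m, z = z)
}

# random symmetric nonnegative weight matrix with zero diagonal
random_structural <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  ut <- upper.tri(m)
  m[ut] <- runif(sum(ut))
  m + t(m)
}

# tiny parcellation: 2 FP (A, B), plus DM / DA regions
tiny_parcellation <- function(n_fp_a = 1, n_fp_b = 1, n_dm = 1, n_da = 1) {
  n <- n_fp_a + n_fp_b + n_dm + n_da
  parcellation(
    seq_len(n),
    c(rep("frontoparietal", n_fp_a + n_fp_b), rep("default-mode", n_dm),
      rep("dorsal-attention", n_da)),
    c(rep("A", n_fp_a), rep("B", n_fp_b), rep(NA, n_dm + n_da))
  )
}

# scaled-down study configuration for pipeline tests
small_study_config <- function(seed = 1L, stages = list()) {
  as_analysis_config(list(
    seed = seed,
    stages = utils::modifyList(
      list(wsbm = FALSE, boundary = FALSE, genes = FALSE, hopf = FALSE),
      stages),
    cohort = list(parcellation_scale = "small", n_subjects = 12L,
                  n_timepoints = 80L),
    wsbm = list(restarts = 5L, n_boot = 200L),
    boundary = list(n_perm = 500L),
    genes = list(n_genes = 200L, n_boot = 100L, n_perm = 40L),
    hopf = list(duration = 80, n_runs = 6L, n_ablation_runs = 6L)
  ))
}

# independent brute-force oracle: mean connectivity between two region sets
brute_group_mean <- function(net, idx1, idx2) {
  vals <- c()
  for (i in idx1) {
    for (j in idx2) {
      if (i < j || !identical(idx1, idx2)) {
        if (i != j) vals <- c(vals, net[i, j])
      }
    }
  }
  mean(vals)
}
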