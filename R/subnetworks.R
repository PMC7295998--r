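#' Weighted stochastic block model log-likelihood
#'
#' Sums, over unordered off-diagonal node pairs, the Gaussian term for the
#' edge weight under the block parameters of the pair's labels. By default
#' only the exponent
#' \deqn{C \mu/\sigma^2 - C^2/(2\sigma^2) - \mu^2/(2\sigma^2)}
#' is accumulated (the generative-model exponent; note this equals
#' \eqn{-(C-\mu)^2/(2\sigma^2)}). With \code{full = TRUE} the Gaussian
#' normalizer \eqn{-\log\sqrt{2\pi\sigma^2}} is included; the full form is
#' what model fitting and all model comparisons use, because the
#' exponent-only objective evaluated at blockwise ML parameters is constant
#' across partitions.
#'
#' @param c_sub symmetric weight matrix of the subgraph.
#' @param z integer block labels in 1..K.
#' @param mu K x K block means.
#' @param sigma2 K x K block variances (> 0).
#' @param full include the Gaussian normalizing constant.
#' @return scalar log-likelihood.
#' @export
wsbm_loglik <- function(c_sub, z, mu, sigma2, full = FALSE) {
  k <- nrow(mu)
  z <- as.integer(z)
  if (any(z < 1 | z > k)) stop("label out of range 1..K")
  if (any(sigma2 <= 0)) stop("variances must be positive")
  n <- length(z)
  ut <- upper.tri(c_sub)
  w <- c_sub[ut]
  zi <- matrix(z, n, n)[ut]        # column label (j of pair i<j)
  zj <- t(matrix(z, n, n))[ut]     # row label
  m <- mu[cbind(zj, zi)]
  s2 <- sigma2[cbind(zj, zi)]
  ll <- sum(w * m / s2 - w^2 / (2 * s2) - m^2 / (2 * s2))
  if (full) ll <- ll - sum(0.5 * log(2 * pi * s2))
  ll
}

# blockwise ML parameters (mean and ML variance, floored) given labels
wsbm_params <- function(c_sub, z, k, variance_floor = 1e-6) {
  mu <- matrix(0, k, k)
  s2 <- matrix(variance_floor, k, k)
  degenerate <- FALSE
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(z == a)
      ib <- which(z == b)
      vals <- if (a == b) {
        if (length(ia) >= 2) c_sub[ia, ia][upper.tri(diag(length(ia)))] else numeric(0)
      } else {
        as.numeric(c_sub[ia, ib])
      }
      if (length(vals) >= 1) {
        m <- mean(vals)
        v <- if (length(vals) >= 2) mean((vals - m)^2) else 0
        mu[a, b] <- mu[b, a] <- m
        s2[a, b] <- s2[b, a] <- max(v, variance_floor)
        if (length(vals) < 2) degenerate <- TRUE
      } else {
        degenerate <- TRUE
      }
    }
  }
  list(mu = mu, sigma2 = s2, degenerate = degenerate)
}

# relabel so the block containing the lowest-index node is 1, the block of
# the next node not yet covered is 2, and so on
canonical_labels <- function(z) {
  map <- integer(max(z))
  nxt <- 1L
  out <- integer(length(z))
  for (i in seq_along(z)) {
    b <- z[i]
    if (map[b] == 0L) {
      map[b] <- nxt
      nxt <- nxt + 1L
    }
    out[i] <- map[b]
  }
  out
}

#' Fit a weighted stochastic block model by greedy maximum likelihood
#'
#' Alternating maximization: given labels, block parameters are the blockwise
#' sample mean and (ML) variance; given parameters, nodes are swept
#' sequentially and each label is set to the choice maximizing the full
#' Gaussian log-likelihood. The best of \code{restarts} random
#' initializations is returned. The full log-likelihood is non-decreasing
#' over iterations within a restart.
#'
#' @param c_sub symmetric weight matrix (N_sub x N_sub).
#' @param k number of blocks (N_sub >= K >= 1).
#' @param restarts random restarts (default 20).
#' @param seed integer seed.
#' @param variance_floor lower bound on block variances (default 1e-6).
#' @param max_sweeps maximum node sweeps per restart (default 500).
#' @return object of class \code{wsbm_fit} with fields \code{z} (canonical
#'   labels), \code{mu}, \code{sigma2}, \code{loglik} (full Gaussian
#'   log-likelihood at the fit), \code{loglik_trace}, \code{K},
#'   \code{n_restarts_used}.
#' @export
fit_wsbm <- function(c_sub, k, restarts = 20L, seed = 1L,
                     variance_floor = 1e-6, max_sweeps = 500L) {
  n <- nrow(c_sub)
  if (k > n) stop("K exceeds the number of nodes")
  if (k < 1) stop("K must be at least 1")
  set.seed(seed)
  best <- NULL
  any_degenerate <- FALSE
  for (r in seq_len(restarts)) {
    z <- sample(rep_len(seq_len(k), n))   # every block nonempty at init
    trace <- numeric(0)
    for (sweep in seq_len(max_sweeps)) {
      par <- wsbm_params(c_sub, z, k, variance_floor)
      any_degenerate <- any_degenerate || par$degenerate
      sdm <- sqrt(par$sigma2)
      changed <- FALSE
      for (i in seq_len(n)) {
        if (sum(z == z[i]) == 1L) next   # never empty a block
        scores <- vapply(seq_len(k), function(kk) {
          s <- 0
          for (l in seq_len(k)) {
            jj <- which(z == l)
            jj <- jj[jj != i]
            if (length(jj)) {
              s <- s + sum(dnorm(c_sub[i, jj], par$mu[kk, l], sdm[kk, l],
                                 log = TRUE))
            }
          }
          s
        }, numeric(1))
        knew <- which.max(scores)
        if (knew != z[i]) {
          z[i] <- knew
          changed <- TRUE
        }
      }
      par <- wsbm_params(c_sub, z, k, variance_floor)
      trace <- c(trace, wsbm_loglik(c_sub, z, par$mu, par$sigma2, full = TRUE))
      if (!changed) break
    }
    ll <- trace[length(trace)]
    if (is.null(best) || ll > best$loglik) {
      best <- list(z = z, loglik = ll, trace = trace)
    }
  }
  if (any_degenerate && k > 1) {
    warning("degenerate block (fewer than 2 intra-block pairs); variance floor applied")
  }
  z <- canonical_labels(best$z)
  par <- wsbm_params(c_sub, z, k, variance_floor)
  structure(list(z = z, mu = par$mu, sigma2 = par$sigma2,
                 loglik = best$loglik, loglik_trace = best$trace,
                 K = as.integer(k), n_restarts_used = as.integer(restarts)),
            class = "wsbm_fit")
}

#' z-score of the Rand coefficient between two partitions
#'
#' The number of node pairs co-clustered in both partitions is compared with
#' its exact expectation and standard deviation under random permutation of
#' one partition's labels over the nodes.
#'
#' @param p1,p2 integer label vectors of equal length.
#' @return scalar z-score; symmetric in its arguments.
#' @export
zrand <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("partitions differ in length")
  n <- length(p1)
  a <- as.numeric(table(p1))
  b <- as.numeric(table(p2))
  m <- n * (n - 1) / 2
  m1 <- sum(a * (a - 1) / 2)
  m2 <- sum(b * (b - 1) / 2)
  nij <- table(p1, p2)
  w <- sum(nij * (nij - 1) / 2)
  ew <- m1 * m2 / m
  t3a <- sum(a * (a - 1) * (a - 2))
  t3b <- sum(b * (b - 1) * (b - 2))
  w4a <- sum(a * (a - 1) * (a - 2) * (a - 3)) +
    sum(a * (a - 1)) ^ 2 - sum((a * (a - 1)) ^ 2)
  w4b <- sum(b * (b - 1) * (b - 2) * (b - 3)) +
    sum(b * (b - 1)) ^ 2 - sum((b * (b - 1)) ^ 2)
  n3 <- n * (n - 1) * (n - 2)
  n4 <- n3 * (n - 3)
  ew2 <- m1 * m2 / m + t3a * t3b / n3 + (m1 ^ 2 - m1 - t3a) * w4b / n4
  vw <- ew2 - ew ^ 2
  if (vw <= 1e-12) {
    stop("z-Rand undefined: zero variance (single-block partitions?)")
  }
  (w - ew) / sqrt(vw)
}

#' Consensus partition by mean pairwise similarity
#'
#' Returns the input partition with the highest mean z-Rand similarity to all
#' the others (ties broken by lowest index).
#'
#' @param partitions list of integer label vectors over a common node set.
#' @return list with \code{consensus}, \code{index} of the chosen partition,
#'   and the pairwise \code{similarity} matrix.
#' @export
consensus_partition <- function(partitions) {
  np <- length(partitions)
  if (np < 2) stop("need at least two partitions")
  lens <- vapply(partitions, length, 1L)
  if (length(unique(lens)) != 1) stop("partitions differ in length")
  sim <- matrix(0, np, np)
  for (i in seq_len(np - 1)) {
    for (j in (i + 1):np) {
      zr <- zrand(partitions[[i]], partitions[[j]])
      sim[i, j] <- zr
      sim[j, i] <- zr
    }
  }
  mean_sim <- rowSums(sim) / (np - 1)
  idx <- which.max(mean_sim)       # which.max takes the first maximum
  list(consensus = partitions[[idx]], index = idx, similarity = sim)
}

#' Permutation null for the consensus partition
#'
#' For every subject, the full WSBM log-likelihood of the consensus labels
#' (with per-subject ML block parameters) is paired with the log-likelihood
#' of a size-preserving random permutation of those labels.
#'
#' @param c_sub_list list of per-subject subgraph weight matrices.
#' @param consensus integer consensus labels.
#' @param seed integer seed.
#' @param variance_floor variance floor for ML parameters.
#' @param identity_perm if TRUE the "permutation" is the identity (testing).
#' @return data.frame(subject, loglik_true, loglik_perm).
#' @export
partition_permutation_null <- function(c_sub_list, consensus, seed = 1L,
                                       variance_floor = 1e-6,
                                       identity_perm = FALSE) {
  k <- max(consensus)
  set.seed(seed)
  res <- lapply(seq_along(c_sub_list), function(s) {
    cs <- c_sub_list[[s]]
    if (nrow(cs) != length(consensus)) stop("consensus does not cover subgraph")
    zp <- if (identity_perm) consensus else sample(consensus)
    pt <- wsbm_params(cs, consensus, k, variance_floor)
    pp <- wsbm_params(cs, zp, k, variance_floor)
    c(loglik_true = wsbm_loglik(cs, consensus, pt$mu, pt$sigma2, full = TRUE),
      loglik_perm = wsbm_loglik(cs, zp, pp$mu, pp$sigma2, full = TRUE))
  })
  out <- as.data.frame(do.call(rbind, res))
  out$subject <- seq_along(c_sub_list)
  out[, c("subject", "loglik_true", "loglik_perm")]
}

#' Bootstrap comparison of block counts
#'
#' Fits the WSBM per subject at each K, then bootstraps subjects to obtain a
#' distribution of mean log-likelihood differences (K = 2 minus each other
#' K), with the one-sided tail fraction P(difference <= 0).
#'
#' @param c_sub_list list of per-subject subgraph weight matrices.
#' @param k_values block counts to compare against K = 2 (default c(1, 3)).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param restarts restarts per fit.
#' @param fits optional precomputed list: fits[[as.character(K)]] is a
#'   numeric vector of per-subject log-likelihoods.
#' @return list with per-K bootstrap \code{distributions} and \code{tail}
#'   fractions.
#' @export
compare_k <- function(c_sub_list, k_values = c(1, 3), n_boot = 1000L,
                      seed = 1L, restarts = 10L, fits = NULL) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  ks <- sort(unique(c(2, k_values)))
  if (is.null(fits)) {
    fits <- lapply(ks, function(k) {
      vapply(seq_along(c_sub_list), function(s) {
        fit_wsbm(c_sub_list[[s]], k, restarts = restarts,
                 seed = derive_seed(seed, "compare_k", s * 10L + k))$loglik
      }, numeric(1))
    })
    names(fits) <- as.character(ks)
  }
  n <- length(fits[["2"]])
  set.seed(derive_seed(seed, "compare_k_boot"))
  others <- setdiff(as.character(ks), "2")
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  dist <- lapply(others, function(kc) {
    d <- fits[["2"]] - fits[[kc]]
    rowMeans(matrix(d[idx], nrow = n_boot))
  })
  names(dist) <- paste0("k2_vs_k", others)
  tails <- vapply(dist, function(d) mean(d <= 0), numeric(1))
  list(distributions = dist, tail = tails, per_subject = fits)
}
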