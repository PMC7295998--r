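# independent oracle: direct numerical maximization of the closed-form
# marginal likelihood of the random-intercept model, using dense per-subject
# covariance matrices (no shortcuts shared with the implementation)
oracle_ri_ml <- function(y, x, subj) {
  groups <- split(seq_along(y), subj)
  negll <- function(par) {
    su2 <- exp(par[1])
    se2 <- exp(par[2])
    xtvx <- matrix(0, ncol(x), ncol(x))
    xtvy <- numeric(ncol(x))
    for (g in groups) {
      v <- se2 * diag(length(g)) + su2
      vi <- solve(v)
      xtvx <- xtvx + t(x[g, , drop = FALSE]) %*% vi %*% x[g, , drop = FALSE]
      xtvy <- xtvy + t(x[g, , drop = FALSE]) %*% vi %*% y[g]
    }
    beta <- solve(xtvx, xtvy)
    ll <- 0
    for (g in groups) {
      v <- se2 * diag(length(g)) + su2
      r <- y[g] - x[g, , drop = FALSE] %*% beta
      ll <- ll - 0.5 * (determinant(v)$modulus + t(r) %*% solve(v, r) +
                          length(g) * log(2 * pi))
    }
    -as.numeric(ll)
  }
  opt <- optim(c(0, 0), negll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  list(loglik = -opt$value, sigma_u2 = exp(opt$par[1]),
       sigma_e2 = exp(opt$par[2]))
}
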