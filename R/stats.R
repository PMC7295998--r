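#' Random-intercept multilevel model by marginal maximum likelihood
#'
#' Fits \eqn{y_{it} = X_{it}\beta + u_{0i} + e_{it}} with
#' \eqn{u_{0i} \sim N(0, \sigma_u^2)} and \eqn{e_{it} \sim N(0, \sigma_e^2)}
#' by maximizing the marginal likelihood, profiling over the variance ratio
#' \eqn{\lambda = \sigma_u^2/\sigma_e^2} (the per-subject covariance
#' \eqn{\sigma_e^2 (I + \lambda J)} admits closed-form inverse and
#' determinant). Wald tests use the residual degrees-of-freedom convention
#' df = n_obs - n_fixed - n_subjects + 1. The robust option applies
#' observation-level Huber weights (tuning constant 1.345) on standardized
#' marginal residuals inside an iteratively reweighted ML loop (an
#' approximation to a dedicated robust multilevel estimator).
#'
#' @param outcome numeric response vector.
#' @param predictors numeric matrix/data.frame of fixed-effect covariates
#'   (no intercept column; one is added), or NULL for intercept-only.
#' @param subject_ids grouping vector.
#' @param robust use Huber-weighted IRLS (default FALSE).
#' @param max_iter IRLS iterations for the robust fit.
#' @return object of class \code{multilevel_fit}: \code{coefficients} table
#'   (estimate, se, t, df, p, ci_lo, ci_hi), \code{sigma_u2},
#'   \code{sigma_e2}, \code{loglik}, \code{n_obs}, \code{n_subjects}.
#' @export
fit_random_intercept_model <- function(outcome, predictors = NULL,
                                       subject_ids, robust = FALSE,
                                       max_iter = 25L) {
  y <- as.numeric(outcome)
  n <- length(y)
  x <- if (is.null(predictors)) {
    matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    pm <- as.matrix(predictors)
    if (is.null(colnames(pm))) colnames(pm) <- paste0("x", seq_len(ncol(pm)))
    cbind(`(Intercept)` = 1, pm)
  }
  if (nrow(x) != n) stop("predictors and outcome differ in length")
  subj <- as.factor(subject_ids)
  if (length(subj) != n) stop("subject_ids and outcome differ in length")
  if (nlevels(subj) < 2) stop("need at least 2 subjects")
  if (any(table(subj) < 2)) {
    warning("subject(s) with a single observation; variance components may be weakly identified")
  }
  if (qr(x)$rank < ncol(x)) stop("singular fixed-effect design")
  w <- rep(1, n)
  fit <- NULL
  for (iter in seq_len(if (robust) max_iter else 1L)) {
    fit <- ri_profile_ml(y, x, subj, w)
    if (!robust) break
    r_std <- (y - x %*% fit$beta) / sqrt(fit$sigma_u2 + fit$sigma_e2)
    w_new <- pmin(1, 1.345 / pmax(abs(r_std), 1e-12))
    if (max(abs(w_new - w)) < 1e-8) {
      w <- w_new
      break
    }
    w <- w_new
  }
  p <- ncol(x)
  df <- n - p - nlevels(subj) + 1
  se <- sqrt(diag(fit$vcov))
  tval <- fit$beta / se
  pval <- 2 * pt(-abs(tval), df)
  crit <- qt(0.975, df)
  coefs <- data.frame(
    estimate = as.numeric(fit$beta), se = se, t = as.numeric(tval), df = df,
    p = as.numeric(pval),
    ci_lo = as.numeric(fit$beta - crit * se),
    ci_hi = as.numeric(fit$beta + crit * se),
    row.names = colnames(x)
  )
  structure(list(coefficients = coefs, sigma_u2 = fit$sigma_u2,
                 sigma_e2 = fit$sigma_e2, loglik = fit$loglik,
                 n_obs = n, n_subjects = nlevels(subj), robust = robust,
                 weights = w),
            class = "multilevel_fit")
}

# profile ML for the random-intercept model with observation weights
# (weights fold into the residual precision: e_it ~ N(0, sigma_e^2 / w_it))
ri_profile_ml <- function(y, x, subj, w) {
  sw <- sqrt(w)
  groups <- split(seq_along(y), subj)
  eval_lambda <- function(lambda) {
    xtvx <- matrix(0, ncol(x), ncol(x))
    xtvy <- numeric(ncol(x))
    logdet <- 0
    for (g in groups) {
      xw <- x[g, , drop = FALSE] * sw[g]
      yw <- y[g] * sw[g]
      swg <- sw[g]
      denom <- 1 + lambda * sum(w[g])
      # V_g^{-1} for weighted obs: diag(w) - lambda w w' / (1 + lambda sum w)
      xs <- colSums(xw * swg)            # t(X) W 1
      ys <- sum(yw * swg)
      xtvx <- xtvx + crossprod(xw) - lambda * tcrossprod(xs) / denom
      xtvy <- xtvy + crossprod(xw, yw) - lambda * xs * ys / denom
      logdet <- logdet + log(denom) - sum(log(w[g]))
    }
    beta <- solve(xtvx, xtvy)
    rss <- 0
    for (g in groups) {
      r <- y[g] - x[g, , drop = FALSE] %*% beta
      rw <- r * w[g]
      denom <- 1 + lambda * sum(w[g])
      rss <- rss + sum(r * rw) - lambda * sum(rw)^2 / denom
    }
    n <- length(y)
    sigma_e2 <- max(rss / n, 1e-300)
    ll <- -n / 2 * log(2 * pi * sigma_e2) - logdet / 2 - n / 2
    list(loglik = ll, beta = beta, sigma_e2 = sigma_e2, xtvx = xtvx)
  }
  opt <- optimize(function(ll) -eval_lambda(exp(ll))$loglik,
                  interval = c(-14, 10), tol = 1e-9)
  cand <- exp(opt$minimum)
  at0 <- eval_lambda(0)
  best_lambda <- if (at0$loglik >= -opt$objective) 0 else cand
  res <- eval_lambda(best_lambda)
  vcov <- res$sigma_e2 * solve(res$xtvx)
  list(beta = res$beta, sigma_e2 = res$sigma_e2,
       sigma_u2 = best_lambda * res$sigma_e2, loglik = res$loglik,
       vcov = vcov, lambda = best_lambda)
}

#' Repeated-measures correlation
#'
#' Within-subject association between two repeatedly measured variables:
#' subject means are absorbed by subject fixed effects (ANCOVA) and a common
#' slope is fit to the within-subject centered covariate. The repeated
#' measures correlation is the signed square root of the partial variance
#' explained by the covariate, bounded in [-1, 1].
#'
#' @param m1,m2 numeric vectors (measure 1 and measure 2).
#' @param subject_ids grouping vector.
#' @return object of class \code{rmcorr_result}: \code{rrm}, \code{slope},
#'   \code{df}, \code{p}.
#' @export
rmcorr <- function(m1, m2, subject_ids) {
  subj <- as.factor(subject_ids)
  if (length(m1) != length(m2) || length(m1) != length(subj)) {
    stop("inputs differ in length")
  }
  if (nlevels(subj) < 2) stop("need at least 2 subjects")
  wv <- tapply(m2, subj, function(v) sum((v - mean(v))^2))
  if (sum(wv) <= 0) stop("no within-subject variance in m2")
  fit <- stats::lm(m1 ~ subj + m2)
  an <- stats::anova(fit)
  ss_m2 <- an["m2", "Sum Sq"]
  ss_err <- an["Residuals", "Sum Sq"]
  df <- an["Residuals", "Df"]
  slope <- stats::coef(fit)[["m2"]]
  rrm <- sign(slope) * sqrt(ss_m2 / (ss_m2 + ss_err))
  fstat <- (ss_m2 / 1) / (ss_err / df)
  p <- pf(fstat, 1, df, lower.tail = FALSE)
  structure(list(rrm = rrm, slope = slope, df = df, p = p),
            class = "rmcorr_result")
}

#' Paired-swap permutation test
#'
#' Null model for the difference in means of two paired session vectors:
#' each paired element is independently swapped between the vectors with
#' probability 1/2 (equivalently, the sign of each paired difference is
#' flipped). The one-sided p (default, matching the convention of reporting
#' the proportion of null differences at or above the observed difference)
#' or two-sided p is returned.
#'
#' @param y1,y2 numeric vectors of equal length (2n session observations).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @param alternative "greater" (default) or "two.sided".
#' @return list with \code{observed} mean difference, \code{p}, and the
#'   null distribution.
#' @export
paired_swap_permutation <- function(y1, y2, n_perm = 10000L, seed = 1L,
                                    alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(y1) != length(y2)) stop("y1 and y2 differ in length")
  d <- y1 - y2
  observed <- mean(d)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), length(d) * n_perm, replace = TRUE),
                  nrow = n_perm)
  null <- as.numeric(signs %*% d) / length(d)
  p <- if (alternative == "greater") {
    mean(null >= observed)
  } else {
    mean(abs(null) >= abs(observed))
  }
  list(observed = observed, p = p, null = null, alternative = alternative)
}

#' Bonferroni correction
#' @param p_values numeric vector of p-values in [0, 1].
#' @param m number of comparisons (must be >= length(p_values); default
#'   length(p_values)).
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must be in [0, 1]")
  if (m < length(p_values)) stop("m must be at least the number of tests")
  pmin(1, m * p_values)
}
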