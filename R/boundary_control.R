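#' Regional boundary control over two target systems
#'
#' For each region i, with k_i the total structural strength of i, k_i(J) the
#' summed strength of i's connections into system J and k_i(L) into system L:
#' if k_i(J) + k_i(L) equals k_i (relative tolerance 1e-9), boundary control
#' is \eqn{1 - (k_i(J)/k_i)^2 - (k_i(L)/k_i)^2}; otherwise it is
#' \eqn{(k_i(J)/k_i)^2 + (k_i(L)/k_i)^2}. A region's own connections into J
#' and L count toward k_i(J)/k_i(L); all of its connections (including those
#' to other systems) count toward k_i. BC is scale-invariant in C_s and lies
#' in [0, 1].
#'
#' @param cs N x N nonnegative structural matrix (typically normalized).
#' @param parc a \code{parcellation}.
#' @param system_j,system_l names of the two target systems (disjoint).
#' @param tol relative tolerance for the equality branch (default 1e-9).
#' @return data.frame with region_id, k, k_j, k_l, bc.
#' @export
boundary_control <- function(cs, parc, system_j = "default-mode",
                             system_l = "dorsal-attention", tol = 1e-9) {
  idx_j <- regions_of(parc, system_j)
  idx_l <- regions_of(parc, system_l)
  if (length(intersect(idx_j, idx_l))) stop("target systems overlap")
  m <- cs
  diag(m) <- 0
  k <- rowSums(m)
  if (any(k == 0)) {
    stop("isolated region(s) with zero strength: ",
         paste(which(k == 0), collapse = ", "))
  }
  kj <- rowSums(m[, idx_j, drop = FALSE])
  kl <- rowSums(m[, idx_l, drop = FALSE])
  fj <- kj / k
  fl <- kl / k
  interior <- abs((kj + kl) - k) <= tol * k
  bc <- ifelse(interior, 1 - fj^2 - fl^2, fj^2 + fl^2)
  data.frame(region_id = parc$region_id, k = k, k_j = kj, k_l = kl, bc = bc)
}

#' Regions above a boundary-control percentile
#'
#' Returns the \code{ceiling(N * (1 - pct/100))} regions with the highest
#' values; ties broken deterministically by lower region index first.
#'
#' @param bc data.frame from \code{boundary_control} (or any frame with
#'   region_id and bc columns).
#' @param pct percentile cutoff in (0, 100); default 95.
#' @return integer vector of region ids.
#' @export
top_percentile_regions <- function(bc, pct = 95) {
  if (pct <= 0 || pct >= 100) stop("pct must be in (0, 100)")
  n <- nrow(bc)
  n_top <- ceiling(n * (1 - pct / 100) - 1e-9)   # guard against 0.95 rounding
  ord <- order(-bc$bc, bc$region_id)
  sort(bc$region_id[ord[seq_len(n_top)]])
}

#' Enrichment of a region set in a target system
#'
#' Observed count of set members inside the target system, compared with (i)
#' a label-permutation null (fraction of permutations with count >= observed)
#' and (ii) the exact hypergeometric tail, which serves as the internal
#' oracle for the permutation estimate.
#'
#' @param region_set integer vector of region ids.
#' @param target_system system name.
#' @param parc a \code{parcellation}.
#' @param n_perm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed.
#' @return list with observed count, p_perm, p_exact, and the null counts.
#' @export
enrichment_test <- function(region_set, target_system, parc,
                            n_perm = 10000L, seed = 1L) {
  if (!all(region_set %in% parc$region_id)) {
    stop("region_set contains unknown region ids")
  }
  target <- parc$region_id[parc$system == target_system]
  if (!length(target)) stop("empty target system: ", target_system)
  if (n_perm < 100) warning("fewer than 100 permutations; p is unreliable")
  observed <- sum(region_set %in% target)
  n <- nrow(parc)
  k <- length(region_set)
  m <- length(target)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_perm), function(i) {
    sum(sample(parc$region_id, k) %in% target)
  }, numeric(1))
  p_perm <- mean(null_counts >= observed)
  p_exact <- phyper(observed - 1, m, n - m, k, lower.tail = FALSE)
  list(observed = observed, p_perm = p_perm, p_exact = p_exact,
       n_perm = n_perm, null_counts = null_counts)
}
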