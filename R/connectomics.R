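#' Functional connectivity matrix from regional timeseries
#'
#' The functional network C_f holds the Pearson correlation between every
#' pair of regional timeseries. The diagonal is set to NA (self-correlations
#' are excluded from all downstream averages).
#'
#' @param ts a \code{regional_timeseries} or a bare regions x timepoints
#'   matrix.
#' @return N x N symmetric correlation matrix with NA diagonal.
#' @export
compute_functional_network <- function(ts) {
  mat <- if (inherits(ts, "regional_timeseries")) ts$mat else ts
  if (anyNA(mat)) stop("timeseries contains missing values")
  if (ncol(mat) < 3) stop("need at least 3 timepoints")
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    stop("constant timeseries for region(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  cf <- cor(t(mat))
  diag(cf) <- NA_real_
  cf
}

# mean of net over all cross pairs between two disjoint index sets, or over
# distinct within pairs when the sets coincide
pair_mean <- function(net, idx1, idx2) {
  if (identical(idx1, idx2)) {
    if (length(idx1) < 2) return(NA_real_)
    block <- net[idx1, idx1]
    mean(block[upper.tri(block)])
  } else {
    mean(net[idx1, idx2])
  }
}

#' System-by-system (or subnetwork-resolved) average connectivity
#'
#' Entry (s, t) is the mean edge weight over all region pairs with one region
#' in group s and the other in group t; diagonal entries average distinct
#' within-group pairs only. Raw values are averaged (no Fisher transform).
#'
#' @param net N x N connectivity matrix (functional or structural); the
#'   diagonal is ignored.
#' @param parc a \code{parcellation}.
#' @param level \code{"systems"} for the eight systems, or
#'   \code{"subnetworks"} to split the frontoparietal system into A and B.
#' @return S x S symmetric matrix with group names as dimnames.
#' @export
average_system_network <- function(net, parc, level = c("systems", "subnetworks")) {
  level <- match.arg(level)
  groups <- system_groups(parc, level)
  group_mean_matrix(net, groups)
}

system_groups <- function(parc, level) {
  groups <- lapply(SYSTEM_NAMES, function(s) which(parc$system == s))
  names(groups) <- SYSTEM_NAMES
  groups <- groups[vapply(groups, length, 1L) > 0]
  if (level == "subnetworks") {
    if (all(is.na(parc$subnetwork))) stop("no subnetwork labels in parcellation")
    groups[["frontoparietal"]] <- NULL
    groups <- c(groups,
                list(`frontoparietal-A` = regions_of(parc, "frontoparietal", "A"),
                     `frontoparietal-B` = regions_of(parc, "frontoparietal", "B")))
  }
  groups
}

#' Group-averaged connectivity for arbitrary region groups
#' @param net N x N matrix.
#' @param groups named list of region index vectors (disjoint).
#' @return symmetric matrix of group-pair means.
#' @export
group_mean_matrix <- function(net, groups) {
  if (any(vapply(groups, length, 1L) == 0)) stop("empty group")
  all_idx <- unlist(groups)
  if (anyDuplicated(all_idx)) stop("groups overlap")
  k <- length(groups)
  out <- matrix(NA_real_, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k)) {
    for (j in i:k) {
      v <- pair_mean(net, groups[[i]], groups[[j]])
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Mean coupling between a frontoparietal subnetwork and a system
#'
#' The mean functional connection over all region pairs with one region in
#' the subnetwork and the other in the target system.
#'
#' @param net N x N functional connectivity matrix.
#' @param parc a \code{parcellation} with subnetwork labels.
#' @param subnet "A" or "B".
#' @param system target system name.
#' @return scalar mean correlation.
#' @export
subnetwork_system_coupling <- function(net, parc, subnet, system) {
  idx_s <- regions_of(parc, "frontoparietal", subnet)
  idx_t <- regions_of(parc, system)
  if (length(intersect(idx_s, idx_t))) {
    stop("subnetwork and system overlap; cross-pair coupling is undefined")
  }
  mean(net[idx_s, idx_t])
}

#' RMS activity of a subnetwork
#'
#' Root mean square of the across-region mean timeseries of the subnetwork.
#'
#' @param ts a \code{regional_timeseries} or matrix.
#' @param parc a \code{parcellation}.
#' @param subnet "A" or "B".
#' @return scalar RMS.
#' @export
subnetwork_rms <- function(ts, parc, subnet) {
  mat <- if (inherits(ts, "regional_timeseries")) ts$mat else ts
  idx <- regions_of(parc, "frontoparietal", subnet)
  m <- colMeans(mat[idx, , drop = FALSE])
  sqrt(mean(m^2))
}

#' Normalize a structural network by its total edge weight
#'
#' After normalization the summed upper-triangle weight is 1; the operation
#' is idempotent.
#'
#' @param cs N x N nonnegative symmetric matrix.
#' @return normalized matrix.
#' @export
normalize_structural <- function(cs) {
  if (any(cs < 0)) stop("structural weights must be nonnegative")
  diag(cs) <- 0
  total <- sum(cs[upper.tri(cs)])
  if (total == 0) stop("all-zero structural matrix cannot be normalized")
  cs / total
}

#' Threshold a structural network by dropping the weakest edges
#'
#' Zeroes the weakest \code{drop_fraction} of nonzero edges (by weight; ties
#' broken in ascending (row, column) order for determinism), then
#' re-normalizes so total weight is 1.
#'
#' @param cs N x N nonnegative symmetric matrix.
#' @param drop_fraction fraction of nonzero edges to remove, in [0, 1).
#' @return thresholded, normalized matrix.
#' @export
threshold_structural <- function(cs, drop_fraction) {
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop("drop_fraction must be in [0, 1)")
  }
  if (any(cs < 0)) stop("structural weights must be nonnegative")
  diag(cs) <- 0
  ut <- which(upper.tri(cs))
  w <- cs[ut]
  nz <- which(w > 0)
  if (!length(nz)) stop("all-zero structural matrix")
  n_drop <- floor(drop_fraction * length(nz) + 1e-9)
  if (n_drop > 0) {
    ord <- nz[order(w[nz], ut[nz])]      # weight, then (row, col) index
    drop <- ord[seq_len(n_drop)]
    w[drop] <- 0
  }
  out <- cs
  out[ut] <- w
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  normalize_structural(out)
}

#' Across-subject mean structural coupling between region groups
#'
#' D[g, h] is the across-subject mean of the group-pair averaged structural
#' weight; the diagonal is set to 0 by convention (self-coupling carries no
#' information in the difference-coupled oscillator model).
#'
#' @param cs_list list of N x N structural matrices, one per subject.
#' @param groups named list of disjoint region index vectors.
#' @return symmetric group x group matrix with zero diagonal.
#' @export
mean_structural_coupling <- function(cs_list, groups) {
  if (!length(cs_list)) stop("need at least one subject")
  mats <- lapply(cs_list, group_mean_matrix, groups = groups)
  d <- Reduce(`+`, mats) / length(mats)
  diag(d) <- 0
  d
}
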