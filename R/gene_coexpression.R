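#' Aggregate probe-level expression to a parcel-by-gene matrix
#'
#' For every probe, the probe's across-parcel mean is subtracted; the
#' centered probe values are then averaged per (parcel, gene). Parcels with
#' any gene left uncovered (no probe observation) are dropped with a message.
#'
#' @param probe_table data.frame with columns parcel, gene, probe, value.
#' @return list with \code{expr} (parcels x genes matrix, parcel ids as
#'   rownames, gene ids as colnames) and \code{dropped_parcels}.
#' @export
aggregate_probes <- function(probe_table) {
  need <- c("parcel", "gene", "probe", "value")
  if (!all(need %in% names(probe_table))) {
    stop("probe table must have columns ", paste(need, collapse = ", "))
  }
  parcels <- sort(unique(probe_table$parcel))
  genes <- sort(unique(probe_table$gene))
  pi <- match(probe_table$parcel, parcels)
  gi <- match(probe_table$gene, genes)
  # probes are nested in genes: identify each (gene, probe) combination
  gp_key <- paste(probe_table$gene, probe_table$probe, sep = "\r")
  gp <- match(gp_key, unique(gp_key))
  centered <- probe_table$value -
    (rowsum(probe_table$value, gp) / rowsum(rep(1, length(gp)), gp))[gp]
  cell <- (gi - 1L) * length(parcels) + pi
  sums <- rowsum(centered, cell)
  counts <- rowsum(rep(1, length(cell)), cell)
  expr <- matrix(NA_real_, nrow = length(parcels), ncol = length(genes),
                 dimnames = list(parcels, genes))
  expr[as.integer(rownames(sums))] <- sums / counts
  covered <- rowSums(is.na(expr)) == 0
  dropped <- parcels[!covered]
  if (length(dropped)) {
    message("dropping ", length(dropped),
            " parcel(s) with incomplete gene coverage")
    expr <- expr[covered, , drop = FALSE]
  }
  list(expr = expr, dropped_parcels = dropped)
}

#' Parcel-by-parcel gene coexpression matrix
#'
#' Pearson correlation between the gene expression profiles of every parcel
#' pair.
#'
#' @param expr parcels x genes matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
coexpression_matrix <- function(expr) {
  if (ncol(expr) < 3) stop("need at least 3 genes")
  sds <- apply(expr, 1, sd)
  if (any(sds == 0)) {
    stop("constant expression profile for parcel(s): ",
         paste(rownames(expr)[sds == 0], collapse = ", "))
  }
  cor(t(expr))
}

# mean coexpression within a label group / between the two groups
coexpr_ratio <- function(r, is_a, is_b) {
  wa <- r[is_a, is_a][upper.tri(diag(sum(is_a)))]
  wb <- r[is_b, is_b][upper.tri(diag(sum(is_b)))]
  bt <- r[is_a, is_b]
  c(within_a = mean(wa), within_b = mean(wb), between = mean(bt),
    ratio_a = mean(wa) / mean(bt), ratio_b = mean(wb) / mean(bt))
}

#' Bootstrap/permutation test of subnetwork gene-coexpression specificity
#'
#' For each bootstrap resample of genes (with replacement, full size): the
#' coexpression matrix is rebuilt; the within/between coexpression ratio is
#' computed; its null expectation is the mean ratio over \code{n_perm}
#' permutations of the subnetwork labels; the bootstrap index is ratio minus
#' null expectation. The p-value is the fraction of bootstrap indices below
#' zero. Ratios (and p-values) are computed per subnetwork (within-A/between
#' and within-B/between).
#'
#' @param expr parcels x genes matrix.
#' @param subnet_labels character vector ("A"/"B") aligned with the rows of
#'   \code{expr}.
#' @param n_boot bootstrap resamples (default 1000).
#' @param n_perm label permutations per bootstrap (default 200).
#' @param seed integer seed.
#' @param with_replacement bootstrap genes with replacement (default TRUE).
#' @return list of class \code{coexpression_result}: observed means and
#'   ratios, per-subnetwork index distributions and p-values.
#' @export
coexpression_bootstrap_test <- function(expr, subnet_labels, n_boot = 1000L,
                                        n_perm = 200L, seed = 1L,
                                        with_replacement = TRUE) {
  if (n_boot < 1 || n_perm < 1) stop("n_boot and n_perm must be at least 1")
  labels <- as.character(subnet_labels)
  if (length(labels) != nrow(expr)) stop("labels must match parcels")
  is_a <- labels == "A"
  is_b <- labels == "B"
  if (sum(is_a) < 2 || sum(is_b) < 2) {
    stop("need at least 2 parcels per subnetwork")
  }
  ng <- ncol(expr)
  texpr <- t(expr)
  set.seed(seed)
  observed <- coexpr_ratio(coexpression_matrix(expr), is_a, is_b)
  idx_a <- numeric(n_boot)
  idx_b <- numeric(n_boot)
  np <- length(labels)
  for (b in seq_len(n_boot)) {
    gs <- sample.int(ng, ng, replace = with_replacement)
    r <- cor(texpr[gs, , drop = FALSE])
    rb <- coexpr_ratio(r, is_a, is_b)
    null_a <- numeric(n_perm)
    null_b <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      pidx <- sample.int(np)
      rp <- coexpr_ratio(r, is_a[pidx], is_b[pidx])
      null_a[p] <- rp[["ratio_a"]]
      null_b[p] <- rp[["ratio_b"]]
    }
    idx_a[b] <- rb[["ratio_a"]] - mean(null_a)
    idx_b[b] <- rb[["ratio_b"]] - mean(null_b)
  }
  structure(list(
    observed = observed,
    index_a = idx_a, index_b = idx_b,
    p_a = mean(idx_a < 0), p_b = mean(idx_b < 0),
    n_boot = n_boot, n_perm = n_perm
  ), class = "coexpression_result")
}
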