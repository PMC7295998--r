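#' Specification of a synthetic cohort
#'
#' Encodes the stated world that the generator emulates: a multi-subject,
#' two-runs-per-subject task-fMRI cohort in which the frontoparietal
#' subnetwork A is positively coupled to the default-mode (DM) system and
#' negatively to the dorsal-attention (DA) system, subnetwork B shows the
#' opposite pattern, structural connectivity carries the matching motif
#' (A-DM and B-DA strong), and behavioral accuracy decreases with
#' frontoparietal-DM coupling.
#'
#' @param n_subjects number of subjects (default 50, desk scale).
#' @param runs_per_subject scans nested within subject (default 2).
#' @param n_timepoints timepoints per run (default 405).
#' @param tr repetition time in seconds (default 0.72).
#' @param coupling_targets named vector \code{(a_dm, b_dm, a_da, b_da)} of
#'   cohort-mean correlation targets; defaults are the empirical couplings
#'   (0.042, -0.082, -0.014, 0.12).
#' @param within_subnetwork_corr correlation between two regions sharing a
#'   latent signal (default 0.9); determines the regional noise SD
#'   \code{noise_sd = sqrt(1/w - 1)} unless \code{noise_sd} is given.
#' @param noise_sd regional additive noise SD; derived from
#'   \code{within_subnetwork_corr} when NULL.
#' @param amplitude_sd between-subject SD of the latent amplitude factors
#'   g_A, g_B (mean 1, truncated at 0.1). Default 0.3.
#' @param structural_motif_means named vector \code{(a_dm, b_dm, a_da, b_da)}
#'   of planted structural block means (pre-normalization).
#' @param structural_background_mean mean of non-motif edges (default 0.3).
#' @param behavior list with \code{intercept}, \code{beta_a}, \code{beta_b},
#'   \code{beta_fc}, \code{subject_sd}, \code{noise_sd}.
#' @param seed integer master seed for the generator.
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_subjects = 50L, runs_per_subject = 2L,
                        n_timepoints = 405L, tr = 0.72,
                        coupling_targets = c(a_dm = 0.042, b_dm = -0.082,
                                             a_da = -0.014, b_da = 0.12),
                        within_subnetwork_corr = 0.9,
                        noise_sd = NULL,
                        amplitude_sd = 0.3,
                        structural_motif_means = c(a_dm = 2.07, b_dm = 0.676,
                                                   a_da = 1.03, b_da = 1.54),
                        structural_background_mean = 0.3,
                        behavior = list(intercept = 0.8, beta_a = 0.05,
                                        beta_b = 0.05, beta_fc = 1.0,
                                        subject_sd = 0.02, noise_sd = 0.02),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, runs_per_subject >= 1)
  if (n_timepoints < 10) stop("n_timepoints must be at least 10")
  ct <- coupling_targets[c("a_dm", "b_dm", "a_da", "b_da")]
  if (anyNA(ct)) stop("coupling_targets must name a_dm, b_dm, a_da, b_da")
  if (any(abs(ct) >= 1)) stop("correlation targets must lie in (-1, 1)")
  mm <- structural_motif_means[c("a_dm", "b_dm", "a_da", "b_da")]
  if (anyNA(mm)) stop("structural_motif_means must name a_dm, b_dm, a_da, b_da")
  if (any(mm < 0)) stop("structural motif means must be nonnegative")
  if (structural_background_mean < 0) stop("background mean must be >= 0")
  w <- within_subnetwork_corr
  if (w <= 0 || w > 1) stop("within_subnetwork_corr must be in (0, 1]")
  if (is.null(noise_sd)) noise_sd <- sqrt(1 / w - 1)
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  # latent coupling coefficients: inflate targets by 1/sqrt(w) so that the
  # region-pair estimator (attenuated by w) and the subnetwork-mean estimator
  # (attenuation ~ 1) straddle the target symmetrically
  coef <- latent_coefficients_from_targets(ct, w)
  # PSD check of the implied latent covariance at g = 1
  lat <- diag(4)
  dimnames(lat) <- list(c("dm", "da", "a", "b"), c("dm", "da", "a", "b"))
  lat["dm", "a"] <- lat["a", "dm"] <- coef$c1
  lat["da", "a"] <- lat["a", "da"] <- -coef$c2
  lat["dm", "b"] <- lat["b", "dm"] <- -coef$c3
  lat["da", "b"] <- lat["b", "da"] <- coef$c4
  lat["a", "b"] <- lat["b", "a"] <- -coef$c1 * coef$c3 - coef$c2 * coef$c4
  ev <- eigen(lat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("coupling targets imply a non-PSD covariance")
  out <- list(
    n_subjects = as.integer(n_subjects),
    runs_per_subject = as.integer(runs_per_subject),
    n_timepoints = as.integer(n_timepoints), tr = tr,
    coupling_targets = ct, within_subnetwork_corr = w,
    noise_sd = noise_sd, amplitude_sd = amplitude_sd,
    structural_motif_means = mm,
    structural_background_mean = structural_background_mean,
    behavior = behavior, seed = as.integer(seed),
    latent_coefficients = coef
  )
  class(out) <- c("cohort_spec", "list")
  out
}

# c1..c4 >= 0; signs of the targets are carried by the construction
# s_A = g (c1 s_DM - c2 s_DA) + sigma_a e_A,
# s_B = g (-c3 s_DM + c4 s_DA) + sigma_b e_B.
latent_coefficients_from_targets <- function(ct, w) {
  infl <- 1 / sqrt(w)
  c1 <- ct[["a_dm"]] * infl
  c2 <- -ct[["a_da"]] * infl
  c3 <- -ct[["b_dm"]] * infl
  c4 <- ct[["b_da"]] * infl
  if (any(c(c1, c2, c3, c4) < 0)) {
    stop("coupling target signs must be a_dm > 0, b_dm < 0, a_da < 0, ",
         "b_da > 0 (planted-world convention)")
  }
  sa2 <- 1 - c1^2 - c2^2
  sb2 <- 1 - c3^2 - c4^2
  if (sa2 <= 0 || sb2 <= 0) stop("coupling targets too large for unit-variance latents")
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4,
       sigma_a = sqrt(sa2), sigma_b = sqrt(sb2))
}

#' Construct a regional timeseries object
#' @param mat regions x timepoints numeric matrix.
#' @param subject_id,run_id identifiers.
#' @param tr repetition time in seconds.
#' @return object of class \code{regional_timeseries}.
#' @export
regional_timeseries <- function(mat, subject_id, run_id, tr = 0.72) {
  if (anyNA(mat)) stop("timeseries contains missing values")
  if (ncol(mat) < 2) stop("timeseries must have at least 2 timepoints")
  structure(list(mat = mat, subject_id = subject_id, run_id = run_id, tr = tr),
            class = "regional_timeseries")
}

#' Draw per-subject latent amplitude factors
#' @keywords internal
draw_amplitudes <- function(n, sd, floor = 0.1) {
  g <- rnorm(n, mean = 1, sd = sd)
  pmax(g, floor)
}

#' Generate cohort regional timeseries with planted coupling structure
#'
#' Each of the eight systems carries an i.i.d. standard-normal latent signal;
#' the two frontoparietal subnetwork latents are linear combinations of the
#' DM and DA latents with subject-amplitude-scaled coefficients (so coupling
#' grows with the subject's amplitude factor g), plus independent residual.
#' Regional signals are latent + independent Gaussian noise; subnetwork
#' regions are additionally scaled by g so that subnetwork RMS tracks g
#' without altering any correlation.
#'
#' @param spec a \code{cohort_spec}.
#' @param parc a \code{parcellation} with subnetwork labels.
#' @param coefficients optional override of the latent coefficients
#'   (list with c1..c4, sigma_a, sigma_b), for controlled experiments.
#' @return list with \code{timeseries} (list of \code{regional_timeseries})
#'   and \code{amplitudes} (data.frame subject, g_a, g_b).
#' @export
generate_cohort_timeseries <- function(spec, parc, coefficients = NULL) {
  if (all(is.na(parc$subnetwork))) stop("parcellation has no subnetwork labels")
  cf <- coefficients %||% spec$latent_coefficients
  nu <- spec$noise_sd
  tp <- spec$n_timepoints
  set.seed(derive_seed(spec$seed, "cohort_timeseries"))
  g_a <- draw_amplitudes(spec$n_subjects, spec$amplitude_sd)
  g_b <- draw_amplitudes(spec$n_subjects, spec$amplitude_sd)
  systems <- SYSTEM_NAMES
  sys_idx <- lapply(systems, function(s) which(parc$system == s))
  names(sys_idx) <- systems
  idx_a <- which(!is.na(parc$subnetwork) & parc$subnetwork == "A")
  idx_b <- which(!is.na(parc$subnetwork) & parc$subnetwork == "B")
  n_regions <- nrow(parc)
  out <- vector("list", spec$n_subjects * spec$runs_per_subject)
  k <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (r in seq_len(spec$runs_per_subject)) {
      lat <- matrix(rnorm(length(systems) * tp), nrow = length(systems),
                    dimnames = list(systems, NULL))
      s_dm <- lat["default-mode", ]
      s_da <- lat["dorsal-attention", ]
      s_a <- g_a[s] * (cf$c1 * s_dm - cf$c2 * s_da) + cf$sigma_a * rnorm(tp)
      s_b <- g_b[s] * (-cf$c3 * s_dm + cf$c4 * s_da) + cf$sigma_b * rnorm(tp)
      mat <- matrix(0, nrow = n_regions, ncol = tp)
      for (sys in systems) {
        idx <- sys_idx[[sys]]
        if (!length(idx)) next
        if (sys == "frontoparietal") next
        noise <- matrix(rnorm(length(idx) * tp, sd = nu), nrow = length(idx))
        mat[idx, ] <- rep(lat[sys, ], each = length(idx)) + noise
      }
      na <- length(idx_a)
      nb <- length(idx_b)
      mat[idx_a, ] <- g_a[s] *
        (rep(s_a, each = na) + matrix(rnorm(na * tp, sd = nu), nrow = na))
      mat[idx_b, ] <- g_b[s] *
        (rep(s_b, each = nb) + matrix(rnorm(nb * tp, sd = nu), nrow = nb))
      k <- k + 1L
      out[[k]] <- regional_timeseries(mat, subject_id = s, run_id = r,
                                      tr = spec$tr)
    }
  }
  list(timeseries = out,
       amplitudes = data.frame(subject = seq_len(spec$n_subjects),
                               g_a = g_a, g_b = g_b))
}

#' Write a generated cohort to a directory tree
#'
#' Timeseries and structural matrices as TSV plus a manifest JSON recording
#' the file layout, subject amplitudes and the generating seed.
#'
#' @param cohort result of \code{generate_cohort_timeseries}.
#' @param structural optional list of structural matrices (one per subject).
#' @param dir output directory (created if needed).
#' @param spec the generating \code{cohort_spec} (echoed in the manifest).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, structural = NULL, dir, spec = NULL) {
  dir.create(file.path(dir, "timeseries"), showWarnings = FALSE,
             recursive = TRUE)
  ts_files <- vapply(cohort$timeseries, function(ts) {
    f <- file.path("timeseries",
                   sprintf("sub-%03d_run-%d.tsv", ts$subject_id, ts$run_id))
    write.table(ts$mat, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    f
  }, character(1))
  st_files <- character(0)
  if (!is.null(structural)) {
    dir.create(file.path(dir, "structural"), showWarnings = FALSE)
    st_files <- vapply(seq_along(structural), function(s) {
      f <- file.path("structural", sprintf("sub-%03d.tsv", s))
      write_matrix(structural[[s]], file.path(dir, f))
      f
    }, character(1))
  }
  write.table(cohort$amplitudes, file.path(dir, "amplitudes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    timeseries = as.list(ts_files), structural = as.list(st_files),
    amplitudes = "amplitudes.tsv",
    n_subjects = nrow(cohort$amplitudes),
    seed = if (!is.null(spec)) spec$seed else NA
  )
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}

#' Read a cohort written by \code{write_cohort}
#' @param dir cohort directory containing manifest.json.
#' @param tr repetition time attached to the timeseries (seconds).
#' @return list with \code{timeseries}, \code{amplitudes},
#'   \code{structural} (possibly empty).
#' @export
read_cohort <- function(dir, tr = 0.72) {
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  ts <- lapply(manifest$timeseries, function(f) {
    m <- as.matrix(read.table(file.path(dir, f), sep = "\t"))
    dimnames(m) <- NULL
    info <- regmatches(f, regexec("sub-([0-9]+)_run-([0-9]+)", f))[[1]]
    regional_timeseries(m, subject_id = as.integer(info[2]),
                        run_id = as.integer(info[3]), tr = tr)
  })
  structural <- lapply(manifest$structural, function(f) {
    unname(read_matrix(file.path(dir, f)))
  })
  amp <- read.table(file.path(dir, "amplitudes.tsv"), header = TRUE,
                    sep = "\t")
  list(timeseries = ts, amplitudes = amp, structural = structural)
}

#' Generate per-subject structural networks with a planted block motif
#'
#' Edges are symmetric, nonnegative gamma draws with zero diagonal. The four
#' motif blocks (A-DM, B-DM, A-DA, B-DA) receive the configured means; all
#' other edges share a small background mean. Each subject receives an
#' independent realization (per-subject noise).
#'
#' @param spec a \code{cohort_spec}.
#' @param parc a \code{parcellation} with subnetwork labels.
#' @param shape gamma shape parameter (default 4, coefficient of variation 0.5).
#' @return list of N x N matrices, one per subject.
#' @export
generate_structural_network <- function(spec, parc, shape = 4) {
  n <- nrow(parc)
  mm <- spec$structural_motif_means
  bg <- spec$structural_background_mean
  idx_a <- which(!is.na(parc$subnetwork) & parc$subnetwork == "A")
  idx_b <- which(!is.na(parc$subnetwork) & parc$subnetwork == "B")
  idx_dm <- which(parc$system == "default-mode")
  idx_da <- which(parc$system == "dorsal-attention")
  mean_mat <- matrix(bg, n, n)
  mean_mat[idx_a, idx_dm] <- mm[["a_dm"]]; mean_mat[idx_dm, idx_a] <- mm[["a_dm"]]
  mean_mat[idx_b, idx_dm] <- mm[["b_dm"]]; mean_mat[idx_dm, idx_b] <- mm[["b_dm"]]
  mean_mat[idx_a, idx_da] <- mm[["a_da"]]; mean_mat[idx_da, idx_a] <- mm[["a_da"]]
  mean_mat[idx_b, idx_da] <- mm[["b_da"]]; mean_mat[idx_da, idx_b] <- mm[["b_da"]]
  diag(mean_mat) <- 0
  ut <- upper.tri(mean_mat)
  mu <- mean_mat[ut]
  set.seed(derive_seed(spec$seed, "structural"))
  lapply(seq_len(spec$n_subjects), function(s) {
    w <- numeric(length(mu))
    pos <- mu > 0
    w[pos] <- rgamma(sum(pos), shape = shape, scale = mu[pos] / shape)
    m <- matrix(0, n, n)
    m[ut] <- w
    m + t(m)
  })
}

#' Generate a probe-level gene expression table with planted subnetwork
#' coexpression structure
#'
#' Expression is generated for every parcel in the parcellation. Each gene
#' has a shared baseline (removed downstream by probe centering across
#' parcels), every frontoparietal parcel loads on a common FP gene profile
#' (coefficient \code{fp_common}) so that FP parcel pairs keep a positive
#' coexpression baseline after centering, and each subnetwork additionally
#' loads on its own latent profile scaled by \code{margin}. Probes add a
#' per-probe offset (removed by probe centering) and measurement noise.
#'
#' @param spec a \code{cohort_spec} (supplies the seed).
#' @param parc a \code{parcellation} with subnetwork labels.
#' @param n_genes number of genes (default 2000; paper scale 16699).
#' @param probes_per_gene probes per gene (>= 1).
#' @param margin planted within-subnetwork coexpression margin (0 = no
#'   effect; default 0.3).
#' @param fp_common loading of the frontoparietal-wide profile shared by
#'   both subnetworks (default 0.4).
#' @param parcel_noise_sd SD of the parcel-by-gene residual (default 0.5).
#' @param probe_noise_sd SD of probe-level measurement noise (default 0.1).
#' @param parcel_ids optional explicit parcel set (indices into parc;
#'   default: all parcels).
#' @return data.frame with columns parcel, gene, probe, value, plus a
#'   \code{subnet_labels} attribute naming each parcel's subnetwork (NA for
#'   non-frontoparietal parcels).
#' @export
generate_gene_expression <- function(spec, parc, n_genes = 2000L,
                                     probes_per_gene = 3L, margin = 0.3,
                                     fp_common = 0.4,
                                     parcel_noise_sd = 0.5,
                                     probe_noise_sd = 0.1,
                                     parcel_ids = NULL) {
  if (n_genes < 2) stop("n_genes must be at least 2")
  if (probes_per_gene < 1) stop("probes_per_gene must be at least 1")
  if (is.null(parcel_ids)) {
    parcel_ids <- seq_len(nrow(parc))
  }
  labels <- parc$subnetwork[parcel_ids]
  np <- length(parcel_ids)
  set.seed(derive_seed(spec$seed, "gene_expression"))
  mu_g <- rnorm(n_genes)                       # shared gene baseline
  lat_fp <- rnorm(n_genes)                     # FP-wide profile
  lat_a <- rnorm(n_genes)                      # subnetwork latent profiles
  lat_b <- rnorm(n_genes)
  value_pg <- matrix(rnorm(np * n_genes, sd = parcel_noise_sd),
                     nrow = np, ncol = n_genes)
  value_pg <- sweep(value_pg, 2, mu_g, `+`)
  is_a <- !is.na(labels) & labels == "A"
  is_b <- !is.na(labels) & labels == "B"
  is_fp <- is_a | is_b
  if (any(is_fp)) value_pg[is_fp, ] <- sweep(value_pg[is_fp, , drop = FALSE],
                                             2, fp_common * lat_fp, `+`)
  if (any(is_a)) value_pg[is_a, ] <- sweep(value_pg[is_a, , drop = FALSE],
                                           2, margin * lat_a, `+`)
  if (any(is_b)) value_pg[is_b, ] <- sweep(value_pg[is_b, , drop = FALSE],
                                           2, margin * lat_b, `+`)
  probe_offset <- matrix(rnorm(n_genes * probes_per_gene, sd = 0.5),
                         nrow = n_genes)
  n_rows <- np * n_genes * probes_per_gene
  parcel <- rep(parcel_ids, times = n_genes * probes_per_gene)
  gene <- rep(rep(seq_len(n_genes), each = np), times = probes_per_gene)
  probe <- rep(seq_len(probes_per_gene), each = np * n_genes)
  value <- as.numeric(value_pg)[rep(seq_len(np * n_genes), probes_per_gene)] +
    probe_offset[cbind(gene, probe)] +
    rnorm(n_rows, sd = probe_noise_sd)
  out <- data.frame(parcel = parcel, gene = gene, probe = probe, value = value)
  attr(out, "subnet_labels") <- setNames(labels, parcel_ids)
  out
}

#' Generate behavioral scores from latent amplitudes and coupling
#'
#' score = intercept - beta_a * g_A + beta_b * g_B - beta_fc * FC(FP, DM)
#' + subject random intercept + noise, clipped to [0, 1] (accuracy-like).
#'
#' @param runs data.frame with columns subject, run, g_a, g_b, fc_fp_dm
#'   (one row per scan, aligned).
#' @param spec a \code{cohort_spec} (behavior parameters and seed).
#' @return the input data.frame with a \code{score} column appended.
#' @export
generate_behavior <- function(runs, spec) {
  need <- c("subject", "run", "g_a", "g_b", "fc_fp_dm")
  if (!all(need %in% names(runs))) {
    stop("runs must have columns ", paste(need, collapse = ", "))
  }
  if (anyNA(runs[need])) stop("behavior inputs contain missing values")
  b <- spec$behavior
  set.seed(derive_seed(spec$seed, "behavior"))
  subj <- sort(unique(runs$subject))
  u <- setNames(rnorm(length(subj), sd = b$subject_sd), subj)
  score <- b$intercept - b$beta_a * runs$g_a + b$beta_b * runs$g_b -
    b$beta_fc * runs$fc_fp_dm + u[as.character(runs$subject)] +
    rnorm(nrow(runs), sd = b$noise_sd)
  runs$score <- pmin(1, pmax(0, score))
  runs
}
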