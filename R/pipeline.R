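#' Run the full synthetic study
#'
#' End-to-end orchestration on a synthetic cohort: cohort generation,
#' functional/structural network construction, subnetwork coupling and RMS
#' summaries, multilevel sign checks, WSBM partitioning with consensus and
#' nulls, boundary control with enrichment, gene-coexpression testing, and
#' the Hopf amplitude experiments. Stage seeds are derived deterministically
#' from the master seed, so identical config implies an identical report.
#'
#' @param config an \code{analysis_config} (see \code{default_config}); a
#'   plain list of overrides is accepted.
#' @return object of class \code{study_report}.
#' @export
run_study <- function(config = as_analysis_config()) {
  if (!inherits(config, "analysis_config")) {
    config <- as_analysis_config(config)
  }
  t_start <- Sys.time()
  stage_log <- function(stage, t0) {
    message(sprintf("[subnetdyn] %-12s seed=%d elapsed=%.1fs", stage,
                    derive_seed(config$seed, stage),
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  message("[subnetdyn] study started, master seed = ", config$seed)
  cc <- config$cohort
  parc <- synthetic_parcellation(cc$parcellation_scale)
  spec <- cohort_spec(
    n_subjects = cc$n_subjects, runs_per_subject = cc$runs_per_subject,
    n_timepoints = cc$n_timepoints, tr = cc$tr,
    coupling_targets = cc$coupling_targets,
    within_subnetwork_corr = cc$within_subnetwork_corr,
    amplitude_sd = cc$amplitude_sd,
    structural_motif_means = cc$structural_motif_means,
    structural_background_mean = cc$structural_background_mean,
    behavior = as.list(cc$behavior), seed = config$seed
  )

  # --- cohort generation + run-level summaries -----------------------------
  t0 <- Sys.time()
  cohort <- generate_cohort_timeseries(spec, parc)
  runs <- run_level_summaries(cohort, parc)
  runs <- generate_behavior(
    merge(runs, cohort$amplitudes, by = "subject", sort = FALSE), spec)
  structural <- generate_structural_network(spec, parc)
  stage_log("cohort", t0)

  # --- multilevel sign checks ----------------------------------------------
  t0 <- Sys.time()
  checks <- sign_checks(runs, structural, parc)
  stage_log("sign_checks", t0)

  # --- WSBM stage ----------------------------------------------------------
  wsbm <- NULL
  if (isTRUE(config$stages$wsbm)) {
    t0 <- Sys.time()
    wsbm <- wsbm_stage(cohort$timeseries, parc, config)
    stage_log("wsbm", t0)
  }

  # --- boundary control stage ----------------------------------------------
  boundary <- NULL
  if (isTRUE(config$stages$boundary)) {
    t0 <- Sys.time()
    cs_mean <- normalize_structural(Reduce(`+`, structural) / length(structural))
    bcfg <- config$boundary
    bc <- boundary_control(cs_mean, parc, bcfg$system_j, bcfg$system_l)
    top <- top_percentile_regions(bc, bcfg$pct)
    enr <- enrichment_test(top, "frontoparietal", parc, n_perm = bcfg$n_perm,
                           seed = derive_seed(config$seed, "enrichment"))
    boundary <- list(bc = bc, top_regions = top,
                     observed = enr$observed, p_perm = enr$p_perm,
                     p_exact = enr$p_exact)
    stage_log("boundary", t0)
  }

  # --- gene coexpression stage ---------------------------------------------
  genes <- NULL
  if (isTRUE(config$stages$genes)) {
    t0 <- Sys.time()
    gcfg <- config$genes
    probes <- generate_gene_expression(
      spec, parc, n_genes = gcfg$n_genes,
      probes_per_gene = gcfg$probes_per_gene, margin = gcfg$margin)
    agg <- aggregate_probes(probes)
    labels <- attr(probes, "subnet_labels")[rownames(agg$expr)]
    fp <- !is.na(labels)
    genes <- coexpression_bootstrap_test(
      agg$expr[fp, , drop = FALSE], labels[fp], n_boot = gcfg$n_boot,
      n_perm = gcfg$n_perm, seed = derive_seed(config$seed, "coexpression"))
    stage_log("coexpression", t0)
  }

  # --- Hopf dynamical model stage ------------------------------------------
  hopf <- NULL
  if (isTRUE(config$stages$hopf)) {
    t0 <- Sys.time()
    hopf <- hopf_stage(config)
    stage_log("hopf", t0)
  }

  message(sprintf("[subnetdyn] study finished in %.1fs",
                  as.numeric(difftime(Sys.time(), t_start, units = "secs"))))
  genes_summary <- if (is.null(genes)) NULL else {
    list(p_a = genes$p_a, p_b = genes$p_b, observed = as.list(genes$observed))
  }
  structure(list(
    config = unclass(config), seed = config$seed,
    version = as.character(utils::packageVersion("subnetdyn")),
    runs = runs, sign_checks = checks, wsbm = wsbm, boundary = boundary,
    genes = genes_summary, hopf = hopf
  ), class = "study_report")
}

# per-run couplings and subnetwork RMS
run_level_summaries <- function(cohort, parc) {
  rows <- lapply(cohort$timeseries, function(ts) {
    cf <- compute_functional_network(ts)
    idx_fp <- regions_of(parc, "frontoparietal")
    idx_dm <- regions_of(parc, "default-mode")
    data.frame(
      subject = ts$subject_id, run = ts$run_id,
      coupling_a_dm = subnetwork_system_coupling(cf, parc, "A", "default-mode"),
      coupling_b_dm = subnetwork_system_coupling(cf, parc, "B", "default-mode"),
      coupling_a_da = subnetwork_system_coupling(cf, parc, "A", "dorsal-attention"),
      coupling_b_da = subnetwork_system_coupling(cf, parc, "B", "dorsal-attention"),
      fc_fp_dm = mean(cf[idx_fp, idx_dm]),
      fc_fp_da = mean(cf[idx_fp, regions_of(parc, "dorsal-attention")]),
      rms_a = subnetwork_rms(ts, parc, "A"),
      rms_b = subnetwork_rms(ts, parc, "B")
    )
  })
  do.call(rbind, rows)
}

# the ten planted sign checks, each with an estimate, a p-value, the
# expected sign, and pass flags
sign_checks <- function(runs, structural, parc) {
  res <- list()
  add <- function(name, estimate, p, expected_sign) {
    res[[length(res) + 1]] <<- data.frame(
      check = name, estimate = estimate, p = p,
      expected_sign = expected_sign,
      pass_sign = sign(estimate) == expected_sign
    )
  }
  # 1-4: mean subnetwork-system couplings (intercept-only multilevel model)
  for (nm in c("coupling_a_dm", "coupling_b_dm", "coupling_a_da",
               "coupling_b_da")) {
    f <- fit_random_intercept_model(runs[[nm]], NULL, runs$subject)
    expected <- if (nm %in% c("coupling_a_dm", "coupling_b_da")) 1 else -1
    add(nm, f$coefficients["(Intercept)", "estimate"],
        f$coefficients["(Intercept)", "p"], expected)
  }
  # 5-6: FP-DM coupling explained by subnetwork RMS (robust multilevel)
  f <- fit_random_intercept_model(runs$fc_fp_dm,
                                  runs[, c("rms_a", "rms_b")],
                                  runs$subject, robust = TRUE)
  add("slope_rms_a_fc_fp_dm", f$coefficients["rms_a", "estimate"],
      f$coefficients["rms_a", "p"], 1)
  add("slope_rms_b_fc_fp_dm", f$coefficients["rms_b", "estimate"],
      f$coefficients["rms_b", "p"], -1)
  # 7-8: behavior explained by subnetwork RMS (robust multilevel)
  f <- fit_random_intercept_model(runs$score, runs[, c("rms_a", "rms_b")],
                                  runs$subject, robust = TRUE)
  add("slope_rms_a_behavior", f$coefficients["rms_a", "estimate"],
      f$coefficients["rms_a", "p"], -1)
  add("slope_rms_b_behavior", f$coefficients["rms_b", "estimate"],
      f$coefficients["rms_b", "p"], 1)
  # 9: FC-behavior association with subnetwork-A RMS covaried
  f <- fit_random_intercept_model(runs$score,
                                  runs[, c("rms_a", "fc_fp_dm")],
                                  runs$subject, robust = TRUE)
  add("slope_fc_fp_dm_behavior", f$coefficients["fc_fp_dm", "estimate"],
      f$coefficients["fc_fp_dm", "p"], -1)
  # 10: structural motif contrasts (A-DM vs B-DM and B-DA vs A-DA), tested
  # jointly via stacked multilevel contrasts across subjects
  blocks <- lapply(structural, function(cs) {
    g <- system_groups(parc, "subnetworks")
    m <- group_mean_matrix(cs, g)
    c(a_dm = m["frontoparietal-A", "default-mode"],
      b_dm = m["frontoparietal-B", "default-mode"],
      a_da = m["frontoparietal-A", "dorsal-attention"],
      b_da = m["frontoparietal-B", "dorsal-attention"])
  })
  bm <- do.call(rbind, blocks)
  ns <- nrow(bm)
  f_dm <- fit_random_intercept_model(
    c(bm[, "a_dm"], bm[, "b_dm"]),
    matrix(rep(c(0, 1), each = ns), ncol = 1,
           dimnames = list(NULL, "is_b")),
    rep(seq_len(ns), 2))
  f_da <- fit_random_intercept_model(
    c(bm[, "a_da"], bm[, "b_da"]),
    matrix(rep(c(0, 1), each = ns), ncol = 1,
           dimnames = list(NULL, "is_b")),
    rep(seq_len(ns), 2))
  est <- min(-f_dm$coefficients["is_b", "estimate"],
             f_da$coefficients["is_b", "estimate"])
  add("structural_motif",
      est,
      max(f_dm$coefficients["is_b", "p"], f_da$coefficients["is_b", "p"]),
      1)
  out <- do.call(rbind, res)
  out$p_adj <- bonferroni(out$p, nrow(out))
  out$significant <- out$p_adj < 0.05
  out$pass <- out$pass_sign
  rownames(out) <- NULL
  out
}

wsbm_stage <- function(timeseries, parc, config) {
  wc <- config$wsbm
  idx_fp <- regions_of(parc, "frontoparietal")
  subj_ids <- vapply(timeseries, function(ts) ts$subject_id, numeric(1))
  c_sub_list <- lapply(sort(unique(subj_ids)), function(s) {
    mats <- lapply(timeseries[subj_ids == s], function(ts) {
      cf <- compute_functional_network(ts)
      cf[idx_fp, idx_fp]
    })
    m <- Reduce(`+`, mats) / length(mats)
    diag(m) <- 0
    m
  })
  fits <- lapply(seq_along(c_sub_list), function(s) {
    fit_wsbm(c_sub_list[[s]], wc$k, restarts = wc$restarts,
             seed = derive_seed(config$seed, "wsbm", s),
             variance_floor = wc$variance_floor,
             max_sweeps = wc$max_sweeps)
  })
  cons <- consensus_partition(lapply(fits, `[[`, "z"))
  null <- partition_permutation_null(
    c_sub_list, cons$consensus,
    seed = derive_seed(config$seed, "wsbm_null"),
    variance_floor = wc$variance_floor)
  contrast <- fit_random_intercept_model(
    c(null$loglik_true, null$loglik_perm),
    matrix(rep(c(0, 1), each = nrow(null)), ncol = 1,
           dimnames = list(NULL, "is_null")),
    rep(null$subject, 2))
  ks <- compare_k(c_sub_list, k_values = c(1, 3), n_boot = wc$n_boot,
                  seed = derive_seed(config$seed, "compare_k"),
                  restarts = max(5L, wc$restarts %/% 2L))
  # ground-truth agreement (the generator plants the A/B split)
  truth <- as.integer(factor(parc$subnetwork[idx_fp], levels = c("A", "B")))
  list(consensus = cons$consensus, consensus_subject = cons$index,
       zrand_to_truth = zrand(cons$consensus, truth),
       null_contrast_beta = contrast$coefficients["is_null", "estimate"],
       null_contrast_p = contrast$coefficients["is_null", "p"],
       compare_k_tail = ks$tail)
}

hopf_stage <- function(config) {
  hc <- config$hopf
  d_group <- motif_coupling_matrix(config$cohort$structural_motif_means)
  base <- build_grouped_config(
    "4", d_group = d_group,
    config_args = list(a = hc$a, g = hc$g, xi = hc$xi, dt = hc$dt,
                       duration = hc$duration, transient = hc$transient,
                       freq_mean_hz = hc$freq_mean_hz,
                       freq_sd_hz = hc$freq_sd_hz,
                       seed = derive_seed(config$seed, "hopf")))
  a_values <- seq(-0.15, 0.1, length.out = hc$n_runs)
  assoc <- function(tab) {
    ct <- stats::cor.test(tab$a_target, tab$r_fp_dm)
    list(r = unname(ct$estimate), p = ct$p.value)
  }
  exp_a <- amplitude_experiment(base, "SN-A", a_values,
                                seed = derive_seed(config$seed, "hopf_a"))
  exp_b <- amplitude_experiment(base, "SN-B", a_values,
                                seed = derive_seed(config$seed, "hopf_b"))
  abl <- ablate_coupling(base)
  a_abl <- seq(-0.15, 0.1, length.out = hc$n_ablation_runs)
  exp_0 <- amplitude_experiment(abl, "SN-A", a_abl,
                                seed = derive_seed(config$seed, "hopf_abl"))
  census <- anticorrelation_census(base, n_runs = hc$n_ablation_runs,
                                   seed = derive_seed(config$seed, "hopf_census"))
  list(sn_a = assoc(exp_a), sn_b = assoc(exp_b), ablation = assoc(exp_0),
       anticorrelation = census[c("count", "n_runs", "p")])
}

#' Write a study report to JSON
#' @param report a \code{study_report}.
#' @param path output file path.
#' @export
write_study_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  out <- report
  out$boundary$bc <- NULL   # per-region table is written separately if needed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Configuration with all planted effects removed
#'
#' Zero coupling targets, exchangeable structural blocks, no behavior
#' effects and no coexpression margin: the null world used to calibrate the
#' pipeline's family-wise error rate.
#'
#' @param config base config (default \code{default_config()}).
#' @return an \code{analysis_config}.
#' @export
null_effects_config <- function(config = as_analysis_config()) {
  if (!inherits(config, "analysis_config")) config <- as_analysis_config(config)
  config$cohort$coupling_targets[] <- 0
  config$cohort$structural_motif_means[] <-
    config$cohort$structural_background_mean
  config$cohort$behavior$beta_a <- 0
  config$cohort$behavior$beta_b <- 0
  config$cohort$behavior$beta_fc <- 0
  config$genes$margin <- 0
  config
}
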