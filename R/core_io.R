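#' @useDynLib subnetdyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor sd rnorm runif rgamma qnorm qt pt pf var optimize
#'   phyper dnorm median quantile fft setNames aggregate pnorm
#' @importFrom utils read.table write.table modifyList
NULL

# Canonical cortical system names (eight-system reduction of a 17-system
# functional atlas).
SYSTEM_NAMES <- c(
  "visual", "somatomotor", "dorsal-attention", "ventral-attention",
  "limbic", "frontoparietal", "default-mode", "temporoparietal"
)

#' Construct a parcellation
#'
#' A parcellation assigns each cortical region to exactly one of eight
#' functional systems, and optionally assigns frontoparietal regions to one
#' of two subnetworks ("A"/"B").
#'
#' @param region_id integer vector of region labels (1..N, unique).
#' @param system character vector of system names, one per region.
#' @param subnetwork optional character vector ("A"/"B"/NA); labels are only
#'   permitted on frontoparietal regions.
#' @return An object of class \code{parcellation} (a data frame with columns
#'   \code{region_id}, \code{system}, \code{subnetwork}).
#' @export
parcellation <- function(region_id, system, subnetwork = NULL) {
  region_id <- as.integer(region_id)
  if (anyDuplicated(region_id)) {
    stop("duplicate region ids: ",
         paste(unique(region_id[duplicated(region_id)]), collapse = ", "))
  }
  if (length(system) != length(region_id)) {
    stop("system must have one entry per region")
  }
  system <- as.character(system)
  bad <- setdiff(unique(system), SYSTEM_NAMES)
  if (length(bad)) {
    stop("unknown system name(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(subnetwork)) {
    subnetwork <- rep(NA_character_, length(region_id))
  } else {
    subnetwork <- as.character(subnetwork)
    subnetwork[!is.na(subnetwork) & subnetwork == ""] <- NA_character_
    if (length(subnetwork) != length(region_id)) {
      stop("subnetwork must have one entry per region")
    }
    lab <- !is.na(subnetwork)
    if (any(lab & system != "frontoparietal")) {
      stop("subnetwork label on non-frontoparietal region: ",
           paste(region_id[lab & system != "frontoparietal"], collapse = ", "))
    }
    if (!all(subnetwork[lab] %in% c("A", "B"))) {
      stop("subnetwork labels must be 'A' or 'B'")
    }
  }
  out <- data.frame(
    region_id = region_id, system = system, subnetwork = subnetwork,
    stringsAsFactors = FALSE
  )
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Read a parcellation lookup table
#'
#' Expects delimited text (tab by default) with columns \code{region_id},
#' \code{system} and optionally \code{subnetwork}.
#'
#' @param path file path.
#' @param sep field separator.
#' @return a \code{parcellation}.
#' @export
read_parcellation <- function(path, sep = "\t") {
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("region_id", "system")
  if (!all(need %in% names(tab))) {
    stop("parcellation table must have columns region_id and system")
  }
  parcellation(tab$region_id, tab$system,
               if ("subnetwork" %in% names(tab)) tab$subnetwork else NULL)
}

#' Write a parcellation lookup table
#' @param parc a \code{parcellation}.
#' @param path output file path.
#' @export
write_parcellation <- function(parc, path) {
  tab <- as.data.frame(parc)
  tab$subnetwork[is.na(tab$subnetwork)] <- ""
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default synthetic parcellations
#'
#' The full scale mirrors a 400-region cortical atlas: 61 frontoparietal
#' regions split 30/31 into subnetworks A and B, 79 default-mode regions and
#' 52 dorsal-attention regions, with the remaining 208 regions spread over
#' the other five systems. The small scale keeps the same system structure at
#' roughly a quarter of the size for fast simulation studies.
#'
#' @param scale \code{"full"} (400 regions) or \code{"small"} (104 regions).
#' @return a \code{parcellation}.
#' @export
synthetic_parcellation <- function(scale = c("full", "small")) {
  scale <- match.arg(scale)
  sizes <- if (scale == "full") {
    c(visual = 58, somatomotor = 68, `dorsal-attention` = 52,
      `ventral-attention` = 45, limbic = 24, frontoparietal = 61,
      `default-mode` = 79, temporoparietal = 13)
  } else {
    c(visual = 15, somatomotor = 17, `dorsal-attention` = 14,
      `ventral-attention` = 12, limbic = 6, frontoparietal = 16,
      `default-mode` = 20, temporoparietal = 4)
  }
  system <- rep(names(sizes), sizes)
  n <- sum(sizes)
  subnetwork <- rep(NA_character_, n)
  fp <- which(system == "frontoparietal")
  n_a <- floor(length(fp) / 2)          # 30 of 61 at full scale
  subnetwork[fp[seq_len(n_a)]] <- "A"
  subnetwork[fp[(n_a + 1):length(fp)]] <- "B"
  parcellation(seq_len(n), system, subnetwork)
}

#' Regions belonging to a system or subnetwork
#'
#' @param parc a \code{parcellation}.
#' @param system a system name, or \code{"frontoparietal"} with
#'   \code{subnetwork} to select one subnetwork.
#' @param subnetwork optional "A" or "B".
#' @return integer vector of row indices (0-based files are converted at I/O;
#'   all in-memory indices are 1-based R indices).
#' @export
regions_of <- function(parc, system, subnetwork = NULL) {
  idx <- which(parc$system == system)
  if (!is.null(subnetwork)) {
    idx <- which(parc$system == "frontoparietal" &
                   !is.na(parc$subnetwork) & parc$subnetwork == subnetwork)
  }
  if (!length(idx)) stop("empty region set for ", system,
                         if (!is.null(subnetwork)) paste0("/", subnetwork))
  idx
}

#' Write a square matrix as tab-delimited text
#'
#' The canonical on-disk matrix format: a header row of region ids, one row
#' per region with the region id in the first column. Values are written with
#' 17 significant digits so that read(write(M)) reproduces M exactly.
#'
#' @param m square numeric matrix.
#' @param path output file path.
#' @param ids optional region ids (default 1..N).
#' @export
write_matrix <- function(m, path, ids = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  n <- nrow(m)
  if (is.null(ids)) ids <- seq_len(n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("region_id", ids), collapse = "\t"), con)
  body <- vapply(seq_len(n), function(i) {
    paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a square matrix written by \code{write_matrix}
#'
#' Also accepts a bare N x N table without header/id column.
#'
#' @param path file path.
#' @return numeric matrix with region ids as dimnames when present.
#' @export
read_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^region_id", first)
  tab <- read.table(path, header = has_header, sep = "\t",
                    check.names = FALSE)
  if (has_header) {
    ids <- tab[[1]]
    tab <- tab[, -1, drop = FALSE]
  } else {
    ids <- seq_len(nrow(tab))
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric cells in matrix file")
  if (nrow(m) != ncol(m)) {
    stop("matrix file is not square: ", nrow(m), " x ", ncol(m))
  }
  dimnames(m) <- list(ids, ids)
  m
}

# ---- configuration -------------------------------------------------------

#' Default analysis configuration
#'
#' Every stage parameter of the pipeline with its documented default. Units:
#' TR in seconds, Hopf durations in seconds, frequencies in Hz.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    paths = list(out = "results"),
    stages = list(wsbm = TRUE, boundary = TRUE, genes = TRUE, hopf = TRUE),
    cohort = list(
      parcellation_scale = "full",
      n_subjects = 50L, runs_per_subject = 2L, n_timepoints = 405L,
      tr = 0.72,
      coupling_targets = c(a_dm = 0.042, b_dm = -0.082,
                           a_da = -0.014, b_da = 0.12),
      within_subnetwork_corr = 0.9,
      amplitude_sd = 0.3,
      structural_motif_means = c(a_dm = 2.07, b_dm = 0.676,
                                 a_da = 1.03, b_da = 1.54),
      structural_background_mean = 0.3,
      behavior = list(intercept = 0.8, beta_a = 0.05, beta_b = 0.05,
                      beta_fc = 1.0, subject_sd = 0.02, noise_sd = 0.02)
    ),
    wsbm = list(k = 2L, restarts = 20L, max_sweeps = 500L,
                variance_floor = 1e-6, n_boot = 1000L),
    boundary = list(system_j = "default-mode", system_l = "dorsal-attention",
                    pct = 95, n_perm = 10000L),
    genes = list(n_genes = 2000L, probes_per_gene = 3L, margin = 0.3,
                 probe_noise_sd = 0.5, n_boot = 1000L, n_perm = 200L),
    hopf = list(a = -0.075, g = 0.1, xi = 0.02, dt = 0.01, duration = 360,
                transient = 20, freq_mean_hz = 0.04, freq_sd_hz = 0.01,
                n_runs = 100L, n_ablation_runs = 200L),
    stats = list(n_perm = 10000L)
  )
}

merge_config <- function(defaults, user, path = "") {
  if (!is.list(user)) stop("config section '", path, "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste0(path, unknown), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]],
                                    as.list(user[[k]]),
                                    paste0(path, k, "."))
    } else {
      v <- user[[k]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(defaults[[k]])) && is.numeric(defaults[[k]])) {
        names(v) <- names(v) %||% names(defaults[[k]])
      }
      defaults[[k]] <- v
    }
  }
  defaults
}

`%||%` <- function(a, b) if (is.null(a) || all(!nzchar(a))) b else a

#' Load an analysis configuration from JSON or YAML
#'
#' Absent keys are filled from \code{default_config()}; unknown keys are
#' rejected (typo protection). The master \code{seed} must be an integer.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @return validated nested list with class \code{analysis_config}.
#' @export
load_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stop("config must be a .json or .yaml/.yml file")
  }
  as_analysis_config(raw)
}

#' Validate a configuration list
#' @param raw nested list of overrides (may be empty).
#' @return validated nested list with class \code{analysis_config}.
#' @export
as_analysis_config <- function(raw = list()) {
  cfg <- merge_config(default_config(), raw)
  if (length(cfg$seed) != 1 || is.na(cfg$seed) ||
      cfg$seed != as.integer(cfg$seed)) {
    stop("seed must be a single integer")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("analysis_config", "list")
  cfg
}

#' Derive a per-stage seed from the master seed
#'
#' Documented counter scheme: each named stage has a fixed code (a polynomial
#' hash of its name); the stage seed is
#' \code{(master * 48271 + code + index) mod (2^31 - 1)}, so any stage can be
#' re-run in isolation with a reproducible seed.
#'
#' @param master master integer seed.
#' @param stage stage name (character).
#' @param index optional sub-index (e.g. subject number).
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, stage, index = 0L) {
  code <- 0
  for (ch in utf8ToInt(stage)) code <- (code * 31 + ch) %% 1000003
  s <- ((as.numeric(master) %% 2147483647) * 48271 + code +
          as.numeric(index)) %% 2147483646
  as.integer(s) + 1L
}
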