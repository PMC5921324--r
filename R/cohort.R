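# Synthetic two-group cohort generator.
#
# Emulates a diffusion-kurtosis regional-metric study of 21 patients vs 19
# controls over 90 atlas regions: grey-matter tables whose across-subject
# correlation structure follows a known small-world latent network,
# subject-level white-matter connectivity matrices, and covariates whose
# cognitive scores are tied to a per-subject network-integrity factor.

GM_METRICS <- c("MK", "AK", "RK", "KFA", "MD", "FA", "Ad", "RD")
WM_METRICS <- c("FN", "length", GM_METRICS)

# Conventional scales for positive-valued diffusion/kurtosis metrics (the
# median of the generated log-normal distribution). Config-exposed.
METRIC_SCALES <- c(
  MK = 0.9, AK = 0.7, RK = 1.2, KFA = 0.3,
  MD = 0.9, FA = 0.35, Ad = 1.2, RD = 0.7,
  FN = 30, length = 60
)

#' Configuration for a synthetic two-group cohort
#'
#' Holds the cohort sizes, effect dials and observation-noise scales used by
#' [generate_gm_cohort()], [generate_wm_cohort()] and
#' [generate_covariates()]. The same config plus the same seed regenerates
#' byte-identical outputs.
#'
#' @param n_patients,n_controls group sizes (defaults 21 and 19).
#' @param n_regions number of atlas regions (default 90).
#' @param metrics character vector of metric names to generate.
#' @param seed master integer seed; every sub-generator derives a
#'   deterministic child seed from it.
#' @param gm_effect clustering-attenuation fraction in `[0, 1]` applied to
#'   the patient-group target correlation structure (within-cluster edge
#'   correlations are scaled by `1 - gm_effect`).
#' @param wm_effect edge-weight attenuation and edge-rewiring fraction in
#'   `[0, 1]` for patient white-matter connectivity matrices.
#' @param noise_sd observation noise SD on the log scale.
#' @param cognition_link slope tying MMSE/MoCA to the subject-level
#'   network-integrity latent factor (points of MMSE per unit of the
#'   integrity factor).
#' @param alpha latent edge-coupling strength used to build the target
#'   correlation matrix (see [cohort_ground_truth()]).
#' @param tau signal SD on the log scale (correlated component).
#' @param false_edge_rate rate of spurious tractography edges in FN
#'   matrices.
#' @param metric_scales named numeric vector of typical metric values.
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_patients
#' @export
cohort_config <- function(n_patients = 21, n_controls = 19, n_regions = 90,
                          metrics = GM_METRICS, seed = 1,
                          gm_effect = 0.5, wm_effect = 0.3,
                          noise_sd = 0.05, cognition_link = 12,
                          alpha = 0.5, tau = 0.2,
                          false_edge_rate = 0.005,
                          metric_scales = METRIC_SCALES) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), metrics = metrics,
    seed = as.integer(seed), gm_effect = gm_effect, wm_effect = wm_effect,
    noise_sd = noise_sd, cognition_link = cognition_link,
    alpha = alpha, tau = tau, false_edge_rate = false_edge_rate,
    metric_scales = metric_scales
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 1 || cfg$n_controls < 1 || cfg$n_regions < 2)
    stop("cohort counts must be positive (and n_regions >= 2)")
  for (f in c("gm_effect", "wm_effect", "false_edge_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("%s must lie in [0, 1]", f))
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  bad <- setdiff(cfg$metrics, names(cfg$metric_scales))
  if (length(bad))
    stop("no scale configured for metric(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d patients / %d controls, %d regions, seed %d\n",
    x$n_patients, x$n_controls, x$n_regions, x$seed))
  cat(sprintf("  gm_effect %.2f  wm_effect %.2f  noise_sd %.3f  cognition_link %.1f\n",
              x$gm_effect, x$wm_effect, x$noise_sd, x$cognition_link))
  cat("  metrics:", paste(x$metrics, collapse = ", "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Latent ground truth

# Ring lattice adjacency on n nodes with the given strides.
ring_lattice <- function(n, strides) {
  A <- matrix(0L, n, n)
  for (s in strides) for (i in seq_len(n)) {
    j <- ((i - 1 + s) %% n) + 1
    A[i, j] <- A[j, i] <- 1L
  }
  A
}

# Watts-Strogatz style graph: ring lattice strides 1..k/2, each edge's far
# endpoint rewired to a uniform random node with probability p. Returns the
# adjacency; edge count is preserved.
watts_strogatz_adj <- function(n, strides = 1:3, p = 0.1) {
  A <- ring_lattice(n, strides)
  for (s in strides) for (i in seq_len(n)) {
    j <- ((i - 1 + s) %% n) + 1
    if (A[i, j] == 1L && stats::runif(1) < p) {
      for (try in 1:50) {
        jn <- sample.int(n, 1)
        if (jn != i && A[i, jn] == 0L) {
          A[i, j] <- A[j, i] <- 0L
          A[i, jn] <- A[jn, i] <- 1L
          break
        }
      }
    }
  }
  A
}

# Logical matrix marking within-cluster pairs: nodes sharing at least one
# common neighbour in the latent graph (triangle-participating edges and
# 2-path pairs). Between-cluster shortcut edges have no common neighbour
# and are excluded.
within_cluster_pairs <- function(A) {
  A2 <- A %*% A
  out <- A2 > 0
  diag(out) <- FALSE
  out
}

# Target correlation matrix of a latent adjacency: corr of X = (I + alpha A) Z
# with Z iid standard normal. Positive semidefinite by construction; edges
# carry the strongest entries, so thresholding the target at the latent edge
# count recovers the latent graph.
target_correlation <- function(A, alpha = 0.5) {
  n <- nrow(A)
  M <- diag(n) + alpha * A
  stats::cov2cor(tcrossprod(M))
}

#' Latent ground truth of a synthetic cohort
#'
#' Builds the per-group latent adjacency matrices, target correlation
#' matrices and the per-subject network-integrity factor implied by a
#' [cohort_config()]. The control network is a Watts-Strogatz ring lattice
#' (90 nodes, 6 neighbours, rewiring 0.1); the patient grey-matter target
#' attenuates the correlations of triangle-participating (within-cluster)
#' edges by `1 - gm_effect`, and the patient white-matter adjacency is a
#' degree-preserving rewiring of a fraction `wm_effect` of the control
#' edges.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort_truth` with elements
#'   `adjacency_control`, `adjacency_patient_wm`, `target_control`,
#'   `target_patient`, `integrity`, `subject_id`, `group`.
#' @export
cohort_ground_truth <- function(config) {
  validate_cohort_config(config)
  n <- config$n_regions
  regions <- default_regions(n)

  A_nc <- with_seed(child_seed(config$seed, "latent"),
                    watts_strogatz_adj(n, 1:3, 0.1))
  dimnames(A_nc) <- list(regions, regions)

  R_nc <- target_correlation(A_nc, config$alpha)
  wc <- within_cluster_pairs(A_nc)
  R_ad <- R_nc
  R_ad[wc] <- R_nc[wc] * (1 - config$gm_effect)
  R_ad <- ensure_pd(R_ad)

  g_nc <- igraph::graph_from_adjacency_matrix(A_nc, "undirected")
  n_swap <- round(config$wm_effect * igraph::ecount(g_nc))
  A_wm_ad <- with_seed(child_seed(config$seed, "wm_latent"), {
    g <- if (n_swap > 0)
      igraph::rewire(g_nc, igraph::keeping_degseq(niter = n_swap))
    else g_nc
    as.matrix(igraph::as_adjacency_matrix(g))
  })
  storage.mode(A_wm_ad) <- "integer"
  dimnames(A_wm_ad) <- list(regions, regions)

  n_tot <- config$n_patients + config$n_controls
  group <- factor(rep(c("patient", "control"),
                      c(config$n_patients, config$n_controls)),
                  levels = c("patient", "control"))
  shift <- config$gm_effect + config$wm_effect
  integrity <- with_seed(child_seed(config$seed, "integrity"),
                         stats::rnorm(n_tot, 0, 0.3)) -
    ifelse(group == "patient", shift, 0)

  out <- list(
    adjacency_control = A_nc,
    adjacency_patient_wm = A_wm_ad,
    target_control = R_nc,
    target_patient = R_ad,
    integrity = integrity,
    subject_id = sprintf("S%03d", seq_len(n_tot)),
    group = group,
    gm_effect = config$gm_effect,
    wm_effect = config$wm_effect
  )
  class(out) <- "cohort_truth"
  out
}

# ---------------------------------------------------------------------------
# Grey matter

# Draw one subjects x regions table of a positive metric: log-normal with
# correlated log-scale component tau * L z and independent noise.
draw_metric_table <- function(ns, R, scale, tau, noise_sd) {
  n <- nrow(R)
  Z <- MASS::mvrnorm(ns, mu = rep(0, n), Sigma = R)
  if (ns == 1L) Z <- matrix(Z, nrow = 1)
  logx <- log(scale) + tau * Z +
    matrix(stats::rnorm(ns * n, 0, noise_sd), ns, n)
  exp(logx)
}

#' Generate grey-matter regional metric tables for a two-group cohort
#'
#' For each configured metric, draws a patients table and a controls table
#' of strictly positive regional values whose across-subject correlation
#' matrix converges (in n) to the group's target correlation matrix. The
#' control target is built on a small-world latent network; the patient
#' target attenuates within-cluster edge correlations by `1 - gm_effect`
#' (see [cohort_ground_truth()]).
#'
#' @param config a [cohort_config()].
#' @return a list with `tables` (per metric: list of `patients` and
#'   `controls` [regional_metric_table()] objects) and `truth`
#'   (the [cohort_ground_truth()]).
#' @examples
#' co <- generate_gm_cohort(cohort_config(seed = 1, metrics = "MK"))
#' dim(co$tables$MK$patients$values)
#' @export
generate_gm_cohort <- function(config) {
  validate_cohort_config(config)
  truth <- cohort_ground_truth(config)
  metrics <- intersect(config$metrics, GM_METRICS)
  regions <- colnames(truth$target_control)
  idx_p <- which(truth$group == "patient")
  idx_c <- which(truth$group == "control")

  tables <- lapply(metrics, function(m) {
    sc <- config$metric_scales[[m]]
    Xp <- with_seed(child_seed(config$seed, paste0("gm_", m, "_patient")),
                    draw_metric_table(config$n_patients, truth$target_patient,
                                      sc, config$tau, config$noise_sd))
    Xc <- with_seed(child_seed(config$seed, paste0("gm_", m, "_control")),
                    draw_metric_table(config$n_controls, truth$target_control,
                                      sc, config$tau, config$noise_sd))
    list(
      patients = regional_metric_table(
        Xp, subject_ids = truth$subject_id[idx_p],
        group = rep("patient", config$n_patients),
        regions = regions, metric = m),
      controls = regional_metric_table(
        Xc, subject_ids = truth$subject_id[idx_c],
        group = rep("control", config$n_controls),
        regions = regions, metric = m)
    )
  })
  names(tables) <- metrics
  list(tables = tables, truth = truth)
}

# ---------------------------------------------------------------------------
# White matter

# One subject's FN matrix: negative-binomial streamline counts on latent
# edges, sporadic false edges with 1-2 streamlines elsewhere.
draw_fn_matrix <- function(A, mu, false_rate) {
  n <- nrow(A)
  ut <- which(upper.tri(A))
  on <- ut[A[ut] == 1L]
  off <- ut[A[ut] == 0L]
  FN <- matrix(0L, n, n)
  FN[on] <- stats::rnbinom(length(on), size = 5, mu = mu)
  if (false_rate > 0 && length(off)) {
    fe <- off[stats::runif(length(off)) < false_rate]
    FN[fe] <- sample(1:2, length(fe), replace = TRUE)
  }
  FN + t(FN)
}

#' Generate subject-level white-matter connectivity matrices
#'
#' For every subject, draws a fiber-number (FN) matrix plus per-edge metric
#' weight matrices (mean fiber length and mean diffusion/kurtosis values on
#' existing edges). Patient matrices are built on a partially rewired latent
#' network and their metric weights are attenuated by `1 - wm_effect`;
#' individual weights also scale with the subject's integrity factor, which
#' ties network strength to the cognitive scores produced by
#' [generate_covariates()].
#'
#' @param config a [cohort_config()].
#' @return a list with `subjects` (per subject: named list of
#'   [connectivity_matrix()] objects, one per metric including `FN` and
#'   `length`) and `truth`.
#' @export
generate_wm_cohort <- function(config) {
  validate_cohort_config(config)
  truth <- cohort_ground_truth(config)
  regions <- colnames(truth$adjacency_control)
  metrics <- intersect(config$metrics, WM_METRICS)
  wm_diff <- setdiff(metrics, c("FN", "length"))

  subjects <- with_seed(child_seed(config$seed, "wm_subjects"), {
    lapply(seq_along(truth$subject_id), function(s) {
      is_pat <- truth$group[s] == "patient"
      A <- if (is_pat) truth$adjacency_patient_wm else truth$adjacency_control
      subj_scale <- exp(0.15 * truth$integrity[s])
      atten <- if (is_pat) 1 - config$wm_effect else 1

      FN <- draw_fn_matrix(A, mu = config$metric_scales[["FN"]] * subj_scale,
                           false_rate = config$false_edge_rate)
      mask <- FN > 0
      out <- list()
      if ("FN" %in% metrics)
        out$FN <- connectivity_matrix(FN, regions, weight_kind = "FN",
                                      level = "subject")
      ut <- which(upper.tri(mask) & mask)
      draw_edge_weights <- function(scale) {
        W <- matrix(0, nrow(A), ncol(A))
        W[ut] <- exp(log(scale) + stats::rnorm(length(ut), 0, 0.15))
        W + t(W)
      }
      if ("length" %in% metrics)
        out$length <- connectivity_matrix(
          draw_edge_weights(config$metric_scales[["length"]]),
          regions, weight_kind = "length", level = "subject")
      for (m in wm_diff)
        out[[m]] <- connectivity_matrix(
          draw_edge_weights(config$metric_scales[[m]] * atten * subj_scale),
          regions, weight_kind = m, level = "subject")
      out
    })
  })
  names(subjects) <- truth$subject_id
  list(subjects = subjects, truth = truth)
}

# ---------------------------------------------------------------------------
# Covariates

#' Generate subject covariates (age, sex, MMSE, MoCA)
#'
#' Ages follow the group demographics of a typical late-onset dementia
#' cohort; sex counts are fixed at 12F/9M (patients) and 9F/10M (controls)
#' in shuffled order; MMSE and MoCA are monotone functions of the
#' subject-level integrity factor (slope `cognition_link`) plus noise,
#' clipped to the instruments' 0-30 range.
#'
#' @param config a [cohort_config()].
#' @return a data.frame with columns `subject_id`, `group`, `age`, `sex`,
#'   `MMSE`, `MoCA`, plus the integrity factor as attribute `"integrity"`.
#' @export
generate_covariates <- function(config) {
  validate_cohort_config(config)
  truth <- cohort_ground_truth(config)
  np <- config$n_patients; nc <- config$n_controls

  with_seed(child_seed(config$seed, "covariates"), {
    age <- c(stats::rnorm(np, 73.6, 6.9), stats::rnorm(nc, 70, 8.1))
    n_f_pat <- min(12L, np); n_f_con <- min(9L, nc)
    sex <- c(sample(rep(c("F", "M"), c(n_f_pat, np - n_f_pat))),
             sample(rep(c("F", "M"), c(n_f_con, nc - n_f_con))))
    clip30 <- function(x) pmin(30, pmax(0, x))
    mmse <- clip30(29.5 + config$cognition_link * truth$integrity +
                     stats::rnorm(np + nc, 0, 0.5))
    moca <- clip30(29 + 1.5 * config$cognition_link * truth$integrity +
                     stats::rnorm(np + nc, 0, 0.5))
    out <- data.frame(
      subject_id = truth$subject_id,
      group = as.character(truth$group),
      age = age, sex = sex, MMSE = mmse, MoCA = moca,
      stringsAsFactors = FALSE
    )
    attr(out, "integrity") <- truth$integrity
    out
  })
}
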