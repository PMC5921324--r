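# End-to-end orchestration: synthetic cohort (or files) -> grey-matter
# correlation networks, small-world curves, white-matter attribute
# comparison, hub tables, permutation curves, cognition correlations, and a
# checksummed manifest.

#' Configuration of a full pipeline run
#'
#' @param cohort a [cohort_config()] describing the synthetic cohort to
#'   generate (file-based inputs can be analysed with the individual
#'   functions; the orchestrated run is cohort-driven).
#' @param out_dir output directory (created if needed).
#' @param grid sparsity grid for sweeps and the permutation test.
#' @param gm_mode graph mode for the grey-matter permutation pipeline
#'   (`"weighted"` follows the thresholded-weighted-matrix convention;
#'   `"binary"` is classical structural-covariance practice).
#' @param sw_mode graph mode for the descriptive small-world curves.
#' @param rank ranking of negative correlations (`"abs"` or `"positive"`).
#' @param sw_metrics metrics whose group small-world curves are computed.
#' @param wm_metrics white-matter layers analysed per subject.
#' @param perm_metric metric used for the group permutation test.
#' @param hub_sparsity sparsity of the network used for hub analysis.
#' @param n_rand null-ensemble size for group small-world curves.
#' @param wm_n_rand null-ensemble size for per-subject networks.
#' @param n_perm permutations for the group test.
#' @param correction multiplicity correction (see [adjust_pvalues()]).
#' @param seed master seed for the run (defaults to the cohort seed).
#' @return an object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), out_dir = "dknet_run",
                       grid = seq(0.06, 0.40, by = 0.01),
                       gm_mode = "weighted", sw_mode = "binary",
                       rank = "abs",
                       sw_metrics = c("MK", "KFA", "AK", "RK"),
                       wm_metrics = c("FN", "length", "MK", "KFA", "AK",
                                      "RK", "MD", "FA", "Ad", "RD"),
                       perm_metric = "MK", hub_sparsity = 0.10,
                       n_rand = 100, wm_n_rand = 20, n_perm = 1000,
                       correction = "BH", seed = cohort$seed) {
  cfg <- list(cohort = cohort, out_dir = out_dir, grid = grid,
              gm_mode = gm_mode, sw_mode = sw_mode, rank = rank,
              sw_metrics = sw_metrics, wm_metrics = wm_metrics,
              perm_metric = perm_metric, hub_sparsity = hub_sparsity,
              n_rand = n_rand, wm_n_rand = wm_n_rand, n_perm = n_perm,
              correction = correction, seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Per-subject network attributes of one weighted WM layer.
subject_wm_attributes <- function(cm, n_rand, seed) {
  tg <- thresholded_graph_from_dense(cm$values, mode = "weighted")
  sw <- small_worldness(tg, n_rand = n_rand, seed = seed)
  ef <- efficiency(tg)
  c(Lp = sw$Lp, Cp = sw$Cp, lambda = sw$lambda, gamma = sw$gamma,
    sigma = sw$sigma, Eloc = ef$Eloc, Eg = ef$Eg)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, then writes into `config$out_dir`:
#' group correlation matrices per metric; small-world curves over the
#' sparsity grid per group and metric; a white-matter attribute comparison
#' table (group means with ANCOVA p-values adjusted across metrics);
#' per-group hub tables plus BrainNet Viewer `.node`/`.edge` exports;
#' permutation-test curves for the configured metric; a
#' partial-correlation table of patient network attributes against MMSE
#' and MoCA; the demographics table; a copy of the configuration; and a
#' JSON manifest with the MD5 checksum of every artifact.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  paths <- character(0)
  warn_log <- character(0)
  note <- function(p) paths <<- c(paths, p)
  capture_warn <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn_log <<- c(warn_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  cohort <- config$cohort
  say("stage synthetic_cohort: %d patients / %d controls, seed %d",
      cohort$n_patients, cohort$n_controls, cohort$seed)
  gm <- capture_warn(generate_gm_cohort(cohort))
  wm <- capture_warn(generate_wm_cohort(cohort))
  cov <- generate_covariates(cohort)
  note(write_tsv(cov, file.path(out, "covariates.tsv")))
  note(write_tsv(demographics_compare(cov), file.path(out, "demographics.tsv")))

  # --- grey matter: correlation matrices and small-world curves -----------
  say("stage gm_networks: %d metrics", length(gm$tables))
  sw_rows <- list()
  hub_graphs <- list()
  for (m in names(gm$tables)) {
    for (grp in c("patients", "controls")) {
      cm <- capture_warn(gm_correlation_matrix(gm$tables[[m]][[grp]]))
      note(write_matrix(cm, file.path(out, sprintf("gm_corr_%s_%s.txt", m, grp))))
      if (m %in% config$sw_metrics) {
        for (S in config$grid) {
          tg <- threshold_by_sparsity(cm, S, mode = config$sw_mode,
                                      rank = config$rank)
          sw <- small_worldness(tg, n_rand = config$n_rand,
                                seed = child_seed(config$seed,
                                                  paste("sw", m, grp, S)))
          sw_rows[[length(sw_rows) + 1L]] <- data.frame(
            metric = m, group = grp, sparsity = S, mode = config$sw_mode,
            Cp = sw$Cp, Lp = sw$Lp, Cprand = sw$Cprand, Lprand = sw$Lprand,
            gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma)
        }
      }
      if (m == config$perm_metric)
        hub_graphs[[grp]] <- threshold_by_sparsity(cm, config$hub_sparsity,
                                                   mode = config$sw_mode,
                                                   rank = config$rank)
    }
  }
  if (length(sw_rows))
    note(write_tsv(do.call(rbind, sw_rows),
                   file.path(out, "gm_smallworld_curves.tsv")))

  # --- hubs ----------------------------------------------------------------
  say("stage hub_analysis at sparsity %.2f", config$hub_sparsity)
  meta <- synthetic_region_metadata(cohort$n_regions)
  for (grp in names(hub_graphs)) {
    ht <- capture_warn(hub_analysis(hub_graphs[[grp]],
                                    classes = meta$class[match(hub_graphs[[grp]]$labels,
                                                               meta$region)]))
    note(write_tsv(ht, file.path(out, sprintf("hubs_%s.tsv", grp))))
    note(write_brainnet(ht, meta, adjacency_of(hub_graphs[[grp]]),
                        file.path(out, sprintf("hubs_%s", grp))))
  }

  # --- permutation test ----------------------------------------------------
  say("stage gm_permutation: metric %s, %d permutations",
      config$perm_metric, config$n_perm)
  pt <- capture_warn(gm_permutation_test(
    gm$tables[[config$perm_metric]]$patients,
    gm$tables[[config$perm_metric]]$controls,
    grid = config$grid, n_perm = config$n_perm,
    seed = child_seed(config$seed, "permutation"),
    mode = config$gm_mode, rank = config$rank))
  perm_df <- rbind(cbind(attribute = "Cp", pt$Cp),
                   cbind(attribute = "Lp", pt$Lp))
  note(write_tsv(perm_df, file.path(out, "gm_permutation_curves.tsv")))

  # --- white matter: per-subject attributes, ANCOVA, cognition ------------
  say("stage wm_networks: %d layers x %d subjects",
      length(config$wm_metrics), length(wm$subjects))
  subj_rows <- list()
  for (sid in names(wm$subjects)) {
    layers <- wm_edge_matrices(wm$subjects[[sid]]$FN,
                               wm$subjects[[sid]][setdiff(config$wm_metrics, "FN")])
    for (m in config$wm_metrics) {
      at <- subject_wm_attributes(layers[[m]], n_rand = config$wm_n_rand,
                                  seed = child_seed(config$seed,
                                                    paste("wm", sid, m)))
      subj_rows[[length(subj_rows) + 1L]] <-
        data.frame(subject_id = sid, metric = m, t(at))
    }
  }
  subj_df <- do.call(rbind, subj_rows)
  subj_df$group <- cov$group[match(subj_df$subject_id, cov$subject_id)]
  note(write_tsv(subj_df, file.path(out, "wm_subject_attributes.tsv")))

  attrs <- c("Lp", "Cp", "lambda", "gamma", "sigma", "Eloc", "Eg")
  cmp_rows <- list()
  for (a in attrs) {
    for (m in config$wm_metrics) {
      d <- subj_df[subj_df$metric == m, ]
      an <- ancova_group_effect(d[[a]], d$group,
                                age = cov$age[match(d$subject_id, cov$subject_id)],
                                sex = cov$sex[match(d$subject_id, cov$subject_id)])
      mp <- tapply(d[[a]], d$group, mean)
      sp <- tapply(d[[a]], d$group, stats::sd)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        attribute = a, metric = m,
        patient = sprintf("%.3f (%.3f)", mp[["patient"]], sp[["patient"]]),
        control = sprintf("%.3f (%.3f)", mp[["control"]], sp[["control"]]),
        F = an$F, p = an$p)
    }
  }
  cmp <- do.call(rbind, cmp_rows)
  cmp$p_adjusted <- as.vector(unlist(tapply(
    cmp$p, cmp$attribute, adjust_pvalues, method = config$correction,
    simplify = FALSE)[unique(cmp$attribute)]))
  note(write_tsv(cmp, file.path(out, "wm_attribute_comparison.tsv")))

  say("stage cognition: partial correlations in the patient group")
  pat <- cov[cov$group == "patient", ]
  pc_rows <- list()
  for (score in c("MMSE", "MoCA")) {
    for (a in attrs) for (m in config$wm_metrics) {
      d <- subj_df[subj_df$metric == m & subj_df$group == "patient", ]
      d <- d[match(pat$subject_id, d$subject_id), ]
      pc <- partial_correlation(d[[a]], pat[[score]],
                                covariates = pat[, c("age", "sex")])
      pc_rows[[length(pc_rows) + 1L]] <- data.frame(
        score = score, attribute = a, metric = m, r = pc$r, p = pc$p,
        evaluable = pc$evaluable)
    }
  }
  pc_df <- do.call(rbind, pc_rows)
  ok <- pc_df$evaluable & !is.na(pc_df$p)
  pc_df$p_adjusted <- NA_real_
  grp_key <- interaction(pc_df$score, pc_df$attribute, drop = TRUE)
  for (k in levels(grp_key)) {
    i <- ok & grp_key == k
    if (any(i)) pc_df$p_adjusted[i] <- adjust_pvalues(pc_df$p[i],
                                                      method = config$correction)
  }
  note(write_tsv(pc_df, file.path(out, "cognition_partial_correlations.tsv")))

  # --- manifest ------------------------------------------------------------
  cfg_copy <- config
  cfg_copy$cohort <- unclass(cfg_copy$cohort)
  cfg_copy$out_dir <- NULL # keep artifact checksums independent of the destination
  cfg_path <- file.path(out, "run_config.json")
  jsonlite::write_json(unclass(cfg_copy), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  note(cfg_path)
  sums <- tools::md5sum(sort(unique(paths)))
  manifest <- list(
    seed = config$seed,
    n_artifacts = length(sums),
    warnings = warn_log,
    files = data.frame(path = basename(names(sums)), md5 = unname(sums),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("run complete: %d artifacts in %s", manifest$n_artifacts, out)
  invisible(manifest)
}
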