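# Synthetic cohort generator: reproducibility, ground-truth contracts,
# convergence to the target correlation structure, and the faithfulness of
# the effect-size dials.

test_that("config validation rejects invalid settings", {
  expect_error(cohort_config(n_patients = 0), "positive")
  expect_error(cohort_config(gm_effect = 1.2), "gm_effect")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(metrics = "XX"), "no scale")
})

test_that("the same config and seed regenerate identical outputs", {
  cfg <- test_cohort(seed = 7, metrics = c("MK", "FA"))
  a <- generate_gm_cohort(cfg); b <- generate_gm_cohort(cfg)
  expect_identical(a, b)
  wa <- generate_wm_cohort(cfg); wb <- generate_wm_cohort(cfg)
  expect_identical(wa, wb)
  expect_identical(generate_covariates(cfg), generate_covariates(cfg))
})

test_that("ground truth matrices satisfy their structural invariants", {
  tr <- cohort_ground_truth(test_cohort(seed = 2))
  for (A in list(tr$adjacency_control, tr$adjacency_patient_wm)) {
    expect_identical(A, t(A))
    expect_true(all(diag(A) == 0))
    expect_true(all(A %in% 0:1))
  }
  # degree-6 ring lattice plus rewiring: edge count preserved
  expect_equal(sum(tr$adjacency_control) / 2, 270)
  ev <- eigen(tr$target_patient, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("gm_effect = 0 leaves the patient target identical to control", {
  tr <- cohort_ground_truth(test_cohort(seed = 3, gm_effect = 0))
  expect_identical(tr$target_patient, tr$target_control)
})

test_that("thresholding the control target recovers the latent network", {
  tr <- cohort_ground_truth(test_cohort(seed = 4))
  cm <- connectivity_matrix(tr$target_control,
                            weight_kind = "correlation", level = "group")
  K <- sum(tr$adjacency_control) / 2
  tg <- threshold_by_sparsity(cm, K / (90 * 89 / 2))
  A <- adjacency_of(tg)
  # thresholding at the latent edge count recovers (nearly all of) the
  # latent edges; 2-path correlations can outrank a few weak shortcut edges
  overlap <- sum(A > 0 & tr$adjacency_control == 1) / 2
  expect_gte(overlap / K, 0.95)
  # and the latent control network is small-world
  sw <- small_worldness(tg, n_rand = 20, seed = 1)
  expect_gt(sw$sigma, 1)
})

test_that("generated values are strictly positive with the right shape", {
  co <- generate_gm_cohort(test_cohort(seed = 5))
  expect_equal(dim(co$tables$MK$patients$values), c(21L, 90L))
  expect_equal(dim(co$tables$MK$controls$values), c(19L, 90L))
  expect_true(all(co$tables$MK$patients$values > 0))
  expect_true(all(co$tables$MK$controls$values > 0))
})

test_that("sample correlations converge to the target as n grows", {
  frob <- function(n) {
    cfg <- test_cohort(seed = 11, n_controls = n, noise_sd = 0.01)
    co <- generate_gm_cohort(cfg)
    C <- suppressWarnings(stats::cor(co$tables$MK$controls$values))
    R <- co$truth$target_control
    sqrt(sum((C - R)[upper.tri(C)]^2))
  }
  d <- vapply(c(50, 200, 500), frob, numeric(1))
  expect_true(all(diff(d) < 0))
})

test_that("FN matrices are integer, masked to latent edges, with rare false edges", {
  cfg <- test_cohort(seed = 6, metrics = c("FN", "FA"), false_edge_rate = 0)
  wm <- generate_wm_cohort(cfg)
  tr <- wm$truth
  for (sid in c("S001", "S040")) {
    FN <- wm$subjects[[sid]]$FN$values
    expect_true(all(FN >= 0) && all(FN == round(FN)))
    expect_identical(FN, t(FN))
    A <- if (tr$group[match(sid, tr$subject_id)] == "patient")
      tr$adjacency_patient_wm else tr$adjacency_control
    expect_true(all(FN[A == 0] == 0)) # no false edges at rate 0
  }
})

test_that("wm_effect attenuates patient edge weights in expectation", {
  cfg <- cohort_config(seed = 8, metrics = c("FN", "FA"),
                       n_patients = 100, n_controls = 100,
                       gm_effect = 0, wm_effect = 0.4)
  wm <- generate_wm_cohort(cfg)
  mean_w <- function(sid) {
    W <- wm$subjects[[sid]]$FA$values
    mean(W[W > 0])
  }
  pats <- wm$truth$subject_id[wm$truth$group == "patient"]
  cons <- wm$truth$subject_id[wm$truth$group == "control"]
  expect_lt(mean(vapply(pats, mean_w, numeric(1))),
            mean(vapply(cons, mean_w, numeric(1))))
})

test_that("wm_effect = 0 gives equal weight distributions in expectation", {
  cfg <- cohort_config(seed = 9, metrics = "FA", n_patients = 60,
                       n_controls = 60, gm_effect = 0, wm_effect = 0)
  wm <- generate_wm_cohort(cfg)
  w_of <- function(sid) { W <- wm$subjects[[sid]]$FA$values; mean(W[W > 0]) }
  pats <- wm$truth$subject_id[wm$truth$group == "patient"]
  cons <- wm$truth$subject_id[wm$truth$group == "control"]
  mp <- vapply(pats, w_of, numeric(1)); mc <- vapply(cons, w_of, numeric(1))
  expect_gt(t.test(mp, mc)$p.value, 0.01)
})

test_that("cognitive scores are bounded and track the integrity factor", {
  cfg <- cohort_config(seed = 10, n_patients = 100, n_controls = 100)
  cov <- generate_covariates(cfg)
  expect_true(all(cov$MMSE >= 0 & cov$MMSE <= 30))
  expect_true(all(cov$MoCA >= 0 & cov$MoCA <= 30))
  expect_gt(cor(attr(cov, "integrity"), cov$MMSE), 0.5)
  expect_lt(mean(cov$MMSE[cov$group == "patient"]),
            mean(cov$MMSE[cov$group == "control"]))

  cfg0 <- cohort_config(seed = 10, n_patients = 100, n_controls = 100,
                        cognition_link = 0)
  cov0 <- generate_covariates(cfg0)
  expect_lt(abs(cor(attr(cov0, "integrity"), cov0$MMSE)), 0.2)
})

test_that("measured group Cp difference grows monotonically with gm_effect", {
  # measured at the latent-network density (270 edges / 4005 pairs), where
  # the weighted clustering difference is not diluted by second-order edges
  dcp <- vapply(c(0, 0.2, 0.5), function(f) {
    cfg <- cohort_config(seed = 12, metrics = "MK", gm_effect = f,
                         n_patients = 200, n_controls = 200)
    co <- generate_gm_cohort(cfg)
    sp <- dknet:::cor_topology_stats(co$tables$MK$controls$values, 0.07) -
      dknet:::cor_topology_stats(co$tables$MK$patients$values, 0.07)
    sp["Cp", 1]
  }, numeric(1))
  expect_true(all(diff(dcp) > 0))
  expect_lt(abs(dcp[1]), 0.05) # null case: no real difference
})
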