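short_cfg <- sim_config(t_end = 1200, output_step = 20)

test_that("pi_regime_scan orders expression with phosphate availability", {
  rs <- pi_regime_scan(factors = c(1, 0.2), config = short_cfg)
  expect_length(rs$trajectories, 2)
  expect_identical(nrow(rs$summary), 2L)
  # weaker autophosphorylation (more external Pi) -> less expression
  expect_lt(rs$summary$auc_PhoA[2], rs$summary$auc_PhoA[1])
  expect_lt(rs$summary$ss_DiPhoBpp[2], rs$summary$ss_DiPhoBpp[1])
  expect_error(pi_regime_scan(factors = c(1, -1)))
})

test_that("promoter_design_scan covers the grid and tracks binding strength", {
  scan <- promoter_design_scan(binding_folds = c(0.5, 1, 2),
                               unbinding_folds = c(1),
                               config = short_cfg)
  expect_identical(nrow(scan), 3L)
  expect_true(is.numeric(attr(scan, "control_auc")))
  expect_gt(attr(scan, "control_auc"), 0)
  # stronger binding -> more active promoter at steady state
  ord <- order(scan$binding_fold)
  expect_true(all(diff(scan$ss_pPhoAa[ord]) > 0))
  # zero binding silences the promoter; only the single pre-existing
  # transcript still leaks a trace of PhoA
  silent <- promoter_design_scan(binding_folds = 0, unbinding_folds = 1,
                                 config = short_cfg,
                                 keep_trajectories = TRUE)
  expect_equal(silent$ss_pPhoAa, 0)
  tcs <- attr(silent, "trajectories")[[1]]
  expect_true(all(diff(tcs$values[, "mRNAa"]) <= 0))
  expect_lt(silent$auc_PhoA, 0.05 * attr(silent, "control_auc"))
})

test_that("starvation-equivalent designs are found or flagged as nearest", {
  scan <- promoter_design_scan(binding_folds = c(0.5, 1),
                               unbinding_folds = c(0.5, 1),
                               config = short_cfg)
  hit <- find_starvation_equivalent_designs(scan, tolerance = 0.01)
  expect_false(attr(hit, "nearest"))
  # the unmodified design reproduces the control exactly
  expect_true(any(hit$binding_fold == 1 & hit$unbinding_fold == 1))
  none <- find_starvation_equivalent_designs(scan[scan$binding_fold == 0.5 &
                                                    scan$unbinding_fold == 1, ],
                                             reference = attr(scan, "control_auc"),
                                             tolerance = 1e-9)
  expect_true(attr(none, "nearest"))
  expect_identical(nrow(none), 1L)
})

test_that("range_sensitivity covers exactly the ranged parameters", {
  M <- range_sensitivity(config = sim_config(t_end = 600, output_step = 20))
  expect_setequal(rownames(M),
                  c("r1", "r2", "r4", "r6", "r12", "r13", "r14", "r15",
                    "r16", "r17", "r18", "r19"))
  expect_identical(colnames(M), pho_network()$species)
  expect_true(all(is.finite(M[, "PhoA"])))
  # a degenerate range contributes a zero row
  r <- default_rates()
  r$lo[r$symbol == "r12"] <- r$value[r$symbol == "r12"]
  r$hi[r$symbol == "r12"] <- r$value[r$symbol == "r12"]
  M0 <- range_sensitivity(rates = r,
                          config = sim_config(t_end = 600, output_step = 20))
  expect_true(all(M0["r12", ] == 0))
})

test_that("sweep_sensitivity records per-cell results without aborting", {
  sw <- sweep_sensitivity(config = sim_config(t_end = 600, output_step = 20),
                          fold_grid = c(0.1, 1, 10), symbols = c("r12"))
  expect_identical(nrow(sw), 3L * 16L)
  expect_false(any(sw$failed))
  phoA <- sw[sw$species == "PhoA", ]
  expect_true(all(diff(phoA$auc_ratio[order(phoA$fold)]) > 0))
  expect_equal(phoA$auc_ratio[phoA$fold == 1], 1, tolerance = 1e-6)
})

test_that("unbinding_noise_study reports finite noise ratios per rate", {
  ns <- unbinding_noise_study(unbinding_rates = c(1000, 5000), n_reps = 3,
                              seed = 2, species = c("mRNAa", "pPhoAa"),
                              anchor_time = 300, t_end = 20, burn_in = 5,
                              output_step = 1)
  expect_identical(nrow(ns), 4L)
  expect_true(all(is.finite(ns$ratio)))
  expect_true(all(ns$ratio > 0))
  expect_true(all(ns$mean > 0))
  # occupancy means fall as unbinding accelerates
  p1 <- ns$mean[ns$species == "pPhoAa" & ns$unbinding_rate == 1000]
  p2 <- ns$mean[ns$species == "pPhoAa" & ns$unbinding_rate == 5000]
  expect_gt(p1, p2)
})
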