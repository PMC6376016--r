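test_that("propensities follow mass-action combinatorics", {
  net <- pho_network()
  ctx <- volume_context()
  r <- default_rates()
  counts <- stats::setNames(rep(0, 16), net$species)
  counts[c("DiPhoR", "PhoBp", "DiPhoBpp", "pPhoA", "mRNAa")] <-
    c(40, 7, 12, 10, 3)
  k <- function(sym) r$value[r$symbol == sym]
  # unimolecular: k * n
  expect_equal(propensity("R1f", counts, r), k("r1") * 40)
  expect_equal(propensity("R20", counts, r), k("r20") * 3)
  # heterobimolecular: (k / omega) * n1 * n2
  expect_equal(propensity("R10f", counts, r),
               k("r10") / ctx$omega * 12 * 10)
  expect_equal(propensity("R8f", counts, r),
               k("r8") / ctx$omega * 40 * 7)
  # homodimerisation: (2k / omega) * n (n - 1) / 2
  expect_equal(propensity("R7f", counts, r),
               2 * k("r7") / ctx$omega * 7 * 6 / 2)
  # absent reactant means zero propensity
  expect_equal(propensity("R3f", counts, r), 0)
  expect_error(propensity("R99", counts, r), "unknown reaction")
  counts["PhoB"] <- -1
  expect_error(propensity("R1f", counts, r), "non-negative")
})

test_that("simulate_ssa is reproducible and seed-sensitive", {
  a <- simulate_ssa(t_end = 30, seed = 11, output_step = 5)
  b <- simulate_ssa(t_end = 30, seed = 11, output_step = 5)
  c <- simulate_ssa(t_end = 30, seed = 12, output_step = 5)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, c$values))
  expect_identical(a$domain, "count")
  expect_true(all(a$values == floor(a$values)))
  expect_true(all(a$values >= 0))
  expect_gt(attr(a, "n_events"), 0)
})

test_that("stochastic control run conserves promoter copies exactly", {
  tc <- simulate_ssa(t_end = 120, seed = 5, output_step = 10)
  expect_true(all(tc$values[, "pPhoA"] + tc$values[, "pPhoAa"] == 10))
  expect_true(all(tc$values[, "pPhoB"] + tc$values[, "pPhoBa"] == 10))
})

test_that("pure decay reaches and holds the absorbing state", {
  net <- subnetwork(pho_network(), "R20")
  init <- c(mRNAa = 25)
  tc <- simulate_ssa(net, init_counts = init, t_end = 5000, seed = 3,
                     output_step = 100)
  y <- tc$values[, "mRNAa"]
  expect_true(all(diff(y) <= 0))
  expect_identical(y[length(y)], 0)
})

test_that("ensembles are reproducible and independent of order", {
  net <- subnetwork(pho_network(), c("R12", "R20"))
  init <- c(pPhoAa = 10, mRNAa = 0)
  e1 <- run_ensemble(net, init = init, t_end = 200, n_reps = 3,
                     base_seed = 9, output_step = 50)
  expect_length(e1, 3)
  # replicate 2 alone equals a direct run with seed base + 2
  solo <- simulate_ssa(net, init_counts = init, t_end = 200, seed = 11,
                       output_step = 50)
  expect_identical(e1[[2]]$values, solo$values)
})

test_that("birth-death motif matches the Poisson stationary law", {
  # transcription from 10 active promoters + decay: stationary
  # distribution is Poisson with mean 10 * r12 / r20
  net <- subnetwork(pho_network(), c("R12", "R20"))
  r <- default_rates()
  lambda <- 10 * r$value[r$symbol == "r12"] / r$value[r$symbol == "r20"]
  reps <- run_ensemble(net, init = c(pPhoAa = 10, mRNAa = round(lambda)),
                       t_end = 1500, n_reps = 40, base_seed = 2,
                       output_step = 25)
  nr <- noise_ratio(reps, "mRNAa", window = c(900, 1500))
  expect_equal(nr$mean, lambda, tolerance = 0.05)
  expect_equal(nr$ratio, 1 / sqrt(lambda), tolerance = 0.15)
})

test_that("two-state promoter matches the binomial stationary law", {
  # binding/unbinding with an abundant transcription factor: occupancy
  # of the 10 promoter copies is binomial(10, p)
  net <- subnetwork(pho_network(), c("R10f", "R10r"))
  r <- default_rates()
  ctx <- volume_context()
  n_tf <- 1500
  reps <- run_ensemble(net,
                       init = c(DiPhoBpp = n_tf, pPhoA = 10, pPhoAa = 0),
                       t_end = 4, n_reps = 20, base_seed = 4,
                       output_step = 0.02, ctx = ctx)
  nr <- noise_ratio(reps, "pPhoAa", window = c(1, 4))
  # quasi-steady occupancy from the measured mean free TF level
  k_on <- r$value[r$symbol == "r10"] / ctx$omega * (n_tf - nr$mean)
  k_off <- r$value[r$symbol == "r10r"]
  p <- k_on / (k_on + k_off)
  expect_equal(nr$mean, 10 * p, tolerance = 0.05)
  expect_equal(nr$ratio, sqrt((1 - p) / (10 * p)), tolerance = 0.2)
})

test_that("noise_ratio flags undefined ratios and validates windows", {
  net <- subnetwork(pho_network(), "R20")
  tc <- simulate_ssa(net, init_counts = c(mRNAa = 0), t_end = 10,
                     seed = 1, output_step = 1)
  nr <- noise_ratio(tc, "mRNAa")
  expect_false(nr$defined)
  expect_true(is.na(nr$ratio))
  expect_error(noise_ratio(tc, "mRNAa", window = c(5, 50)))
})

test_that("simulate_ssa validates initial counts", {
  expect_error(simulate_ssa(init_counts = c(mRNAa = 1), t_end = 10),
               "cover")
  bad <- concentration_to_count(default_initial_state())
  bad["PhoB"] <- 1.5
  expect_error(simulate_ssa(init_counts = bad, t_end = 10),
               "non-negative integers")
})
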