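short_cfg <- sim_config(t_end = 1200, output_step = 10)

test_that("unit conversion matches the 1-molecule contract and round-trips", {
  ctx <- volume_context(1)
  expect_equal(ctx$omega, 602.214076, tolerance = 1e-12)
  expect_equal(signif(count_to_concentration(1, ctx), 3), 0.00166)
  counts <- c(0, 1, 7, 10, 132, 1000, 123456)
  expect_identical(
    concentration_to_count(count_to_concentration(counts, ctx), ctx),
    counts)
  ctx2 <- volume_context(0.37)
  expect_identical(
    concentration_to_count(count_to_concentration(counts, ctx2), ctx2),
    counts)
  expect_error(concentration_to_count(-1), "non-negative")
  expect_error(count_to_concentration(-1), "non-negative")
})

test_that("default initial state matches the documented pre-starvation setup", {
  init <- default_initial_state()
  expect_equal(unname(init["DiPhoR"]), 0.22)
  expect_equal(unname(init["PhoB"]), 0.22)
  expect_equal(unname(init["mRNAa"]), 0.00166)
  expect_equal(concentration_to_count(unname(init["pPhoA"])), 10)
  zero <- c("DiPhoRp", "DiPhoBpp", "C_RppB", "C_RpB", "C_RBp",
            "pPhoAa", "pPhoBa", "PhoA")
  expect_true(all(init[zero] == 0))
})

test_that("ode_rhs conserves promoter totals pointwise", {
  net <- pho_network()
  init <- default_initial_state()
  d <- ode_rhs(init, default_rates(), net)
  expect_length(d, 16)
  expect_true(all(is.finite(d)))
  expect_equal(unname(d["pPhoA"] + d["pPhoAa"]), 0)
  expect_equal(unname(d["pPhoB"] + d["pPhoBa"]), 0)
  # at a random positive state too
  set.seed(42)
  y <- stats::setNames(stats::runif(16, 0, 1), net$species)
  d2 <- ode_rhs(y, default_rates(), net)
  expect_equal(unname(d2["pPhoA"] + d2["pPhoAa"]), 0)
})

test_that("phosphoprotein mass balances in the rhs", {
  # with synthesis and degradation switched off, total PhoB mass
  # (PhoB + PhoBp + 2 DiPhoBpp + complexes + bound promoters) is conserved
  net <- pho_network()
  r <- set_rates(default_rates(),
                 c(r15 = 0, r18 = 0))
  set.seed(7)
  y <- stats::setNames(stats::runif(16, 0, 1), net$species)
  d <- ode_rhs(y, r, net)
  phoB_mass <- d["PhoB"] + d["PhoBp"] + 2 * d["DiPhoBpp"] +
    d["C_RppB"] + d["C_RpB"] + d["C_RBp"] +
    2 * d["pPhoAa"] + 2 * d["pPhoBa"]
  expect_equal(unname(phoB_mass), 0, tolerance = 1e-12)
})

test_that("control simulation is physical over the starvation onset", {
  tc <- simulate_ode(config = short_cfg)
  expect_s3_class(tc, "pho_timecourse")
  expect_true(all(tc$values >= 0))
  totA <- tc$values[, "pPhoA"] + tc$values[, "pPhoAa"]
  expect_true(all(abs(totA * volume_context()$omega - 10) < 1e-6))
  # PhoA accumulates monotonically early in starvation
  phoA <- tc$values[, "PhoA"]
  expect_true(all(diff(phoA) >= 0))
  expect_gt(phoA[length(phoA)], 0.1)
})

test_that("auc matches closed forms and converges with the grid", {
  # linear trajectory: integral of y = t over [0, 10] is 50
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,X", paste(0:10, 0:10, sep = ",")), p)
  tc <- read_timecourse_csv(p)
  expect_equal(auc(tc, "X"), 50)
  # grid refinement changes the control AUC by < 0.1%
  cfg_fine <- sim_config(t_end = 1200, output_step = 5)
  a1 <- auc(simulate_ode(config = short_cfg), "PhoA")
  a2 <- auc(simulate_ode(config = cfg_fine), "PhoA")
  expect_lt(abs(a1 - a2) / a2, 1e-3)
})

test_that("steady_state_value and time_to_peak behave on known shapes", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_s,X,Y",
               paste(0:20, c(0:10, 9:0), rep(5, 21), sep = ",")), p)
  tc <- read_timecourse_csv(p)
  expect_equal(time_to_peak(tc, "X"), 10)
  expect_equal(time_to_peak(tc, "Y"), 0)  # earliest tie on a constant
  ss <- steady_state_value(tc, "Y")
  expect_equal(as.numeric(ss), 5)
  expect_true(attr(ss, "stationary"))
  expect_warning(steady_state_value(tc, "X", window_fraction = 0.5),
                 "not at steady state")
})

test_that("simulate_ode validates inputs", {
  expect_error(sim_config(t_end = -1))
  bad_init <- default_initial_state()[-1]
  expect_error(simulate_ode(init = bad_init))
})
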