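test_that("control network has the documented size and composition", {
  net <- pho_network()
  expect_length(net$reactions, 29)
  expect_length(net$species, 16)
  expect_identical(dim(net$S), c(16L, 29L))
  # 8 reversible pairs (f/r ids) + 13 irreversible reactions
  ids <- vapply(net$reactions, `[[`, "", "id")
  fwd <- grep("f$", ids, value = TRUE)
  rev <- grep("r$", ids, value = TRUE)
  expect_length(fwd, 8)
  expect_length(rev, 8)
  expect_setequal(sub("f$", "", fwd), sub("r$", "", rev))
})

test_that("reverse reactions negate their forward stoichiometry", {
  net <- pho_network()
  ids <- colnames(net$S)
  for (f in grep("f$", ids, value = TRUE)) {
    r <- sub("f$", "r", f)
    expect_identical(net$S[, r], -net$S[, f],
                     info = paste(f, "vs", r))
  }
})

test_that("promoter totals are structurally conserved", {
  net <- pho_network()
  expect_true(all(net$S["pPhoA", ] + net$S["pPhoAa", ] == 0L))
  expect_true(all(net$S["pPhoB", ] + net$S["pPhoBa", ] == 0L))
})

test_that("expression reactions are catalytic and degradation is first order", {
  net <- pho_network()
  # transcription/translation leave their catalyst untouched
  for (id in c("R12", "R14")) expect_true(all(net$S[, id] >= 0L))
  for (id in c("R13", "R15", "R16")) expect_true(all(net$S[, id] >= 0L))
  # degradation removes exactly one molecule of one species
  for (id in c("R17", "R18", "R19", "R20", "R21")) {
    expect_identical(sum(net$S[, id]), -1L)
    expect_identical(sum(net$S[, id] != 0L), 1L)
  }
  # no degradation channel for promoters or phosphotransfer complexes
  undecaying <- c("pPhoA", "pPhoAa", "pPhoB", "pPhoBa",
                  "C_RppB", "C_RpB", "C_RBp")
  deg <- c("R17", "R18", "R19", "R20", "R21")
  expect_true(all(net$S[undecaying, deg] == 0L))
})

test_that("reaction orders and reactant indexing are consistent", {
  net <- pho_network()
  expect_true(all(net$order %in% 1:2))
  expect_true(all((net$order == 1L) == (net$reactant2 == 0L)))
  # the only homodimerisation is PhoBp + PhoBp -> DiPhoBpp
  homo <- which(net$order == 2L & net$reactant1 == net$reactant2)
  expect_identical(colnames(net$S)[homo], "R7f")
  expect_identical(net$species[net$reactant1[homo]], "PhoBp")
})

test_that("subnetwork extraction keeps touched species and errors on bad ids", {
  net <- pho_network()
  sub <- subnetwork(net, c("R12", "R20"))
  expect_setequal(sub$species, c("pPhoAa", "mRNAa"))
  expect_length(sub$reactions, 2)
  expect_error(subnetwork(net, "R99"), "unknown reaction id")
})

test_that("rate table covers all reactions with valid bounds", {
  net <- pho_network()
  r <- default_rates()
  expect_setequal(net$rate_symbols, r$symbol)
  expect_true(all(r$value > 0))
  ranged <- !is.na(r$lo) & !is.na(r$hi)
  expect_true(all(r$value[ranged] >= r$lo[ranged]))
  expect_true(all(r$value[ranged] <= r$hi[ranged]))
  bimol <- r$symbol[r$units == "per-uM-per-second"]
  expect_setequal(bimol, c("r3", "r5", "r7", "r8", "r10", "r11"))
})

test_that("rate edits validate their symbols", {
  r <- default_rates()
  r2 <- set_rates(r, c(r4 = 20))
  expect_equal(r2$value[r2$symbol == "r4"], 20)
  expect_error(set_rates(r, c(bogus = 1)), "bogus")
  f <- apply_fold_changes(r, c(r12 = 2))
  expect_equal(f$value[f$symbol == "r12"],
               2 * r$value[r$symbol == "r12"])
  # fold changes may leave the literature range (emulated conditions)
  big <- apply_fold_changes(r, c(r4 = 100))
  expect_equal(big$value[big$symbol == "r4"],
               100 * r$value[r$symbol == "r4"])
  expect_error(apply_fold_changes(r, c(nope = 2)), "nope")
})

test_that("model config files are validated", {
  p <- withr::local_tempfile(fileext = ".yml")
  writeLines("r4: 20\nr12: 0.1\nPhoB: 0.3", p)
  cfg <- read_model_config(p)
  expect_equal(cfg$rates$value[cfg$rates$symbol == "r4"], 20)
  expect_equal(cfg$rates$value[cfg$rates$symbol == "r12"], 0.1)
  expect_equal(unname(cfg$init["PhoB"]), 0.3)
  bad <- withr::local_tempfile(fileext = ".yml")
  writeLines("r4: 20\nunknown_rate: 1", bad)
  expect_error(read_model_config(bad), "unknown_rate")
})
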