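make_curves <- function(...) {
  args <- list(...)
  do.call(rbind, lapply(names(args), function(cd) {
    v <- args[[cd]]
    data.frame(time_min = seq(0, 30, length.out = length(v)),
               condition = cd, reading_au = v)
  }))
}

test_that("normalization maps the reference end to 100 and the run minimum to 0", {
  cv <- make_curves(TAX = seq(0, 10, length.out = 7))
  norm <- normalize_polymerization(cv, "TAX")
  expect_equal(norm$value_pct[7], 100)
  expect_equal(norm$value_pct[1], 0)

  cv2 <- make_curves(TAX = seq(2, 12, length.out = 7), FLAT = rep(2, 7))
  norm2 <- normalize_polymerization(cv2, "TAX")
  expect_true(all(norm2$value_pct[norm2$condition == "FLAT"] == 0))

  expect_error(normalize_polymerization(make_curves(TAX = rep(5, 7)), "TAX"),
               "degenerate")
  expect_error(normalize_polymerization(cv, "MISSING"), "not present")
})

test_that("normalization equals the closed-form affine transform", {
  pz <- gen_polymerization(v_true = 2.0, plateau = 40, noise_sd = 0,
                           seed = 5)
  tr <- attr(pz, "truth")$transform
  norm <- normalize_polymerization(pz, "TAX")
  # invert the generator's AU mapping (gain 3, offset 50) analytically
  pct <- (pz$reading_au - 50) / 3
  expected <- 100 * (pct - tr[["pmin"]]) / (tr[["ref_end"]] - tr[["pmin"]])
  expect_equal(norm$value_pct, expected, tolerance = 1e-9)
})

test_that("normalization cancels gain and offset of the raw readings", {
  pz <- gen_polymerization(v_true = 2.5, plateau = 30, noise_sd = 0,
                           seed = 6)
  n1 <- normalize_polymerization(pz, "TAX")
  pz2 <- pz
  pz2$reading_au <- 7.3 * pz$reading_au - 120
  n2 <- normalize_polymerization(pz2, "TAX")
  expect_equal(n1$value_pct, n2$value_pct, tolerance = 1e-9)
})

test_that("curve statistics recover slopes and end points", {
  tt <- seq(0, 30, by = 1)
  st <- curve_stats(tt, tt)          # 0 -> 30% over 30 min
  expect_equal(st$vmax, 1.0)
  expect_equal(st$mep, 30)

  st2 <- curve_stats(tt, rep(20, length(tt)))
  expect_equal(st2$vmax, 0)
  expect_equal(st2$mep, 20)

  expect_error(curve_stats(c(0, 1), c(1, 2), window = 3), "at least")
  expect_error(curve_stats(c(0, 0, 1), c(1, 2, 3)), "increasing")
})

test_that("Vmax approximates the analytic logistic slope at 30-s sampling", {
  pz <- gen_polymerization(v_true = 2.8, plateau = 35, noise_sd = 0,
                           seed = 1, n_timepoints = 61)
  tab <- polymerization_table(pz)
  truth <- attr(pz, "truth")
  for (cd in tab$condition) {
    expect_equal(tab$vmax[tab$condition == cd],
                 unname(truth$vmax_norm[cd]), tolerance = 0.05)
    expect_equal(tab$mep[tab$condition == cd],
                 unname(truth$mep_norm[cd]), tolerance = 1e-6)
  }
})

test_that("fold changes are exact ratios with an identity control", {
  dmso <- list(vmax = 1.0, mep = 20.5)
  expect_equal(fold_changes(dmso, dmso)$fc_vmax, 1.0)
  expect_equal(fold_changes(dmso, dmso)$fc_mep, 1.0)
  fc <- fold_changes(list(vmax = 2.8, mep = 34.5), dmso)
  expect_equal(round(fc$fc_mep, 1), 1.7)
  fc2 <- fold_changes(list(vmax = 0.4, mep = 10.2), dmso)
  expect_equal(round(fc2$fc_mep, 1), 0.5)
  expect_equal(fc2$classification, "suppressor")
  expect_error(fold_changes(dmso, list(vmax = 0, mep = 1)), "zero")
})

test_that("planted MEP fold changes are recovered from noisy runs", {
  pz <- gen_polymerization(v_true = 2.8, fc_mep_target = 1.7,
                           noise_sd = 0.01, seed = 3)
  tab <- polymerization_table(pz)
  expect_equal(tab$fc_mep[tab$condition == "TEST"], 1.7, tolerance = 0.1)
})

test_that("phenotype scores are total abnormalities per cell", {
  expect_equal(phenotype_score(c(0, 0, 0, 0), 100), 0)
  expect_equal(phenotype_score(c(10, 5, 3, 2), 20), 1.0)
  expect_equal(phenotype_score(c(1, 0, 0, 0), 1), 1.0)
  expect_error(phenotype_score(c(1, 2), 0), "positive")
  # linear and scale-invariant
  expect_equal(phenotype_score(3 * c(2, 1), 3 * 10),
               phenotype_score(c(2, 1), 10))
})

test_that("polymer state proportions sum to one and respect bounds", {
  expect_equal(unname(polymer_state_proportions(50, 100)), c(0.5, 0.5))
  expect_equal(unname(polymer_state_proportions(0, 10)), c(0, 1))
  expect_error(polymer_state_proportions(11, 10), "n_polymerized")
  set.seed(5)
  draw <- rbinom(1, 627, 0.3)
  p <- polymer_state_proportions(draw, 627)
  ci <- qbinom(c(0.025, 0.975), 627, 0.3) / 627
  expect_gte(p[["polymerized"]], ci[1])
  expect_lte(p[["polymerized"]], ci[2])
})

test_that("growth EC50 interpolates linearly in log10 concentration", {
  v <- 2
  tt <- 0:10
  series <- rbind(
    data.frame(time_h = tt, concentration_um = 10,
               confluence_pct = 20 + 0.9 * v * tt),
    data.frame(time_h = tt, concentration_um = 100,
               confluence_pct = 20 + 0.1 * v * tt)
  )
  vehicle <- data.frame(time_h = tt, confluence_pct = 20 + v * tt)
  res <- growth_ec50(series, vehicle)
  expect_true(res$assigned)
  expect_equal(res$ec50, 10^1.5, tolerance = 1e-9)
})

test_that("growth EC50 is not assigned without a bracket or positive vehicle", {
  tt <- 0:10
  series <- rbind(
    data.frame(time_h = tt, concentration_um = 10,
               confluence_pct = 20 + 1.9 * tt),
    data.frame(time_h = tt, concentration_um = 100,
               confluence_pct = 20 + 1.8 * tt)
  )
  vehicle <- data.frame(time_h = tt, confluence_pct = 20 + 2 * tt)
  res <- growth_ec50(series, vehicle)
  expect_false(res$assigned)
  expect_match(res$reason, "bracket")

  res2 <- growth_ec50(series,
                      data.frame(time_h = tt, confluence_pct = 20 - tt))
  expect_false(res2$assigned)
  expect_match(res2$reason, "vehicle")
})

test_that("growth EC50 is equivariant to concentration units", {
  cs <- gen_cell_series(ec50_true = 25, noise = 0, seed = 9)
  r1 <- growth_ec50(cs$growth, cs$vehicle)
  g2 <- cs$growth
  g2$concentration_um <- g2$concentration_um * 1000
  r2 <- growth_ec50(g2, cs$vehicle)
  expect_equal(r2$ec50 / r1$ec50, 1000, tolerance = 1e-6)
})

test_that("death EC50 recovers exact 4PL data to high precision", {
  doses <- 10^seq(-0.5, 3, by = 0.5)
  y <- 1 / (1 + (50 / doses)^1)
  res <- death_ec50(doses, y)
  expect_true(res$assigned)
  expect_equal(res$ec50, 50, tolerance = 1e-6)
})

test_that("death EC50 refuses flat or underdetermined inputs", {
  doses <- 10^seq(-0.5, 3, by = 0.5)
  flat <- death_ec50(doses, rep(0.03, length(doses)))
  expect_false(flat$assigned)
  few <- death_ec50(c(1, 10, 100), c(0.1, 0.5, 0.9))
  expect_false(few$assigned)
  expect_match(few$reason, "fewer than 4")
})
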