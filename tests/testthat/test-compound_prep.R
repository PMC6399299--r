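test_that("Lipinski violations are counted rule by rule", {
  expect_equal(lipinski_violations(300, 2, 1, 4), 0L)
  # paclitaxel-like descriptors: MW and HBA rules violated
  expect_equal(lipinski_violations(853.9, 3.0, 4, 14), 2L)
  expect_equal(lipinski_violations(501, 5.01, 6, 11), 4L)
  expect_error(lipinski_violations(NA, 2, 1, 4), "mw")
})

test_that("the drug-like filter applies <2 violations plus the MW window", {
  tab <- data.frame(
    ligand_id = c("small", "one_viol", "clean", "two_viol"),
    mw = c(150, 600, 300, 600),
    logp = c(1, 2, 2, 6),
    hbd = c(0, 1, 1, 1),
    hba = c(2, 4, 4, 4)
  )
  kept <- druglike_filter(tab)
  expect_setequal(kept$ligand_id, c("one_viol", "clean"))
})

test_that("the filter recovers the generator's planted drug-like set", {
  tab <- gen_compound_table(200, druglike_fraction = 0.4, seed = 3)
  kept <- druglike_filter(tab)
  expect_equal(nrow(kept), 80L)
  expect_setequal(kept$ligand_id, attr(tab, "truth")$druglike_ids)
})

test_that("dedup keeps the first record per structure key", {
  tab <- data.frame(ligand_id = c("a", "b", "c"),
                    structure_key = c("K1", "K1", "K2"))
  out <- dedupe_by_key(tab)
  expect_equal(out$ligand_id, c("a", "c"))
  expect_identical(dedupe_by_key(out), out)
  expect_error(dedupe_by_key(data.frame(structure_key = c("K1", ""))),
               "empty")

  gen <- gen_compound_table(100, druglike_fraction = 1, dup_fraction = 0.25,
                            seed = 3)
  expect_equal(nrow(dedupe_by_key(gen)), 75L)
})

test_that("filter and dedup commute on the surviving key set", {
  tab <- gen_compound_table(120, druglike_fraction = 0.6,
                            dup_fraction = 0.2, seed = 11)
  k1 <- sort(dedupe_by_key(druglike_filter(tab))$structure_key)
  k2 <- sort(druglike_filter(dedupe_by_key(tab))$structure_key)
  expect_identical(k1, k2)
})

test_that("Ki conversion matches the Boltzmann relation", {
  expect_equal(ki_from_docking(0), 1.0)
  expect_equal(ki_from_docking(-1.9872036e-3 * 300), exp(-1),
               tolerance = 1e-12)
  # monotone and log-linear with slope 1/(RT)
  dg <- seq(-10, 0, by = 0.5)
  ki <- ki_from_docking(dg)
  expect_true(all(diff(ki) > 0))
  slopes <- diff(log(ki)) / diff(dg)
  expect_equal(slopes, rep(1 / (1.9872036e-3 * 300), length(slopes)),
               tolerance = 1e-9)
  expect_error(ki_from_docking(NaN), "non-finite")
})

test_that("the docking confidence filter is strict at -6 kcal/mol", {
  rec <- data.frame(ligand_id = c("at", "below"),
                    delta_g = c(-6.0, -6.1))
  out <- docking_confidence_filter(rec)
  expect_equal(out$ligand_id, "below")
  expect_equal(out$ki, ki_from_docking(-6.1))

  gen <- gen_docking_table(10, n_confident = 4, seed = 2)
  out <- docking_confidence_filter(gen)
  expect_setequal(out$ligand_id, attr(gen, "truth")$confident_ids)
})

test_that("target enrichment counts descend with alphabetical ties", {
  hits <- data.frame(target = c("ER", "ER", "ER", "TUB"))
  out <- target_enrichment(hits)
  expect_equal(out$target_family, c("ER", "TUB"))
  expect_equal(out$ligand_count, c(3L, 1L))

  out <- target_enrichment(data.frame(target = rep(NA_character_, 5)))
  expect_equal(out$target_family, "other")
  expect_equal(out$ligand_count, 5L)

  set.seed(77)
  fams <- sample(c("ER", "TUB", "MAPK14", "DHODH"), 36, replace = TRUE,
                 prob = c(12, 4, 4, 3) / 23)
  out <- target_enrichment(data.frame(target_family = fams))
  expect_equal(sum(out$ligand_count), 36L)
  expect_equal(out$ligand_count,
               sort(as.integer(table(fams)), decreasing = TRUE))
})
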