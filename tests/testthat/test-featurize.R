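test_that("the default schema has 80 uniquely named descriptors x 6 shells", {
  sc <- default_schema()
  expect_equal(length(sc$descriptor_names), 80L)
  expect_false(anyDuplicated(sc$descriptor_names) > 0)
  expect_equal(sc$total_length, sc$shell_count * 80L)
})

# Hand-built single-residue models for centroid checks.
two_atom_model <- function(xyz_list, resid = "CYS",
                           elety = c("CB", "SG")) {
  rows <- lapply(seq_along(xyz_list), function(i) {
    data.frame(record = "ATOM", elety = elety[i], element = "C",
               chain = "A", resno = 1L, insert = "", resid = resid,
               x = xyz_list[[i]][1], y = xyz_list[[i]][2],
               z = xyz_list[[i]][3], occupancy = 1, is_heavy = TRUE)
  })
  structure(list(structure_id = "hand", model_number = 1L,
                 atoms = do.call(rbind, rows)),
            class = "structure_model")
}

test_that("residue centers follow the side-chain centroid rule", {
  m <- two_atom_model(list(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unname(residue_center(m, list(chain = "A", resno = 1L))),
               c(1, 0, 0))

  gly <- two_atom_model(list(c(1, 2, 3)), resid = "GLY", elety = "CA")
  expect_equal(unname(residue_center(gly, list(chain = "A", resno = 1L))),
               c(1, 2, 3))

  # ASP side chain with 4 heavy atoms at known coordinates
  coords <- list(c(0, 0, 0), c(1, 1, 0), c(2, 0, 1), c(3, 1, 1))
  asp <- two_atom_model(coords, resid = "ASP",
                        elety = c("CB", "CG", "OD1", "OD2"))
  expected <- colMeans(do.call(rbind, coords))
  expect_equal(unname(residue_center(asp, list(chain = "A", resno = 1L))),
               unname(expected))
})

test_that("an empty microenvironment gives an all-zero vector", {
  m <- gen_toy_complex(3, 0, seed = 1)
  me <- featurize_microenvironment(m, c(500, 500, 500))
  expect_equal(length(me$values), 480L)
  expect_true(all(me$values == 0))
  expect_true(all(me$bits == 0))
})

test_that("a single nearby carbon lands in shell 1 element counts", {
  m <- two_atom_model(list(c(0.5, 0, 0)), resid = "ALA", elety = "CB")
  me <- featurize_microenvironment(m, c(0, 0, 0))
  v <- me$values
  expect_equal(unname(v["s1.elem.C"]), 1)
  expect_equal(unname(v["s1.heavy.total"]), 1)
  expect_equal(sum(v[grep("elem\\.", names(v))]), 1)
  expect_equal(sum(v[grep("heavy.total", names(v), fixed = TRUE)]), 1)
})

test_that("shell assignment matches a brute-force binning oracle", {
  set.seed(9)
  m <- gen_toy_complex(8, 2, seed = 9)
  ctr <- residue_center(m, residue_table(m)[3, ])
  me <- featurize_microenvironment(m, ctr)
  at <- m$atoms[m$atoms$record == "ATOM" & m$atoms$is_heavy, ]
  d <- sqrt((at$x - ctr[1])^2 + (at$y - ctr[2])^2 + (at$z - ctr[3])^2)
  for (k in 1:6) {
    in_shell <- sum(d > (k - 1) & d <= k & d > 1e-9)
    expect_equal(unname(me$values[paste0("s", k, ".heavy.total")]),
                 in_shell)
  }
  # partition property: shell totals sum to all heavy atoms within 6 A
  expect_equal(sum(me$values[grep("heavy.total", names(me$values),
                                  fixed = TRUE)]),
               sum(d > 1e-9 & d <= 6))
})

test_that("binarization counts strictly positive entries", {
  sc <- default_schema()
  expect_true(all(binarize(numeric(480), sc) == 0))
  v <- numeric(480)
  v[1:3] <- c(0, 1, 7)
  expect_equal(binarize(v, sc)[1:3], c(0L, 1L, 1L))
  set.seed(4)
  r <- abs(rnorm(480)) * rbinom(480, 1, 0.5)
  expect_equal(sum(binarize(r, sc)), sum(r > 0))
  expect_error(binarize(numeric(481), sc), "multiple")
})

test_that("pocket featurization preserves order, cardinality, determinism", {
  m <- gen_toy_complex(5, 2, seed = 6)
  pk <- extract_pocket(m, list_ligand_instances(m)[1, ])
  fs1 <- featurize_pocket(m, pk)
  fs2 <- featurize_pocket(m, pk)
  expect_equal(nrow(fs1$values), 5L)
  expect_equal(ncol(fs1$values), 480L)
  expect_identical(fs1$residue_refs,
                   paste0(pk$residues$chain, ":", pk$residues$resno,
                          pk$residues$insert, "/", pk$residues$resid))
  expect_identical(fs1$values, fs2$values)
})

test_that("descriptors are invariant to rigid motion", {
  m <- gen_toy_complex(6, 1, seed = 8)
  fs <- toy_featureset(m)
  fst <- toy_featureset(transform_model(m, angle = 1.1, shift = c(-7, 2, 9)))
  expect_lt(max(abs(fs$values - fst$values)), 1e-9)
})

test_that("the co-crystal ligand does not contribute to descriptors", {
  m <- gen_toy_complex(4, 0, seed = 10)
  fs1 <- toy_featureset(m)
  # doubling the ligand atom count must not change any residue vector
  m2 <- m
  extra <- m2$atoms[m2$atoms$record == "HETATM", ]
  extra$resno <- 901L
  m2$atoms <- rbind(m2$atoms, extra)
  lig <- attr(m, "truth")$ligand
  fs2 <- featurize_pocket(m2, extract_pocket(m2, lig))
  expect_identical(fs1$values, fs2$values)
})

test_that("feature sets from different schemas cannot be compared", {
  m <- gen_toy_complex(3, 0, seed = 2)
  fs <- toy_featureset(m)
  other <- fs
  other$schema_id <- "other-v9"
  expect_error(align_pockets(fs, other), "schema mismatch")
})

test_that("feature sets serialize to JSON and TSV", {
  m <- gen_toy_complex(3, 0, seed = 2)
  fs <- toy_featureset(m)
  jp <- tempfile(fileext = ".json")
  write_featureset(fs, jp, "json")
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$schema_id, fs$schema_id)
  expect_equal(length(back$values), 3L)
  tp <- tempfile(fileext = ".tsv")
  write_featureset(fs, tp, "tsv")
  tsv <- read.table(tp, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(dim(tsv), c(3L, 481L))
})
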