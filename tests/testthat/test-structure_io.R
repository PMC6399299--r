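minimal_ala_pdb <- paste(
  c("ATOM      1  N   ALA A   1      10.000  10.000  10.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.000  10.000  10.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.000  10.000  10.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      11.000  11.000  10.000  1.00  0.00           C",
    "END"),
  collapse = "\n")

test_that("a minimal PDB parses into one residue with five atoms", {
  m <- parse_structure(minimal_ala_pdb, "pdb")
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 5L)
  res <- residue_table(m)
  expect_equal(nrow(res), 1L)
  expect_equal(res$resid, "ALA")
  expect_true(all(m$atoms$is_heavy))
})

test_that("alternate locations resolve to the highest occupancy", {
  altloc_pdb <- paste(
    c("ATOM      1  N   ALA A   1      10.000  10.000  10.000  1.00  0.00           N",
      "ATOM      2  CA AALA A   1      11.000  10.000  10.000  0.60  0.00           C",
      "ATOM      3  CA BALA A   1      11.500  10.000  10.000  0.40  0.00           C",
      "ATOM      4  C   ALA A   1      12.000  10.000  10.000  1.00  0.00           C",
      "ATOM      5  O   ALA A   1      13.000  10.000  10.000  1.00  0.00           O",
      "END"),
    collapse = "\n")
  m <- parse_structure(altloc_pdb, "pdb")
  ca <- m$atoms[m$atoms$elety == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$occupancy, 0.6)
  expect_equal(ca$x, 11.0)
})

test_that("parse errors are informative", {
  expect_error(parse_structure(tempfile(fileext = ".pdb"), "pdb"),
               "failed to parse")
})

test_that("generated complexes survive a PDB round trip", {
  m <- gen_toy_complex(8, 2, seed = 1)
  path <- tempfile(fileext = ".pdb")
  structure_to_pdb(m, path)
  m2 <- parse_structure(path, "pdb")
  expect_equal(nrow(residue_table(m2)), nrow(residue_table(m)))
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_lt(max(abs(m2$atoms$x - m$atoms$x),
                abs(m2$atoms$y - m$atoms$y),
                abs(m2$atoms$z - m$atoms$z)), 1e-3)
})

test_that("ligand enumeration excludes solvent, additives and fragments", {
  base <- gen_toy_complex(3, 0, seed = 5)
  hoh <- toy_row <- base$atoms[base$atoms$record == "HETATM", ][1, ]
  hoh$resid <- "HOH"; hoh$resno <- 950L; hoh$element <- "O"
  m <- base
  m$atoms <- rbind(m$atoms, hoh)
  lig <- list_ligand_instances(m)
  expect_equal(lig$het_code, "LIG")

  gol <- base$atoms[base$atoms$record == "HETATM", ][1:6, ]
  gol$resid <- "GOL"; gol$resno <- 951L
  m$atoms <- rbind(m$atoms, gol)
  expect_false("GOL" %in% list_ligand_instances(m)$het_code)
})

test_that("the minimum heavy-atom count gates ligand enumeration", {
  base <- gen_toy_complex(2, 0, seed = 7, n_ligand_atoms = 12)
  het <- base$atoms[base$atoms$record == "HETATM", ]
  small5 <- het[1:5, ]; small5$resid <- "LG5"; small5$resno <- 901L
  small6 <- het[1:6, ]; small6$resid <- "LG6"; small6$resno <- 902L
  m <- base
  m$atoms <- rbind(m$atoms, small5, small6)
  lig <- list_ligand_instances(m, min_heavy_atoms = 6L)
  expect_setequal(lig$het_code, c("LIG", "LG6"))
})

test_that("pocket membership is inclusive at the cutoff and strict beyond", {
  m <- gen_toy_complex(8, 0, seed = 1,
                       distances = c(3, 4, 5, 5.5, 5.9, 6.0, 6.1, 10))
  lig <- list_ligand_instances(m)[1, ]
  pk <- extract_pocket(m, lig, cutoff = 6.0)
  expect_equal(nrow(pk$residues), 6L)   # 6.0 in, 6.1 and 10 out
  expect_true(all(pk$residues$resno %in% 1:6))
})

test_that("pockets are monotone in the cutoff and exclude hetero groups", {
  m <- gen_toy_complex(6, 4, seed = 11)
  lig <- list_ligand_instances(m)[1, ]
  prev <- character(0)
  for (cutoff in c(3, 4.5, 6, 8, 12)) {
    pk <- extract_pocket(m, lig, cutoff = cutoff)
    keys <- paste(pk$residues$chain, pk$residues$resno)
    expect_true(all(prev %in% keys))
    prev <- keys
  }
  # ligand's own residue never a member
  pk <- extract_pocket(m, lig, cutoff = 50)
  expect_false(any(pk$residues$resno == 900))
})

test_that("pocket extraction is rigid-motion invariant and deterministic", {
  m <- gen_toy_complex(7, 3, seed = 3)
  lig <- list_ligand_instances(m)[1, ]
  pk1 <- extract_pocket(m, lig)
  pk2 <- extract_pocket(m, lig)
  expect_identical(pk1$residues$resno, pk2$residues$resno)
  mt <- transform_model(m)
  pk3 <- extract_pocket(mt, lig)
  expect_identical(pk1$residues$resno, pk3$residues$resno)
})

test_that("pocket serialization writes JSON and TSV", {
  m <- gen_toy_complex(5, 0, seed = 2)
  pk <- extract_pocket(m, list_ligand_instances(m)[1, ])
  jp <- tempfile(fileext = ".json")
  write_pocket(pk, jp, "json")
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$pocket_id, pk$pocket_id)
  expect_equal(nrow(back$residues), nrow(pk$residues))
  tp <- tempfile(fileext = ".tsv")
  write_pocket(pk, tp, "tsv")
  tsv <- read.table(tp, header = TRUE, sep = "\t")
  expect_equal(tsv$seq_number, pk$residues$resno)
})
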