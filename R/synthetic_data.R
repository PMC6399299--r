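#' Synthetic data generators
#'
#' Every pipeline stage can be exercised on generated inputs with known
#' ground truth: toy protein-ligand complexes with planted ligand-residue
#' distances, perturbed pocket copies for planted-similarity recovery,
#' compound tables with known filter/dedupe survivors, logistic
#' polymerization curves with analytic Vmax/MEP, and dose-response growth
#' and death series with planted EC50s. All generators are deterministic
#' under a fixed seed and attach their ground truth as the `"truth"`
#' attribute of the returned object.
#'
#' @name synthetic_data
NULL

unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

perp_vector <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * u) * u
  v / sqrt(sum(v^2))
}

toy_atom_row <- function(record, elety, element, chain, resno, resid, xyz) {
  data.frame(record = record, elety = elety, element = element,
             chain = chain, resno = resno, insert = "", resid = resid,
             x = xyz[1], y = xyz[2], z = xyz[3], occupancy = 1,
             is_heavy = !(element %in% c("H", "D")),
             stringsAsFactors = FALSE)
}

# Place one residue so that its minimum heavy-atom distance to the ligand
# is exactly `dist`: the anchor atom (CB, or CA for glycine) sits at
# L* + dist * u where L* is the ligand atom farthest along u; every other
# atom is displaced from the anchor with a non-negative radial component.
place_residue <- function(resid, resno, dist, lig_xyz, chain = "A") {
  u <- unit_vector()
  t1 <- perp_vector(u)
  proj <- as.vector(lig_xyz %*% u)
  lstar <- lig_xyz[which.max(proj), ]
  anchor <- lstar + dist * u
  side <- SIDECHAIN_ATOMS[[resid]]
  atom_names <- c(names(BACKBONE_ATOMS), names(side))
  elements <- c(unname(BACKBONE_ATOMS), unname(side))
  anchor_name <- if (length(side) > 0L) names(side)[1] else "CA"
  rows <- list()
  k <- 0
  for (i in seq_along(atom_names)) {
    nm <- atom_names[i]
    if (nm == anchor_name) {
      xyz <- anchor
    } else {
      k <- k + 1
      alpha <- 0.25 + 0.45 * k + runif(1, 0, 0.2)
      beta <- runif(1, -1, 1)
      xyz <- anchor + alpha * u + beta * t1
    }
    rows[[i]] <- toy_atom_row("ATOM", nm, elements[i], chain, resno, resid,
                              xyz)
  }
  do.call(rbind, rows)
}

#' Generate a toy protein-ligand complex
#'
#' One compact hetero ligand near the origin, `n_pocket_residues` residues
#' whose nearest heavy atom lies at a planted distance at or below the
#' pocket cutoff, and `n_decoy_residues` residues planted beyond 7
#' Angstrom. Residue types are sampled uniformly from the 20 standard
#' amino acids; geometry is minimal (backbone plus side-chain pseudo-atoms
#' with correct element labels).
#'
#' @param n_pocket_residues Number of pocket residues (>= 1).
#' @param n_decoy_residues Number of beyond-cutoff residues.
#' @param seed RNG seed.
#' @param distances Optional planted pocket distances (Angstrom, recycled
#'   to `n_pocket_residues`); default sampled in \[3, 6\].
#' @param decoy_distances Optional planted decoy distances; default
#'   sampled in \[7.2, 12\].
#' @param n_ligand_atoms Ligand heavy-atom count (default 8).
#' @param ligand_het Het code of the ligand (default `"LIG"`).
#' @param structure_id Model identifier.
#' @return A `structure_model` with a `"truth"` attribute (planted
#'   distances, residue keys and types).
#' @export
gen_toy_complex <- function(n_pocket_residues, n_decoy_residues = 0L,
                            seed = 1L, distances = NULL,
                            decoy_distances = NULL, n_ligand_atoms = 8L,
                            ligand_het = "LIG", structure_id = "toy") {
  stopifnot(n_pocket_residues >= 1L)
  set.seed(seed)
  lig_xyz <- rbind(c(0, 0, 0),
                   matrix(runif(3L * (n_ligand_atoms - 1L), -0.5, 0.5),
                          ncol = 3))
  lig_elem <- c("C", "O", "N", rep("C", max(0L, n_ligand_atoms - 3L)))
  lig_elem <- lig_elem[seq_len(n_ligand_atoms)]
  lig_rows <- lapply(seq_len(n_ligand_atoms), function(i) {
    toy_atom_row("HETATM", paste0("C", i), lig_elem[i], "X", 900L,
                 ligand_het, lig_xyz[i, ])
  })
  if (is.null(distances)) {
    distances <- runif(n_pocket_residues, 3, 6)
  }
  distances <- rep_len(distances, n_pocket_residues)
  if (n_decoy_residues > 0L) {
    if (is.null(decoy_distances)) {
      decoy_distances <- runif(n_decoy_residues, 7.2, 12)
    }
    decoy_distances <- rep_len(decoy_distances, n_decoy_residues)
  } else {
    decoy_distances <- numeric(0)
  }
  all_dist <- c(distances, decoy_distances)
  types <- sample(AA3, length(all_dist), replace = TRUE)
  res_rows <- lapply(seq_along(all_dist), function(i) {
    place_residue(types[i], i, all_dist[i], lig_xyz)
  })
  atoms <- do.call(rbind, c(res_rows, lig_rows))
  rownames(atoms) <- NULL
  model <- structure(
    list(structure_id = structure_id, model_number = 1L, atoms = atoms),
    class = "structure_model"
  )
  attr(model, "truth") <- list(
    seed = seed,
    pocket_keys = residue_key("A", seq_len(n_pocket_residues), ""),
    pocket_distances = distances,
    decoy_distances = decoy_distances,
    residue_types = types,
    ligand = list(het_code = ligand_het, chain = "X", resno = 900L)
  )
  model
}

#' Render a structure model as PDB text
#'
#' Fixed-format ATOM/HETATM records (occupancy, B-factor 0, element
#' column), terminated by TER/END. Output re-parses through
#' [parse_structure()] without loss.
#'
#' @param model A `structure_model`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when written to file).
#' @export
structure_to_pdb <- function(model, path = NULL) {
  at <- model$atoms
  lines <- vapply(seq_len(nrow(at)), function(i) {
    sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            at$record[i], i,
            if (nchar(at$elety[i]) < 4L) paste0(" ", at$elety[i])
            else at$elety[i],
            " ", at$resid[i],
            if (at$chain[i] == " ") "A" else at$chain[i],
            at$resno[i],
            if (nzchar(at$insert[i])) at$insert[i] else " ",
            at$x[i], at$y[i], at$z[i], at$occupancy[i], 0,
            at$element[i])
  }, character(1))
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Perturb a toy complex
#'
#' Adds Gaussian coordinate jitter to every atom and relabels a random
#' fraction of polymer residues to a different random amino-acid type
#' (side-chain atoms are regenerated around the old side-chain centroid).
#'
#' @param model A `structure_model`.
#' @param jitter_sd Coordinate noise SD (Angstrom).
#' @param relabel_fraction Fraction of polymer residues to relabel.
#' @param seed RNG seed.
#' @return A perturbed `structure_model`; `"truth"` records the relabeled
#'   residue keys.
#' @export
perturb_pocket <- function(model, jitter_sd = 0, relabel_fraction = 0,
                           seed = 1L) {
  stopifnot(jitter_sd >= 0, relabel_fraction >= 0, relabel_fraction <= 1)
  set.seed(seed)
  at <- model$atoms
  if (jitter_sd > 0) {
    at$x <- at$x + rnorm(nrow(at), 0, jitter_sd)
    at$y <- at$y + rnorm(nrow(at), 0, jitter_sd)
    at$z <- at$z + rnorm(nrow(at), 0, jitter_sd)
  }
  res <- unique(at[at$record == "ATOM",
                   c("chain", "resno", "insert", "resid")])
  n_rel <- round(relabel_fraction * nrow(res))
  relabeled <- character(0)
  if (n_rel > 0L) {
    pick <- sample(nrow(res), n_rel)
    for (i in pick) {
      old <- res$resid[i]
      new <- sample(setdiff(AA3, old), 1L)
      sel <- at$record == "ATOM" & at$chain == res$chain[i] &
        at$resno == res$resno[i] & at$insert == res$insert[i]
      sub <- at[sel, , drop = FALSE]
      bb <- sub[sub$elety %in% names(BACKBONE_ATOMS), , drop = FALSE]
      sc_old <- sub[!(sub$elety %in% names(BACKBONE_ATOMS)), , drop = FALSE]
      center <- if (nrow(sc_old) > 0L) {
        colMeans(as.matrix(sc_old[, c("x", "y", "z")]))
      } else {
        unlist(bb[bb$elety == "CA", c("x", "y", "z")])
      }
      side <- SIDECHAIN_ATOMS[[new]]
      sc_new <- if (length(side) > 0L) {
        do.call(rbind, lapply(seq_along(side), function(k) {
          toy_atom_row("ATOM", names(side)[k], unname(side[k]),
                       res$chain[i], res$resno[i], new,
                       center + runif(3, -1.0, 1.0))
        }))
      } else {
        NULL
      }
      bb$resid <- new
      at <- rbind(at[!sel, , drop = FALSE], bb, sc_new)
      relabeled <- c(relabeled,
                     residue_key(res$chain[i], res$resno[i], res$insert[i]))
    }
    at <- at[order(at$record == "HETATM", at$chain, at$resno), ,
             drop = FALSE]
    rownames(at) <- NULL
  }
  out <- structure(
    list(structure_id = paste0(model$structure_id, "_perturbed"),
         model_number = 1L, atoms = at),
    class = "structure_model"
  )
  truth <- attr(model, "truth")
  if (is.null(truth)) truth <- list()
  truth$jitter_sd <- jitter_sd
  truth$relabel_fraction <- relabel_fraction
  truth$relabeled_keys <- sort(relabeled)
  truth$perturb_seed <- seed
  attr(out, "truth") <- truth
  out
}

random_structure_key <- function(n) {
  vapply(seq_len(n), function(i) {
    paste0(paste(sample(LETTERS, 14, replace = TRUE), collapse = ""), "-",
           paste(sample(LETTERS, 10, replace = TRUE), collapse = ""), "-N")
  }, character(1))
}

#' Generate a compound table with known filter survivors
#'
#' Drug-like records are sampled strictly inside every Lipinski bound and
#' the 170-1000 Da window (a subset carries exactly one violation, which
#' still passes the fewer-than-2 rule); non-drug-like records either carry
#' two violations or fall outside the weight window. A fraction of records
#' are duplicates (same structure key) of earlier records.
#'
#' @param n Total records.
#' @param druglike_fraction Fraction of the unique records that are
#'   drug-like.
#' @param dup_fraction Fraction of `n` that are duplicates.
#' @param seed RNG seed.
#' @param families Target-family labels to sample for annotation.
#' @return Data frame (ligand_id, mw, logp, hbd, hba, structure_key,
#'   target_family, druglike) with a `"truth"` attribute listing planted
#'   drug-like ids, unique keys and expected filter+dedupe survivors.
#' @export
gen_compound_table <- function(n, druglike_fraction = 0.5,
                               dup_fraction = 0, seed = 1L,
                               families = c("ER", "TUB", "MAPK14",
                                            "DHODH", "other")) {
  stopifnot(druglike_fraction >= 0, druglike_fraction <= 1,
            dup_fraction >= 0, dup_fraction <= 1)
  set.seed(seed)
  empty <- data.frame(ligand_id = character(0), mw = numeric(0),
                      logp = numeric(0), hbd = integer(0),
                      hba = integer(0), structure_key = character(0),
                      target_family = character(0), druglike = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    attr(empty, "truth") <- list(druglike_ids = character(0),
                                 survivor_ids = character(0))
    return(empty)
  }
  n_dup <- round(dup_fraction * n)
  n_unique <- n - n_dup
  n_dl <- round(druglike_fraction * n_unique)
  gen_druglike <- function(m) {
    one_violation <- runif(m) < 0.3
    mw <- ifelse(one_violation, runif(m, 501, 990), runif(m, 200, 480))
    data.frame(mw = mw, logp = runif(m, -1, 4.5),
               hbd = sample(0:5, m, replace = TRUE),
               hba = sample(0:10, m, replace = TRUE))
  }
  gen_nondruglike <- function(m) {
    kind <- sample(3, m, replace = TRUE)
    mw <- ifelse(kind == 1, runif(m, 1001, 1600),
                 ifelse(kind == 2, runif(m, 60, 169), runif(m, 200, 480)))
    logp <- ifelse(kind == 3, runif(m, 5.5, 9), runif(m, -1, 4.5))
    hbd <- ifelse(kind == 3, sample(6:9, m, replace = TRUE),
                  sample(0:5, m, replace = TRUE))
    data.frame(mw = mw, logp = logp, hbd = hbd,
               hba = sample(0:10, m, replace = TRUE))
  }
  desc <- rbind(
    if (n_dl > 0L) cbind(gen_druglike(n_dl), druglike = TRUE),
    if (n_unique - n_dl > 0L)
      cbind(gen_nondruglike(n_unique - n_dl), druglike = FALSE)
  )
  desc$structure_key <- random_structure_key(n_unique)
  desc$target_family <- sample(families, n_unique, replace = TRUE,
                               prob = c(0.35, 0.15, 0.12, 0.08, 0.3))
  desc <- desc[sample(n_unique), , drop = FALSE]
  if (n_dup > 0L) {
    src <- sample(n_unique, n_dup, replace = TRUE)
    desc <- rbind(desc, desc[src, , drop = FALSE])
  }
  desc$ligand_id <- sprintf("CMP%05d", seq_len(n))
  rownames(desc) <- NULL
  out <- desc[, c("ligand_id", "mw", "logp", "hbd", "hba",
                  "structure_key", "target_family", "druglike")]
  surv <- out[out$druglike & !duplicated(out$structure_key), , drop = FALSE]
  attr(out, "truth") <- list(
    druglike_ids = out$ligand_id[out$druglike],
    n_unique = n_unique,
    survivor_ids = surv$ligand_id,
    survivor_keys = surv$structure_key,
    seed = seed
  )
  out
}

#' Generate a docking-score table with planted high-confidence binders
#'
#' @param n Total records.
#' @param n_confident Records with docking score strictly below the
#'   cutoff.
#' @param seed RNG seed.
#' @param cutoff Confidence cutoff (kcal/mol).
#' @return Data frame (ligand_id, delta_g) with `"truth"` listing the
#'   planted confident ids.
#' @export
gen_docking_table <- function(n, n_confident, seed = 1L, cutoff = -6) {
  stopifnot(n_confident <= n)
  set.seed(seed)
  dg <- c(runif(n_confident, cutoff - 6, cutoff - 0.1),
          runif(n - n_confident, cutoff + 0.1, cutoff + 4))
  conf <- c(rep(TRUE, n_confident), rep(FALSE, n - n_confident))
  ord <- sample(n)
  out <- data.frame(ligand_id = sprintf("DCK%04d", seq_len(n)),
                    delta_g = dg[ord], stringsAsFactors = FALSE)
  attr(out, "truth") <- list(confident_ids = out$ligand_id[conf[ord]],
                             seed = seed)
  out
}

logistic_pct <- function(t, vmax, plateau, t0) {
  plateau / (1 + exp(-4 * vmax * (t - t0) / plateau))
}

#' Generate a tubulin polymerization run with known statistics
#'
#' Logistic curves in percent units whose analytic maximum slope equals the
#' planted Vmax: a paclitaxel-like reference (plateau defines 100% after
#' normalization), a DMSO-like control, and one test condition. Curves are
#' emitted in arbitrary fluorescence units through an affine gain/offset
#' plus optional Gaussian noise; the ground truth carries the exact
#' statistics of the normalized noiseless curves.
#'
#' @param v_true Test-condition max slope (%/min, percent scale).
#' @param plateau Test-condition plateau (%); ignored when
#'   `fc_mep_target` is given (the plateau is then solved so the planted
#'   MEP fold change equals the target).
#' @param noise_sd Reading noise as a fraction of the 100% span.
#' @param n_timepoints Samples over the 30-min window (default 61, i.e.
#'   30-second sampling).
#' @param seed RNG seed.
#' @param fc_mep_target Optional planted MEP fold change vs DMSO.
#' @param ref,dmso Reference / control parameters (vmax, plateau, t0).
#' @param t0 Test-curve inflection time (min).
#' @return Long data frame (time_min, condition, reading_au) with
#'   conditions TAX, DMSO, TEST and a `"truth"` attribute (normalized
#'   vmax/mep per condition, fold changes, transform constants).
#' @export
gen_polymerization <- function(v_true = 2.8, plateau = 35,
                               noise_sd = 0, n_timepoints = 61L,
                               seed = 1L, fc_mep_target = NULL,
                               ref = list(vmax = 5.8, plateau = 100,
                                          t0 = 8),
                               dmso = list(vmax = 1.0, plateau = 20.5,
                                           t0 = 10),
                               t0 = 10) {
  stopifnot(plateau > 0, v_true > 0)
  set.seed(seed)
  times <- seq(0, 30, length.out = n_timepoints)
  pct <- function(pl) {
    list(
      TAX = logistic_pct(times, ref$vmax, ref$plateau, ref$t0),
      DMSO = logistic_pct(times, dmso$vmax, dmso$plateau, dmso$t0),
      TEST = logistic_pct(times, v_true, pl, t0)
    )
  }
  norm_mep <- function(pl) {
    p <- pct(pl)
    pmin_ <- min(unlist(p))
    ref_end <- p$TAX[n_timepoints]
    fc <- (p$TEST[n_timepoints] - pmin_) / (p$DMSO[n_timepoints] - pmin_)
    fc
  }
  if (!is.null(fc_mep_target)) {
    plateau <- uniroot(function(pl) norm_mep(pl) - fc_mep_target,
                       interval = c(0.5, 400))$root
  }
  p <- pct(plateau)
  pmin_ <- min(unlist(p))
  ref_end <- p$TAX[n_timepoints]
  scale_ <- 100 / (ref_end - pmin_)
  vmaxes <- c(TAX = ref$vmax, DMSO = dmso$vmax, TEST = v_true)
  truth <- list(
    conditions = names(p),
    vmax_norm = vmaxes * scale_,
    mep_norm = vapply(p, function(x) (x[n_timepoints] - pmin_) * scale_,
                      numeric(1)),
    plateau_test = plateau,
    transform = c(pmin = pmin_, ref_end = ref_end, scale = scale_),
    seed = seed
  )
  truth$fc_vmax <- truth$vmax_norm / truth$vmax_norm[["DMSO"]]
  truth$fc_mep <- truth$mep_norm / truth$mep_norm[["DMSO"]]
  gain <- 3
  offset <- 50
  rows <- lapply(names(p), function(cd) {
    au <- offset + gain * p[[cd]] +
      rnorm(n_timepoints, 0, noise_sd * gain * 100)
    data.frame(time_min = times, condition = cd, reading_au = au,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate live-cell growth and death series with planted EC50s
#'
#' Per-dose growth slopes follow a four-parameter logistic in log dose with
#' midpoint `ec50_true` (slope at the EC50 is half the vehicle slope);
#' dead-cell fractions at fixed times follow a 4PL from 0 to 1 with
#' midpoints `ec50_death`. Gaussian noise on confluence readings and death
#' fractions.
#'
#' @param ec50_true Proliferation EC50 (uM).
#' @param hill Hill slope of both dose responses.
#' @param vehicle_slope Vehicle growth rate (confluence %/h).
#' @param noise Confluence noise SD as a fraction of the vehicle growth
#'   span; also the death-fraction noise SD (absolute).
#' @param doses Concentrations (uM).
#' @param seed RNG seed.
#' @param ec50_death Named or length-2 vector of death EC50s for 24 h and
#'   48 h (defaults to `ec50_true * c(2, 1.5)`).
#' @param times_h Growth sampling times (h).
#' @param death_reps Replicates per dose in the death series.
#' @return List with `growth` (time_h, concentration_um, confluence_pct),
#'   `vehicle` (time_h, confluence_pct), `death` (time_h,
#'   concentration_um, dead_fraction) and a `"truth"` attribute.
#' @export
gen_cell_series <- function(ec50_true = 25, hill = 1, vehicle_slope = 2,
                            noise = 0.02,
                            doses = 10^seq(0, 2.5, by = 0.5), seed = 1L,
                            ec50_death = NULL,
                            times_h = seq(0, 24, by = 4),
                            death_reps = 2L) {
  set.seed(seed)
  if (is.null(ec50_death)) {
    ec50_death <- c(h24 = ec50_true * 2, h48 = ec50_true * 1.5)
  }
  slope_at <- function(d) vehicle_slope / (1 + (d / ec50_true)^hill)
  conf_sd <- noise * vehicle_slope * max(times_h)
  growth <- do.call(rbind, lapply(doses, function(d) {
    data.frame(time_h = times_h, concentration_um = d,
               confluence_pct = 20 + slope_at(d) * times_h +
                 rnorm(length(times_h), 0, conf_sd))
  }))
  vehicle <- data.frame(
    time_h = times_h,
    confluence_pct = 20 + vehicle_slope * times_h +
      rnorm(length(times_h), 0, conf_sd)
  )
  death <- do.call(rbind, lapply(seq_along(ec50_death), function(k) {
    ec <- ec50_death[k]
    tm <- c(24, 48)[k]
    do.call(rbind, lapply(seq_len(death_reps), function(r) {
      data.frame(time_h = tm, concentration_um = doses,
                 dead_fraction = 1 / (1 + (ec / doses)^hill) +
                   rnorm(length(doses), 0, noise))
    }))
  }))
  rownames(growth) <- rownames(death) <- NULL
  out <- list(growth = growth, vehicle = vehicle, death = death)
  attr(out, "truth") <- list(
    ec50_p = if (ec50_true >= min(doses) && ec50_true <= max(doses))
      ec50_true else NA_real_,
    ec50_p_assignable = ec50_true >= min(doses) && ec50_true <= max(doses),
    ec50_d24 = unname(ec50_death[1]),
    ec50_d48 = unname(ec50_death[2]),
    hill = hill, vehicle_slope = vehicle_slope, seed = seed
  )
  out
}
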