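#' Structure parsing and pocket extraction
#'
#' Binding pockets are defined geometrically: every polymer residue with at
#' least one heavy atom within a distance cutoff (default 6 Angstrom) of a
#' heavy atom of the bound ligand is a pocket member. Parsing of the
#' deposited coordinate formats is delegated to bio3d; this module owns
#' altloc resolution, model selection, ligand enumeration and the pocket
#' distance rule.
#'
#' @name structure_io
NULL

# Hetero groups never treated as screenable ligands: waters, common ions and
# crystallization additives.
DEFAULT_HET_EXCLUDE <- c(
  "HOH", "DOD", "WAT",
  "NA", "K", "CL", "MG", "ZN", "CA", "MN", "FE", "CU", "NI", "CD", "BR", "IOD",
  "GOL", "EDO", "SO4", "PO4", "ACT", "DMS", "PEG", "MPD"
)

element_from_name <- function(elety) {
  # Fallback when the element column is absent: strip digits/primes, take
  # the leading alphabetic character (two-letter elements are rare in
  # protein entries and carry an explicit element field when they matter).
  nm <- gsub("[^A-Za-z]", "", elety)
  toupper(substr(nm, 1, 1))
}

#' Parse a coordinate file into a structure model
#'
#' Reads a PDB or mmCIF file (or literal PDB text) and returns the first
#' coordinate model with alternate locations resolved to the
#' highest-occupancy conformer (lexicographic altloc id breaks ties).
#' Hydrogens are retained but flagged non-heavy.
#'
#' @param source Path to a coordinate file, or a character vector of raw PDB
#'   lines when `format = "pdb"`.
#' @param format Either `"pdb"` or `"mmcif"`.
#' @param structure_id Identifier stored on the model; defaults to the file
#'   base name.
#' @return A `structure_model`: list with `structure_id`, `model_number` and
#'   an `atoms` data frame (record, elety, element, chain, resno, insert,
#'   resid, x, y, z, occupancy, is_heavy).
#' @export
parse_structure <- function(source, format = c("pdb", "mmcif"),
                            structure_id = NULL) {
  format <- match.arg(format)
  if (format == "pdb" && length(source) == 1L && !file.exists(source) &&
      grepl("\n", source, fixed = TRUE)) {
    source <- strsplit(source, "\n", fixed = TRUE)[[1]]
  }
  if (length(source) == 1L && !file.exists(source)) {
    stop("failed to parse ", format, " input: file not found: ", source,
         call. = FALSE)
  }
  from_text <- length(source) > 1L
  path <- source
  if (from_text) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(source, path)
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) {
      stop("failed to parse ", format, " input '",
           if (from_text) "<text>" else source, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    stop("empty model: no ATOM/HETATM records found", call. = FALSE)
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  miss <- is.na(elem) | elem == ""
  elem[miss] <- element_from_name(at$elety[miss])
  elem <- toupper(trimws(elem))

  atoms <- data.frame(
    record = at$type,
    elety = trimws(at$elety),
    element = elem,
    alt = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    chain = ifelse(is.na(at$chain) | at$chain == "", " ", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resid = trimws(at$resid),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in input", call. = FALSE)
  }
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  atoms$is_heavy <- !(atoms$element %in% c("H", "D"))

  if (is.null(structure_id)) {
    structure_id <- if (from_text) "structure" else
      sub("\\.(pdb|ent|cif)$", "", basename(source), ignore.case = TRUE)
  }
  structure(
    list(structure_id = structure_id, model_number = 1L, atoms = atoms),
    class = "structure_model"
  )
}

# Keep, per (chain, resno, insert, resid, atom name), the conformer with the
# highest occupancy; ties broken by lexicographically smallest altloc id.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "\r")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$alt)
  keep <- ord[!duplicated(key[ord])]
  atoms[sort(keep), , drop = FALSE]
}

#' @export
print.structure_model <- function(x, ...) {
  np <- sum(x$atoms$record == "ATOM")
  nh <- sum(x$atoms$record == "HETATM")
  cat("structure_model '", x$structure_id, "': ", np, " polymer atoms, ",
      nh, " hetero atoms, ", nrow(residue_table(x)), " polymer residues\n",
      sep = "")
  invisible(x)
}

residue_key <- function(chain, resno, insert) {
  paste0(chain, ":", resno, insert)
}

#' Polymer residues of a model
#'
#' @param model A `structure_model`.
#' @return Data frame with one row per polymer residue (chain, resno,
#'   insert, resid, n_heavy), ordered by (chain, resno, insert).
#' @export
residue_table <- function(model) {
  at <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    return(data.frame(chain = character(), resno = integer(),
                      insert = character(), resid = character(),
                      n_heavy = integer(), stringsAsFactors = FALSE))
  }
  key <- residue_key(at$chain, at$resno, at$insert)
  first <- !duplicated(key)
  res <- data.frame(
    chain = at$chain[first], resno = at$resno[first],
    insert = at$insert[first], resid = at$resid[first],
    n_heavy = as.integer(tapply(at$is_heavy, key, sum)[key[first]]),
    stringsAsFactors = FALSE
  )
  res[order(res$chain, res$resno, res$insert), , drop = FALSE]
}

#' Enumerate co-crystal ligand instances
#'
#' Hetero groups that are not solvent/ions/additives and carry at least
#' `min_heavy_atoms` heavy atoms, ordered by (chain, resno).
#'
#' @param model A `structure_model`.
#' @param min_heavy_atoms Minimum heavy-atom count (default 6, which drops
#'   small fragments such as glycerol-sized additives even when not on the
#'   exclusion list).
#' @param exclude Character vector of het codes to skip.
#' @return Data frame (het_code, chain, resno, insert, n_heavy); zero rows
#'   when no ligand qualifies.
#' @export
list_ligand_instances <- function(model, min_heavy_atoms = 6L,
                                  exclude = DEFAULT_HET_EXCLUDE) {
  at <- model$atoms[model$atoms$record == "HETATM", , drop = FALSE]
  empty <- data.frame(het_code = character(), chain = character(),
                      resno = integer(), insert = character(),
                      n_heavy = integer(), stringsAsFactors = FALSE)
  if (nrow(at) == 0L) return(empty)
  at <- at[!(at$resid %in% exclude), , drop = FALSE]
  if (nrow(at) == 0L) return(empty)
  key <- paste(at$resid, residue_key(at$chain, at$resno, at$insert))
  first <- !duplicated(key)
  lig <- data.frame(
    het_code = at$resid[first], chain = at$chain[first],
    resno = at$resno[first], insert = at$insert[first],
    n_heavy = as.integer(tapply(at$is_heavy, key, sum)[key[first]]),
    stringsAsFactors = FALSE
  )
  lig <- lig[lig$n_heavy >= min_heavy_atoms, , drop = FALSE]
  lig <- lig[order(lig$chain, lig$resno, lig$insert), , drop = FALSE]
  rownames(lig) <- NULL
  lig
}

ligand_atoms <- function(model, ligand) {
  at <- model$atoms
  sel <- at$record == "HETATM" & at$resid == ligand$het_code &
    at$chain == ligand$chain & at$resno == ligand$resno
  if (!is.null(ligand$insert) && nzchar(ligand$insert)) {
    sel <- sel & at$insert == ligand$insert
  }
  at[sel, , drop = FALSE]
}

#' Extract the ligand-binding pocket
#'
#' A polymer residue belongs to the pocket iff its minimum heavy-atom to
#' heavy-atom distance to the ligand is `<= cutoff` (inclusive). The ligand
#' itself and all other hetero groups are never pocket members. Residues
#' from all chains within the cutoff are included.
#'
#' @param model A `structure_model`.
#' @param ligand One row of [list_ligand_instances()] output (or a list with
#'   `het_code`, `chain`, `resno`).
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return A `pocket_definition`: list with `pocket_id`, `residues` (data
#'   frame ordered by chain/resno/insert), `cutoff` and `ligand` locator.
#' @export
extract_pocket <- function(model, ligand, cutoff = 6.0) {
  stopifnot(cutoff > 0)
  lat <- ligand_atoms(model, ligand)
  lat <- lat[lat$is_heavy, , drop = FALSE]
  if (nrow(lat) == 0L) {
    stop("invalid ligand: no heavy atoms for ", ligand$het_code,
         " ", ligand$chain, ":", ligand$resno, call. = FALSE)
  }
  pat <- model$atoms[model$atoms$record == "ATOM" & model$atoms$is_heavy, ,
                     drop = FALSE]
  if (nrow(pat) == 0L) {
    stop("model has no polymer heavy atoms", call. = FALSE)
  }
  lxyz <- as.matrix(lat[, c("x", "y", "z")])
  pxyz <- as.matrix(pat[, c("x", "y", "z")])
  # min distance from each protein atom to any ligand heavy atom
  d2 <- outer(rowSums(pxyz^2), rowSums(lxyz^2), "+") -
    2 * (pxyz %*% t(lxyz))
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  key <- residue_key(pat$chain, pat$resno, pat$insert)
  res_min <- tapply(mind, key, min)
  # inclusive boundary; 1e-9 guards against representation error for
  # distances constructed to sit exactly at the cutoff
  keep_keys <- names(res_min)[res_min <= cutoff + 1e-9]

  res <- residue_table(model)
  rk <- residue_key(res$chain, res$resno, res$insert)
  residues <- res[rk %in% keep_keys, , drop = FALSE]
  residues$min_dist <- as.numeric(res_min[rk[rk %in% keep_keys]])
  rownames(residues) <- NULL
  structure(
    list(
      pocket_id = paste(model$structure_id, ligand$het_code,
                        paste0(ligand$chain, ligand$resno), sep = "_"),
      residues = residues,
      cutoff = cutoff,
      ligand = list(het_code = ligand$het_code, chain = ligand$chain,
                    resno = ligand$resno)
    ),
    class = "pocket_definition"
  )
}

#' @export
print.pocket_definition <- function(x, ...) {
  cat("pocket_definition '", x$pocket_id, "': ", nrow(x$residues),
      " residues within ", x$cutoff, " A of ", x$ligand$het_code, "\n",
      sep = "")
  invisible(x)
}

#' Serialize a pocket definition
#'
#' Writes JSON (full definition) or a BED-like TSV
#' (structure_id, chain, seq_number, res_type).
#'
#' @param pocket A `pocket_definition`.
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pocket <- function(pocket, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(pocket_id = pocket$pocket_id, cutoff = pocket$cutoff,
           ligand = pocket$ligand, residues = pocket$residues),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    structure_id <- sub("_.*$", "", pocket$pocket_id)
    out <- data.frame(structure_id = structure_id,
                      chain = pocket$residues$chain,
                      seq_number = pocket$residues$resno,
                      res_type = pocket$residues$resid)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
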