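#' Chemical similarity network
#'
#' Compounds are related by the Tanimoto similarity (Tc) of hashed circular
#' fingerprints: atom-centered neighborhood identifiers up to a bond radius
#' (default 2), hashed into a fixed-length bit vector (default 2048 bits).
#' Identifiers are built from order-independent atom invariants, so the
#' same molecular graph yields the same bits regardless of SMILES atom
#' order. Edges connect pairs with Tc strictly above a threshold (default
#' 0.75); nodes carry a pocket-similarity (PFS) color class: `high_sim`
#' for PFS < -3, `low_sim` for PFS > -2, `intermediate` for the band in
#' between, `unscored` when no PFS is available.
#'
#' SMILES parsing into a molecular graph is delegated to
#' ChemmineR/ChemmineOB; single-atom molecules (which the SDF container
#' class rejects) are recovered from the raw V2000 block.
#'
#' @name chem_network
NULL

# Deterministic string hash: polynomial rolling hash mod 2^31-1 (prime),
# reduced to a bucket. Pure double arithmetic, exact below 2^53.
string_bucket <- function(s, n_bits) {
  p <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% p
  }
  (h %% n_bits) + 1L
}

# Molecular graph (atoms: element; bonds: i, j, order) from one SMILES.
smiles_to_graph <- function(smiles, id = "cmp") {
  sdf_txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " ", id)),
    error = function(e) "")
  lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) {
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1L) {
    stop("unparsable SMILES: '", smiles, "'", call. = FALSE)
  }
  atom_lines <- lines[5:(4 + n_atoms)]
  element <- toupper(trimws(substr(atom_lines, 32, 34)))
  bonds <- if (!is.na(n_bonds) && n_bonds > 0L) {
    bl <- lines[(5 + n_atoms):(4 + n_atoms + n_bonds)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  list(element = element, bonds = bonds)
}

#' Hashed circular fingerprint of a molecule
#'
#' Computes atom-centered neighborhood identifiers: the radius-0 invariant
#' combines element, heavy-atom degree and bond-order sum; each further
#' radius concatenates the sorted (bond order, neighbor identifier) list.
#' All identifiers up to `radius` are hashed into `n_bits` buckets.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood bond radius (default 2).
#' @param n_bits Fingerprint length (default 2048).
#' @param ligand_id Identifier stored on the fingerprint.
#' @return A `fingerprint` object: list with `ligand_id`, `bits`
#'   (integer 0/1 of length `n_bits`), `radius`.
#' @export
fingerprint <- function(smiles, radius = 2L, n_bits = 2048L,
                        ligand_id = smiles) {
  g <- smiles_to_graph(smiles, id = "cmp")
  n <- length(g$element)
  nb <- vector("list", n)
  if (nrow(g$bonds) > 0L) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[r]; j <- g$bonds$j[r]; o <- g$bonds$order[r]
      nb[[i]] <- rbind(nb[[i]], c(j, o))
      nb[[j]] <- rbind(nb[[j]], c(i, o))
    }
  }
  degree <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  bosum <- vapply(nb, function(x) if (is.null(x)) 0L else sum(x[, 2]),
                  integer(1))
  inv <- paste0(g$element, "|d", degree, "|b", bosum)
  ids <- inv
  if (radius >= 1L) {
    for (k in seq_len(radius)) {
      inv_new <- vapply(seq_len(n), function(a) {
        if (is.null(nb[[a]])) return(paste0("(", inv[a], ")"))
        parts <- sort(paste0(nb[[a]][, 2], ":", inv[nb[[a]][, 1]]))
        paste0("(", inv[a], ";", paste(parts, collapse = ","), ")")
      }, character(1))
      inv <- inv_new
      ids <- c(ids, inv)
    }
  }
  bits <- integer(n_bits)
  for (s in unique(ids)) {
    bits[string_bucket(s, n_bits)] <- 1L
  }
  structure(list(ligand_id = ligand_id, bits = bits, radius = radius),
            class = "fingerprint")
}

#' Tanimoto similarity of two chemical fingerprints
#'
#' @param a,b `fingerprint` objects (or raw 0/1 vectors) of equal length.
#' @return Tc in `[0, 1]`; 0 for two empty vectors.
#' @export
tanimoto_chem <- function(a, b) {
  ba <- if (inherits(a, "fingerprint")) a$bits else a
  bb <- if (inherits(b, "fingerprint")) b$bits else b
  tanimoto(ba, bb)
}

classify_pfs <- function(pfs, bands = c(-3, -2)) {
  ifelse(is.na(pfs), "unscored",
         ifelse(pfs < bands[1], "high_sim",
                ifelse(pfs > bands[2], "low_sim", "intermediate")))
}

#' Build the PFS-annotated chemical similarity network
#'
#' All-pairs fingerprint Tanimoto over a compound table; undirected edges
#' where Tc is strictly above the threshold; node color classes from the
#' PFS bands (`high_sim` below the lower band edge, `low_sim` above the
#' upper one, `intermediate` inside, `unscored` without a PFS).
#'
#' @param compounds Data frame with `ligand_id` and `smiles` columns
#'   (unique ids), or `NULL` when `fingerprints` is given.
#' @param pfs_map Named numeric vector mapping ligand_id to PFS (optional).
#' @param tc_threshold Edge threshold (strict; default 0.75).
#' @param bands Length-2 PFS band edges (default `c(-3, -2)`).
#' @param radius,n_bits Fingerprint parameters.
#' @param fingerprints Optional list of precomputed `fingerprint` objects
#'   (used instead of computing from SMILES; enables injecting known bit
#'   patterns).
#' @return A `compound_network`: list with `nodes` (ligand_id, pfs,
#'   color_class), `edges` (id_a, id_b, tc) and an igraph `graph`.
#' @export
build_network <- function(compounds = NULL, pfs_map = NULL,
                          tc_threshold = 0.75, bands = c(-3, -2),
                          radius = 2L, n_bits = 2048L,
                          fingerprints = NULL) {
  if (is.null(fingerprints)) {
    stopifnot(!is.null(compounds), !anyDuplicated(compounds$ligand_id))
    fingerprints <- lapply(seq_len(nrow(compounds)), function(i) {
      fingerprint(compounds$smiles[i], radius = radius, n_bits = n_bits,
                  ligand_id = compounds$ligand_id[i])
    })
  }
  ids <- vapply(fingerprints, `[[`, character(1), "ligand_id")
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  B <- do.call(rbind, lapply(fingerprints, `[[`, "bits"))
  edges <- data.frame(id_a = character(0), id_b = character(0),
                      tc = numeric(0), stringsAsFactors = FALSE)
  if (n >= 2L) {
    inter <- B %*% t(B)
    ones <- rowSums(B)
    un <- outer(ones, ones, "+") - inter
    Tc <- ifelse(un == 0, 0, inter / un)
    idx <- which(upper.tri(Tc) & Tc > tc_threshold, arr.ind = TRUE)
    if (nrow(idx) > 0L) {
      edges <- data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
                          tc = Tc[idx], stringsAsFactors = FALSE)
      edges <- edges[order(edges$id_a, edges$id_b), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  pfs <- rep(NA_real_, n)
  if (!is.null(pfs_map)) {
    pfs <- unname(pfs_map[ids])
  }
  nodes <- data.frame(ligand_id = ids, pfs = pfs,
                      color_class = classify_pfs(pfs, bands),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  structure(list(nodes = nodes, edges = edges, graph = g,
                 tc_threshold = tc_threshold, bands = bands),
            class = "compound_network")
}

#' @export
print.compound_network <- function(x, ...) {
  comp <- igraph::components(x$graph)
  cat("compound_network: ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (Tc > ", x$tc_threshold, "), ", comp$no, " components\n",
      sep = "")
  invisible(x)
}

#' Write a compound network
#'
#' GraphML via igraph, or plain TSVs (edge list and node table).
#'
#' @param net A `compound_network`.
#' @param path Output file (for `"tsv"`, the edge list; the node table goes
#'   to `paste0(path, ".nodes.tsv")`).
#' @param format `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net$graph, path, format = "graphml")
  } else {
    write.table(net$edges, path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
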