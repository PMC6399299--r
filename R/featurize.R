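#' Microenvironment featurization
#'
#' Each pocket residue is described by the protein matter surrounding its
#' side-chain centroid: six concentric radial shells of width 1 Angstrom,
#' each summarized by 80 physicochemical descriptors, giving a 480-length
#' vector. Descriptors are counts (or indicator bins) over the heavy atoms
#' falling in a shell: element counts, residue-type and residue-class
#' counts, backbone/side-chain split, hydrogen-bond donors/acceptors,
#' charged-group and aromatic-ring membership, total heavy atoms, a binned
#' Kyte-Doolittle hydropathy sum, and element-by-class cross counts.
#' Only polymer atoms contribute: the co-crystal ligand and other hetero
#' groups are excluded so that pockets remain comparable across ligands.
#'
#' @name featurize
NULL

KD_BREAKS <- c(-Inf, -10, -2, 2, 10, Inf)

schema_descriptor_names <- function() {
  cross_classes <- c(AA_CLASSES, "backbone")
  c(
    paste0("elem.", c("C", "N", "O", "S", "P", "other")),
    paste0("res.", AA3),
    paste0("class.", AA_CLASSES),
    c("backbone.count", "sidechain.count"),
    c("hbd.count", "hba.count"),
    c("poscharge.count", "negcharge.count"),
    "aromatic.ring.count",
    "heavy.total",
    paste0("kd.bin", 1:5),
    as.vector(outer(c("C", "N", "O", "S", "P"), cross_classes,
                    function(e, cl) paste0("cross.", e, ".", cl)))
  )
}

#' The default microenvironment descriptor schema
#'
#' 6 shells of width 1 Angstrom, 80 count-type descriptors per shell
#' (total length 480), binarization threshold 0 (presence/absence) for
#' every descriptor.
#'
#' @return A `pf_schema` object.
#' @export
default_schema <- function() {
  nm <- schema_descriptor_names()
  stopifnot(length(nm) == 80L, !anyDuplicated(nm))
  structure(
    list(
      schema_id = "default-v1",
      shell_count = 6L,
      shell_width = 1.0,
      descriptor_names = nm,
      thresholds = setNames(numeric(80L), nm),
      total_length = 480L
    ),
    class = "pf_schema"
  )
}

schema_vector_names <- function(schema) {
  as.vector(vapply(seq_len(schema$shell_count), function(k) {
    paste0("s", k, ".", schema$descriptor_names)
  }, character(length(schema$descriptor_names))))
}

# Per-atom annotation of all polymer heavy atoms: residue type/class,
# backbone flag, donor/acceptor/charge/aromatic membership, KD hydropathy.
annotate_model <- function(model) {
  cached <- attr(model, "pf_annotation")
  if (!is.null(cached)) return(cached)
  at <- model$atoms[model$atoms$record == "ATOM" & model$atoms$is_heavy, ,
                    drop = FALSE]
  resid <- at$resid
  elety <- at$elety
  in_set <- function(tab) {
    hit <- logical(nrow(at))
    for (aa in names(tab)) {
      hit <- hit | (resid == aa & elety %in% tab[[aa]])
    }
    hit
  }
  ann <- data.frame(
    x = at$x, y = at$y, z = at$z,
    element = at$element,
    resid = resid,
    class = unname(AA_CLASS[resid]),
    is_backbone = elety %in% c("N", "CA", "C", "O", "OXT"),
    stringsAsFactors = FALSE
  )
  ann$is_hbd <- (elety == "N") | in_set(HBD_SIDECHAIN)
  ann$is_hba <- (elety %in% c("O", "OXT")) | in_set(HBA_SIDECHAIN)
  ann$is_pos <- in_set(POS_GROUP_ATOMS)
  ann$is_neg <- in_set(NEG_GROUP_ATOMS)
  ann$is_aromatic <- in_set(AROMATIC_RING_ATOMS)
  ann$kd <- unname(KYTE_DOOLITTLE[resid])
  ann$kd[is.na(ann$kd)] <- 0
  ann$class[is.na(ann$class)] <- "special"
  ann
}

# 80 descriptor values for one shell's atoms.
shell_descriptors <- function(sub) {
  elem_count <- function(e) sum(sub$element == e)
  v <- c(
    vapply(c("C", "N", "O", "S", "P"), elem_count, numeric(1)),
    sum(!(sub$element %in% c("C", "N", "O", "S", "P"))),
    vapply(AA3, function(a) sum(sub$resid == a), numeric(1)),
    vapply(AA_CLASSES, function(cl) sum(sub$class == cl), numeric(1)),
    sum(sub$is_backbone), sum(!sub$is_backbone),
    sum(sub$is_hbd), sum(sub$is_hba),
    sum(sub$is_pos), sum(sub$is_neg),
    sum(sub$is_aromatic),
    nrow(sub)
  )
  kd_bins <- numeric(5)
  if (nrow(sub) > 0L) {
    kd_sum <- sum(sub$kd)
    kd_bins[findInterval(kd_sum, KD_BREAKS, left.open = TRUE)] <- 1
  }
  cross <- as.vector(vapply(c(AA_CLASSES, "backbone"), function(cl) {
    in_cl <- if (cl == "backbone") sub$is_backbone else sub$class == cl
    vapply(c("C", "N", "O", "S", "P"),
           function(e) sum(in_cl & sub$element == e), numeric(1))
  }, numeric(5)))
  unname(c(v, kd_bins, cross))
}

#' Geometric center of a residue
#'
#' Unweighted centroid of the side-chain heavy atoms; for glycine (no side
#' chain) the alpha-carbon position is used. Falls back to CA when no
#' side-chain heavy atom is present.
#'
#' @param model A `structure_model`.
#' @param residue A one-row residue locator (list or data frame row with
#'   `chain`, `resno`, and optionally `insert`).
#' @return Numeric length-3 coordinate (Angstrom).
#' @export
residue_center <- function(model, residue) {
  at <- model$atoms
  ins <- if (is.null(residue$insert)) "" else residue$insert
  sel <- at$record == "ATOM" & at$chain == residue$chain &
    at$resno == residue$resno & at$insert == ins & at$is_heavy
  ra <- at[sel, , drop = FALSE]
  if (nrow(ra) == 0L) {
    stop("residue ", residue$chain, ":", residue$resno,
         " has no heavy atoms", call. = FALSE)
  }
  sc <- ra[!(ra$elety %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
  if (nrow(sc) == 0L) sc <- ra[ra$elety == "CA", , drop = FALSE]
  if (nrow(sc) == 0L) sc <- ra
  colMeans(as.matrix(sc[, c("x", "y", "z")]))
}

#' Featurize one microenvironment
#'
#' Assigns every polymer heavy atom at distance `0 < d <= 6` Angstrom from
#' `center` to exactly one radial shell (shell k covers `(k-1, k]` times the
#' shell width) and aggregates the schema's 80 descriptors per shell,
#' shell-major (all of shell 1, then shell 2, ...).
#'
#' @param model A `structure_model`.
#' @param center Numeric length-3 coordinate.
#' @param schema A `pf_schema` (default [default_schema()]).
#' @return List with `values` (named numeric, length 480), `bits` (integer
#'   0/1), `center`, `schema_id`.
#' @export
featurize_microenvironment <- function(model, center,
                                       schema = default_schema()) {
  stopifnot(length(center) == 3L, all(is.finite(center)))
  ann <- annotate_model(model)
  w <- schema$shell_width
  ns <- schema$shell_count
  d <- sqrt((ann$x - center[1])^2 + (ann$y - center[2])^2 +
              (ann$z - center[3])^2)
  shell <- ceiling(d / w - 1e-9)
  keep <- d > 1e-9 & shell >= 1L & shell <= ns
  ann <- ann[keep, , drop = FALSE]
  shell <- shell[keep]
  values <- as.vector(vapply(seq_len(ns), function(k) {
    shell_descriptors(ann[shell == k, , drop = FALSE])
  }, numeric(length(schema$descriptor_names))))
  names(values) <- schema_vector_names(schema)
  list(
    center = center,
    values = values,
    bits = binarize(values, schema),
    schema_id = schema$schema_id
  )
}

#' Binarize a descriptor vector
#'
#' A bit is set iff the value strictly exceeds the descriptor's threshold
#' (0 for all count-type descriptors in the default schema, realizing
#' presence/absence "shared bit" comparison).
#'
#' @param values Numeric vector whose length is a multiple of the schema's
#'   descriptor count (normally the full 480-vector).
#' @param schema A `pf_schema`.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize <- function(values, schema = default_schema()) {
  nd <- length(schema$thresholds)
  if (length(values) %% nd != 0L) {
    stop("value vector length ", length(values),
         " is not a multiple of the schema's ", nd, " descriptors",
         call. = FALSE)
  }
  thr <- rep(unname(schema$thresholds), length(values) %/% nd)
  as.integer(values > thr)
}

#' Featurize every residue of a pocket
#'
#' @param model A `structure_model` (the one the pocket was extracted from).
#' @param pocket A `pocket_definition`.
#' @param schema A `pf_schema`.
#' @return A `pf_featureset`: list with `pocket_id`, `residue_refs`,
#'   `values` and `bits` matrices (residues x 480, pocket order preserved),
#'   `schema_id`, and optional `ligand`/`target` annotations.
#' @export
featurize_pocket <- function(model, pocket, schema = default_schema()) {
  res <- pocket$residues
  if (nrow(res) == 0L) stop("pocket has no residues", call. = FALSE)
  attr(model, "pf_annotation") <- annotate_model(model)
  refs <- paste0(residue_key(res$chain, res$resno, res$insert), "/",
                 res$resid)
  rows <- lapply(seq_len(nrow(res)), function(i) {
    ctr <- tryCatch(residue_center(model, res[i, ]), error = function(e) {
      stop("featurization failed at residue ", refs[i], ": ",
           conditionMessage(e), call. = FALSE)
    })
    featurize_microenvironment(model, ctr, schema)
  })
  values <- do.call(rbind, lapply(rows, `[[`, "values"))
  bits <- do.call(rbind, lapply(rows, `[[`, "bits"))
  rownames(values) <- rownames(bits) <- refs
  colnames(bits) <- colnames(values)
  structure(
    list(
      pocket_id = pocket$pocket_id,
      residue_refs = refs,
      values = values,
      bits = bits,
      schema_id = schema$schema_id,
      ligand = pocket$ligand
    ),
    class = "pf_featureset"
  )
}

#' @export
print.pf_featureset <- function(x, ...) {
  cat("pf_featureset '", x$pocket_id, "': ", length(x$residue_refs),
      " residues x ", ncol(x$values), " descriptors (schema ",
      x$schema_id, ")\n", sep = "")
  invisible(x)
}

#' Serialize a feature set
#'
#' JSON keeps the full per-residue vectors with the schema id; TSV writes a
#' dense residues x 480 matrix with shell-major column headers.
#'
#' @param fs A `pf_featureset`.
#' @param path Output file.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_featureset <- function(fs, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(pocket_id = fs$pocket_id, schema_id = fs$schema_id,
           residue_refs = fs$residue_refs,
           values = apply(fs$values, 1, identity, simplify = FALSE)),
      path, auto_unbox = TRUE, digits = NA
    )
  } else {
    out <- data.frame(residue = fs$residue_refs, fs$values,
                      check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
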