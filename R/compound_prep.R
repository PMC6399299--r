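#' Drug-like library preparation and docking post-processing
#'
#' Builds the screenable compound library: Lipinski rule-of-five filtering
#' with fewer than 2 violations plus a 170-1000 Da molecular-weight window,
#' then structure-key (InChIKey-style) deduplication. Docking scores are
#' converted to inhibition constants by the Boltzmann relation
#' Ki = exp(dG / (R T)) with R = 1.9872036e-3 kcal/(K mol) and T = 300 K,
#' and high-confidence binders are those with dG strictly below -6 kcal/mol.
#' Hydrogen-bond acceptor counts are taken as supplied (N+O counts); logP
#' is a supplied descriptor, not computed.
#'
#' @name compound_prep
NULL

GAS_CONSTANT_KCAL <- 1.9872036e-3  # kcal K^-1 mol^-1
DOCKING_TEMPERATURE <- 300         # K

#' Count Lipinski rule violations
#'
#' Rules: MW > 500, logP > 5, H-bond donors > 5, H-bond acceptors > 10.
#'
#' @param mw Molecular weight (Da).
#' @param logp Octanol-water partition coefficient.
#' @param hbd,hba Hydrogen-bond donor / acceptor counts.
#' @return Integer vector of violation counts (0-4).
#' @export
lipinski_violations <- function(mw, logp, hbd, hba) {
  args <- list(mw = mw, logp = logp, hbd = hbd, hba = hba)
  for (nm in names(args)) {
    if (any(is.na(args[[nm]]))) {
      stop("missing descriptor '", nm, "'", call. = FALSE)
    }
  }
  as.integer(mw > 500) + as.integer(logp > 5) +
    as.integer(hbd > 5) + as.integer(hba > 10)
}

#' Filter a compound table to drug-like records
#'
#' Keeps records with fewer than 2 Lipinski violations and molecular weight
#' inside the inclusive 170-1000 Da window.
#'
#' @param table Data frame with columns `mw`, `logp`, `hbd`, `hba` (plus
#'   any others, preserved).
#' @param mw_min,mw_max Molecular-weight window (Da).
#' @param max_violations Records with at least this many violations are
#'   dropped (default 2, i.e. at most 1 violation passes).
#' @return The filtered data frame.
#' @export
druglike_filter <- function(table, mw_min = 170, mw_max = 1000,
                            max_violations = 2L) {
  v <- lipinski_violations(table$mw, table$logp, table$hbd, table$hba)
  keep <- v < max_violations & table$mw >= mw_min & table$mw <= mw_max
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deduplicate compounds by structure key
#'
#' One record per `structure_key` (InChIKey or equivalent), keeping the
#' first occurrence in input order.
#'
#' @param table Data frame with a `structure_key` column.
#' @return The deduplicated data frame.
#' @export
dedupe_by_key <- function(table) {
  key <- table$structure_key
  if (is.null(key)) stop("missing 'structure_key' column", call. = FALSE)
  if (any(is.na(key) | key == "")) {
    stop("empty structure_key in row(s) ",
         paste(head(which(is.na(key) | key == "")), collapse = ", "),
         call. = FALSE)
  }
  out <- table[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert a docking score to an inhibition constant
#'
#' `Ki = exp(dG / (R T))` in molar units; strictly increasing in the
#' docking score, so more negative scores mean tighter predicted binding.
#'
#' @param delta_g Docking score (kcal/mol).
#' @param R Gas constant (kcal/(K mol)).
#' @param T Temperature (K).
#' @return Ki in molar.
#' @export
ki_from_docking <- function(delta_g, R = GAS_CONSTANT_KCAL,
                            T = DOCKING_TEMPERATURE) {
  stopifnot(R > 0, T > 0)
  if (any(!is.finite(delta_g))) {
    stop("non-finite docking score", call. = FALSE)
  }
  exp(delta_g / (R * T))
}

#' Keep high-confidence docking records
#'
#' Strict cutoff: records with `delta_g < cutoff` (default -6 kcal/mol)
#' survive; a score exactly at the cutoff is removed.
#'
#' @param records Data frame with a `delta_g` column.
#' @param cutoff Confidence cutoff (kcal/mol).
#' @return The filtered data frame, with a `ki` column added.
#' @export
docking_confidence_filter <- function(records, cutoff = -6) {
  out <- records[records$delta_g < cutoff, , drop = FALSE]
  out$ki <- ki_from_docking(out$delta_g)
  rownames(out) <- NULL
  out
}

#' Target-family enrichment of screen hits
#'
#' Counts hits per annotated target family, descending, with alphabetical
#' tie-break. Unannotated hits fall into family `"other"`.
#'
#' @param hits Data frame with a `target` (or `target_family`) column.
#' @return Data frame (target_family, ligand_count).
#' @export
target_enrichment <- function(hits) {
  fam <- hits$target_family
  if (is.null(fam)) fam <- hits$target
  if (is.null(fam)) fam <- rep(NA_character_, nrow(hits))
  fam[is.na(fam) | fam == ""] <- "other"
  tab <- table(fam)
  out <- data.frame(target_family = names(tab),
                    ligand_count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ligand_count, out$target_family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a compound table (TSV/CSV)
#'
#' Expects a header with at least (ligand_id, mw, logp, hbd, hba,
#' structure_key); `smiles` and `target_family` are optional.
#'
#' @param path Input file.
#' @param sep Field separator (default tab).
#' @return Data frame.
#' @export
read_compound_table <- function(path, sep = "\t") {
  read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
             quote = "\"", comment.char = "")
}
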