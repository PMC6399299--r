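# Independent oracles and small builders shared across the test files.

# All permutations of 1..n (recursive, deterministic order).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(p >= k, p + 1L, p))
  }))
}

# Exhaustive-enumeration pocket score: maximum total similarity over all
# one-to-one (partial) matchings restricted to pairs with T >= tau,
# obtained by enumerating full permutations of the zero-padded square
# matrix (excluded pairs contribute 0, so padding is equivalent to
# allowing unmatched residues). Returns the PFS (negated maximum).
brute_pfs <- function(Tm, tau) {
  W <- ifelse(Tm >= tau, Tm, 0)
  sq <- max(nrow(W), ncol(W))
  Wp <- matrix(0, sq, sq)
  Wp[seq_len(nrow(W)), seq_len(ncol(W))] <- W
  P <- all_perms(sq)
  -max(apply(P, 1, function(pp) sum(Wp[cbind(seq_len(sq), pp)])))
}

# Minimal stand-in feature set built directly from a bit matrix.
make_fs <- function(bits, id = "fs", schema_id = "default-v1") {
  rownames(bits) <- paste0("r", seq_len(nrow(bits)))
  list(pocket_id = id, residue_refs = rownames(bits), bits = bits,
       values = bits, schema_id = schema_id,
       ligand = list(het_code = "LIG"))
}

random_bits <- function(n_rows, n_cols = 30L, p = 0.4) {
  matrix(as.integer(runif(n_rows * n_cols) < p), nrow = n_rows)
}

# Rigid-body transform of a structure model (rotation about z + shift).
transform_model <- function(model, angle = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(angle), -sin(angle), 0,
                sin(angle), cos(angle), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  model$atoms$x <- xyz[, 1]
  model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# Featurize the (single) planted ligand pocket of a toy model.
toy_featureset <- function(model, cutoff = 6.0, schema = default_schema()) {
  lig <- attr(model, "truth")$ligand
  if (is.null(lig)) lig <- list_ligand_instances(model)[1, ]
  featurize_pocket(model, extract_pocket(model, lig, cutoff = cutoff),
                   schema = schema)
}

summary_table_path <- function() {
  system.file("extdata", "serm_microtubule_summary.tsv",
              package = "pocketscreen")
}
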