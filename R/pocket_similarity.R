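#' Pocket similarity scoring
#'
#' Two pockets are compared by the Tanimoto similarity of their residues'
#' binarized microenvironment vectors. Residues are put in one-to-one
#' correspondence by a maximum-weight bipartite matching over all pairs
#' whose Tanimoto similarity reaches an inclusion cutoff `tau`; the pocket
#' similarity score (PFS) is the negated sum of matched similarities, so
#' more negative means more similar. Screening significance uses the strict
#' cutoff PFS < -3.5.
#'
#' @name pocket_similarity
NULL

#' Tanimoto similarity of two bit vectors
#'
#' `|A and B| / |A or B|`; defined as 0 when both vectors are all-zero.
#'
#' @param bitsA,bitsB Equal-length 0/1 vectors.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(bitsA, bitsB) {
  if (length(bitsA) != length(bitsB)) {
    stop("bit vectors differ in length (", length(bitsA), " vs ",
         length(bitsB), ")", call. = FALSE)
  }
  a <- bitsA != 0
  b <- bitsB != 0
  un <- sum(a | b)
  if (un == 0L) return(0)
  sum(a & b) / un
}

# All-pairs Tanimoto between the rows of two bit matrices.
pair_score_matrix <- function(bitsA, bitsB) {
  A <- (bitsA != 0) * 1L
  B <- (bitsB != 0) * 1L
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), "+") - inter
  T <- ifelse(un == 0, 0, inter / un)
  dimnames(T) <- list(rownames(bitsA), rownames(bitsB))
  T
}

# Exact maximum-weight assignment on a square matrix (Hungarian algorithm,
# shortest-augmenting-path formulation with dual potentials, O(n^3)).
# Returns for each row the assigned column. Weights must be finite;
# maximization is solved as min-cost on (max(w) - w).
solve_assignment <- function(w) {
  n <- nrow(w)
  stopifnot(n == ncol(w), all(is.finite(w)))
  if (n == 0L) return(integer(0))
  cost <- max(w) - w
  # 1-based translation of the classic potentials algorithm; index n+1 is
  # the virtual "unassigned" column slot.
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)       # p[j]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1) break
    }
  }
  assign_row <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assign_row[p[j]] <- j
  assign_row
}

#' Optimally align two pockets
#'
#' Maximum-weight one-to-one matching between the residues of two feature
#' sets on the bipartite graph whose edges are residue pairs with Tanimoto
#' similarity `>= tau`. The PFS is the negated total matched similarity.
#'
#' @param fsA,fsB `pf_featureset` objects sharing a schema.
#' @param tau Minimum pair similarity for a pair to enter the matching
#'   (default 0.5).
#' @return A `pocket_alignment`: list with `pairs` (data frame residue_a,
#'   residue_b, similarity), `pfs`, `tau` and the two pocket ids.
#' @export
align_pockets <- function(fsA, fsB, tau = 0.5) {
  if (!identical(fsA$schema_id, fsB$schema_id)) {
    stop("schema mismatch: '", fsA$schema_id, "' vs '", fsB$schema_id, "'",
         call. = FALSE)
  }
  Tm <- pair_score_matrix(fsA$bits, fsB$bits)
  n <- nrow(Tm)
  m <- ncol(Tm)
  if (n == 0L || m == 0L) stop("empty pocket", call. = FALSE)
  W <- ifelse(Tm >= tau, Tm, 0)
  sq <- max(n, m)
  Wp <- matrix(0, sq, sq)
  Wp[seq_len(n), seq_len(m)] <- W
  col_of <- solve_assignment(Wp)
  pairs <- data.frame(row = integer(0), col = integer(0),
                      similarity = numeric(0))
  for (i in seq_len(n)) {
    j <- col_of[i]
    if (j <= m && Tm[i, j] >= tau && W[i, j] > 0) {
      pairs <- rbind(pairs, data.frame(row = i, col = j,
                                       similarity = Tm[i, j]))
    }
  }
  pairs <- pairs[order(pairs$row, pairs$col), , drop = FALSE]
  out <- data.frame(
    residue_a = fsA$residue_refs[pairs$row],
    residue_b = fsB$residue_refs[pairs$col],
    similarity = pairs$similarity,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      pocket_a = fsA$pocket_id,
      pocket_b = fsB$pocket_id,
      pairs = out,
      tau = tau,
      pfs = -sum(out$similarity)
    ),
    class = "pocket_alignment"
  )
}

#' @export
print.pocket_alignment <- function(x, ...) {
  cat("pocket_alignment ", x$pocket_a, " vs ", x$pocket_b, ": ",
      nrow(x$pairs), " matched pairs, PFS = ", format(x$pfs, digits = 4),
      " (tau = ", x$tau, ")\n", sep = "")
  invisible(x)
}

#' Is a PFS significant?
#'
#' Strict inequality: `pfs < threshold`, default threshold -3.5.
#'
#' @param pfs Numeric PFS value(s).
#' @param threshold Significance cutoff.
#' @return Logical vector.
#' @export
pfs_significant <- function(pfs, threshold = -3.5) {
  pfs < threshold
}

#' Screen a pocket against a database of pockets
#'
#' Aligns the query to every database entry and returns hits ranked by PFS
#' ascending (most similar first), with a stable pocket-id tie-break.
#'
#' @param query A `pf_featureset`.
#' @param db List of `pf_featureset` objects (same schema as the query).
#' @param tau Pair-inclusion cutoff passed to [align_pockets()].
#' @param threshold Significance cutoff passed to [pfs_significant()].
#' @return Data frame (pocket_id, cognate_ligand, target, n_pairs, pfs,
#'   significant), one row per database entry.
#' @export
screen_database <- function(query, db, tau = 0.5, threshold = -3.5) {
  if (length(db) == 0L) {
    warning("empty pocket database: no hits")
    return(data.frame(pocket_id = character(), cognate_ligand = character(),
                      target = character(), n_pairs = integer(),
                      pfs = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(db, function(fs) {
    al <- align_pockets(query, fs, tau = tau)
    data.frame(
      pocket_id = fs$pocket_id,
      cognate_ligand = if (is.null(fs$ligand$het_code)) NA_character_
                       else fs$ligand$het_code,
      target = if (is.null(fs$target)) NA_character_ else fs$target,
      n_pairs = nrow(al$pairs),
      pfs = al$pfs,
      stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, rows)
  hits$significant <- pfs_significant(hits$pfs, threshold)
  hits <- hits[order(hits$pfs, hits$pocket_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write screen hits as TSV
#'
#' @param hits Output of [screen_database()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
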