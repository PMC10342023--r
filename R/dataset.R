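# Labeled-dataset assembly with negative sampling at a configurable class
# ratio, and grouped k-fold splitting (groups = structures) so peptide
# bonds of one protein never straddle a train/test boundary.

#' Assemble a labeled dataset from features and mapped cleavage sites
#'
#' Positives are the P1 residues of mapped events; the negative pool is
#' every other residue with a complete feature vector in the same
#' structures. `neg_ratio` negatives per positive are sampled without
#' replacement (globally across structures) with the given seed;
#' `neg_ratio = Inf` (or `"all"`) keeps the whole pool.
#'
#' @param feats Row-bound feature tables from [build_feature_vectors()].
#' @param mapped Mapped events (rows with `mapped == TRUE` are used) with
#'   columns `structure_id`, `chain`, `residue_index`.
#' @param neg_ratio Negatives per positive (default 1), or `Inf`/`"all"`.
#' @param seed Integer seed for the negative draw.
#' @return Data frame: the feature rows of selected examples plus `label`
#'   (1 positive / 0 negative) and `group` (structure id). Attribute
#'   `sampling` records ratio and seed.
#' @export
build_dataset <- function(feats, mapped, neg_ratio = 1, seed = 1) {
  if (identical(neg_ratio, "all")) neg_ratio <- Inf
  ok <- mapped[mapped$mapped, , drop = FALSE]
  if (nrow(ok) == 0L) stop("no mapped positive events")
  # P1 residue_index is an index within the chain's residue order
  feats$.row <- seq_len(nrow(feats))
  pos_rows <- integer(0)
  for (i in seq_len(nrow(ok))) {
    sub <- feats[feats$structure_id == ok$structure_id[i] &
                   feats$chain == ok$chain[i], , drop = FALSE]
    if (ok$residue_index[i] > nrow(sub)) {
      stop("residue_index out of range for structure ",
           ok$structure_id[i])
    }
    pos_rows <- c(pos_rows, sub$.row[ok$residue_index[i]])
  }
  pos_rows <- unique(pos_rows)
  pos <- feats[pos_rows, , drop = FALSE]
  pos <- pos[pos$complete, , drop = FALSE]
  if (nrow(pos) == 0L) stop("no positive example has complete features")
  pool <- feats[feats$complete & !feats$.row %in% pos_rows &
                  feats$structure_id %in% unique(pos$structure_id), ,
                drop = FALSE]
  if (is.finite(neg_ratio)) {
    n_neg <- round(neg_ratio * nrow(pos))
    if (nrow(pool) < n_neg) {
      stop("negative pool (", nrow(pool), ") smaller than requested ",
           n_neg)
    }
    set.seed(as.integer(seed))
    neg <- pool[sample(nrow(pool), n_neg), , drop = FALSE]
  } else {
    neg <- pool
  }
  out <- rbind(cbind(pos, label = 1L), cbind(neg, label = 0L))
  out$group <- out$structure_id
  out$.row <- NULL
  rownames(out) <- NULL
  attr(out, "sampling") <- list(neg_ratio = neg_ratio, seed = seed)
  out
}

#' Grouped k-fold splits
#'
#' Partitions the groups (not the rows) into k folds of nearly equal group
#' count after a seeded shuffle, so no group appears in both the train and
#' test side of any fold.
#'
#' @param groups Character vector of group labels, one per row.
#' @param k Number of folds (default 10).
#' @param seed Integer seed for the shuffle.
#' @return List of k integer vectors of row indices (the test rows of each
#'   fold).
#' @export
group_kfold <- function(groups, k = 10, seed = 1) {
  g <- unique(groups)
  if (length(g) < k) {
    stop("need at least k = ", k, " groups, got ", length(g))
  }
  set.seed(as.integer(seed))
  g <- sample(g)
  fold_of_group <- rep(seq_len(k), length.out = length(g))
  lapply(seq_len(k), function(f) {
    which(groups %in% g[fold_of_group == f])
  })
}
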