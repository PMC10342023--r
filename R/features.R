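# Per-residue structural features used as predictors of proteolytic
# susceptibility: relative solvent accessibility, three-state secondary
# structure (one-hot), normalized temperature factor, protruded-loop
# length, and the flexible-termini flag. Predicted models replace the
# temperature factor with the model-confidence score.

# Theoretical maximum accessible surface area per residue (Tien et al.
# 2013, "theoretical" column), square Angstroms.
MAX_ASA <- c(
  A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
  Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
  L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
  S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
)

#' Relative solvent accessibility
#'
#' Absolute accessible surface divided by the residue's theoretical maximum
#' (Tien et al. values), clamped to \[0, 1\]. Nonstandard residues get
#' `NA` (feature missing).
#'
#' @param abs_acc Absolute ASA, square Angstroms (vector).
#' @param res_letter One-letter residue codes (vector, recycled rules of
#'   base R apply).
#' @return Numeric vector in \[0, 1\] with `NA` for nonstandard residues.
#' @export
relative_accessibility <- function(abs_acc, res_letter) {
  if (any(abs_acc < 0, na.rm = TRUE)) stop("absolute ASA must be >= 0")
  mx <- MAX_ASA[res_letter]
  pmin(1, abs_acc / unname(mx))
}

#' Protruded-loop length feature
#'
#' Every residue inside a maximal run of loop residues is assigned the
#' length of that run (residue count); helix and strand residues get 0.
#' Long protruded loops are cleavage-prone, and the whole loop shares that
#' property, hence the run length is broadcast to all its residues.
#'
#' @param ss3 Character vector over `{"helix", "strand", "loop"}`.
#' @return Integer vector of raw loop lengths, same length as `ss3`.
#' @export
loop_length_feature <- function(ss3) {
  stopifnot(length(ss3) > 0)
  r <- rle(ss3 == "loop")
  vals <- ifelse(r$values, r$lengths, 0L)
  as.integer(rep(vals, r$lengths))
}

#' Flexible N-/C-termini feature
#'
#' Flags the unstructured terminal regions: residues before the first
#' "qualifying" regular secondary-structure element and after the last one.
#' A regular element qualifies when its run length reaches
#' `min_helix_len` (helix) or `min_strand_len` (strand); shorter elements
#' are treated as part of the unstructured terminus. A chain with no
#' qualifying element is flagged entirely.
#'
#' @param ss3 Character vector over `{"helix", "strand", "loop"}`.
#' @param min_helix_len Minimum helix run length to qualify (default 4).
#' @param min_strand_len Minimum strand run length to qualify (default 3).
#' @return Integer 0/1 vector, same length as `ss3`.
#' @export
termini_feature <- function(ss3, min_helix_len = 4, min_strand_len = 3) {
  n <- length(ss3)
  stopifnot(n > 0)
  r <- rle(ss3)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- (r$values == "helix" & r$lengths >= min_helix_len) |
    (r$values == "strand" & r$lengths >= min_strand_len)
  flag <- rep(1L, n)
  if (any(qual)) {
    first <- starts[which(qual)[1]]
    last <- ends[which(qual)[sum(qual)]]
    flag[seq(first, last)] <- 0L
  }
  flag
}

# ---- min-max normalization -------------------------------------------------

#' Fit min-max normalization bounds
#'
#' @param x Data frame (or list) of raw feature values.
#' @param features Character vector of column names to fit.
#' @return An object of class `norm_bounds`: named list of `c(min, max)`.
#' @export
fit_normalization <- function(x, features) {
  b <- lapply(features, function(f) {
    v <- x[[f]]
    if (is.null(v)) stop("no column '", f, "' to fit bounds on")
    v <- v[is.finite(v)]
    if (length(unique(v)) < 2) {
      stop("feature '", f, "' is constant; min-max bounds are degenerate")
    }
    range(v)
  })
  names(b) <- features
  structure(b, class = "norm_bounds")
}

#' Apply min-max normalization bounds
#'
#' Values are scaled to `(x - min) / (max - min)` and clamped to \[0, 1\],
#' so out-of-range values at prediction time stay valid fractions.
#'
#' @param x Numeric vector.
#' @param bounds A `c(min, max)` pair (one element of a `norm_bounds`).
#' @return Numeric vector in \[0, 1\].
#' @export
apply_normalization <- function(x, bounds) {
  pmin(1, pmax(0, (x - bounds[1]) / (bounds[2] - bounds[1])))
}

# ---- feature assembly ------------------------------------------------------

#' Build the per-residue feature table for one chain
#'
#' Combines accessibility, secondary structure, temperature factor (or
#' model confidence), loop length, and the termini flag into one row per
#' residue. Accessibility and secondary structure come either from a
#' parsed DSSP table or, when `dssp = NULL`, from the internal
#' Shrake-Rupley and hydrogen-bond assigners. An explicit `ss3` vector
#' overrides the secondary-structure source (used with synthetic
#' structures that carry ground-truth labels).
#'
#' The temperature factor of experimental structures is min-max scaled per
#' structure (`bfactor_norm`), because B-factor scales are not comparable
#' across crystals; predicted models instead carry
#' `confidence_norm = tempfactor / 100`. Loop length is returned raw
#' (`loop_len`); corpus-level min-max scaling happens at training time so
#' test folds never touch training bounds.
#'
#' @param structure A `structure_model`.
#' @param chain_id Chain identifier.
#' @param dssp Optional data frame from [parse_dssp()].
#' @param ss3 Optional explicit three-state assignment for the chain.
#' @param sasa_n_points Point count for the internal SASA fallback.
#' @return Data frame with one row per residue: identification columns
#'   (`structure_id`, `chain`, `resno`, `insert`, `res_name`,
#'   `one_letter`), features (`rel_acc`, `ss_helix`, `ss_strand`,
#'   `ss_loop`, `bfactor_norm` or `confidence_norm`, `loop_len`,
#'   `terminus`) and `complete` (whether every feature is defined; only
#'   complete rows enter datasets).
#' @export
build_feature_vectors <- function(structure, chain_id, dssp = NULL,
                                  ss3 = NULL, sasa_n_points = 960) {
  res <- chain_residues(structure, chain_id)
  n <- nrow(res)
  if (n == 0L) stop("chain '", chain_id, "' has no residues")

  if (!is.null(dssp)) {
    d <- dssp[dssp$chain == chain_id, , drop = FALSE]
    idx <- match(paste(res$resno, res$insert), paste(d$resno, d$insert))
    acc <- d$acc[idx]
    ss_src <- rep(NA_character_, n)
    ss_src[!is.na(idx)] <- ss8_to_ss3(d$ss8[idx[!is.na(idx)]])
  } else {
    sas <- shrake_rupley_sasa(structure, n_points = sasa_n_points)
    sas <- sas[sas$chain == chain_id, , drop = FALSE]
    acc <- sas$acc
    ss_src <- assign_ss3(structure, chain_id)
  }
  if (!is.null(ss3)) {
    stopifnot(length(ss3) == n)
    ss_src <- ss3
  }
  ss_for_runs <- ifelse(is.na(ss_src), "loop", ss_src)
  rel_acc <- relative_accessibility(acc, res$one_letter)
  out <- data.frame(
    structure_id = structure$structure_id,
    chain = res$chain, resno = res$resno, insert = res$insert,
    res_name = res$resid, one_letter = res$one_letter,
    rel_acc = rel_acc,
    ss_helix = as.integer(ss_src == "helix"),
    ss_strand = as.integer(ss_src == "strand"),
    ss_loop = as.integer(ss_src == "loop"),
    loop_len = loop_length_feature(ss_for_runs),
    terminus = termini_feature(ss_for_runs),
    stringsAsFactors = FALSE
  )
  if (structure$source_kind == "predicted") {
    out$confidence_norm <- res$tempfactor / 100
  } else {
    b <- res$tempfactor
    if (length(unique(b)) < 2) {
      out$bfactor_norm <- rep(0.5, n)  # flat B-factor carries no signal
    } else {
      out$bfactor_norm <- apply_normalization(b, range(b))
    }
  }
  feat_cols <- setdiff(names(out), c("structure_id", "chain", "resno",
                                     "insert", "res_name", "one_letter"))
  out$complete <- stats::complete.cases(out[feat_cols]) &
    out$one_letter != "X" & !is.na(ss_src)
  out
}

#' Feature columns used by the susceptibility model
#'
#' @param source_kind `"experimental"` or `"predicted"`.
#' @return Character vector of model feature names (normalized scale:
#'   `loop_len` appears as `loop_len_norm`).
#' @export
model_features <- function(source_kind = c("experimental", "predicted")) {
  source_kind <- match.arg(source_kind)
  base <- c("rel_acc", "ss_helix", "ss_strand", "ss_loop", "loop_len_norm",
            "terminus")
  if (source_kind == "experimental") c(base, "bfactor_norm")
  else c(base, "confidence_norm")
}

#' Normalize a raw feature table for model fitting or scoring
#'
#' Fits (or applies) corpus-level min-max bounds for relative accessibility
#' and loop length, producing the `rel_acc` and `loop_len_norm` columns on
#' the model scale. Residues with `loop_len = 0` (helix/strand) keep
#' `loop_len_norm = 0`.
#'
#' @param feats Feature table from [build_feature_vectors()] (possibly
#'   row-bound over many structures).
#' @param bounds Optional `norm_bounds` fitted on a training corpus; when
#'   `NULL`, bounds are fitted on `feats`.
#' @return List with elements `feats` (normalized table) and `bounds`.
#' @export
normalize_features <- function(feats, bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- fit_normalization(feats[feats$complete, , drop = FALSE],
                                c("rel_acc", "loop_len"))
  }
  feats$rel_acc <- apply_normalization(feats$rel_acc, bounds[["rel_acc"]])
  feats$loop_len_norm <- ifelse(
    feats$loop_len == 0, 0,
    apply_normalization(feats$loop_len, bounds[["loop_len"]])
  )
  list(feats = feats, bounds = bounds)
}
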