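# High-level pipeline commands behind the command-line interface. Each
# command is a plain function so scripted use and the CLI share one code
# path; every run is reproducible from its arguments and seed.

#' Featurize a structure: one row per residue with all features
#'
#' @param structure_path PDB file.
#' @param chain_id Chain to featurize (default: first chain).
#' @param source_kind `"experimental"` or `"predicted"`.
#' @param dssp_path Optional classic DSSP output for the structure; when
#'   absent, the internal accessibility and secondary-structure assigners
#'   are used.
#' @param out Optional TSV output path.
#' @return The feature table, invisibly when `out` is given.
#' @export
cmd_featurize <- function(structure_path, chain_id = NULL,
                          source_kind = "experimental", dssp_path = NULL,
                          out = NULL) {
  st <- read_structure(structure_path, source_kind)
  if (is.null(chain_id)) chain_id <- structure_chains(st)[1]
  dssp <- if (!is.null(dssp_path)) parse_dssp(dssp_path)
  feats <- build_feature_vectors(st, chain_id, dssp = dssp)
  if (!is.null(out)) {
    utils::write.table(feats, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(feats))
  }
  feats
}

#' Train the susceptibility scorer on a labeled dataset
#'
#' Fits corpus normalization bounds and the LDA scorer on the full
#' dataset at the requested training ratio, runs grouped k-fold CV for
#' the quality report, and serializes the model.
#'
#' @param dataset Labeled dataset from [build_dataset()] (full negative
#'   pool).
#' @param neg_ratio Training negatives per positive (default 1).
#' @param k CV folds (default 10).
#' @param seed Integer seed.
#' @param source_kind Feature regime.
#' @param model_out Optional JSON path for the fitted model.
#' @return List with `model`, `bounds`, `cv` (a `cv_result`).
#' @export
cmd_train <- function(dataset, neg_ratio = 1, k = 10, seed = 1,
                      source_kind = "experimental", model_out = NULL) {
  fcols <- model_features(source_kind)
  cv <- cross_validate(dataset, k = k, neg_ratio = neg_ratio,
                       seed = seed, source_kind = source_kind)
  train_s <- sample_training_ratio(dataset, neg_ratio,
                                   seed = as.integer(seed) + 500L)
  nrm <- normalize_features(train_s)
  model <- lda_fit(as.matrix(nrm$feats[, fcols]), train_s$label)
  if (!is.null(model_out)) {
    write_lda_model(model, model_out, bounds = nrm$bounds,
                    source_kind = source_kind)
  }
  list(model = model, bounds = nrm$bounds, cv = cv)
}

#' Score every peptide bond of a structure
#'
#' Applies a fitted model to a structure and reports the susceptibility
#' score at each P1 residue (no cleaved/uncleaved threshold is applied:
#' how many bonds a protease actually cleaves depends on colocalization,
#' so thresholding is left to the user). Optionally writes a TSV and an
#' annotated PDB with scores in the temperature-factor column for
#' visualization.
#'
#' @param model An `lda_scorer` (or list from [read_lda_model()]).
#' @param bounds `norm_bounds` fitted with the model (not needed when
#'   `model` comes from [read_lda_model()]).
#' @param structure_path PDB file to score.
#' @param chain_id Chain (default: first).
#' @param source_kind Feature regime; must match the model.
#' @param dssp_path Optional DSSP output.
#' @param out_tsv,out_pdb Optional output paths.
#' @return Data frame of residue identification plus `score`.
#' @export
cmd_predict <- function(model, bounds = NULL, structure_path,
                        chain_id = NULL, source_kind = "experimental",
                        dssp_path = NULL, out_tsv = NULL, out_pdb = NULL) {
  if (!inherits(model, "lda_scorer") && is.list(model) &&
      !is.null(model$model)) {
    bounds <- model$bounds
    source_kind <- model$source_kind
    model <- model$model
  }
  if (is.null(bounds)) stop("normalization bounds are required")
  st <- read_structure(structure_path, source_kind)
  if (is.null(chain_id)) chain_id <- structure_chains(st)[1]
  dssp <- if (!is.null(dssp_path)) parse_dssp(dssp_path)
  feats <- build_feature_vectors(st, chain_id, dssp = dssp)
  feats <- normalize_features(feats, bounds = bounds)$feats
  fcols <- model_features(source_kind)
  score <- rep(NA_real_, nrow(feats))
  ok <- feats$complete
  score[ok] <- lda_predict(model, as.matrix(feats[ok, fcols]))
  out <- data.frame(feats[c("structure_id", "chain", "resno", "insert",
                            "res_name")], score = score)
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(out_pdb)) {
    res <- st$residues
    full <- rep(0, nrow(res))
    sel <- res$chain == chain_id
    full[sel] <- ifelse(is.na(score), 0, score)
    write_score_structure(st, full, out_pdb)
  }
  out
}

#' Fuse structural scores with PSSM specificity scores
#'
#' @param structural_scores,pssm_scores Candidate-site score vectors.
#' @param labels Training labels for the combiner (fit mode), or `NULL`
#'   with `combiner` supplied (predict mode).
#' @param combiner Optional fitted combiner.
#' @return List with `combiner` and `posterior`.
#' @export
cmd_combine <- function(structural_scores, pssm_scores, labels = NULL,
                        combiner = NULL) {
  if (is.null(combiner)) {
    if (is.null(labels)) stop("need labels to fit the combiner")
    combiner <- combiner_fit(structural_scores, pssm_scores, labels)
  }
  list(combiner = combiner,
       posterior = combiner_predict(combiner, structural_scores,
                                    pssm_scores))
}

#' Per-protein event-count summary of a curated dataset
#'
#' @param n_events Number of proteolytic events retained.
#' @param n_proteins Number of distinct substrate structures/proteins.
#' @return List with `mean` (events per protein) and the inputs.
#' @export
events_per_protein <- function(n_events, n_proteins) {
  stopifnot(n_proteins > 0)
  list(mean = n_events / n_proteins, n_events = n_events,
       n_proteins = n_proteins)
}

#' Dataset-construction step counts shipped with the package
#'
#' Reads the per-step event/substrate/protease counts of the reference
#' cleavage-event corpora (experimental-structure training set, the
#' predicted-model extension, and the held-out testing set) from the
#' package's data file.
#'
#' @return Data frame with columns `dataset`, `stage`, `events`,
#'   `substrates`, `proteases`.
#' @export
dataset_counts <- function() {
  path <- system.file("extdata", "dataset_counts.tsv",
                      package = "strucleave", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
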