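# End-to-end synthetic benchmarks: a planted-signal corpus that exercises
# the full pipeline (toy structures -> features -> planted events ->
# mapping -> dataset -> grouped CV), with the generating model's
# Bayes-optimal AUC available as an oracle.

#' Generate a synthetic corpus of toy structures with computed features
#'
#' Structures are generated with per-structure seeds derived from `seed`;
#' features use the ground-truth secondary-structure labels and the
#' internal Shrake-Rupley accessibility, then corpus-level min-max
#' normalization.
#'
#' @param n_structures Number of toy structures (default 200).
#' @param seed Integer base seed.
#' @param sasa_n_points Sphere points for SASA (default 240; toy backbones
#'   need no denser sampling, see the methods vignette).
#' @return List with `structures` (named list of `structure_model`s),
#'   `feats_raw` (row-bound raw feature table), `feats` (normalized) and
#'   `bounds` (corpus `norm_bounds`).
#' @export
generate_toy_corpus <- function(n_structures = 200, seed = 1,
                                sasa_n_points = 240) {
  seed <- as.integer(seed)
  structures <- list()
  feats <- vector("list", n_structures)
  for (i in seq_len(n_structures)) {
    sid <- sprintf("toy%03d", i)
    st <- generate_toy_structure(random_toy_spec(seed + i * 1009L),
                                 structure_id = sid)
    structures[[sid]] <- st
    feats[[i]] <- build_feature_vectors(st, "A",
                                        ss3 = attr(st, "ss_true"),
                                        sasa_n_points = sasa_n_points)
  }
  feats_raw <- do.call(rbind, feats)
  nrm <- normalize_features(feats_raw)
  list(structures = structures, feats_raw = feats_raw,
       feats = nrm$feats, bounds = nrm$bounds)
}

#' Planted-signal end-to-end benchmark
#'
#' Plants cleavage events on a toy corpus with a logistic feature model,
#' maps them back onto the structures through the standard event-mapping
#' path, assembles the labeled dataset, and runs grouped k-fold CV with
#' the LDA scorer. The generating model's Bayes AUC (true probabilities
#' vs planted labels) upper-bounds achievable performance and is returned
#' alongside.
#'
#' @param n_structures Number of toy structures.
#' @param seed Integer seed driving corpus generation, planting, sampling
#'   and folds.
#' @param plant A `plant_model`.
#' @param k CV folds.
#' @param neg_ratio Training negatives per positive.
#' @param corpus Optional precomputed corpus from [generate_toy_corpus()]
#'   (reused across ratio-sweep runs).
#' @param shuffle_labels Permute labels before CV (null benchmark).
#' @return List with `cv` (a `cv_result`), `bayes_auc`, `dataset`,
#'   `n_positive`, `n_pool`, and the corpus.
#' @export
planted_benchmark <- function(n_structures = 200, seed = 1,
                              plant = plant_model(), k = 10,
                              neg_ratio = 1, corpus = NULL,
                              shuffle_labels = FALSE) {
  seed <- as.integer(seed)
  if (is.null(corpus)) {
    corpus <- generate_toy_corpus(n_structures, seed = seed)
  }
  planted <- plant_cleavage_events(corpus$feats, plant, seed = seed + 7L)
  ev <- planted$events
  # route the events through the standard mapping path (substrate
  # sequence = chain sequence here, so the alignment is the identity)
  seqs <- vapply(corpus$structures, extract_sequence, character(1), "A")
  chains <- stats::setNames(rep("A", length(corpus$structures)),
                            names(corpus$structures))
  mapped <- map_events(ev, seqs, corpus$structures, chains)
  dataset <- build_dataset(corpus$feats_raw, mapped, neg_ratio = Inf)
  if (shuffle_labels) {
    set.seed(seed + 13L)
    dataset$label <- sample(dataset$label)
  }
  cv <- cross_validate(dataset, k = k, neg_ratio = neg_ratio,
                       seed = seed)
  cc <- corpus$feats$complete
  bayes <- roc_auc(planted$true_prob[cc], planted$labels[cc])$auc
  list(cv = cv, bayes_auc = bayes, dataset = dataset,
       n_positive = sum(dataset$label == 1),
       n_pool = nrow(dataset), corpus = corpus, planted = planted)
}

#' Structure-plus-motif fusion benchmark
#'
#' Builds a corpus where the planted cleavage logit is the sum of the
#' structural term and a sequence-motif term (true log-odds of the
#' residue's Schechter-Berger window under a generating motif). Trains
#' the structural LDA and a PSSM on a grouped training half and
#' evaluates structural-only, PSSM-only and fused AUCs on the held-out
#' half.
#'
#' Two details matter for the fusion. The combiner consumes the
#' structural score on the discriminant (logit) scale, where it is
#' Gaussian within each class under the structural model, rather than
#' the bounded bimodal posterior. And the combiner is fitted by
#' stacking: the training groups are split in half, each half is scored
#' by models fitted on the other half, and the Gaussian naive Bayes is
#' fitted on those out-of-fold scores - in-sample scores overstate the
#' PSSM's reliability (it is built from the very training positives) and
#' mis-weight the fusion.
#'
#' @param n_structures Number of toy structures.
#' @param seed Integer seed.
#' @param plant Structural part of the planted model.
#' @param weights Generating motif weights (default [motif_weights()] with
#'   K/R enriched at P1 and A/G at P2).
#' @param motif_scale Coefficient on the true motif log-odds (bits) in the
#'   planted logit.
#' @return List with `auc_structural`, `auc_pssm`, `auc_fused` (held-out),
#'   `n_test`, plus the fitted pieces.
#' @export
fusion_benchmark <- function(n_structures = 120, seed = 1,
                             plant = plant_model(intercept = -8.4),
                             weights = motif_weights(
                               enriched = list(P1 = c("K", "R"),
                                               P2 = c("A", "G")),
                               p_enriched = 0.6),
                             motif_scale = 0.6) {
  seed <- as.integer(seed)
  corpus <- generate_toy_corpus(n_structures, seed = seed)
  feats <- corpus$feats
  seqs <- vapply(corpus$structures, extract_sequence, character(1), "A")
  # true motif log-odds per residue window
  true_lo <- log2(weights / (1 / 20))
  idx <- stats::ave(seq_len(nrow(feats)),
                    paste(feats$structure_id, feats$chain),
                    FUN = seq_along)
  motif_bits <- numeric(nrow(feats))
  n_left <- sum(!grepl("p$", colnames(weights)))
  offs <- seq_len(ncol(weights)) - n_left
  for (r in seq_len(nrow(feats))) {
    sq <- seqs[[feats$structure_id[r]]]
    pos <- idx[r] + offs
    keep <- pos >= 1 & pos <= nchar(sq)
    aa <- substring(sq, pos[keep], pos[keep])
    motif_bits[r] <- sum(true_lo[cbind(match(aa, rownames(true_lo)),
                                       which(keep))])
  }
  logit <- plant_probabilities(plant, feats)
  logit <- log(logit / (1 - logit)) + motif_scale * motif_bits
  p <- stats::plogis(logit)
  p[!feats$complete] <- 0
  set.seed(seed + 7L)
  labels <- rbinom(length(p), 1, p)
  # grouped train/test halves
  gids <- names(corpus$structures)
  set.seed(seed + 11L)
  train_g <- sample(gids, floor(length(gids) / 2))
  fcols <- model_features("experimental")
  train_idx <- which(feats$structure_id %in% train_g & feats$complete)
  test_idx <- which(!feats$structure_id %in% train_g & feats$complete)

  fit_pair <- function(rows) {
    # structural scorer on a 1:1 sampled set + PSSM from the positives
    tr <- data.frame(feats[rows, ], label = labels[rows])
    tr_s <- sample_training_ratio(tr, 1, seed = seed + 17L)
    fit <- lda_fit(as.matrix(tr_s[, fcols]), tr_s$label)
    pos_tr <- rows[labels[rows] == 1]
    win <- vapply(pos_tr, function(r) {
      sq <- seqs[[feats$structure_id[r]]]
      pos <- idx[r] + offs
      aa <- ifelse(pos >= 1 & pos <= nchar(sq),
                   substring(sq, pos, pos), "X")
      paste(aa, collapse = "")
    }, character(1))
    list(lda = fit, pssm = build_pssm(win, window = colnames(weights)))
  }
  score_rows <- function(models, rows) {
    s_struct <- stats::qlogis(
      lda_predict(models$lda, as.matrix(feats[rows, fcols])))
    s_pssm <- vapply(rows, function(r) {
      pssm_score(models$pssm, seqs[[feats$structure_id[r]]], idx[r])
    }, numeric(1))
    cbind(structural = s_struct, pssm = s_pssm)
  }
  full <- fit_pair(train_idx)
  # stacked combiner: out-of-fold scores over a grouped half-split
  set.seed(seed + 23L)
  half_g <- sample(train_g, floor(length(train_g) / 2))
  idx_a <- train_idx[feats$structure_id[train_idx] %in% half_g]
  idx_b <- setdiff(train_idx, idx_a)
  sc_a <- score_rows(fit_pair(idx_b), idx_a)
  sc_b <- score_rows(fit_pair(idx_a), idx_b)
  comb <- combiner_fit(c(sc_a[, 1], sc_b[, 1]), c(sc_a[, 2], sc_b[, 2]),
                       labels[c(idx_a, idx_b)])
  sc_te <- score_rows(full, test_idx)
  fused <- combiner_predict(comb, sc_te[, 1], sc_te[, 2])
  y_te <- labels[test_idx]
  list(
    auc_structural = roc_auc(sc_te[, 1], y_te)$auc,
    auc_pssm = roc_auc(sc_te[, 2], y_te)$auc,
    auc_fused = roc_auc(fused, y_te)$auc,
    n_test = length(y_te), n_test_pos = sum(y_te),
    pssm = full$pssm, lda = full$lda, combiner = comb
  )
}
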