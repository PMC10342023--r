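# Synthetic toy structures and planted cleavage models. Backbones are
# built from ideal covalent geometry with per-state (phi, psi) dihedrals,
# so helices and strands have physically sensible hydrogen-bond geometry
# and loops are smooth random walks with the canonical ~3.8 A Ca-Ca step.
# Cleavage events are planted by a logistic model over the computed
# structural features, which makes the Bayes-optimal AUC of every corpus
# known exactly.

# ideal backbone internal coordinates (Engh-Huber-like)
BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7, a_ca_c_o = 120.8
)

deg <- function(x) x * pi / 180

# place atom D given A, B, C: |C-D| = r, angle(B,C,D) = theta,
# dihedral(A,B,C,D) = chi (degrees)
nerf_place <- function(A, B, C, r, theta, chi) {
  theta <- deg(theta); chi <- deg(chi)
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-r * cos(theta), r * sin(theta) * cos(chi),
          r * sin(theta) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Specification of a synthetic toy structure
#'
#' @param plan List of `c(state, length)` pairs (state in
#'   helix/strand/loop), e.g. `list(c("loop", 5), c("helix", 10))`.
#' @param seed Integer seed; fixed seed gives byte-identical structures.
#' @param bfactor_base Baseline residue B-factor.
#' @param bfactor_loop Additional B-factor for loop residues (flexible
#'   regions are more mobile).
#' @param bfactor_sd Gaussian noise SD on residue B-factors.
#' @return Object of class `toy_spec`.
#' @export
toy_spec <- function(plan, seed = 1, bfactor_base = 20,
                     bfactor_loop = 10, bfactor_sd = 2) {
  lens <- vapply(plan, function(p) as.integer(p[2]), integer(1))
  states <- vapply(plan, function(p) p[1], character(1))
  stopifnot(all(lens >= 1),
            all(states %in% c("helix", "strand", "loop")))
  structure(list(plan = plan, seed = as.integer(seed),
                 bfactor_base = bfactor_base, bfactor_loop = bfactor_loop,
                 bfactor_sd = bfactor_sd),
            class = "toy_spec")
}

#' Random toy-structure specification
#'
#' Alternates loop segments with regular elements (helix or strand), the
#' way small single-domain chains look: terminal loops of 3-8 residues,
#' 2-4 regular elements (helices 4-12, strands 3-8) joined by loops of
#' 2-10 residues.
#'
#' @param seed Integer seed.
#' @param ... Passed to [toy_spec()].
#' @return A `toy_spec`.
#' @export
random_toy_spec <- function(seed = 1, ...) {
  set.seed(as.integer(seed))
  n_reg <- sample(2:4, 1)
  plan <- list(c("loop", sample(3:8, 1)))
  for (i in seq_len(n_reg)) {
    if (runif(1) < 0.6) {
      plan <- c(plan, list(c("helix", sample(4:12, 1))))
    } else {
      plan <- c(plan, list(c("strand", sample(3:8, 1))))
    }
    tail_len <- if (i == n_reg) sample(3:8, 1) else sample(2:10, 1)
    plan <- c(plan, list(c("loop", tail_len)))
  }
  toy_spec(plan, seed = seed, ...)
}

loop_dihedrals <- function(n) {
  # coil-region (phi, psi) basins: polyproline/extended, alpha, left-alpha
  basin <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  phi <- numeric(n); psi <- numeric(n)
  phi[basin == 1] <- runif(sum(basin == 1), -120, -60)
  psi[basin == 1] <- runif(sum(basin == 1), 100, 170)
  phi[basin == 2] <- runif(sum(basin == 2), -90, -40)
  psi[basin == 2] <- runif(sum(basin == 2), -60, -10)
  phi[basin == 3] <- runif(sum(basin == 3), 40, 80)
  psi[basin == 3] <- runif(sum(basin == 3), 10, 60)
  cbind(phi, psi)
}

#' Generate a synthetic toy structure
#'
#' Builds a backbone-only (N, CA, C, O) chain from ideal covalent geometry
#' with state-dependent dihedrals: helices (phi, psi) = (-57, -47), which
#' reproduces the canonical ~1.5 A rise per residue and ~100 degree turn;
#' strands (-139, 135), ~3.3 A rise; loops drawn from coil dihedral
#' basins, giving a smooth random walk with the fixed ~3.8 A Ca-Ca step.
#' Residue identities are drawn uniformly from the 20 standard amino
#' acids. B-factors are base + loop bonus + Gaussian noise, shared by the
#' residue's atoms. The ground-truth three-state labels are attached as
#' attribute `ss_true` so feature logic can be tested independently of
#' geometric secondary-structure assignment.
#'
#' @param spec A `toy_spec`.
#' @param structure_id Identifier for the generated model.
#' @return A `structure_model` (source kind experimental, chain "A") with
#'   attribute `ss_true`.
#' @export
generate_toy_structure <- function(spec, structure_id = "toy") {
  set.seed(spec$seed)
  states <- unlist(lapply(spec$plan,
                          function(p) rep(p[1], as.integer(p[2]))))
  n <- length(states)
  stopifnot(n >= 2)
  phi <- numeric(n); psi <- numeric(n)
  phi[states == "helix"] <- -57; psi[states == "helix"] <- -47
  phi[states == "strand"] <- -139; psi[states == "strand"] <- 135
  nl <- sum(states == "loop")
  if (nl > 0) {
    d <- loop_dihedrals(nl)
    phi[states == "loop"] <- d[, 1]
    psi[states == "loop"] <- d[, 2]
  }
  g <- BB_GEOM
  N <- matrix(NA_real_, n, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  th <- deg(g$a_n_ca_c)
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  for (i in 2:n) {
    N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                         g$b_c_n, g$a_ca_c_n, psi[i - 1])
    CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                          g$b_n_ca, g$a_c_n_ca, 180)  # trans omega
    C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                         g$b_ca_c, g$a_n_ca_c, phi[i])
  }
  for (i in 1:n) {
    nxt_psi <- if (i < n) psi[i] else psi[i]
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, nxt_psi + 180)
  }
  letters1 <- sample(AA1, n, replace = TRUE)
  resid3 <- AA3[match(letters1, AA1)]
  b_res <- spec$bfactor_base + spec$bfactor_loop * (states == "loop") +
    rnorm(n, 0, spec$bfactor_sd)
  b_res <- pmax(b_res, 1)
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(n), each = 4),
    insert = "",
    resid = rep(resid3, each = 4),
    elety = rep(c("N", "CA", "C", "O"), n),
    elesy = rep(c("N", "C", "C", "O"), n),
    x = as.vector(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1]))),
    y = as.vector(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2]))),
    z = as.vector(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3]))),
    o = 1,
    b = rep(b_res, each = 4),
    stringsAsFactors = FALSE
  )
  st <- new_structure_model(structure_id, "experimental", atoms)
  attr(st, "ss_true") <- states
  st
}

#' Planted logistic cleavage model
#'
#' Coefficients over the model-scale feature columns; a residue is a
#' cleavage site with probability `logistic(beta . f + intercept)`. The
#' defaults weight the features the way cleavage-prone regions behave:
#' exposed residues, long protruded loops, flexible (high-B) regions and
#' unstructured termini are more susceptible; the secondary-structure
#' binaries themselves carry no extra weight beyond what loop length
#' encodes.
#'
#' @param beta Named coefficients over feature columns.
#' @param intercept Intercept on the logit scale; the default gives toy
#'   corpora a positive rate of roughly 8%.
#' @return Object of class `plant_model`.
#' @export
plant_model <- function(beta = c(rel_acc = 4, ss_helix = 0, ss_strand = 0,
                                 ss_loop = 0, loop_len_norm = 3,
                                 terminus = 2, bfactor_norm = 2),
                        intercept = -8) {
  stopifnot(all(is.finite(beta)), is.finite(intercept))
  structure(list(beta = beta, intercept = intercept),
            class = "plant_model")
}

#' True cleavage probabilities of a planted model on a feature table
#'
#' @param plant A `plant_model`.
#' @param feats Normalized feature table containing the model's columns.
#' @return Numeric vector of probabilities.
#' @export
plant_probabilities <- function(plant, feats) {
  X <- as.matrix(feats[, names(plant$beta), drop = FALSE])
  as.numeric(stats::plogis(X %*% plant$beta + plant$intercept))
}

#' Plant cleavage events on a feature table
#'
#' Labels every residue cleaved with its planted probability (seeded
#' Bernoulli draws) and returns both the event table and the true
#' probabilities, so the Bayes-optimal AUC of the corpus can be computed
#' as an oracle.
#'
#' @param feats Normalized feature table (row-bound over structures) with
#'   `structure_id`, `chain`, and a within-chain residue order.
#' @param plant A `plant_model`.
#' @param seed Integer seed for the Bernoulli draws.
#' @return List with `events` (a `cleavage_events` table; `substrate_id`
#'   is the structure id, `p1_pos` the residue index within the chain),
#'   `labels` (0/1 per row of `feats`), `true_prob`.
#' @export
plant_cleavage_events <- function(feats, plant = plant_model(), seed = 1) {
  p <- plant_probabilities(plant, feats)
  p[!feats$complete] <- 0
  set.seed(as.integer(seed))
  lab <- rbinom(length(p), 1, p)
  # residue index within each chain, in table order
  idx <- stats::ave(seq_len(nrow(feats)),
                    paste(feats$structure_id, feats$chain),
                    FUN = seq_along)
  pos <- which(lab == 1)
  ev <- if (length(pos) > 0) {
    cleavage_events(feats$structure_id[pos], idx[pos],
                    protease_code = "SYN01",
                    source_ref = paste0("synthetic:",
                                        feats$structure_id[pos]))
  } else {
    cleavage_events(character(0), integer(0))
  }
  ev$chain <- feats$chain[pos]
  list(events = ev, labels = lab, true_prob = p)
}

#' Generate aligned cleavage-window peptides from position weights
#'
#' @param weights 20 x W matrix of per-position letter probabilities
#'   (rows named by one-letter codes, columns = window positions).
#' @param n Number of peptides.
#' @param seed Integer seed.
#' @return Character vector of `n` window strings.
#' @export
generate_motif_peptides <- function(weights, n, seed = 1) {
  stopifnot(nrow(weights) == 20,
            all(abs(colSums(weights) - 1) < 1e-8))
  set.seed(as.integer(seed))
  W <- ncol(weights)
  cols <- lapply(seq_len(W), function(j) {
    sample(rownames(weights), n, replace = TRUE, prob = weights[, j])
  })
  do.call(paste0, cols)
}

#' Uniform-background motif weights with enriched letters at chosen positions
#'
#' Convenience builder for generating-model PSSM weights: starts from the
#' uniform distribution and boosts the given letters at the given window
#' positions to probability `p_enriched` (shared equally), renormalizing
#' the rest.
#'
#' @param window Window labels (default [sb_window()]).
#' @param enriched Named list: window position -> character vector of
#'   enriched letters.
#' @param p_enriched Total probability mass of the enriched letters.
#' @return 20 x W weight matrix.
#' @export
motif_weights <- function(window = sb_window(),
                          enriched = list(P1 = c("K", "R")),
                          p_enriched = 0.6) {
  W <- length(window)
  w <- matrix(1 / 20, nrow = 20, ncol = W,
              dimnames = list(AA1, window))
  for (posname in names(enriched)) {
    j <- match(posname, window)
    if (is.na(j)) stop("unknown window position: ", posname)
    lets <- enriched[[posname]]
    w[, j] <- (1 - p_enriched) / (20 - length(lets))
    w[lets, j] <- p_enriched / length(lets)
  }
  w
}
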