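# Three-state secondary structure: DSSP 8-state collapse, plus an internal
# hydrogen-bond-based assigner used when no DSSP output is available.

#' Collapse DSSP 8-state secondary structure to three states
#'
#' H, G, I (helices) map to `helix`; E, B (extended/bridge) to `strand`;
#' T, S and `'-'` to `loop`.
#'
#' @param ss8 Character vector of DSSP classes.
#' @return Character vector over `{"helix", "strand", "loop"}`.
#' @export
ss8_to_ss3 <- function(ss8) {
  map <- c(H = "helix", G = "helix", I = "helix",
           E = "strand", B = "strand",
           T = "loop", S = "loop", "-" = "loop")
  out <- map[ss8]
  if (any(is.na(out))) {
    stop("unknown DSSP class(es): ",
         paste(unique(ss8[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Assign three-state secondary structure from backbone geometry
#'
#' A compact Kabsch-Sander-style assigner used as a fallback when no DSSP
#' output is supplied. Backbone amide hydrogens are reconstructed (N-H
#' parallel to the preceding C=O, 1.0 A), hydrogen-bond energies are
#' computed with the electrostatic model
#' E = 0.084 * 332 * (1/rON + 1/rCH - 1/rOH - 1/rCN) kcal/mol,
#' and a bond is called at E < -0.5 kcal/mol. Two consecutive i+4 -> i
#' turns make a helix; parallel/antiparallel bridge patterns make strand;
#' everything else is loop.
#'
#' @param structure A `structure_model`.
#' @param chain_id Chain to assign.
#' @return Character vector over `{"helix", "strand", "loop"}`, one per
#'   residue of the chain.
#' @export
assign_ss3 <- function(structure, chain_id) {
  res <- chain_residues(structure, chain_id)
  n <- nrow(res)
  at <- structure$atoms[structure$atoms$chain == chain_id, , drop = FALSE]
  key <- paste(at$resno, at$insert, sep = "\r")
  rkey <- paste(res$resno, res$insert, sep = "\r")
  get_atom <- function(name) {
    m <- at[at$elety == name, , drop = FALSE]
    out <- matrix(NA_real_, n, 3)
    idx <- match(paste(m$resno, m$insert, sep = "\r"), rkey)
    ok <- !is.na(idx)
    out[idx[ok], ] <- cbind(m$x, m$y, m$z)[ok, , drop = FALSE]
    out
  }
  N <- get_atom("N"); CA <- get_atom("CA")
  C <- get_atom("C"); O <- get_atom("O")
  # amide H of residue i from the C=O of residue i-1
  H <- matrix(NA_real_, n, 3)
  if (n >= 2) {
    for (i in 2:n) {
      v <- C[i - 1, ] - O[i - 1, ]
      nv <- sqrt(sum(v^2))
      if (is.finite(nv) && nv > 0) H[i, ] <- N[i, ] + v / nv
    }
  }
  dist1 <- function(a, b) sqrt(sum((a - b)^2))
  hbond <- matrix(FALSE, n, n)  # hbond[i, j]: NH of i donates to CO of j
  for (i in seq_len(n)) {
    if (any(is.na(H[i, ])) || any(is.na(N[i, ]))) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2 || any(is.na(C[j, ])) || any(is.na(O[j, ]))) next
      rON <- dist1(O[j, ], N[i, ])
      if (rON > 5.2) next
      e <- 0.084 * 332 * (1 / rON + 1 / dist1(C[j, ], H[i, ]) -
                            1 / dist1(O[j, ], H[i, ]) -
                            1 / dist1(C[j, ], N[i, ]))
      hbond[i, j] <- is.finite(e) && e < -0.5
    }
  }
  turn4 <- rep(FALSE, n)  # turn4[i]: NH(i+4) -> CO(i)
  if (n >= 5) for (i in seq_len(n - 4)) turn4[i] <- hbond[i + 4, i]
  ss <- rep("loop", n)
  if (n >= 5) {
    for (i in 2:(n - 4)) {
      if (turn4[i - 1] && turn4[i]) ss[i:(i + 3)] <- "helix"
    }
  }
  for (i in 2:max(2, n - 1)) {
    if (i >= n) break
    for (j in seq_len(n)) {
      if (abs(i - j) <= 2 || j < 2 || j >= n) next
      para <- (hbond[j, i - 1] && hbond[i + 1, j]) ||
        (hbond[i, j - 1] && hbond[j + 1, i])
      anti <- (hbond[i, j] && hbond[j, i]) ||
        (hbond[j - 1, i + 1] && hbond[i - 1, j + 1])
      if ((para || anti) && ss[i] != "helix") ss[i] <- "strand"
    }
  }
  ss
}
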