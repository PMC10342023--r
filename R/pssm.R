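# Protease primary-specificity models: position-specific scoring matrices
# over the Schechter-Berger window around the scissile bond (default
# P4..P1 | P1'..P4'), in log2-odds (bits) against a background.

#' Default Schechter-Berger window labels
#' @param n_left Positions on the non-prime side (default 4).
#' @param n_right Positions on the prime side (default 4).
#' @return Character vector, e.g. `c("P4","P3","P2","P1","P1p","P2p",...)`.
#' @export
sb_window <- function(n_left = 4, n_right = 4) {
  c(paste0("P", n_left:1), paste0("P", seq_len(n_right), "p"))
}

#' Build a position-specific scoring matrix from cleavage-site windows
#'
#' Entry for amino acid `a` at window position `j` is
#' `log2( ((count(a, j) + alpha * b_a) / (N_j + alpha)) / b_a )`
#' where `N_j` is the number of non-X letters in column `j`, `b_a` the
#' background frequency, and `alpha` the total pseudocount mass
#' distributed proportionally to the background (so columns matching the
#' background give exactly zero bits). `X` letters are skipped per
#' column.
#'
#' @param peptides Character vector of fixed-width window strings (P1 at
#'   position `n_left`).
#' @param alpha Pseudocount mass (default 1).
#' @param background Named numeric vector of background frequencies over
#'   the 20 amino acids (default uniform 0.05), or `"uniform"`.
#' @param window Window labels; length must equal `nchar(peptides)`.
#' @return Object of class `pssm`: list with `matrix` (20 x window,
#'   bits), `window`, `alpha`, `background`, `n_peptides`.
#' @export
build_pssm <- function(peptides, alpha = 1, background = "uniform",
                       window = sb_window()) {
  if (length(peptides) == 0L) stop("empty peptide set")
  W <- length(window)
  if (any(nchar(peptides) != W)) {
    stop("all peptides must have window length ", W)
  }
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(1 / 20, 20), AA1)
  }
  stopifnot(all(AA1 %in% names(background)),
            abs(sum(background) - 1) < 1e-6)
  background <- background[AA1]
  mat <- matrix(0, nrow = 20, ncol = W, dimnames = list(AA1, window))
  letters_by_col <- do.call(rbind, strsplit(peptides, ""))
  for (j in seq_len(W)) {
    col <- letters_by_col[, j]
    col <- col[col != "X"]
    bad <- setdiff(unique(col), AA1)
    if (length(bad) > 0) {
      stop("nonstandard letter(s) in peptides: ",
           paste(bad, collapse = ", "))
    }
    nj <- length(col)
    cnt <- table(factor(col, levels = AA1))
    mat[, j] <- log2(((as.numeric(cnt) + alpha * background) /
                        (nj + alpha)) / background)
  }
  structure(
    list(matrix = mat, window = window, alpha = alpha,
         background = background, n_peptides = length(peptides)),
    class = "pssm"
  )
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM over window", paste(x$window, collapse = " "),
      "built from", x$n_peptides, "peptides (bits)\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Score a candidate cleavage site with a PSSM
#'
#' Sums matrix entries over the window aligned so that P1 sits at
#' `p1_index` of the sequence. Window positions falling outside the
#' sequence, and `X` letters, contribute 0 bits.
#'
#' @param pssm A `pssm`.
#' @param sequence Protein sequence (string).
#' @param p1_index 1-based P1 position(s); vectorized.
#' @return Numeric score(s) in bits.
#' @export
pssm_score <- function(pssm, sequence, p1_index) {
  n <- nchar(sequence)
  if (any(p1_index < 1 | p1_index > n)) {
    stop("p1_index outside sequence (length ", n, ")")
  }
  W <- length(pssm$window)
  n_left <- sum(!grepl("p$", pssm$window))
  offsets <- seq_len(W) - n_left  # P1 at offset 0
  chars <- strsplit(sequence, "")[[1]]
  vapply(p1_index, function(p1) {
    pos <- p1 + offsets
    keep <- pos >= 1 & pos <= n
    s <- 0
    for (j in which(keep)) {
      aa <- chars[pos[j]]
      if (aa %in% rownames(pssm$matrix)) s <- s + pssm$matrix[aa, j]
    }
    s
  }, numeric(1))
}

#' Write a PSSM as TSV plus a JSON sidecar
#'
#' The TSV holds the matrix (rows = amino acids, columns = window
#' positions); the sidecar `<path>.json` records alpha, background and
#' window so the model is fully reconstructable.
#'
#' @param pssm A `pssm`.
#' @param path TSV output path.
#' @return Invisibly, `path`.
#' @export
write_pssm <- function(pssm, path) {
  df <- data.frame(aa = rownames(pssm$matrix), pssm$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(alpha = pssm$alpha, background = as.list(pssm$background),
         window = pssm$window, n_peptides = pssm$n_peptides),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a PSSM written by [write_pssm()]
#' @param path TSV path (expects `<path>.json` sidecar).
#' @return A `pssm`.
#' @export
read_pssm <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$aa
  colnames(mat) <- meta$window
  structure(
    list(matrix = mat, window = meta$window, alpha = meta$alpha,
         background = unlist(meta$background)[rownames(mat)],
         n_peptides = meta$n_peptides),
    class = "pssm"
  )
}
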