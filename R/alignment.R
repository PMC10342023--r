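# Global pairwise alignment used to map substrate-sequence positions onto
# structure residues. Needleman-Wunsch with affine gaps (Gotoh), BLOSUM62
# scoring, and fixed tie-breaking so the position map is deterministic.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global alignment of a substrate sequence against a structure sequence
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh's algorithm):
#' BLOSUM62 substitution scores, gap open 10, gap extend 0.5 (a gap of
#' length L costs `10 + 0.5 * (L - 1)`). Ties in the traceback prefer
#' match/mismatch over a gap in the second sequence over a gap in the
#' first, which makes the returned map deterministic.
#'
#' @param seq_a Substrate sequence (string; letters outside the 20 standard
#'   plus X are scored as X).
#' @param seq_b Structure sequence (string).
#' @param gap_open Gap opening penalty (positive number, default 10).
#' @param gap_extend Gap extension penalty (positive number, default 0.5).
#' @return An object of class `alignment_map`: list with `map` (integer
#'   vector of length `nchar(seq_a)`; `map[i]` is the aligned position in
#'   `seq_b` or `NA` for a gap), `score`, `identity` (percent identity
#'   over aligned columns) and the two aligned strings.
#' @export
global_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  sub <- blosum62_matrix()
  a_s <- ifelse(a %in% rownames(sub), a, "X")
  b_s <- ifelse(b %in% rownames(sub), b, "X")
  n <- length(a); m <- length(b)
  NEG <- -1e9
  # M: a[i] aligned to b[j]; Ix: gap in b (a[i] unaligned); Iy: gap in a
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) Ix[2:(n + 1), 1] <- -gap_open - gap_extend * (0:(n - 1))
  if (m >= 1) Iy[1, 2:(m + 1)] <- -gap_open - gap_extend * (0:(m - 1))
  for (i in 2:(n + 1)) {
    si <- sub[a_s[i - 1], b_s]
    for (j in 2:(m + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
        si[j - 1]
      Ix[i, j] <- max(M[i - 1, j] - gap_open, Ix[i - 1, j] - gap_extend,
                      Iy[i - 1, j] - gap_open)
      Iy[i, j] <- max(M[i, j - 1] - gap_open, Iy[i, j - 1] - gap_extend,
                      Ix[i, j - 1] - gap_open)
    }
  }
  # traceback, preferring diagonal (M), then up (Ix), then left (Iy)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], Ix[i, j], Iy[i, j]))
  map <- rep(NA_integer_, n)
  al_a <- character(0); al_b <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      map[i - 1] <- j - 1
      al_a <- c(a[i - 1], al_a); al_b <- c(b[j - 1], al_b)
      sc <- sub[a_s[i - 1], b_s[j - 1]]
      prev <- c(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      al_a <- c(a[i - 1], al_a); al_b <- c("-", al_b)
      cand <- c(M[i - 1, j] - gap_open, Ix[i - 1, j] - gap_extend,
                Iy[i - 1, j] - gap_open)
      state <- which.max(cand)
      i <- i - 1
    } else {
      al_a <- c("-", al_a); al_b <- c(b[j - 1], al_b)
      cand <- c(M[i, j - 1] - gap_open, Iy[i, j - 1] - gap_extend,
                Ix[i, j - 1] - gap_open)
      state <- c(1, 3, 2)[which.max(cand)]
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- 3
    if (j == 1 && i > 1) state <- 2
  }
  map <- as.integer(map)
  aligned <- !is.na(map)
  ident <- if (any(aligned)) {
    100 * mean(a[aligned] == b[map[aligned]])
  } else 0
  structure(
    list(map = map, score = max(M[n + 1, m + 1], Ix[n + 1, m + 1],
                                Iy[n + 1, m + 1]),
         identity = ident,
         aligned_a = paste(al_a, collapse = ""),
         aligned_b = paste(al_b, collapse = "")),
    class = "alignment_map"
  )
}

#' @export
print.alignment_map <- function(x, ...) {
  cat("global alignment, score", format(x$score), "identity",
      sprintf("%.1f%%", x$identity), "\n")
  cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n")
  invisible(x)
}
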