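# Hand-written fixtures and independent oracles shared across the tests.

pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          b = 20, occ = 1, ele = substr(name, 1, 1),
                          record = "ATOM") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
    sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, resid, chain, resno, x, y, z, occ, b, ele)
}

# one ALA residue, 5 atoms (backbone + CB), chain A, B = 20
write_single_residue_pdb <- function(path, b = 20) {
  writeLines(c(
    pdb_atom_line(1, "N",  "ALA", "A", 1, 11.104, 6.134, -6.504, b),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 11.639, 6.071, -5.147, b),
    pdb_atom_line(3, "C",  "ALA", "A", 1, 13.134, 6.380, -5.141, b),
    pdb_atom_line(4, "O",  "ALA", "A", 1, 13.675, 6.852, -4.141, b),
    pdb_atom_line(5, "CB", "ALA", "A", 1, 10.880, 7.066, -4.269, b),
    "END"), path)
  path
}

# chain A: ALA, GLY, TRP (3 residues); chain B: SER, VAL (2 residues)
write_two_chain_pdb <- function(path) {
  lines <- character(0)
  resA <- c("ALA", "GLY", "TRP"); resB <- c("SER", "VAL")
  s <- 0
  for (i in seq_along(resA)) {
    for (nm in c("N", "CA", "C", "O")) {
      s <- s + 1
      lines <- c(lines, pdb_atom_line(s, nm, resA[i], "A", i,
                                      3.8 * i + s %% 2, s %% 3, 0,
                                      b = 10 + i))
    }
  }
  for (i in seq_along(resB)) {
    for (nm in c("N", "CA", "C", "O")) {
      s <- s + 1
      lines <- c(lines, pdb_atom_line(s, nm, resB[i], "B", i,
                                      3.8 * i, 10 + s %% 3, 5,
                                      b = 30 + i))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

dssp_line <- function(serial, resno, chain, aa, ss, acc, icode = " ") {
  sprintf("%5d%5d%1s%1s %1s  %1s%17s%4d", serial, resno, icode, chain,
          aa, ss, "", acc)
}

write_dssp_fixture <- function(path, ss = c("H", "H", "E"),
                               acc = c(100, 50, 20),
                               aa = c("A", "G", "W"), chain = "A",
                               breaks = integer(0)) {
  body <- character(0)
  s <- 0
  for (i in seq_along(ss)) {
    if (i %in% breaks) {
      s <- s + 1
      body <- c(body, sprintf("%5d%5s %1s!%21s", s, "", " ", ""))
    }
    s <- s + 1
    body <- c(body, dssp_line(s, i, chain, aa[i], ss[i], acc[i]))
  }
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    body), path)
  path
}

# ---- oracles ---------------------------------------------------------------

# Mann-Whitney pair-counting AUC
auc_pair_oracle <- function(scores, labels) {
  p <- scores[labels == 1]; n <- scores[labels == 0]
  (sum(outer(p, n, ">")) + 0.5 * sum(outer(p, n, "=="))) /
    (length(p) * length(n))
}

# brute-force maximal-run scanner for the loop-length feature
loop_len_oracle <- function(ss3) {
  n <- length(ss3)
  out <- integer(n)
  for (i in seq_len(n)) {
    if (ss3[i] != "loop") next
    lo <- i; while (lo > 1 && ss3[lo - 1] == "loop") lo <- lo - 1
    hi <- i; while (hi < n && ss3[hi + 1] == "loop") hi <- hi + 1
    out[i] <- hi - lo + 1
  }
  out
}

# exhaustive global-alignment score: enumerates every alignment path,
# affine gap cost open + extend * (L - 1), same convention as the package
align_score_oracle <- function(a, b, sub, gap_open = 10,
                               gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  best <- -Inf
  rec <- function(i, j, last, score) {
    if (i > n && j > m) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= n && j <= m) {
      rec(i + 1, j + 1, "M", score + sub[av[i], bv[j]])
    }
    if (i <= n) {
      rec(i + 1, j, "X",
          score - if (identical(last, "X")) gap_extend else gap_open)
    }
    if (j <= m) {
      rec(i, j + 1, "Y",
          score - if (identical(last, "Y")) gap_extend else gap_open)
    }
  }
  rec(1, 1, "", 0)
  best
}

# score of a concrete alignment (two gapped strings), same gap convention
aligned_strings_score <- function(al_a, al_b, sub, gap_open = 10,
                                  gap_extend = 0.5) {
  a <- strsplit(al_a, "")[[1]]; b <- strsplit(al_b, "")[[1]]
  s <- 0; last <- ""
  for (k in seq_along(a)) {
    if (a[k] != "-" && b[k] != "-") {
      s <- s + sub[a[k], b[k]]; last <- "M"
    } else if (a[k] == "-") {
      s <- s - if (identical(last, "Y")) gap_extend else gap_open
      last <- "Y"
    } else {
      s <- s - if (identical(last, "X")) gap_extend else gap_open
      last <- "X"
    }
  }
  s
}

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

random_aa_string <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
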