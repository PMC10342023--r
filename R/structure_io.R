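# Reading and writing protein structures and DSSP output.
#
# Structures are held as a `structure_model`: a list with the atom table
# (one row per kept atom) and a per-residue summary table. Only the first
# MODEL of multi-model files and alternate locations '' or 'A' are kept, so
# every residue has a single conformer. HETATM records (including waters)
# are dropped.

#' Read a protein structure from a fixed-column PDB file
#'
#' Parses ATOM records of a PDB file into a `structure_model`. Waters and
#' other HETATM records are dropped, as are alternate locations other than
#' `''`/`'A'`; only the first MODEL of a multi-model file is used. The
#' per-residue temperature factor is the unweighted mean over the residue's
#' atoms. For `source_kind = "predicted"` the temperature-factor column is
#' interpreted as a per-residue model confidence in \[0, 100\] (pLDDT
#' convention) rather than a crystallographic B-factor.
#'
#' @param path Path to a PDB file.
#' @param source_kind `"experimental"` (default) or `"predicted"`.
#' @param structure_id Identifier stored with the model; defaults to the
#'   file name without extension.
#' @return An object of class `structure_model`: a list with elements
#'   `structure_id`, `source_kind`, `atoms` (data frame with chain, resno,
#'   insert, resid, elety, elesy, x, y, z, o, b) and `residues` (data frame
#'   with chain, resno, insert, resid, one_letter, tempfactor).
#' @export
read_structure <- function(path, source_kind = c("experimental", "predicted"),
                           structure_id = NULL) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(structure_id)) {
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("could not parse PDB file '", path, "': ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  alt <- at$alt
  alt[is.na(alt)] <- ""
  at <- at[alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in '", path, "'")
  ins <- at$insert
  ins[is.na(ins)] <- ""
  atoms <- data.frame(
    chain  = as.character(at$chain),
    resno  = as.integer(at$resno),
    insert = as.character(ins),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    elesy  = guess_element(at),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    stringsAsFactors = FALSE
  )
  new_structure_model(structure_id, source_kind, atoms)
}

guess_element <- function(at) {
  ele <- at$elesy
  bad <- is.na(ele) | ele == ""
  if (any(bad)) {
    # fall back to the first alphabetic character of the atom name
    ele[bad] <- substr(gsub("[^A-Za-z].*$", "",
                            gsub("^[0-9]*", "", at$elety[bad])), 1, 1)
  }
  toupper(ele)
}

new_structure_model <- function(structure_id, source_kind, atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  # preserve file order of residues (first occurrence)
  idx <- !duplicated(key)
  res <- data.frame(
    chain  = atoms$chain[idx],
    resno  = atoms$resno[idx],
    insert = atoms$insert[idx],
    resid  = atoms$resid[idx],
    stringsAsFactors = FALSE
  )
  one <- AA3TO1[res$resid]
  one[is.na(one)] <- "X"
  res$one_letter <- unname(one)
  res$tempfactor <- as.numeric(
    tapply(atoms$b, factor(key, levels = key[idx]), mean)
  )
  structure(
    list(structure_id = structure_id, source_kind = source_kind,
         atoms = atoms, residues = res),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$structure_id, "' (", x$source_kind, ")\n",
      sep = "")
  tab <- table(x$residues$chain)
  cat("  chains:",
      paste(sprintf("%s (%d residues)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  invisible(x)
}

#' Chain identifiers of a structure
#' @param structure A `structure_model`.
#' @return Character vector of chain ids in file order.
#' @export
structure_chains <- function(structure) {
  unique(structure$residues$chain)
}

#' Extract the one-letter sequence of a chain
#'
#' One letter per resolved residue, in residue order; residues outside the
#' 20 standard amino acids (e.g. MSE) become `'X'`.
#'
#' @param structure A `structure_model`.
#' @param chain_id Chain identifier.
#' @return A single string (possibly `""` for an empty chain).
#' @export
extract_sequence <- function(structure, chain_id) {
  if (!chain_id %in% structure$residues$chain) {
    stop("chain '", chain_id, "' not present in structure '",
         structure$structure_id, "'")
  }
  paste(structure$residues$one_letter[structure$residues$chain == chain_id],
        collapse = "")
}

#' Residue table of one chain
#' @param structure A `structure_model`.
#' @param chain_id Chain identifier.
#' @return The per-residue data frame restricted to the chain.
#' @export
chain_residues <- function(structure, chain_id) {
  if (!chain_id %in% structure$residues$chain) {
    stop("chain '", chain_id, "' not present in structure '",
         structure$structure_id, "'")
  }
  out <- structure$residues[structure$residues$chain == chain_id, ,
                            drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- DSSP ------------------------------------------------------------------

#' Parse classic DSSP output
#'
#' Reads the residue lines of a classic-format DSSP file (the fixed-column
#' layout produced by `mkdssp` with default options). Chain-break lines
#' (`'!'` in the amino-acid column) are skipped; a blank secondary-structure
#' column becomes `'-'`.
#'
#' @param path Path to a DSSP output file.
#' @return Data frame with columns `chain`, `resno`, `insert`, `aa`, `ss8`
#'   (one of H, G, I, E, B, T, S, `-`) and `acc` (absolute accessible
#'   surface, square Angstroms).
#' @export
parse_dssp <- function(path) {
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L) {
    stop("not a classic DSSP file (missing '  #  RESIDUE' header): ", path)
  }
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 38]
  aa <- substr(body, 14, 14)
  keep <- aa != "!"
  body <- body[keep]
  aa <- aa[keep]
  ss8 <- substr(body, 17, 17)
  ss8[ss8 == " "] <- "-"
  bad <- !ss8 %in% c("H", "G", "I", "E", "B", "T", "S", "-")
  if (any(bad)) {
    # DSSP variants emit P (polyproline) in newer versions; treat as loop
    ss8[bad] <- "-"
  }
  acc <- as.numeric(substr(body, 35, 38))
  if (any(is.na(acc))) stop("unparseable ACC field in DSSP file: ", path)
  if (any(acc < 0)) stop("negative accessibility in DSSP file: ", path)
  data.frame(
    chain  = substr(body, 12, 12),
    resno  = as.integer(substr(body, 6, 10)),
    insert = trimws(substr(body, 11, 11)),
    aa     = aa,
    ss8    = ss8,
    acc    = acc,
    stringsAsFactors = FALSE
  )
}

# ---- writing ---------------------------------------------------------------

#' Write a structure with per-residue scores in the temperature-factor column
#'
#' Writes fixed-column ATOM records identical to the input structure except
#' that the temperature-factor column carries `score * 100`, formatted
#' `%6.2f`, for every atom of the residue. Reading the file back recovers
#' the scores to two decimals; this is the standard way to colour a
#' structure by prediction score in a molecular viewer.
#'
#' @param structure A `structure_model`.
#' @param scores Numeric vector in \[0, 1\], one per residue of the
#'   structure (all chains, file order).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_score_structure <- function(structure, scores, path) {
  res <- structure$residues
  if (length(scores) != nrow(res)) {
    stop("need one score per residue: got ", length(scores), " scores for ",
         nrow(res), " residues")
  }
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("scores must be finite and within [0, 1]")
  }
  key <- paste(structure$atoms$chain, structure$atoms$resno,
               structure$atoms$insert, sep = "\r")
  rkey <- paste(res$chain, res$resno, res$insert, sep = "\r")
  b <- scores[match(key, rkey)] * 100
  write_pdb_atoms(structure$atoms, b, path)
  invisible(path)
}

#' Write the atom table of a structure as a PDB file
#'
#' @param structure A `structure_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(structure, path) {
  write_pdb_atoms(structure$atoms, structure$atoms$b, path)
  invisible(path)
}

write_pdb_atoms <- function(atoms, b, path) {
  # PDB v3.3 ATOM record; atom names of <4 characters start in column 14
  name <- ifelse(nchar(atoms$elety) >= 4, substr(atoms$elety, 1, 4),
                 sprintf(" %-3s", atoms$elety))
  lines <- sprintf(
    "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)) %% 100000L, name, atoms$resid, atoms$chain,
    atoms$resno, ifelse(atoms$insert == "", " ", atoms$insert),
    atoms$x, atoms$y, atoms$z, atoms$o, b, atoms$elesy
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
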