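# Mapping proteolytic events (substrate id, 1-based P1 position, protease
# code) onto structure residues, and the automated curation filter that
# drops publication groups of cleavages buried in the hydrophobic core.

#' Construct a cleavage-event table
#'
#' @param substrate_id Substrate identifiers.
#' @param p1_pos 1-based position of the P1 residue (the residue on the
#'   N-terminal side of the cleaved bond) in the substrate sequence.
#' @param protease_code Protease identifiers (MEROPS codes in real data).
#' @param source_ref Publication/record tokens grouping events for
#'   curation.
#' @return Data frame of class `cleavage_events`.
#' @export
cleavage_events <- function(substrate_id, p1_pos, protease_code = "unknown",
                            source_ref = "unknown") {
  p1_pos <- as.integer(p1_pos)
  if (any(p1_pos < 1)) stop("p1_pos must be >= 1 (1-based)")
  out <- data.frame(substrate_id = substrate_id, p1_pos = p1_pos,
                    protease_code = protease_code, source_ref = source_ref,
                    stringsAsFactors = FALSE)
  class(out) <- c("cleavage_events", "data.frame")
  out
}

#' Read a cleavage-event table from TSV
#'
#' Expects columns `substrate_id`, `p1_pos`, and optionally
#' `protease_code`, `source_ref`.
#'
#' @param path TSV file path.
#' @return A `cleavage_events` data frame.
#' @export
read_events <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("substrate_id", "p1_pos") %in% names(x))) {
    stop("event table needs columns substrate_id, p1_pos: ", path)
  }
  cleavage_events(
    x$substrate_id, x$p1_pos,
    if ("protease_code" %in% names(x)) x$protease_code else "unknown",
    if ("source_ref" %in% names(x)) x$source_ref else "unknown"
  )
}

#' Map one cleavage event onto a structure chain
#'
#' Uses a substrate-to-structure alignment map to find the structure
#' residue carrying the P1 position. The event is rejected (with a reason)
#' when P1 falls into an alignment gap (residue unresolved in the
#' structure, e.g. a disordered region) or when the aligned residue letter
#' differs from the substrate letter at P1 (default policy; set
#' `allow_mismatch = TRUE` to map anyway).
#'
#' @param event One row of a `cleavage_events` table.
#' @param posmap An `alignment_map` from [global_align()] of substrate
#'   sequence vs structure chain sequence.
#' @param substrate_seq The substrate sequence that was aligned.
#' @param structure_seq The structure chain sequence that was aligned.
#' @param allow_mismatch Map events whose aligned letters differ.
#' @return List with `mapped` (logical), `residue_index` (1-based index in
#'   the structure chain, or NA) and `reason` (`"ok"`, `"unresolved"`,
#'   `"mismatch"`).
#' @export
map_event <- function(event, posmap, substrate_seq, structure_seq,
                      allow_mismatch = FALSE) {
  p1 <- event$p1_pos
  if (p1 < 1 || p1 > nchar(substrate_seq)) {
    stop("p1_pos ", p1, " outside substrate sequence (length ",
         nchar(substrate_seq), ")")
  }
  j <- posmap$map[p1]
  if (is.na(j)) {
    return(list(mapped = FALSE, residue_index = NA_integer_,
                reason = "unresolved"))
  }
  if (substr(substrate_seq, p1, p1) != substr(structure_seq, j, j) &&
      !allow_mismatch) {
    return(list(mapped = FALSE, residue_index = NA_integer_,
                reason = "mismatch"))
  }
  list(mapped = TRUE, residue_index = as.integer(j), reason = "ok")
}

#' Map a table of cleavage events onto structure chains
#'
#' Convenience wrapper over [global_align()] and [map_event()] for many
#' events sharing substrate sequences and structures. A warning is issued
#' when substrate/structure identity falls below `min_identity` percent.
#'
#' @param events A `cleavage_events` table.
#' @param substrate_seqs Named character vector of substrate sequences.
#' @param structures Named list of `structure_model`s (names =
#'   substrate_id).
#' @param chain_map Named character vector: substrate_id -> chain id.
#' @param allow_mismatch Passed to [map_event()].
#' @param min_identity Warn below this percent identity (default 90).
#' @return Data frame: the events plus `mapped`, `structure_id`, `chain`,
#'   `residue_index`, `reason`.
#' @export
map_events <- function(events, substrate_seqs, structures, chain_map,
                       allow_mismatch = FALSE, min_identity = 90) {
  out <- as.data.frame(events)
  out$mapped <- FALSE
  out$structure_id <- NA_character_
  out$chain <- NA_character_
  out$residue_index <- NA_integer_
  out$reason <- NA_character_
  for (sid in unique(out$substrate_id)) {
    rows <- which(out$substrate_id == sid)
    if (!sid %in% names(substrate_seqs) || !sid %in% names(structures)) {
      out$reason[rows] <- "no_structure"
      next
    }
    st <- structures[[sid]]
    ch <- if (sid %in% names(chain_map)) chain_map[[sid]] else
      structure_chains(st)[1]
    sseq <- substrate_seqs[[sid]]
    tseq <- extract_sequence(st, ch)
    pm <- if (sseq == tseq) identity_alignment(sseq) else
      global_align(sseq, tseq)
    if (pm$identity < min_identity) {
      warning("substrate '", sid, "' aligns to structure at ",
              sprintf("%.1f%%", pm$identity), " identity")
    }
    for (r in rows) {
      m <- map_event(out[r, ], pm, sseq, tseq, allow_mismatch)
      out$mapped[r] <- m$mapped
      out$structure_id[r] <- st$structure_id
      out$chain[r] <- ch
      out$residue_index[r] <- m$residue_index
      out$reason[r] <- m$reason
    }
  }
  out
}

identity_alignment <- function(seq) {
  n <- nchar(seq)
  structure(list(map = seq_len(n), score = NA_real_, identity = 100,
                 aligned_a = seq, aligned_b = seq),
            class = "alignment_map")
}

#' Automated curation filter for publication groups of buried cleavages
#'
#' Multiple cleavages reported by a single publication that sit
#' predominantly inside the hydrophobic core indicate that the substrate
#' lost its native fold during the experiment; such groups are excluded as
#' a whole. A group (same `source_ref`) is dropped when it has at least
#' `min_group` mapped sites and more than `core_fraction` of them are
#' buried (`rel_acc < burial_threshold`). This is an automated,
#' threshold-based stand-in for visual inspection, and it emits an audit
#' log justifying every removal.
#'
#' @param mapped Data frame of mapped events with a `rel_acc` column
#'   (relative accessibility of the P1 residue) and `source_ref`.
#' @param burial_threshold Relative accessibility below which a site
#'   counts as buried (default 0.05).
#' @param core_fraction Fraction of buried sites above which the group is
#'   excluded (default 0.5, strict inequality).
#' @param min_group Minimum group size for the rule to apply (default 2).
#' @return List with `retained` (data frame), `excluded` (data frame) and
#'   `log` (character vector, one line per excluded group).
#' @export
curation_filter <- function(mapped, burial_threshold = 0.05,
                            core_fraction = 0.5, min_group = 2) {
  stopifnot("rel_acc" %in% names(mapped), "source_ref" %in% names(mapped))
  drop <- rep(FALSE, nrow(mapped))
  log <- character(0)
  for (ref in unique(mapped$source_ref)) {
    rows <- which(mapped$source_ref == ref)
    if (length(rows) < min_group) next
    buried <- mapped$rel_acc[rows] < burial_threshold
    frac <- mean(buried)
    if (frac > core_fraction) {
      drop[rows] <- TRUE
      log <- c(log, sprintf(
        "excluded source '%s': %d/%d sites buried (rel_acc < %.2f) = %.0f%% > %.0f%%",
        ref, sum(buried), length(rows), burial_threshold, 100 * frac,
        100 * core_fraction))
    }
  }
  list(retained = mapped[!drop, , drop = FALSE],
       excluded = mapped[drop, , drop = FALSE],
       log = log)
}
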