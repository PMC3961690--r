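AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

check_sequence <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters), c(AA_STANDARD, "X"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid residue letter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  letters
}

#' Find -CXXC- motifs in a protein sequence
#'
#' Returns all 0-based start indices `i` with a cysteine at `i` and at
#' `i + 3`, any two residues in between. Overlapping motifs are all
#' reported; an empty integer vector means no motif.
#'
#' @param seq One-letter upper-case amino-acid string (standard alphabet
#'   plus `X`).
#' @return Integer vector of 0-based motif start indices.
#' @export
find_cxxc <- function(seq) {
  check_sequence(seq)
  hits <- gregexpr("C(?=..C)", seq, perl = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits) - 1L
}

#' Extract the extended active-site positions around a -CXXC- motif
#'
#' Beyond the cysteine pair itself, the reactivity of a thioredoxin-fold
#' active site is tuned by residues at characteristic positions: an acidic
#' residue on strand beta-1 six positions before the N-terminal cysteine, an
#' acidic residue downstream in helix alpha-1 (seven positions after the
#' cysteine by default, six in some reductant-provision families), and a
#' distal partner on strand beta-2 capable of stabilizing a buried
#' carboxylate anion through a hydrogen bond or salt bridge. The partner
#' cannot sit at a fixed offset across families, so it is located as the
#' first residue from `partner_residues` within `partner_window`
#' (offsets relative to the N-terminal cysteine), or taken from an explicit
#' offset override.
#'
#' Slots whose position falls outside the sequence are marked missing
#' (`NA`), never silently truncated.
#'
#' @param seq One-letter amino-acid string.
#' @param motif_index 0-based index returned by [find_cxxc()].
#' @param sequence_id Free-text identifier carried into the record.
#' @param acidic_offset Offset of the downstream helix alpha-1 acidic slot
#'   (default `+7`; use `+6` for CcmG-like spacing).
#' @param partner_window Length-2 integer vector of offsets scanned for the
#'   distal partner (default `c(20, 35)`).
#' @param partner_residues Residues accepted as the distal partner.
#' @param partner_offset Optional explicit partner offset (overrides the
#'   window scan, e.g. from a curated alignment column).
#' @param annotations Optional named list of user annotations (e.g.
#'   `buried = TRUE`); burial cannot be computed from sequence and is only
#'   ever accepted as an annotation.
#' @return An object of class `extended_site_record` with elements
#'   `sequence_id`, `cys_n_pos`, `xx_residues`, `beta1_minus6`,
#'   `alpha1_residue`, `alpha1_offset`, `partner_residue`, `partner_offset`,
#'   `annotations`.
#' @export
extract_extended_site <- function(seq, motif_index, sequence_id = "",
                                  acidic_offset = 7L,
                                  partner_window = c(20L, 35L),
                                  partner_residues = c("Q", "N", "K", "R", "H"),
                                  partner_offset = NULL,
                                  annotations = list()) {
  letters <- check_sequence(seq)
  n <- length(letters)
  i <- as.integer(motif_index) # 0-based
  if (i < 0L || i + 3L >= n ||
      letters[i + 1L] != "C" || letters[i + 4L] != "C") {
    stop(sprintf("motif_index %d is not the 0-based start of a C..C motif", i),
         call. = FALSE)
  }
  at <- function(offset) {
    pos <- i + offset # 0-based
    if (pos < 0L || pos >= n) NA_character_ else letters[pos + 1L]
  }
  xx <- paste0(letters[i + 2L], letters[i + 3L])
  beta1 <- at(-6L)
  alpha1 <- at(as.integer(acidic_offset))

  if (!is.null(partner_offset)) {
    partner_res <- at(as.integer(partner_offset))
    partner_off <- if (is.na(partner_res)) NA_integer_ else
      as.integer(partner_offset)
    if (is.na(partner_res)) partner_res <- NA_character_
  } else {
    stopifnot(length(partner_window) == 2L,
              partner_window[1L] <= partner_window[2L])
    partner_res <- NA_character_
    partner_off <- NA_integer_
    for (off in seq.int(partner_window[1L], partner_window[2L])) {
      r <- at(off)
      if (!is.na(r) && r %in% partner_residues) {
        partner_res <- r
        partner_off <- as.integer(off)
        break
      }
    }
  }
  structure(
    list(
      sequence_id = as.character(sequence_id),
      cys_n_pos = i,
      xx_residues = xx,
      beta1_minus6 = beta1,
      alpha1_residue = alpha1,
      alpha1_offset = as.integer(acidic_offset),
      partner_residue = partner_res,
      partner_offset = partner_off,
      annotations = annotations
    ),
    class = "extended_site_record"
  )
}

record_slot <- function(record, slot) {
  switch(slot,
         beta1_minus6 = record$beta1_minus6,
         alpha1 = record$alpha1_residue,
         partner = record$partner_residue,
         xx = record$xx_residues,
         stop(sprintf("unknown slot \"%s\"", slot), call. = FALSE))
}

#' Tabulate residue conservation at an extended-site slot
#'
#' Counts and percentages of the residues occupying one extended-site slot
#' across a set of records. Records with the slot missing are excluded from
#' the denominator and reported separately via the `n_missing` attribute.
#'
#' @param records List of [extract_extended_site()] records.
#' @param slot One of `"beta1_minus6"`, `"alpha1"`, `"partner"`, `"xx"`.
#' @return A `conservation_table` data frame with columns `residue`,
#'   `count`, `percent` (descending count order), and attributes `slot`,
#'   `total` (records with the slot present), `n_missing`.
#' @export
tabulate_conservation <- function(records, slot) {
  if (inherits(records, "extended_site_record")) records <- list(records)
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1),
                       "extended_site_record")))
  values <- vapply(records, record_slot, character(1), slot = slot)
  present <- values[!is.na(values)]
  if (length(present) == 0L) {
    stop(sprintf("slot \"%s\" is missing from every record", slot),
         call. = FALSE)
  }
  counts <- sort(table(present), decreasing = TRUE)
  out <- data.frame(
    residue = names(counts),
    count = as.integer(counts),
    percent = 100 * as.integer(counts) / length(present),
    stringsAsFactors = FALSE
  )
  attr(out, "slot") <- slot
  attr(out, "total") <- length(present)
  attr(out, "n_missing") <- sum(is.na(values))
  class(out) <- c("conservation_table", "data.frame")
  out
}

#' Classify an active site from its extended-motif residues
#'
#' Deterministic rule cascade over the qualitative electrostatic logic of
#' the extended active-site motif. With an acidic residue (D/E) on strand
#' beta-1 six positions before the N-terminal cysteine:
#' a hydrogen-bonding partner (Q/N) on beta-2 stabilizes the buried
#' carboxylate, keeps its pKa low, and pushes the attacking cysteine's pKa
#' up (cDsbD-like); a salt-bridging partner (K/R) couples the two
#' ionizations into microscopic pKa behaviour, suiting a bidirectional
#' enzyme (E. coli thioredoxin-like); no partner leaves the buried acid
#' unstabilized with a high pKa, so the cysteine pKa is dominated by the
#' helix dipole and stays low (human thioredoxin / DsbA-like). Without a
#' beta-1 acid, the cysteine sits at a near-physiological pKa
#' (reductant-provision-like, e.g. CcmG/ResA/StoA). A proline or glycine
#' between the cysteines appends a thiolate-stabilizing-XX modifier. Records
#' that fit no rule (e.g. a missing beta-1 slot, or a histidine partner)
#' return `"unclassified"`.
#'
#' Classification depends only on the examined slots, never on the rest of
#' the sequence.
#'
#' @param record An [extract_extended_site()] record.
#' @return A list with `class` (label), `rule` (`"R1"`-`"R4"` or `NA`),
#'   `description`, `xx_modifier` (logical), and `trace` (character vector
#'   of every rule evaluation, in firing order).
#' @export
classify_active_site <- function(record) {
  stopifnot(inherits(record, "extended_site_record"))
  acidic <- !is.na(record$beta1_minus6) && record$beta1_minus6 %in% c("D", "E")
  partner <- record$partner_residue
  trace <- character(0)
  note <- function(msg) trace[[length(trace) + 1L]] <<- msg

  cls <- "unclassified"
  rule <- NA_character_
  desc <- "no classification rule matched"
  if (is.na(record$beta1_minus6)) {
    note("beta1 -6 slot missing: cannot evaluate acid rules")
  } else if (acidic) {
    note(sprintf("acidic residue %s at beta1 -6", record$beta1_minus6))
    if (!is.na(partner) && partner %in% c("Q", "N")) {
      note(sprintf("hydrogen-bonding partner %s at +%d", partner,
                   record$partner_offset))
      cls <- "stabilized_acid"
      rule <- "R1"
      desc <- "stabilized buried acid; elevated attacking-cysteine pKa (cDsbD-like)"
    } else if (!is.na(partner) && partner %in% c("K", "R")) {
      note(sprintf("salt-bridging partner %s at +%d", partner,
                   record$partner_offset))
      cls <- "coupled_microscopic"
      rule <- "R2"
      desc <- "coupled microscopic pKa values; bidirectional (thioredoxin-like)"
    } else if (is.na(partner)) {
      note("no distal partner found in window")
      cls <- "unstabilized_acid"
      rule <- "R3"
      desc <- paste("unstabilized buried acid; low attacking-cysteine pKa",
                    "dominated by the helix dipole (human Trx / DsbA-like)")
    } else {
      note(sprintf("partner %s matches no stabilization rule", partner))
    }
  } else {
    note(sprintf("no acidic residue at beta1 -6 (found %s)",
                 record$beta1_minus6))
    cls <- "no_beta1_acid"
    rule <- "R4"
    desc <- "no beta1 acid; near-physiological attacking-cysteine pKa (reductant-provision-like)"
  }
  xx_mod <- grepl("[PG]", record$xx_residues)
  if (xx_mod) {
    note(sprintf("P/G in XX residues (%s): thiolate-stabilizing XX",
                 record$xx_residues))
    desc <- paste(desc, "+ thiolate-stabilizing XX")
  }
  list(class = cls, rule = rule, description = desc,
       xx_modifier = xx_mod, trace = trace)
}

#' @export
as.data.frame.extended_site_record <- function(x, ...) {
  data.frame(
    sequence_id = x$sequence_id,
    cys_n_pos = x$cys_n_pos,
    cys_n_pos_1based = x$cys_n_pos + 1L,
    xx_residues = x$xx_residues,
    beta1_minus6 = ifelse(is.na(x$beta1_minus6), NA, x$beta1_minus6),
    alpha1_residue = x$alpha1_residue,
    alpha1_offset = x$alpha1_offset,
    partner_residue = x$partner_residue,
    partner_offset = x$partner_offset,
    stringsAsFactors = FALSE
  )
}

#' @export
print.extended_site_record <- function(x, ...) {
  cat(sprintf(
    "Extended active site %s: Cys at %d (0-based), XX = %s, -6 = %s, +%d = %s, partner = %s@+%s\n",
    x$sequence_id, x$cys_n_pos, x$xx_residues,
    ifelse(is.na(x$beta1_minus6), "missing", x$beta1_minus6),
    x$alpha1_offset,
    ifelse(is.na(x$alpha1_residue), "missing", x$alpha1_residue),
    ifelse(is.na(x$partner_residue), "none", x$partner_residue),
    ifelse(is.na(x$partner_offset), "-", x$partner_offset)
  ))
  invisible(x)
}
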