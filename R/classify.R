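#' Classification parameters
#'
#' Controls how an aligned target sequence is assigned an editing-outcome
#' label. The cut-site window is the half-width (in nt) of the bond interval
#' `[cut_index - window_nt, cut_index + window_nt]` an unprogrammed indel
#' must overlap to count as NHEJ. `hdr_mode` selects between requiring exact
#' identity with the reconstructed HDR allele (`"exact_allele"`) and the
#' tolerant default (`"edits_present"`): all programmed edits reproduced, no
#' other indels, and at most `max_outside_mismatches` additional
#' substitutions (sequencing errors otherwise deflate both the HDR and WT
#' bins). Substitution-only changes near the cut do not count as NHEJ unless
#' `count_substitutions_in_window_as_nhej` is set: indels are the imprecision
#' currency throughout.
#'
#' @param window_nt Half-width of the cut-site window in nt (default 5).
#' @param hdr_mode `"edits_present"` (default) or `"exact_allele"`.
#' @param max_outside_mismatches Substitutions tolerated beyond the
#'   programmed edits in `edits_present` mode (default 2).
#' @param count_substitutions_in_window_as_nhej Treat unprogrammed
#'   substitutions overlapping the window as NHEJ (default `FALSE`).
#' @return An object of class `class_params`.
#' @export
class_params <- function(window_nt = 5L,
                         hdr_mode = c("edits_present", "exact_allele"),
                         max_outside_mismatches = 2L,
                         count_substitutions_in_window_as_nhej = FALSE) {
  hdr_mode <- match.arg(hdr_mode)
  window_nt <- as.integer(window_nt)
  stopifnot(window_nt >= 0L, max_outside_mismatches >= 0L)
  structure(
    list(window_nt = window_nt, hdr_mode = hdr_mode,
         max_outside_mismatches = as.integer(max_outside_mismatches),
         count_substitutions_in_window_as_nhej =
           isTRUE(count_substitutions_in_window_as_nhej)),
    class = "class_params"
  )
}

# expand an event table into atomic substitutions (one row per base) and
# whole indel events
.atomize_events <- function(events) {
  mm <- events[events$kind == "mismatch", , drop = FALSE]
  subs <- if (nrow(mm) == 0L) {
    data.frame(pos = integer(), alt = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(seq_len(nrow(mm)), function(k) {
      data.frame(pos = mm$ref_pos[k] + seq_len(mm$length[k]) - 1L,
                 alt = strsplit(mm$bases[k], "", fixed = TRUE)[[1]],
                 stringsAsFactors = FALSE)
    }))
  }
  indels <- events[events$kind %in% c("insertion", "deletion"), , drop = FALSE]
  list(subs = subs, indels = indels)
}

# canonical programmed events: expected HDR allele aligned back to the
# amplicon, so programmed edit coordinates share the aligner's left-shifted
# normalisation
.programmed_events <- function(locus, donor, scoring) {
  allele <- expected_hdr_allele(locus, donor)
  ev <- global_align(allele, locus$amplicon, scoring)$events
  .atomize_events(ev[ev$kind != "match_run", , drop = FALSE])
}

.indel_key <- function(indels) {
  if (nrow(indels) == 0L) return(character())
  paste(indels$kind, indels$ref_pos, indels$length, indels$bases, sep = ":")
}

# does any indel event overlap the bond window [lo, hi]?
.indel_overlaps <- function(indels, lo, hi) {
  if (nrow(indels) == 0L) return(logical())
  b_lo <- indels$ref_pos
  b_hi <- ifelse(indels$kind == "deletion",
                 indels$ref_pos + indels$length, indels$ref_pos)
  b_lo <= hi & b_hi >= lo
}

.classify_one <- function(sequence, count, locus, donor, params, scoring,
                          hdr_allele, prog) {
  wt <- identical(sequence, locus$amplicon)
  is_hdr_exact <- identical(sequence, hdr_allele)

  if (is_hdr_exact || wt) {
    label <- if (is_hdr_exact) "HDR" else "WT"
    allele_seq <- if (is_hdr_exact) hdr_allele else locus$amplicon
    aln <- global_align(allele_seq, locus$amplicon, scoring)
  } else {
    aln <- global_align(sequence, locus$amplicon, scoring)
    label <- NA_character_
  }
  at <- .atomize_events(aln$events)

  prog_keys <- .indel_key(prog$indels)
  q_keys <- .indel_key(at$indels)
  prog_sub_keys <- paste(prog$subs$pos, prog$subs$alt)
  q_sub_keys <- paste(at$subs$pos, at$subs$alt)

  marker <- all(prog_keys %in% q_keys) && all(prog_sub_keys %in% q_sub_keys)
  extra_indels <- at$indels[!(q_keys %in% prog_keys), , drop = FALSE]
  lo <- locus$cut_index - params$window_nt
  hi <- locus$cut_index + params$window_nt
  indel_in_window <- any(.indel_overlaps(extra_indels, lo, hi))

  if (is.na(label)) {
    extra_subs <- sum(!(q_sub_keys %in% prog_sub_keys))
    if (params$hdr_mode == "edits_present" && marker &&
        nrow(extra_indels) == 0L &&
        extra_subs <= params$max_outside_mismatches) {
      label <- "HDR"
    } else if (indel_in_window) {
      label <- "NHEJ"
    } else if (params$count_substitutions_in_window_as_nhej &&
               nrow(at$subs) > 0L &&
               any(!(q_sub_keys %in% prog_sub_keys) &
                   at$subs$pos >= lo & at$subs$pos < hi)) {
      label <- "NHEJ"
    } else {
      label <- "AMBIGUOUS"
    }
  }

  list(sequence = sequence, count = count, label = label,
       cigar = events_to_cigar(aln$events),
       hdr_marker_present = marker, indel_in_window = indel_in_window)
}

#' Classify one target sequence
#'
#' Decision order: (1) exact identity with the reconstructed HDR allele gives
#' HDR; (2) exact identity with the amplicon gives WT; (3) otherwise the
#' sequence is globally aligned to the amplicon and, in `edits_present` mode,
#' labelled HDR when every programmed edit is reproduced with no other indels
#' and at most `max_outside_mismatches` stray substitutions; (4) otherwise
#' NHEJ when any non-programmed indel overlaps the cut-site bond window; (5)
#' otherwise AMBIGUOUS. A read carrying the programmed edits plus an extra
#' indel is imprecise (NHEJ) — precise repair is scarless — and is flagged
#' via `hdr_marker_present` for auditing. Both audit flags are populated for
#' every label.
#'
#' @param sequence Target sequence (plus orientation, primer-trimmed).
#' @param count Read count behind the sequence.
#' @param locus A [locus_spec()].
#' @param donor A [donor_spec()].
#' @param params A [class_params()].
#' @param scoring A [scoring_scheme()].
#' @return A one-row `data.frame`: `sequence`, `count`, `label`, `cigar`,
#'   `hdr_marker_present`, `indel_in_window`.
#' @export
classify_sequence <- function(sequence, count, locus, donor,
                              params = class_params(),
                              scoring = scoring_scheme()) {
  hdr_allele <- expected_hdr_allele(locus, donor)
  prog <- .programmed_events(locus, donor, scoring)
  res <- .classify_one(sequence, count, locus, donor, params, scoring,
                       hdr_allele, prog)
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Classify every target sequence in a sample
#'
#' Vectorised [classify_sequence()] over a unique-sequence table; counts are
#' carried through and input order is preserved.
#'
#' @param targets Target `data.frame` (`sequence`, `count`) from
#'   [identify_targets()] / [preprocess_sample()].
#' @param locus A [locus_spec()].
#' @param donor A [donor_spec()].
#' @param params A [class_params()].
#' @param scoring A [scoring_scheme()].
#' @return A `data.frame` of allele calls, one row per unique sequence, with
#'   columns `sequence`, `count`, `label`, `cigar`, `hdr_marker_present`,
#'   `indel_in_window`.
#' @export
classify_sample <- function(targets, locus, donor,
                            params = class_params(),
                            scoring = scoring_scheme()) {
  if (nrow(targets) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      label = character(), cigar = character(),
                      hdr_marker_present = logical(),
                      indel_in_window = logical(),
                      stringsAsFactors = FALSE))
  }
  hdr_allele <- expected_hdr_allele(locus, donor)
  prog <- .programmed_events(locus, donor, scoring)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    .classify_one(targets$sequence[i], targets$count[i], locus, donor,
                  params, scoring, hdr_allele, prog)
  })
  out <- do.call(rbind, lapply(rows, as.data.frame,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
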