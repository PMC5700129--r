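#' Alignment scoring scheme
#'
#' Parameters for global pairwise alignment of a target sequence against the
#' wild-type amplicon. In `affine` mode a gap run of length L costs
#' `gap_open + L * gap_extend`; in `linear` mode each gapped base costs
#' `gap_extend` and `gap_open` is forced to zero. The defaults favour
#' consolidated gaps so that an indel allele is represented as one discrete
#' event rather than scattered single-base gaps.
#'
#' @param match Score for an identical aligned pair (must exceed `mismatch`).
#' @param mismatch Score for a substituted aligned pair.
#' @param gap_open Gap opening penalty, non-positive (ignored in linear mode).
#' @param gap_extend Per-base gap penalty, non-positive.
#' @param mode `"affine"` or `"linear"`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme()
#' scoring_scheme(match = 1, mismatch = -1, gap_extend = -1, mode = "linear")
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = -6,
                           gap_extend = -1, mode = c("affine", "linear")) {
  mode <- match.arg(mode)
  if (!is.numeric(match) || !is.numeric(mismatch) || match <= mismatch)
    stop("scoring_scheme: 'match' must be numeric and exceed 'mismatch'")
  if (gap_open > 0 || gap_extend > 0)
    stop("scoring_scheme: gap penalties must be non-positive")
  if (mode == "linear") gap_open <- 0
  structure(
    list(match = as.numeric(match), mismatch = as.numeric(mismatch),
         gap_open = as.numeric(gap_open), gap_extend = as.numeric(gap_extend),
         mode = mode),
    class = "scoring_scheme"
  )
}

.check_dna <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop(sprintf("%s must be a single non-empty string", what))
  if (grepl("[^ACGT]", x))
    stop(sprintf("%s contains characters outside A/C/G/T", what))
  invisible(x)
}

#' Global pairwise alignment of a query against a reference
#'
#' Computes an optimal Needleman-Wunsch global alignment under the given
#' scoring scheme (three-state recurrence for affine gaps), with a
#' deterministic traceback (diagonal preferred over deletion over insertion on
#' ties) followed by left-shifting of every indel to its leftmost
#' score-equivalent position, the usual normalisation for variant coordinates
#' in repeat or homopolymer context. End gaps are charged ordinary gap
#' penalties: target sequences are primer-trimmed to the full amplicon span
#' before alignment, so terminal gaps are genuine indels.
#'
#' @param query Query DNA string (A/C/G/T only; the observed allele).
#' @param reference Reference DNA string (the wild-type amplicon).
#' @param scoring A [scoring_scheme()].
#' @return An object of class `nw_alignment`: a list with `ref_aligned` and
#'   `query_aligned` (equal-length gapped strings over A/C/G/T/-), `score`
#'   (the dynamic-programming optimum), and `events`, the edit-event table
#'   from [extract_events()].
#' @examples
#' aln <- global_align("AGT", "ACGT",
#'   scoring_scheme(match = 1, mismatch = -1, gap_extend = -1, mode = "linear"))
#' aln$score
#' aln$events
#' @export
global_align <- function(query, reference, scoring = scoring_scheme()) {
  .check_dna(query, "query")
  .check_dna(reference, "reference")
  stopifnot(inherits(scoring, "scoring_scheme"))
  raw <- nw_align_cpp(reference, query, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  shifted <- left_shift_indels(raw$ref_aligned, raw$query_aligned)
  aln <- structure(
    list(ref_aligned = shifted$ref_aligned,
         query_aligned = shifted$query_aligned,
         score = raw$score, events = NULL, scoring = scoring),
    class = "nw_alignment"
  )
  aln$events <- extract_events(aln)
  aln
}

# Shift every gap run to its leftmost score-equivalent position. A deletion
# run over ref[a..b] may move one column left when the preceding column is a
# match and ref[a-1] == ref[b] (the displaced base still matches after the
# swap); insertions are symmetric on the query. Runs are rescanned until the
# configuration is stable, which also merges runs that become adjacent.
left_shift_indels <- function(ref_aligned, query_aligned) {
  r <- strsplit(ref_aligned, "", fixed = TRUE)[[1]]
  q <- strsplit(query_aligned, "", fixed = TRUE)[[1]]
  repeat {
    moved <- FALSE
    gap_in_q <- q == "-"
    gap_in_r <- r == "-"
    runs <- rle(ifelse(gap_in_q, "D", ifelse(gap_in_r, "I", "A")))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in seq_along(runs$values)) {
      kind <- runs$values[k]
      if (kind == "A") next
      a <- starts[k]; b <- ends[k]
      while (a > 1L && r[a - 1L] != "-" && q[a - 1L] != "-" &&
             r[a - 1L] == q[a - 1L] &&
             (if (kind == "D") r[a - 1L] == r[b] else q[a - 1L] == q[b])) {
        if (kind == "D") {
          # move the matched query base from column a-1 to column b
          q[b] <- q[a - 1L]; q[a - 1L] <- "-"
          # ref row keeps its bases; the gap run is now [a-1, b-1]
        } else {
          r[b] <- r[a - 1L]; r[a - 1L] <- "-"
        }
        a <- a - 1L; b <- b - 1L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(ref_aligned = paste(r, collapse = ""),
       query_aligned = paste(q, collapse = ""))
}

#' Extract edit events from a global alignment
#'
#' Scans alignment columns and reports maximal runs of the four column kinds:
#' `match_run`, `mismatch`, `insertion` (gap in the reference) and `deletion`
#' (gap in the query). Coordinates are 0-based reference positions; an
#' insertion is placed at the bond index before which the bases are inserted.
#' The run lengths satisfy the conservation identities: match + mismatch +
#' deletion lengths sum to the reference length, and match + mismatch +
#' insertion lengths to the query length.
#'
#' @param alignment An `nw_alignment`, or a list with `ref_aligned` and
#'   `query_aligned` gapped strings.
#' @return A `data.frame` with columns `kind`, `ref_pos`, `length`, `bases`
#'   (query bases for mismatches and insertions, empty otherwise), ordered
#'   along the reference.
#' @export
extract_events <- function(alignment) {
  r <- strsplit(alignment$ref_aligned, "", fixed = TRUE)[[1]]
  q <- strsplit(alignment$query_aligned, "", fixed = TRUE)[[1]]
  if (length(r) != length(q))
    stop("malformed alignment: gapped strings differ in length")
  if (any(r == "-" & q == "-"))
    stop("malformed alignment: gap-gap column")
  kind <- ifelse(r == "-", "insertion",
          ifelse(q == "-", "deletion",
          ifelse(r == q, "match_run", "mismatch")))
  runs <- rle(kind)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  # reference coordinate consumed before each column (0-based)
  rpos_before <- cumsum(c(0L, as.integer(r != "-")))[seq_along(r)]
  bases <- character(length(runs$values))
  for (k in seq_along(runs$values)) {
    if (runs$values[k] %in% c("mismatch", "insertion"))
      bases[k] <- paste(q[starts[k]:ends[k]], collapse = "")
  }
  data.frame(
    kind = runs$values,
    ref_pos = rpos_before[starts],
    length = runs$lengths,
    bases = bases,
    stringsAsFactors = FALSE
  )
}

#' Recompute an alignment score from its event list
#'
#' Sums per-event contributions under a scoring scheme: used to check score
#' additivity against the dynamic-programming optimum.
#'
#' @param events Event table from [extract_events()].
#' @param scoring A [scoring_scheme()].
#' @return Numeric score.
#' @export
score_from_events <- function(events, scoring) {
  contrib <- function(kind, len) {
    switch(kind,
      match_run = scoring$match * len,
      mismatch  = scoring$mismatch * len,
      insertion = scoring$gap_open + scoring$gap_extend * len,
      deletion  = scoring$gap_open + scoring$gap_extend * len,
      stop("unknown event kind: ", kind))
  }
  if (nrow(events) == 0L) return(0)
  sum(mapply(contrib, events$kind, events$length))
}

#' CIGAR-like run-length encoding of an event list
#'
#' `M` for match runs, `X` for mismatch runs, `I` for insertions, `D` for
#' deletions, in reference order (e.g. `"58M2D80M"`).
#'
#' @param events Event table from [extract_events()].
#' @return A single string.
#' @export
events_to_cigar <- function(events) {
  if (nrow(events) == 0L) return("")
  code <- c(match_run = "M", mismatch = "X", insertion = "I", deletion = "D")
  paste0(events$length, code[events$kind], collapse = "")
}

#' @export
print.nw_alignment <- function(x, ...) {
  cat("Global alignment (score ", x$score, ")\n", sep = "")
  cat("ref:   ", x$ref_aligned, "\n", sep = "")
  cat("query: ", x$query_aligned, "\n", sep = "")
  cat("cigar: ", events_to_cigar(x$events), "\n", sep = "")
  invisible(x)
}

#' Render an alignment as a two-line gapped text pair
#'
#' @param alignment An `nw_alignment`.
#' @return Character vector of length two (reference line, query line).
#' @export
alignment_as_text <- function(alignment) {
  c(alignment$ref_aligned, alignment$query_aligned)
}
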