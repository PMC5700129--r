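#' Read a FASTQ file into a read set
#'
#' Thin wrapper over Biostrings FASTQ parsing (Phred+33; gzip accepted).
#'
#' @param path FASTQ path.
#' @return An object of class `read_set`: a list with `read_id`, `sequence`
#'   (character) and `mean_q` (per-read mean Phred quality).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e))
  )
  q <- S4Vectors::mcols(x)$qualities
  mean_q <- as.numeric(BiocGenerics::mean(
    methods::as(Biostrings::PhredQuality(q), "IntegerList")))
  ids <- sub("\\s.*$", "", names(x))
  structure(
    list(read_id = ids, sequence = as.character(x), mean_q = mean_q),
    class = "read_set"
  )
}

#' Build a read set from in-memory reads
#'
#' @param sequences Named character vector of read sequences.
#' @param qualities Integer vector of flat per-read Phred qualities (or a
#'   numeric vector of per-read mean qualities).
#' @return A `read_set`.
#' @export
read_set <- function(sequences, qualities) {
  stopifnot(length(sequences) == length(qualities))
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("read_%07d", seq_along(sequences))
  structure(
    list(read_id = ids, sequence = unname(sequences),
         mean_q = as.numeric(qualities)),
    class = "read_set"
  )
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set of ", length(x$sequence), " reads\n", sep = "")
  invisible(x)
}

#' Filter reads on mean base quality
#'
#' Retains reads whose mean Phred quality is at least `min_mean_q`
#' (default 20), preserving order. The number discarded is attached as the
#' attribute `n_discarded`.
#'
#' @param reads A `read_set`.
#' @param min_mean_q Minimum mean Phred quality.
#' @return The filtered `read_set`.
#' @export
filter_low_quality <- function(reads, min_mean_q = 20) {
  stopifnot(inherits(reads, "read_set"))
  keep <- reads$mean_q >= min_mean_q
  out <- structure(
    list(read_id = reads$read_id[keep], sequence = reads$sequence[keep],
         mean_q = reads$mean_q[keep]),
    class = "read_set"
  )
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Collapse reads to unique sequences with counts
#'
#' Groups exactly identical sequences, conserving the read count, and sorts
#' by descending count with ties broken lexicographically by sequence.
#'
#' @param reads A `read_set` or a character vector of sequences.
#' @return A `data.frame` with columns `sequence` and `count`.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (inherits(reads, "read_set")) reads$sequence else
    as.character(reads)
  if (length(seqs) == 0L) {
    return(data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(seqs, useNA = "no")
  out <- data.frame(sequence = as.character(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove low-frequency unique sequences
#'
#' Drops unique sequences observed fewer than `min_count` times (strictly
#' below the threshold: a sequence seen exactly `min_count` times is kept).
#' The removed read mass and number of removed sequences are attached as
#' attributes `removed_mass` and `removed_n`.
#'
#' @param uniques Unique-sequence `data.frame` from [collapse_reads()].
#' @param min_count Frequency threshold (default 10).
#' @return The filtered `data.frame`.
#' @export
filter_low_frequency <- function(uniques, min_count = 10L) {
  min_count <- as.integer(min_count)
  stopifnot(min_count >= 1L)
  keep <- uniques$count >= min_count
  out <- uniques[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed_mass") <- sum(uniques$count[!keep])
  attr(out, "removed_n") <- sum(!keep)
  out
}

# smallest 0-based offset in [0, window) at which `primer` matches `seq`
# starting there with <= max_mm substitutions; NA if none
.anchor_offset <- function(primer, seqs, window, max_mm, from_end = FALSE) {
  np <- nchar(primer)
  ns <- nchar(seqs)
  vapply(seq_along(seqs), function(i) {
    if (np > ns[i]) return(NA_integer_)
    s <- Biostrings::DNAString(seqs[i])
    offs <- 0:(min(window, ns[i] - np + 1L) - 1L)
    starts <- if (from_end) ns[i] - np + 1L - offs else offs + 1L
    starts <- starts[starts >= 1L]
    if (length(starts) == 0L) return(NA_integer_)
    ed <- Biostrings::neditStartingAt(Biostrings::DNAString(primer), s,
                                      starting.at = starts,
                                      with.indels = FALSE)
    hit <- which(ed <= max_mm)
    if (length(hit) == 0L) NA_integer_ else offs[hit[1L]]
  }, integer(1))
}

#' Identify and orient target sequences
#'
#' A unique sequence is a "target sequence" when the forward primer matches
#' (allowing up to `max_primer_mismatch` substitutions, no indels) within the
#' first 5 nt of one end and the reverse complement of the reverse primer
#' within the last 5 nt of the other end. Sequences matching in reverse
#' orientation are reverse-complemented into plus orientation; retained
#' sequences are trimmed to the span from the forward-primer start through
#' the reverse-primer end (the defined ends of the amplicon), and identical
#' trimmed sequences are re-aggregated. Sequences without both anchors
#' (including any shorter than a primer) are discarded; their count is
#' attached as attributes `discarded_n` (sequences) and `discarded_mass`
#' (reads).
#'
#' @param uniques Unique-sequence `data.frame`.
#' @param locus A [locus_spec()].
#' @param max_primer_mismatch Substitutions tolerated in each primer match.
#' @return Target-sequence `data.frame` (`sequence`, `count`), sorted by
#'   descending count then sequence.
#' @export
identify_targets <- function(uniques, locus, max_primer_mismatch = 0L) {
  stopifnot(inherits(locus, "locus_spec"))
  window <- 5L
  if (nrow(uniques) == 0L) {
    out <- uniques
    attr(out, "discarded_n") <- 0L
    attr(out, "discarded_mass") <- 0L
    return(out)
  }
  fwd <- locus$fwd_primer
  rev_rc <- revcomp(locus$rev_primer)

  orient_one <- function(seqv) {
    for (flip in c(FALSE, TRUE)) {
      s <- if (flip) revcomp(seqv) else seqv
      o_f <- .anchor_offset(fwd, s, window, max_primer_mismatch)
      if (is.na(o_f)) next
      o_r <- .anchor_offset(rev_rc, s, window, max_primer_mismatch,
                            from_end = TRUE)
      if (is.na(o_r)) next
      lo <- o_f + 1L
      hi <- nchar(s) - o_r
      if (hi - lo + 1L < nchar(fwd) + nchar(rev_rc)) next
      return(substr(s, lo, hi))
    }
    NA_character_
  }
  trimmed <- vapply(uniques$sequence, orient_one, character(1),
                    USE.NAMES = FALSE)
  keep <- !is.na(trimmed)
  disc_n <- sum(!keep)
  disc_mass <- sum(uniques$count[!keep])
  if (!any(keep)) {
    out <- data.frame(sequence = character(), count = integer(),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(count ~ sequence,
                            data = data.frame(sequence = trimmed[keep],
                                              count = uniques$count[keep],
                                              stringsAsFactors = FALSE),
                            FUN = sum)
    out <- agg[order(-agg$count, agg$sequence), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "discarded_n") <- disc_n
  attr(out, "discarded_mass") <- disc_mass
  out
}

#' Preprocess a sample end to end
#'
#' Quality filter, collapse to unique sequences, frequency filter, then
#' primer-anchored target identification and trimming, in that order.
#'
#' @param reads A `read_set` or a FASTQ path.
#' @param locus A [locus_spec()].
#' @param min_mean_q Mean-quality threshold (default 20).
#' @param min_count Unique-sequence frequency threshold (default 10).
#' @param max_primer_mismatch Substitutions tolerated per primer anchor.
#' @return A list with `targets` (unique-sequence `data.frame`) and
#'   `stage_counts`, a named list tracking read and sequence counts through
#'   every stage (`n_raw`, `n_quality_pass`, `n_unique`, `n_freq_pass_seqs`,
#'   `n_freq_pass_reads`, `n_target_seqs`, `n_target_reads`).
#' @export
preprocess_sample <- function(reads, locus, min_mean_q = 20,
                              min_count = 10L, max_primer_mismatch = 0L) {
  if (is.character(reads)) reads <- read_fastq(reads)
  stopifnot(inherits(reads, "read_set"))
  n_raw <- length(reads$sequence)
  qpass <- filter_low_quality(reads, min_mean_q)
  uniques <- collapse_reads(qpass)
  fpass <- filter_low_frequency(uniques, min_count)
  targets <- identify_targets(fpass, locus, max_primer_mismatch)
  list(
    targets = targets,
    stage_counts = list(
      n_raw = n_raw,
      n_quality_pass = length(qpass$sequence),
      n_unique = nrow(uniques),
      n_freq_pass_seqs = nrow(fpass),
      n_freq_pass_reads = sum(fpass$count),
      n_target_seqs = nrow(targets),
      n_target_reads = sum(targets$count)
    )
  )
}
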