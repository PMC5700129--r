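#' Configure an amplicon read simulation
#'
#' Describes a mixture of wild-type, HDR and NHEJ-indel alleles plus
#' sequencing nuisance classes, emulating single-orientation HiSeq/MiSeq-style
#' amplicon reads that span the full amplicon. Reads are drawn from mutually
#' exclusive classes: a fraction `frac_offtarget` of off-target reads
#' (shuffled amplicon, no primers), a fraction `frac_low_quality` of
#' low-quality reads (flat `q_low` base qualities), and the remaining mass
#' split across WT/HDR/NHEJ in proportion to `1 - p_hdr - p_nhej`, `p_hdr`
#' and `p_nhej`.
#'
#' The default indel model reflects empirical SpCas9 repair spectra at most
#' loci: deletions dominate (`p_deletion = 0.8`), deletion lengths fall off
#' geometrically (`del_len_geometric_p = 0.35`, capped at 25 nt), insertions
#' are mostly the canonical +1 (`ins_len_geometric_p = 0.9`, capped at 5 nt),
#' and breakpoints stay within 1 nt of the cut bond
#' (`position_jitter_nt = 1`). Deletion intervals are chosen uniformly among
#' those containing the jittered cut bond; insertions are placed at the
#' jittered bond with bases drawn uniformly from A/C/G/T.
#'
#' @param locus A [locus_spec()].
#' @param donor A [donor_spec()].
#' @param n_reads Number of reads to emit (default 50000).
#' @param p_hdr,p_nhej Allele-mixture fractions (wild type takes the rest).
#' @param indel_model Named list overriding any of `p_deletion`,
#'   `del_len_geometric_p`, `max_del_len`, `ins_len_geometric_p`,
#'   `max_ins_len`, `position_jitter_nt`.
#' @param subst_error_rate Per-base substitution sequencing-error rate.
#' @param q_high,q_low Flat Phred qualities for normal and low-quality reads.
#' @param frac_low_quality,frac_offtarget,frac_reverse_orientation Nuisance
#'   read fractions.
#' @param seed Integer seed; simulation is byte-deterministic given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(locus, donor, n_reads = 50000L,
                              p_hdr = 0.04, p_nhej = 0.16,
                              indel_model = list(),
                              subst_error_rate = 0.001,
                              q_high = 35L, q_low = 10L,
                              frac_low_quality = 0,
                              frac_offtarget = 0,
                              frac_reverse_orientation = 0,
                              seed = 1L) {
  stopifnot(inherits(locus, "locus_spec"), inherits(donor, "donor_spec"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads <= 0L)
    stop("simulation_config: n_reads must be a positive integer")
  fr <- c(p_hdr = p_hdr, p_nhej = p_nhej, frac_low_quality = frac_low_quality,
          frac_offtarget = frac_offtarget,
          frac_reverse_orientation = frac_reverse_orientation,
          subst_error_rate = subst_error_rate)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("simulation_config: all fractions must lie in [0, 1]")
  if (p_hdr + p_nhej > 1)
    stop("simulation_config: p_hdr + p_nhej must not exceed 1")
  if (frac_low_quality + frac_offtarget > 1)
    stop("simulation_config: nuisance fractions must not exceed 1 in total")
  im <- list(p_deletion = 0.8, del_len_geometric_p = 0.35, max_del_len = 25L,
             ins_len_geometric_p = 0.9, max_ins_len = 5L,
             position_jitter_nt = 1L)
  stopifnot(all(names(indel_model) %in% names(im)))
  im[names(indel_model)] <- indel_model
  if (im$del_len_geometric_p <= 0 || im$del_len_geometric_p > 1 ||
      im$ins_len_geometric_p <= 0 || im$ins_len_geometric_p > 1)
    stop("simulation_config: geometric parameters must lie in (0, 1]")
  if (im$position_jitter_nt < 0)
    stop("simulation_config: position_jitter_nt must be >= 0")
  structure(
    list(locus = locus, donor = donor, n_reads = n_reads,
         p_hdr = p_hdr, p_nhej = p_nhej, indel_model = im,
         subst_error_rate = subst_error_rate,
         q_high = as.integer(q_high), q_low = as.integer(q_low),
         frac_low_quality = frac_low_quality,
         frac_offtarget = frac_offtarget,
         frac_reverse_orientation = frac_reverse_orientation,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# length 1..max with P(l) proportional to geometric p (truncated, renormalised)
.rtruncgeom <- function(n, p, max_len) {
  if (n == 0L) return(integer())
  probs <- p * (1 - p)^(seq_len(max_len) - 1L)
  sample.int(max_len, n, replace = TRUE, prob = probs)
}

.BASES <- c("A", "C", "G", "T")

# one NHEJ allele: sequence plus its true event description
.draw_nhej_allele <- function(amplicon, cut, im) {
  b <- cut + sample.int(2L * im$position_jitter_nt + 1L, 1L) -
    im$position_jitter_nt - 1L
  n <- nchar(amplicon)
  b <- max(1L, min(n - 1L, b))
  if (stats::runif(1) < im$p_deletion) {
    len <- .rtruncgeom(1L, im$del_len_geometric_p, im$max_del_len)
    # deletion interval [s, s + len) containing the bond b
    s_lo <- max(0L, b - len)
    s_hi <- min(n - len, b)
    s <- if (s_hi <= s_lo) s_lo else
      s_lo + sample.int(s_hi - s_lo + 1L, 1L) - 1L
    seqv <- paste0(substr(amplicon, 1L, s), substr(amplicon, s + len + 1L, n))
    list(sequence = seqv, kind = "deletion", ref_pos = s, length = len,
         bases = "")
  } else {
    len <- .rtruncgeom(1L, im$ins_len_geometric_p, im$max_ins_len)
    ins <- paste(sample(.BASES, len, replace = TRUE), collapse = "")
    seqv <- paste0(substr(amplicon, 1L, b), ins, substr(amplicon, b + 1L, n))
    list(sequence = seqv, kind = "insertion", ref_pos = b, length = len,
         bases = ins)
  }
}

#' Simulate one amplicon sequencing sample
#'
#' Emits `n_reads` single-orientation reads with a known per-read truth
#' class. WT reads are the amplicon; HDR reads the reconstructed
#' [expected_hdr_allele()]; NHEJ reads carry one indel whose breakpoint lies
#' within `position_jitter_nt` of the cut bond; off-target reads are
#' independently shuffled amplicons lacking the primers; low-quality reads
#' are wild-type sequence with flat `q_low` qualities. Every retained base is
#' then passed through the per-base substitution error channel, and a
#' fraction of reads is emitted reverse-complemented. The run is
#' deterministic given `config$seed` (the caller's RNG state is restored on
#' exit).
#'
#' @param config A [simulation_config()].
#' @param fastq_path Optional path; when given, reads are written as
#'   Phred+33 FASTQ.
#' @param truth_path Optional path; when given, the truth table is written as
#'   TSV.
#' @param sample_id Prefix used in read identifiers.
#' @return Invisibly, a list with `sequences` (named character vector),
#'   `qualities` (integer flat quality per read) and `truth` (a `data.frame`
#'   with `read_id`, `true_class`, and `event_kind`/`event_ref_pos`/
#'   `event_length`/`event_bases` for NHEJ reads).
#' @export
simulate_sample <- function(config, fastq_path = NULL, truth_path = NULL,
                            sample_id = "S1") {
  stopifnot(inherits(config, "simulation_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  locus <- config$locus
  amplicon <- locus$amplicon
  hdr_allele <- expected_hdr_allele(locus, config$donor)
  n <- config$n_reads
  p_rem <- 1 - config$frac_offtarget - config$frac_low_quality
  p_wt <- 1 - config$p_hdr - config$p_nhej
  cls <- sample(
    c("OFFTARGET", "LOWQ", "WT", "HDR", "NHEJ"), n, replace = TRUE,
    prob = c(config$frac_offtarget, config$frac_low_quality,
             p_rem * p_wt, p_rem * config$p_hdr, p_rem * config$p_nhej)
  )

  seqs <- character(n)
  ev_kind <- rep(NA_character_, n)
  ev_pos <- rep(NA_integer_, n)
  ev_len <- rep(NA_integer_, n)
  ev_bases <- rep(NA_character_, n)

  seqs[cls == "WT" | cls == "LOWQ"] <- amplicon
  seqs[cls == "HDR"] <- hdr_allele
  amp_chars <- strsplit(amplicon, "", fixed = TRUE)[[1]]
  for (i in which(cls == "OFFTARGET")) {
    seqs[i] <- paste(sample(amp_chars), collapse = "")
  }
  for (i in which(cls == "NHEJ")) {
    al <- .draw_nhej_allele(amplicon, locus$cut_index, config$indel_model)
    seqs[i] <- al$sequence
    ev_kind[i] <- al$kind; ev_pos[i] <- al$ref_pos
    ev_len[i] <- al$length; ev_bases[i] <- al$bases
  }

  # per-base substitution sequencing error
  if (config$subst_error_rate > 0) {
    widths <- nchar(seqs)
    n_err <- stats::rbinom(n, widths, config$subst_error_rate)
    for (i in which(n_err > 0L)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(widths[i], n_err[i])
      for (p in pos) {
        ch[p] <- sample(setdiff(.BASES, ch[p]), 1L)
      }
      seqs[i] <- paste(ch, collapse = "")
    }
  }

  if (config$frac_reverse_orientation > 0) {
    flip <- stats::runif(n) < config$frac_reverse_orientation
    if (any(flip)) {
      seqs[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(seqs[flip])))
    }
  }

  ids <- sprintf("%s_%07d", sample_id, seq_len(n))
  quals <- ifelse(cls == "LOWQ", config$q_low, config$q_high)
  truth <- data.frame(
    read_id = ids, true_class = cls,
    event_kind = ev_kind, event_ref_pos = ev_pos,
    event_length = ev_len, event_bases = ev_bases,
    stringsAsFactors = FALSE
  )
  names(seqs) <- ids

  if (!is.null(fastq_path)) {
    dna <- Biostrings::DNAStringSet(seqs)
    qstr <- Biostrings::BStringSet(
      vapply(seq_len(n), function(i)
        strrep(rawToChar(as.raw(quals[i] + 33L)), nchar(seqs[i])),
        character(1))
    )
    Biostrings::writeXStringSet(dna, fastq_path, format = "fastq",
                                qualities = qstr)
  }
  if (!is.null(truth_path)) {
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(list(sequences = seqs, qualities = quals, truth = truth))
}

#' Simulate a pair of conditions with a known ratio fold-change
#'
#' Runs [simulate_sample()] for two configurations (e.g. a nanoparticle
#' condition against a standard RNP control) and records the fold-change of
#' the configured HDR:NHEJ ratios,
#' `(p_hdr_a / p_nhej_a) / (p_hdr_b / p_nhej_b)`. The fold-change is flagged
#' undefined (`NA`) when either condition has `p_nhej = 0` or the control has
#' `p_hdr = 0`.
#'
#' @param cfg_a,cfg_b [simulation_config()] objects (independent seeds).
#' @param fastq_a,fastq_b,truth_a,truth_b Optional output paths.
#' @return Invisibly, a list with `sample_a`, `sample_b`, and
#'   `truth_fold_change` (number or `NA`).
#' @export
simulate_paired_conditions <- function(cfg_a, cfg_b,
                                       fastq_a = NULL, truth_a = NULL,
                                       fastq_b = NULL, truth_b = NULL) {
  a <- simulate_sample(cfg_a, fastq_a, truth_a, sample_id = "A")
  b <- simulate_sample(cfg_b, fastq_b, truth_b, sample_id = "B")
  fold <- NA_real_
  if (cfg_a$p_nhej > 0 && cfg_b$p_nhej > 0 && cfg_b$p_hdr > 0) {
    fold <- (cfg_a$p_hdr / cfg_a$p_nhej) / (cfg_b$p_hdr / cfg_b$p_nhej)
  }
  invisible(list(sample_a = a, sample_b = b, truth_fold_change = fold))
}
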