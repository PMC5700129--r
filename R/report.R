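#' Summarise editing outcomes for one sample
#'
#' Computes per-sample outcome counts, allele percentages and the HDR:indel
#' ratio, the headline precise-to-imprecise editing statistic. Percentages
#' are taken over classified target reads (ambiguous reads stay in the
#' denominator but join neither numerator); the raw-read denominator remains
#' available through `stage_counts`. A sample without NHEJ reads gets an
#' undefined (NA) ratio rather than an infinite one; an optional pseudocount
#' mode adds 0.5 to both counts instead. Clonal genotype data (e.g. Sanger
#' calls, one clone per row with `count = 1`) flow through the same
#' statistic.
#'
#' @param calls Allele-call `data.frame` with at least `label` and `count`
#'   (from [classify_sample()], or clone-mode labels via [clone_calls()]).
#' @param stage_counts Optional preprocessing stage counts (from
#'   [preprocess_sample()]), carried into the summary.
#' @param sample_id Sample identifier.
#' @param pseudocount Use the +0.5/+0.5 pseudocount ratio when `TRUE`.
#' @return An object of class `sample_summary`: `sample_id`, `stage_counts`,
#'   `reads_wt`, `reads_hdr`, `reads_nhej`, `reads_ambiguous`, `n_target`,
#'   `pct_hdr`, `pct_nhej`, `hdr_indel_ratio`, `ratio_defined`.
#' @examples
#' summarize_sample(clone_calls(c(rep("HDR", 8), rep("NHEJ", 8),
#'                                rep("WT", 18))))
#' @export
summarize_sample <- function(calls, stage_counts = NULL,
                             sample_id = "sample", pseudocount = FALSE) {
  stopifnot(is.data.frame(calls), all(c("label", "count") %in% names(calls)))
  cnt <- function(lab) sum(calls$count[calls$label == lab])
  reads_wt <- cnt("WT"); reads_hdr <- cnt("HDR")
  reads_nhej <- cnt("NHEJ"); reads_amb <- cnt("AMBIGUOUS")
  n_target <- sum(calls$count)
  if (n_target > 0L) {
    pct_hdr <- 100 * reads_hdr / n_target
    pct_nhej <- 100 * reads_nhej / n_target
  } else {
    pct_hdr <- NA_real_; pct_nhej <- NA_real_
  }
  if (pseudocount) {
    ratio <- (reads_hdr + 0.5) / (reads_nhej + 0.5)
    defined <- n_target > 0L
  } else {
    defined <- reads_nhej > 0L
    ratio <- if (defined) reads_hdr / reads_nhej else NA_real_
  }
  structure(
    list(sample_id = sample_id, stage_counts = stage_counts,
         reads_wt = reads_wt, reads_hdr = reads_hdr,
         reads_nhej = reads_nhej, reads_ambiguous = reads_amb,
         n_target = n_target, pct_hdr = pct_hdr, pct_nhej = pct_nhej,
         hdr_indel_ratio = ratio, ratio_defined = defined),
    class = "sample_summary"
  )
}

#' Clone-mode allele calls
#'
#' Wraps per-clone genotype labels (e.g. from Sanger sequencing of isolated
#' clones) as an allele-call table with one count per clone, so clonal data
#' run through [summarize_sample()] unchanged.
#'
#' @param labels Character vector over `"WT"`, `"HDR"`, `"NHEJ"`,
#'   `"AMBIGUOUS"`, one element per clone.
#' @return An allele-call `data.frame` with `label` and `count` columns.
#' @export
clone_calls <- function(labels) {
  stopifnot(all(labels %in% c("WT", "HDR", "NHEJ", "AMBIGUOUS")))
  data.frame(label = as.character(labels), count = 1L,
             stringsAsFactors = FALSE)
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Sample '", x$sample_id, "': ", x$n_target, " target reads | WT ",
      x$reads_wt, ", HDR ", x$reads_hdr, ", NHEJ ", x$reads_nhej,
      ", ambiguous ", x$reads_ambiguous, "\n", sep = "")
  cat(sprintf("  HDR%% = %.3f, NHEJ%% = %.3f, HDR:indel ratio = %s\n",
              x$pct_hdr, x$pct_nhej,
              if (x$ratio_defined) sprintf("%.3f", x$hdr_indel_ratio)
              else "undefined"))
  invisible(x)
}

#' Fold enrichment of HDR:indel ratios between conditions
#'
#' The ratio of a sample's HDR:indel ratio to a control's, the statistic used
#' to compare delivery conditions. Undefined (NA, with `defined = FALSE`)
#' whenever either ratio is undefined or the control ratio is zero; flags
#' propagate rather than raising errors.
#'
#' @param sample,control `sample_summary` objects.
#' @return A list with `sample_id`, `control_id`, `fold_enrichment`,
#'   `defined`.
#' @export
compare_conditions <- function(sample, control) {
  stopifnot(inherits(sample, "sample_summary"),
            inherits(control, "sample_summary"))
  defined <- isTRUE(sample$ratio_defined) && isTRUE(control$ratio_defined) &&
    !is.na(control$hdr_indel_ratio) && control$hdr_indel_ratio > 0
  fold <- if (defined) sample$hdr_indel_ratio / control$hdr_indel_ratio
          else NA_real_
  list(sample_id = sample$sample_id, control_id = control$sample_id,
       fold_enrichment = fold, defined = defined)
}

.summary_as_list <- function(s) {
  list(sample_id = s$sample_id,
       stage_counts = s$stage_counts,
       reads_wt = s$reads_wt, reads_hdr = s$reads_hdr,
       reads_nhej = s$reads_nhej, reads_ambiguous = s$reads_ambiguous,
       n_target = s$n_target,
       pct_hdr = s$pct_hdr, pct_nhej = s$pct_nhej,
       hdr_indel_ratio = if (s$ratio_defined) s$hdr_indel_ratio else NULL,
       ratio_defined = s$ratio_defined)
}

#' Run the full classification pipeline over FASTQ samples
#'
#' For each sample: preprocess (quality filter, collapse, frequency filter,
#' primer-anchored target identification), align every target sequence to
#' the wild-type amplicon, classify, and summarise. Deterministic given its
#' inputs. When `out_dir` is given, writes per sample a per-allele TSV
#' (`<sample>_alleles.tsv`: sequence, count, label, CIGAR-like event string,
#' audit flags) and a JSON summary (`<sample>_summary.json`), plus a
#' cross-sample `comparison.tsv` of fold enrichments against the control
#' when `control` names one of the samples.
#'
#' @param fastq_paths Named character vector of FASTQ paths (names are
#'   sample ids; unnamed paths use the file stem).
#' @param locus_config Path to a YAML locus/donor config, or a list with
#'   `locus` and `donor` elements.
#' @param min_mean_q,min_count,max_primer_mismatch Preprocessing thresholds.
#' @param params A [class_params()].
#' @param scoring A [scoring_scheme()].
#' @param out_dir Optional report directory (created if absent).
#' @param control Optional sample id used as the fold-enrichment
#'   denominator.
#' @return A list with `summaries` (named list of `sample_summary`),
#'   `calls` (named list of allele-call tables), and `comparisons` (a
#'   `data.frame`, possibly empty).
#' @export
run_pipeline <- function(fastq_paths, locus_config,
                         min_mean_q = 20, min_count = 10L,
                         max_primer_mismatch = 0L,
                         params = class_params(),
                         scoring = scoring_scheme(),
                         out_dir = NULL, control = NULL) {
  cfg <- if (is.character(locus_config)) read_locus_config(locus_config)
         else locus_config
  if (is.null(cfg$locus) || is.null(cfg$donor))
    .locus_error("pipeline needs both a locus and a donor definition")
  ids <- names(fastq_paths)
  if (is.null(ids)) ids <- rep(NA_character_, length(fastq_paths))
  ids[is.na(ids) | ids == ""] <-
    tools::file_path_sans_ext(basename(fastq_paths[is.na(ids) | ids == ""]),
                              compression = TRUE)
  missing <- !file.exists(fastq_paths)
  if (any(missing))
    stop("FASTQ file(s) not found: ",
         paste(fastq_paths[missing], collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  summaries <- list(); calls <- list()
  for (k in seq_along(fastq_paths)) {
    pre <- preprocess_sample(fastq_paths[[k]], cfg$locus, min_mean_q,
                             min_count, max_primer_mismatch)
    cl <- classify_sample(pre$targets, cfg$locus, cfg$donor, params, scoring)
    sm <- summarize_sample(cl, pre$stage_counts, sample_id = ids[k])
    summaries[[ids[k]]] <- sm
    calls[[ids[k]]] <- cl
    if (!is.null(out_dir)) {
      utils::write.table(cl, file.path(out_dir,
                                       paste0(ids[k], "_alleles.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(.summary_as_list(sm),
                           file.path(out_dir,
                                     paste0(ids[k], "_summary.json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
    }
  }

  comparisons <- data.frame(sample_id = character(), control_id = character(),
                            fold_enrichment = numeric(), defined = logical(),
                            stringsAsFactors = FALSE)
  if (!is.null(control)) {
    if (!control %in% ids)
      stop("control sample '", control, "' not among the inputs")
    ctl <- summaries[[control]]
    rows <- lapply(setdiff(ids, control), function(id) {
      cc <- compare_conditions(summaries[[id]], ctl)
      data.frame(sample_id = cc$sample_id, control_id = cc$control_id,
                 fold_enrichment = cc$fold_enrichment, defined = cc$defined,
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) comparisons <- do.call(rbind, rows)
    if (!is.null(out_dir))
      utils::write.table(comparisons, file.path(out_dir, "comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(summaries = summaries, calls = calls, comparisons = comparisons)
}
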