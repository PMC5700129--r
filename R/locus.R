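#' @importFrom Rcpp evalCpp
#' @useDynLib ampliconHDR, .registration = TRUE
NULL

.locus_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("locus_error", "error")))
}
.donor_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("donor_error", "error")))
}

#' Reverse complement of a DNA string
#'
#' @param x A single DNA string.
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# 0-based start positions of exact (overlap-aware) occurrences of pattern
.find_all <- function(pattern, subject) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                Biostrings::DNAString(subject))
  BiocGenerics::start(m) - 1L
}

#' Derive the Cas9 cut-site coordinate from the protospacer
#'
#' Locates the protospacer (with its NGG PAM) on the requested strand of the
#' amplicon and returns the blunt SpCas9 cut site: the phosphodiester bond 3
#' nt 5' of the PAM on the protospacer strand, expressed as a 0-based bond
#' index in plus-strand amplicon coordinates (the bond between
#' `amplicon[cut_index - 1]` and `amplicon[cut_index]`, 0-based).
#'
#' @param amplicon Wild-type amplicon sequence (plus strand, A/C/G/T).
#' @param protospacer Protospacer sequence, 17-20 nt, read 5'->3' on its own
#'   strand (PAM not included).
#' @param pam_strand `"plus"` if protospacer+PAM read 5'->3' matches the
#'   amplicon as given, `"minus"` if they match its reverse complement.
#' @return Integer bond index.
#' @examples
#' # protospacer ends 3 nt before the PAM "TGG"; cut falls 3 nt 5' of the PAM
#' amp <- paste0("AAAACCCCGGGGTTTTACGT", "ACGTACGTACGTACGTACGT", "TGG",
#'               "AAAACCCCGGGGTTTT")
#' derive_cut_index(amp, "ACGTACGTACGTACGTACGT", "plus")
#' @export
derive_cut_index <- function(amplicon, protospacer, pam_strand = c("plus", "minus")) {
  pam_strand <- match.arg(pam_strand)
  .check_dna(amplicon, "amplicon")
  .check_dna(protospacer, "protospacer")
  if (nchar(protospacer) < 17L || nchar(protospacer) > 20L)
    .locus_error("protospacer must be 17-20 nt, got ", nchar(protospacer))
  L <- nchar(protospacer)
  n <- nchar(amplicon)
  if (pam_strand == "plus") {
    hits <- .find_all(protospacer, amplicon)
    # require NGG immediately 3' of the protospacer on the plus strand
    if (length(hits) > 0L)
      hits <- hits[hits + L + 3L <= n &
                   substring(amplicon, hits + L + 2L, hits + L + 3L) == "GG"]
    if (length(hits) == 0L)
      .locus_error("protospacer with NGG PAM not found on plus strand")
    if (length(hits) > 1L)
      .locus_error("protospacer matches the amplicon more than once")
    cut <- hits + L - 3L
  } else {
    hits <- .find_all(revcomp(protospacer), amplicon)
    # NGG on the minus strand appears as CCN 5' of the match on the plus strand
    if (length(hits) > 0L)
      hits <- hits[hits - 3L >= 0L &
                   substring(amplicon, hits - 2L, hits - 1L) == "CC"]
    if (length(hits) == 0L)
      .locus_error("protospacer with NGG PAM not found on minus strand")
    if (length(hits) > 1L)
      .locus_error("protospacer matches the amplicon more than once")
    cut <- hits + 3L
  }
  if (cut <= 0L || cut >= n)
    .locus_error("derived cut site falls outside the amplicon interior")
  as.integer(cut)
}

#' Describe an amplicon locus
#'
#' Bundles the wild-type amplicon, the guide (protospacer + PAM strand) and
#' the sequencing primer pair, and derives the Cas9 cut-site bond index. All
#' coordinates in the package are 0-based; the cut site is a bond index
#' (between-base), so a cut at `cut_index` separates `amplicon[cut_index - 1]`
#' from `amplicon[cut_index]` (0-based).
#'
#' @param name Locus identifier.
#' @param amplicon Wild-type amplicon (plus strand; must start with
#'   `fwd_primer` and end with the reverse complement of `rev_primer`).
#' @param protospacer Protospacer, 17-20 nt, 5'->3' on its own strand.
#' @param pam_strand `"plus"` or `"minus"`.
#' @param fwd_primer,rev_primer PCR primer sequences, 5'->3' on their own
#'   strands.
#' @return An object of class `locus_spec` with the input fields plus
#'   `cut_index`.
#' @export
locus_spec <- function(name, amplicon, protospacer,
                       pam_strand = c("plus", "minus"),
                       fwd_primer, rev_primer) {
  pam_strand <- match.arg(pam_strand)
  .check_dna(amplicon, "amplicon")
  .check_dna(fwd_primer, "fwd_primer")
  .check_dna(rev_primer, "rev_primer")
  if (substr(amplicon, 1L, nchar(fwd_primer)) != fwd_primer)
    .locus_error("fwd_primer is not a prefix of the amplicon")
  rcrev <- revcomp(rev_primer)
  if (substr(amplicon, nchar(amplicon) - nchar(rcrev) + 1L,
             nchar(amplicon)) != rcrev)
    .locus_error("reverse complement of rev_primer is not a suffix of the amplicon")
  cut <- derive_cut_index(amplicon, protospacer, pam_strand)
  structure(
    list(name = as.character(name), amplicon = amplicon,
         protospacer = protospacer, pam_strand = pam_strand,
         fwd_primer = fwd_primer, rev_primer = rev_primer,
         cut_index = cut),
    class = "locus_spec"
  )
}

#' @export
print.locus_spec <- function(x, ...) {
  cat("Locus '", x$name, "': ", nchar(x$amplicon), " bp amplicon, ",
      "protospacer on ", x$pam_strand, " strand, cut bond at ",
      x$cut_index, "\n", sep = "")
  invisible(x)
}

#' Build a table of programmed edits
#'
#' Each row is one edit in 0-based reference (amplicon) coordinates:
#' substitutions and deletions give the replaced interval
#' `[ref_pos, ref_pos + nchar(ref_bases))`, insertions give the bond index
#' before which `alt_bases` are inserted (with empty `ref_bases`).
#'
#' @param kind Character vector over `"substitution"`, `"insertion"`,
#'   `"deletion"`.
#' @param ref_pos Integer vector of 0-based positions (bond index for
#'   insertions).
#' @param ref_bases Reference bases removed (`""` for insertions).
#' @param alt_bases Replacement bases (`""` for deletions).
#' @return A `data.frame` of edits, sorted by `ref_pos`.
#' @export
edit_table <- function(kind, ref_pos, ref_bases, alt_bases) {
  ed <- data.frame(kind = as.character(kind), ref_pos = as.integer(ref_pos),
                   ref_bases = as.character(ref_bases),
                   alt_bases = as.character(alt_bases),
                   stringsAsFactors = FALSE)
  ok <- (ed$kind == "substitution" & nchar(ed$ref_bases) > 0 & nchar(ed$alt_bases) > 0) |
        (ed$kind == "insertion" & nchar(ed$ref_bases) == 0 & nchar(ed$alt_bases) > 0) |
        (ed$kind == "deletion" & nchar(ed$ref_bases) > 0 & nchar(ed$alt_bases) == 0)
  if (!all(ok))
    .donor_error("edit kind inconsistent with empty/non-empty ref/alt bases")
  ed[order(ed$ref_pos), , drop = FALSE]
}

#' Apply programmed edits to a reference sequence
#'
#' Edits are validated (inside the reference, non-overlapping, `ref_bases`
#' matching the reference) and applied in reference coordinates.
#'
#' @param amplicon Reference DNA string.
#' @param edits An [edit_table()].
#' @return The edited sequence; its length is the reference length plus the
#'   net of insertion minus deletion lengths.
#' @export
apply_edits <- function(amplicon, edits) {
  .check_dna(amplicon, "amplicon")
  if (is.null(edits) || nrow(edits) == 0L)
    .donor_error("edit list is empty; a donor identical to the reference is rejected")
  edits <- edits[order(edits$ref_pos), , drop = FALSE]
  n <- nchar(amplicon)
  lo <- edits$ref_pos
  hi <- edits$ref_pos + nchar(edits$ref_bases)  # half-open [lo, hi)
  if (any(lo < 0L) || any(hi > n))
    .donor_error("edit falls outside the amplicon")
  if (nrow(edits) > 1L && any(lo[-1L] < hi[-nrow(edits)]))
    .donor_error("edits overlap")
  for (k in seq_len(nrow(edits))) {
    if (nchar(edits$ref_bases[k]) > 0 &&
        substr(amplicon, lo[k] + 1L, hi[k]) != edits$ref_bases[k])
      .donor_error("ref_bases of edit at position ", lo[k],
                   " do not match the amplicon")
  }
  # right-to-left so earlier coordinates stay valid
  out <- amplicon
  for (k in rev(seq_len(nrow(edits)))) {
    out <- paste0(substr(out, 1L, lo[k]), edits$alt_bases[k],
                  substr(out, hi[k] + 1L, nchar(out)))
  }
  out
}

# Derive an edit table by comparing an edited core against its reference span
.edits_from_diff <- function(ref_core, alt_core, offset, scoring) {
  if (nchar(ref_core) == 0L && nchar(alt_core) == 0L)
    return(edit_table(character(), integer(), character(), character()))
  if (nchar(ref_core) == 0L)
    return(edit_table("insertion", offset, "", alt_core))
  if (nchar(alt_core) == 0L)
    return(edit_table("deletion", offset, ref_core, ""))
  ev <- global_align(alt_core, ref_core, scoring)$events
  ev <- ev[ev$kind != "match_run", , drop = FALSE]
  if (nrow(ev) == 0L)
    return(edit_table(character(), integer(), character(), character()))
  ref_bases <- vapply(seq_len(nrow(ev)), function(k) {
    if (ev$kind[k] == "insertion") "" else
      substr(ref_core, ev$ref_pos[k] + 1L, ev$ref_pos[k] + ev$length[k])
  }, character(1))
  kind <- c(mismatch = "substitution", insertion = "insertion",
            deletion = "deletion")[ev$kind]
  edit_table(kind, ev$ref_pos + offset, ref_bases, ev$bases)
}

#' Describe an ssODN donor template
#'
#' Normalises the donor to plus-strand amplicon coordinates, resolves its
#' programmed edits, and validates the homology-arm geometry: after strand
#' normalisation the ssODN must read (upstream arm)(edited core)(downstream
#' arm) with both arms matching the amplicon exactly. Edits may be declared
#' explicitly (they then take precedence) or inferred by diffing the edited
#' core against the reference span between the arms. The biotin end is
#' carried as metadata only; it has no computational effect.
#'
#' @param locus A [locus_spec()].
#' @param ssodn Donor sequence 5'->3' on the strand given by `strand`.
#' @param strand `"pam"` if the ssODN sequence follows the protospacer/PAM
#'   strand of the locus, `"non_pam"` otherwise.
#' @param arm_upstream_nt,arm_downstream_nt Homology-arm lengths (nt) at the
#'   5' and 3' ends of the plus-strand-normalised ssODN.
#' @param edits Optional explicit [edit_table()]; inferred from the sequence
#'   when `NULL`.
#' @param biotin_end `"none"`, `"five_prime"` or `"three_prime"` (metadata).
#' @return An object of class `donor_spec` with the normalised plus-strand
#'   ssODN (`ssodn_plus`), the resolved `edits`, and the input metadata.
#' @export
donor_spec <- function(locus, ssodn, strand = c("pam", "non_pam"),
                       arm_upstream_nt, arm_downstream_nt, edits = NULL,
                       biotin_end = c("none", "five_prime", "three_prime")) {
  stopifnot(inherits(locus, "locus_spec"))
  strand <- match.arg(strand)
  biotin_end <- match.arg(biotin_end)
  .check_dna(ssodn, "ssodn")
  arm_upstream_nt <- as.integer(arm_upstream_nt)
  arm_downstream_nt <- as.integer(arm_downstream_nt)
  if (arm_upstream_nt < 0L || arm_downstream_nt < 0L)
    .donor_error("homology-arm lengths must be non-negative")
  on_plus <- (strand == "pam") == (locus$pam_strand == "plus")
  ssodn_plus <- if (on_plus) ssodn else revcomp(ssodn)
  if (on_plus == FALSE) {
    # arms are named on the given strand; swap after reverse complementing
    tmp <- arm_upstream_nt
    arm_upstream_nt <- arm_downstream_nt
    arm_downstream_nt <- tmp
  }
  n <- nchar(ssodn_plus)
  if (arm_upstream_nt + arm_downstream_nt > n)
    .donor_error("homology arms longer than the ssODN")
  up <- substr(ssodn_plus, 1L, arm_upstream_nt)
  down <- substr(ssodn_plus, n - arm_downstream_nt + 1L, n)
  core <- substr(ssodn_plus, arm_upstream_nt + 1L, n - arm_downstream_nt)
  up_hits <- if (arm_upstream_nt > 0L) .find_all(up, locus$amplicon) else integer()
  down_hits <- if (arm_downstream_nt > 0L) .find_all(down, locus$amplicon) else integer()
  if (arm_upstream_nt > 0L && length(up_hits) == 0L)
    .donor_error("upstream homology arm does not match the amplicon")
  if (arm_downstream_nt > 0L && length(down_hits) == 0L)
    .donor_error("downstream homology arm does not match the amplicon")
  if (is.null(edits)) {
    if (length(up_hits) != 1L || length(down_hits) != 1L)
      .donor_error("homology arms must match the amplicon uniquely to infer edits")
    core_lo <- up_hits + arm_upstream_nt        # 0-based start of ref core
    core_hi <- down_hits                        # 0-based end (exclusive)
    if (core_hi < core_lo)
      .donor_error("homology arms overlap on the amplicon")
    ref_core <- substr(locus$amplicon, core_lo + 1L, core_hi)
    edits <- .edits_from_diff(ref_core, core, core_lo, scoring_scheme())
  }
  if (is.null(edits) || nrow(edits) == 0L)
    .donor_error("donor is identical to the reference (no edits)")
  donor <- structure(
    list(ssodn = ssodn, ssodn_plus = ssodn_plus, strand = strand,
         biotin_end = biotin_end,
         arm_upstream_nt = arm_upstream_nt,
         arm_downstream_nt = arm_downstream_nt,
         edits = edits),
    class = "donor_spec"
  )
  # the normalised ssODN must be a contiguous slice of the edited allele
  allele <- expected_hdr_allele(locus, donor)
  if (length(.find_all(ssodn_plus, allele)) == 0L)
    .donor_error("ssODN is inconsistent with the declared edits/arms")
  donor
}

#' @export
print.donor_spec <- function(x, ...) {
  cat("ssODN donor: ", nchar(x$ssodn), " nt on ", x$strand, " strand, arms ",
      x$arm_upstream_nt, "/", x$arm_downstream_nt, " nt, ",
      nrow(x$edits), " programmed edit(s), biotin ", x$biotin_end,
      "\n", sep = "")
  invisible(x)
}

#' Reconstruct the expected HDR allele
#'
#' Applies the donor's programmed edits to the wild-type amplicon, yielding
#' the full precise-repair (HDR) allele a scarless template-directed repair
#' event would produce.
#'
#' @param locus A [locus_spec()].
#' @param donor A [donor_spec()] (or any list with an `edits` table).
#' @return The expected HDR allele sequence.
#' @export
expected_hdr_allele <- function(locus, donor) {
  apply_edits(locus$amplicon, donor$edits)
}

#' Read a locus/donor description from a YAML config file
#'
#' One document per locus with top-level keys `locus` and (optionally)
#' `donor`. `locus` holds `name`, `amplicon` (inline, or `amplicon_fasta`, a
#' FASTA path relative to the config file), `protospacer`, `pam_strand`,
#' `fwd_primer`, `rev_primer`. `donor` holds `ssodn`, `strand`,
#' `arm_upstream_nt`, `arm_downstream_nt`, optional `biotin_end` and optional
#' `edits` (a list of records with `kind`, `ref_pos`, `ref_bases`,
#' `alt_bases`).
#'
#' @param path Path to the YAML file.
#' @return A list with elements `locus` (a `locus_spec`) and `donor` (a
#'   `donor_spec` or `NULL`).
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path))
    .locus_error("locus config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$locus))
    .locus_error("config has no 'locus' section: ", path)
  lc <- cfg$locus
  amplicon <- lc[["amplicon"]]   # exact: don't partial-match amplicon_fasta
  if (is.null(amplicon) && !is.null(lc[["amplicon_fasta"]])) {
    fa <- file.path(dirname(path), lc[["amplicon_fasta"]])
    seqs <- Biostrings::readDNAStringSet(fa)
    amplicon <- as.character(seqs[[1L]])
  }
  locus <- locus_spec(
    name = lc$name %||% tools::file_path_sans_ext(basename(path)),
    amplicon = toupper(amplicon), protospacer = toupper(lc$protospacer),
    pam_strand = lc$pam_strand %||% "plus",
    fwd_primer = toupper(lc$fwd_primer), rev_primer = toupper(lc$rev_primer)
  )
  donor <- NULL
  if (!is.null(cfg$donor)) {
    dc <- cfg$donor
    edits <- NULL
    if (!is.null(dc$edits)) {
      edits <- edit_table(
        kind = vapply(dc$edits, `[[`, "", "kind"),
        ref_pos = vapply(dc$edits, function(e) as.integer(e$ref_pos), 1L),
        ref_bases = vapply(dc$edits, function(e) toupper(e$ref_bases %||% ""), ""),
        alt_bases = vapply(dc$edits, function(e) toupper(e$alt_bases %||% ""), "")
      )
    }
    donor <- donor_spec(
      locus, ssodn = toupper(dc$ssodn), strand = dc$strand %||% "pam",
      arm_upstream_nt = dc$arm_upstream_nt,
      arm_downstream_nt = dc$arm_downstream_nt,
      edits = edits, biotin_end = dc$biotin_end %||% "none"
    )
  }
  list(locus = locus, donor = donor)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
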