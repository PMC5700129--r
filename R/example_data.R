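#' Synthetic example locus and donor
#'
#' A fully synthetic 140-bp amplicon locus (randomly generated once and
#' frozen; it corresponds to no genomic sequence) with a 20-nt protospacer on
#' the plus strand and a cut bond at index 72, sized so that a single
#' HiSeq/MiSeq-style amplicon read spans it end to end. Three donors mirror
#' the edit sizes commonly programmed with ssODN templates: a 3-nt switch at
#' the cut (as in a BFP-to-GFP conversion), a 12-nt insertion, or an 18-nt
#' insertion, each flanked by 30-nt homology arms.
#'
#' @param edit Which programmed edit the donor carries: `"switch3"`,
#'   `"ins12"` or `"ins18"`.
#' @return A list with elements `locus` (a [locus_spec()]) and `donor`
#'   (a [donor_spec()]).
#' @examples
#' ex <- example_locus("switch3")
#' ex$locus
#' ex$donor$edits
#' @export
example_locus <- function(edit = c("switch3", "ins12", "ins18")) {
  edit <- match.arg(edit)
  amplicon <- paste0(
    "AAAACTCCATGTGTAACTCCGGAAGTAGAATCTTGCACTCGGCCTTTCCATATCTCGTGAACCCCCTGCA",
    "CGCCCTGGAGTACAATTAGGATATTCATCCCTACACTGTATATGCCGAACGTTCTAATAAACGACTTAGC"
  )
  locus <- locus_spec(
    name = "synthetic140",
    amplicon = amplicon,
    protospacer = "CGTGAACCCCCTGCACGCCC",
    pam_strand = "plus",
    fwd_primer = substr(amplicon, 1L, 20L),
    rev_primer = revcomp(substr(amplicon, 121L, 140L))
  )
  cut <- locus$cut_index
  edits <- switch(edit,
    switch3 = edit_table("substitution", cut,
                         substr(amplicon, cut + 1L, cut + 3L), "TGA"),
    ins12 = edit_table("insertion", cut, "", "GGATCCGAATTC"),
    ins18 = edit_table("insertion", cut, "", "GGATCCGAATTCAAGCTT")
  )
  core_len <- nchar(edits$ref_bases)
  ssodn <- paste0(substr(amplicon, cut - 29L, cut), edits$alt_bases,
                  substr(amplicon, cut + core_len + 1L, cut + core_len + 30L))
  donor <- donor_spec(locus, ssodn, strand = "pam",
                      arm_upstream_nt = 30L, arm_downstream_nt = 30L,
                      edits = edits)
  list(locus = locus, donor = donor)
}
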