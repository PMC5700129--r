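test_that("cut site falls 3 nt 5' of the PAM, on either strand", {
  # 20-nt protospacer at a known offset, followed by TGG
  proto <- "GATTACAGATTACAGATTAC"
  amp <- paste0("ACGTTGCAGGTTTACGGCATAACGT", proto, "TGG",
                "CCATGGGTTACCGGATCAAGCTTACTACGATCGATTGCACTGCAC")
  # protospacer starts at 0-based 25, ends at bond 45; cut is 3 nt upstream
  expect_identical(derive_cut_index(amp, proto, "plus"), 45L - 3L)

  # the same construct reverse-complemented mirrors the coordinate
  expect_identical(derive_cut_index(revcomp(amp), proto, "minus"),
                   nchar(amp) - derive_cut_index(amp, proto, "plus"))
})

test_that("degenerate guide placements are locus-definition errors", {
  proto <- "GATTACAGATTACAGATTAC"
  twice <- paste0("AAACCC", proto, "TGGTTTAAACCC", proto, "TGGAAACCC")
  expect_error(derive_cut_index(twice, proto, "plus"), class = "locus_error")
  no_pam <- paste0("AAACCC", proto, "TACTTTAAACCC")
  expect_error(derive_cut_index(no_pam, proto, "plus"), class = "locus_error")
  expect_error(derive_cut_index("ACGTACGTACGTACGTACGTACGT", proto, "plus"),
               class = "locus_error")
  expect_error(derive_cut_index(twice, "NGATTACA", "plus"))
})

test_that("locus_spec validates primers and protospacer length", {
  ex <- fix_switch3$locus
  expect_s3_class(ex, "locus_spec")
  expect_identical(ex$cut_index, 72L)
  expect_error(
    locus_spec("x", ex$amplicon, ex$protospacer, "plus",
               fwd_primer = "TTTTTTTT", rev_primer = ex$rev_primer),
    class = "locus_error"
  )
  expect_error(
    locus_spec("x", ex$amplicon, substr(ex$protospacer, 1, 10), "plus",
               ex$fwd_primer, ex$rev_primer),
    class = "locus_error"
  )
})

test_that("edits apply in reference coordinates with validation", {
  # direct application of one substitution
  expect_identical(
    apply_edits("AAACCCGGG", edit_table("substitution", 4L, "C", "T")),
    "AAACTCGGG"
  )
  # length arithmetic for an insertion donor
  amp <- fix_ins12$locus$amplicon
  allele <- expected_hdr_allele(fix_ins12$locus, fix_ins12$donor)
  expect_identical(nchar(allele), nchar(amp) + 12L)

  expect_error(apply_edits("AAACCCGGG",
                           edit_table(character(), integer(),
                                      character(), character())),
               class = "donor_error")
  expect_error(apply_edits("AAACCCGGG", edit_table("substitution", 4L, "G", "T")),
               class = "donor_error")
  expect_error(apply_edits("AAACCCGGG", edit_table("deletion", 8L, "GG", "")),
               class = "donor_error")
  expect_error(
    apply_edits("AAACCCGGG",
                edit_table(c("substitution", "deletion"), c(4L, 4L),
                           c("CC", "CC"), c("TT", ""))),
    class = "donor_error"
  )
})

test_that("expected HDR allele differs from the amplicon", {
  for (fix in list(fix_switch3, fix_ins12)) {
    allele <- expected_hdr_allele(fix$locus, fix$donor)
    expect_false(identical(allele, fix$locus$amplicon))
  }
})

test_that("edit round trip: alignment recovers the programmed net length change", {
  set.seed(11)
  sch <- scoring_scheme()
  for (fix in list(fix_switch3, fix_ins12, example_locus("ins18"))) {
    allele <- expected_hdr_allele(fix$locus, fix$donor)
    ev <- global_align(allele, fix$locus$amplicon, sch)$events
    net <- sum(ev$length[ev$kind == "insertion"]) -
      sum(ev$length[ev$kind == "deletion"])
    expect_identical(net, sum(nchar(fix$donor$edits$alt_bases)) -
                       sum(nchar(fix$donor$edits$ref_bases)))
  }
})

test_that("a 12-nt insertion donor aligns back as exactly one 12-nt insertion", {
  allele <- expected_hdr_allele(fix_ins12$locus, fix_ins12$donor)
  ev <- global_align(allele, fix_ins12$locus$amplicon, scoring_scheme())$events
  ins <- ev[ev$kind == "insertion", ]
  expect_identical(nrow(ins), 1L)
  expect_identical(ins$length, 12L)
  expect_identical(nrow(ev[ev$kind %in% c("deletion", "mismatch"), ]), 0L)
})

test_that("donor strand normalization is an involution", {
  loc <- fix_switch3$locus
  d_pam <- fix_switch3$donor
  d_nonpam <- donor_spec(loc, revcomp(d_pam$ssodn), strand = "non_pam",
                         arm_upstream_nt = d_pam$arm_downstream_nt,
                         arm_downstream_nt = d_pam$arm_upstream_nt)
  expect_identical(d_nonpam$ssodn_plus, d_pam$ssodn_plus)
  expect_identical(d_nonpam$edits, d_pam$edits)
  expect_identical(expected_hdr_allele(loc, d_nonpam),
                   expected_hdr_allele(loc, d_pam))
})

test_that("donor edits can be inferred from the ssODN sequence alone", {
  loc <- fix_switch3$locus
  inferred <- donor_spec(loc, fix_switch3$donor$ssodn, strand = "pam",
                         arm_upstream_nt = 30L, arm_downstream_nt = 30L)
  expect_identical(expected_hdr_allele(loc, inferred),
                   expected_hdr_allele(loc, fix_switch3$donor))
  # a donor identical to the reference is rejected
  expect_error(
    donor_spec(loc, substr(loc$amplicon, 31L, 90L), strand = "pam",
               arm_upstream_nt = 30L, arm_downstream_nt = 30L),
    class = "donor_error"
  )
})

test_that("locus/donor round-trips through the YAML config format", {
  dir <- withr::local_tempdir()
  fix <- fix_switch3
  cfg <- list(
    locus = list(name = fix$locus$name, amplicon = fix$locus$amplicon,
                 protospacer = fix$locus$protospacer,
                 pam_strand = fix$locus$pam_strand,
                 fwd_primer = fix$locus$fwd_primer,
                 rev_primer = fix$locus$rev_primer),
    donor = list(ssodn = fix$donor$ssodn, strand = "pam",
                 arm_upstream_nt = 30L, arm_downstream_nt = 30L)
  )
  path <- file.path(dir, "locus.yaml")
  yaml::write_yaml(cfg, path)
  rt <- read_locus_config(path)
  expect_identical(rt$locus$cut_index, fix$locus$cut_index)
  expect_identical(rt$donor$edits$alt_bases, fix$donor$edits$alt_bases)

  # amplicon supplied via FASTA
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(synthetic140 = fix$locus$amplicon)),
    file.path(dir, "amp.fasta"))
  cfg$locus$amplicon <- NULL
  cfg$locus$amplicon_fasta <- "amp.fasta"
  yaml::write_yaml(cfg, path)
  rt2 <- read_locus_config(path)
  expect_identical(rt2$locus$amplicon, fix$locus$amplicon)
})
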