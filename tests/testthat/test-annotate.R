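test_that("transition/transversion classification follows base chemistry", {
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "G"), "transversion")
  expect_equal(classify_substitution(c("C", "G", "A"), c("A", "A", "T")),
               c("transversion", "transition", "transversion"))
  expect_error(classify_substitution("C", "C"), "differ")
  expect_error(classify_substitution("C", "U"), "A/C/G/T")
})

test_that("coding substitutions annotate with HGVS c./p. on the plus strand", {
  fx <- toy_plus()  # CDS ATG GAA TAG at genomic 11..19
  mis <- annotate_variant("chr1", 14, "G", "A", fx$tm, fx$g)
  expect_equal(mis$klass, "missense")
  expect_equal(mis$hgvs_c, "c.4G>A")
  expect_equal(mis$hgvs_p, "p.E2K")
  stop <- annotate_variant("chr1", 14, "G", "T", fx$tm, fx$g)
  expect_equal(stop$klass, "stopgain")
  expect_equal(stop$hgvs_p, "p.E2X")
  syn <- annotate_variant("chr1", 16, "A", "G", fx$tm, fx$g)  # GAA->GAG
  expect_equal(syn$klass, "synonymous")
  expect_error(annotate_variant("chr1", 14, "C", "A", fx$tm, fx$g),
               "does not match")
})

test_that("minus-strand annotation complements the coding alleles", {
  mfx <- toy_minus()  # CDS ATGGAAGGATTACCCTAG read off the minus strand
  p4 <- cds_to_genomic(4, mfx$tm)
  plus_ref <- substr(unclass(mfx$g)[["chr1"]], p4, p4)
  expect_equal(plus_ref, "C")  # coding base c.4 is G
  v <- annotate_variant("chr1", p4, "C", "T", mfx$tm, mfx$g)
  expect_equal(v$hgvs_c, "c.4G>A")
  expect_equal(v$klass, "missense")
  expect_equal(v$hgvs_p, "p.E2K")
})

test_that("splice-window and UTR positions classify by offset and side", {
  mfx <- toy_minus()
  donor <- annotate_variant("chr1", 30,
                            substr(unclass(mfx$g)[["chr1"]], 30, 30), "A",
                            mfx$tm, mfx$g)
  expect_equal(donor$klass, "splice")
  expect_match(donor$hgvs_c, "^c\\.9\\+1")
  deep <- annotate_variant("chr1", 25,
                           substr(unclass(mfx$g)[["chr1"]], 25, 25), "A",
                           mfx$tm, mfx$g)
  expect_equal(deep$klass, "intronic")
  utr3 <- annotate_variant("chr1", 10,
                           substr(unclass(mfx$g)[["chr1"]], 10, 10), "C",
                           mfx$tm, mfx$g)
  expect_equal(utr3$klass, "UTR3")
  other <- annotate_variant("chr2", 10, "A", "C", mfx$tm, mfx$g)
  expect_equal(other$klass, "intergenic")
})

test_that("printed HGVS dialects parse to the right classes", {
  s <- parse_hgvs("c.G2740T", "p.E914X")
  expect_equal(s$klass, "stopgain")
  expect_equal(s$cds_pos, 2740L)
  expect_equal(s$aa_ref, "E"); expect_equal(s$aa_alt, "X")
  expect_equal(parse_hgvs("c.C2826T", "p.D942D")$klass, "synonymous")
  expect_equal(parse_hgvs("c.2162G>A", "p.R721Q")$klass, "missense")
  expect_equal(parse_hgvs("c.*3C>T")$klass, "UTR3")
  expect_equal(parse_hgvs("c.*20C>T")$klass, "UTR3")
  expect_equal(parse_hgvs("c.-12G>A")$klass, "UTR5")
  sp <- parse_hgvs("c.1682+1G>A")
  expect_equal(sp$klass, "splice")
  expect_equal(sp$cds_pos, 1682L)
  expect_equal(sp$intron_offset, 1L)
  expect_error(parse_hgvs("g.123A>T"), "c\\. string")
  expect_error(parse_hgvs("c.12AA>T"), "unparseable")
  expect_error(parse_hgvs("c.121C>G", "p.L41fs"), "unparseable")
})

test_that("parse_hgvs inverts annotate_variant on synthetic fixtures", {
  set.seed(3)
  for (fx in list(toy_plus(), toy_minus())) {
    cdsg_len <- nchar(cds_sequence(fx$tm, fx$g))
    for (cp in seq_len(cdsg_len)) {
      gp <- cds_to_genomic(cp, fx$tm)
      ref <- substr(unclass(fx$g)[["chr1"]], gp, gp)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        v <- annotate_variant("chr1", gp, ref, alt, fx$tm, fx$g)
        back <- parse_hgvs(v$hgvs_c, v$hgvs_p)
        expect_equal(back$klass, v$klass)
        expect_equal(back$cds_pos, v$cds_pos)
        expect_equal(back$aa_ref, v$aa_ref)
        expect_equal(back$aa_alt, v$aa_alt)
      }
    }
  }
})

test_that("di-pyrimidine and UV-signature flags follow the pyrimidine strand", {
  g <- genome(c(chr1 = "TCG"))
  fl <- dipyrimidine_flags("chr1", 2, "C", "T", g)
  expect_true(fl$dipyrimidine); expect_true(fl$uv_signature)
  expect_equal(fl$pyrimidine_strand, "+")
  g2 <- genome(c(chr1 = "ACA"))
  fl2 <- dipyrimidine_flags("chr1", 2, "C", "T", g2)
  expect_false(fl2$dipyrimidine); expect_false(fl2$uv_signature)
  # purine reference: the event lives on the minus strand
  g3 <- genome(c(chr1 = "AGT"))
  fl3 <- dipyrimidine_flags("chr1", 2, "G", "A", g3)
  expect_true(fl3$dipyrimidine); expect_true(fl3$uv_signature)
  expect_equal(fl3$pyrimidine_strand, "-")
  # C>A at a di-pyrimidine site: flagged site but not UV signature
  fl4 <- dipyrimidine_flags("chr1", 2, "C", "A", g)
  expect_true(fl4$dipyrimidine); expect_false(fl4$uv_signature)
  # N neighbor disqualifies conservatively
  g5 <- genome(c(chr1 = "NCA"))
  expect_false(dipyrimidine_flags("chr1", 2, "C", "T", g5)$dipyrimidine)
})

test_that("flags are invariant under re-expressing the event on the other strand", {
  set.seed(19)
  for (i in 1:100) {
    s <- paste(sample(c("A", "C", "G", "T"), 21, replace = TRUE),
               collapse = "")
    pos <- sample(2:20, 1)
    ref <- substr(s, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    g_fwd <- genome(c(chr1 = s))
    g_rev <- genome(c(chr1 = reverse_complement(s)))
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    a <- dipyrimidine_flags("chr1", pos, ref, alt, g_fwd)
    b <- dipyrimidine_flags("chr1", 22 - pos, comp[[ref]], comp[[alt]],
                            g_rev)
    expect_equal(a$dipyrimidine, b$dipyrimidine)
    expect_equal(a$uv_signature, b$uv_signature)
    expect_equal(a$substitution_class, b$substitution_class)
  }
})

test_that("novelty triage is allele-exact across catalogs", {
  calls <- data.frame(contig = "chr1", pos = c(100, 100, 200),
                      ref = c("G", "G", "C"), alt = c("A", "T", "T"),
                      stringsAsFactors = FALSE)
  cat1 <- data.frame(contig = "chr1", pos = 100, ref = "G", alt = "A",
                     id = "rs116506614", source = "dbsnp", af = 0.005,
                     stringsAsFactors = FALSE)
  cat2 <- data.frame(contig = "chr1", pos = c(100, 200),
                     ref = c("G", "C"), alt = c("A", "T"),
                     id = c("COSM1", "COSM2"), source = "cosmic",
                     af = NA, stringsAsFactors = FALSE)
  out <- lookup_novelty(calls, list(cat1, cat2))
  expect_equal(out$novelty, c("reference", "novel", "reference"))
  expect_equal(out$catalog_ids[1], "dbsnp:rs116506614;cosmic:COSM1")
  expect_true(is.na(out$catalog_ids[2]))
})

test_that("damage labels aggregate as any-damaging", {
  calls <- data.frame(contig = "chr1", pos = c(1, 2, 3), ref = "C",
                      alt = "T", stringsAsFactors = FALSE)
  labels <- data.frame(
    contig = "chr1", pos = c(1, 1, 2), ref = "C", alt = "T",
    predictor = c("sift", "polyphen", "sift"),
    label = c("tolerated", "probably_damaging", "tolerated"),
    stringsAsFactors = FALSE)
  out <- attach_damage_labels(calls, labels)
  expect_equal(out$damage, c("damaging", "tolerated", NA))
})

test_that("annotator agrees with the translate-and-diff oracle", {
  set.seed(23)
  n_checked <- 0
  for (rep in 1:6) {
    cfg <- sim_config(seed = 100 + rep, genome_length = 3000,
                      cds_codons = 40, n_exons = sample(3:5, 1))
    ref <- make_reference(cfg, strand = if (rep %% 2) "-" else "+")
    span <- range(ref$tm$exon_start, ref$tm$exon_end)
    seqc <- unclass(ref$genome)[[ref$tm$contig]]
    positions <- sample(seq(span[1] - 3, span[2] + 3), 90, replace = TRUE)
    for (p in positions) {
      refb <- substr(seqc, p, p)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1)
      v <- annotate_variant(ref$tm$contig, p, refb, altb, ref$tm,
                            ref$genome)
      expect_equal(v$klass, oracle_klass(p, refb, altb, ref$tm,
                                         ref$genome),
                   info = sprintf("rep=%d pos=%d %s>%s", rep, p, refb,
                                  altb))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 500)
})
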