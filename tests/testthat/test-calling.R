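test_that("VAF arithmetic and the zero-depth signal", {
  expect_equal(compute_vaf(30, 1000), 3)
  expect_equal(compute_vaf(0, 500), 0)
  expect_equal(compute_vaf(1000, 1000), 100)
  expect_warning(v <- compute_vaf(0, 0), "undefined")
  expect_true(is.na(v))
})

test_that("germ-line calling applies the 20% threshold inclusively", {
  cfg <- call_config()
  het <- call_germline(pileup_row("S1", 100, "A", 1000, c(G = 480)), cfg)
  expect_equal(nrow(het), 1L)
  expect_equal(het$origin, "germline")
  expect_equal(het$genotype, "het")
  none <- call_germline(pileup_row("S1", 100, "A", 1000, c(G = 199)), cfg)
  expect_equal(nrow(none), 0L)
  edge <- call_germline(pileup_row("S1", 100, "A", 1000, c(G = 200)), cfg)
  expect_equal(nrow(edge), 1L)
  hom <- call_germline(pileup_row("S1", 100, "A", 1000, c(G = 950)), cfg)
  expect_equal(hom$genotype, "hom")
})

test_that("paired discordance designates somatic, germ-line and absent", {
  cfg <- call_config()
  L <- pileup_row("S_L", 100, "A", 3000, c(G = 150))
  R <- pileup_row("S_R", 100, "A", 3000, c(G = 1))
  som <- call_paired_discordant(L, R, cfg, pair_id = "P1")
  expect_equal(som$origin, "somatic")
  expect_equal(som$side, "left")
  expect_equal(som$vaf_percent, 5)
  both <- call_paired_discordant(
    pileup_row("S_L", 100, "A", 1000, c(G = 450)),
    pileup_row("S_R", 100, "A", 1000, c(G = 520)), cfg)
  expect_equal(both$origin, "germline")
  neither <- call_paired_discordant(
    pileup_row("S_L", 100, "A", 1000, c()),
    pileup_row("S_R", 100, "A", 1000, c()), cfg)
  expect_equal(nrow(neither), 0L)
  expect_error(call_paired_discordant(
    pileup_row("S_L", 100, "A", 1000, c()),
    pileup_row("S_R", 100, "C", 1000, c())), "reference")
})

test_that("each allele at a site gets exactly one designation", {
  cfg <- call_config()
  L <- pileup_row("S_L", 7, "C", 2000, c(A = 90, T = 60))
  R <- pileup_row("S_R", 7, "C", 2000, c(A = 85))
  all_calls <- call_paired_discordant(L, R, cfg, include_absent = TRUE)
  expect_equal(nrow(all_calls), 3L)  # one row per alt base
  expect_setequal(all_calls$alt, c("A", "G", "T"))
  expect_equal(all_calls$origin[all_calls$alt == "A"], "germline")
  expect_equal(all_calls$origin[all_calls$alt == "T"], "somatic")
  expect_equal(all_calls$origin[all_calls$alt == "G"], "absent")
})

test_that("designations are symmetric under left/right swap", {
  cfg <- call_config()
  set.seed(42)
  for (i in 1:20) {
    d1 <- sample(500:5000, 1); d2 <- sample(500:5000, 1)
    L <- pileup_row("S_L", 9, "G", d1,
                    c(A = rbinom(1, d1, 0.03), T = rbinom(1, d1, 0.005)))
    R <- pileup_row("S_R", 9, "G", d2,
                    c(A = rbinom(1, d2, 0.004)))
    ab <- call_paired_discordant(L, R, cfg, include_absent = TRUE)
    ba <- call_paired_discordant(R, L, cfg, include_absent = TRUE)
    expect_equal(ab$origin, ba$origin)
    swap <- c(left = "right", right = "left", both = "both")
    expect_equal(unname(swap[ab$side[!is.na(ab$side)]]),
                 ba$side[!is.na(ba$side)])
  }
})

test_that("raising presence thresholds never creates somatic calls", {
  set.seed(7)
  for (i in 1:15) {
    d <- sample(600:4000, 1)
    L <- pileup_row("S_L", 3, "T", d, c(C = rbinom(1, d, 0.02)))
    R <- pileup_row("S_R", 3, "T", d, c(C = rbinom(1, d, 0.002)))
    loose <- call_paired_discordant(L, R, call_config(
      presence_vaf_percent = 0.5), include_absent = TRUE)
    strict <- call_paired_discordant(L, R, call_config(
      presence_vaf_percent = 2), include_absent = TRUE)
    was_absent <- loose$alt[loose$origin == "absent"]
    still <- strict$origin[match(was_absent, strict$alt)]
    expect_true(all(still == "absent"))
  }
})

test_that("somatic retention filters use inclusive boundaries", {
  cfg <- call_config()
  calls <- data.frame(
    sample_id = "S", pair_id = "P", contig = "chr1", pos = c(1, 2, 3, 4),
    ref = "C", alt = "T", alt_count = c(123, 24, 150, 10),
    depth = c(4070, 599, 5000, 650),
    vaf_percent = c(3.02, 4.0, 2.99, 1.5), origin = "somatic",
    genotype = NA, side = "left", filter = NA, stringsAsFactors = FALSE)
  out <- apply_somatic_filters(calls, cfg)
  expect_equal(out$filter, c("PASS", "LOW_DEPTH", "LOW_VAF", "LOW_VAF"))
  # exact boundary values are retained
  edge <- calls[1, ]; edge$vaf_percent <- 3; edge$depth <- 600
  expect_equal(apply_somatic_filters(edge, cfg)$filter, "PASS")
  # raising min_depth can only shrink the PASS set
  stricter <- apply_somatic_filters(calls, call_config(min_depth = 5000))
  expect_lte(sum(stricter$filter == "PASS"), sum(out$filter == "PASS"))
})

test_that("recurrence exclusion removes every occurrence across pairs", {
  mk <- function(pair, pos, alt = "T") {
    data.frame(sample_id = paste0(pair, "_L"), pair_id = pair,
               contig = "chr1", pos = pos, ref = "C", alt = alt,
               alt_count = 50, depth = 1000, vaf_percent = 5,
               origin = "somatic", genotype = NA, side = "left",
               filter = "PASS", stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("P1", 100), mk("P2", 100), mk("P3", 200))
  res <- exclude_recurrent(calls)
  expect_equal(res$retained$pos, 200)
  expect_equal(nrow(res$excluded), 2L)
  expect_true(all(res$excluded$filter == "RECURRENT"))
  # all-unique panel: nothing excluded
  uniq <- rbind(mk("P1", 100), mk("P2", 200))
  expect_equal(nrow(exclude_recurrent(uniq)$excluded), 0L)
  # same identity twice within one pair is one occurrence, not recurrence
  within <- rbind(mk("P1", 100), mk("P1", 100))
  expect_equal(nrow(exclude_recurrent(within)$excluded), 0L)
})

test_that("coverage summary is the fraction of sites at threshold", {
  expect_equal(summarize_coverage(c(1200, 900, 1500, 2000), 1000), 0.75)
  expect_equal(summarize_coverage(c(1500, 2000), 1000), 1)
  expect_error(summarize_coverage(integer(), 1000), "no sites")
})

test_that("the exact-test gate matches the enumeration oracle", {
  set.seed(11)
  alpha <- 0.01
  cfg <- call_config(somatic_fisher_alpha = alpha)
  for (i in 1:200) {
    dL <- sample(200:1500, 1); dR <- sample(200:1500, 1)
    aL <- rbinom(1, dL, runif(1, 0.005, 0.06))
    aR <- rbinom(1, dR, 0.003)
    L <- pileup_row("S_L", 5, "G", dL, c(T = aL))
    R <- pileup_row("S_R", 5, "G", dR, c(T = aR))
    gated <- call_paired_discordant(L, R, cfg)
    ungated <- call_paired_discordant(L, R, call_config())
    som_t <- any(ungated$origin == "somatic" & ungated$alt == "T")
    if (!som_t) next
    p_oracle <- oracle_fisher(aL, dL - aL, aR, dR - aR)
    expect_equal(any(gated$origin == "somatic" & gated$alt == "T"),
                 p_oracle < alpha)
  }
})

test_that("pileup TSV and pair manifest round-trip", {
  pu <- rbind(pileup_row("S1", 10, "A", 800, c(C = 40)),
              pileup_row("S2", 10, "A", 900, c()))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "pu.tsv")
  write_pileups(pu, path)
  expect_equal(read_pileups(path), pu, ignore_attr = TRUE)
  mpath <- file.path(dir, "pairs.tsv")
  writeLines(c("pair_id\tleft_sample\tright_sample\tphenotype",
               "P1\tS1\tS2\tclear"), mpath)
  m <- read_pair_manifest(mpath)
  expect_equal(m$left_sample, "S1")
  writeLines(c("pair_id\tleft_sample\tright_sample\tphenotype",
               "P1\tS1\tS1\tclear"), mpath)
  expect_error(read_pair_manifest(mpath), "same sample")
})
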