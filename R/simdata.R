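#' Configuration for the paired-lens amplicon simulator
#'
#' Defaults emulate the observed structure of paired-lens targeted-amplicon
#' deep sequencing: heavy-tailed per-site depths centred near 3000x
#' (lognormal), germ-line heterozygous VAFs spread around 50%, somatic VAFs
#' uniform on 3-13%, a per-base miscall rate of 0.1%, and a configurable
#' fraction of somatic events placed as pyrimidine-strand C>T changes at
#' di-pyrimidine sites (the UV signature).
#'
#' @param seed integer seed; all randomness in the simulator flows from it.
#' @param genome_length contig length (>= 300).
#' @param gc_fraction genome GC content.
#' @param n_pairs number of left/right sample pairs.
#' @param n_individuals cohort size for genotype-panel simulation.
#' @param depth_meanlog,depth_sdlog lognormal depth model (per site, per
#'   sample).
#' @param error_rate per-base miscall probability (uniform over the three
#'   wrong bases; see `ct_bias`).
#' @param germline_maf_spectrum population allele frequencies from which
#'   germ-line variant AFs are drawn.
#' @param n_germline_sites number of segregating germ-line variant sites.
#' @param het_vaf_sd SD (percentage points) of heterozygous VAF around 50.
#' @param somatic_vaf_range closed VAF interval (percent) for injected
#'   somatic variants.
#' @param somatic_per_pair_rate Poisson mean of somatic variants per pair.
#' @param uv_fraction fraction of somatic events forced to be
#'   pyrimidine-strand C>T at di-pyrimidine-eligible sites.
#' @param n_exons exon count of the simulated transcript (>= 3 mirrors
#'   multi-exon panel genes).
#' @param cds_codons CDS length in codons (excluding the stop).
#' @param utr_length length of each simulated UTR.
#' @param clear_fraction fraction of pairs labeled `clear` (the rest
#'   `cataract`); default mirrors a 35:22 clear:cataract panel.
#' @param ct_bias extra weight on C>T / G>A miscalls (1 = unbiased); a
#'   deamination-artifact stress mode for UV-signature inference.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 20000L,
                       gc_fraction = 0.5,
                       n_pairs = 20L,
                       n_individuals = 225L,
                       depth_meanlog = log(3000),
                       depth_sdlog = 0.5,
                       error_rate = 0.001,
                       germline_maf_spectrum = c(0.35, 0.05, 0.02, 0.005),
                       n_germline_sites = 8L,
                       het_vaf_sd = 3,
                       somatic_vaf_range = c(3, 13),
                       somatic_per_pair_rate = 3,
                       uv_fraction = 0.5,
                       n_exons = 3L,
                       cds_codons = 120L,
                       utr_length = 30L,
                       clear_fraction = 35 / 57,
                       ct_bias = 1) {
  stopifnot(genome_length >= 300L, gc_fraction >= 0, gc_fraction <= 1,
            n_pairs >= 1L, error_rate >= 0, error_rate < 1,
            all(germline_maf_spectrum > 0),
            all(germline_maf_spectrum <= 1),
            length(somatic_vaf_range) == 2L,
            somatic_vaf_range[1] > 0, somatic_vaf_range[2] < 100,
            somatic_vaf_range[1] <= somatic_vaf_range[2],
            uv_fraction >= 0, uv_fraction <= 1,
            n_exons >= 1L, cds_codons >= 2L, ct_bias >= 1)
  structure(as.list(environment()), class = "sim_config")
}

.random_genome <- function(length, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), length, replace = TRUE, prob = probs),
        collapse = "")
}

.random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  all_codons <- apply(expand.grid(BASES, BASES, BASES), 1, paste,
                      collapse = "")
  sense <- setdiff(all_codons, stops)
  paste0("ATG",
         paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""),
         sample(stops, 1L))
}

#' Simulate a reference contig carrying a minus-strand multi-exon transcript
#'
#' Generates a random genome at the requested GC content and embeds a valid
#' transcript (CDS starting ATG, ending in a stop, length a multiple of
#' three, flanked by UTRs) split over `n_exons` exons. The transcript is
#' placed on the minus strand by default, mirroring the orientation of the
#' genes the paired-lens design targets.
#'
#' @param cfg a [sim_config()].
#' @param strand strand on which to place the transcript.
#' @return list with `genome` (a [genome()]) and `tm`
#'   (a [transcript_model()]).
#' @export
make_reference <- function(cfg, strand = "-") {
  set.seed(cfg$seed)
  strand <- match.arg(strand, c("-", "+"))
  gseq <- .random_genome(cfg$genome_length, cfg$gc_fraction)
  cds <- .random_cds(cfg$cds_codons)
  utr5 <- .random_genome(cfg$utr_length, cfg$gc_fraction)
  utr3 <- .random_genome(cfg$utr_length, cfg$gc_fraction)
  tx <- paste0(utr5, cds, utr3)
  tx_len <- nchar(tx)
  # contiguous exon chunks of the transcript
  cuts <- sort(sample(seq_len(tx_len - 1L), cfg$n_exons - 1L))
  chunk_start <- c(1L, cuts + 1L)
  chunk_end <- c(cuts, tx_len)
  sizes <- chunk_end - chunk_start + 1L
  introns <- if (cfg$n_exons > 1L) {
    sample(80:200, cfg$n_exons - 1L, replace = TRUE)
  } else integer()
  span <- sum(sizes) + sum(introns)
  if (span + 200L > cfg$genome_length) {
    stop("genome_length too small for the requested transcript")
  }
  pos0 <- 101L
  # genomic order: transcript-last chunk first for minus strand
  g_order <- if (strand == "-") rev(seq_len(cfg$n_exons)) else
    seq_len(cfg$n_exons)
  exon_start <- integer(cfg$n_exons); exon_end <- integer(cfg$n_exons)
  gpos <- pos0
  for (j in seq_len(cfg$n_exons)) {
    k <- g_order[j]
    chunk <- substr(tx, chunk_start[k], chunk_end[k])
    plus_seq <- if (strand == "-") reverse_complement(chunk) else chunk
    exon_start[k] <- gpos
    exon_end[k] <- gpos + sizes[k] - 1L
    substr(gseq, exon_start[k], exon_end[k]) <- plus_seq
    gpos <- exon_end[k] + if (j < cfg$n_exons) introns[j] else 0L
    if (j < cfg$n_exons) gpos <- gpos + 1L
  }
  ord <- order(exon_start)
  tm_try <- list(exon_start = exon_start[ord], exon_end = exon_end[ord],
                 strand = strand)
  g <- genome(c(sim1 = gseq))
  # transcript coordinates of CDS bounds -> genomic
  ex_tx <- .exonic_genomic(structure(
    c(tm_try, list(contig = "sim1", cds_start = min(exon_start),
                   cds_end = max(exon_end))), class = "transcript_model"))
  cds_tx <- ex_tx[(cfg$utr_length + 1L):(cfg$utr_length + nchar(cds))]
  tm <- transcript_model("SIMGENE", "SIMTX1", "sim1", strand,
                         exon_start[ord], exon_end[ord],
                         min(cds_tx), max(cds_tx))
  stopifnot(cds_sequence(tm, g) == cds)
  list(genome = g, tm = tm)
}

# plus-strand sites eligible for a pyrimidine-strand C>T at a di-pyrimidine
.uv_eligible <- function(g, contig, positions) {
  keep <- vapply(positions, function(p) {
    ref <- substr(contig_seq(g, contig), p, p)
    if (!ref %in% c("C", "G")) return(FALSE)
    alt <- if (ref == "C") "T" else "A"
    fl <- dipyrimidine_flags(contig, p, ref, alt, g)
    fl$dipyrimidine
  }, TRUE)
  positions[keep]
}

.truncnorm <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

#' Inject germ-line and somatic variants and emit paired pileups
#'
#' For each pair, shared germ-line variants are drawn from the population
#' AF spectrum (Hardy-Weinberg genotypes); heterozygous per-lens VAFs are
#' Normal(50, `het_vaf_sd`) truncated to 20-80, homozygous near 100.
#' Somatic variants (Poisson per pair) are assigned to one lens with VAF
#' uniform in `somatic_vaf_range`; a `uv_fraction` of them is placed only at
#' di-pyrimidine-eligible sites as pyrimidine-strand C>T. Depths are
#' lognormal; allele counts are multinomial given the true VAF with
#' symmetric per-base miscalls at `error_rate` (optionally C>T biased).
#'
#' @param cfg a [sim_config()].
#' @param g a [genome()] from [make_reference()].
#' @param tm the matching [transcript_model()].
#' @return list with `pileups` (all samples), `pairs` (manifest
#'   data.frame), and `truth` (list with `germline` and `somatic`
#'   data.frames).
#' @export
inject_and_pileup <- function(cfg, g, tm) {
  set.seed(cfg$seed + 1L)
  contig <- tm$contig
  sites <- sort(.exonic_genomic(tm))
  seqc <- contig_seq(g, contig)
  refs <- substring(seqc, sites, sites)
  uv_sites <- .uv_eligible(g, contig, sites)
  if (cfg$uv_fraction > 0 && length(uv_sites) == 0L) {
    stop("uv_fraction > 0 but no di-pyrimidine-eligible site in the model")
  }
  # segregating germ-line sites
  gl_pos <- sort(sample(sites, cfg$n_germline_sites))
  gl_ref <- substring(seqc, gl_pos, gl_pos)
  gl_alt <- vapply(gl_ref, function(r) sample(setdiff(BASES, r), 1L), "",
                   USE.NAMES = FALSE)
  gl_af <- sample(cfg$germline_maf_spectrum, cfg$n_germline_sites,
                  replace = TRUE)
  pair_ids <- sprintf("P%02d", seq_len(cfg$n_pairs))
  n_clear <- round(cfg$n_pairs * cfg$clear_fraction)
  pairs <- data.frame(
    pair_id = pair_ids,
    left_sample = paste0(pair_ids, "_L"),
    right_sample = paste0(pair_ids, "_R"),
    phenotype = c(rep("clear", n_clear),
                  rep("cataract", cfg$n_pairs - n_clear)),
    stringsAsFactors = FALSE)
  truth_gl <- list(); truth_som <- list()
  # per sample: list of (pos, alt, vaf)
  sample_variants <- stats::setNames(
    vector("list", 2L * cfg$n_pairs),
    c(pairs$left_sample, pairs$right_sample))
  add_var <- function(sample, pos, alt, vaf) {
    sample_variants[[sample]][[length(sample_variants[[sample]]) + 1L]] <<-
      list(pos = pos, alt = alt, vaf = vaf)
  }
  for (i in seq_len(cfg$n_pairs)) {
    pid <- pairs$pair_id[i]
    ls <- pairs$left_sample[i]; rs <- pairs$right_sample[i]
    # germ-line genotypes, shared by both lenses
    gt <- stats::rbinom(cfg$n_germline_sites, 2L, gl_af)
    for (k in which(gt > 0L)) {
      genotype <- if (gt[k] == 1L) "het" else "hom"
      for (s in c(ls, rs)) {
        vaf <- if (genotype == "het") {
          .truncnorm(1L, 50, cfg$het_vaf_sd, 20, 80)
        } else {
          .truncnorm(1L, 99.5, 0.4, 98, 100)
        }
        add_var(s, gl_pos[k], gl_alt[k], vaf)
      }
      truth_gl[[length(truth_gl) + 1L]] <- data.frame(
        pair_id = pid, contig = contig, pos = gl_pos[k], ref = gl_ref[k],
        alt = gl_alt[k], genotype = genotype, af = gl_af[k],
        stringsAsFactors = FALSE)
    }
    # somatic, single-lens by construction
    n_som <- stats::rpois(1L, cfg$somatic_per_pair_rate)
    if (n_som == 0L) next
    n_uv <- round(n_som * cfg$uv_fraction)
    taken <- gl_pos
    for (m in seq_len(n_som)) {
      uv <- m <= n_uv
      pool <- setdiff(if (uv) uv_sites else sites, taken)
      if (!length(pool)) next
      p <- if (length(pool) == 1L) pool else sample(pool, 1L)
      taken <- c(taken, p)
      r <- substr(seqc, p, p)
      a <- if (uv) {
        if (r == "C") "T" else "A"
      } else {
        sample(setdiff(BASES, r), 1L)
      }
      side <- sample(c("left", "right"), 1L)
      s <- if (side == "left") ls else rs
      vaf <- stats::runif(1L, cfg$somatic_vaf_range[1],
                          cfg$somatic_vaf_range[2])
      add_var(s, p, a, vaf)
      truth_som[[length(truth_som) + 1L]] <- data.frame(
        pair_id = pid, side = side, sample_id = s, contig = contig,
        pos = p, ref = r, alt = a, true_vaf = vaf, uv_signature = uv,
        stringsAsFactors = FALSE)
    }
  }
  # pileups
  e <- cfg$error_rate
  pu <- vector("list", length(sample_variants))
  names(pu) <- names(sample_variants)
  err_weight <- function(from, to) {
    w <- rep(1, 4); names(w) <- BASES
    if (cfg$ct_bias > 1) {
      if (from == "C") w["T"] <- cfg$ct_bias
      if (from == "G") w["A"] <- cfg$ct_bias
    }
    w[to] / sum(w[setdiff(BASES, from)])
  }
  for (s in names(sample_variants)) {
    depth <- pmax(50L,
                  as.integer(round(stats::rlnorm(length(sites),
                                                 cfg$depth_meanlog,
                                                 cfg$depth_sdlog))))
    vars <- sample_variants[[s]]
    var_pos <- vapply(vars, `[[`, 0, "pos")
    cnt <- matrix(0L, nrow = length(sites), ncol = 4L,
                  dimnames = list(NULL, BASES))
    for (j in seq_along(sites)) {
      p_true <- stats::setNames(numeric(4L), BASES)
      p_true[refs[j]] <- 1
      for (v in vars[var_pos == sites[j]]) {
        p_true[v$alt] <- p_true[v$alt] + v$vaf / 100
        p_true[refs[j]] <- p_true[refs[j]] - v$vaf / 100
      }
      p_obs <- p_true * (1 - e)
      for (b in BASES) {
        others <- setdiff(BASES, b)
        p_obs[b] <- p_obs[b] + sum(vapply(
          others, function(x) p_true[x] * e * err_weight(x, b), 0))
      }
      cnt[j, ] <- stats::rmultinom(1L, depth[j], p_obs)[, 1L]
    }
    pu[[s]] <- data.frame(sample_id = s, contig = contig, pos = sites,
                          ref = refs, depth = depth,
                          A = cnt[, "A"], C = cnt[, "C"], G = cnt[, "G"],
                          T = cnt[, "T"], stringsAsFactors = FALSE)
  }
  pileups <- do.call(rbind, pu)
  rownames(pileups) <- NULL
  truth <- list(
    germline = do.call(rbind, c(list(data.frame()), truth_gl)),
    somatic = do.call(rbind, c(list(data.frame()), truth_som)))
  list(pileups = pileups, pairs = pairs, truth = truth)
}

#' Hardy-Weinberg cohort genotypes for a set of variants
#'
#' @param cfg a [sim_config()] (uses `seed` and `n_individuals`).
#' @param variants data.frame with columns `contig`, `pos`, `ref`, `alt`,
#'   `af` (population allele frequencies).
#' @param phenotype_counts named integer vector of phenotype labels to
#'   assign; defaults emulate a 225-individual case-control panel (64
#'   clear-lens controls, 161 cataract cases across subtypes).
#' @return list with `genotypes` (individuals x variants matrix of 0/1/2)
#'   and `phenotypes` (character vector).
#' @export
make_cohort_genotypes <- function(cfg, variants,
                                  phenotype_counts = c(clear = 64,
                                                       cortical = 43,
                                                       nuclear = 67,
                                                       PSC = 2,
                                                       mixed = 49)) {
  set.seed(cfg$seed + 2L)
  stopifnot(all(variants$af >= 0), all(variants$af <= 1))
  n <- cfg$n_individuals
  gmat <- vapply(variants$af,
                 function(af) stats::rbinom(n, 2L, af),
                 integer(n))
  if (is.null(dim(gmat))) gmat <- matrix(gmat, nrow = n)
  rownames(gmat) <- sprintf("I%03d", seq_len(n))
  colnames(gmat) <- paste(variants$contig, variants$pos, variants$ref,
                          variants$alt, sep = ":")
  ph <- rep(names(phenotype_counts), times = phenotype_counts)
  ph <- ph[seq_len(min(n, length(ph)))]
  if (length(ph) < n) ph <- c(ph, rep(names(phenotype_counts)[1],
                                      n - length(ph)))
  list(genotypes = gmat, phenotypes = ph)
}

#' Write a simulation to disk (pileups, manifest, catalog, truth)
#'
#' The catalog contains the injected germ-line variants labeled as known
#' ("reference") records, so novelty triage can be exercised downstream:
#' injected somatic variants are then expected to be novel.
#'
#' @param sim result of [inject_and_pileup()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pileups = file.path(dir, "pileups.tsv"),
             pairs = file.path(dir, "pairs.tsv"),
             catalog = file.path(dir, "catalog.tsv"),
             truth = file.path(dir, "truth.json"))
  write_pileups(sim$pileups, paths["pileups"])
  utils::write.table(sim$pairs, paths["pairs"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  gl <- sim$truth$germline
  cat_df <- if (nrow(gl)) {
    u <- unique(gl[c("contig", "pos", "ref", "alt", "af")])
    data.frame(contig = u$contig, pos = u$pos, ref = u$ref, alt = u$alt,
               id = sprintf("SIMREF%03d", seq_len(nrow(u))),
               source = "simcat", af = u$af, stringsAsFactors = FALSE)
  } else {
    data.frame(contig = character(), pos = integer(), ref = character(),
               alt = character(), id = character(), source = character(),
               af = numeric())
  }
  utils::write.table(cat_df, paths["catalog"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(sim$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
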