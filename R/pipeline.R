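#' Run paired discordance calling over a whole panel
#'
#' Applies [call_paired_discordant()] to every pair in the manifest, keeps
#' the somatic designations, applies the retention filters and the
#' cross-pair recurrence exclusion, and returns all calls together with a
#' filter-accounting log in which the counts always conserve:
#' `n_in = n_retained + n_low_vaf + n_low_depth + n_recurrent`.
#'
#' @param pileups pileup data.frame covering all samples.
#' @param pairs pair manifest data.frame (see [read_pair_manifest()]).
#' @param cfg a [call_config()].
#' @param phenotype optionally restrict to pairs with this phenotype.
#' @return list with `calls` (every somatic call, `filter` set, RECURRENT
#'   occurrences included), `retained` (PASS, non-recurrent), and `log`
#'   (named integer vector of the accounting counts).
#' @export
run_paired_panel <- function(pileups, pairs, cfg = call_config(),
                             phenotype = NULL) {
  if (!is.null(phenotype)) pairs <- pairs[pairs$phenotype %in% phenotype, ]
  per_pair <- lapply(seq_len(nrow(pairs)), function(i) {
    left <- pileups[pileups$sample_id == pairs$left_sample[i], ]
    right <- pileups[pileups$sample_id == pairs$right_sample[i], ]
    calls <- call_paired_discordant(left, right, cfg,
                                    pair_id = pairs$pair_id[i])
    calls[calls$origin == "somatic", , drop = FALSE]
  })
  somatic <- do.call(rbind, c(list(empty_calls()), per_pair))
  rownames(somatic) <- NULL
  somatic <- apply_somatic_filters(somatic, cfg)
  pass <- somatic[somatic$filter == "PASS", , drop = FALSE]
  rec <- exclude_recurrent(pass)
  calls <- rbind(somatic[somatic$filter != "PASS", , drop = FALSE],
                 rec$retained, rec$excluded)
  calls <- order_calls(calls)
  rownames(calls) <- NULL
  log <- c(n_in = nrow(somatic),
           n_low_vaf = sum(grepl("LOW_VAF", somatic$filter)),
           n_low_depth = sum(somatic$filter == "LOW_DEPTH"),
           n_recurrent = nrow(rec$excluded),
           n_retained = nrow(rec$retained))
  stopifnot(log["n_in"] ==
              sum(log[c("n_low_vaf", "n_low_depth",
                        "n_recurrent", "n_retained")]))
  list(calls = calls, retained = rec$retained, log = log)
}

#' Write calls as a flat TSV
#' @param calls calls data.frame.
#' @param path output path.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Read calls written by [write_calls_tsv()]
#' @param path input path.
#' @return calls data.frame.
#' @export
read_calls_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write calls as minimal VCF v4.2
#'
#' One record per (contig, pos, alt); `ORIGIN`, `VAF`, `DP`, `PAIR` and
#' `SIDE` are emitted as INFO keys and the retention status goes in the
#' FILTER column (non-PASS records are retained so exclusion accounting
#' stays auditable downstream).
#'
#' @param calls calls data.frame.
#' @param path output path.
#' @param source_tag value for the `##source` header line.
#' @export
write_calls_vcf <- function(calls, path, source_tag = "paircall") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Designation: germline, somatic or ambiguous\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele frequency, percent\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth in the carrier sample\">",
    "##INFO=<ID=PAIR,Number=1,Type=String,Description=\"Pair identifier\">",
    "##INFO=<ID=SIDE,Number=1,Type=String,Description=\"Carrier side: left, right or both\">",
    "##FILTER=<ID=LOW_VAF,Description=\"VAF below the somatic retention floor\">",
    "##FILTER=<ID=LOW_DEPTH,Description=\"Depth below the somatic retention floor\">",
    "##FILTER=<ID=RECURRENT,Description=\"Variant identity observed in more than one pair\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- vapply(seq_len(nrow(calls)), function(i) {
    x <- calls[i, ]
    info <- sprintf("ORIGIN=%s;VAF=%.4f;DP=%d;PAIR=%s;SIDE=%s",
                    x$origin, x$vaf_percent, x$depth,
                    ifelse(is.na(x$pair_id), ".", x$pair_id),
                    ifelse(is.na(x$side), ".", x$side))
    filt <- ifelse(is.na(x$filter), ".", gsub(",", ";", x$filter))
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
            x$contig, x$pos, x$ref, x$alt, filt, info)
  }, "")
  writeLines(c(hdr, recs), path)
}

#' Write a machine-readable run manifest
#'
#' Records the configuration, input file checksums, seed and the
#' filter-accounting counts of a run.
#'
#' @param path output JSON path.
#' @param config list of configuration values.
#' @param inputs character vector of input file paths (md5-summed).
#' @param counts named numeric vector of accounting counts.
#' @param seed seed used, if any.
#' @export
write_run_manifest <- function(path, config = list(), inputs = character(),
                               counts = NULL, seed = NULL) {
  manifest <- list(
    tool = "paircall",
    version = as.character(utils::packageVersion("paircall")),
    seed = seed,
    config = config,
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    counts = as.list(counts))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' One-call somatic pipeline from files on disk
#'
#' Reads pileups and a pair manifest, runs [run_paired_panel()], and writes
#' the calls (TSV and VCF), the retained set, and a run manifest into
#' `out_dir`.
#'
#' @param pileup_path pileup TSV.
#' @param pairs_path pair manifest TSV.
#' @param out_dir output directory.
#' @param cfg a [call_config()].
#' @param phenotype optional phenotype restriction.
#' @return invisibly, the [run_paired_panel()] result.
#' @export
run_call_somatic <- function(pileup_path, pairs_path, out_dir,
                             cfg = call_config(), phenotype = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pileups <- read_pileups(pileup_path)
  pairs <- read_pair_manifest(pairs_path)
  res <- run_paired_panel(pileups, pairs, cfg, phenotype = phenotype)
  write_calls_tsv(res$calls, file.path(out_dir, "somatic_calls.tsv"))
  write_calls_tsv(res$retained, file.path(out_dir, "somatic_retained.tsv"))
  write_calls_vcf(res$calls, file.path(out_dir, "somatic_calls.vcf"))
  write_run_manifest(file.path(out_dir, "run_manifest.json"),
                     config = unclass(cfg),
                     inputs = c(pileup_path, pairs_path),
                     counts = res$log)
  invisible(res)
}

#' Germ-line calling pipeline from files on disk
#'
#' @param pileup_path pileup TSV.
#' @param out_dir output directory.
#' @param cfg a [call_config()].
#' @return invisibly, the calls data.frame.
#' @export
run_call_germline <- function(pileup_path, out_dir, cfg = call_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pileups <- read_pileups(pileup_path)
  calls <- call_germline(pileups, cfg)
  write_calls_tsv(calls, file.path(out_dir, "germline_calls.tsv"))
  write_run_manifest(file.path(out_dir, "run_manifest.json"),
                     config = unclass(cfg), inputs = pileup_path,
                     counts = c(n_calls = nrow(calls)))
  invisible(calls)
}

#' Simulation pipeline: generate a reference and paired pileups on disk
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @return invisibly, the simulation result (plus `genome`/`tm`).
#' @export
run_simulate <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(cfg)
  sim <- inject_and_pileup(cfg, ref$genome, ref$tm)
  paths <- write_simulation(sim, out_dir)
  write_genome_fasta(ref$genome, file.path(out_dir, "genome.fa"))
  write_transcript_models(list(ref$tm), file.path(out_dir, "transcripts.tsv"))
  write_run_manifest(file.path(out_dir, "run_manifest.json"),
                     config = unclass(cfg), inputs = unname(paths),
                     counts = c(n_germline = nrow(sim$truth$germline),
                                n_somatic = nrow(sim$truth$somatic)),
                     seed = cfg$seed)
  invisible(c(sim, ref))
}

#' Annotation pipeline from files on disk
#'
#' @param calls_path calls TSV (from the calling pipelines).
#' @param genome_path reference FASTA.
#' @param transcripts_path transcript spec TSV.
#' @param out_dir output directory.
#' @param catalog_paths optional character vector of catalog TSVs.
#' @param damage_path optional damage-label TSV.
#' @return invisibly, the annotated calls.
#' @export
run_annotate <- function(calls_path, genome_path, transcripts_path, out_dir,
                         catalog_paths = NULL, damage_path = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- read_calls_tsv(calls_path)
  g <- read_genome_fasta(genome_path)
  tms <- read_transcript_models(transcripts_path)
  catalogs <- if (length(catalog_paths)) lapply(catalog_paths, read_catalog)
  labels <- if (!is.null(damage_path)) read_damage_labels(damage_path)
  ann <- annotate_calls(calls, tms[[1L]], g, catalogs = catalogs,
                        damage_labels = labels)
  write_calls_tsv(ann, file.path(out_dir, "annotated_calls.tsv"))
  write_run_manifest(file.path(out_dir, "run_manifest.json"),
                     inputs = c(calls_path, genome_path, transcripts_path,
                                catalog_paths, damage_path),
                     counts = c(n_calls = nrow(ann)))
  invisible(ann)
}

#' Summary pipeline: tally classes/flags of an annotated panel on disk
#'
#' @param annotated_path annotated calls TSV.
#' @param out_dir output directory.
#' @return invisibly, the `panel_summary`.
#' @export
run_summarize <- function(annotated_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- read_calls_tsv(annotated_path)
  s <- tally_classes(ann)
  jsonlite::write_json(unclass(s), file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(s)
}
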