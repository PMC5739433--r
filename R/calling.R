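#' Calling thresholds for germ-line and paired somatic designation
#'
#' Defaults reproduce the thresholds used in paired-lens amplicon surveys:
#' an allele is "present" in a sample at VAF >= 1% (with a small supporting
#' read floor guarding degenerate low-depth sites), germ-line designation at
#' VAF >= 20%, and somatic retention at VAF >= 3% with depth >= 600 reads.
#' All boundaries are inclusive on the stated side.
#'
#' @param presence_vaf_percent VAF floor (percent) for an allele to count as
#'   present in a sample during paired comparison.
#' @param germline_vaf_percent germ-line designation threshold (percent).
#' @param somatic_min_vaf_percent somatic retention VAF floor (percent).
#' @param min_depth somatic retention depth floor (reads).
#' @param het_range_percent closed VAF interval called heterozygous; above it
#'   a germ-line call is labeled homozygous.
#' @param min_alt_reads minimum supporting reads for presence.
#' @param somatic_fisher_alpha if non-`NULL`, a somatic designation must also
#'   reject the two-sided exact test comparing alt/ref counts between the two
#'   samples at this level (a count-level analogue of a somatic-caller
#'   significance gate).
#' @return A `call_config` list.
#' @export
call_config <- function(presence_vaf_percent = 1.0,
                        germline_vaf_percent = 20.0,
                        somatic_min_vaf_percent = 3.0,
                        min_depth = 600L,
                        het_range_percent = c(20, 80),
                        min_alt_reads = 4L,
                        somatic_fisher_alpha = NULL) {
  stopifnot(presence_vaf_percent > 0,
            presence_vaf_percent < somatic_min_vaf_percent ||
              isTRUE(all.equal(presence_vaf_percent, somatic_min_vaf_percent)),
            somatic_min_vaf_percent <= germline_vaf_percent,
            germline_vaf_percent <= 100,
            min_depth >= 0, min_alt_reads >= 0,
            length(het_range_percent) == 2,
            het_range_percent[1] <= het_range_percent[2])
  if (!is.null(somatic_fisher_alpha)) {
    stopifnot(somatic_fisher_alpha > 0, somatic_fisher_alpha < 1)
  }
  structure(list(presence_vaf_percent = presence_vaf_percent,
                 germline_vaf_percent = germline_vaf_percent,
                 somatic_min_vaf_percent = somatic_min_vaf_percent,
                 min_depth = as.integer(min_depth),
                 het_range_percent = as.numeric(het_range_percent),
                 min_alt_reads = as.integer(min_alt_reads),
                 somatic_fisher_alpha = somatic_fisher_alpha),
            class = "call_config")
}

BASES <- c("A", "C", "G", "T")

#' Variant allele frequency as a percentage
#'
#' VAF = 100 x (variant-supporting reads) / (total reads at the site).
#'
#' @param alt_count variant-supporting read count.
#' @param depth total read depth (> 0).
#' @return VAF in percent; `NA_real_` (with a warning) when depth is zero,
#'   where the VAF is undefined.
#' @examples
#' compute_vaf(30, 1000) # 3
#' @export
compute_vaf <- function(alt_count, depth) {
  stopifnot(all(alt_count >= 0), all(alt_count <= depth | depth == 0))
  out <- ifelse(depth > 0, 100 * alt_count / depth, NA_real_)
  if (anyNA(out)) warning("VAF undefined at zero-depth site(s)")
  out
}

#' Read per-site allele-count (pileup) tables
#'
#' Tab-delimited with columns `sample_id`, `contig`, `pos` (1-based), `ref`,
#' `depth`, `count_A`, `count_C`, `count_G`, `count_T`. The sum of the four
#' base counts may be below `depth` (N or other calls).
#'
#' @param path pileup TSV path.
#' @return data.frame with columns `sample_id, contig, pos, ref, depth, A, C,
#'   G, T`.
#' @export
read_pileups <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "contig", "pos", "ref", "depth",
            paste0("count_", BASES))
  if (!all(need %in% names(df))) {
    stop("pileup file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  out <- df[c("sample_id", "contig", "pos", "ref", "depth")]
  for (b in BASES) out[[b]] <- as.integer(df[[paste0("count_", b)]])
  validate_pileups(out)
}

#' Write pileup tables in the package's TSV layout
#' @param pu pileup data.frame as returned by [read_pileups()].
#' @param path output path.
#' @export
write_pileups <- function(pu, path) {
  out <- pu[c("sample_id", "contig", "pos", "ref", "depth")]
  for (b in BASES) out[[paste0("count_", b)]] <- pu[[b]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

validate_pileups <- function(pu) {
  stopifnot(all(pu$ref %in% BASES), all(pu$depth >= 0))
  cnt <- as.matrix(pu[BASES])
  if (any(cnt < 0)) stop("negative allele count")
  if (any(rowSums(cnt) > pu$depth)) {
    stop("allele counts exceed depth at some site(s)")
  }
  pu
}

#' Read a left/right pair manifest
#'
#' Tab-delimited columns `pair_id`, `left_sample`, `right_sample`,
#' `phenotype`.
#'
#' @param path manifest TSV path.
#' @return data.frame of pairs.
#' @export
read_pair_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pair_id", "left_sample", "right_sample", "phenotype")
  if (!all(need %in% names(df))) {
    stop("pair manifest missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$left_sample == df$right_sample)) {
    stop("a pair lists the same sample on both sides")
  }
  df[need]
}

empty_calls <- function() {
  data.frame(sample_id = character(), pair_id = character(),
             contig = character(), pos = integer(), ref = character(),
             alt = character(), alt_count = integer(), depth = integer(),
             vaf_percent = numeric(), origin = character(),
             genotype = character(), side = character(),
             filter = character(), stringsAsFactors = FALSE)
}

order_calls <- function(calls) {
  calls[order(calls$contig, calls$pos, calls$alt), , drop = FALSE]
}

#' Call germ-line variants from pileup rows by VAF threshold
#'
#' One call is emitted per non-reference allele whose VAF meets the
#' germ-line threshold. Calls within the heterozygous VAF interval are
#' labeled `het`, above it `hom`.
#'
#' @param pileups pileup data.frame (one or more samples/sites).
#' @param cfg a [call_config()].
#' @return calls data.frame sorted by (contig, pos, alt); zero rows when no
#'   allele qualifies.
#' @export
call_germline <- function(pileups, cfg = call_config()) {
  validate_pileups(pileups)
  rows <- lapply(seq_len(nrow(pileups)), function(i) {
    site <- pileups[i, ]
    alts <- setdiff(BASES, site$ref)
    counts <- unlist(site[alts])
    keep <- site$depth > 0 &
      100 * counts / max(site$depth, 1L) >= cfg$germline_vaf_percent
    if (!any(keep)) return(NULL)
    vaf <- 100 * counts[keep] / site$depth
    data.frame(sample_id = site$sample_id, pair_id = NA_character_,
               contig = site$contig, pos = site$pos, ref = site$ref,
               alt = alts[keep], alt_count = as.integer(counts[keep]),
               depth = site$depth, vaf_percent = vaf, origin = "germline",
               genotype = ifelse(vaf <= cfg$het_range_percent[2],
                                 "het", "hom"),
               side = NA_character_, filter = "PASS",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(list(empty_calls()), rows))
  rownames(out) <- NULL
  order_calls(out)
}

.present <- function(count, depth, cfg) {
  depth > 0 & count >= cfg$min_alt_reads &
    100 * count / pmax(depth, 1L) >= cfg$presence_vaf_percent
}

#' Designate alleles by paired discordance between two samples
#'
#' For each non-reference allele at each shared site, the allele is
#' "present" in a sample when its VAF and supporting-read count clear the
#' presence floors. Presence in exactly one member of the pair designates
#' the allele somatic (the call carries that sample's counts); presence in
#' both designates it germ-line; in neither, absent. With
#' `somatic_fisher_alpha` set, a somatic designation must additionally
#' reject the two-sided exact test on the alt/ref counts of the two samples.
#'
#' @param left,right pileup data.frames for the two samples; sites are
#'   matched on (contig, pos) and must agree on the reference base.
#' @param cfg a [call_config()].
#' @param pair_id identifier copied onto the calls.
#' @param include_absent emit rows for absent designations too (default
#'   drops them).
#' @return calls data.frame with `origin` in somatic/germline (and absent if
#'   requested) and `side` in left/right/both.
#' @export
call_paired_discordant <- function(left, right, cfg = call_config(),
                                   pair_id = NA_character_,
                                   include_absent = FALSE) {
  validate_pileups(left); validate_pileups(right)
  key_l <- paste(left$contig, left$pos)
  key_r <- paste(right$contig, right$pos)
  common <- intersect(key_l, key_r)
  if (length(common) == 0L) return(empty_calls())
  li <- match(common, key_l)
  ri <- match(common, key_r)
  if (any(left$ref[li] != right$ref[ri])) {
    stop("left and right pileups disagree on the reference base")
  }
  rows <- lapply(seq_along(common), function(k) {
    L <- left[li[k], ]; R <- right[ri[k], ]
    alts <- setdiff(BASES, L$ref)
    cl <- unlist(L[alts]); cr <- unlist(R[alts])
    pl <- .present(cl, L$depth, cfg)
    pr <- .present(cr, R$depth, cfg)
    origin <- ifelse(pl & pr, "germline",
                     ifelse(pl | pr, "somatic", "absent"))
    if (!is.null(cfg$somatic_fisher_alpha)) {
      for (j in which(origin == "somatic")) {
        p <- fisher_exact_2x2(matrix(c(cl[j], L$depth - cl[j],
                                       cr[j], R$depth - cr[j]),
                                     nrow = 2, byrow = TRUE))
        if (p >= cfg$somatic_fisher_alpha) origin[j] <- "absent"
      }
    }
    keep <- if (include_absent) rep(TRUE, length(alts)) else origin != "absent"
    if (!any(keep)) return(NULL)
    side <- ifelse(origin == "germline", "both",
                   ifelse(origin == "absent", NA_character_,
                          ifelse(pl, "left", "right")))
    carrier_is_left <- is.na(side) | side != "right"
    data.frame(sample_id = ifelse(carrier_is_left, L$sample_id, R$sample_id),
               pair_id = pair_id, contig = L$contig, pos = L$pos,
               ref = L$ref, alt = alts,
               alt_count = as.integer(ifelse(carrier_is_left, cl, cr)),
               depth = as.integer(ifelse(carrier_is_left, L$depth, R$depth)),
               vaf_percent = ifelse(carrier_is_left,
                                    100 * cl / pmax(L$depth, 1L),
                                    100 * cr / pmax(R$depth, 1L)),
               origin = origin, genotype = NA_character_, side = side,
               filter = NA_character_, stringsAsFactors = FALSE)[keep, ]
  })
  out <- do.call(rbind, c(list(empty_calls()), rows))
  rownames(out) <- NULL
  order_calls(out)
}

#' Apply somatic retention filters (VAF and depth floors)
#'
#' Sets the `filter` field: `LOW_VAF` when the VAF is below the somatic
#' floor, `LOW_DEPTH` when depth is below the minimum, both (comma-joined)
#' when both fail, `PASS` otherwise. Input order is preserved.
#'
#' @param calls somatic calls data.frame.
#' @param cfg a [call_config()].
#' @return the calls with `filter` filled in.
#' @export
apply_somatic_filters <- function(calls, cfg = call_config()) {
  if (nrow(calls) == 0L) return(calls)
  stopifnot(all(calls$origin == "somatic"))
  low_vaf <- calls$vaf_percent < cfg$somatic_min_vaf_percent
  low_depth <- calls$depth < cfg$min_depth
  status <- character(nrow(calls))
  status[low_vaf & !low_depth] <- "LOW_VAF"
  status[!low_vaf & low_depth] <- "LOW_DEPTH"
  status[low_vaf & low_depth] <- "LOW_VAF,LOW_DEPTH"
  status[!low_vaf & !low_depth] <- "PASS"
  calls$filter <- status
  calls
}

#' Exclude variants recurring across pairs within a panel
#'
#' A variant identity (contig, pos, ref, alt) observed in more than one pair
#' is treated as recurrent (likely artifact or unrecognized germ-line) and
#' all of its occurrences are excluded; retained calls each occur in exactly
#' one pair. Multiple calls of the same identity within one pair count as a
#' single occurrence.
#'
#' @param calls PASS somatic calls data.frame with `pair_id` filled.
#' @return list with `retained` and `excluded` data.frames; excluded rows
#'   have `filter` set to `RECURRENT`.
#' @export
exclude_recurrent <- function(calls) {
  if (nrow(calls) == 0L) {
    return(list(retained = calls, excluded = calls))
  }
  id <- paste(calls$contig, calls$pos, calls$ref, calls$alt)
  pairs_per_id <- tapply(calls$pair_id, id,
                         function(p) length(unique(p)))
  recurrent <- id %in% names(pairs_per_id)[pairs_per_id > 1L]
  excluded <- calls[recurrent, , drop = FALSE]
  if (nrow(excluded)) excluded$filter <- "RECURRENT"
  list(retained = calls[!recurrent, , drop = FALSE], excluded = excluded)
}

#' Fraction of pileup sites at or above a depth threshold
#'
#' @param depths integer vector of site depths (non-empty).
#' @param threshold depth threshold.
#' @return fraction in `[0, 1]`.
#' @examples
#' summarize_coverage(c(1200, 900, 1500, 2000), 1000) # 0.75
#' @export
summarize_coverage <- function(depths, threshold) {
  if (length(depths) == 0L) stop("no sites supplied")
  mean(depths >= threshold)
}
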