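# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own code paths.

# Full-enumeration two-sided exact test for a 2x2 table: sum the
# hypergeometric probabilities of every margin-preserving table whose
# probability does not exceed that of the observed table. Log-space
# arithmetic; the (1 + 1e-7) guard absorbs representation error when two
# tables are equiprobable.
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  lp <- function(x) {
    lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(r1 + r2, c1)
  }
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- exp(lp(xs))
  p_obs <- exp(lp(a))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Brute-force consequence oracle: rebuild the spliced transcript by walking
# the exon chain, substitute the base, translate both full coding sequences
# with a locally defined codon table, and diff the proteins.
CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aas <- strsplit(paste0(
    "FFLLSSSSYYXXCCXW", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

oracle_translate <- function(nt) {
  paste(CODON_TABLE[substring(nt, seq(1, nchar(nt) - 2, 3),
                              seq(3, nchar(nt), 3))], collapse = "")
}

oracle_complement <- function(x) chartr("ACGT", "TGCA", x)

oracle_klass <- function(pos, ref, alt, tm, g, splice_window = 2L) {
  seqc <- unclass(g)[[tm$contig]]
  # own exon walk, transcript orientation
  txpos <- unlist(Map(seq.int, tm$exon_start, tm$exon_end))
  if (tm$strand == "-") txpos <- rev(txpos)
  cds_idx <- which(txpos >= tm$cds_start & txpos <= tm$cds_end)
  i <- match(pos, txpos)
  if (is.na(i)) {
    if (pos >= min(tm$exon_start) && pos <= max(tm$exon_end)) {
      dist <- min(abs(pos - c(tm$exon_start, tm$exon_end)))
      return(if (dist <= splice_window) "splice" else "intronic")
    }
    # flank: side relative to CDS in transcript orientation
    upstream <- if (tm$strand == "+") pos < min(tm$exon_start)
                else pos > max(tm$exon_end)
    return(if (upstream) "UTR5" else "UTR3")
  }
  if (!(i %in% cds_idx)) {
    return(if (i < min(cds_idx)) "UTR5" else "UTR3")
  }
  tx <- substring(seqc, txpos, txpos)
  if (tm$strand == "-") tx <- oracle_complement(tx)
  cds_ref <- tx[cds_idx]
  cds_alt <- cds_ref
  ci <- i - min(cds_idx) + 1L
  cds_alt[ci] <- if (tm$strand == "-") oracle_complement(alt) else alt
  p_ref <- oracle_translate(paste(cds_ref, collapse = ""))
  p_alt <- oracle_translate(paste(cds_alt, collapse = ""))
  ai <- (ci - 1L) %/% 3L + 1L
  aref <- substr(p_ref, ai, ai); aalt <- substr(p_alt, ai, ai)
  if (aref == aalt) "synonymous"
  else if (aalt == "X") "stopgain"
  else if (aref == "X") "stoploss"
  else "missense"
}

# toy fixtures ---------------------------------------------------------

toy_plus <- function() {
  g <- genome(c(chr1 = paste0("AACCGGTTAA", "ATGGAATAG", "CCGGTTAACCG")))
  tm <- transcript_model("TOY", "TX1", "chr1", "+", 11, 19, 11, 19)
  list(g = g, tm = tm)
}

# minus-strand two-exon model whose CDS covers all exonic bases
toy_minus <- function(cds = "ATGGAAGGATTACCCTAG") {
  stopifnot(nchar(cds) == 18)
  chunk1 <- substr(cds, 1, 9); chunk2 <- substr(cds, 10, 18)
  plus <- paste0("AACCGGTTAA", reverse_complement(chunk2), "CCCCCCCCCCC",
                 reverse_complement(chunk1), "TTTTT")
  g <- genome(c(chr1 = plus))
  tm <- transcript_model("TOY2", "TX2", "chr1", "-",
                         c(11, 31), c(19, 39), 11, 39)
  list(g = g, tm = tm)
}

# one pileup row
pileup_row <- function(sample_id, pos, ref, depth, counts,
                       contig = "chr1") {
  cnt <- stats::setNames(c(0L, 0L, 0L, 0L), c("A", "C", "G", "T"))
  cnt[names(counts)] <- as.integer(counts)
  left <- depth - sum(cnt)
  stopifnot(left >= 0)
  cnt[ref] <- cnt[ref] + left
  data.frame(sample_id = sample_id, contig = contig, pos = pos, ref = ref,
             depth = depth, A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
             T = cnt[["T"]], stringsAsFactors = FALSE)
}
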