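#' Reference sequences as a named character vector
#'
#' A genome here is simply a named character vector of uppercase nucleotide
#' strings (alphabet A/C/G/T/N), one element per contig. This is the in-memory
#' form every coordinate and context operation works against; FASTA files are
#' read into it with [read_genome_fasta()].
#'
#' @param sequences named character vector of nucleotide strings.
#' @return A validated `genome` object (named character vector).
#' @examples
#' g <- genome(c(chr1 = "ACGTACGT"))
#' @export
genome <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences)) > 0) {
    stop("contig names must be unique and non-empty")
  }
  sequences <- stats::setNames(toupper(as.character(sequences)),
                               names(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    stop("contig ", names(sequences)[bad][1],
         " contains characters outside A/C/G/T/N")
  }
  structure(sequences, class = "genome")
}

#' Read a (multi-contig, line-wrapped) FASTA file into a genome
#'
#' @param path path to an uncompressed or gzipped FASTA file.
#' @return A `genome` object.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  # drop description after first whitespace, as aligners do
  names(ss) <- sub("\\s.*$", "", names(ss))
  genome(stats::setNames(as.character(ss), names(ss)))
}

#' Write a genome to FASTA
#'
#' @param g a `genome` object.
#' @param path output path.
#' @export
write_genome_fasta <- function(g, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(unclass(g)), path)
}

contig_seq <- function(g, contig) {
  if (!contig %in% names(g)) stop("unknown contig: ", contig)
  unclass(g)[[contig]]
}

#' Single-transcript gene model with strand-aware CDS structure
#'
#' All coordinates are 1-based, closed intervals on the plus strand of the
#' contig. Exons must be non-overlapping and sorted by genomic start; the CDS
#' endpoints must fall inside exons and the CDS length must be a positive
#' multiple of three (start plus at least one codon plus stop). Only one
#' transcript per gene is modeled: the analysis annotates against a single
#' RefSeq-style transcript, as is usual for targeted gene panels.
#'
#' @param gene gene symbol.
#' @param tx_id transcript identifier (e.g. an NM_ accession).
#' @param contig contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end integer vectors of exon endpoints (1-based,
#'   closed), parallel and sorted by `exon_start`.
#' @param cds_start,cds_end genomic endpoints of the CDS
#'   (`cds_start <= cds_end` regardless of strand).
#' @return A `transcript_model` object.
#' @examples
#' tm <- transcript_model("TOY", "TX1", "chr1", "+", 11, 19, 11, 19)
#' @export
transcript_model <- function(gene, tx_id, contig, strand,
                             exon_start, exon_end, cds_start, cds_end) {
  strand <- match.arg(strand, c("+", "-"))
  exon_start <- as.integer(exon_start)
  exon_end <- as.integer(exon_end)
  if (length(exon_start) != length(exon_end) || length(exon_start) == 0) {
    stop("exon_start and exon_end must be non-empty parallel vectors")
  }
  if (any(exon_end < exon_start)) stop("exon end before exon start")
  if (is.unsorted(exon_start, strictly = TRUE)) {
    stop("exons must be sorted by genomic start")
  }
  if (length(exon_start) > 1 &&
      any(exon_start[-1] <= exon_end[-length(exon_end)])) {
    stop("exons must not overlap")
  }
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start > cds_end) stop("cds_start must be <= cds_end")
  in_exon <- function(p) any(p >= exon_start & p <= exon_end)
  if (!in_exon(cds_start) || !in_exon(cds_end)) {
    stop("CDS endpoints must fall inside exons")
  }
  tm <- structure(
    list(gene = gene, tx_id = tx_id, contig = contig, strand = strand,
         exon_start = exon_start, exon_end = exon_end,
         cds_start = cds_start, cds_end = cds_end),
    class = "transcript_model")
  L <- length(.cds_genomic(tm))
  if (L %% 3L != 0L || L < 6L) {
    stop("CDS length must be a multiple of 3 and at least 6 (got ", L, ")")
  }
  tm
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), CDS %d..%d (%d nt)\n",
              x$gene, x$tx_id, x$contig, x$strand, length(x$exon_start),
              x$cds_start, x$cds_end, length(.cds_genomic(x))))
  invisible(x)
}

# Exonic genomic positions in transcript (5'->3') orientation.
.exonic_genomic <- function(tm) {
  pos <- unlist(mapply(seq.int, tm$exon_start, tm$exon_end, SIMPLIFY = FALSE),
                use.names = FALSE)
  if (tm$strand == "-") rev(pos) else pos
}

# Genomic positions of CDS bases, transcript orientation; element i is the
# genomic position of CDS base c.i.
.cds_genomic <- function(tm) {
  ex <- .exonic_genomic(tm)
  ex[ex >= tm$cds_start & ex <= tm$cds_end]
}

#' Map a genomic position to a CDS/HGVS-c coordinate
#'
#' Walks the exon chain in transcript orientation, so that on minus-strand
#' models increasing genomic position maps to decreasing CDS position.
#' Intronic positions carry an HGVS-style signed offset from the nearest
#' exonic CDS base in transcript orientation (positive past a donor,
#' negative before an acceptor). Exonic non-coding positions and flanking
#' positions outside the exon span are classified `UTR5` / `UTR3` by their
#' side of the CDS in transcript orientation, anchored to the first/last
#' CDS base with a signed offset (HGVS `c.-k` / `c.*k` counting). A
#' position on a contig the model does not live on is `intergenic`.
#'
#' @param pos 1-based genomic position on `tm$contig`.
#' @param tm a [transcript_model()].
#' @param contig optional contig name of `pos`; when given and different
#'   from the model's contig the result is `intergenic`.
#' @return A list of class `cds_coordinate` with fields `cds_pos`,
#'   `intron_offset` and `region` (one of CDS, UTR5, UTR3, intron,
#'   intergenic).
#' @examples
#' tm <- transcript_model("TOY", "TX1", "chr1", "+", 11, 19, 11, 19)
#' genomic_to_cds(11, tm) # c.1
#' @export
genomic_to_cds <- function(pos, tm, contig = NULL) {
  pos <- as.integer(pos)
  stopifnot(length(pos) == 1L, !is.na(pos))
  out <- function(cds_pos, offset, region) {
    structure(list(cds_pos = cds_pos, intron_offset = offset, region = region),
              class = "cds_coordinate")
  }
  if (!is.null(contig) && contig != tm$contig) {
    return(out(NA_integer_, 0L, "intergenic"))
  }
  ex <- .exonic_genomic(tm)      # transcript orientation
  cdsg <- .cds_genomic(tm)
  L <- length(cdsg)
  c1 <- match(cdsg[1L], ex)      # transcript index of first CDS base
  c2 <- match(cdsg[L], ex)
  # transcript-orientation comparison: is a before b along the transcript?
  before <- if (tm$strand == "+") `<` else `>`
  utr_out <- function(ti) {
    if (ti < c1) out(1L, as.integer(ti - c1), "UTR5")
    else out(L, as.integer(ti - c2), "UTR3")
  }
  exonic_idx <- match(pos, ex)
  if (!is.na(exonic_idx)) {
    ci <- match(pos, cdsg)
    if (!is.na(ci)) return(out(ci, 0L, "CDS"))
    return(utr_out(exonic_idx))
  }
  if (pos < min(tm$exon_start) || pos > max(tm$exon_end)) {
    # flanking position: extend the transcript index past the span
    ti <- if (before(pos, if (tm$strand == "+") min(tm$exon_start)
                     else max(tm$exon_end))) {
      d <- if (tm$strand == "+") min(tm$exon_start) - pos
           else pos - max(tm$exon_end)
      1L - d
    } else {
      d <- if (tm$strand == "+") pos - max(tm$exon_end)
           else min(tm$exon_start) - pos
      length(ex) + d
    }
    return(utr_out(ti))
  }
  # intronic: nearest exonic base in genomic distance; sign of the offset
  # follows transcript orientation relative to that anchor
  d_dn <- pos - tm$exon_end[tm$exon_end < pos]    # distance past exon ends
  d_up <- tm$exon_start[tm$exon_start > pos] - pos
  prev_end <- if (length(d_dn)) max(tm$exon_end[tm$exon_end < pos]) else NA
  next_start <- if (length(d_up)) min(tm$exon_start[tm$exon_start > pos]) else NA
  d_prev <- pos - prev_end
  d_next <- next_start - pos
  anchor <- if (d_prev <= d_next) prev_end else next_start
  dist <- min(d_prev, d_next)
  # signed offset in transcript orientation: +dist if pos lies after the
  # anchor along the transcript, -dist if before
  offset <- if (before(anchor, pos)) dist else -dist
  ci <- match(anchor, cdsg)
  if (is.na(ci)) {
    # anchor exonic base is UTR; still an intron, anchored to the nearest
    # CDS base for reporting
    ci <- if (before(anchor, cdsg[1L])) 1L else L
  }
  out(ci, as.integer(offset), "intron")
}

#' @export
print.cds_coordinate <- function(x, ...) {
  cat(sprintf("<cds_coordinate> region=%s cds_pos=%s offset=%+d\n",
              x$region, x$cds_pos, x$intron_offset))
  invisible(x)
}

#' Map a CDS coordinate back to a genomic position
#'
#' Inverse of [genomic_to_cds()] on exonic CDS positions; intron offsets are
#' honored by stepping away from the anchor base against or along the genome
#' according to strand.
#'
#' @param cds_pos CDS position (1-based) or a `cds_coordinate`.
#' @param tm a [transcript_model()].
#' @param intron_offset signed HGVS intron offset (ignored when `cds_pos` is
#'   a `cds_coordinate`).
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(cds_pos, tm, intron_offset = 0L) {
  if (inherits(cds_pos, "cds_coordinate")) {
    intron_offset <- cds_pos$intron_offset
    cds_pos <- cds_pos$cds_pos
  }
  cds_pos <- as.integer(cds_pos)
  cdsg <- .cds_genomic(tm)
  if (is.na(cds_pos) || cds_pos < 1L || cds_pos > length(cdsg)) {
    stop("cds_pos out of range 1..", length(cdsg))
  }
  anchor <- cdsg[cds_pos]
  if (intron_offset == 0L) return(anchor)
  step <- if (tm$strand == "+") intron_offset else -intron_offset
  anchor + step
}

#' Extract the codon containing a CDS position
#'
#' @param cds_pos 1-based CDS position.
#' @param tm a [transcript_model()].
#' @param g a [genome()].
#' @return list with `codon` (3-mer in transcript orientation, i.e. already
#'   reverse-complemented for minus-strand models) and `frame_index`
#'   (0..2, position of `cds_pos` within its codon).
#' @export
codon_at <- function(cds_pos, tm, g) {
  cds_pos <- as.integer(cds_pos)
  cdsg <- .cds_genomic(tm)
  if (cds_pos < 1L || cds_pos > length(cdsg)) {
    stop("cds_pos out of range 1..", length(cdsg))
  }
  frame <- (cds_pos - 1L) %% 3L
  idx <- (cds_pos - frame):(cds_pos - frame + 2L)
  seqc <- contig_seq(g, tm$contig)
  bases <- substring(seqc, cdsg[idx], cdsg[idx])
  if (any(!nzchar(bases))) stop("codon spans positions missing from contig")
  if (tm$strand == "-") bases <- .complement(bases)
  list(codon = paste(bases, collapse = ""), frame_index = frame)
}

#' Plus-strand sequence context around a position
#'
#' @param pos 1-based genomic position.
#' @param g a [genome()].
#' @param contig contig name.
#' @param flank number of bases to each side (>= 1); the window is clipped at
#'   contig ends.
#' @return Plus-strand window string whose center base (when not clipped on
#'   the left) is the genome base at `pos`.
#' @export
seq_context <- function(pos, g, contig, flank = 1L) {
  stopifnot(flank >= 1L)
  seqc <- contig_seq(g, contig)
  n <- nchar(seqc)
  if (pos < 1L || pos > n) stop("position ", pos, " off contig ", contig)
  substr(seqc, max(1L, pos - flank), min(n, pos + flank))
}

.complement <- function(b) {
  chartr("ACGTN", "TGCAN", b)
}

#' Reverse-complement a nucleotide string
#' @param s nucleotide string (A/C/G/T/N).
#' @return reverse complement string.
#' @export
reverse_complement <- function(s) {
  paste(rev(strsplit(.complement(s), "")[[1L]]), collapse = "")
}

#' Spliced CDS sequence of a transcript model, transcript orientation
#' @param tm a [transcript_model()].
#' @param g a [genome()].
#' @return the CDS nucleotide string (starts with the start codon).
#' @export
cds_sequence <- function(tm, g) {
  cdsg <- .cds_genomic(tm)
  seqc <- contig_seq(g, tm$contig)
  bases <- substring(seqc, cdsg, cdsg)
  if (tm$strand == "-") bases <- .complement(bases)
  paste(bases, collapse = "")
}

#' Translate a coding nucleotide sequence with the standard code
#'
#' Stop codons translate to `X` (the single-letter convention used in the
#' amplicon-panel literature for nonsense changes, e.g. `p.E914X`).
#'
#' @param nt coding nucleotide string, length a multiple of 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(nt) {
  stopifnot(nchar(nt) %% 3 == 0)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE,
                                           if.fuzzy.codon = "X"))
  gsub("\\*", "X", aa)
}

#' Read transcript models from a tab-delimited spec
#'
#' Columns: `gene`, `transcript_id`, `contig`, `strand`, `exon_starts`
#' (comma list), `exon_ends` (comma list), `cds_start`, `cds_end`; all
#' coordinates 1-based, closed.
#'
#' @param path path to the TSV file.
#' @return named list of [transcript_model()] objects keyed by gene symbol.
#' @export
read_transcript_models <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "transcript_id", "contig", "strand",
            "exon_starts", "exon_ends", "cds_start", "cds_end")
  if (!all(need %in% names(df))) {
    stop("transcript spec missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  split_ints <- function(s) as.integer(strsplit(s, ",")[[1L]])
  out <- lapply(seq_len(nrow(df)), function(i) {
    transcript_model(df$gene[i], df$transcript_id[i], df$contig[i],
                     df$strand[i], split_ints(df$exon_starts[i]),
                     split_ints(df$exon_ends[i]),
                     df$cds_start[i], df$cds_end[i])
  })
  stats::setNames(out, df$gene)
}

#' Write transcript models to the tab-delimited spec format
#' @param tms named list of [transcript_model()] objects.
#' @param path output path.
#' @export
write_transcript_models <- function(tms, path) {
  df <- do.call(rbind, lapply(tms, function(tm) {
    data.frame(gene = tm$gene, transcript_id = tm$tx_id, contig = tm$contig,
               strand = tm$strand,
               exon_starts = paste(tm$exon_start, collapse = ","),
               exon_ends = paste(tm$exon_end, collapse = ","),
               cds_start = tm$cds_start, cds_end = tm$cds_end,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read transcript models from BED12
#'
#' BED12 is 0-based half-open; rows are converted to the package's 1-based
#' closed convention at this boundary.
#'
#' @param path BED12 file; column 4 is taken as `gene|transcript_id` or the
#'   gene symbol alone.
#' @return named list of [transcript_model()] objects.
#' @export
read_bed12 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("BED12 requires 12 columns, got ", ncol(df))
  out <- lapply(seq_len(nrow(df)), function(i) {
    chrom_start <- as.integer(df[i, 2])
    name <- strsplit(df[i, 4], "|", fixed = TRUE)[[1L]]
    sizes <- as.integer(strsplit(sub(",$", "", df[i, 11]), ",")[[1L]])
    offs <- as.integer(strsplit(sub(",$", "", df[i, 12]), ",")[[1L]])
    exon_start <- chrom_start + offs + 1L
    exon_end <- exon_start + sizes - 1L
    transcript_model(
      gene = name[1L],
      tx_id = if (length(name) > 1L) name[2L] else name[1L],
      contig = df[i, 1], strand = df[i, 6],
      exon_start = exon_start, exon_end = exon_end,
      cds_start = as.integer(df[i, 7]) + 1L,
      cds_end = as.integer(df[i, 8]))
  })
  stats::setNames(out, vapply(out, function(tm) tm$gene, ""))
}
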