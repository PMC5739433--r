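PURINES <- c("A", "G")
PYRIMIDINES <- c("C", "T")

#' Classify a substitution as transition or transversion
#'
#' Transitions exchange bases within a chemical class (A<->G, C<->T);
#' transversions cross classes.
#'
#' @param ref,alt single bases in A/C/G/T, `ref != alt`. Vectorized.
#' @return character vector of `"transition"` / `"transversion"`.
#' @examples
#' classify_substitution("C", "T") # transition
#' classify_substitution("C", "G") # transversion
#' @export
classify_substitution <- function(ref, alt) {
  if (any(!(ref %in% BASES)) || any(!(alt %in% BASES))) {
    stop("ref and alt must be A/C/G/T")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  same_class <- (ref %in% PURINES) == (alt %in% PURINES)
  ifelse(same_class, "transition", "transversion")
}

#' Annotate a single-nucleotide substitution against a transcript model
#'
#' Maps the genomic position to a CDS coordinate; for minus-strand models
#' the coding ref/alt are the complements of the plus-strand pair. Coding
#' positions are translated before and after substitution to classify the
#' change (synonymous, missense, stopgain, stoploss) and to emit HGVS-style
#' `c.` and `p.` names (`c.4G>A`, `p.E2K`; stops written `X`). Intronic
#' positions within the splice window of an exon boundary are classified
#' `splice` with offset notation (`c.1682+1G>A`); other intronic positions
#' are `intronic`; exonic non-coding positions are `UTR5`/`UTR3`; positions
#' outside the transcript span are `intergenic`.
#'
#' @param contig,pos,ref,alt plus-strand description of the substitution.
#' @param tm a [transcript_model()].
#' @param g a [genome()].
#' @param splice_window intron offsets (absolute value) treated as splice
#'   sites; default 2 captures donor/acceptor dinucleotides.
#' @return list of class `consequence`: `klass`, `hgvs_c`, `hgvs_p`,
#'   `aa_ref`, `aa_alt`, `aa_pos`, `cds_pos`, `intron_offset`,
#'   `coding_ref`, `coding_alt`.
#' @export
annotate_variant <- function(contig, pos, ref, alt, tm, g,
                             splice_window = 2L) {
  stopifnot(ref %in% BASES, alt %in% BASES, ref != alt)
  if (contig != tm$contig) {
    return(.consequence("intergenic"))
  }
  genome_ref <- substr(contig_seq(g, contig), pos, pos)
  if (nzchar(genome_ref) && genome_ref != ref) {
    stop("ref allele ", ref, " does not match genome base ", genome_ref,
         " at ", contig, ":", pos)
  }
  cc <- genomic_to_cds(pos, tm)
  minus <- tm$strand == "-"
  cref <- if (minus) .complement(ref) else ref
  calt <- if (minus) .complement(alt) else alt
  if (cc$region == "intergenic") return(.consequence("intergenic"))
  if (cc$region %in% c("UTR5", "UTR3")) {
    hgvs_c <- sprintf("c.%s%d%s>%s",
                      if (cc$region == "UTR5") "-" else "*",
                      abs(cc$intron_offset), cref, calt)
    return(.consequence(cc$region, hgvs_c = hgvs_c, cds_pos = cc$cds_pos,
                        intron_offset = cc$intron_offset,
                        coding_ref = cref, coding_alt = calt))
  }
  if (cc$region == "intron") {
    off <- cc$intron_offset
    hgvs_c <- sprintf("c.%d%s%d%s>%s", cc$cds_pos,
                      if (off > 0) "+" else "-", abs(off), cref, calt)
    klass <- if (abs(off) <= splice_window) "splice" else "intronic"
    return(.consequence(klass, hgvs_c = hgvs_c, cds_pos = cc$cds_pos,
                        intron_offset = off,
                        coding_ref = cref, coding_alt = calt))
  }
  # coding
  cd <- codon_at(cc$cds_pos, tm, g)
  codon_ref <- cd$codon
  codon_alt <- codon_ref
  substr(codon_alt, cd$frame_index + 1L, cd$frame_index + 1L) <- calt
  stopifnot(substr(codon_ref, cd$frame_index + 1L,
                   cd$frame_index + 1L) == cref)
  aa_ref <- translate_cds(codon_ref)
  aa_alt <- translate_cds(codon_alt)
  aa_pos <- (cc$cds_pos - 1L) %/% 3L + 1L
  klass <- if (aa_ref == aa_alt) "synonymous"
           else if (aa_alt == "X") "stopgain"
           else if (aa_ref == "X") "stoploss"
           else "missense"
  .consequence(klass,
               hgvs_c = sprintf("c.%d%s>%s", cc$cds_pos, cref, calt),
               hgvs_p = sprintf("p.%s%d%s", aa_ref, aa_pos, aa_alt),
               aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos,
               cds_pos = cc$cds_pos, intron_offset = 0L,
               coding_ref = cref, coding_alt = calt)
}

.consequence <- function(klass, hgvs_c = NA_character_,
                         hgvs_p = NA_character_, aa_ref = NA_character_,
                         aa_alt = NA_character_, aa_pos = NA_integer_,
                         cds_pos = NA_integer_, intron_offset = 0L,
                         coding_ref = NA_character_,
                         coding_alt = NA_character_) {
  structure(list(klass = klass, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
                 aa_ref = aa_ref, aa_alt = aa_alt, aa_pos = aa_pos,
                 cds_pos = cds_pos, intron_offset = as.integer(intron_offset),
                 coding_ref = coding_ref, coding_alt = coding_alt),
            class = "consequence")
}

#' Parse printed HGVS c./p. strings into a consequence
#'
#' Understands the dialects used in annotated amplicon-panel variant tables:
#' `c.G2740T` (ANNOVAR ref-pos-alt order), `c.2162G>A`, splice offsets
#' `c.1682+1G>A`, 3'-UTR positions `c.*20C>T`, 5'-UTR `c.-12G>A`; protein
#' names `p.E914X`, `p.P72R` (may be empty for non-coding classes). The
#' class is derived from the strings alone: UTR star/minus prefix, splice
#' offset, otherwise synonymous / stopgain / stoploss / missense from the
#' amino-acid pair.
#'
#' @param hgvs_c coding-DNA change string (required).
#' @param hgvs_p protein change string or `NA`/empty.
#' @return a `consequence` list (fields not recoverable from the strings are
#'   `NA`).
#' @examples
#' parse_hgvs("c.G2740T", "p.E914X")$klass # stopgain
#' parse_hgvs("c.*3C>T")$klass             # UTR3
#' @export
parse_hgvs <- function(hgvs_c, hgvs_p = NA_character_) {
  stopifnot(length(hgvs_c) == 1L)
  s <- sub("^c\\.", "", hgvs_c)
  if (identical(s, hgvs_c)) stop("not a c. string: '", hgvs_c, "'")
  aa <- .parse_hgvs_p(hgvs_p)
  # UTR positions: c.*20C>T / c.-12G>A
  m <- regmatches(s, regexec("^([*-])([0-9]+)([ACGT])>([ACGT])$", s))[[1L]]
  if (length(m)) {
    return(.consequence(if (m[2] == "*") "UTR3" else "UTR5",
                        hgvs_c = hgvs_c,
                        coding_ref = m[4], coding_alt = m[5]))
  }
  # splice/intronic offsets: c.1682+1G>A
  m <- regmatches(s, regexec("^([0-9]+)([+-])([0-9]+)([ACGT])>([ACGT])$",
                             s))[[1L]]
  if (length(m)) {
    off <- as.integer(m[4]) * if (m[3] == "+") 1L else -1L
    return(.consequence(if (abs(off) <= 2L) "splice" else "intronic",
                        hgvs_c = hgvs_c, cds_pos = as.integer(m[2]),
                        intron_offset = off,
                        coding_ref = m[5], coding_alt = m[6]))
  }
  # coding: c.2162G>A or ANNOVAR c.G2740T
  m <- regmatches(s, regexec("^([0-9]+)([ACGT])>([ACGT])$", s))[[1L]]
  if (length(m)) {
    cds_pos <- as.integer(m[2]); cref <- m[3]; calt <- m[4]
  } else {
    m <- regmatches(s, regexec("^([ACGT])([0-9]+)([ACGT])$", s))[[1L]]
    if (!length(m)) stop("unparseable c. token: '", hgvs_c, "'")
    cref <- m[2]; cds_pos <- as.integer(m[3]); calt <- m[4]
  }
  klass <- if (is.na(aa$ref)) "missense"
           else if (aa$ref == aa$alt) "synonymous"
           else if (aa$alt == "X") "stopgain"
           else if (aa$ref == "X") "stoploss"
           else "missense"
  .consequence(klass, hgvs_c = hgvs_c,
               hgvs_p = if (is.na(aa$ref)) NA_character_ else hgvs_p,
               aa_ref = aa$ref, aa_alt = aa$alt, aa_pos = aa$pos,
               cds_pos = cds_pos, coding_ref = cref, coding_alt = calt)
}

.parse_hgvs_p <- function(hgvs_p) {
  if (is.null(hgvs_p) || length(hgvs_p) == 0L || is.na(hgvs_p) ||
      !nzchar(hgvs_p)) {
    return(list(ref = NA_character_, alt = NA_character_, pos = NA_integer_))
  }
  s <- sub("^p\\.", "", hgvs_p)
  m <- regmatches(s, regexec("^([A-Z*])([0-9]+)([A-Z*])$", s))[[1L]]
  if (!length(m)) stop("unparseable p. token: '", hgvs_p, "'")
  norm <- function(a) if (a == "*") "X" else a
  list(ref = norm(m[2]), alt = norm(m[4]), pos = as.integer(m[3]))
}

#' Di-pyrimidine context and UV-signature flags for a substitution
#'
#' The pyrimidine strand is the strand on which the reference base is C or T
#' (for plus-strand purine refs the event is expressed on the minus strand
#' with complemented alleles). The site is a di-pyrimidine when at least one
#' immediately adjacent base on that strand (5' or 3') is also a pyrimidine
#' -- the substrate for UV photodimers. The UV-signature flag marks
#' di-pyrimidine sites whose pyrimidine-strand change is C>T. An `N`
#' neighbor disqualifies the flag (conservative).
#'
#' @param contig,pos,ref,alt plus-strand description of the substitution.
#' @param g a [genome()].
#' @return list of class `context_flags`: `substitution_class`,
#'   `dipyrimidine`, `uv_signature`, `pyrimidine_strand`.
#' @examples
#' g <- genome(c(chr1 = "TCG"))
#' dipyrimidine_flags("chr1", 2, "C", "T", g)$uv_signature # TRUE
#' @export
dipyrimidine_flags <- function(contig, pos, ref, alt, g) {
  stopifnot(ref %in% BASES, alt %in% BASES, ref != alt)
  seqc <- contig_seq(g, contig)
  n <- nchar(seqc)
  left <- if (pos > 1L) substr(seqc, pos - 1L, pos - 1L) else ""
  right <- if (pos < n) substr(seqc, pos + 1L, pos + 1L) else ""
  if (ref %in% PYRIMIDINES) {
    pyr_strand <- "+"
    neigh_is_pyr <- c(left, right) %in% PYRIMIDINES
    change_ct <- ref == "C" && alt == "T"
  } else {
    pyr_strand <- "-"
    # a minus-strand pyrimidine sits opposite a plus-strand purine
    neigh_is_pyr <- c(left, right) %in% PURINES
    change_ct <- ref == "G" && alt == "A"
  }
  dipy <- any(neigh_is_pyr)
  structure(list(substitution_class = classify_substitution(ref, alt),
                 dipyrimidine = dipy,
                 uv_signature = dipy && change_ct,
                 pyrimidine_strand = pyr_strand),
            class = "context_flags")
}

#' Read a local known-variant catalog
#'
#' Tab-delimited columns `contig`, `pos`, `ref`, `alt`, `id`, `source` and
#' optionally `af`. Several files may be combined with `rbind`.
#'
#' @param path catalog TSV path.
#' @return data.frame of catalog records.
#' @export
read_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "id", "source")
  if (!all(need %in% names(df))) {
    stop("catalog missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (!"af" %in% names(df)) df$af <- NA_real_
  df[c(need, "af")]
}

#' Triage variants as novel or reference against catalogs
#'
#' A variant is `reference` when its exact (contig, pos, ref, alt) identity
#' appears in at least one catalog; matching is allele-exact, not
#' position-only. Matched identifiers are concatenated, tagged with their
#' source.
#'
#' @param calls calls data.frame with contig/pos/ref/alt.
#' @param catalogs a catalog data.frame or list of them
#'   (see [read_catalog()]).
#' @return the calls with `novelty` (`novel`/`reference`) and `catalog_ids`
#'   (semicolon-joined `source:id`, `NA` when novel) columns added.
#' @export
lookup_novelty <- function(calls, catalogs) {
  if (is.data.frame(catalogs)) catalogs <- list(catalogs)
  cat_all <- do.call(rbind, catalogs)
  key <- function(df) paste(df$contig, df$pos, df$ref, df$alt)
  ck <- key(cat_all)
  ids <- vapply(key(calls), function(k) {
    hit <- which(ck == k)
    if (!length(hit)) NA_character_
    else paste(paste0(cat_all$source[hit], ":", cat_all$id[hit]),
               collapse = ";")
  }, "", USE.NAMES = FALSE)
  calls$novelty <- ifelse(is.na(ids), "novel", "reference")
  calls$catalog_ids <- ids
  calls
}

#' Read externally computed damage labels (e.g. SIFT / PolyPhen verdicts)
#'
#' Labels are consumed as annotations, never computed. Columns `contig`,
#' `pos`, `ref`, `alt`, `predictor`, `label` and optionally `score`.
#'
#' @param path damage-label TSV path.
#' @return data.frame of labels.
#' @export
read_damage_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("contig", "pos", "ref", "alt", "predictor", "label")
  if (!all(need %in% names(df))) {
    stop("damage-label file missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}

#' Attach an aggregate damage verdict to calls
#'
#' A variant is `damaging` when any provided predictor labels it damaging or
#' probably damaging; `tolerated` when labels exist but none damaging; `NA`
#' without labels.
#'
#' @param calls calls data.frame.
#' @param labels data.frame from [read_damage_labels()].
#' @return calls with a `damage` column added.
#' @export
attach_damage_labels <- function(calls, labels) {
  key <- function(df) paste(df$contig, df$pos, df$ref, df$alt)
  lk <- key(labels)
  damaging_lab <- c("damaging", "probably_damaging", "D", "P")
  calls$damage <- vapply(key(calls), function(k) {
    hit <- labels$label[lk == k]
    if (!length(hit)) NA_character_
    else if (any(hit %in% damaging_lab)) "damaging" else "tolerated"
  }, "", USE.NAMES = FALSE)
  calls
}

#' Annotate a table of calls end to end
#'
#' Convenience wrapper applying [annotate_variant()], [dipyrimidine_flags()]
#' and optionally [lookup_novelty()] / [attach_damage_labels()] to each call
#' row.
#'
#' @param calls calls data.frame (contig, pos, ref, alt, ...).
#' @param tm a [transcript_model()].
#' @param g a [genome()].
#' @param catalogs optional catalog data.frame(s) for novelty triage.
#' @param damage_labels optional damage-label data.frame.
#' @return the calls with `klass`, `hgvs_c`, `hgvs_p`,
#'   `substitution_class`, `dipyrimidine`, `uv_signature` (and `novelty`,
#'   `catalog_ids`, `damage` when inputs given) columns added.
#' @export
annotate_calls <- function(calls, tm, g, catalogs = NULL,
                           damage_labels = NULL) {
  cons <- lapply(seq_len(nrow(calls)), function(i) {
    annotate_variant(calls$contig[i], calls$pos[i], calls$ref[i],
                     calls$alt[i], tm, g)
  })
  flags <- lapply(seq_len(nrow(calls)), function(i) {
    dipyrimidine_flags(calls$contig[i], calls$pos[i], calls$ref[i],
                       calls$alt[i], g)
  })
  chr_or_na <- function(xs, f) {
    if (length(xs) == 0L) character() else
      vapply(xs, function(x) x[[f]], FUN.VALUE = vector(mode = "character",
                                                        length = 1L))
  }
  calls$klass <- chr_or_na(cons, "klass")
  calls$hgvs_c <- chr_or_na(cons, "hgvs_c")
  calls$hgvs_p <- chr_or_na(cons, "hgvs_p")
  calls$substitution_class <- chr_or_na(flags, "substitution_class")
  calls$dipyrimidine <- vapply(flags, `[[`, TRUE, "dipyrimidine")
  calls$uv_signature <- vapply(flags, `[[`, TRUE, "uv_signature")
  if (!is.null(catalogs)) calls <- lookup_novelty(calls, catalogs)
  if (!is.null(damage_labels)) {
    calls <- attach_damage_labels(calls, damage_labels)
  }
  calls
}
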