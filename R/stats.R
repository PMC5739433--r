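#' Panel allele frequency from carrier genotypes
#'
#' AF = (het carriers + 2 x hom carriers) / (2 x diploid individuals).
#' Reported as alternate-allele frequency; folding at 0.5 to a strictly
#' "minor" frequency is a presentation choice left to the caller.
#'
#' @param genotypes data.frame with columns `sample_id` and `genotype`
#'   (`"het"`/`"hom"`), one row per carrier of the variant; zero rows for an
#'   unobserved variant.
#' @param panel data.frame with a `sample_id` column (the cohort), or an
#'   integer giving the cohort size when carrier membership need not be
#'   checked.
#' @return allele frequency in `[0, 1]`.
#' @examples
#' panel_maf(data.frame(sample_id = "S1", genotype = "het"), 225)
#' @export
panel_maf <- function(genotypes, panel) {
  if (is.data.frame(panel)) {
    n <- nrow(panel)
    if (nrow(genotypes) &&
        !all(genotypes$sample_id %in% panel$sample_id)) {
      stop("carrier(s) not in panel")
    }
  } else {
    n <- as.integer(panel)
  }
  if (n <= 0L) stop("panel must contain at least one individual")
  if (nrow(genotypes) == 0L) return(0)
  stopifnot(all(genotypes$genotype %in% c("het", "hom")),
            anyDuplicated(genotypes$sample_id) == 0L)
  (sum(genotypes$genotype == "het") + 2 * sum(genotypes$genotype == "hom")) /
    (2 * n)
}

#' Tally consequence classes and context flags over annotated calls
#'
#' @param annotated data.frame from [annotate_calls()] (columns `klass`,
#'   `substitution_class`, `dipyrimidine`, optionally `uv_signature`,
#'   `novelty`, `damage`, `pair_id`).
#' @return list of class `panel_summary`: `n`, `by_class` (named integer
#'   vector over consequence classes), `by_substitution`, `n_dipyrimidine`,
#'   `n_uv_signature`, `by_novelty`, `n_damaging`, `pairs_with_variant`,
#'   `n_pairs_observed`.
#' @export
tally_classes <- function(annotated) {
  classes <- c("synonymous", "missense", "stopgain", "stoploss", "splice",
               "UTR5", "UTR3", "intronic", "intergenic")
  cnt <- function(col, levels) {
    if (!col %in% names(annotated) || nrow(annotated) == 0L) {
      return(stats::setNames(integer(length(levels)), levels))
    }
    tab <- table(factor(annotated[[col]], levels = levels))
    stats::setNames(as.integer(tab), levels)
  }
  by_class <- cnt("klass", classes)
  if (nrow(annotated) && sum(by_class) != nrow(annotated)) {
    stop("unknown consequence class in input")
  }
  flag_sum <- function(col) {
    if (col %in% names(annotated)) sum(annotated[[col]], na.rm = TRUE)
    else NA_integer_
  }
  structure(list(
    n = nrow(annotated),
    by_class = by_class,
    by_substitution = cnt("substitution_class",
                          c("transition", "transversion")),
    n_dipyrimidine = flag_sum("dipyrimidine"),
    n_uv_signature = flag_sum("uv_signature"),
    by_novelty = cnt("novelty", c("novel", "reference")),
    n_damaging = if ("damage" %in% names(annotated)) {
      sum(annotated$damage == "damaging", na.rm = TRUE)
    } else NA_integer_,
    pairs_with_variant = if ("pair_id" %in% names(annotated)) {
      length(unique(annotated$pair_id[!is.na(annotated$pair_id)]))
    } else NA_integer_
  ), class = "panel_summary")
}

#' @export
print.panel_summary <- function(x, ...) {
  cat("<panel_summary>", x$n, "variant(s)\n")
  nz <- x$by_class[x$by_class > 0]
  if (length(nz)) {
    cat("  classes:", paste(names(nz), nz, sep = "=", collapse = " "), "\n")
  }
  cat("  substitutions:",
      paste(names(x$by_substitution), x$by_substitution,
            sep = "=", collapse = " "), "\n")
  if (!is.na(x$n_dipyrimidine)) {
    cat("  di-pyrimidine:", x$n_dipyrimidine, "\n")
  }
  invisible(x)
}

as_2x2 <- function(t) {
  m <- if (is.matrix(t)) t else matrix(as.numeric(t), nrow = 2, byrow = TRUE)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0) || any(m != round(m))) {
    stop("2x2 cells must be non-negative integers")
  }
  if (sum(m) == 0) stop("all-zero 2x2 table")
  m
}

#' Two-sided Fisher's exact test p-value for a 2x2 table
#'
#' Two-sided by the standard rule: the sum, over all tables with the
#' observed margins, of hypergeometric probabilities no larger than that of
#' the observed table.
#'
#' @param t 2x2 matrix or length-4 vector `(a, b, c, d)` row-wise.
#' @return the two-sided p-value in `(0, 1]`.
#' @examples
#' fisher_exact_2x2(c(2, 0, 0, 2)) # 1/3
#' @export
fisher_exact_2x2 <- function(t) {
  m <- as_2x2(t)
  stats::fisher.test(m, alternative = "two.sided")$p.value
}

#' Pearson chi-square test for a 2x2 table
#'
#' No continuity correction by default (set `correct = TRUE` for Yates).
#'
#' @param t 2x2 matrix or length-4 vector row-wise.
#' @param correct apply Yates continuity correction.
#' @return list with `statistic` and `p`.
#' @examples
#' chi_square_2x2(c(20, 10, 10, 20))
#' @export
chi_square_2x2 <- function(t, correct = FALSE) {
  m <- as_2x2(t)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square requires all margins > 0")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p = unname(ht$p.value))
}

#' Compare two panels on a summary metric with Fisher's exact test
#'
#' Builds a 2x2 table from two panel summaries under an explicit
#' construction and returns the exact-test p-value. Constructions:
#' `pairs_with_variant` tabulates pairs with / without at least one
#' qualifying variant against panel membership (requires `n_pairs`);
#' `variant_counts` tabulates qualifying variant counts against the number
#' of pairs surveyed (a count-versus-exposure table).
#'
#' @param a,b `panel_summary` objects (see [tally_classes()]).
#' @param n_pairs_a,n_pairs_b total pairs surveyed in each panel.
#' @param metric `"total"`, `"damaging"` or `"novel"`.
#' @param construction `"pairs_with_variant"` (default) or
#'   `"variant_counts"`.
#' @return list with `table` (2x2 matrix) and `p`.
#' @export
compare_panels <- function(a, b, n_pairs_a, n_pairs_b,
                           metric = c("total", "damaging", "novel"),
                           construction = c("pairs_with_variant",
                                            "variant_counts")) {
  metric <- match.arg(metric)
  construction <- match.arg(construction)
  pick <- function(s) {
    v <- switch(metric,
                total = s$n,
                damaging = s$n_damaging,
                novel = unname(s$by_novelty["novel"]))
    if (is.na(v)) stop("metric '", metric, "' unavailable in panel summary")
    v
  }
  if (construction == "pairs_with_variant") {
    wa <- a$pairs_with_variant; wb <- b$pairs_with_variant
    if (is.na(wa) || is.na(wb)) {
      stop("pairs_with_variant construction needs pair ids in the summaries")
    }
    if (metric != "total") {
      stop("pairs_with_variant construction is defined for metric 'total'; ",
           "use variant_counts for class-restricted metrics")
    }
    tab <- matrix(c(wa, n_pairs_a - wa, wb, n_pairs_b - wb),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(panel = c("a", "b"),
                                  pairs = c("with", "without")))
  } else {
    tab <- matrix(c(pick(a), n_pairs_a, pick(b), n_pairs_b),
                  nrow = 2, byrow = TRUE,
                  dimnames = list(panel = c("a", "b"),
                                  count = c("variants", "pairs")))
  }
  list(table = tab, p = fisher_exact_2x2(tab))
}

#' Genomic positions present in both of two variant sets
#'
#' @param a,b data.frames with `contig` and `pos` columns.
#' @return data.frame of the shared (contig, pos) keys.
#' @export
shared_positions <- function(a, b) {
  ka <- unique(paste(a$contig, a$pos))
  kb <- unique(paste(b$contig, b$pos))
  shared <- intersect(ka, kb)
  if (!length(shared)) {
    return(data.frame(contig = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(shared, " ")
  data.frame(contig = vapply(parts, `[`, "", 1L),
             pos = as.integer(vapply(parts, `[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Bonferroni-adjusted p-values alongside raw ones
#'
#' Thin wrapper over [stats::p.adjust()] kept for report symmetry: multiple
#' panel comparisons are corrected with Bonferroni by default and both raw
#' and adjusted values are reported.
#'
#' @param p numeric vector of raw p-values.
#' @param method adjustment method (default `"bonferroni"`).
#' @return data.frame with `p_raw` and `p_adjusted`.
#' @export
adjust_pvalues <- function(p, method = "bonferroni") {
  data.frame(p_raw = p, p_adjusted = stats::p.adjust(p, method = method))
}
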