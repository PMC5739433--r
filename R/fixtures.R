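#' Embedded variant tables from a paired-lens amplicon sequencing study
#'
#' The package ships, as plain TSV under `extdata/`, the published variant
#' tables of a targeted-amplicon deep-sequencing survey of EPHA2 and TP53
#' coding SNVs in an age-related cataract case-control panel and a paired
#' post-mortem lens panel. They serve as desk-scale regression fixtures:
#' their printed HGVS names, alleles, depths, VAFs, di-pyrimidine footnotes
#' and carrier tallies can be re-parsed and re-tallied with the package's
#' annotation and summary functions.
#'
#' Available tables:
#' \describe{
#'   \item{`epha2_germline_panel`}{EPHA2 germ-line coding SNVs (VAF > 20%)
#'     in the 225-individual case-control panel, with per-phenotype carrier
#'     counts and panel MAFs.}
#'   \item{`tp53_germline_panel`}{TP53 germ-line coding SNVs in the same
#'     panel.}
#'   \item{`epha2_somatic_clear`}{somatic (paired-discordant, VAF >= 3%,
#'     depth >= 600) EPHA2 SNVs from 35 clear lens pairs; `dipyrimidine`
#'     transcribes the printed di-pyrimidine-site flag.}
#'   \item{`epha2_somatic_cataract`}{the corresponding table from 22
#'     cataract lens pairs.}
#' }
#'
#' @param name one of the table names above.
#' @return the table as a data.frame.
#' @examples
#' tab <- study_table("epha2_somatic_cataract")
#' nrow(tab) # 33
#' @export
study_table <- function(name = c("epha2_germline_panel",
                                 "tp53_germline_panel",
                                 "epha2_somatic_clear",
                                 "epha2_somatic_cataract")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "paircall",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  if ("dipyrimidine" %in% names(df)) {
    df$dipyrimidine <- df$dipyrimidine == 1L
  }
  df
}

#' Annotate a somatic study table from its printed strings
#'
#' Re-derives each row's consequence class by parsing the printed HGVS
#' strings with [parse_hgvs()] and the substitution class from the printed
#' plus-strand alleles with [classify_substitution()], and marks novelty
#' from the presence of any catalog identifier. The result is directly
#' consumable by [tally_classes()].
#'
#' @param tab a somatic table from [study_table()].
#' @return the table with `klass`, `substitution_class`, `novelty` and
#'   `damage` columns added.
#' @export
reannotate_study_table <- function(tab) {
  cons <- lapply(seq_len(nrow(tab)), function(i) {
    parse_hgvs(tab$hgvs_c[i], tab$hgvs_p[i])
  })
  tab$klass <- vapply(cons, `[[`, "", "klass")
  tab$substitution_class <- classify_substitution(tab$ref, tab$alt)
  has_id <- !(is.na(tab$cosmic_id) & is.na(tab$dbsnp_id) &
                is.na(tab$exac_af))
  tab$novelty <- ifelse(has_id, "reference", "novel")
  tab$damage <- ifelse(is.na(tab$sift), NA_character_,
                       ifelse(tab$sift == "D", "damaging", "tolerated"))
  tab
}
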