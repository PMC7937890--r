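# Published reference values shipped with the package (plain-text inputs for
# the cut-off reconstruction).

#' Published per-replicate 95% CI lower limits
#'
#' The per-biological-replicate 95% confidence-interval lower limits of the
#' fold-enrichment and PV score distributions from the original KT2440
#' RAP-Seq experiments (the retained replicates: three for RsmA and RsmE, two
#' for RsmI), together with the cut-off values the study established from
#' them. Feeding the limits to [select_cutoffs()] reproduces the published
#' cut-offs.
#'
#' @return data.frame with columns `protein`, `replicate`, `fe_ci_lower`,
#'   `pv_ci_lower`, `fe_cutoff_published`, `pv_cutoff_published`.
#' @export
reference_ci_limits <- function() {
  path <- system.file("extdata", "reference_ci_limits.tsv",
                      package = "rsmtargets", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reproduce the published cut-offs from the reference CI limits
#'
#' @return named list of [select_cutoffs()] results, one per protein.
#' @export
reference_cutoffs <- function() {
  ref <- reference_ci_limits()
  out <- lapply(split(ref, ref$protein), function(d) {
    select_cutoffs(d$fe_ci_lower, d$pv_ci_lower, d$protein[1])
  })
  out[unique(ref$protein)]
}
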