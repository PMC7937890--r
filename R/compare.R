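# Regulon comparison across the three Rsm proteins: Venn partition of the
# target sets, exclusivity fractions, recovery scoring against planted truth,
# and the competitive-colonization fitness index.

#' Venn partition of three target sets
#'
#' Exact counts of the 7 disjoint membership classes, per-set sizes, the
#' union size and per-set exclusive fractions. Inclusion-exclusion identities
#' hold exactly by construction.
#'
#' @param sets named list of three character vectors (locus identifiers).
#' @return object of class `venn_summary`: list with `set_sizes`,
#'   `class_counts` (named by the [venn_design()] class keys when the sets
#'   are named RsmA/RsmE/RsmI, else by membership patterns), `union_size`,
#'   `exclusive_counts` and `exclusive_fraction_pct` (1 decimal).
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3)
  if (is.null(names(sets))) names(sets) <- c("RsmA", "RsmE", "RsmI")
  sets <- lapply(sets, unique)
  all_ids <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1L) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  pattern <- apply(member, 1, function(m) paste(which(m), collapse = ""))
  key <- c("1" = "A", "2" = "E", "3" = "I", "12" = "AE", "13" = "AI",
           "23" = "EI", "123" = "AEI")
  counts <- stats::setNames(integer(7), VENN_CLASSES)
  tab <- table(pattern)
  counts[key[names(tab)]] <- as.integer(tab)
  sizes <- vapply(sets, length, 0L)
  excl <- counts[c("A", "E", "I")]
  names(excl) <- names(sets)
  structure(list(
    set_sizes = sizes,
    class_counts = counts,
    union_size = length(all_ids),
    exclusive_counts = excl,
    exclusive_fraction_pct = ifelse(sizes > 0,
                                    round(100 * excl / sizes, 1), NA_real_)),
    class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat("venn_summary: sizes",
      paste(names(x$set_sizes), x$set_sizes, sep = "=", collapse = " "),
      "| union", x$union_size, "\n classes:",
      paste(names(x$class_counts), x$class_counts, sep = "=", collapse = " "),
      "\n")
  invisible(x)
}

#' Exclusive target fractions per protein
#'
#' Fraction of each protein's targets bound by no other protein, as a percent
#' rounded to 1 decimal; absent (NA) for an empty set.
#'
#' @param venn a [venn_partition()] result.
#' @return named numeric vector of percents.
#' @export
exclusivity_fractions <- function(venn) {
  stopifnot(inherits(venn, "venn_summary"))
  venn$exclusive_fraction_pct
}

#' Recovery of planted targets by the called target sets
#'
#' Per protein: true positives are called loci that are planted; an ambiguous
#' call counts as correct when either candidate locus is planted (set
#' `strict = TRUE` to require the chosen locus). Repeat copies can be mapped
#' onto their family unit with `locus_map` so that calls and truth share a
#' namespace. Precision is undefined (NA) for an empty call set; TP + FN
#' always equals the planted count.
#'
#' @param called named list (per protein) of either character vectors of loci
#'   or data.frames with `locus` and optionally `alt_locus`.
#' @param truth a [plant_targets()] result or a named list of planted locus
#'   vectors.
#' @param locus_map optional named character vector renaming called loci
#'   (e.g. repeat copy -> family).
#' @param strict ignore `alt_locus` candidates.
#' @return data.frame with one row per protein: `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @export
recovery_metrics <- function(called, truth, locus_map = NULL, strict = FALSE) {
  planted <- if (inherits(truth, "synthetic_truth")) truth_sets(truth) else truth
  stopifnot(all(names(called) %in% names(planted)))
  remap <- function(x) {
    if (is.null(locus_map)) return(x)
    hit <- x %in% names(locus_map)
    x[hit] <- locus_map[x[hit]]
    x
  }
  rows <- lapply(names(called), function(p) {
    truth_p <- unique(planted[[p]])
    cl <- called[[p]]
    if (is.data.frame(cl)) {
      main <- remap(cl$locus)
      alt <- if (!strict && "alt_locus" %in% names(cl)) remap(cl$alt_locus)
             else rep(NA_character_, length(main))
    } else {
      main <- remap(cl); alt <- rep(NA_character_, length(main))
    }
    correct <- main %in% truth_p | (!is.na(alt) & alt %in% truth_p)
    recovered <- unique(c(main[main %in% truth_p],
                          alt[!is.na(alt) & alt %in% truth_p]))
    tp <- length(recovered)
    fp <- sum(!correct)
    fn <- length(truth_p) - tp
    precision <- if (length(main)) tp / (tp + fp) else NA_real_
    recall <- if (length(truth_p)) tp / length(truth_p) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(protein = p, n_called = length(main), n_planted = length(truth_p),
               tp = tp, fp = fp, fn = fn,
               precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Competitive colonization fitness index
#'
#' Ratio-of-ratios statistic for a 1:1 competition assay:
#' `(pct_wt_in / pct_mut_in) / (pct_wt_out / pct_mut_out)`, i.e. the inverse
#' of the output wild-type:mutant ratio normalized by the inoculum ratio.
#' A value of 1 indicates equal colonization capacity; the index is invariant
#' to rescaling either percentage pair.
#'
#' @param pct_wt_out,pct_mut_out percentages of wild type and mutant
#'   recovered after colonization.
#' @param pct_wt_in,pct_mut_in percentages in the initial inoculum.
#' @return the fitness index.
#' @export
competition_index <- function(pct_wt_out, pct_mut_out, pct_wt_in, pct_mut_in) {
  vals <- c(pct_wt_out, pct_mut_out, pct_wt_in, pct_mut_in)
  if (any(vals <= 0)) stop("all percentages must be > 0 (no recovered cells?)")
  (pct_wt_in / pct_mut_in) / (pct_wt_out / pct_mut_out)
}
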