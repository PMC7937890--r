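# Assignment of enriched regions to RNA molecules. Libraries are unstranded,
# so candidate features are collected from both strands; the summit (position
# of maximal read pile-up) disambiguates divergently transcribed gene pairs.

#' Assign peaks to annotated RNA features
#'
#' Candidates are all features overlapping the peak on either strand. The
#' chosen feature is the one containing the summit if any (summit containment
#' overrides overlap length, the published disambiguation rule for divergent
#' gene pairs), otherwise the feature with maximal overlap length. A tie on
#' overlap length with no summit containment sets the ambiguity flag and
#' reports the runner-up locus. A peak overlapping no feature is intergenic
#' and labelled with its nearest flanking loci.
#'
#' @param targets data.frame of surviving target regions (columns `replicon`,
#'   `start`, `end`, `summit`; any score columns are carried through).
#' @param annotation a [genome_annotation()].
#' @param summit_override if `FALSE`, pure maximal overlap decides even when
#'   a feature contains the summit.
#' @param co_cover_frac,co_min_overlap a non-chosen candidate is reported as
#'   a co-assigned locus when the peak covers at least `co_cover_frac` of its
#'   length and at least `co_min_overlap` nt of it. Adjacent transcripts that
#'   are both enriched merge into one region whose summit can only name one
#'   of them; a fully covered runner-up is itself made of significant bins,
#'   whereas mere coverage spill past an enriched feature cannot reach beyond
#'   the tag extension length (100 nt by default), so these defaults separate
#'   the two cases. Use [expand_coassigned()] to materialize such loci as
#'   target rows.
#' @return `targets` with added columns `locus` (locus_id or
#'   `intergenic:<left>|<right>` label), `feature_type`, `overlap_len`,
#'   `summit_in_feature`, `ambiguous`, `alt_locus`, `co_loci` (comma-joined),
#'   `shared_placement` (repeat-element copies share their placement with
#'   identical copies).
#' @export
assign_features <- function(targets, annotation, summit_override = TRUE,
                            co_cover_frac = 0.8, co_min_overlap = 150) {
  stopifnot(inherits(annotation, "genome_annotation"))
  targets <- as.data.frame(targets, stringsAsFactors = FALSE)
  n <- nrow(targets)
  locus <- character(n); ftype <- character(n); ovl <- integer(n)
  in_feat <- logical(n); amb <- logical(n); alt <- rep(NA_character_, n)
  shared <- logical(n); co <- character(n)
  feats <- annotation$features
  for (i in seq_len(n)) {
    f <- feats[feats$replicon == targets$replicon[i], , drop = FALSE]
    o <- pmin(f$end, targets$end[i]) - pmax(f$start, targets$start[i])
    cand <- which(o > 0)
    if (!length(cand)) {
      left <- which(f$end <= targets$start[i])
      right <- which(f$start >= targets$end[i])
      lab_l <- if (length(left)) f$locus_id[left[which.max(f$end[left])]] else "NA"
      lab_r <- if (length(right)) f$locus_id[right[which.min(f$start[right])]] else "NA"
      locus[i] <- paste0("intergenic:", lab_l, "|", lab_r)
      ftype[i] <- "intergenic"
      ovl[i] <- 0L
      next
    }
    s <- targets$summit[i]
    contains <- cand[f$start[cand] <= s & f$end[cand] > s]
    pick_from <- if (summit_override && length(contains)) contains else cand
    best <- pick_from[order(-o[pick_from], f$start[pick_from])]
    chosen <- best[1]
    if (!(summit_override && length(contains)) && length(best) > 1 &&
        o[best[2]] == o[best[1]]) {
      amb[i] <- TRUE
      alt[i] <- f$locus_id[best[2]]
    }
    locus[i] <- f$locus_id[chosen]
    ftype[i] <- f$type[chosen]
    ovl[i] <- o[chosen]
    in_feat[i] <- chosen %in% contains
    shared[i] <- f$type[chosen] == "repeat_element"
    flen <- f$end[cand] - f$start[cand]
    co_idx <- cand[o[cand] >= co_cover_frac * flen &
                   o[cand] >= co_min_overlap & cand != chosen]
    co[i] <- paste(f$locus_id[co_idx], collapse = ",")
  }
  targets$locus <- locus
  targets$feature_type <- ftype
  targets$overlap_len <- ovl
  targets$summit_in_feature <- in_feat
  targets$ambiguous <- amb
  targets$alt_locus <- alt
  targets$co_loci <- co
  targets$shared_placement <- shared
  targets
}

#' Materialize co-assigned loci as additional target rows
#'
#' Each locus listed in `co_loci` (see [assign_features()]) becomes its own
#' target row carrying the peak's scores, flagged `coassigned`. Run before
#' [collapse_to_unique()] so that a merged region spanning several enriched
#' transcripts contributes each of them as a target.
#'
#' @param assigned data.frame from [assign_features()].
#' @return `assigned` with the extra rows and a `coassigned` flag column.
#' @export
expand_coassigned <- function(assigned) {
  assigned$coassigned <- logical(nrow(assigned))
  has <- which(nzchar(assigned$co_loci %||% character(nrow(assigned))))
  if (!length(has)) return(assigned)
  extra <- lapply(has, function(i) {
    loci <- strsplit(assigned$co_loci[i], ",", fixed = TRUE)[[1]]
    rows <- assigned[rep(i, length(loci)), , drop = FALSE]
    rows$locus <- loci
    rows$coassigned <- TRUE
    rows
  })
  out <- rbind(assigned, do.call(rbind, extra))
  out <- out[order(out$replicon, out$start, out$locus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse assigned targets to unique RNA molecules
#'
#' Redundancies where the analysis finds more than one peak in a single RNA
#' molecule are discarded: targets are grouped by assigned locus and the peak
#' with the highest PV score is kept per locus (leftmost on ties). The
#' operation is idempotent.
#'
#' @param assigned data.frame from [assign_features()] with a `pv` (or
#'   `pv_score`) column.
#' @return one row per distinct locus, with `n_peaks` giving the number of
#'   collapsed peaks.
#' @export
collapse_to_unique <- function(assigned) {
  assigned <- .as_pv(assigned)
  if (nrow(assigned) == 0L) {
    assigned$n_peaks <- integer()
    return(assigned)
  }
  ord <- order(assigned$locus, -assigned$pv, assigned$start)
  a <- assigned[ord, , drop = FALSE]
  first <- !duplicated(a$locus)
  res <- a[first, , drop = FALSE]
  res$n_peaks <- as.integer(table(a$locus)[res$locus])
  res <- res[order(res$replicon, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.as_pv <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  if (!"pv" %in% names(x) && "pv_score" %in% names(x)) x$pv <- x$pv_score
  stopifnot(all(c("locus", "pv", "start", "replicon") %in% names(x)))
  x
}
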