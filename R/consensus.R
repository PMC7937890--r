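# Replicate logic: technical-replicate consensus peaks, FE/PV score
# distributions, confidence-interval-based cut-off selection, and the
# biological-replicate discard rule.

#' Consensus of peaks across technical replicates
#'
#' A consensus peak exists iff a peak in the first replicate overlaps (by at
#' least 1 nt) a chain of peaks, one per other replicate, all pairwise
#' overlapping (for intervals, pairwise overlap is equivalent to a common
#' intersection point). Matching is greedy left-to-right, each input peak used
#' at most once. The consensus interval is the union of the members; its
#' representative FE and PV are the configured aggregate of the members'
#' (mean by default), and its summit comes from the best-scoring member.
#'
#' @param peak_lists list of >= 2 peak data.frames (as from [call_peaks()] or
#'   previous consensus), each sorted by coordinate and internally
#'   non-overlapping per replicon.
#' @param aggregate `"mean"` or `"median"`.
#' @return data.frame of consensus peaks with columns `replicon`, `start`,
#'   `end`, `summit`, `fe`, `pv`, `n_members`, and per-member `fe_i`/`pv_i`.
#' @export
technical_consensus <- function(peak_lists, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  stopifnot(length(peak_lists) >= 2)
  peak_lists <- lapply(peak_lists, .as_scored_peaks)
  for (pl in peak_lists) .check_sorted_disjoint(pl)
  agg <- if (aggregate == "mean") mean else stats::median
  reps <- unique(unlist(lapply(peak_lists, function(p) unique(p$replicon))))
  out <- list()
  for (r in sort(reps)) {
    sub <- lapply(peak_lists, function(p) p[p$replicon == r, , drop = FALSE])
    if (any(vapply(sub, nrow, 0L) == 0L)) next
    used <- lapply(sub, function(p) logical(nrow(p)))
    first <- sub[[1]]
    for (i in seq_len(nrow(first))) {
      lo <- first$start[i]; hi <- first$end[i]
      picks <- integer(length(sub)); picks[1] <- i
      ok <- TRUE
      for (j in seq_along(sub)[-1]) {
        p <- sub[[j]]
        cand <- which(!used[[j]] & p$start < hi & p$end > lo)
        if (!length(cand)) { ok <- FALSE; break }
        pick <- cand[1]                         # leftmost compatible
        picks[j] <- pick
        lo <- max(lo, p$start[pick]); hi <- min(hi, p$end[pick])
      }
      if (!ok) next
      for (j in seq_along(sub)) used[[j]][picks[j]] <- TRUE
      fe_m <- vapply(seq_along(sub), function(j) sub[[j]]$fe[picks[j]], 0)
      pv_m <- vapply(seq_along(sub), function(j) sub[[j]]$pv[picks[j]], 0)
      su_m <- vapply(seq_along(sub), function(j) sub[[j]]$summit[picks[j]], 0)
      row <- data.frame(
        replicon = r,
        start = min(vapply(seq_along(sub), function(j) sub[[j]]$start[picks[j]], 0)),
        end = max(vapply(seq_along(sub), function(j) sub[[j]]$end[picks[j]], 0)),
        summit = su_m[which.max(pv_m)],
        fe = agg(fe_m), pv = agg(pv_m), n_members = length(sub),
        stringsAsFactors = FALSE)
      for (j in seq_along(sub)) {
        row[[paste0("fe_", j)]] <- fe_m[j]
        row[[paste0("pv_", j)]] <- pv_m[j]
      }
      out[[length(out) + 1L]] <- row
    }
  }
  if (!length(out)) {
    base <- data.frame(replicon = character(), start = integer(),
                       end = integer(), summit = integer(), fe = numeric(),
                       pv = numeric(), n_members = integer(),
                       stringsAsFactors = FALSE)
    for (j in seq_along(peak_lists)) {
      base[[paste0("fe_", j)]] <- numeric()
      base[[paste0("pv_", j)]] <- numeric()
    }
    return(base)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# accept either raw peak tables (pv_score/fold_enrichment) or consensus
# tables (fe/pv)
.as_scored_peaks <- function(p) {
  p <- as.data.frame(p, stringsAsFactors = FALSE)
  if (!"fe" %in% names(p) && "fold_enrichment" %in% names(p)) {
    p$fe <- p$fold_enrichment
  }
  if (!"pv" %in% names(p) && "pv_score" %in% names(p)) p$pv <- p$pv_score
  stopifnot(all(c("replicon", "start", "end", "summit", "fe", "pv") %in% names(p)))
  p
}

.check_sorted_disjoint <- function(p) {
  for (r in unique(p$replicon)) {
    q <- p[p$replicon == r, , drop = FALSE]
    if (is.unsorted(q$start)) stop("peak list is not sorted by coordinate")
    if (nrow(q) > 1 && any(q$start[-1] < q$end[-nrow(q)])) {
      stop("peak list contains overlapping peaks")
    }
  }
  invisible(TRUE)
}

#' FE and PV score distributions of a consensus table
#'
#' Histograms in the published convention: bins labelled by the upper limit
#' of each value interval (upper-limit inclusive), with frequencies and the
#' cumulative percent per bin. Values above the last stated limit fall into a
#' final open-ended bin.
#'
#' @param consensus consensus peak data.frame (columns `fe`, `pv`).
#' @param fe_breaks,pv_breaks increasing bin upper limits.
#' @return list with `fe` and `pv` data.frames (`upper`, `freq`, `cum_pct`),
#'   each carrying a `statistic` attribute.
#' @export
score_distributions <- function(consensus,
                                fe_breaks = seq(1, 10, by = 0.5),
                                pv_breaks = seq(50, 500, by = 25)) {
  if (nrow(consensus) == 0L) stop("no peaks to summarize")
  list(fe = .hist_summary(consensus$fe, fe_breaks, "FE"),
       pv = .hist_summary(consensus$pv, pv_breaks, "PV"))
}

.hist_summary <- function(values, uppers, label) {
  stopifnot(!is.unsorted(uppers))
  edges <- c(-Inf, uppers, Inf)
  freq <- as.integer(table(cut(values, edges, right = TRUE)))
  df <- data.frame(upper = c(uppers, Inf), freq = freq,
                   cum_pct = 100 * cumsum(freq) / length(values))
  attr(df, "statistic") <- label
  df
}

#' Lower limit of the 95% confidence interval of a score distribution
#'
#' Default method is the t-based confidence interval of the mean:
#' `mean - t(1 - alpha/2, n - 1) * s / sqrt(n)` with s the sample standard
#' deviation. A distribution-percentile alternative (`quantile(values,
#' alpha/2)`) is available.
#'
#' @param values numeric vector, length >= 2.
#' @param alpha two-sided confidence level complement (default 0.05).
#' @param method `"t"` or `"percentile"`.
#' @return the lower limit; for zero-variance input, the common value.
#' @export
ci_lower_limit <- function(values, alpha = 0.05, method = c("t", "percentile")) {
  method <- match.arg(method)
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  if (method == "percentile") {
    return(unname(stats::quantile(values, alpha / 2)))
  }
  s <- stats::sd(values)
  if (s == 0) return(values[1])
  mean(values) - stats::qt(1 - alpha / 2, n - 1) * s / sqrt(n)
}

#' Select per-protein FE and PV cut-offs from per-replicate CI limits
#'
#' The FE cut-off is the minimum of the per-replicate FE confidence-interval
#' lower limits, rounded down to the nearest multiple of `fe_step` (0.05);
#' the PV cut-off is the arithmetic mean of the per-replicate PV limits,
#' rounded down to the nearest multiple of `pv_step` (5). This rule
#' reproduces all six published KT2440 cut-offs from the published
#' per-replicate limits; both components are configurable.
#'
#' @param fe_limits,pv_limits per-biological-replicate 95% CI lower limits.
#' @param protein protein name (metadata only).
#' @param fe_step,pv_step rounding grids.
#' @param fe_rule,pv_rule aggregation functions over the replicate limits.
#' @return object of class `cutoff_set` with fields `protein`, `fe_limits`,
#'   `pv_limits`, `fe_cutoff`, `pv_cutoff`.
#' @export
select_cutoffs <- function(fe_limits, pv_limits, protein = "",
                           fe_step = 0.05, pv_step = 5,
                           fe_rule = min, pv_rule = mean) {
  if (!length(fe_limits) || !length(pv_limits)) {
    stop("empty confidence-interval limit list")
  }
  floor_to <- function(x, step) {
    v <- floor(x / step + 1e-9) * step
    round(v, 10)
  }
  structure(list(protein = protein,
                 fe_limits = fe_limits, pv_limits = pv_limits,
                 fe_cutoff = floor_to(fe_rule(fe_limits), fe_step),
                 pv_cutoff = floor_to(pv_rule(pv_limits), pv_step)),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("cutoff_set %s: FE >= %s (limits %s), PV > %s (limits %s)\n",
              x$protein, format(x$fe_cutoff),
              paste(format(x$fe_limits), collapse = "/"),
              format(x$pv_cutoff),
              paste(format(x$pv_limits), collapse = "/")), ...)
  invisible(x)
}

#' Filter targets across biological replicates against cut-offs
#'
#' A target survives iff it is present in every biological replicate table
#' and satisfies `fe >= fe_cutoff` and `pv > pv_cutoff` in every one of them.
#' Pre-annotation, targets are matched across replicates by >= 1 nt interval
#' overlap (the same greedy chain rule as [technical_consensus()]); if every
#' table carries a `locus` column they are matched by locus instead.
#'
#' @param bio_tables list of per-biological-replicate consensus tables.
#' @param cutoffs a [cutoff_set()].
#' @return surviving target table with union interval, best summit and
#'   per-replicate `fe_i`/`pv_i` columns (or per-locus rows when matched by
#'   locus).
#' @export
filter_targets <- function(bio_tables, cutoffs) {
  stopifnot(inherits(cutoffs, "cutoff_set"), length(bio_tables) >= 1)
  bio_tables <- lapply(bio_tables, .as_scored_peaks)
  n <- length(bio_tables)
  by_locus <- all(vapply(bio_tables, function(t) "locus" %in% names(t), TRUE))
  if (by_locus) {
    common <- Reduce(intersect, lapply(bio_tables, function(t) t$locus))
    if (!length(common)) return(.empty_target_table(n))
    rows <- lapply(bio_tables, function(t) t[match(common, t$locus), , drop = FALSE])
    fe <- do.call(cbind, lapply(rows, function(t) t$fe))
    pv <- do.call(cbind, lapply(rows, function(t) t$pv))
    keep <- apply(fe >= cutoffs$fe_cutoff & pv > cutoffs$pv_cutoff, 1, all)
    base <- rows[[1]][keep, c("locus", "replicon", "start", "end", "summit"),
                      drop = FALSE]
    matched <- cbind(base,
                     stats::setNames(as.data.frame(fe[keep, , drop = FALSE]),
                                     paste0("fe_", seq_len(n))),
                     stats::setNames(as.data.frame(pv[keep, , drop = FALSE]),
                                     paste0("pv_", seq_len(n))))
  } else {
    if (n == 1L) {
      m <- bio_tables[[1]]
      m$fe_1 <- m$fe; m$pv_1 <- m$pv
      matched <- m
    } else {
      matched <- technical_consensus(bio_tables, aggregate = "mean")
    }
    fe <- as.matrix(matched[, paste0("fe_", seq_len(n)), drop = FALSE])
    pv <- as.matrix(matched[, paste0("pv_", seq_len(n)), drop = FALSE])
    keep <- if (nrow(matched)) {
      apply(fe >= cutoffs$fe_cutoff & pv > cutoffs$pv_cutoff, 1, all)
    } else logical()
    matched <- matched[keep, , drop = FALSE]
  }
  matched$fe <- rowMeans(as.matrix(
    matched[, paste0("fe_", seq_len(n)), drop = FALSE]))
  matched$pv <- rowMeans(as.matrix(
    matched[, paste0("pv_", seq_len(n)), drop = FALSE]))
  rownames(matched) <- NULL
  matched
}

.empty_target_table <- function(n) {
  df <- data.frame(locus = character(), replicon = character(),
                   start = integer(), end = integer(), summit = integer(),
                   stringsAsFactors = FALSE)
  for (j in seq_len(n)) {
    df[[paste0("fe_", j)]] <- numeric()
    df[[paste0("pv_", j)]] <- numeric()
  }
  df$fe <- numeric(); df$pv <- numeric()
  df
}
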