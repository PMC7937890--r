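# MACS-style enrichment peak calling of a pulldown library against its
# total-RNA control: tag extension, binned coverage, Poisson scoring against a
# local background lambda, candidate-bin merging, and empirical sample-swap
# FDR. All parameters are explicit configuration.

#' Peak-calling parameters
#'
#' @param extension tag extension length d, nt: each tag is extended from its
#'   5' end toward 3' on its strand to this fragment length.
#' @param bin_width coverage bin width, nt.
#' @param p_threshold candidate Poisson p-value threshold; a bin is a
#'   candidate when its PV score exceeds `-10 log10(p_threshold)`.
#' @param lambda_windows window lengths, nt, for the local background rate
#'   (strictly increasing).
#' @param merge_gap candidate bins closer than this are merged into one peak;
#'   defaults to the extension length.
#' @param min_length merged intervals shorter than this are dropped; defaults
#'   to two bins.
#' @return object of class `peak_params`.
#' @export
peak_params <- function(extension = 100L,
                        bin_width = 10L,
                        p_threshold = 1e-5,
                        lambda_windows = c(1000L, 5000L, 10000L),
                        merge_gap = extension,
                        min_length = 2L * bin_width) {
  stopifnot(extension > 0, bin_width > 0,
            p_threshold > 0, p_threshold < 1,
            all(diff(lambda_windows) > 0), all(lambda_windows > 0),
            merge_gap >= 0, min_length > 0)
  structure(list(extension = as.integer(extension),
                 bin_width = as.integer(bin_width),
                 p_threshold = p_threshold,
                 lambda_windows = as.integer(lambda_windows),
                 merge_gap = as.integer(merge_gap),
                 min_length = as.integer(min_length)),
            class = "peak_params")
}

#' Poisson survival-function score
#'
#' `-10 log10 P(X >= k)` for `X ~ Poisson(lambda)`, the PV score convention.
#' Computed in log space, so there is no underflow even for scores of several
#' thousand. Returns 0 for `k = 0` (the tail probability is 1), is strictly
#' increasing in `k` and strictly decreasing in `lambda`.
#'
#' @param k observed count(s), non-negative integers.
#' @param lambda expected count(s), > 0.
#' @return numeric PV score(s), >= 0.
#' @export
poisson_sf_score <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0")
  if (any(k < 0)) stop("k must be >= 0")
  # P(X >= k) = P(X > k - 1); log10 via log.p
  score <- -10 * stats::ppois(k - 1, lambda, lower.tail = FALSE,
                              log.p = TRUE) / log(10)
  score[k == 0] <- 0
  pmax(score, 0)
}

# number of sorted fragments [s, e) overlapping each query interval [qs, qe)
# = #(s < qe) - #(e <= qs); all coordinates integer
.count_overlaps <- function(s_sorted, e_sorted, qs, qe) {
  findInterval(qe - 1L, s_sorted) - findInterval(qs, e_sorted)
}

# extend tags to fragments of length d toward 3' on their strand, clipped to
# the replicon; returns list(start=, end=) sorted copies are made by callers
.extend_tags <- function(pos, strand, d, replicon_length) {
  start <- ifelse(strand == "+", pos, pmax(pos - d + 1L, 0L))
  end <- ifelse(strand == "+", pmin(pos + d, replicon_length), pos + 1L)
  list(start = as.integer(start), end = as.integer(end))
}

#' Local background rate for candidate intervals
#'
#' For each query interval, the expected control fragment count is the
#' maximum of the genome-wide rate, the rate measured on the interval itself,
#' and the rates measured in windows centered on the interval (clipped at
#' replicon edges), each scaled to the interval length and to the treatment
#' library depth. Fragment counts use overlap counting, so an interval of
#' length L collects fragments at a rate proportional to `L + d`. Including
#' the interval's own control rate matters because the control here is a
#' transcriptome, not flat input DNA: without it, any sharply bounded
#' abundant transcript would out-score its window-averaged background.
#'
#' @param control_frags list with sorted `start` and `end` integer vectors of
#'   the control fragments on the replicon.
#' @param qs,qe query interval starts/ends (0-based half-open).
#' @param params a [peak_params()].
#' @param lambda_bg genome-wide control rate for an interval of this length,
#'   already scaled to treatment depth.
#' @param depth_ratio treatment/control total tag count ratio.
#' @param replicon_length replicon length, nt.
#' @return numeric vector of lambda values.
#' @export
local_lambda <- function(control_frags, qs, qe, params, lambda_bg,
                         depth_ratio, replicon_length) {
  d <- params$extension
  ilen <- qe - qs
  lam <- rep_len(lambda_bg, length(qs))
  mid <- (qs + qe) / 2
  cs <- control_frags$start
  ce <- control_frags$end
  # the interval itself as a degenerate window
  lam <- pmax(lam, .count_overlaps(cs, ce, qs, qe) * depth_ratio)
  for (W in params$lambda_windows) {
    ws <- pmax(0, ceiling(mid - W / 2))
    we <- pmin(replicon_length, floor(mid + W / 2))
    cnt <- .count_overlaps(cs, ce, as.integer(ws), as.integer(we))
    lam_w <- cnt * (ilen + d) / (we - ws + d) * depth_ratio
    lam <- pmax(lam, lam_w)
  }
  lam
}

#' Call enrichment peaks in a pulldown library against its control
#'
#' Pipeline: extend each tag to the configured fragment length from its 5'
#' end; count fragments per bin; score each bin's count against the local
#' control lambda with [poisson_sf_score()]; mark bins whose score exceeds
#' `-10 log10(p_threshold)`; merge marked bins separated by at most
#' `merge_gap`; drop merged intervals shorter than `min_length`. For each
#' peak, the summit is the position of maximal treatment fragment coverage
#' (leftmost on ties), `tag_count` the number of treatment fragments
#' overlapping the peak, `pv_score` the score of the summit's bin and
#' `fold_enrichment` the summit bin count over its local lambda. The control
#' is scaled to the treatment depth by the ratio of total tag counts.
#'
#' @param treatment pulldown [tag_library()].
#' @param control total-RNA control [tag_library()].
#' @param params a [peak_params()].
#' @param replicons replicon table (`name`, `length`).
#' @return peak data.frame sorted by coordinate with columns `replicon`,
#'   `start`, `end`, `length`, `summit`, `tag_count`, `pv_score`,
#'   `fold_enrichment`, `fdr_percent` (NA until [empirical_fdr()]).
#' @export
call_peaks <- function(treatment, control, params, replicons) {
  stopifnot(inherits(treatment, "tag_library"), inherits(control, "tag_library"),
            inherits(params, "peak_params"))
  t_rep <- unique(treatment$tags$replicon)
  c_rep <- unique(control$tags$replicon)
  if (length(setdiff(c(t_rep, c_rep), replicons$name))) {
    stop("replicon mismatch between libraries and replicon table")
  }
  n_t <- nrow(treatment$tags)
  n_c <- nrow(control$tags)
  depth_ratio <- n_t / n_c
  G <- sum(replicons$length)
  d <- params$extension
  bw <- params$bin_width
  score_min <- -10 * log10(params$p_threshold)
  out <- list()
  for (i in seq_len(nrow(replicons))) {
    rep_name <- replicons$name[i]
    L <- replicons$length[i]
    tt <- treatment$tags[treatment$tags$replicon == rep_name, , drop = FALSE]
    ct <- control$tags[control$tags$replicon == rep_name, , drop = FALSE]
    if (nrow(tt) == 0L) next
    tf <- .extend_tags(tt$pos, tt$strand, d, L)
    cf <- .extend_tags(ct$pos, ct$strand, d, L)
    tf_s <- sort(tf$start); tf_e <- sort(tf$end)
    cf_s <- sort(cf$start); cf_e <- sort(cf$end)
    bin_starts <- seq.int(0L, L - 1L, by = bw)
    bin_ends <- pmin(bin_starts + bw, L)
    k <- .count_overlaps(tf_s, tf_e, bin_starts, bin_ends)
    lambda_bg <- n_c * (bin_ends - bin_starts + d) / G * depth_ratio
    lam <- local_lambda(list(start = cf_s, end = cf_e), bin_starts, bin_ends,
                        params, lambda_bg, depth_ratio, L)
    score <- poisson_sf_score(k, lam)
    cand <- which(score > score_min)
    if (!length(cand)) next
    # merge candidate bins separated by <= merge_gap
    gap_bins <- floor(params$merge_gap / bw)
    grp <- cumsum(c(1L, diff(cand) > gap_bins + 1L))
    for (g in unique(grp)) {
      bins <- cand[grp == g]
      ps <- bin_starts[bins[1]]
      pe <- bin_ends[bins[length(bins)]]
      if (pe - ps < params$min_length) next
      # treatment pileup inside the peak for the summit (paired fragments)
      inpk <- which(tf$start < pe & tf$end > ps)
      ss <- pmax(tf$start[inpk], ps) - ps
      ee <- pmin(tf$end[inpk], pe) - ps
      add <- tabulate(ss + 1L, nbins = pe - ps + 1L)
      sub <- tabulate(ee + 1L, nbins = pe - ps + 1L)
      cov <- cumsum(add - sub)[seq_len(pe - ps)]
      summit <- ps + which.max(cov) - 1L
      sbin <- which(bin_starts <= summit & bin_ends > summit)[1]
      out[[length(out) + 1L]] <- data.frame(
        replicon = rep_name, start = ps, end = pe, length = pe - ps,
        summit = summit, tag_count = length(inpk),
        pv_score = score[sbin],
        fold_enrichment = k[sbin] / lam[sbin],
        fdr_percent = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(stats::setNames(
      data.frame(character(), integer(), integer(), integer(), integer(),
                 integer(), numeric(), numeric(), numeric(),
                 stringsAsFactors = FALSE),
      PEAK_COLUMNS))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$replicon, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Empirical sample-swap FDR
#'
#' For each forward peak with PV score s, the FDR percent is
#' `100 * #(swapped peaks with score >= s) / #(forward peaks with score >= s)`,
#' capped at 100. The swapped peak list comes from calling peaks with the
#' treatment and control roles exchanged. The raw ratio is then monotonized
#' by a running minimum over ascending scores (step-up style), so the
#' reported FDR is non-increasing in s.
#'
#' @param forward_peaks peak table from the forward comparison.
#' @param swapped_peaks peak table from the swapped comparison.
#' @return `forward_peaks` with `fdr_percent` filled in.
#' @export
empirical_fdr <- function(forward_peaks, swapped_peaks) {
  if (nrow(forward_peaks) == 0L) return(forward_peaks)
  s <- forward_peaks$pv_score
  sw <- sort(swapped_peaks$pv_score)
  fw <- sort(s)
  n_sw <- length(sw) - findInterval(s - 1e-9, sw)   # swapped >= s
  n_fw <- length(fw) - findInterval(s - 1e-9, fw)   # forward >= s
  raw <- pmin(100, 100 * n_sw / n_fw)
  ord <- order(s)
  fdr <- raw
  fdr[ord] <- cummin(raw[ord])
  forward_peaks$fdr_percent <- fdr
  forward_peaks
}
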