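# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (direct summation, exhaustive enumeration,
# row-by-row loops) and share no code with the implementation paths they
# check.

# -10 log10 P(X >= k) by direct log-space summation of Poisson terms,
# accumulated with log-sum-exp until additional terms are negligible
oracle_poisson_score <- function(k, lambda) {
  if (k == 0) return(0)
  j <- k
  log_terms <- c()
  repeat {
    lt <- -lambda + j * log(lambda) - lgamma(j + 1)
    log_terms <- c(log_terms, lt)
    if (lt < max(log_terms) - 80) break
    j <- j + 1
  }
  m <- max(log_terms)
  log_p <- m + log(sum(exp(log_terms - m)))
  -10 * log_p / log(10)
}

# exhaustive greedy chain matching over k peak lists on one replicon:
# leftmost first-list peak, then leftmost unused compatible partner per list,
# compatibility = nonempty common intersection
oracle_consensus_intervals <- function(lists) {
  used <- lapply(lists, function(l) rep(FALSE, nrow(l)))
  out <- list()
  for (i in seq_len(nrow(lists[[1]]))) {
    lo <- lists[[1]]$start[i]; hi <- lists[[1]]$end[i]
    picks <- c(i); ok <- TRUE
    for (j in seq_along(lists)[-1]) {
      found <- FALSE
      for (m in seq_len(nrow(lists[[j]]))) {
        if (!used[[j]][m] && lists[[j]]$start[m] < hi && lists[[j]]$end[m] > lo) {
          picks <- c(picks, m)
          lo <- max(lo, lists[[j]]$start[m]); hi <- min(hi, lists[[j]]$end[m])
          found <- TRUE
          break
        }
      }
      if (!found) { ok <- FALSE; break }
    }
    if (!ok) next
    for (j in seq_along(lists)) used[[j]][picks[j]] <- TRUE
    out[[length(out) + 1L]] <- c(
      start = min(vapply(seq_along(lists), function(j) lists[[j]]$start[picks[j]], 0)),
      end = max(vapply(seq_along(lists), function(j) lists[[j]]$end[picks[j]], 0)))
  }
  do.call(rbind, out)
}

# membership-pattern enumeration
oracle_venn_counts <- function(sets) {
  ids <- unique(unlist(sets))
  counts <- c(A = 0, E = 0, I = 0, AE = 0, AI = 0, EI = 0, AEI = 0)
  keymap <- c("100" = "A", "010" = "E", "001" = "I", "110" = "AE",
              "101" = "AI", "011" = "EI", "111" = "AEI")
  for (id in ids) {
    pat <- paste(as.integer(c(id %in% sets[[1]], id %in% sets[[2]],
                              id %in% sets[[3]])), collapse = "")
    counts[keymap[pat]] <- counts[keymap[pat]] + 1
  }
  counts
}

# per-peak max-overlap / summit-containment assignment
oracle_assign <- function(peak, feats) {
  o <- pmin(feats$end, peak$end) - pmax(feats$start, peak$start)
  cand <- which(o > 0)
  if (!length(cand)) return(NA_character_)
  within <- cand[feats$start[cand] <= peak$summit & feats$end[cand] > peak$summit]
  if (length(within)) {
    within <- within[order(-o[within], feats$start[within])]
    return(feats$locus_id[within[1]])
  }
  cand <- cand[order(-o[cand], feats$start[cand])]
  feats$locus_id[cand[1]]
}

# random sorted non-overlapping peak list on one replicon
random_peak_list <- function(n, span = 10000, replicon = "chr") {
  if (n == 0) {
    return(data.frame(replicon = character(), start = integer(),
                      end = integer(), summit = integer(), fe = numeric(),
                      pv = numeric(), stringsAsFactors = FALSE))
  }
  starts <- sort(sample.int(span - 60, n))
  # enforce disjointness by spacing
  starts <- starts + (seq_len(n) - 1) * 60
  widths <- sample(20:60, n, replace = TRUE)
  data.frame(replicon = replicon, start = starts, end = starts + widths,
             summit = starts + floor(widths / 2),
             fe = round(runif(n, 1, 10), 3), pv = round(runif(n, 10, 400), 2),
             stringsAsFactors = FALSE)
}

# minimal annotation: features at given starts/ends on one replicon
tiny_annotation <- function(starts, ends, strands = NULL, genome_len = 10000,
                            replicon = "chr", types = NULL, names = NULL) {
  n <- length(starts)
  genome_annotation(
    data.frame(name = replicon, length = genome_len),
    data.frame(locus_id = sprintf("G%03d", seq_len(n)),
               type = types %||% rep("coding_gene", n),
               replicon = replicon,
               start = starts, end = ends,
               strand = strands %||% rep("+", n),
               name = names %||% rep(NA_character_, n),
               stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small simulation config used by several tests (fast, single protein runs)
small_sim_config <- function(...) {
  simulation_config(genome_length = 60000, n_coding = 100, n_ncrna = 6,
                    n_repeat_families = 1, repeat_copies = 3,
                    n_pseudogene = 2, n_divergent_pairs = 5,
                    design = venn_design(A = 2, E = 2, I = 2, AE = 1, AI = 1,
                                         EI = 1, AEI = 2),
                    depth_pulldown = 30000, depth_control = 60000,
                    bio_reps = c(RsmA = 2L, RsmE = 2L, RsmI = 2L), ...)
}
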