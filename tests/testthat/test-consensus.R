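test_that("consensus over identical replicates is the identity on intervals and scores", {
  set.seed(5)
  pl <- random_peak_list(12)
  cons <- technical_consensus(list(pl, pl, pl))
  expect_equal(cons$start, pl$start)
  expect_equal(cons$end, pl$end)
  expect_equal(cons$fe, pl$fe)
  expect_equal(cons$pv, pl$pv)
  expect_true(all(cons$n_members == 3L))
})

test_that("a peak missing from one replicate is excluded", {
  pl <- data.frame(replicon = "chr", start = c(100L, 500L), end = c(200L, 600L),
                   summit = c(150L, 550L), fe = c(3, 4), pv = c(80, 90))
  cons <- technical_consensus(list(pl, pl, pl[1, ]))
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100L)
})

test_that("consensus equals the exhaustive greedy oracle on random instances", {
  for (s in 1:20) {
    set.seed(s)
    lists <- lapply(1:3, function(i) random_peak_list(sample(0:20, 1)))
    got <- technical_consensus(lists)
    want <- oracle_consensus_intervals(lists)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, unname(want[, "start"]))
      expect_equal(got$end, unname(want[, "end"]))
    }
    expect_lte(nrow(got), min(vapply(lists, nrow, 0L)))
  }
})

test_that("unsorted or overlapping input is rejected", {
  pl <- random_peak_list(5)
  expect_error(technical_consensus(list(pl[5:1, ], pl)), "sorted")
  bad <- pl; bad$end[1] <- bad$start[2] + 10L
  expect_error(technical_consensus(list(bad, pl)), "overlap")
})

test_that("score distributions use upper-limit-inclusive bins and cumulate to 100", {
  cons <- data.frame(fe = c(2, 3, 4), pv = c(60, 80, 100))
  d <- score_distributions(cons, fe_breaks = c(3, 5), pv_breaks = c(75, 150))
  expect_equal(d$fe$freq, c(2L, 1L, 0L))
  expect_equal(d$fe$cum_pct[length(d$fe$cum_pct)], 100)
  expect_true(all(diff(d$fe$cum_pct) >= 0))
  expect_error(score_distributions(cons[0, ]), "no peaks")

  one <- score_distributions(data.frame(fe = 2.2, pv = 90),
                             fe_breaks = c(1, 3), pv_breaks = c(100))
  expect_equal(sum(one$fe$freq > 0), 1L)
  expect_equal(one$fe$cum_pct[one$fe$freq > 0], 100)

  set.seed(9)
  vals <- runif(200, 0, 12)
  breaks <- seq(1, 10, by = 1.5)
  d2 <- score_distributions(data.frame(fe = vals, pv = vals * 40),
                            fe_breaks = breaks)
  brute <- vapply(seq_along(breaks), function(i) {
    lo <- if (i == 1) -Inf else breaks[i - 1]
    sum(vals > lo & vals <= breaks[i])
  }, 0L)
  expect_equal(d2$fe$freq, c(brute, sum(vals > max(breaks))))
  expect_equal(sum(d2$fe$freq), 200L)
})

test_that("ci_lower_limit matches the textbook t interval", {
  expect_equal(ci_lower_limit(c(4, 4, 4)), 4)
  v <- c(2, 3, 4, 5, 6)
  want <- mean(v) - qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(ci_lower_limit(v), want)
  expect_equal(ci_lower_limit(v + 1.7), want + 1.7)   # translation equivariance
  expect_lte(ci_lower_limit(v), mean(v))
  expect_error(ci_lower_limit(3), "at least 2")
  expect_equal(ci_lower_limit(v, method = "percentile"),
               unname(quantile(v, 0.025)))
})

test_that("cut-off selection reproduces the published values from the published limits", {
  expect_equal(select_cutoffs(c(2.15, 2.33, 2.33), c(130, 135, 128))$fe_cutoff, 2.15)
  expect_equal(select_cutoffs(c(2.68, 2.53), c(153, 137))$fe_cutoff, 2.5)
  expect_equal(select_cutoffs(c(4, 4.22, 4.62), c(180, 150, 181))$pv_cutoff, 170)
  expect_equal(select_cutoffs(c(2.15, 2.33, 2.33), c(130, 135, 128))$pv_cutoff, 130)
  expect_equal(select_cutoffs(c(2.68, 2.53), c(153, 137))$pv_cutoff, 145)
  expect_equal(select_cutoffs(c(4, 4.22, 4.62), c(180, 150, 181))$fe_cutoff, 4)
  # floating-point floor guard: 2.15 / 0.05 must not round down to 2.10
  expect_equal(select_cutoffs(2.15, 100)$fe_cutoff, 2.15)
  expect_error(select_cutoffs(numeric(), 100), "empty")
})

test_that("targets below cut-off in any biological replicate are discarded", {
  cut_a <- select_cutoffs(c(2.15, 2.33, 2.33), c(130, 135, 128), "RsmA")
  cfc <- data.frame(replicon = "chr", start = 100L, end = 300L, summit = 200L,
                    fe = 1.82, pv = 500)
  cfc2 <- cfc; cfc2$fe <- 1.88
  expect_equal(nrow(filter_targets(list(cfc, cfc2), cut_a)), 0L)

  ok <- cfc; ok$fe <- 3.0
  ok2 <- cfc2; ok2$fe <- 2.4
  expect_equal(nrow(filter_targets(list(ok, ok2), cut_a)), 1L)

  low_pv <- ok; low_pv$pv <- 120          # below PV cut-off in one replicate
  expect_equal(nrow(filter_targets(list(low_pv, ok2), cut_a)), 0L)
})

test_that("filtering equals a brute-force row check and is monotone in the cut-offs", {
  set.seed(31)
  for (rep in 1:5) {
    tabs <- lapply(1:2, function(i) random_peak_list(15))
    # force identical intervals so presence/matching is not the limiting factor
    tabs[[2]]$start <- tabs[[1]]$start; tabs[[2]]$end <- tabs[[1]]$end
    tabs[[2]]$summit <- tabs[[1]]$summit
    prev <- Inf
    for (fe_cut in c(2, 4, 6)) {
      co <- select_cutoffs(fe_cut, 100, fe_step = 1e-9, pv_step = 1e-9)
      got <- filter_targets(tabs, co)
      brute <- sum(vapply(seq_len(nrow(tabs[[1]])), function(i) {
        all(vapply(tabs, function(t) t$fe[i] >= co$fe_cutoff &
                                     t$pv[i] > co$pv_cutoff, TRUE))
      }, TRUE))
      expect_equal(nrow(got), brute)
      expect_lte(nrow(got), prev)
      prev <- nrow(got)
    }
  }
  co <- select_cutoffs(1, 10)
  expect_equal(nrow(filter_targets(list(random_peak_list(0),
                                        random_peak_list(0)), co)), 0L)
})
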