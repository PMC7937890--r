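test_that("poisson_sf_score matches the direct-summation oracle and is monotone", {
  ks <- c(0:20, 50, 120, 500)
  lambdas <- c(0.1, 0.5, 1, 2, 5, 10, 50)
  for (lam in lambdas) {
    got <- poisson_sf_score(ks, lam)
    want <- vapply(ks, oracle_poisson_score, 0, lambda = lam)
    expect_equal(got, want, tolerance = 1e-9)
  }
  expect_equal(poisson_sf_score(0, 5), 0)
  expect_gt(poisson_sf_score(6, 5), poisson_sf_score(5, 5))
  expect_gt(poisson_sf_score(10, 2), poisson_sf_score(10, 3))
  # no underflow deep in the tail
  expect_gt(poisson_sf_score(500, 0.1), 3000)
  expect_error(poisson_sf_score(3, 0), "lambda")
})

test_that("local_lambda equals the background under uniform control and obeys the max rule", {
  params <- peak_params()
  L <- 20000L
  # exactly uniform control: one fragment start every 10 nt
  pos <- seq(0L, L - 101L, by = 10L)
  frags <- list(start = pos, end = pos + 100L)
  qs <- c(5000L, 12000L); qe <- qs + 10L
  lam_bg <- 20   # at or above the uniform window rates (~11 per bin)
  lam <- local_lambda(frags, qs, qe, params, lam_bg, 1, L)
  # uniform rate windows never exceed a background set above their rate
  expect_equal(lam, rep(lam_bg, 2))

  # a control spike inside the 1 kb window only
  spike <- sort(c(pos, rep(5100L, 400L)))
  lam_spiked <- local_lambda(list(start = spike, end = spike + 100L),
                             qs, qe, params, 0.1, 1, L)
  expect_gt(lam_spiked[1], lam_spiked[2])
  expect_gt(lam_spiked[1], 0.1)
})

test_that("local_lambda agrees with a brute-force window count", {
  set.seed(21)
  L <- 30000L
  pos <- sort(sample.int(L - 100L, 3000, replace = TRUE)) - 1L
  frags <- list(start = pos, end = pos + 100L)
  params <- peak_params()
  qs <- as.integer(seq(500, L - 600, length.out = 37)); qe <- qs + 10L
  ratio <- 0.6
  got <- local_lambda(frags, qs, qe, params, 1e-9, ratio, L)
  want <- vapply(seq_along(qs), function(i) {
    best <- 1e-9
    # the interval itself
    n_self <- sum(pos < qe[i] & pos + 100L > qs[i])
    best <- max(best, n_self * ratio)
    mid <- (qs[i] + qe[i]) / 2
    for (W in params$lambda_windows) {
      ws <- max(0, ceiling(mid - W / 2)); we <- min(L, floor(mid + W / 2))
      n <- sum(pos < we & pos + 100L > ws)
      best <- max(best, n * (10 + 100) / (we - ws + 100) * ratio)
    }
    best
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
})

make_lib <- function(pos, role, strand = NULL, protein = "RsmA", id = role) {
  n <- length(pos)
  tag_library(id, protein, role, 1, 1,
              data.frame(replicon = "chr", pos = as.integer(pos),
                         strand = strand %||% rep("+", n)))
}

test_that("identical treatment and control yield no peaks", {
  reps <- data.frame(name = "chr", length = 50000)
  params <- peak_params()
  for (s in 1:3) {
    set.seed(s)
    pos <- sample.int(49000, 20000, replace = TRUE) - 1L
    lib_t <- make_lib(pos, "pulldown")
    lib_c <- make_lib(pos, "total_control")
    pk <- call_peaks(lib_t, lib_c, params, reps)
    expect_equal(nrow(pk), 0L)
  }
})

test_that("a planted enriched locus gives one overlapping peak with high FE", {
  cfg <- simulation_config(genome_length = 60000, n_coding = 80, n_ncrna = 0,
                           n_repeat_families = 0, n_pseudogene = 0,
                           n_divergent_pairs = 0,
                           design = venn_design(1, 0, 0, 0, 0, 0, 0),
                           enrichment_range = c(16, 16),
                           depth_pulldown = 30000, depth_control = 60000,
                           bio_reps = c(RsmA = 2L, RsmE = 2L, RsmI = 2L))
  ann <- generate_genome_annotation(cfg, 13)
  tr <- plant_targets(ann, cfg, 13)
  libs <- simulate_tag_libraries(ann, tr, cfg, 13, proteins = "RsmA")
  pk <- call_peaks(libs[[2]], libs[[1]], peak_params(), ann$replicons)
  locus <- truth_sets(tr)$RsmA
  feat <- ann$features[ann$features$locus_id == locus, ]
  hit <- pk$start < feat$end & pk$end > feat$start
  expect_equal(sum(hit), 1L)
  expect_gt(pk$fold_enrichment[hit], 4)
})

test_that("peak structural invariants hold on simulated data", {
  cfg <- small_sim_config()
  ann <- generate_genome_annotation(cfg, 17)
  tr <- plant_targets(ann, cfg, 17)
  libs <- simulate_tag_libraries(ann, tr, cfg, 17, proteins = "RsmE")
  params <- peak_params()
  pk <- call_peaks(libs[[2]], libs[[1]], params, ann$replicons)
  expect_gt(nrow(pk), 0)
  expect_true(all(pk$end - pk$start >= params$min_length))
  expect_true(all(pk$start <= pk$summit & pk$summit < pk$end))
  expect_true(all(diff(pk$start) > 0))
  expect_true(all(pk$start[-1] >= pk$end[-nrow(pk)]))   # non-overlapping
  expect_true(all(is.finite(pk$pv_score)) && all(pk$pv_score >= 0))
  expect_true(all(is.finite(pk$fold_enrichment)) && all(pk$fold_enrichment >= 0))
  # determinism
  pk2 <- call_peaks(libs[[2]], libs[[1]], params, ann$replicons)
  expect_identical(pk, pk2)
})

test_that("duplicating every tag preserves FE and does not lower peak scores", {
  cfg <- small_sim_config()
  ann <- generate_genome_annotation(cfg, 19)
  tr <- plant_targets(ann, cfg, 19)
  libs <- simulate_tag_libraries(ann, tr, cfg, 19, proteins = "RsmA")
  ctrl <- libs[[1]]; pd <- libs[[2]]
  params <- peak_params()
  pk1 <- call_peaks(pd, ctrl, params, ann$replicons)
  double <- function(l) {
    tag_library(l$sample_id, l$protein, l$role, l$bio_rep, l$tech_rep,
                rbind(l$tags, l$tags))
  }
  pk2 <- call_peaks(double(pd), double(ctrl), params, ann$replicons)
  m <- merge(pk1, pk2, by = "summit")
  expect_gt(nrow(m), 0)
  expect_equal(m$fold_enrichment.x, m$fold_enrichment.y, tolerance = 1e-9)
  expect_true(all(m$pv_score.y >= m$pv_score.x - 1e-9))
})

test_that("degenerate inputs are handled", {
  reps <- data.frame(name = "chr", length = 50000)
  one <- make_lib(25000, "pulldown")
  ctrl <- make_lib(seq(0, 49000, by = 50), "total_control")
  expect_equal(nrow(call_peaks(one, ctrl, peak_params(), reps)), 0L)
  other <- tag_library("x", "RsmA", "pulldown", 1, 1,
                       data.frame(replicon = "chrZ", pos = 5L, strand = "+"))
  expect_error(call_peaks(other, ctrl, peak_params(), reps), "replicon")
})

test_that("empirical sample-swap FDR counts score exceedances", {
  fw <- data.frame(replicon = "chr", start = c(0, 100), end = c(50, 150),
                   length = 50L, summit = c(10L, 110L), tag_count = 5L,
                   pv_score = c(100, 50), fold_enrichment = 2,
                   fdr_percent = NA_real_)
  none <- fw[0, ]
  expect_equal(empirical_fdr(fw, none)$fdr_percent, c(0, 0))
  expect_equal(empirical_fdr(fw, fw)$fdr_percent, c(100, 100))
  sw <- fw[1, ]; sw$pv_score <- 60
  expect_equal(empirical_fdr(fw, sw)$fdr_percent, c(0, 50))
  # non-increasing in score
  set.seed(3)
  fw_n <- fw[rep(1, 30), ]; fw_n$pv_score <- runif(30, 10, 300)
  sw_n <- fw[rep(1, 20), ]; sw_n$pv_score <- runif(20, 10, 300)
  got <- empirical_fdr(fw_n, sw_n)
  ord <- order(got$pv_score)
  expect_true(all(diff(got$fdr_percent[ord]) <= 1e-9))
})
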