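test_that("annotation generation is deterministic and honors the requested layout", {
  cfg <- small_sim_config()
  a1 <- generate_genome_annotation(cfg, seed = 3)
  a2 <- generate_genome_annotation(cfg, seed = 3)
  expect_identical(a1, a2)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_annotation(a1, f1); write_annotation(a2, f2)
  expect_identical(readLines(f1), readLines(f2))

  f <- a1$features
  # non-overlapping with gaps
  expect_true(all(f$start[-1] >= f$end[-nrow(f)]))
  # requested divergent (-,+) pairs sharing an upstream gap
  pair_idx <- which(f$strand[-nrow(f)] == "-" & f$strand[-1] == "+" &
                    f$type[-nrow(f)] == "coding_gene" &
                    f$type[-1] == "coding_gene")
  expect_gte(length(pair_idx), cfg$n_divergent_pairs)
  # repeat copies share a family name, >= 3 loci
  rep_f <- f[f$type == "repeat_element", ]
  expect_equal(nrow(rep_f), 3L)
  expect_equal(length(unique(rep_f$name)), 1L)
})

test_that("zero features and capacity overflow are handled", {
  cfg0 <- simulation_config(n_coding = 0, n_ncrna = 0, n_repeat_families = 0,
                            n_pseudogene = 0, n_divergent_pairs = 0,
                            design = venn_design(0, 0, 0, 0, 0, 0, 0))
  a <- generate_genome_annotation(cfg0, 1)
  expect_equal(nrow(a$features), 0L)

  cfg_big <- simulation_config(genome_length = 10000, n_coding = 200,
                               design = venn_design(0, 0, 0, 0, 0, 0, 0))
  expect_error(generate_genome_annotation(cfg_big, 1), "exceeds genome length")
})

test_that("planting reproduces the designed Venn partition exactly", {
  cfg <- small_sim_config()
  ann <- generate_genome_annotation(cfg, 5)

  tr0 <- plant_targets(ann, simulation_config(design = venn_design(0,0,0,0,0,0,0)),
                       seed = 5)
  expect_equal(lengths(truth_sets(tr0)), c(RsmA = 0L, RsmE = 0L, RsmI = 0L))

  for (s in 1:5) {
    tr <- plant_targets(ann, cfg, seed = s)
    sets <- truth_sets(tr)
    expect_equal(oracle_venn_counts(sets), unclass(cfg$design)[names(oracle_venn_counts(sets))])
    vp <- venn_partition(sets)
    expect_equal(unname(vp$class_counts), unname(unclass(cfg$design)))
    expect_true(all(tr$targets[paste0("ef_", c("RsmA","RsmE","RsmI"))] >= 1,
                    na.rm = TRUE))
  }

  infeasible <- small_sim_config()
  infeasible$design <- venn_design(A = 500, E = 0, I = 0, AE = 0, AI = 0,
                                   EI = 0, AEI = 0)
  expect_error(plant_targets(ann, infeasible, 1), "infeasible")
})

test_that("the study-scale reference design has the published arithmetic", {
  d <- reference_venn_design()
  sizes <- design_set_sizes(d)
  expect_equal(unname(sizes), c(241L, 261L, 206L))
  expect_equal(sum(d), 437L)                              # unique transcripts
  expect_equal(unname(d["AEI"]), 75L)                     # common targets
  expect_true(all(d[c("AE", "AI", "EI")] >= 36 & d[c("AE", "AI", "EI")] <= 45))
  expect_equal(sum(d[c("AE", "AI", "EI")]), 121L)
})

test_that("library depths are exact and simulation is seed-deterministic", {
  cfg <- small_sim_config()
  ann <- generate_genome_annotation(cfg, 2)
  tr <- plant_targets(ann, cfg, 2)
  libs1 <- simulate_tag_libraries(ann, tr, cfg, 2, proteins = "RsmA")
  libs2 <- simulate_tag_libraries(ann, tr, cfg, 2, proteins = "RsmA")
  expect_identical(libs1, libs2)
  for (l in libs1) {
    want <- if (l$role == "pulldown") cfg$depth_pulldown else cfg$depth_control
    expect_equal(nrow(l$tags), want)
    expect_true(all(l$tags$pos >= 0 & l$tags$pos < cfg$genome_length))
  }
  # replicate structure: per bio rep one control + tech_reps pulldowns
  roles <- table(vapply(libs1, function(l) l$role, ""))
  expect_equal(unname(roles["total_control"]), 2L)
  expect_equal(unname(roles["pulldown"]), 2L * cfg$tech_reps)
})

test_that("planted enrichment matches the closed-form compositional expectation", {
  # one strongly planted locus; at large depth the normalized pulldown/control
  # ratio at that locus approaches ef / Z with Z the weighted mean enrichment
  cfg <- simulation_config(genome_length = 50000, n_coding = 40, n_ncrna = 0,
                           n_repeat_families = 0, n_pseudogene = 0,
                           n_divergent_pairs = 0,
                           design = venn_design(1, 0, 0, 0, 0, 0, 0),
                           enrichment_range = c(8, 8),
                           background_fraction = 0.05,
                           bio_sdlog = 0,
                           depth_pulldown = 1000000, depth_control = 1000000,
                           bio_reps = c(RsmA = 2L, RsmE = 2L, RsmI = 2L))
  ann <- generate_genome_annotation(cfg, 9)
  tr <- plant_targets(ann, cfg, 9)
  exp_fe <- expected_relative_enrichment(ann, tr, cfg, "RsmA", 9)
  expect_equal(exp_fe$ef, 8, tolerance = 1e-12)
  libs <- simulate_tag_libraries(ann, tr, cfg, 9, proteins = "RsmA")
  ctrl <- libs[[1]]; pd <- libs[[2]]
  locus <- exp_fe$unit_id
  feat <- ann$features[ann$features$locus_id == locus, ]
  n_pd <- sum(pd$tags$pos >= feat$start & pd$tags$pos < feat$end)
  n_ct <- sum(ctrl$tags$pos >= feat$start & ctrl$tags$pos < feat$end)
  ratio <- (n_pd / nrow(pd$tags)) / (n_ct / nrow(ctrl$tags))
  expect_equal(ratio, exp_fe$relative_fe, tolerance = 0.05)
})

test_that("with all enrichment factors 1 pulldown and control expectations agree", {
  cfg <- small_sim_config(enrichment_range = c(1, 1))
  ann <- generate_genome_annotation(cfg, 4)
  tr <- plant_targets(ann, cfg, 4)
  exp_fe <- expected_relative_enrichment(ann, tr, cfg, "RsmA", 4)
  expect_true(all(abs(exp_fe$relative_fe - 1) < 1e-12))
})
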