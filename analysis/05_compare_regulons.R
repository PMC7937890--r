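#!/usr/bin/env Rscript
# Step 5 -- regulon comparison and recovery scoring.
#
# Compares the three called regulons (Venn partition, exclusivity fractions),
# scores them against the planted truth, and reproduces the published
# Venn arithmetic at study scale: sizes 241/261/206 with 75 triple-shared
# targets force 121 targets shared by exactly two proteins.

suppressPackageStartupMessages(library(rsmtargets))
seed <- 101L
out <- "results/compare"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
res <- run_pipeline(pipeline_config(simulation = cfg, seed = seed),
                    "results/pipeline")

print(res$venn)
ex <- exclusivity_fractions(res$venn)
message(sprintf("exclusive fractions: %s",
                paste(names(ex), sprintf("%.1f%%", ex), collapse = ", ")))
message("recovery against planted truth:")
print(res$recovery[, c("protein", "tp", "fp", "fn", "precision", "recall", "f1")])
jsonlite::write_json(list(venn = unclass(res$venn), recovery = res$recovery),
                     file.path(out, "comparison.json"),
                     auto_unbox = TRUE, digits = NA)

# study-scale arithmetic: plant the reference partition and recover it
ref <- reference_venn_design()
cfg_ref <- simulation_config(design = ref, seed = seed)
truth_ref <- plant_targets(generate_genome_annotation(cfg_ref), cfg_ref)
vp <- venn_partition(truth_sets(truth_ref))
stopifnot(identical(unname(vp$set_sizes), c(241L, 261L, 206L)),
          vp$union_size == 437L,
          sum(vp$class_counts[c("AE", "AI", "EI")]) == 121L)
message(sprintf("study-scale partition: sizes %s, union %d, exactly-two total %d",
                paste(vp$set_sizes, collapse = "/"), vp$union_size,
                sum(vp$class_counts[c("AE", "AI", "EI")])))

# the fitness-index arithmetic used for the colonization assays
message(sprintf("competition index, equal recovery vs equal inoculum: %.2f",
                competition_index(50, 50, 50, 50)))
message(sprintf("competition index, mutant outcompeted 80:20 from a 1:1 start: %.2f",
                competition_index(80, 20, 50, 50)))
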