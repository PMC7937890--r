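#!/usr/bin/env Rscript
# Step 1 -- simulate the study conditions.
#
# Builds the synthetic genome annotation (900 compact features on a 500 kb
# replicon, including head-to-head gene pairs and IS-like repeat families),
# plants the three Rsm target sets with the designed Venn partition, and
# writes the annotation, the ground truth, and one example pulldown/control
# library pair as plain-text artifacts under results/sim/.

suppressPackageStartupMessages(library(rsmtargets))
seed <- 101L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
ann <- generate_genome_annotation(cfg)
truth <- plant_targets(ann, cfg)

write_annotation(ann, file.path(out, "annotation.gff3"))
write_truth(truth, file.path(out, "truth.tsv"))
jsonlite::write_json(list(seed = seed,
                          genome_length = cfg$genome_length,
                          depths = c(pulldown = cfg$depth_pulldown,
                                     control = cfg$depth_control),
                          bio_reps = as.list(cfg$bio_reps),
                          tech_reps = cfg$tech_reps,
                          design = as.list(unclass(cfg$design))),
                     file.path(out, "config.json"),
                     auto_unbox = TRUE, digits = NA)

f <- ann$features
message(sprintf("annotation: %d features (%d coding, %d ncRNA, %d repeat copies, %d pseudogenes)",
                nrow(f), sum(f$type == "coding_gene"), sum(f$type == "ncRNA"),
                sum(f$type == "repeat_element"), sum(f$type == "pseudogene")))
sizes <- design_set_sizes(cfg$design)
message(sprintf("planted regulons: RsmA %d, RsmE %d, RsmI %d (union %d, %d common to all three)",
                sizes["RsmA"], sizes["RsmE"], sizes["RsmI"],
                sum(cfg$design), cfg$design["AEI"]))

# one example library pair on disk; the later steps re-derive all libraries
# deterministically from the seed instead of storing ~7M BED records
libs <- simulate_tag_libraries(ann, truth, cfg, proteins = "RsmA")
write_tag_library(libs[[1]], file.path(out, "example_RsmA_b1_ctrl.bed"))
write_tag_library(libs[[2]], file.path(out, "example_RsmA_b1_t1_pd.bed"))
message("wrote annotation.gff3, truth.tsv, config.json and one example library pair to ", out)
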