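# Synthetic genomes, planted Rsm target sets with a designed overlap
# structure, and pulldown/control tag libraries with the study's replicate
# scheme (3 proteins x 2-3 biological replicates x 3 technical extractions),
# plus ground truth for recovery scoring.

RSM_PROTEINS <- c("RsmA", "RsmE", "RsmI")

# disjoint Venn class keys: singles, pairs, triple
VENN_CLASSES <- c("A", "E", "I", "AE", "AI", "EI", "AEI")

.class_members <- list(A = "RsmA", E = "RsmE", I = "RsmI",
                       AE = c("RsmA", "RsmE"), AI = c("RsmA", "RsmI"),
                       EI = c("RsmE", "RsmI"),
                       AEI = c("RsmA", "RsmE", "RsmI"))

#' Venn overlap design for planted target sets
#'
#' Counts for the 7 disjoint overlap classes of three protein target sets,
#' keyed `A`, `E`, `I` (exclusive), `AE`, `AI`, `EI` (shared by exactly two)
#' and `AEI` (shared by all three).
#'
#' @param A,E,I exclusive class counts.
#' @param AE,AI,EI exactly-two class counts.
#' @param AEI triple class count.
#' @return named integer vector of class `venn_design`.
#' @export
venn_design <- function(A, E, I, AE, AI, EI, AEI) {
  d <- c(A = A, E = E, I = I, AE = AE, AI = AI, EI = EI, AEI = AEI)
  if (any(d < 0) || any(d != round(d))) stop("class counts must be non-negative integers")
  structure(stats::setNames(as.integer(d), VENN_CLASSES), class = "venn_design")
}

#' Per-protein set sizes implied by a Venn design
#' @param design a [venn_design()].
#' @return named integer vector (`RsmA`, `RsmE`, `RsmI`).
#' @export
design_set_sizes <- function(design) {
  c(RsmA = sum(design[c("A", "AE", "AI", "AEI")]),
    RsmE = sum(design[c("E", "AE", "EI", "AEI")]),
    RsmI = sum(design[c("I", "AI", "EI", "AEI")]))
}

#' Study-scale reference Venn design
#'
#' The partition consistent with the published KT2440 regulon sizes: per-protein
#' totals 241 (RsmA), 261 (RsmE) and 206 (RsmI), 75 targets shared by all
#' three proteins, each exactly-two class between 36 and 45, union 437. By
#' inclusion-exclusion the exactly-two classes must total 121; the partition
#' used here is AE = 40, AI = 40, EI = 41.
#'
#' @return a [venn_design()].
#' @export
reference_venn_design <- function() {
  venn_design(A = 86, E = 105, I = 50, AE = 40, AI = 40, EI = 41, AEI = 75)
}

#' Simulation configuration
#'
#' Defaults define the desk-scale study conditions: a 500 kb single-replicon
#' genome carrying 900 compact features, tag depths of 200,000 (pulldown) and
#' 400,000 (total-RNA control) per library -- about 1/5 of the study's printed
#' per-sample tag counts on about 1/12 of the genome, which reproduces the
#' study's 60-76x coverage -- the retained replicate structure (RsmA 2, RsmE 3,
#' RsmI 2 biological replicates, 3 technical extractions each), and planted
#' enrichment factors log-uniform on [4, 16].
#'
#' @param genome_length replicon length, nt.
#' @param replicon_name replicon name.
#' @param n_coding,n_ncrna,n_pseudogene feature counts by type.
#' @param n_repeat_families,repeat_copies IS-like repeat families and exact
#'   copies per family (copies are position-identical units, >= 3 loci total).
#' @param n_divergent_pairs head-to-head gene pairs sharing an upstream gap.
#' @param coding_len,ncrna_len,pseudo_len length ranges, nt.
#' @param repeat_len repeat copy length, nt.
#' @param min_gap minimum intergenic gap, nt.
#' @param design a [venn_design()] of planted-target classes.
#' @param enrichment_range planted enrichment factors are drawn log-uniformly
#'   over this interval (all >= 1).
#' @param abundance_sdlog sdlog of the log-normal transcript abundance model.
#' @param bio_sdlog sdlog of the per-biological-replicate abundance jitter.
#' @param background_fraction fraction of tag mass scattered uniformly over
#'   the genome (models intergenic background).
#' @param depth_pulldown,depth_control tags per library.
#' @param bio_reps named integer vector of biological replicates per protein
#'   (2 or 3).
#' @param tech_reps technical replicate extractions per culture.
#' @param resample_fraction fraction of each technical replicate's tags drawn
#'   fresh from the biological-replicate expectation (the rest are shared with
#'   the culture's master pool); in (0, 1].
#' @param seed default master seed used when the generator functions are not
#'   given one explicitly.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 500000,
                              replicon_name = "simchr1",
                              n_coding = 835,
                              n_ncrna = 40,
                              n_repeat_families = 3,
                              repeat_copies = 3,
                              n_pseudogene = 16,
                              n_divergent_pairs = 30,
                              coding_len = c(200, 500),
                              ncrna_len = c(80, 300),
                              pseudo_len = c(200, 400),
                              repeat_len = 250,
                              min_gap = 20,
                              design = venn_design(A = 10, E = 12, I = 10,
                                                   AE = 10, AI = 10, EI = 10,
                                                   AEI = 15),
                              enrichment_range = c(4, 16),
                              abundance_sdlog = 1.0,
                              bio_sdlog = 0.05,
                              background_fraction = 0.05,
                              depth_pulldown = 200000,
                              depth_control = 400000,
                              bio_reps = c(RsmA = 2L, RsmE = 3L, RsmI = 2L),
                              tech_reps = 3L,
                              resample_fraction = 0.3,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(genome_length > 0, depth_pulldown > 0, depth_control > 0,
            tech_reps >= 1, all(bio_reps %in% 2:3) || all(bio_reps >= 1),
            resample_fraction > 0, resample_fraction <= 1,
            background_fraction >= 0, background_fraction < 1,
            enrichment_range[1] >= 1,
            enrichment_range[2] >= enrichment_range[1])
  if (!inherits(design, "venn_design")) stop("design must be a venn_design()")
  if (is.null(names(bio_reps)) || !all(RSM_PROTEINS %in% names(bio_reps))) {
    stop("bio_reps must be named for ", paste(RSM_PROTEINS, collapse = ", "))
  }
  structure(cfg, class = "simulation_config")
}

# deterministic substream seeds: a small string hash folded with the master
# seed, kept below 2^31
.derive_seed <- function(master, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(master) * 48271 + h) %% 2147483647)
}

#' Generate a synthetic genome annotation
#'
#' Lays out non-overlapping features left to right, separated by intergenic
#' gaps, with the requested number of divergent (-,+) gene pairs sharing an
#' upstream gap, and repeat families whose copies are identical-length units
#' scattered over the replicon. No sequence is generated, positions only.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed (defaults to the config's).
#' @return a [genome_annotation()].
#' @export
generate_genome_annotation <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(.derive_seed(seed, "annotation"))
  n_repeat <- config$n_repeat_families * config$repeat_copies
  n_feat <- config$n_coding + config$n_ncrna + n_repeat + config$n_pseudogene
  if (n_feat == 0L) {
    return(genome_annotation(
      data.frame(name = config$replicon_name, length = config$genome_length),
      data.frame(locus_id = character(), type = character(),
                 replicon = character(), start = integer(), end = integer(),
                 strand = character(), name = character())))
  }
  if (config$n_divergent_pairs * 2 > config$n_coding) {
    stop("more divergent pairs than coding genes allow")
  }
  rlen <- function(n, range) {
    if (n == 0) integer() else as.integer(round(stats::runif(n, range[1], range[2])))
  }
  spec <- data.frame(
    locus_id = c(sprintf("SYG_%04d", seq_len(config$n_coding)),
                 sprintf("SYR_%03d", seq_len(config$n_ncrna)),
                 if (n_repeat) sprintf("SYIS_f%d_c%d",
                                       rep(seq_len(config$n_repeat_families),
                                           each = config$repeat_copies),
                                       rep(seq_len(config$repeat_copies),
                                           config$n_repeat_families)),
                 sprintf("SYP_%03d", seq_len(config$n_pseudogene))),
    type = rep(c("coding_gene", "ncRNA", "repeat_element", "pseudogene"),
               c(config$n_coding, config$n_ncrna, n_repeat, config$n_pseudogene)),
    len = c(rlen(config$n_coding, config$coding_len),
            rlen(config$n_ncrna, config$ncrna_len),
            rep(as.integer(config$repeat_len), n_repeat),
            rlen(config$n_pseudogene, config$pseudo_len)),
    name = c(rep(NA_character_, config$n_coding + config$n_ncrna),
             if (n_repeat) rep(sprintf("SYIS_f%d",
                                       seq_len(config$n_repeat_families)),
                               each = config$repeat_copies),
             rep(NA_character_, config$n_pseudogene)),
    stringsAsFactors = FALSE)
  total_feat <- sum(spec$len)
  gap_budget <- config$genome_length - total_feat - (n_feat + 1) * config$min_gap
  if (gap_budget < 0) {
    stop("feature demand (", total_feat, " nt + minimum gaps) exceeds genome length ",
         config$genome_length)
  }
  # order: divergent pairs are (-,+) coding pairs placed as units; everything
  # else shuffled around them
  pair_genes <- seq_len(config$n_divergent_pairs * 2)   # first coding genes
  singles <- setdiff(seq_len(n_feat), pair_genes)
  units <- c(split(pair_genes, rep(seq_len(config$n_divergent_pairs),
                                   each = 2)),
             as.list(singles))
  units <- units[sample.int(length(units))]
  order_idx <- unlist(units, use.names = FALSE)
  spec <- spec[order_idx, , drop = FALSE]
  is_pair_first <- unlist(lapply(units, function(u) {
    if (length(u) == 2L) c(TRUE, FALSE) else FALSE
  }), use.names = FALSE)
  is_pair_second <- unlist(lapply(units, function(u) {
    if (length(u) == 2L) c(FALSE, TRUE) else FALSE
  }), use.names = FALSE)
  strand <- ifelse(is_pair_first, "-",
                   ifelse(is_pair_second, "+",
                          sample(c("+", "-"), n_feat, replace = TRUE)))
  w <- stats::rexp(n_feat + 1) + 1e-6
  extra <- floor(w / sum(w) * gap_budget)
  gaps <- extra + config$min_gap
  starts <- cumsum(c(gaps[1],
                     if (n_feat > 1) spec$len[-n_feat] + gaps[2:n_feat]))
  features <- data.frame(locus_id = spec$locus_id, type = spec$type,
                         replicon = config$replicon_name,
                         start = as.integer(starts),
                         end = as.integer(starts + spec$len),
                         strand = strand, name = spec$name,
                         stringsAsFactors = FALSE)
  genome_annotation(
    data.frame(name = config$replicon_name, length = config$genome_length),
    features)
}

#' Plantable target units of an annotation
#'
#' Non-repeat features are one unit each; a repeat family's identical copies
#' form a single unit (multi-mapping tags cannot distinguish them).
#'
#' @param annotation a [genome_annotation()].
#' @return data.frame with `unit_id` and comma-joined `members`.
#' @export
target_units <- function(annotation) {
  f <- annotation$features
  if (nrow(f) == 0L) {
    return(data.frame(unit_id = character(), members = character(),
                      stringsAsFactors = FALSE))
  }
  is_rep <- f$type == "repeat_element"
  units <- data.frame(unit_id = f$locus_id[!is_rep],
                      members = f$locus_id[!is_rep],
                      stringsAsFactors = FALSE)
  if (any(is_rep)) {
    fam <- split(f$locus_id[is_rep], f$name[is_rep])
    units <- rbind(units,
                   data.frame(unit_id = names(fam),
                              members = vapply(fam, paste, "", collapse = ","),
                              stringsAsFactors = FALSE))
  }
  units[order(units$unit_id), , drop = FALSE]
}

#' Map repeat copies to their family unit
#'
#' @param annotation a [genome_annotation()].
#' @return named character vector, copy locus_id -> family unit_id.
#' @export
repeat_family_map <- function(annotation) {
  f <- annotation$features
  is_rep <- f$type == "repeat_element"
  stats::setNames(f$name[is_rep], f$locus_id[is_rep])
}

#' Plant target sets with a designed Venn partition
#'
#' Samples target units without replacement and assigns them to the 7 disjoint
#' overlap classes of the design, so the Venn partition of the three planted
#' sets equals the design exactly. Per (protein, unit) enrichment factors are
#' drawn i.i.d. log-uniformly over the configured range.
#'
#' @param annotation a [genome_annotation()].
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return object of class `synthetic_truth`: list with the `design`, a
#'   `targets` data.frame (`unit_id`, `venn_class`, `members`, `ef_RsmA`,
#'   `ef_RsmE`, `ef_RsmI`; NA enrichment where the protein does not bind the
#'   unit) and the `units` table.
#' @export
plant_targets <- function(annotation, config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  design <- config$design
  set.seed(.derive_seed(seed, "plant"))
  units <- target_units(annotation)
  total <- sum(design)
  if (total > nrow(units)) {
    need <- design[design > 0]
    stop("infeasible Venn design: ", total, " targets requested over ",
         nrow(units), " available units (classes ",
         paste(names(need), need, sep = "=", collapse = ", "), ")")
  }
  picked <- if (total > 0) units[sample.int(nrow(units), total), , drop = FALSE]
            else units[0, , drop = FALSE]
  cls <- rep(names(design), design)
  ef <- matrix(NA_real_, nrow = total, ncol = 3,
               dimnames = list(NULL, paste0("ef_", RSM_PROTEINS)))
  lo <- log(config$enrichment_range[1]); hi <- log(config$enrichment_range[2])
  for (i in seq_len(total)) {
    for (p in .class_members[[cls[i]]]) {
      ef[i, paste0("ef_", p)] <- exp(stats::runif(1, lo, hi))
    }
  }
  targets <- cbind(data.frame(unit_id = picked$unit_id, venn_class = cls,
                              members = picked$members,
                              stringsAsFactors = FALSE),
                   as.data.frame(ef))
  rownames(targets) <- NULL
  structure(list(design = design, targets = targets, units = units),
            class = "synthetic_truth")
}

#' Planted target sets by protein
#' @param truth a [plant_targets()] result.
#' @return named list of unit_id character vectors.
#' @export
truth_sets <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  t <- truth$targets
  out <- lapply(RSM_PROTEINS, function(p) t$unit_id[!is.na(t[[paste0("ef_", p)]])])
  stats::setNames(out, RSM_PROTEINS)
}

# per-feature expected tag weights for one (protein, role); returns a list
# with feature weights and the background mass fraction
.library_weights <- function(annotation, truth, config, protein, role) {
  f <- annotation$features
  ab <- attr(truth, "abundance")
  w <- ab[f$locus_id]
  if (role == "pulldown" && protein != "none") {
    ef_col <- paste0("ef_", protein)
    t <- truth$targets[!is.na(truth$targets[[ef_col]]), , drop = FALSE]
    if (nrow(t)) {
      members <- strsplit(t$members, ",", fixed = TRUE)
      ef_by_locus <- stats::setNames(rep(t[[ef_col]], lengths(members)),
                                     unlist(members))
      hit <- f$locus_id %in% names(ef_by_locus)
      w[hit] <- w[hit] * ef_by_locus[f$locus_id[hit]]
    }
  }
  w
}

# draw n tag positions (0-based) given feature weights + uniform background
.draw_positions <- function(n, features, w, background_fraction, genome_length) {
  if (nrow(features) == 0L || sum(w) <= 0) background_fraction <- 1
  n_bg <- stats::rbinom(1, n, background_fraction)
  n_ft <- n - n_bg
  pos_bg <- if (n_bg) as.integer(floor(stats::runif(n_bg) * genome_length)) else integer()
  pos_ft <- integer()
  if (n_ft > 0 && nrow(features) > 0) {
    idx <- sample.int(nrow(features), n_ft, replace = TRUE, prob = w)
    len <- features$end - features$start
    pos_ft <- features$start[idx] + as.integer(floor(stats::runif(n_ft) * len[idx]))
  }
  c(pos_ft, pos_bg)
}

#' Simulate pulldown and control tag libraries
#'
#' For each protein and biological replicate, draws one total-RNA control
#' library and `tech_reps` pulldown libraries. Transcript abundances are
#' log-normal (one transcriptome per simulation, small per-culture jitter);
#' planted units are drawn from the upper half of the abundance distribution
#' (pulldown enrichment is only observable for expressed transcripts) and have
#' their pulldown weight multiplied by the planted enrichment factor before
#' normalization to library depth. Repeat-family copies share one per-copy
#' abundance and enrichment (multi-mapping tags are allocated symmetrically).
#' Technical replicates share `1 - resample_fraction` of their culture's
#' master tag pool and draw the rest fresh. Libraries are unstranded: tag
#' strands are random.
#'
#' @param annotation a [genome_annotation()].
#' @param truth a [plant_targets()] result (its planted units must exist in
#'   the annotation).
#' @param config a [simulation_config()].
#' @param seed integer master seed; per-library substreams are derived from it
#'   by fixed-order hashing, so adding a library never perturbs others.
#' @param proteins which proteins to simulate (default all three).
#' @return list of [tag_library()] objects.
#' @export
simulate_tag_libraries <- function(annotation, truth, config,
                                   seed = config$seed,
                                   proteins = RSM_PROTEINS) {
  stopifnot(inherits(annotation, "genome_annotation"),
            inherits(truth, "synthetic_truth"),
            inherits(config, "simulation_config"))
  if (config$depth_pulldown <= 0 || config$depth_control <= 0) {
    stop("zero-depth configuration")
  }
  f <- annotation$features
  if (!all(unlist(strsplit(truth$targets$members, ",")) %in% f$locus_id)) {
    stop("truth refers to loci absent from the annotation")
  }
  truth <- .with_abundance(truth, annotation, config, seed)
  G <- sum(annotation$replicons$length)
  out <- list()
  for (protein in proteins) {
    n_bio <- config$bio_reps[[protein]]
    w_pd <- .library_weights(annotation, truth, config, protein, "pulldown")
    w_ct <- .library_weights(annotation, truth, config, protein, "total_control")
    for (b in seq_len(n_bio)) {
      set.seed(.derive_seed(seed, paste0(protein, "_bio", b)))
      jit <- if (nrow(f)) exp(stats::rnorm(nrow(f), 0, config$bio_sdlog)) else numeric()
      wb_pd <- w_pd * jit
      wb_ct <- w_ct * jit
      # total-RNA control
      set.seed(.derive_seed(seed, paste0(protein, "_bio", b, "_ctrl")))
      pos <- .draw_positions(config$depth_control, f, wb_ct,
                             config$background_fraction, G)
      out[[length(out) + 1L]] <- tag_library(
        sprintf("%s_b%d_ctrl", protein, b), protein, "total_control",
        b, 1L,
        data.frame(replicon = config$replicon_name, pos = pos,
                   strand = sample(c("+", "-"), length(pos), replace = TRUE),
                   stringsAsFactors = FALSE),
        replicons = annotation$replicons)
      # shared master pool for the culture's technical extractions
      set.seed(.derive_seed(seed, paste0(protein, "_bio", b, "_master")))
      master <- .draw_positions(config$depth_pulldown, f, wb_pd,
                                config$background_fraction, G)
      n_keep <- as.integer(round((1 - config$resample_fraction) *
                                 config$depth_pulldown))
      for (tr in seq_len(config$tech_reps)) {
        set.seed(.derive_seed(seed, paste0(protein, "_bio", b, "_tech", tr)))
        kept <- if (n_keep > 0) master[sample.int(length(master), n_keep)] else integer()
        fresh <- .draw_positions(config$depth_pulldown - n_keep, f, wb_pd,
                                 config$background_fraction, G)
        pos <- c(kept, fresh)
        out[[length(out) + 1L]] <- tag_library(
          sprintf("%s_b%d_t%d_pd", protein, b, tr), protein, "pulldown",
          b, tr,
          data.frame(replicon = config$replicon_name, pos = pos,
                     strand = sample(c("+", "-"), length(pos), replace = TRUE),
                     stringsAsFactors = FALSE),
          replicons = annotation$replicons)
      }
    }
  }
  out
}

# attach the per-feature abundance vector (one transcriptome per simulation)
.with_abundance <- function(truth, annotation, config, seed) {
  f <- annotation$features
  set.seed(.derive_seed(seed, "abundance"))
  is_rep <- f$type == "repeat_element"
  ab <- stats::setNames(numeric(nrow(f)), f$locus_id)
  # one draw per non-repeat feature, one shared per-copy draw per family
  ab[!is_rep] <- stats::rlnorm(sum(!is_rep), 0, config$abundance_sdlog)
  if (any(is_rep)) {
    fams <- unique(f$name[is_rep])
    fam_ab <- stats::setNames(stats::rlnorm(length(fams), 0,
                                            config$abundance_sdlog), fams)
    ab[is_rep] <- fam_ab[f$name[is_rep]]
  }
  # planted units: redraw from the upper half of the abundance distribution
  planted <- unique(truth$targets$unit_id)
  if (length(planted)) {
    up <- exp(abs(stats::rnorm(length(planted), 0, config$abundance_sdlog)))
    for (i in seq_along(planted)) {
      members <- strsplit(truth$targets$members[truth$targets$unit_id ==
                                                planted[i]][1], ",")[[1]]
      ab[members] <- up[i]
    }
  }
  attr(truth, "abundance") <- ab
  truth
}

#' Expected relative pulldown/control enrichment of planted units
#'
#' Closed-form expectation: with feature weights w and enrichment factors e,
#' the normalized pulldown/control coverage ratio at a planted unit tends to
#' e / Z in the infinite-depth limit, where Z = sum(w e) / sum(w) over the
#' feature (non-background) mass. Useful as an oracle for the simulator and
#' to reason about compositional normalization.
#'
#' @param annotation,truth,config,seed as in [simulate_tag_libraries()].
#' @param protein protein name.
#' @return data.frame with `unit_id`, planted `ef` and expected `relative_fe`.
#' @export
expected_relative_enrichment <- function(annotation, truth, config, protein,
                                         seed = config$seed) {
  truth <- .with_abundance(truth, annotation, config, seed)
  w_ct <- .library_weights(annotation, truth, config, protein, "total_control")
  w_pd <- .library_weights(annotation, truth, config, protein, "pulldown")
  Z <- sum(w_pd) / sum(w_ct)
  ef_col <- paste0("ef_", protein)
  t <- truth$targets[!is.na(truth$targets[[ef_col]]), , drop = FALSE]
  data.frame(unit_id = t$unit_id, ef = t[[ef_col]],
             relative_fe = t[[ef_col]] / Z, stringsAsFactors = FALSE)
}

#' Write the planted truth as TSV
#' @param truth a [plant_targets()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  t <- truth$targets
  for (col in paste0("ef_", RSM_PROTEINS)) {
    t[[col]] <- ifelse(is.na(t[[col]]), NA, sprintf("%.4f", t[[col]]))
  }
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
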