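# End-to-end orchestration: simulate (or load) tag libraries, call peaks per
# technical replicate, build per-culture consensus tables, derive or apply
# cut-offs, filter across biological replicates, annotate surviving regions,
# collapse to unique RNA targets, and compare/evaluate the three regulons.
# Every threshold, count and discard decision lands in an audit table modeled
# on the published per-stage summary.

#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [simulation_config()]) or `inputs` (paths
#' to on-disk tag libraries and annotation) must be provided.
#'
#' @param simulation a [simulation_config()], or NULL.
#' @param inputs list with `annotation` (GFF3 path) and `libraries` (a
#'   data.frame with columns `path`, `sample_id`, `protein`, `role`,
#'   `bio_rep`, `tech_rep`), or NULL.
#' @param peak_params a [peak_params()].
#' @param threshold list: `mode` "fixed" (apply `fe`/`pv` as cut-offs) or
#'   "adaptive" (derive cut-offs per protein from the per-replicate
#'   confidence-interval limits with [select_cutoffs()]); `alpha` for the CI.
#' @param compute_fdr also run the swapped comparison and attach empirical
#'   FDR values to each peak table.
#' @param proteins proteins to process.
#' @param seed master seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            peak_params = rsmtargets::peak_params(),
                            threshold = list(mode = "fixed", fe = 1.0, pv = 50,
                                             alpha = 0.05),
                            compute_fdr = FALSE,
                            proteins = RSM_PROTEINS,
                            seed = 1L) {
  if (is.null(simulation) == is.null(inputs)) {
    stop("provide exactly one of 'simulation' or 'inputs'")
  }
  if (!is.null(simulation)) stopifnot(inherits(simulation, "simulation_config"))
  stopifnot(threshold$mode %in% c("fixed", "adaptive"))
  structure(list(simulation = simulation, inputs = inputs,
                 peak_params = peak_params, threshold = threshold,
                 compute_fdr = compute_fdr, proteins = proteins,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, sample_id, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed",
         if (nzchar(sample_id)) paste0(" for sample '", sample_id, "'"),
         ": ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full target-identification pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if needed. Per protein the
#'   pipeline writes per-replicate peak tables, per-culture consensus tables,
#'   FE/PV histogram TSVs, `cutoffs.json` and `unique_targets.tsv`, plus
#'   `venn.json`, `audit.tsv`, `recovery.json` (when simulated truth exists)
#'   and a `manifest.json` listing every artifact with its md5 content hash.
#'   Identical config and seed give identical manifest hashes.
#' @return invisibly, a list with the in-memory results (`annotation`,
#'   `truth`, per-protein `targets`, `cutoffs`, `venn`, `recovery`, `audit`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    annotation <- .stage("simulate", "", generate_genome_annotation(sim, seed))
    truth <- .stage("simulate", "", plant_targets(annotation, sim, seed))
    libs <- .stage("simulate", "",
                   simulate_tag_libraries(annotation, truth, sim, seed,
                                          proteins = config$proteins))
  } else {
    annotation <- .stage("load", "", load_annotation(config$inputs$annotation))
    spec <- config$inputs$libraries
    libs <- lapply(seq_len(nrow(spec)), function(i) {
      .stage("load", spec$sample_id[i],
             load_tag_library(spec$path[i], spec$sample_id[i], spec$protein[i],
                              spec$role[i], spec$bio_rep[i], spec$tech_rep[i],
                              replicons = annotation$replicons))
    })
    truth <- NULL
  }
  replicons <- annotation$replicons
  write_annotation(annotation, file.path(out_dir, "annotation.gff3"))
  if (!is.null(truth)) write_truth(truth, file.path(out_dir, "truth.tsv"))

  meta <- data.frame(
    idx = seq_along(libs),
    protein = vapply(libs, function(l) l$protein, ""),
    role = vapply(libs, function(l) l$role, ""),
    bio = vapply(libs, function(l) l$bio_rep, 0L),
    tech = vapply(libs, function(l) l$tech_rep, 0L),
    stringsAsFactors = FALSE)

  all_targets <- list()
  cutoffs_all <- list()
  audit <- list()
  for (protein in config$proteins) {
    pm <- meta[meta$protein == protein, , drop = FALSE]
    bio_ids <- sort(unique(pm$bio))
    bio_tables <- list()
    fe_limits <- c(); pv_limits <- c()
    for (b in bio_ids) {
      ctrl_idx <- pm$idx[pm$bio == b & pm$role == "total_control"]
      pd_idx <- pm$idx[pm$bio == b & pm$role == "pulldown"]
      if (length(ctrl_idx) != 1L || length(pd_idx) < 1L) {
        stop("pipeline stage 'pairing' failed for sample '", protein,
             "_b", b, "': need one control and >=1 pulldown library")
      }
      control <- libs[[ctrl_idx]]
      peak_lists <- lapply(pd_idx, function(j) {
        lib <- libs[[j]]
        pk <- .stage("peakcall", lib$sample_id,
                     call_peaks(lib, control, config$peak_params, replicons))
        if (config$compute_fdr) {
          sw <- .stage("peakcall_swap", lib$sample_id,
                       call_peaks(control, lib, config$peak_params, replicons))
          pk <- empirical_fdr(pk, sw)
        }
        write_peak_table(pk, file.path(out_dir,
                                       paste0("peaks_", lib$sample_id, ".tsv")))
        pk
      })
      cons <- .stage("consensus", paste0(protein, "_b", b),
                     if (length(peak_lists) >= 2) technical_consensus(peak_lists)
                     else .as_scored_peaks(peak_lists[[1]]))
      utils::write.table(.round4(cons),
                         file.path(out_dir,
                                   sprintf("consensus_%s_b%d.tsv", protein, b)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      bio_tables[[length(bio_tables) + 1L]] <- cons
      if (nrow(cons) >= 2) {
        fe_limits <- c(fe_limits, ci_lower_limit(cons$fe,
                                                 config$threshold$alpha %||% 0.05))
        pv_limits <- c(pv_limits, ci_lower_limit(cons$pv,
                                                 config$threshold$alpha %||% 0.05))
        dist <- score_distributions(cons)
        utils::write.table(.round4(dist$fe),
                           file.path(out_dir,
                                     sprintf("hist_fe_%s_b%d.tsv", protein, b)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(.round4(dist$pv),
                           file.path(out_dir,
                                     sprintf("hist_pv_%s_b%d.tsv", protein, b)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    cutoffs <- .stage("cutoffs", protein, {
      if (config$threshold$mode == "adaptive") {
        if (!length(fe_limits)) stop("no replicate CI limits available")
        select_cutoffs(fe_limits, pv_limits, protein)
      } else {
        structure(list(protein = protein, fe_limits = fe_limits,
                       pv_limits = pv_limits,
                       fe_cutoff = config$threshold$fe,
                       pv_cutoff = config$threshold$pv),
                  class = "cutoff_set")
      }
    })
    cutoffs_all[[protein]] <- cutoffs
    surv <- .stage("filter", protein, filter_targets(bio_tables, cutoffs))
    assigned <- .stage("annotate", protein,
                       expand_coassigned(assign_features(surv, annotation)))
    uniq <- .stage("collapse", protein, collapse_to_unique(assigned))
    all_targets[[protein]] <- uniq
    utils::write.table(.round4(uniq),
                       file.path(out_dir,
                                 sprintf("unique_targets_%s.tsv", protein)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    audit[[protein]] <- data.frame(
      protein = protein,
      bio_replicates = length(bio_ids),
      consensus_peaks = paste(vapply(bio_tables, nrow, 0L), collapse = "/"),
      fe_ci_limits = paste(sprintf("%.4f", fe_limits), collapse = "/"),
      pv_ci_limits = paste(sprintf("%.4f", pv_limits), collapse = "/"),
      fe_cutoff = cutoffs$fe_cutoff, pv_cutoff = cutoffs$pv_cutoff,
      surviving_regions = nrow(surv),
      unique_targets = nrow(uniq),
      stringsAsFactors = FALSE)
  }
  audit <- do.call(rbind, audit)
  utils::write.table(audit, file.path(out_dir, "audit.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    lapply(cutoffs_all, function(co) co[c("protein", "fe_limits", "pv_limits",
                                          "fe_cutoff", "pv_cutoff")]),
    file.path(out_dir, "cutoffs.json"), auto_unbox = TRUE, digits = NA)

  venn <- NULL; recovery <- NULL
  if (length(all_targets) == 3L) {
    fam <- repeat_family_map(annotation)
    sets <- lapply(all_targets, function(t) {
      l <- t$locus
      hit <- l %in% names(fam)
      l[hit] <- fam[l[hit]]
      unique(l)
    })
    venn <- venn_partition(sets)
    jsonlite::write_json(unclass(venn), file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(truth) && length(all_targets)) {
    recovery <- recovery_metrics(
      lapply(all_targets, function(t) t[, c("locus", "alt_locus")]),
      truth, locus_map = repeat_family_map(annotation))
    jsonlite::write_json(recovery, file.path(out_dir, "recovery.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = seed, artifacts = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(annotation = annotation, truth = truth,
                 targets = all_targets, cutoffs = cutoffs_all, venn = venn,
                 recovery = recovery, audit = audit, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.round4 <- function(df) {
  num <- vapply(df, is.numeric, TRUE) &
    !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) round(x, 4))
  df
}
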