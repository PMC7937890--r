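# Shared domain types and readers/writers for the formats the pipeline touches
# (BED tag libraries, GFF3 annotations, TSV peak tables, bedGraph coverage).
# Internal coordinates are 0-based half-open everywhere; GFF3 I/O converts at
# the boundary.

FEATURE_TYPES <- c("coding_gene", "ncRNA", "repeat_element", "pseudogene")

#' Construct a genome annotation
#'
#' Container for one or more replicons and the features annotated on them.
#' Feature coordinates are 0-based half-open; strand is recorded even though
#' the sequencing libraries the pipeline analyses are unstranded, because
#' strand is what defines divergent (head-to-head) gene pairs.
#'
#' @param replicons data.frame with columns `name` and `length` (nt).
#' @param features data.frame with columns `locus_id`, `type` (one of
#'   `coding_gene`, `ncRNA`, `repeat_element`, `pseudogene`), `replicon`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`) and optionally
#'   `name` (repeat copies share their family name here).
#' @return An object of class `genome_annotation`.
#' @export
genome_annotation <- function(replicons, features) {
  replicons <- as.data.frame(replicons, stringsAsFactors = FALSE)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "length") %in% names(replicons)))
  req <- c("locus_id", "type", "replicon", "start", "end", "strand")
  if (!all(req %in% names(features))) {
    stop("features must have columns: ", paste(req, collapse = ", "))
  }
  if (!"name" %in% names(features)) features$name <- NA_character_
  if (anyDuplicated(replicons$name)) stop("duplicate replicon names")
  if (nrow(features)) {
    if (anyDuplicated(features$locus_id)) {
      stop("duplicate locus identifiers: ",
           paste(unique(features$locus_id[duplicated(features$locus_id)]),
                 collapse = ", "))
    }
    bad_type <- setdiff(unique(features$type), FEATURE_TYPES)
    if (length(bad_type)) stop("unknown feature type: ", paste(bad_type, collapse = ", "))
    if (!all(features$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
    if (any(features$start >= features$end)) stop("feature start must be < end")
    if (any(features$start < 0)) stop("negative feature start")
    len <- stats::setNames(replicons$length, replicons$name)
    unknown <- setdiff(unique(features$replicon), replicons$name)
    if (length(unknown)) stop("feature on unknown replicon: ", paste(unknown, collapse = ", "))
    if (any(features$end > len[features$replicon])) {
      stop("feature extends beyond replicon length")
    }
    features <- features[order(features$replicon, features$start, features$end), ,
                         drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(replicons = replicons, features = features),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$replicons), "replicon(s),",
      nrow(x$features), "feature(s)\n")
  if (nrow(x$features)) print(table(x$features$type))
  invisible(x)
}

#' Construct a tag library
#'
#' One sample's aligned sequencing tag positions (5' ends) with its protein,
#' role and replicate metadata. Tags are points on 0-based coordinates.
#'
#' @param sample_id character scalar.
#' @param protein one of `"RsmA"`, `"RsmE"`, `"RsmI"`, `"none"`.
#' @param role `"pulldown"` or `"total_control"`.
#' @param bio_rep,tech_rep positive integers (a total-RNA control carries the
#'   tech_rep 1 by convention).
#' @param tags data.frame with columns `replicon`, `pos` (0-based 5' position)
#'   and `strand`.
#' @param replicons optional replicon table (`name`, `length`) used to bounds
#'   check the tag positions.
#' @return An object of class `tag_library`.
#' @export
tag_library <- function(sample_id, protein, role, bio_rep, tech_rep, tags,
                        replicons = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  protein <- match.arg(protein, c("RsmA", "RsmE", "RsmI", "none"))
  role <- match.arg(role, c("pulldown", "total_control"))
  stopifnot(bio_rep >= 1, tech_rep >= 1)
  tags <- as.data.frame(tags, stringsAsFactors = FALSE)
  if (!all(c("replicon", "pos", "strand") %in% names(tags))) {
    stop("tags must have columns replicon, pos, strand")
  }
  if (nrow(tags) == 0L) stop("tag library '", sample_id, "' has no tags")
  if (!is.null(replicons)) {
    len <- stats::setNames(replicons$length, replicons$name)
    unknown <- setdiff(unique(tags$replicon), replicons$name)
    if (length(unknown)) {
      stop("tag on unknown replicon: ", paste(unknown, collapse = ", "))
    }
    if (any(tags$pos < 0) || any(tags$pos >= len[tags$replicon])) {
      stop("tag position outside replicon bounds in '", sample_id, "'")
    }
  }
  structure(list(sample_id = sample_id, protein = protein, role = role,
                 bio_rep = as.integer(bio_rep), tech_rep = as.integer(tech_rep),
                 tags = tags),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library %s [%s %s bio%d tech%d]: %d tags\n",
              x$sample_id, x$protein, x$role, x$bio_rep, x$tech_rep,
              nrow(x$tags)))
  invisible(x)
}

#' Load a tag library from a BED file
#'
#' Each BED record contributes one tag at its 5' coordinate: `start` for
#' plus-strand records, `end - 1` for minus-strand records (0-based).
#'
#' @param path BED file (>= 3 columns; strand defaults to `+` when absent).
#' @param sample_id,protein,role,bio_rep,tech_rep sample metadata, see
#'   [tag_library()].
#' @param replicons replicon table (`name`, `length`) naming the known
#'   replicon set; records on unknown replicons are a rejection error.
#' @return A [tag_library()].
#' @export
load_tag_library <- function(path, sample_id, protein, role,
                             bio_rep = 1L, tech_rep = 1L, replicons) {
  gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                 error = function(e) {
                   bad <- .first_malformed_bed_line(path)
                   stop("malformed BED record in '", path, "'",
                        if (!is.na(bad)) paste0(" at line ", bad), ": ",
                        conditionMessage(e), call. = FALSE)
                 })
  if (length(gr) == 0L) stop("tag library '", sample_id, "' has no tags")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  # rtracklayer yields 1-based closed intervals; 5' of + is start-1 in 0-based,
  # 5' of - is end-1.
  pos <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1L,
                GenomicRanges::end(gr) - 1L)
  tags <- data.frame(replicon = as.character(GenomicRanges::seqnames(gr)),
                     pos = as.integer(pos), strand = strand,
                     stringsAsFactors = FALSE)
  tag_library(sample_id, protein, role, bio_rep, tech_rep, tags,
              replicons = replicons)
}

.first_malformed_bed_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (grepl("^(#|track|browser)", lines[i]) || !nzchar(lines[i])) next
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) < 3L || is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3])))) {
      return(i)
    }
  }
  NA_integer_
}

#' Write a tag library as BED
#'
#' Tags are written as 1-nt intervals covering the 5' base, so that
#' [load_tag_library()] round-trips the positions exactly.
#'
#' @param lib a [tag_library()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tag_library <- function(lib, path) {
  stopifnot(inherits(lib, "tag_library"))
  t <- lib$tags
  df <- data.frame(t$replicon, t$pos, t$pos + 1L,
                   paste0(lib$sample_id, "_", seq_len(nrow(t))), 0L, t$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a genome annotation from GFF3
#'
#' Replicon lengths are taken from `##sequence-region` pragmas. 1-based closed
#' GFF coordinates are converted to the internal 0-based half-open convention.
#' Feature types are mapped from the GFF `type` column through `type_map`.
#'
#' @param path GFF3 file with `##sequence-region` pragmas.
#' @param type_map named character vector mapping GFF types to the internal
#'   feature types; GFF types absent from the map are skipped.
#' @return A [genome_annotation()].
#' @export
load_annotation <- function(path,
                            type_map = c(gene = "coding_gene",
                                         ncRNA = "ncRNA",
                                         repeat_region = "repeat_element",
                                         pseudogene = "pseudogene")) {
  pragmas <- grep("^##sequence-region", readLines(path, warn = FALSE),
                  value = TRUE)
  if (!length(pragmas)) {
    stop("GFF3 file lacks ##sequence-region pragmas: ", path)
  }
  pf <- do.call(rbind, strsplit(trimws(pragmas), "[ \t]+"))
  replicons <- data.frame(name = pf[, 2],
                          length = as.numeric(pf[, 4]),
                          stringsAsFactors = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% names(type_map)
  gr <- gr[keep]
  meta <- S4Vectors_mcols(gr)
  locus <- if ("ID" %in% names(meta)) as.character(meta$ID) else NA_character_
  nm <- if ("Name" %in% names(meta)) as.character(meta$Name) else NA_character_
  features <- data.frame(
    locus_id = locus,
    type = unname(type_map[as.character(gr$type)]),
    replicon = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    name = nm,
    stringsAsFactors = FALSE)
  if (any(is.na(features$locus_id))) stop("GFF3 feature without ID attribute")
  genome_annotation(replicons, features)
}

# mcols() without importing all of S4Vectors into the NAMESPACE surface
S4Vectors_mcols <- function(x) GenomicRanges::mcols(x)

#' Write a genome annotation as GFF3
#'
#' Deterministic writer (no date stamps) emitting `##sequence-region` pragmas,
#' so that identical inputs give byte-identical files and
#' [load_annotation()] round-trips exactly.
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @param type_map named character vector, inverse of the [load_annotation()]
#'   mapping (internal type -> GFF type).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path,
                             type_map = c(coding_gene = "gene",
                                          ncRNA = "ncRNA",
                                          repeat_element = "repeat_region",
                                          pseudogene = "pseudogene")) {
  stopifnot(inherits(annotation, "genome_annotation"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d",
                     annotation$replicons$name,
                     as.integer(annotation$replicons$length)), con)
  f <- annotation$features
  if (nrow(f)) {
    attrs <- paste0("ID=", f$locus_id,
                    ifelse(is.na(f$name), "", paste0(";Name=", f$name)))
    writeLines(paste(f$replicon, "rsmtargets", unname(type_map[f$type]),
                     f$start + 1L, f$end, ".", f$strand, ".", attrs,
                     sep = "\t"), con)
  }
  invisible(path)
}

PEAK_COLUMNS <- c("replicon", "start", "end", "length", "summit", "tag_count",
                  "pv_score", "fold_enrichment", "fdr_percent")

#' Write a peak table as TSV
#'
#' Columns are fixed (`replicon`, `start`, `end`, `length`, `summit`,
#' `tag_count`, `pv_score`, `fold_enrichment`, `fdr_percent`); real-valued
#' scores are serialized at 4 decimal places so outputs are diff-stable.
#'
#' @param peaks peak data.frame as returned by [call_peaks()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  peaks <- as.data.frame(peaks, stringsAsFactors = FALSE)
  if (nrow(peaks) && !"length" %in% names(peaks)) {
    peaks$length <- peaks$end - peaks$start
  }
  if (nrow(peaks) == 0L) {
    peaks <- stats::setNames(
      data.frame(character(), integer(), integer(), integer(), integer(),
                 integer(), numeric(), numeric(), numeric()),
      PEAK_COLUMNS)
  }
  missing <- setdiff(PEAK_COLUMNS, names(peaks))
  if (length(missing)) stop("peak table lacks columns: ",
                            paste(missing, collapse = ", "))
  out <- peaks[, PEAK_COLUMNS, drop = FALSE]
  for (col in c("pv_score", "fold_enrichment", "fdr_percent")) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA, sprintf("%.4f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak table written by [write_peak_table()]
#'
#' @param path TSV file.
#' @return peak data.frame; a header-only file gives an empty table.
#' @export
read_peak_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(replicon = "character"))
  missing <- setdiff(PEAK_COLUMNS, names(df))
  if (length(missing)) {
    stop("peak table schema error, missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in c("start", "end", "length", "summit", "tag_count")) {
    df[[col]] <- as.integer(df[[col]])
  }
  for (col in c("pv_score", "fold_enrichment", "fdr_percent")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write a per-position coverage vector as bedGraph
#'
#' Runs of equal coverage are merged; zero-coverage runs are omitted. The sum
#' of interval lengths times values equals the total coverage mass of the
#' input vector.
#'
#' @param coverage non-negative numeric vector; element `i` is the coverage of
#'   0-based position `i - 1`.
#' @param replicon replicon name.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coverage_track <- function(coverage, replicon, path) {
  if (any(coverage < 0)) stop("negative coverage value")
  r <- rle(as.numeric(coverage))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values > 0
  gr <- GenomicRanges::GRanges(
    rep(replicon, sum(keep)),
    IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
    score = r$values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
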