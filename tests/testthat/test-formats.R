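replicons <- data.frame(name = "chr1", length = 1000)

test_that("BED tags load at their 5' coordinate and bad records are rejected", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t175\tt1\t0\t+",
               "chr1\t100\t175\tt2\t0\t-"), bed)
  lib <- load_tag_library(bed, "s1", "RsmA", "pulldown", replicons = replicons)
  expect_equal(lib$tags$pos, c(100L, 174L))
  expect_equal(lib$tags$strand, c("+", "-"))

  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chrX\t5\t30\tt1\t0\t+", bad)
  expect_error(load_tag_library(bad, "s1", "RsmA", "pulldown",
                                replicons = replicons), "chrX")

  mal <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t20\tt\t0\t+", "chr1\toops"), mal)
  expect_error(load_tag_library(mal, "s1", "RsmA", "pulldown",
                                replicons = replicons), "line 2")
})

test_that("tag libraries round-trip through BED", {
  set.seed(11)
  tags <- data.frame(replicon = "chr1", pos = sample.int(1000, 50) - 1L,
                     strand = sample(c("+", "-"), 50, replace = TRUE))
  lib <- tag_library("s1", "RsmE", "total_control", 1, 1, tags,
                     replicons = replicons)
  f <- withr::local_tempfile(fileext = ".bed")
  write_tag_library(lib, f)
  back <- load_tag_library(f, "s1", "RsmE", "total_control",
                           replicons = replicons)
  expect_equal(back$tags$pos, tags$pos)
  expect_equal(back$tags$strand, tags$strand)
})

test_that("tag library invariants are enforced", {
  expect_error(tag_library("s", "RsmA", "pulldown", 1, 1,
                           data.frame(replicon = character(), pos = integer(),
                                      strand = character())), "no tags")
  expect_error(tag_library("s", "RsmA", "pulldown", 1, 1,
                           data.frame(replicon = "chr1", pos = 1000L,
                                      strand = "+"),
                           replicons = replicons), "bounds")
})

test_that("GFF3 coordinates convert and annotations round-trip byte-identically", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chr1 1 1000",
               "chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=L1;Name=gA",
               "chr1\tsrc\tncRNA\t101\t150\t.\t-\t.\tID=L2"), gff)
  ann <- load_annotation(gff)
  expect_equal(ann$features$start, c(10L, 100L))
  expect_equal(ann$features$end, c(20L, 150L))
  expect_equal(ann$features$type, c("coding_gene", "ncRNA"))
  expect_equal(ann$replicons$length, 1000)

  out1 <- withr::local_tempfile(fileext = ".gff3")
  out2 <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, out1)
  write_annotation(load_annotation(out1), out2)
  expect_identical(readLines(out1), readLines(out2))
  expect_equal(load_annotation(out1)$features, ann$features)
})

test_that("annotation validation rejects duplicates and out-of-bounds features", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "##sequence-region chr1 1 1000",
               "chr1\tsrc\tgene\t1\t20\t.\t+\t.\tID=PP_0001",
               "chr1\tsrc\tgene\t30\t40\t.\t+\t.\tID=PP_0001"), gff)
  expect_error(load_annotation(gff), "duplicate")
  expect_error(
    genome_annotation(replicons,
                      data.frame(locus_id = "a", type = "coding_gene",
                                 replicon = "chr1", start = 990, end = 1010,
                                 strand = "+")),
    "beyond replicon")
})

test_that("peak tables round-trip at 4 decimals, empty table included", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_peak_table(data.frame(), f)
  expect_equal(nrow(read_peak_table(f)), 0L)

  one <- data.frame(replicon = "chr1", start = 100L, end = 300L,
                    length = 200L, summit = 180L, tag_count = 55L,
                    pv_score = 123.4567, fold_enrichment = 3.21,
                    fdr_percent = 0)
  write_peak_table(one, f)
  expect_equal(read_peak_table(f)$length, 200L)

  set.seed(42)
  n <- 50
  starts <- cumsum(sample(50:500, n))
  peaks <- data.frame(
    replicon = "chr1", start = starts, end = starts + sample(20:400, n),
    summit = starts + 5L, tag_count = sample.int(5000, n),
    pv_score = round(runif(n, 0, 3000), 4),
    fold_enrichment = round(runif(n, 0, 50), 4),
    fdr_percent = round(runif(n, 0, 100), 4))
  peaks$length <- peaks$end - peaks$start
  peaks <- peaks[, c("replicon", "start", "end", "length", "summit",
                     "tag_count", "pv_score", "fold_enrichment", "fdr_percent")]
  write_peak_table(peaks, f)
  back <- read_peak_table(f)
  expect_equal(back, peaks)

  broken <- withr::local_tempfile(fileext = ".tsv")
  writeLines("replicon\tstart\tend", broken)
  expect_error(read_peak_table(broken), "schema")
})

test_that("coverage tracks are run-length merged and reconstruct exactly", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  write_coverage_track(c(0, 2, 2, 1), "chr1", f)
  got <- read.table(f, sep = "\t")
  expect_equal(got$V2, c(1, 3))           # 0-based starts
  expect_equal(got$V3, c(3, 4))
  expect_equal(got$V4, c(2, 1))

  write_coverage_track(rep(0, 10), "chr1", f)
  expect_equal(length(readLines(f)), 0L)

  expect_error(write_coverage_track(c(1, -1), "chr1", f), "negative")

  set.seed(7)
  cov <- sample(0:5, 1e4, replace = TRUE)
  write_coverage_track(cov, "chr1", f)
  tr <- read.table(f, sep = "\t")
  rebuilt <- numeric(1e4)
  for (i in seq_len(nrow(tr))) rebuilt[(tr$V2[i] + 1):tr$V3[i]] <- tr$V4[i]
  expect_equal(rebuilt, as.numeric(cov))
  expect_equal(sum((tr$V3 - tr$V2) * tr$V4), sum(cov))
})
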