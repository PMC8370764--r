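test_that("AIRR tables parse with segment-level gene normalization", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(
    "junction\tjunction_aa\tv_call\tj_call\tduplicate_count\tproductive",
    "TGTGCAAGCTTT\tCASF\tTRBV3*01\tTRBJ2-5*02\t5\tT",
    "TGTGCAAGCTTC\tCASF\ttcrbv12-1\tTRBJ1-1\t2\tT",
    "TGTGCAAGCT\t\tTRBV2\tTRBJ2-3\t3\tF"
  ), tsv)
  recs <- read_airr_table(tsv)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$v_call, c("TRBV3", "TRBV12-1", "TRBV2"))
  expect_equal(recs$j_call, c("TRBJ2-5", "TRBJ1-1", "TRBJ2-3"))
  expect_equal(recs$read_count, c(5L, 2L, 3L))
  expect_equal(recs$productive, c(TRUE, TRUE, FALSE))
})

test_that("missing required columns and malformed rows are hard errors", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("junction\tv_call\tj_call\tproductive",
               "TGT\tTRBV3\tTRBJ1-1\tT"), tsv)
  expect_error(read_airr_table(tsv), "duplicate_count")

  bad_count <- tempfile(fileext = ".tsv")
  writeLines(c(
    "junction\tv_call\tj_call\tduplicate_count\tproductive",
    "TGTGCA\tTRBV3\tTRBJ1-1\t0\tT"
  ), bad_count)
  expect_error(read_airr_table(bad_count), "count")

  empty <- tempfile(fileext = ".tsv")
  file.create(empty)
  expect_error(read_airr_table(empty), "empty")
})

test_that("legacy dialect reading is equivalent to AIRR reading", {
  recs <- make_records(5, count = c(2, 3, 4, 5, 6))
  recs$v_call <- c("TRBV3", "TRBV2", "TRBV3", "TRBV19", "TRBV2")
  airr <- write_airr_tmp(recs)
  legacy <- tempfile(fileext = ".tsv")
  writeLines(c(
    "CDR3nt\tV\tJ\tcount\tinFrame",
    sprintf("%s\t%s\t%s\t%d\t%d", recs$cdr3_nt, recs$v_call, recs$j_call,
            recs$read_count, as.integer(recs$productive))
  ), legacy)
  from_airr <- read_airr_table(airr)
  from_legacy <- read_legacy_table(legacy, "clonocalc")
  expect_equal(from_legacy, from_airr)

  expect_error(read_legacy_table(legacy, "no_such_dialect"), "unknown")
  expect_error(read_legacy_table(airr, "clonocalc"), "dialect")
  header_only <- tempfile(fileext = ".tsv")
  writeLines("CDR3nt\tV\tJ\tcount\tinFrame", header_only)
  expect_error(read_legacy_table(header_only, "clonocalc"), "empty")
})

test_that("write/read round trip is lossless and conserves reads", {
  set.seed(42)
  recs <- make_records(100, count = sample.int(500, 100, replace = TRUE),
                       productive = sample(c(TRUE, FALSE), 100,
                                           replace = TRUE))
  recs$v_call <- sample(c("TRBV3", "TRBV2", "TRBV19"), 100, replace = TRUE)
  recs$j_call <- sample(c("TRBJ2-5", "TRBJ1-1"), 100, replace = TRUE)
  back <- read_airr_table(write_airr_tmp(recs))
  expect_equal(back, recs)
  expect_equal(sum(back$read_count), sum(recs$read_count))

  empty <- recs[0, , drop = FALSE]
  back0 <- read_airr_table(write_airr_tmp(empty))
  expect_equal(nrow(back0), 0)
})

test_that("manifests validate uniqueness and resolve relative paths", {
  dir <- tempfile()
  dir.create(dir)
  man <- data.frame(
    sample_id = c("s1", "s2"), mouse_id = c("m1", "m1"),
    group = "Ag1", site = c("pln_left", "pln_right"),
    timepoint_weeks = 4, capture = "laser_GC",
    path = c("s1.tsv", "s2.tsv"), stringsAsFactors = FALSE
  )
  p <- file.path(dir, "manifest.tsv")
  write_manifest(man, p)
  got <- read_manifest(p)
  expect_equal(got$sample_id, c("s1", "s2"))
  expect_equal(got$path, file.path(dir, c("s1.tsv", "s2.tsv")))

  dup <- man
  dup$site <- "pln_left"  # same mouse+site+timepoint twice
  write_manifest(dup, p)
  expect_error(read_manifest(p), "duplicate")

  bad <- man
  bad$group <- "Mystery"
  write_manifest(bad, p)
  expect_error(read_manifest(p), "group")
})
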