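test_that("aggregation merges by key, sums counts, ignores record order", {
  recs <- data.frame(
    cdr3_nt = c("TGTGCATTT", "TGTGCATTT"), cdr3_aa = "",
    v_call = "TRBV3", j_call = "TRBJ2-5",
    read_count = c(2L, 3L), productive = TRUE, stringsAsFactors = FALSE
  )
  rep <- aggregate_repertoire(recs)
  expect_equal(rep$n_unique, 1)
  expect_equal(rep$clonotypes$read_count, 5L)
  expect_equal(rep$clonotypes$frequency, 1)

  # same CDR3, different V: distinct under nt_vj, merged under nt_only
  recs2 <- recs
  recs2$v_call <- c("TRBV3", "TRBV2")
  expect_equal(aggregate_repertoire(recs2, "nt_vj")$n_unique, 2)
  expect_equal(aggregate_repertoire(recs2, "nt_only")$n_unique, 1)

  set.seed(7)
  many <- make_records(50, count = sample.int(20, 50, replace = TRUE))
  shuffled <- many[sample.int(nrow(many)), , drop = FALSE]
  rownames(shuffled) <- NULL
  expect_equal(aggregate_repertoire(shuffled), aggregate_repertoire(many))
})

test_that("aggregation is a commutative, associative reduction", {
  set.seed(11)
  recs <- make_records(200, count = sample.int(30, 200, replace = TRUE))
  # duplicate some keys across chunks so merging actually sums
  recs <- rbind(recs, recs[sample.int(200, 80), , drop = FALSE])
  full <- aggregate_repertoire(recs)
  for (i in 1:5) {
    cut <- sample(seq_len(nrow(recs) - 1), 1)
    part <- merge_repertoires(
      aggregate_repertoire(recs[seq_len(cut), , drop = FALSE]),
      aggregate_repertoire(recs[(cut + 1):nrow(recs), , drop = FALSE])
    )
    expect_equal(part$clonotypes, full$clonotypes)
    expect_equal(part$n_total_reads, full$n_total_reads)
  }
})

test_that("annotation filter keeps productive clonotypes with copy >= 2", {
  recs <- rbind(
    make_records(cdr3 = "AAAGGGTTT", count = 5L, productive = TRUE),
    make_records(cdr3 = "AAAGGGTTC", count = 1L, productive = TRUE),
    make_records(cdr3 = "AAAGGGTTAT", count = 4L, productive = FALSE)
  )
  rep <- annotation_filter(aggregate_repertoire(recs))
  expect_equal(rep$n_unique, 1)
  expect_equal(rep$clonotypes$cdr3_nt, "AAAGGGTTT")
  expect_equal(rep$clonotypes$frequency, 1)
  expect_equal(rep$filter_log$n_before, 3L)
  expect_equal(rep$filter_log$n_after, 1L)

  # idempotent; no-op case only renormalizes
  again <- annotation_filter(rep)
  expect_equal(again$clonotypes, rep$clonotypes)

  # inconsistent productive flags within one clonotype are rejected
  mixed <- rbind(
    make_records(cdr3 = "AAAGGGTTT", count = 2L, productive = TRUE),
    make_records(cdr3 = "AAAGGGTTT", count = 2L, productive = FALSE)
  )
  expect_error(annotation_filter(aggregate_repertoire(mixed)),
               "inconsistent")
})

test_that("above-median filter is strict, with pinned boundary behavior", {
  rep <- make_repertoire(c(5, 4, 3, 2, 2))
  out <- median_abundance_filter(rep)
  expect_equal(out$n_unique, 2)
  expect_equal(sort(out$clonotypes$read_count), c(4L, 5L))
  expect_equal(sum(out$clonotypes$frequency), 1, tolerance = 1e-9)

  # all counts at the median: nothing is strictly above it
  expect_warning(out2 <- median_abundance_filter(make_repertoire(c(2, 2, 2))),
                 "all clonotypes")
  expect_equal(out2$n_unique, 0)
  expect_equal(out2$filter_log$n_after[1], 0L)

  expect_warning(out3 <- median_abundance_filter(make_repertoire(10)),
                 "all clonotypes")
  expect_equal(out3$n_unique, 0)
})

test_that("filters only remove, and survivor frequencies stay proportional", {
  set.seed(13)
  for (i in 1:10) {
    rep <- random_repertoire(60)
    rep$clonotypes$productive <- sample(c(TRUE, FALSE), 60, replace = TRUE,
                                        prob = c(0.9, 0.1))
    out <- suppressWarnings(filter_repertoire(rep))
    expect_true(all(out$clonotypes$key %in% rep$clonotypes$key))
    if (out$n_unique > 1) {
      before <- rep$clonotypes$frequency[
        match(out$clonotypes$key, rep$clonotypes$key)]
      ratio <- out$clonotypes$frequency / before
      expect_lt(diff(range(ratio)), 1e-9)
      expect_equal(sum(out$clonotypes$frequency), 1, tolerance = 1e-9)
    }
  }
})
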