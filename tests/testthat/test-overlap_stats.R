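test_that("Morisita-Horn matches hand-computed and boundary cases", {
  a <- make_repertoire(c(2, 2), cdr3 = c("AAA", "CCC"))
  b <- make_repertoire(c(1, 1, 2), cdr3 = c("AAA", "CCC", "GGG"))
  expect_equal(morisita_horn(a, b), 4 / 7, tolerance = 1e-15)
  expect_equal(morisita_horn(b, a), 4 / 7, tolerance = 1e-15)

  expect_identical(morisita_horn(a, a), 1)
  disjoint <- make_repertoire(c(3, 4), cdr3 = c("TTT", "GGG"))
  expect_identical(morisita_horn(a, disjoint), 0)

  empty <- aggregate_repertoire(make_records(0))
  expect_error(morisita_horn(a, empty), "undefined")
  other_key <- make_repertoire(c(1, 1), cdr3 = c("AAA", "CCC"))
  other_key$key_mode <- "aa_vj"
  expect_error(morisita_horn(a, other_key), "key")
})

test_that("Morisita-Horn agrees with the per-clonotype scan oracle", {
  set.seed(101)
  for (i in 1:20) {
    a <- random_repertoire(sample(10:80, 1), universe_size = 100)
    b <- random_repertoire(sample(10:80, 1), universe_size = 100)
    expect_equal(morisita_horn(a, b), oracle_mhi(a, b), tolerance = 1e-12)
  }
})

test_that("overlap table lists shared clonotypes in percent, ordered", {
  a <- make_repertoire(c(2, 2), cdr3 = c("AAA", "CCC"))
  b <- make_repertoire(c(1, 1, 2), cdr3 = c("AAA", "CCC", "GGG"))
  tab <- overlap_table(a, b)
  expect_equal(nrow(tab), 2)
  row1 <- tab[tab$key == paste("AAA", "TRBV3", "TRBJ2-5", sep = "|"), ]
  expect_equal(row1$freq_a, 50)
  expect_equal(row1$freq_b, 25)
  expect_true(all(diff(tab$freq_a) <= 0))

  disjoint <- make_repertoire(c(3, 4), cdr3 = c("TTT", "GGG"))
  expect_equal(nrow(overlap_table(a, disjoint)), 0)
  self_tab <- overlap_table(b, b)
  expect_equal(self_tab$freq_a, self_tab$freq_b)
})

test_that("overlap regression behaves on exact and independent data", {
  a <- make_repertoire(c(8, 4, 2, 1), cdr3 = c("AAA", "CCC", "GGG", "TTT"))
  tab <- overlap_table(a, a)
  fit <- overlap_regression(tab)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$slope, 1, tolerance = 1e-12)

  two <- tab[1:2, ]
  expect_equal(overlap_regression(two)$r_squared, 1, tolerance = 1e-12)
  expect_error(overlap_regression(tab[1, , drop = FALSE]), "insufficient")

  set.seed(5)
  indep <- data.frame(key = sprintf("k%03d", 1:100),
                      freq_a = runif(100, 0.01, 10),
                      freq_b = runif(100, 0.01, 10))
  expect_lt(overlap_regression(indep)$r_squared, 0.1)
  fit_log <- overlap_regression(indep, transform = "log10")
  expect_true(fit_log$r_squared >= 0 && fit_log$r_squared <= 1)
})

test_that("top clonotypes use deterministic tie-breaking and cap at size", {
  rep <- make_repertoire(c(5, 4, 3, 3, 1),
                         cdr3 = c("AAA", "CCC", "TTT", "GGG", "CGC"))
  top1 <- top_clonotypes(rep, 1)
  expect_equal(top1$cdr3_nt, "AAA")
  top4 <- top_clonotypes(rep, 4)
  # tie at count 3 between GGG and TTT: lexicographically smaller key wins
  expect_equal(top4$cdr3_nt, c("AAA", "CCC", "GGG", "TTT"))
  expect_message(all5 <- top_clonotypes(rep, 10), "only")
  expect_equal(nrow(all5), 5)
})

test_that("relative intersection counts presence and is monotone", {
  top <- make_repertoire(c(5, 4), cdr3 = c("AAA", "CCC"))$clonotypes
  sup <- make_repertoire(c(1, 1, 1), cdr3 = c("AAA", "CCC", "GGG"))
  expect_equal(relative_intersection(top, sup), 100)
  dis <- make_repertoire(c(1, 1), cdr3 = c("TTT", "GGG"))
  expect_equal(relative_intersection(top, dis), 0)

  twenty <- make_repertoire(rep(2, 20),
                            cdr3 = sprintf("AAA%02d", 1:20))$clonotypes
  eleven <- make_repertoire(rep(2, 11),
                            cdr3 = sprintf("AAA%02d", 1:11))
  expect_equal(relative_intersection(twenty, eleven), 55)

  set.seed(3)
  base <- random_repertoire(30, universe_size = 60)
  bigger <- merge_repertoires(base, random_repertoire(30, universe_size = 60))
  expect_gte(relative_intersection(twenty, bigger),
             relative_intersection(twenty, base))
})

test_that("sharing spectrum counts clonotypes by multiplicity", {
  sets <- list(m1 = c("a", "b"), m2 = c("b", "c"), m3 = c("b", "d"))
  st <- sharing_counts(sets)
  expect_equal(unname(st$counts), c(3L, 0L, 1L))
  expect_equal(st$members[["3"]], "b")
  expect_equal(sum(st$counts), length(unique(unlist(sets))))

  same <- list(m1 = letters[1:5], m2 = letters[1:5], m3 = letters[1:5])
  expect_equal(unname(sharing_counts(same)$counts), c(0L, 0L, 5L))

  disj <- list(m1 = c("a", "b"), m2 = c("c"), m3 = c("d", "e"))
  expect_equal(unname(sharing_counts(disj)$counts), c(5L, 0L, 0L))

  vs <- c(a = "TRBV3", b = "TRBV3", c = "TRBV2", d = "TRBV19")
  bk <- sharing_counts(sets, v_calls = vs)$segment_breakdown
  expect_equal(unname(as.integer(bk[["3"]]["TRBV3"])), 1L)
  expect_equal(sum(bk[["1"]]), 3)
})

test_that("venn regions decompose three sets exactly", {
  sets <- list(x = c("a", "b", "s"), y = c("b", "c", "s"), z = c("s", "d"))
  v <- venn_regions(sets)
  expect_equal(unname(v["x"]), 1L)          # a
  expect_equal(unname(v["x&y"]), 1L)        # b
  expect_equal(unname(v["x&y&z"]), 1L)      # s
  expect_equal(sum(v), length(unique(unlist(sets))))
})

test_that("group summary applies exact rank tests at small n", {
  res <- mhi_group_summary(c(0.4, 0.5, 0.45, 0.1, 0.15, 0.12),
                           rep(c("hi", "lo"), each = 3),
                           alternative = "greater")
  expect_equal(res$test, "mann_whitney_u")
  expect_equal(res$statistic, 9)
  expect_equal(res$p_value, 0.05, tolerance = 1e-12)

  same <- suppressWarnings(
    mhi_group_summary(c(0.3, 0.3, 0.3, 0.3), c("a", "a", "b", "b")))
  expect_equal(same$p_value, 1)

  kw <- suppressWarnings(mhi_group_summary(rep(0.2, 9),
                                           rep(c("a", "b", "c"), each = 3)))
  expect_equal(kw$test, "kruskal_wallis")
  expect_error(mhi_group_summary(c(1, 2), c("a", "b")), "insufficient")
})
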