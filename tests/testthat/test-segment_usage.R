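panel_sjl <- gene_panel("SJL")

test_that("usage tables support both weightings and zero-fill the panel", {
  recs <- rbind(
    make_records(cdr3 = "AAAGGG", v = "TRBV2", count = 6L),
    make_records(cdr3 = "CCCGGG", v = "TRBV3", count = 2L)
  )
  rep <- aggregate_repertoire(recs)
  rw <- usage_table(rep, "TRBV", panel_sjl, "read_weighted")
  expect_equal(rw$frequency[rw$segment == "TRBV2"], 0.75)
  expect_equal(rw$frequency[rw$segment == "TRBV3"], 0.25)
  cw <- usage_table(rep, "TRBV", panel_sjl, "clonotype_weighted")
  expect_equal(cw$frequency[cw$segment == "TRBV2"], 0.5)
  expect_equal(cw$frequency[cw$segment == "TRBV3"], 0.5)
  for (tab in list(rw, cw)) {
    expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
    expect_true(all(tab$frequency[!tab$segment %in%
                                    c("TRBV2", "TRBV3")] == 0))
    expect_setequal(setdiff(panel_sjl$present_v, tab$segment), character(0))
  }

  solo <- aggregate_repertoire(make_records(3, v = "TRBV3"))
  st <- usage_table(solo, "TRBV", panel_sjl)
  expect_equal(st$frequency[st$segment == "TRBV3"], 1)
})

test_that("segments deleted from the strain panel raise off-panel warnings", {
  rep <- aggregate_repertoire(make_records(2, v = "TRBV13-1"))
  expect_warning(tab <- usage_table(rep, "TRBV", panel_sjl), "off-panel")
  expect_false(tab$in_panel[tab$segment == "TRBV13-1"])
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
})

test_that("Sidak adjustment follows the closed form and its identities", {
  p <- c(0.001, 0.01, 0.05, 0.2)
  expect_equal(sidak_adjust(p, 1), p)
  for (m in c(5, 20)) {
    expect_equal(sidak_adjust(p, m), 1 - (1 - p)^m)
    expect_true(all(sidak_adjust(p, m) >= p))
  }
})

test_that("usage comparison handles identical, separated and degenerate cases", {
  mk_tab <- function(f_v3, seed) {
    set.seed(seed)
    f_v3 <- f_v3 + 0.003 * (seed %% 7)  # keep replicate values untied
    segs <- panel_sjl$present_v
    noise <- runif(length(segs) - 1)
    f <- c(f_v3, (1 - f_v3) * noise / sum(noise))
    rep <- make_repertoire(pmax(2L, as.integer(1000 * f)),
                           cdr3 = sprintf("AAA%02d", seq_along(segs)),
                           v = c("TRBV3", setdiff(segs, "TRBV3")))
    usage_table(rep, "TRBV", panel_sjl)
  }
  a <- lapply(1:3, function(i) mk_tab(0.6, i))
  b <- lapply(1:3, function(i) mk_tab(0.05, 100 + i))
  cmp <- compare_usage(a, b)
  v3 <- cmp[cmp$segment == "TRBV3", ]
  # complete 3-vs-3 separation: exact Mann-Whitney floor of 2/20
  expect_equal(v3$p, 0.1, tolerance = 1e-12)
  expect_equal(v3$p_sidak, 1 - (1 - v3$p)^v3$m, tolerance = 1e-12)
  expect_true(all(cmp$p_sidak >= cmp$p, na.rm = TRUE))

  same <- compare_usage(a, a)
  expect_true(all(is.na(same$p) | same$p > 0.99))
  # zero variance in both groups with equal means: untestable, not p = 1
  const <- lapply(1:2, function(i) {
    rep <- aggregate_repertoire(make_records(2, v = "TRBV3"))
    usage_table(rep, "TRBV", panel_sjl)
  })
  cc <- compare_usage(const, const)
  expect_true(all(is.na(cc$p)))
  expect_equal(unique(cc$m), 0)

  cmp_aov <- compare_usage(a, b, method = "anova")
  expect_lt(cmp_aov[cmp_aov$segment == "TRBV3", "p"], 0.05)
})
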