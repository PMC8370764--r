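small_cfg <- function(seed = 1, n_mice = 1, depth = 1e5, ...) {
  synth_config(seed = seed, n_mice = n_mice, n_background_clones = 200L,
               depth = depth, ...)
}

test_that("identical configurations give identical outputs", {
  cfg <- small_cfg(seed = 99)
  u1 <- sample_clone_universe(cfg)
  u2 <- sample_clone_universe(cfg)
  expect_identical(u1$mice, u2$mice)
  s1 <- simulate_sequencing(u1)
  s2 <- simulate_sequencing(u2)
  expect_identical(s1, s2)
})

test_that("adding mice never perturbs existing mice", {
  u2 <- sample_clone_universe(small_cfg(seed = 4, n_mice = 2))
  u3 <- sample_clone_universe(small_cfg(seed = 4, n_mice = 3))
  expect_identical(u2$mice[[1]], u3$mice[[1]])
  expect_identical(u2$mice[[2]], u3$mice[[2]])
})

test_that("latent frequencies are a valid paired structure", {
  cfg <- small_cfg(seed = 2)
  u <- sample_clone_universe(cfg)
  df <- u$mice[[1]]
  expect_equal(sum(df$freq_left), 1, tolerance = 1e-12)
  expect_equal(sum(df$freq_right), 1, tolerance = 1e-12)
  dom <- df[df$role == "dominant", ]
  expect_equal(nrow(dom), cfg$n_dominant_shared)
  expect_equal(sum(dom$freq_left), cfg$dominant_mass, tolerance = 1e-12)
  expect_equal(sum(dom$freq_right), cfg$dominant_mass, tolerance = 1e-12)
  # dominant clones present on both sides; background private to one side
  expect_true(all(dom$freq_left > 0 & dom$freq_right > 0))
  bg <- df[df$role == "background" & !df$public, ]
  expect_true(all((bg$freq_left > 0) != (bg$freq_right > 0)))
  # in-frame CDR3s translate consistently
  expect_true(all(nchar(dom$cdr3_nt) == 3 * nchar(dom$cdr3_aa)))
  expect_equal(translate_nt(dom$cdr3_nt[1]), dom$cdr3_aa[1])

  pbs <- sample_clone_universe(small_cfg(seed = 2, group = "PBS_like"))
  expect_false(any(pbs$mice[[1]]$role == "dominant"))
  expect_error(synth_config(n_dominant_shared = 0L, dominant_mass = 0.5),
               "configuration")
})

test_that("perfect correlation gives identical dominant frequencies", {
  u <- sample_clone_universe(
    small_cfg(seed = 8, left_right_dominant_correlation = 1))
  dom <- u$mice[[1]][u$mice[[1]]$role == "dominant", ]
  expect_equal(dom$freq_left, dom$freq_right, tolerance = 1e-12)
})

test_that("sequencing conserves depth and recovers latent frequencies", {
  cfg <- small_cfg(seed = 3)
  ss <- simulate_sequencing(sample_clone_universe(cfg))
  for (s in ss) {
    expect_equal(sum(s$records$read_count), cfg$depth)
  }

  # one clone at latent frequency 0.5 sequenced at 1e6: binomial 3-sigma
  cfg2 <- small_cfg(seed = 6, dominant_mass = 0.5, n_dominant_shared = 1L,
                    nonproductive_fraction = 0, depth = 1e6)
  u2 <- sample_clone_universe(cfg2)
  s2 <- simulate_sequencing(u2)[[1]]
  dom_key <- u2$mice[[1]][u2$mice[[1]]$role == "dominant", "cdr3_nt"]
  obs <- s2$records$read_count[s2$records$cdr3_nt == dom_key] / cfg2$depth
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / cfg2$depth))
})

test_that("nonproductive decoys appear at the configured rate and are filtered", {
  cfg <- small_cfg(seed = 5, nonproductive_fraction = 0.3)
  s <- simulate_sequencing(sample_clone_universe(cfg))[[1]]
  rep <- aggregate_repertoire(s$records)
  frac_nonprod <- mean(!rep$clonotypes$productive)
  expect_gt(frac_nonprod, 0.22)
  expect_lt(frac_nonprod, 0.38)
  filt <- annotation_filter(rep)
  expect_true(all(filt$clonotypes$productive))
})

test_that("time decay shrinks the early dominant block but keeps it present", {
  cfg <- small_cfg(seed = 10)
  u <- sample_clone_universe(cfg)
  same <- apply_time_decay(u, decay_factor = 1)
  expect_identical(same$mice, u$mice)

  late <- apply_time_decay(u, decay_factor = 0.3)
  df <- late$mice[[1]]
  dom <- df[df$role == "dominant", ]
  expect_equal(sum(dom$freq_left), cfg$dominant_mass * 0.3, tolerance = 1e-12)
  expect_equal(sum(dom$freq_right), cfg$dominant_mass * 0.3,
               tolerance = 1e-12)
  expect_true(all(dom$freq_left > 0))
  expect_true(any(df$role == "late_dominant"))
  expect_equal(sum(df$freq_left), 1, tolerance = 1e-12)
  expect_equal(sum(df$freq_right), 1, tolerance = 1e-12)
  # late-emerging dominants are private per side
  ld <- df[df$role == "late_dominant", ]
  expect_true(all((ld$freq_left > 0) != (ld$freq_right > 0)))
})

test_that("written studies round trip through the manifest reader", {
  cfg <- small_cfg(seed = 12, depth = 2e4)
  u <- sample_clone_universe(cfg)
  ss <- simulate_sequencing(u)
  dir <- tempfile("study")
  manifest_path <- write_synth_study(ss, dir, universes = list(u))
  man <- read_manifest(manifest_path)
  expect_equal(nrow(man), 2)
  recs <- read_airr_table(man$path[1])
  expect_equal(sum(recs$read_count), cfg$depth)
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})
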