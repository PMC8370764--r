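# Seeded generator of paired left/right TCRbeta repertoires emulating the
# clonal structure of an antigen-driven paired-lymph-node study: a small
# dominant clonotype block shared between the two draining nodes of one
# individual, a heavy-tailed mostly-private background with a public pool,
# strain-restricted V/J usage with antigen-specific TRBV enrichment, and
# temporal decay of the dominant block.

#' Configuration of the paired-repertoire generative model
#'
#' All parameters of the generator, including the RNG seed; an identical
#' configuration yields bit-identical output tables. Defaults emulate the
#' study conditions the package targets: per-sample unique-clonotype counts
#' of order 3 x 10^3, read depths of 10^6, 20 dominant clonotypes shared
#' between the left and right node of one individual carrying half of the
#' read mass in the antigen condition, and a mostly private Zipf background.
#'
#' @param seed Master RNG seed; every sample derives its own stream from it.
#' @param n_mice Number of individuals in the group.
#' @param group `"Ag_like"` (shared dominant block, TRBV3-enriched),
#'   `"PBS_like"` (no dominant block) or `"GST_like"` (weaker, less
#'   correlated dominant block).
#' @param strain Panel strain, default `"SJL"`.
#' @param n_background_clones Background clones per sample (default 3000).
#' @param n_dominant_shared Size D of the shared dominant block (default 20).
#' @param dominant_mass Total frequency mass s of the dominant block per
#'   sample; group-specific default (Ag 0.5, GST 0.15, PBS 0).
#' @param background_public_fraction Probability that a background clone is
#'   drawn from the cross-mouse public pool (default 0.1).
#' @param public_pool_size Size of the shared public pool (default 500).
#' @param clone_size_law `"zipf"` (default) or `"lognormal"` for background
#'   clone sizes.
#' @param zipf_alpha Zipf exponent of the background law (default 1).
#' @param dominant_zipf_alpha Zipf exponent within the dominant block
#'   (default 0.5: dominant clone sizes are flatter than the background
#'   tail, spanning roughly one order of magnitude across the block).
#' @param lognormal_sdlog Log-sd for the lognormal law (default 2).
#' @param left_right_dominant_correlation In \[0, 1\]; 1 means identical
#'   dominant frequencies on both sides, smaller values add independent
#'   log-normal jitter with log-sd `0.8 * (1 - correlation)` per side
#'   (default 0.5).
#' @param depth Sequencing depth in reads per sample (default 1e6).
#' @param decay_factor Multiplier on the dominant-block mass at a later
#'   timepoint (default 0.3).
#' @param nonproductive_fraction Fraction of a sample's unique clones that
#'   are out-of-frame decoys (default 0.05).
#' @param decoy_mass Total frequency mass of the decoy block (default 0.02;
#'   forced to 0 when `nonproductive_fraction` is 0).
#' @param singleton_decoy_rate Extra productive singleton records appended
#'   per observed clonotype after sequencing, to exercise the copy-number
#'   filter (default 0; note a nonzero rate adds reads beyond `depth`).
#' @param v_usage,j_usage Optional named probability vectors over the
#'   panel's segments for background clones; default uniform over the panel.
#' @param dominant_v_usage,dominant_j_usage Same for dominant clones;
#'   default boosts TRBV3 (weight 0.5) and TRBJ2-5 (weight 0.3) in the
#'   `Ag_like` group.
#' @param timepoint_weeks Timepoint label of the base universe (default 4).
#' @param panel_path Gene-panel TSV, see [load_gene_panels()].
#' @return A `synth_config` object (validated list).
#' @export
synth_config <- function(seed = 1L,
                         n_mice = 3L,
                         group = c("Ag_like", "PBS_like", "GST_like"),
                         strain = "SJL",
                         n_background_clones = 3000L,
                         n_dominant_shared = 20L,
                         dominant_mass = NULL,
                         background_public_fraction = 0.1,
                         public_pool_size = 500L,
                         clone_size_law = c("zipf", "lognormal"),
                         zipf_alpha = 1,
                         dominant_zipf_alpha = 0.5,
                         lognormal_sdlog = 2,
                         left_right_dominant_correlation = 0.5,
                         depth = 1e6,
                         decay_factor = 0.3,
                         nonproductive_fraction = 0.05,
                         decoy_mass = 0.02,
                         singleton_decoy_rate = 0,
                         v_usage = NULL, j_usage = NULL,
                         dominant_v_usage = NULL, dominant_j_usage = NULL,
                         timepoint_weeks = 4,
                         panel_path = system.file("extdata",
                                                  "gene_panels.tsv",
                                                  package = "tcrshare")) {
  group <- match.arg(group)
  clone_size_law <- match.arg(clone_size_law)
  panel <- gene_panel(strain, panel_path)
  if (is.null(dominant_mass)) {
    dominant_mass <- switch(group, Ag_like = 0.5, GST_like = 0.15,
                            PBS_like = 0)
  }
  if (n_dominant_shared == 0 && dominant_mass > 0) {
    stop("configuration error: dominant_mass > 0 requires ",
         "n_dominant_shared > 0")
  }
  stopifnot(dominant_mass >= 0, dominant_mass < 1,
            background_public_fraction >= 0, background_public_fraction <= 1,
            left_right_dominant_correlation >= 0,
            left_right_dominant_correlation <= 1,
            decay_factor > 0, decay_factor <= 1,
            nonproductive_fraction >= 0, nonproductive_fraction < 1,
            depth >= 1, n_background_clones >= 1, n_mice >= 1)
  if (nonproductive_fraction == 0) decoy_mass <- 0
  if (decoy_mass + dominant_mass >= 1) {
    stop("dominant_mass + decoy_mass must be < 1 to leave background mass")
  }
  norm_usage <- function(u, segs, default_boost = NULL) {
    if (is.null(u)) {
      u <- stats::setNames(rep(1, length(segs)), segs)
      if (!is.null(default_boost)) {
        boost_seg <- intersect(names(default_boost), segs)
        u[boost_seg] <- default_boost[boost_seg] * sum(u)
      }
    }
    if (is.null(names(u)) || !all(names(u) %in% segs)) {
      stop("usage map must be named by segments of the ", panel$strain,
           " panel")
    }
    full <- stats::setNames(rep(0, length(segs)), segs)
    full[names(u)] <- u
    full / sum(full)
  }
  ag <- group == "Ag_like"
  cfg <- structure(list(
    seed = as.integer(seed), n_mice = as.integer(n_mice), group = group,
    strain = strain, panel = panel,
    n_background_clones = as.integer(n_background_clones),
    n_dominant_shared = as.integer(n_dominant_shared),
    dominant_mass = dominant_mass,
    background_public_fraction = background_public_fraction,
    public_pool_size = as.integer(public_pool_size),
    clone_size_law = clone_size_law, zipf_alpha = zipf_alpha,
    dominant_zipf_alpha = dominant_zipf_alpha,
    lognormal_sdlog = lognormal_sdlog,
    left_right_dominant_correlation = left_right_dominant_correlation,
    depth = depth, decay_factor = decay_factor,
    nonproductive_fraction = nonproductive_fraction,
    decoy_mass = decoy_mass,
    singleton_decoy_rate = singleton_decoy_rate,
    v_usage = norm_usage(v_usage, panel$present_v),
    j_usage = norm_usage(j_usage, panel$present_j),
    dominant_v_usage = norm_usage(
      dominant_v_usage, panel$present_v,
      if (ag) c(TRBV3 = 0.5) else NULL),
    dominant_j_usage = norm_usage(
      dominant_j_usage, panel$present_j,
      if (ag) c("TRBJ2-5" = 0.3) else NULL),
    timepoint_weeks = timepoint_weeks
  ), class = "synth_config")
  stopifnot(abs(sum(cfg$v_usage) - 1) < 1e-9,
            abs(sum(cfg$j_usage) - 1) < 1e-9,
            abs(sum(cfg$dominant_v_usage) - 1) < 1e-9,
            abs(sum(cfg$dominant_j_usage) - 1) < 1e-9)
  cfg
}

# n random clones with V/J drawn from usage maps (assumes RNG already seeded)
draw_clones <- function(n, v_usage, j_usage, productive = TRUE) {
  if (n == 0L) {
    return(data.frame(cdr3_nt = character(0), cdr3_aa = character(0),
                      v_call = character(0), j_call = character(0),
                      productive = logical(0), stringsAsFactors = FALSE))
  }
  cdr3 <- if (productive) random_cdr3(n) else random_cdr3_nonproductive(n)
  cdr3$v_call <- sample(names(v_usage), n, replace = TRUE, prob = v_usage)
  cdr3$j_call <- sample(names(j_usage), n, replace = TRUE, prob = j_usage)
  cdr3$productive <- productive
  cdr3
}

# Background clone sizes. Under the zipf law the background occupies the
# ranks *below* the dominant block of the same power law (ranks offset+1 ..
# offset+n, renormalized), so the largest private background clone stays
# smaller than the smallest shared dominant clone — the scale separation
# that makes the sample's top clonotypes the shared ones.
background_weights <- function(cfg, n, offset = 0L) {
  if (cfg$clone_size_law == "zipf") {
    w <- (offset + seq_len(n))^(-cfg$zipf_alpha)
    w <- w / sum(w)
  } else {
    w <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$lognormal_sdlog)
    w <- w / sum(w)
  }
  # random rank assignment so clone identity is independent of clone size
  sample(w)
}

#' Sample the latent clone universe of a group
#'
#' Draws, for every mouse of the configured group, the latent clone
#' definitions and true frequencies of its left and right samples: a
#' dominant block of `n_dominant_shared` clones shared between the two
#' sides with correlated frequencies and total mass `dominant_mass` per
#' side (absent when that mass is 0, as in the PBS-like group); a
#' heavy-tailed background private to each side except for draws from a
#' cross-mouse public pool; and a small block of out-of-frame decoy clones.
#' Each (mouse, side, block) uses its own RNG stream derived from the master
#' seed, so adding mice or sides never perturbs existing samples.
#'
#' @param config A [synth_config()] object.
#' @return A `clone_universe` object: list with `config`,
#'   `timepoint_weeks`, and `mice` — a named list of per-mouse data frames
#'   with columns `cdr3_nt`, `cdr3_aa`, `v_call`, `j_call`, `productive`,
#'   `role` (dominant/background/decoy), `public`, `freq_left`,
#'   `freq_right` (each side's frequencies sum to 1).
#' @export
sample_clone_universe <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  pool <- with_seed(derive_seed(cfg$seed, "public_pool"), {
    draw_clones(cfg$public_pool_size, cfg$v_usage, cfg$j_usage)
  })
  s <- cfg$dominant_mass
  d_n <- if (s > 0) cfg$n_dominant_shared else 0L
  f_pub <- cfg$background_public_fraction
  n_real <- d_n + cfg$n_background_clones
  n_decoy <- if (cfg$nonproductive_fraction > 0) {
    max(1L, round(cfg$nonproductive_fraction * n_real /
                    (1 - cfg$nonproductive_fraction)))
  } else 0L
  decoy_mass <- if (n_decoy > 0) cfg$decoy_mass else 0
  bg_mass <- 1 - s - decoy_mass
  sdlog <- (1 - cfg$left_right_dominant_correlation) * 0.8

  mice <- list()
  for (m in seq_len(cfg$n_mice)) {
    mouse_id <- sprintf("%s_m%d", cfg$group, m)
    blocks <- list()
    if (d_n > 0) {
      blocks$dominant <- with_seed(
        derive_seed(cfg$seed, "mouse", m, "dominant"), {
          cl <- draw_clones(d_n, cfg$dominant_v_usage, cfg$dominant_j_usage)
          base <- zipf_weights(d_n, cfg$dominant_zipf_alpha)
          jit_l <- if (sdlog > 0) exp(stats::rnorm(d_n, 0, sdlog)) else 1
          jit_r <- if (sdlog > 0) exp(stats::rnorm(d_n, 0, sdlog)) else 1
          wl <- base * jit_l
          wr <- base * jit_r
          cl$role <- "dominant"
          cl$public <- FALSE
          cl$freq_left <- s * wl / sum(wl)
          cl$freq_right <- s * wr / sum(wr)
          cl
        })
    }
    for (side in c("left", "right")) {
      blk <- with_seed(derive_seed(cfg$seed, "mouse", m, side, "background"), {
        n_bg <- cfg$n_background_clones
        n_pub <- stats::rbinom(1, n_bg, f_pub)
        n_pub <- min(n_pub, nrow(pool))
        pub <- if (n_pub > 0) {
          pool[sample.int(nrow(pool), n_pub), , drop = FALSE]
        } else pool[0, , drop = FALSE]
        priv <- draw_clones(n_bg - n_pub, cfg$v_usage, cfg$j_usage)
        cl <- rbind(pub, priv)
        cl$role <- "background"
        cl$public <- c(rep(TRUE, n_pub), rep(FALSE, n_bg - n_pub))
        w <- background_weights(cfg, n_bg, offset = d_n)
        cl$freq_left <- if (side == "left") bg_mass * w else 0
        cl$freq_right <- if (side == "right") bg_mass * w else 0
        if (n_decoy > 0) {
          dec <- draw_clones(n_decoy, cfg$v_usage, cfg$j_usage,
                             productive = FALSE)
          dec$role <- "decoy"
          dec$public <- FALSE
          wd <- zipf_weights(n_decoy, cfg$zipf_alpha)
          dec$freq_left <- if (side == "left") decoy_mass * wd else 0
          dec$freq_right <- if (side == "right") decoy_mass * wd else 0
          cl <- rbind(cl, dec)
        }
        cl
      })
      blocks[[side]] <- blk
    }
    df <- do.call(rbind, unname(blocks))
    rownames(df) <- NULL
    df <- collapse_duplicate_clones(df)
    mice[[mouse_id]] <- df
  }
  structure(list(config = cfg, timepoint_weeks = cfg$timepoint_weeks,
                 mice = mice),
            class = "clone_universe")
}

# a randomly drawn clone may (rarely) collide with an existing key, e.g. a
# public-pool clone drawn on both sides; merge by summing per-side mass
collapse_duplicate_clones <- function(df) {
  key <- paste(df$cdr3_nt, df$v_call, df$j_call, sep = "|")
  if (!anyDuplicated(key)) return(df)
  fl <- rowsum(df$freq_left, key, reorder = FALSE)
  fr <- rowsum(df$freq_right, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$freq_left <- fl[match(key[first], rownames(fl)), 1]
  out$freq_right <- fr[match(key[first], rownames(fr)), 1]
  rownames(out) <- NULL
  out
}

#' Advance a clone universe to a later timepoint
#'
#' Multiplies the dominant-block mass of every sample by `decay_factor`,
#' keeping the early dominant clones present at reduced frequency (never
#' deleting them). The freed mass is redistributed half to newly drawn
#' late-emerging dominant clones, private to each side, and half
#' proportionally to the background — so late samples have new private
#' dominants while the early dominants linger at low frequency, which is
#' what produces the asymmetric early-vs-late top-20 intersection.
#'
#' @param universe A [sample_clone_universe()] result.
#' @param decay_factor In (0, 1\]; 1 returns the universe unchanged apart
#'   from the timepoint label.
#' @param timepoint_weeks Timepoint label of the decayed universe.
#' @return A new `clone_universe`.
#' @export
apply_time_decay <- function(universe,
                             decay_factor = universe$config$decay_factor,
                             timepoint_weeks = universe$timepoint_weeks + 5) {
  stopifnot(inherits(universe, "clone_universe"),
            decay_factor > 0, decay_factor <= 1)
  cfg <- universe$config
  out <- universe
  out$timepoint_weeks <- timepoint_weeks
  if (decay_factor == 1) return(out)
  for (m in seq_along(out$mice)) {
    df <- out$mice[[m]]
    dom <- which(df$role == "dominant")
    bg <- which(df$role == "background")
    for (side in c("left", "right")) {
      col <- paste0("freq_", side)
      s_side <- sum(df[[col]][dom])
      if (s_side == 0) next
      freed <- s_side * (1 - decay_factor)
      df[[col]][dom] <- df[[col]][dom] * decay_factor
      bg_side <- bg[df[[col]][bg] > 0]
      bg_tot <- sum(df[[col]][bg_side])
      if (bg_tot > 0) {
        df[[col]][bg_side] <- df[[col]][bg_side] *
          (bg_tot + freed / 2) / bg_tot
        late_mass <- freed / 2
      } else {
        late_mass <- freed
      }
      late <- with_seed(
        derive_seed(cfg$seed, "mouse", m, side, "late", timepoint_weeks), {
          cl <- draw_clones(cfg$n_dominant_shared, cfg$dominant_v_usage,
                            cfg$dominant_j_usage)
          w <- zipf_weights(cfg$n_dominant_shared, cfg$dominant_zipf_alpha)
          cl$role <- "late_dominant"
          cl$public <- FALSE
          cl$freq_left <- if (side == "left") late_mass * w else 0
          cl$freq_right <- if (side == "right") late_mass * w else 0
          cl
        })
      df <- rbind(df, late)
    }
    rownames(df) <- NULL
    out$mice[[m]] <- collapse_duplicate_clones(df)
  }
  out
}

#' Simulate sequencing of a clone universe
#'
#' Draws read counts for every sample by multinomial sampling of the latent
#' frequencies at the configured depth (clones sampled zero times are absent
#' from the output, emulating finite sequencing depth). Optionally appends
#' productive singleton decoy records at `singleton_decoy_rate` per observed
#' clonotype, which the copy-number filter is meant to remove.
#'
#' @param universe A `clone_universe`.
#' @param depth Reads per sample (default from the configuration).
#' @return Named list of samples; each element is a list with `meta` (named
#'   list: sample_id, mouse_id, group, site, timepoint_weeks, capture) and
#'   `records` (a clonotype record `data.frame` as from
#'   [read_airr_table()]).
#' @export
simulate_sequencing <- function(universe, depth = universe$config$depth) {
  stopifnot(inherits(universe, "clone_universe"))
  cfg <- universe$config
  tp <- universe$timepoint_weeks
  samples <- list()
  for (m in seq_along(universe$mice)) {
    mouse_id <- names(universe$mice)[m]
    df <- universe$mice[[m]]
    for (side in c("left", "right")) {
      col <- paste0("freq_", side)
      present <- df[[col]] > 0
      sub <- df[present, , drop = FALSE]
      freq <- sub[[col]] / sum(sub[[col]])
      counts <- with_seed(
        derive_seed(cfg$seed, "mouse", m, side, "seq", tp), {
          k <- as.vector(stats::rmultinom(1, size = depth, prob = freq))
          extra <- NULL
          if (cfg$singleton_decoy_rate > 0) {
            n_obs <- sum(k > 0)
            n_sing <- round(cfg$singleton_decoy_rate * n_obs)
            if (n_sing > 0) {
              extra <- draw_clones(n_sing, cfg$v_usage, cfg$j_usage)
            }
          }
          list(k = k, extra = extra)
        })
      keep <- counts$k > 0
      records <- data.frame(
        cdr3_nt = sub$cdr3_nt[keep], cdr3_aa = sub$cdr3_aa[keep],
        v_call = sub$v_call[keep], j_call = sub$j_call[keep],
        read_count = counts$k[keep], productive = sub$productive[keep],
        stringsAsFactors = FALSE
      )
      if (!is.null(counts$extra)) {
        extra <- counts$extra
        records <- rbind(records, data.frame(
          cdr3_nt = extra$cdr3_nt, cdr3_aa = extra$cdr3_aa,
          v_call = extra$v_call, j_call = extra$j_call,
          read_count = 1L, productive = TRUE, stringsAsFactors = FALSE
        ))
      }
      sample_id <- sprintf("%s_%s_w%g", mouse_id, side, tp)
      samples[[sample_id]] <- list(
        meta = list(sample_id = sample_id, mouse_id = mouse_id,
                    group = cfg$group,
                    site = if (side == "left") "pln_left" else "pln_right",
                    timepoint_weeks = tp, capture = "laser_GC"),
        records = records
      )
    }
  }
  samples
}

#' Write a simulated study to disk
#'
#' Writes one AIRR TSV per sample, a manifest TSV, and a ground-truth JSON
#' (configuration echo plus the dominant-clone identities and latent
#' frequencies per mouse) into `dir`.
#'
#' @param samples Concatenated sample lists from [simulate_sequencing()]
#'   (possibly several groups/timepoints).
#' @param dir Output directory (created if needed).
#' @param universes Optional list of `clone_universe` objects to record in
#'   the ground-truth file.
#' @return The manifest path, invisibly.
#' @export
write_synth_study <- function(samples, dir, universes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (s in samples) {
    fname <- paste0(s$meta$sample_id, ".tsv")
    write_airr_table(s$records, file.path(dir, fname))
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = s$meta$sample_id, mouse_id = s$meta$mouse_id,
      group = s$meta$group, site = s$meta$site,
      timepoint_weeks = s$meta$timepoint_weeks, capture = s$meta$capture,
      path = fname, stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, manifest_path)
  if (!is.null(universes)) {
    truth <- lapply(universes, function(u) {
      list(
        config = u$config[setdiff(names(u$config), "panel")],
        timepoint_weeks = u$timepoint_weeks,
        dominant_clones = lapply(u$mice, function(df) {
          dom <- df[df$role %in% c("dominant", "late_dominant"), , drop = FALSE]
          dom[, c("cdr3_nt", "v_call", "j_call", "role",
                  "freq_left", "freq_right")]
        })
      )
    })
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(manifest_path)
}
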