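# TRBV/TRBJ segment-usage tables and multiplicity-corrected group
# comparisons, honoring strain-specific gene panels (SJL mice carry genomic
# deletions of roughly half the TRBV locus, so the testable segment family
# differs by strain).

#' Load gene panels from a TSV resource
#'
#' A panel is the closed vocabulary of TRBV/TRBJ segments present in a mouse
#' strain's germline. Panels ship as an editable TSV with columns `strain`,
#' `axis`, `segment`; the bundled file covers a synthetic SJL-like panel
#' (with the strain's characteristic TRBV deletions) and a B6-like full
#' panel. Bundled panels are curated approximations for simulation and
#' testing, not an authoritative germline reference.
#'
#' @param path Panel TSV; defaults to the bundled resource.
#' @return Named list of `gene_panel` objects, one per strain, each a list
#'   with `strain`, `present_v`, `present_j`.
#' @export
load_gene_panels <- function(path = system.file("extdata", "gene_panels.tsv",
                                                package = "tcrshare")) {
  tab <- read_tsv_raw(path)
  needed <- c("strain", "axis", "segment")
  if (!all(needed %in% names(tab))) {
    stop("panel file '", path, "' must have columns ",
         paste(needed, collapse = ", "))
  }
  out <- lapply(split(tab, tab$strain), function(s) {
    structure(list(strain = s$strain[1],
                   present_v = s$segment[s$axis == "TRBV"],
                   present_j = s$segment[s$axis == "TRBJ"]),
              class = "gene_panel")
  })
  out
}

#' Fetch one strain's gene panel
#'
#' @param strain Strain name as listed in the panel resource (`"SJL"` or
#'   `"B6s"` for the bundled file).
#' @param path Panel TSV path, see [load_gene_panels()].
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(strain, path = system.file("extdata",
                                                  "gene_panels.tsv",
                                                  package = "tcrshare")) {
  panels <- load_gene_panels(path)
  if (!strain %in% names(panels)) {
    stop("no panel for strain '", strain, "'; available: ",
         paste(names(panels), collapse = ", "))
  }
  panels[[strain]]
}

#' Segment-usage table for one repertoire
#'
#' Relative usage of TRBV (or TRBJ) segments in a filtered repertoire,
#' either weighted by read mass (`read_weighted`: the summed clonotype
#' frequencies per segment, so expanded clones dominate) or by clonotype
#' counts (`clonotype_weighted`: each unique clonotype counts once).
#' Panel segments not observed are reported with frequency 0; observed
#' segments outside the panel are kept but flagged `in_panel = FALSE` with a
#' warning, since under a correct strain assignment they indicate an
#' annotation problem.
#'
#' @param rep A `tcr_repertoire` (normally after [filter_repertoire()]).
#' @param axis `"TRBV"` or `"TRBJ"`.
#' @param panel A `gene_panel` for the sample's strain.
#' @param weighting `"read_weighted"` (default) or `"clonotype_weighted"`.
#' @return A `data.frame` with columns `sample_id`, `axis`, `segment`,
#'   `frequency`, `in_panel`, `weighting`; frequencies sum to 1.
#' @export
usage_table <- function(rep, axis = c("TRBV", "TRBJ"), panel,
                        weighting = c("read_weighted", "clonotype_weighted")) {
  axis <- match.arg(axis)
  weighting <- match.arg(weighting)
  stopifnot(inherits(rep, "tcr_repertoire"), inherits(panel, "gene_panel"))
  segments <- if (axis == "TRBV") rep$clonotypes$v_call else rep$clonotypes$j_call
  panel_segs <- if (axis == "TRBV") panel$present_v else panel$present_j
  w <- if (weighting == "read_weighted") {
    rep$clonotypes$frequency
  } else {
    if (rep$n_unique > 0) rep(1 / rep$n_unique, rep$n_unique) else numeric(0)
  }
  freq <- stats::setNames(numeric(length(panel_segs)), panel_segs)
  if (length(segments) > 0) {
    obs <- rowsum(w, group = segments, reorder = TRUE)
    obs_segs <- rownames(obs)
    known <- intersect(obs_segs, panel_segs)
    freq[known] <- obs[known, 1]
    off <- setdiff(obs_segs, panel_segs)
    if (length(off) > 0) {
      warning("segment(s) outside the ", panel$strain, " panel: ",
              paste(off, collapse = ", "), "; reported as off-panel")
      freq <- c(freq, stats::setNames(obs[off, 1], off))
    }
  }
  sample_id <- if (!is.null(rep$meta$sample_id)) rep$meta$sample_id else NA
  data.frame(
    sample_id = sample_id, axis = axis, segment = names(freq),
    frequency = unname(freq),
    in_panel = names(freq) %in% panel_segs,
    weighting = weighting,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Sidak family-wise adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` tests; equals `p` at `m = 1` and is
#' monotone in both arguments.
#'
#' @param p Numeric vector of unadjusted p-values.
#' @param m Number of tests in the family.
#' @return Adjusted p-values, same length as `p`.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(m >= 1)
  pmin(1, 1 - (1 - p)^m)
}

#' Compare segment usage between two groups
#'
#' Per-segment two-sample comparison of usage frequencies across replicate
#' samples, with Sidak family-wise correction over the panel segments of one
#' axis. Methods: `"wilcox"` (exact Mann-Whitney when feasible; the default),
#' `"t"` (Welch), or `"anova"` (a two-way group-by-segment fixed-effects fit
#' whose per-segment group contrasts share a pooled error term, the classic
#' "two-way ANOVA with Sidak's multiple comparisons" layout). Segments with
#' zero variance and equal means in both groups carry no information and are
#' reported untestable (`p = NA`) rather than `p = 1`; untestable and
#' off-panel segments are excluded from the correction multiplicity `m`, so
#' strain deletions do not dilute the correction.
#'
#' @param tables_a,tables_b Lists of [usage_table()] outputs (one per
#'   replicate sample), all on the same axis and panel.
#' @param method `"wilcox"`, `"t"`, or `"anova"`.
#' @return A `data.frame` with one row per segment: `segment`, `mean_a`,
#'   `mean_b`, `diff`, `statistic`, `p`, `p_sidak`, `testable`, `m` (the
#'   family size used).
#' @export
compare_usage <- function(tables_a, tables_b,
                          method = c("wilcox", "t", "anova")) {
  method <- match.arg(method)
  stopifnot(length(tables_a) >= 2, length(tables_b) >= 2)
  mat_a <- usage_matrix(tables_a)
  mat_b <- usage_matrix(tables_b)
  if (!identical(rownames(mat_a), rownames(mat_b))) {
    stop("usage tables of the two groups cover different segment panels; ",
         "recompute both under one panel")
  }
  in_panel <- attr(mat_a, "in_panel")
  segs <- rownames(mat_a)
  mean_a <- rowMeans(mat_a)
  mean_b <- rowMeans(mat_b)
  zero_var <- apply(mat_a, 1, stats::var) == 0 &
    apply(mat_b, 1, stats::var) == 0
  testable <- in_panel & !(zero_var & mean_a == mean_b)
  p <- rep(NA_real_, length(segs))
  statistic <- rep(NA_real_, length(segs))
  if (method == "anova") {
    long <- rbind(
      usage_long(mat_a, "A"),
      usage_long(mat_b, "B")
    )
    long <- long[long$segment %in% segs[testable], , drop = FALSE]
    fit <- stats::aov(frequency ~ group * segment, data = long)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    n_a <- ncol(mat_a)
    n_b <- ncol(mat_b)
    for (i in which(testable)) {
      se <- sqrt(mse * (1 / n_a + 1 / n_b))
      statistic[i] <- (mean_a[i] - mean_b[i]) / se
      p[i] <- 2 * stats::pt(-abs(statistic[i]), df = fit$df.residual)
    }
  } else {
    for (i in which(testable)) {
      x <- mat_a[i, ]
      y <- mat_b[i, ]
      if (method == "wilcox") {
        exact <- max(length(x), length(y)) <= 8 && !anyDuplicated(c(x, y))
        ht <- suppressWarnings(
          stats::wilcox.test(x, y, exact = exact, correct = !exact))
      } else {
        ht <- stats::t.test(x, y)
      }
      statistic[i] <- unname(ht$statistic)
      p[i] <- ht$p.value
    }
  }
  m <- sum(testable)
  data.frame(
    segment = segs, mean_a = unname(mean_a), mean_b = unname(mean_b),
    diff = unname(mean_a - mean_b), statistic = statistic, p = p,
    p_sidak = ifelse(is.na(p), NA_real_, sidak_adjust(p, max(m, 1))),
    testable = testable, m = m,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# segments x samples matrix from a list of usage tables; keeps the union of
# segments in first-table order, off-panel flagged via attribute
usage_matrix <- function(tables) {
  segs <- unique(unlist(lapply(tables, `[[`, "segment")))
  in_panel <- rep(TRUE, length(segs))
  mat <- matrix(0, nrow = length(segs), ncol = length(tables),
                dimnames = list(segs, NULL))
  for (j in seq_along(tables)) {
    t_j <- tables[[j]]
    mat[match(t_j$segment, segs), j] <- t_j$frequency
    in_panel[match(t_j$segment, segs)] <- t_j$in_panel
  }
  segs_sorted <- sort(segs)
  perm <- match(segs_sorted, segs)
  out <- mat[perm, , drop = FALSE]
  attr(out, "in_panel") <- in_panel[perm]
  out
}

usage_long <- function(mat, group) {
  data.frame(
    frequency = as.vector(mat),
    segment = rep(rownames(mat), times = ncol(mat)),
    group = group, stringsAsFactors = FALSE
  )
}
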