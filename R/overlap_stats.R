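# Between-repertoire similarity and sharing statistics: Morisita-Horn index,
# shared-clonotype overlap tables with regression, top-N relative
# intersection, cross-individual sharing spectra, and group-level rank tests.

check_comparable <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "tcr_repertoire"), inherits(rep_b, "tcr_repertoire"))
  if (rep_a$key_mode != rep_b$key_mode) {
    stop("repertoires use different clonotype keys ('", rep_a$key_mode,
         "' vs '", rep_b$key_mode, "'); recompute under a common key")
  }
}

#' Morisita-Horn similarity between two repertoires
#'
#' The abundance-weighted similarity
#' \deqn{MHI = \frac{2 \sum_i p_i q_i}{\sum_i p_i^2 + \sum_i q_i^2}}
#' where the sum runs over the union of clonotypes and \eqn{p_i}, \eqn{q_i}
#' are the relative frequencies of clonotype \eqn{i} in the two repertoires
#' (0 where absent). MHI is symmetric and lies in \[0, 1\]: 0 for disjoint
#' clonotype sets, 1 when the frequency vectors coincide. Because the index
#' is quadratic in frequencies it is dominated by the most expanded clones,
#' which is what makes it the statistic of choice for asking whether the
#' *dominant* clonotypes of two sites coincide.
#'
#' An empty repertoire has no defined similarity; this is raised as an error
#' rather than returned as 0, so that samples emptied by filtering surface
#' instead of masquerading as "no overlap".
#'
#' @param rep_a,rep_b `tcr_repertoire` objects under the same key mode.
#' @return A single number in \[0, 1\].
#' @examples
#' recs <- data.frame(
#'   cdr3_nt = c("TGTGCAAGC", "TGTGCAAGG", "TGTGCAAGT"),
#'   cdr3_aa = "", v_call = "TRBV3", j_call = "TRBJ2-5",
#'   read_count = c(2L, 2L, 2L), productive = TRUE)
#' a <- aggregate_repertoire(recs[1:2, ])
#' b <- aggregate_repertoire(recs)
#' morisita_horn(a, b)
#' @export
morisita_horn <- function(rep_a, rep_b) {
  check_comparable(rep_a, rep_b)
  if (rep_a$n_unique == 0 || rep_b$n_unique == 0) {
    stop("Morisita-Horn index is undefined for an empty repertoire ",
         "(did a filter remove all clonotypes?)")
  }
  p <- rep_a$clonotypes$frequency
  q_all <- rep_b$clonotypes$frequency
  idx <- match(rep_a$clonotypes$key, rep_b$clonotypes$key)
  q_on_a <- ifelse(is.na(idx), 0, q_all[idx])
  cross <- sum(p * q_on_a)
  2 * cross / (sum(p^2) + sum(q_all^2))
}

#' Shared-clonotype overlap table
#'
#' Lists exactly the clonotypes present in both repertoires with their
#' frequencies in percent — the data behind a left-vs-right dot plot, one
#' dot per shared clonotype. Rows are ordered by descending `freq_a`, ties
#' broken by key, so the table is deterministic.
#'
#' @inheritParams morisita_horn
#' @return A `data.frame` with columns `key`, `v_call`, `j_call`, `freq_a`,
#'   `freq_b` (percent).
#' @export
overlap_table <- function(rep_a, rep_b) {
  check_comparable(rep_a, rep_b)
  idx <- match(rep_a$clonotypes$key, rep_b$clonotypes$key)
  shared <- which(!is.na(idx))
  out <- data.frame(
    key = rep_a$clonotypes$key[shared],
    v_call = rep_a$clonotypes$v_call[shared],
    j_call = rep_a$clonotypes$j_call[shared],
    freq_a = 100 * rep_a$clonotypes$frequency[shared],
    freq_b = 100 * rep_b$clonotypes$frequency[idx[shared]],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$freq_a, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regression through a shared-clonotype dot plot
#'
#' Ordinary least squares of `freq_b` on `freq_a` over the shared clonotypes,
#' either on the percent scale (`percent_linear`, the default, matching a
#' 0-10 percent dot-plot axis) or after log10 transformation of both axes
#' (`log10`; shared clonotypes always have positive frequencies, so the
#' transform is well defined).
#'
#' @param table Output of [overlap_table()] with at least 2 rows.
#' @param transform `"percent_linear"` or `"log10"`.
#' @return A list with `slope`, `intercept`, `r_squared`, `n` and
#'   `transform`.
#' @export
overlap_regression <- function(table, transform = c("percent_linear", "log10")) {
  transform <- match.arg(transform)
  if (nrow(table) < 2) {
    stop("insufficient data: regression needs at least 2 shared clonotypes, ",
         "got ", nrow(table))
  }
  x <- table$freq_a
  y <- table$freq_b
  if (transform == "log10") {
    x <- log10(x)
    y <- log10(y)
  }
  fit <- stats::lm(y ~ x)
  # collinear data are legitimate here (e.g. identical repertoires);
  # summary()'s perfect-fit warning is expected, not a problem
  r2 <- if (stats::var(y) == 0) 1 else {
    suppressWarnings(summary(fit)$r.squared)
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n = nrow(table), transform = transform)
}

#' Most frequent clonotypes of a repertoire
#'
#' The `n` highest-frequency clonotypes, ties at the cut broken
#' deterministically by key (lexicographic). If the repertoire holds fewer
#' than `n` clonotypes all are returned and a message notes the shortfall.
#'
#' @param rep A `tcr_repertoire`.
#' @param n Number of clonotypes to return (default 20).
#' @return A `data.frame` slice of the repertoire's clonotype table, in rank
#'   order.
#' @export
top_clonotypes <- function(rep, n = 20L) {
  stopifnot(inherits(rep, "tcr_repertoire"), n >= 1)
  if (rep$n_unique < n) {
    message("repertoire has only ", rep$n_unique, " clonotypes (< n = ", n,
            "); returning all")
  }
  utils::head(rep$clonotypes, n)
}

#' Relative intersection of a top-clonotype set with another repertoire
#'
#' The percentage of a given clonotype set (typically the top 20 of one
#' sample) that is present anywhere in another repertoire, regardless of
#' frequency. Used to ask whether initially dominant clonotypes persist at a
#' later timepoint even after their frequencies have decayed.
#'
#' @param top Output of [top_clonotypes()] (or a character vector of keys).
#' @param rep_other The repertoire to look the clonotypes up in.
#' @return Percentage in \[0, 100\].
#' @export
relative_intersection <- function(top, rep_other) {
  stopifnot(inherits(rep_other, "tcr_repertoire"))
  keys <- if (is.character(top)) top else top$key
  if (length(keys) == 0) stop("relative intersection of an empty set")
  100 * sum(keys %in% rep_other$clonotypes$key) / length(keys)
}

#' Cross-individual clonotype sharing spectrum
#'
#' Given one clonotype set per individual (for paired-site designs, the
#' union of that individual's two samples), counts how many distinct
#' clonotypes occur in exactly k of the n individuals, k = 1..n. Clonotypes
#' found in all (or several) individuals of an antigen group are candidate
#' antigen-driven public clonotypes. Presence/absence only; frequencies play
#' no role here.
#'
#' @param sets Named list (length >= 2) of character vectors of clonotype
#'   keys, one per individual.
#' @param v_calls Optional named character vector mapping clonotype key to
#'   TRBV segment, used to break each sharing level down by segment.
#' @param group Optional group label carried into the result.
#' @return A `sharing_table` object: list with `group`, `n_individuals`,
#'   `counts` (named integer vector over k), `members` (list of key vectors
#'   per k) and `segment_breakdown` (list of per-k segment count tables, if
#'   `v_calls` given).
#' @export
sharing_counts <- function(sets, v_calls = NULL, group = NULL) {
  stopifnot(is.list(sets), length(sets) >= 2)
  sets <- lapply(sets, unique)
  all_keys <- unlist(sets, use.names = FALSE)
  multiplicity <- table(all_keys)
  n <- length(sets)
  counts <- integer(n)
  members <- vector("list", n)
  names(counts) <- names(members) <- as.character(seq_len(n))
  breakdown <- if (is.null(v_calls)) NULL else vector("list", n)
  if (!is.null(breakdown)) names(breakdown) <- names(counts)
  for (k in seq_len(n)) {
    mk <- sort(names(multiplicity)[multiplicity == k])
    counts[k] <- length(mk)
    members[[k]] <- mk
    if (!is.null(breakdown)) {
      seg <- v_calls[mk]
      seg[is.na(seg)] <- "unknown"
      breakdown[[k]] <- table(seg)
    }
  }
  structure(
    list(group = group, n_individuals = n, counts = counts,
         members = members, segment_breakdown = breakdown),
    class = "sharing_table"
  )
}

#' @export
print.sharing_table <- function(x, ...) {
  cat("Clonotype sharing spectrum",
      if (!is.null(x$group)) paste0(" (group ", x$group, ")"), "\n", sep = "")
  for (k in seq_len(x$n_individuals)) {
    cat("  in exactly ", k, " of ", x$n_individuals, " individuals: ",
        x$counts[k], " clonotypes\n", sep = "")
  }
  invisible(x)
}

#' Venn-region decomposition for three individuals
#'
#' The 7-region decomposition (a only, b only, c only, ab, ac, bc, abc) of
#' three clonotype sets, as counts.
#'
#' @param sets Named list of exactly 3 character vectors of clonotype keys.
#' @return Named integer vector over the 7 regions, names like `"a"`,
#'   `"ab"`, `"abc"` in terms of the list names.
#' @export
venn_regions <- function(sets) {
  stopifnot(is.list(sets), length(sets) == 3)
  nm <- names(sets)
  if (is.null(nm)) nm <- c("a", "b", "c")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  region <- apply(member, 1, function(row) paste(nm[row], collapse = "&"))
  labels <- c(nm[1], nm[2], nm[3],
              paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
              paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&"))
  out <- stats::setNames(integer(7), labels)
  tab <- table(region)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Group summary and rank test for similarity values
#'
#' Summarises per-pair similarity values (e.g. Morisita-Horn indices) by
#' group and tests for a group difference: a Mann-Whitney U (Wilcoxon
#' rank-sum) test for two groups — exact when both groups have at most 8
#' untied values, the tie-corrected normal approximation otherwise — or a
#' Kruskal-Wallis test for three or more groups.
#'
#' @param values Numeric vector of similarity values.
#' @param groups Vector of group labels, same length.
#' @param alternative Alternative hypothesis for the two-group test
#'   (`"two.sided"`, `"greater"`, `"less"`; `greater` means the first group,
#'   in factor order, tends larger).
#' @return A list with `summary` (data.frame: group, n, mean, sd), `test`
#'   (test name), `statistic` and `p_value`.
#' @export
mhi_group_summary <- function(values, groups, alternative = "two.sided") {
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  split_vals <- split(values, groups)
  sizes <- lengths(split_vals)
  if (any(sizes < 2)) {
    stop("insufficient data: every group needs at least 2 values; group '",
         names(sizes)[sizes < 2][1], "' has ", min(sizes))
  }
  summ <- data.frame(
    group = names(split_vals),
    n = as.integer(sizes),
    mean = vapply(split_vals, mean, numeric(1)),
    sd = vapply(split_vals, stats::sd, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (nlevels(groups) == 2) {
    x <- split_vals[[1]]
    y <- split_vals[[2]]
    if (length(unique(c(x, y))) == 1) {
      # fully tied data carry no rank information: no evidence of difference
      return(list(summary = summ, test = "mann_whitney_u",
                  statistic = length(x) * length(y) / 2, p_value = 1))
    }
    exact <- max(sizes) <= 8 && !anyDuplicated(c(x, y))
    ht <- stats::wilcox.test(x, y, alternative = alternative,
                             exact = exact, correct = !exact)
    list(summary = summ, test = "mann_whitney_u",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  } else {
    ht <- stats::kruskal.test(values, groups)
    list(summary = summ, test = "kruskal_wallis",
         statistic = unname(ht$statistic), p_value = ht$p.value)
  }
}

#' Full pairwise overlap result for one sample pair
#'
#' Convenience wrapper computing the Morisita-Horn index, the shared
#' clonotype table, its regression fit, and the top-N intersection
#' statistics in one call.
#'
#' @inheritParams morisita_horn
#' @param top_n Size of the dominant-clonotype set compared (default 20).
#' @param transform Regression transform, see [overlap_regression()].
#' @return A `pair_overlap` object (list) with fields `sample_a`,
#'   `sample_b`, `mhi`, `n_shared`, `overlap_table`, `regression` (or NULL
#'   if < 2 shared), `top_n`, `top_n_shared`, `relative_intersection_pct`.
#' @export
pair_overlap <- function(rep_a, rep_b, top_n = 20L,
                         transform = "percent_linear") {
  check_comparable(rep_a, rep_b)
  tab <- overlap_table(rep_a, rep_b)
  top <- top_clonotypes(rep_a, top_n)
  res <- list(
    sample_a = if (!is.null(rep_a$meta$sample_id)) rep_a$meta$sample_id else NA,
    sample_b = if (!is.null(rep_b$meta$sample_id)) rep_b$meta$sample_id else NA,
    mhi = morisita_horn(rep_a, rep_b),
    n_shared = nrow(tab),
    overlap_table = tab,
    regression = if (nrow(tab) >= 2) overlap_regression(tab, transform),
    top_n = nrow(top),
    top_n_shared = sum(top$key %in% rep_b$clonotypes$key),
    relative_intersection_pct = relative_intersection(top, rep_b)
  )
  structure(res, class = "pair_overlap")
}

#' @export
print.pair_overlap <- function(x, ...) {
  cat("Pair overlap ", x$sample_a, " vs ", x$sample_b, "\n", sep = "")
  cat(sprintf("  MHI: %.4f   shared clonotypes: %d\n", x$mhi, x$n_shared))
  cat(sprintf("  top-%d shared: %d (%.1f%%)\n", x$top_n, x$top_n_shared,
              x$relative_intersection_pct))
  if (!is.null(x$regression)) {
    cat(sprintf("  regression (%s): slope %.3f, r^2 %.3f\n",
                x$regression$transform, x$regression$slope,
                x$regression$r_squared))
  }
  invisible(x)
}
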