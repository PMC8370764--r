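# Aggregation of rearrangement records into clonotypes under a configurable
# identity key, and the two-stage filter chain: productivity + copy-number
# ("annotation") filter, then the per-sample above-median abundance filter.

KEY_MODES <- c("nt_vj", "aa_vj", "nt_only")

#' Build clonotype identity keys
#'
#' A clonotype is operationally a unique rearrangement; which fields define
#' "unique" is configurable. The default, `nt_vj`, keys on the CDR3
#' nucleotide sequence together with the V and J segment — the strictest of
#' the common conventions. `aa_vj` keys on the amino-acid CDR3 (convergent
#' nucleotide variants merge); `nt_only` ignores segment calls.
#'
#' @param records Clonotype record `data.frame`.
#' @param key_mode One of `"nt_vj"`, `"aa_vj"`, `"nt_only"`.
#' @return Character vector of keys, one per record.
#' @export
clonotype_key <- function(records, key_mode = "nt_vj") {
  key_mode <- match.arg(key_mode, KEY_MODES)
  switch(key_mode,
    nt_vj = paste(records$cdr3_nt, records$v_call, records$j_call, sep = "|"),
    aa_vj = paste(records$cdr3_aa, records$v_call, records$j_call, sep = "|"),
    nt_only = records$cdr3_nt
  )
}

new_repertoire <- function(clonotypes, meta = NULL, key_mode = "nt_vj",
                           filter_log = NULL) {
  if (is.null(filter_log)) {
    filter_log <- data.frame(rule = character(0), n_before = integer(0),
                             n_after = integer(0), stringsAsFactors = FALSE)
  }
  structure(
    list(meta = meta, clonotypes = clonotypes,
         n_total_reads = sum(clonotypes$read_count),
         n_unique = nrow(clonotypes),
         key_mode = key_mode, filter_log = filter_log),
    class = "tcr_repertoire"
  )
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  id <- if (!is.null(x$meta$sample_id)) x$meta$sample_id else "<unnamed>"
  cat("TCRbeta repertoire '", id, "' (key: ", x$key_mode, ")\n", sep = "")
  cat("  clonotypes: ", x$n_unique, "   total reads: ", x$n_total_reads,
      "\n", sep = "")
  if (nrow(x$filter_log) > 0) {
    for (i in seq_len(nrow(x$filter_log))) {
      cat("  filter ", x$filter_log$rule[i], ": ", x$filter_log$n_before[i],
          " -> ", x$filter_log$n_after[i], " clonotypes\n", sep = "")
    }
  }
  invisible(x)
}

# Deterministic clonotype order: descending read count, ties by key. This is
# also the tie-break contract of top_clonotypes().
order_clonotypes <- function(df) {
  df[order(-df$read_count, df$key), , drop = FALSE]
}

#' Aggregate records into a repertoire
#'
#' Sums the read counts of records sharing a clonotype key and computes
#' relative frequencies `read_count / n_total_reads`. The reduction is
#' order-invariant: permuting or splitting the record stream (see
#' [merge_repertoires()]) yields the same repertoire. A clonotype whose
#' constituent records disagree on the productive flag is kept with
#' `productive = NA`; [annotation_filter()] rejects such inconsistencies.
#'
#' @param records Clonotype record `data.frame` (may have zero rows, giving
#'   an empty repertoire).
#' @param key_mode Clonotype identity key, see [clonotype_key()].
#' @param meta Optional named list of sample metadata (carried through).
#' @return A `tcr_repertoire` object.
#' @export
aggregate_repertoire <- function(records, key_mode = "nt_vj", meta = NULL) {
  key_mode <- match.arg(key_mode, KEY_MODES)
  if (nrow(records) == 0) {
    empty <- data.frame(key = character(0), cdr3_nt = character(0),
                        cdr3_aa = character(0), v_call = character(0),
                        j_call = character(0), read_count = integer(0),
                        frequency = numeric(0), productive = logical(0),
                        stringsAsFactors = FALSE)
    return(new_repertoire(empty, meta = meta, key_mode = key_mode))
  }
  records <- validate_records(records)
  key <- clonotype_key(records, key_mode)
  # representative record per key: the highest-count one (ties: first in key
  # order) supplies the descriptive fields not part of the key
  ord <- order(key, -records$read_count)
  rec_o <- records[ord, , drop = FALSE]
  key_o <- key[ord]
  first <- !duplicated(key_o)
  counts <- rowsum(records$read_count, group = key, reorder = TRUE)
  prod_sum <- rowsum(as.integer(records$productive), group = key,
                     reorder = TRUE)
  n_per <- rowsum(rep(1L, nrow(records)), group = key, reorder = TRUE)
  ukey <- key_o[first]
  productive <- ifelse(prod_sum[ukey, 1] == n_per[ukey, 1], TRUE,
                       ifelse(prod_sum[ukey, 1] == 0, FALSE, NA))
  df <- data.frame(
    key = ukey,
    cdr3_nt = rec_o$cdr3_nt[first],
    cdr3_aa = rec_o$cdr3_aa[first],
    v_call = rec_o$v_call[first],
    j_call = rec_o$j_call[first],
    read_count = as.integer(counts[ukey, 1]),
    stringsAsFactors = FALSE
  )
  df$frequency <- df$read_count / sum(df$read_count)
  df$productive <- as.logical(productive)
  df <- order_clonotypes(df)
  rownames(df) <- NULL
  new_repertoire(df, meta = meta, key_mode = key_mode)
}

#' Merge two repertoires built under the same key
#'
#' Sums read counts clonotype-wise, so that aggregating a record stream in
#' arbitrary chunks and merging gives the same result as aggregating it at
#' once. Only meaningful for unfiltered repertoires (filter logs must be
#' empty); merging filtered repertoires would conflate provenance.
#'
#' @param a,b `tcr_repertoire` objects with identical `key_mode`.
#' @return A merged `tcr_repertoire`.
#' @export
merge_repertoires <- function(a, b) {
  stopifnot(inherits(a, "tcr_repertoire"), inherits(b, "tcr_repertoire"))
  if (a$key_mode != b$key_mode) {
    stop("cannot merge repertoires with different key modes ('",
         a$key_mode, "' vs '", b$key_mode, "')")
  }
  if (nrow(a$filter_log) > 0 || nrow(b$filter_log) > 0) {
    stop("cannot merge filtered repertoires; merge before filtering")
  }
  both <- rbind(a$clonotypes, b$clonotypes)
  if (nrow(both) == 0) return(a)
  counts <- rowsum(both$read_count, group = both$key, reorder = TRUE)
  prod_sum <- rowsum(as.integer(both$productive), group = both$key,
                     reorder = TRUE)
  n_per <- rowsum(rep(1L, nrow(both)), group = both$key, reorder = TRUE)
  ord <- order(both$key)
  both_o <- both[ord, , drop = FALSE]
  first <- !duplicated(both_o$key)
  df <- both_o[first, c("key", "cdr3_nt", "cdr3_aa", "v_call", "j_call"),
               drop = FALSE]
  ukey <- df$key
  df$read_count <- as.integer(counts[ukey, 1])
  df$frequency <- df$read_count / sum(df$read_count)
  df$productive <- as.logical(
    ifelse(prod_sum[ukey, 1] == n_per[ukey, 1], TRUE,
           ifelse(prod_sum[ukey, 1] == 0, FALSE, NA)))
  df <- order_clonotypes(df)
  rownames(df) <- NULL
  new_repertoire(df, meta = a$meta, key_mode = a$key_mode)
}

append_filter_log <- function(rep, rule, n_before, n_after) {
  rep$filter_log <- rbind(
    rep$filter_log,
    data.frame(rule = rule, n_before = n_before, n_after = n_after,
               stringsAsFactors = FALSE)
  )
  rep
}

renormalize <- function(rep) {
  rep$n_unique <- nrow(rep$clonotypes)
  rep$n_total_reads <- sum(rep$clonotypes$read_count)
  if (rep$n_unique > 0) {
    rep$clonotypes$frequency <-
      rep$clonotypes$read_count / rep$n_total_reads
  }
  rep
}

#' Productivity and copy-number ("annotation") filter
#'
#' Keeps exactly the clonotypes that are in-frame (productive) and supported
#' by at least `min_count` reads (default 2, discarding singletons that are
#' likely PCR or sequencing artifacts). Frequencies are renormalized over the
#' survivors and the step is appended to the repertoire's filter log. The
#' filter is idempotent.
#'
#' @param rep A `tcr_repertoire`.
#' @param min_count Minimum copy number to retain (default 2).
#' @return The filtered `tcr_repertoire`; empty (with a warning) if nothing
#'   survives.
#' @export
annotation_filter <- function(rep, min_count = 2L) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  inconsistent <- is.na(rep$clonotypes$productive)
  if (any(inconsistent)) {
    stop("clonotype(s) with inconsistent productive flags across records: ",
         paste(utils::head(rep$clonotypes$key[inconsistent], 3),
               collapse = ", "))
  }
  n_before <- rep$n_unique
  keep <- rep$clonotypes$productive &
    rep$clonotypes$read_count >= min_count
  rep$clonotypes <- rep$clonotypes[keep, , drop = FALSE]
  rownames(rep$clonotypes) <- NULL
  rep <- renormalize(rep)
  rep <- append_filter_log(rep, sprintf("annotation(min_count=%d)", min_count),
                           n_before, rep$n_unique)
  if (n_before > 0 && rep$n_unique == 0) {
    warning("annotation filter removed all clonotypes; empty repertoire")
  }
  rep
}

#' Above-median abundance filter
#'
#' Computes the median of the clonotype read counts of this sample and keeps
#' only clonotypes whose count is strictly greater than it. "Above" is read
#' literally: counts equal to the median are removed, so a sample whose
#' counts are all identical empties out (with a warning). The even-count
#' median uses the standard midpoint convention. Because every clonotype of
#' a sample shares the same read total, filtering on counts and on relative
#' abundances is equivalent; counts avoid floating-point median artifacts.
#' This filter is intentionally not idempotent and is applied exactly once,
#' after [annotation_filter()].
#'
#' @param rep A `tcr_repertoire`, normally the output of
#'   [annotation_filter()].
#' @return The filtered `tcr_repertoire`.
#' @export
median_abundance_filter <- function(rep) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  n_before <- rep$n_unique
  if (n_before == 0) {
    return(append_filter_log(rep, "above_median", 0L, 0L))
  }
  med <- stats::median(rep$clonotypes$read_count)
  keep <- rep$clonotypes$read_count > med
  rep$clonotypes <- rep$clonotypes[keep, , drop = FALSE]
  rownames(rep$clonotypes) <- NULL
  rep <- renormalize(rep)
  rep <- append_filter_log(rep, sprintf("above_median(median=%g)", med),
                           n_before, rep$n_unique)
  if (rep$n_unique == 0) {
    warning("above-median filter removed all clonotypes ",
            "(all counts equal the median); empty repertoire")
  }
  rep
}

#' Standard filter chain
#'
#' Applies [annotation_filter()] then [median_abundance_filter()], in that
#' order, which is the order the two rules are meant to compose (the result
#' differs if swapped: the median is taken over annotated clonotypes only).
#'
#' @inheritParams annotation_filter
#' @param median_filter Apply the above-median step (default `TRUE`).
#' @return The filtered `tcr_repertoire`.
#' @export
filter_repertoire <- function(rep, min_count = 2L, median_filter = TRUE) {
  rep <- annotation_filter(rep, min_count = min_count)
  if (median_filter) rep <- median_abundance_filter(rep)
  rep
}
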