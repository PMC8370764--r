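# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately written as plain scans/enumerations, independent of the
# package's match()-based implementations.

# quick clonotype record builder; cdr3 defaults to distinct in-frame strings
make_records <- function(n = NULL, cdr3 = NULL, v = "TRBV3", j = "TRBJ2-5",
                         count = 2L, productive = TRUE, aa = "") {
  if (is.null(cdr3)) {
    stopifnot(!is.null(n))
    cdr3 <- sprintf("TGTGCAAGC%06d", seq_len(n))  # distinct uppercase keys
  }
  n <- length(cdr3)
  data.frame(cdr3_nt = cdr3, cdr3_aa = rep_len(aa, n),
             v_call = rep_len(v, n), j_call = rep_len(j, n),
             read_count = as.integer(rep_len(count, n)),
             productive = rep_len(productive, n),
             stringsAsFactors = FALSE)
}

# repertoire straight from counts (one clonotype per count entry)
make_repertoire <- function(counts, cdr3 = NULL, productive = TRUE,
                            v = "TRBV3", j = "TRBJ2-5", sample_id = NULL) {
  recs <- make_records(n = length(counts), cdr3 = cdr3, v = v, j = j,
                       count = counts, productive = productive)
  meta <- if (!is.null(sample_id)) list(sample_id = sample_id)
  aggregate_repertoire(recs, meta = meta)
}

# random repertoire over a labelled clone universe (keys "c1".."cN")
random_repertoire <- function(n_clones, universe_size = 2 * n_clones,
                              max_count = 50L) {
  keys <- sample(sprintf("c%04d", seq_len(universe_size)), n_clones)
  counts <- sample.int(max_count, n_clones, replace = TRUE)
  make_repertoire(counts, cdr3 = keys)
}

# Morisita-Horn oracle: per-clonotype scan over the union, no match()
oracle_mhi <- function(rep_a, rep_b) {
  ka <- rep_a$clonotypes$key
  kb <- rep_b$clonotypes$key
  pa <- rep_a$clonotypes$frequency
  pb <- rep_b$clonotypes$frequency
  union_keys <- unique(c(ka, kb))
  num <- 0
  d_a <- 0
  d_b <- 0
  for (k in union_keys) {
    p <- 0
    q <- 0
    ia <- which(ka == k)
    ib <- which(kb == k)
    if (length(ia) == 1) p <- pa[ia]
    if (length(ib) == 1) q <- pb[ib]
    num <- num + p * q
    d_a <- d_a + p^2
    d_b <- d_b + q^2
  }
  2 * num / (d_a + d_b)
}

# sharing-spectrum oracle: per-clonotype membership count over the union
oracle_sharing <- function(sets) {
  union_keys <- unique(unlist(sets, use.names = FALSE))
  k_of <- vapply(union_keys, function(key) {
    sum(vapply(sets, function(s) key %in% s, logical(1)))
  }, integer(1))
  counts <- integer(length(sets))
  for (k in seq_along(sets)) counts[k] <- sum(k_of == k)
  names(counts) <- as.character(seq_along(sets))
  counts
}

# write records as an AIRR TSV in a temp file
write_airr_tmp <- function(records) {
  path <- tempfile(fileext = ".tsv")
  write_airr_table(records, path)
  path
}

# filtered left/right repertoire pair from one synthetic mouse
synth_pair <- function(cfg, universe = NULL) {
  if (is.null(universe)) universe <- sample_clone_universe(cfg)
  ss <- simulate_sequencing(universe)
  lapply(ss[1:2], function(s) {
    suppressWarnings(suppressMessages(
      filter_repertoire(aggregate_repertoire(s$records,
                                             meta = s$meta))))
  })
}
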