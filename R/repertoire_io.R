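# Reading and writing clonotype tables (AIRR rearrangement TSV and legacy
# extractor-export dialects) and sample manifests.

AIRR_COLUMNS <- c(cdr3_nt = "junction", cdr3_aa = "junction_aa",
                  v_call = "v_call", j_call = "j_call",
                  read_count = "duplicate_count", productive = "productive")

# junction_aa may legitimately be absent (untranslated tables).
AIRR_REQUIRED <- setdiff(unname(AIRR_COLUMNS), "junction_aa")

#' Normalize V/J gene-segment names
#'
#' Uppercases, trims whitespace, strips allele suffixes (everything from
#' `"*"` on), and applies a synonym table so spelling variants from different
#' upstream tools map to canonical IMGT segment names (e.g. `"TCRBV3*01"`
#' becomes `"TRBV3"`). All analyses in this package operate at segment
#' resolution, so allele information is deliberately discarded on ingest.
#'
#' @param x Character vector of gene calls.
#' @param synonyms Named character vector of regular-expression replacements
#'   applied after basic cleanup (`names` are patterns, values replacements).
#' @return Character vector of normalized segment names.
#' @examples
#' normalize_gene_call(c("TRBV3*01", " tcrbv12-1 ", "TRBJ2-5*02"))
#' @export
normalize_gene_call <- function(x, synonyms = default_gene_synonyms()) {
  x <- toupper(trimws(x))
  x <- sub("\\*.*$", "", x)
  x <- gsub("[[:space:]]+", "", x)
  for (i in seq_along(synonyms)) {
    x <- sub(names(synonyms)[i], synonyms[[i]], x)
  }
  x
}

#' Default gene-name synonym table
#'
#' Maps common upstream spellings (`TCRBV`, `TCRBJ`, `TRBV 3`-style) onto
#' IMGT `TRBV`/`TRBJ` prefixes. Extend or replace via the `synonyms` argument
#' of the readers.
#'
#' @return Named character vector of pattern/replacement pairs.
#' @export
default_gene_synonyms <- function() {
  c("^TCRBV" = "TRBV", "^TCRBJ" = "TRBJ", "^TCRB-?V" = "TRBV",
    "^TCRB-?J" = "TRBJ", "^MTRBV" = "TRBV", "^MTRBJ" = "TRBJ")
}

parse_productive <- function(x, path, true_values = c("T", "TRUE", "1", "YES"),
                             false_values = c("F", "FALSE", "0", "NO")) {
  u <- toupper(trimws(x))
  out <- rep(NA, length(u))
  out[u %in% true_values] <- TRUE
  out[u %in% false_values] <- FALSE
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("unparseable productive flag in '", path, "' at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value '", x[bad[1]], "')")
  }
  out
}

parse_read_count <- function(x, path) {
  n <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(n) | n != floor(n) | n < 1)
  if (length(bad) > 0) {
    stop("invalid read count in '", path, "' at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value '", x[bad[1]], "'); counts must be integers >= 1")
  }
  as.integer(n)
}

validate_records <- function(records, context = "clonotype records") {
  stopifnot(is.data.frame(records))
  needed <- c("cdr3_nt", "cdr3_aa", "v_call", "j_call", "read_count",
              "productive")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop(context, ": missing field(s) ", paste(missing, collapse = ", "))
  }
  if (nrow(records) == 0) return(records)
  bad_v <- !startsWith(records$v_call, "TRBV")
  bad_j <- !startsWith(records$j_call, "TRBJ")
  if (any(bad_v)) {
    stop(context, ": v_call not a TRBV segment after normalization: '",
         records$v_call[which(bad_v)[1]], "'")
  }
  if (any(bad_j)) {
    stop(context, ": j_call not a TRBJ segment after normalization: '",
         records$j_call[which(bad_j)[1]], "'")
  }
  has_aa <- records$productive & nzchar(records$cdr3_aa)
  bad_len <- has_aa & nchar(records$cdr3_nt) != 3L * nchar(records$cdr3_aa)
  if (any(bad_len)) {
    stop(context, ": productive record with inconsistent CDR3 lengths ",
         "(nt must be 3 x aa): '", records$cdr3_nt[which(bad_len)[1]], "'")
  }
  records
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  if (file.size(path) == 0) stop("empty input: '", path, "' has no content")
  utils::read.delim(path, sep = "\t", quote = "", colClasses = "character",
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Read an AIRR rearrangement TSV into clonotype records
#'
#' Parses the columns `junction`, `junction_aa` (optional), `v_call`,
#' `j_call`, `duplicate_count` and `productive` of the AIRR Rearrangement
#' schema. Gene calls are normalized to segment level
#' (see [normalize_gene_call()]); rows with unparseable counts or flags raise
#' an error rather than being dropped, so data corruption is never silent.
#'
#' @param path Path to a tab-separated rearrangement file with a header.
#' @param synonyms Gene-name synonym table passed to [normalize_gene_call()].
#' @return A `data.frame` of clonotype records with columns `cdr3_nt`,
#'   `cdr3_aa`, `v_call`, `j_call`, `read_count` (integer) and `productive`
#'   (logical).
#' @seealso [write_airr_table()], [read_legacy_table()]
#' @export
read_airr_table <- function(path, synonyms = default_gene_synonyms()) {
  tab <- read_tsv_raw(path)
  missing <- setdiff(AIRR_REQUIRED, names(tab))
  if (length(missing) > 0) {
    stop("'", path, "' is not a valid AIRR rearrangement table: missing ",
         "column(s) ", paste(missing, collapse = ", "))
  }
  # a header-only table is a legitimate empty record set (write/read round
  # trip of zero records); a file with no content at all errors above
  records <- data.frame(
    cdr3_nt = toupper(tab[["junction"]]),
    cdr3_aa = if ("junction_aa" %in% names(tab)) {
      toupper(tab[["junction_aa"]])
    } else character(nrow(tab)),
    v_call = normalize_gene_call(tab[["v_call"]], synonyms),
    j_call = normalize_gene_call(tab[["j_call"]], synonyms),
    read_count = parse_read_count(tab[["duplicate_count"]], path),
    productive = parse_productive(tab[["productive"]], path),
    stringsAsFactors = FALSE
  )
  validate_records(records, context = paste0("'", path, "'"))
}

#' Built-in legacy table dialects
#'
#' Column-layout registry for tab-separated clonotype exports of upstream
#' CDR3 extraction tools. Each dialect maps the internal record fields to the
#' dialect's column names and declares how the frame status is encoded.
#' The `"clonocalc"` dialect covers `CDR3nt / CDR3aa / V / J / count /
#' inFrame(1|0)` exports.
#'
#' @return Named list of dialect definitions.
#' @export
legacy_dialects <- function() {
  list(
    clonocalc = list(
      columns = c(cdr3_nt = "CDR3nt", cdr3_aa = "CDR3aa", v_call = "V",
                  j_call = "J", read_count = "count", productive = "inFrame"),
      productive_true = c("1", "TRUE", "T"),
      productive_false = c("0", "FALSE", "F"),
      aa_optional = TRUE
    ),
    mitcr_export = list(
      columns = c(cdr3_nt = "CDR3 nucleotide sequence",
                  cdr3_aa = "CDR3 amino acid sequence",
                  v_call = "V segments", j_call = "J segments",
                  read_count = "Read count", productive = "in-frame"),
      productive_true = c("1", "TRUE", "T", "YES"),
      productive_false = c("0", "FALSE", "F", "NO"),
      aa_optional = TRUE
    )
  )
}

#' Read a legacy clonotype table
#'
#' Reads a tab-separated clonotype export under a registered legacy dialect
#' (see [legacy_dialects()]) and returns records with semantics identical to
#' [read_airr_table()]: the same data read through either path yields the
#' same record collection.
#'
#' @param path Path to the legacy table.
#' @param dialect Name of a registered dialect.
#' @param synonyms Gene-name synonym table.
#' @return A `data.frame` of clonotype records (see [read_airr_table()]).
#' @export
read_legacy_table <- function(path, dialect = "clonocalc",
                              synonyms = default_gene_synonyms()) {
  registry <- legacy_dialects()
  if (!dialect %in% names(registry)) {
    stop("unknown legacy dialect '", dialect, "'; registered dialects: ",
         paste(names(registry), collapse = ", "))
  }
  spec <- registry[[dialect]]
  tab <- read_tsv_raw(path)
  required <- spec$columns
  if (isTRUE(spec$aa_optional)) {
    required <- required[names(required) != "cdr3_aa"]
  }
  missing <- setdiff(unname(required), names(tab))
  if (length(missing) > 0) {
    stop("'", path, "' does not match dialect '", dialect, "': missing ",
         "column(s) ", paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("empty input: '", path, "' contains no records")
  aa_col <- spec$columns[["cdr3_aa"]]
  records <- data.frame(
    cdr3_nt = toupper(tab[[spec$columns[["cdr3_nt"]]]]),
    cdr3_aa = if (aa_col %in% names(tab)) toupper(tab[[aa_col]]) else "",
    v_call = normalize_gene_call(tab[[spec$columns[["v_call"]]]], synonyms),
    j_call = normalize_gene_call(tab[[spec$columns[["j_call"]]]], synonyms),
    read_count = parse_read_count(tab[[spec$columns[["read_count"]]]], path),
    productive = parse_productive(tab[[spec$columns[["productive"]]]], path,
                                  spec$productive_true,
                                  spec$productive_false),
    stringsAsFactors = FALSE
  )
  validate_records(records, context = paste0("'", path, "'"))
}

#' Write clonotype records as an AIRR rearrangement TSV
#'
#' Emits the six modeled AIRR columns as UTF-8, tab-separated, unquoted text.
#' The round trip `read_airr_table(write_airr_table(x))` reproduces `x`
#' exactly on the modeled fields.
#'
#' @param records Clonotype record `data.frame` (see [read_airr_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_airr_table <- function(records, path) {
  records <- validate_records(records)
  out <- data.frame(
    junction = records$cdr3_nt,
    junction_aa = records$cdr3_aa,
    v_call = records$v_call,
    j_call = records$j_call,
    duplicate_count = records$read_count,
    productive = ifelse(records$productive, "T", "F"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

MANIFEST_COLUMNS <- c("sample_id", "mouse_id", "group", "site",
                      "timepoint_weeks", "capture", "path")
MANIFEST_GROUPS <- c("Ag1", "Ag2", "GST", "PBS", "naive",
                     "Ag_like", "PBS_like", "GST_like")
MANIFEST_SITES <- c("pln_left", "pln_right", "skin", "whole_pln")
MANIFEST_CAPTURES <- c("laser_GC", "facs_tfh", "skin_biopsy", "whole_node")

#' Read a sample manifest
#'
#' A manifest is a TSV with columns `sample_id`, `mouse_id`, `group`, `site`,
#' `timepoint_weeks`, `capture`, `path` describing one sequenced sample per
#' row. `path` entries are resolved relative to the manifest's directory
#' unless absolute. Sample ids and `(mouse_id, site, timepoint_weeks)`
#' combinations must be unique.
#'
#' @param path Path to the manifest TSV.
#' @return A `data.frame` with one validated row per sample.
#' @export
read_manifest <- function(path) {
  tab <- read_tsv_raw(path)
  missing <- setdiff(MANIFEST_COLUMNS, names(tab))
  if (length(missing) > 0) {
    stop("manifest '", path, "' is missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (nrow(tab) == 0) stop("empty input: manifest '", path, "' has no samples")
  tab$timepoint_weeks <- as.numeric(tab$timepoint_weeks)
  if (any(is.na(tab$timepoint_weeks) | tab$timepoint_weeks < 0)) {
    stop("manifest '", path, "': timepoint_weeks must be non-negative numbers")
  }
  if (anyDuplicated(tab$sample_id)) {
    stop("manifest '", path, "': duplicate sample_id '",
         tab$sample_id[duplicated(tab$sample_id)][1], "'")
  }
  key <- paste(tab$mouse_id, tab$site, tab$timepoint_weeks)
  if (anyDuplicated(key)) {
    stop("manifest '", path, "': duplicate (mouse_id, site, timepoint) '",
         key[duplicated(key)][1], "'")
  }
  bad_group <- setdiff(unique(tab$group), MANIFEST_GROUPS)
  if (length(bad_group) > 0) {
    stop("manifest '", path, "': unknown group(s) ",
         paste(bad_group, collapse = ", "))
  }
  bad_site <- setdiff(unique(tab$site), MANIFEST_SITES)
  if (length(bad_site) > 0) {
    stop("manifest '", path, "': unknown site(s) ",
         paste(bad_site, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", tab$path)
  tab$path[rel] <- file.path(dirname(path), tab$path[rel])
  tab
}

#' Write a sample manifest
#'
#' @param manifest Manifest `data.frame` (see [read_manifest()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(MANIFEST_COLUMNS, names(manifest))
  if (length(missing) > 0) {
    stop("manifest is missing column(s) ", paste(missing, collapse = ", "))
  }
  utils::write.table(manifest[, MANIFEST_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
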