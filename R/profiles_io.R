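# Readers and writers for the tab-separated tables the pipeline consumes:
# sample x feature abundance matrices, per-sample metadata, and
# module-definition files mapping module IDs to KO sets.

#' Construct an abundance table
#'
#' An abundance table is a dense, non-negative sample x feature matrix tagged
#' with a modality (`"taxon"` for genus-level profiles, `"module"` for
#' KEGG-style functional modules or KO-level precursors) and a unit
#' (`"count"` for read counts, `"relative"` for per-sample proportions).
#'
#' @param values Numeric matrix, samples in rows, features in columns. Both
#'   dimensions must carry unique names.
#' @param modality `"taxon"` or `"module"`.
#' @param unit `"count"` or `"relative"`. For relative tables every row sum
#'   must be at most `1 + 1e-9`.
#' @param feature_annotation Optional named character vector mapping feature
#'   identifiers to a group label (phylum for taxa, KEGG pathway for modules).
#' @return An object of class `abundance_table`: a list with elements
#'   `values`, `modality`, `unit` and `feature_annotation`.
#' @export
abundance_table <- function(values, modality = c("taxon", "module"),
                            unit = c("count", "relative"),
                            feature_annotation = NULL) {
  modality <- match.arg(modality)
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("abundance values must be finite (dense tables, no missing cells)")
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative abundance for sample '%s', feature '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (unit == "relative" && any(rowSums(values) > 1 + 1e-9)) {
    bad <- rownames(values)[rowSums(values) > 1 + 1e-9][1L]
    stop(sprintf("relative abundances of sample '%s' sum to more than 1", bad))
  }
  if (!is.null(feature_annotation)) {
    if (is.null(names(feature_annotation)))
      stop("'feature_annotation' must be a named vector")
    feature_annotation <-
      feature_annotation[names(feature_annotation) %in% colnames(values)]
  }
  structure(list(values = values, modality = modality, unit = unit,
                 feature_annotation = feature_annotation),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d features [%s, %s]\n",
              nrow(x$values), ncol(x$values), x$modality, x$unit))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Subset an abundance table by sample and/or feature
#'
#' @param x An `abundance_table`.
#' @param i Sample index or names.
#' @param j Feature index or names.
#' @param ... Ignored.
#' @return An `abundance_table` over the selected rows/columns.
#' @export
`[.abundance_table` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  abundance_table(v, modality = x$modality, unit = x$unit,
                  feature_annotation = x$feature_annotation)
}

sample_ids <- function(x) rownames(x$values)
feature_ids <- function(x) colnames(x$values)

#' Read an abundance table from a tab-separated file
#'
#' Expects samples as rows: the first column holds sample identifiers, the
#' header row holds feature identifiers, and every remaining cell is numeric.
#'
#' @param path Path to a TSV file.
#' @inheritParams abundance_table
#' @return An `abundance_table`.
#' @export
read_abundance_table <- function(path, modality = c("taxon", "module"),
                                 unit = c("count", "relative")) {
  modality <- match.arg(modality)
  unit <- match.arg(unit)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("abundance table must have a sample-ID column and >= 1 feature")
  ids <- raw[[1L]]
  feats <- colnames(raw)[-1L]
  m <- matrix(NA_real_, nrow(raw), length(feats),
              dimnames = list(ids, feats))
  for (j in seq_along(feats)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & nzchar(trimws(col)))
    if (length(bad) == 0L) bad <- which(is.na(num))
    if (length(bad) > 0L)
      stop(sprintf(
        "malformed numeric cell '%s' at sample '%s', feature '%s' in %s",
        col[bad[1L]], ids[bad[1L]], feats[j], path))
    m[, j] <- num
  }
  abundance_table(m, modality = modality, unit = unit)
}

#' Write an abundance table to a tab-separated file
#'
#' @param x An `abundance_table`.
#' @param path Output path.
#' @param digits Significant digits for the values (default 6).
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, digits = 6L) {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(sample_id = rownames(x$values),
                   signif(x$values, digits), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- sample metadata --------------------------------------------------------

.meta_binary_flags <- c("steroid", "mesalamine", "immunosuppressant",
                        "contraceptive", "antidepressant", "ppi")
.meta_required_cols <- c("sample_id", "age", "sex", "diagnosis", "crp",
                         "fcal", .meta_binary_flags, "hads_d", "weimus")

#' Validate a per-sample metadata table
#'
#' The metadata carries the nuisance covariates (age, sex, diagnosis, CRP and
#' six medication flags), the two inflammation markers and the two
#' psychometric scores: HADS-D (depression subscale, 0-21) and WEIMuS
#' (fatigue, 0-68). CRP (mg/l) and faecal calprotectin (ug/g) may be missing
#' (`NA`); everything else must be complete.
#'
#' @param df A data frame with columns `sample_id`, `age`, `sex` (0/1),
#'   `diagnosis` (`"CD"`/`"UC"`), `crp`, `fcal`, the six medication flags
#'   `steroid`, `mesalamine`, `immunosuppressant`, `contraceptive`,
#'   `antidepressant`, `ppi` (each 0/1), `hads_d` and `weimus`.
#' @return The validated data frame with class `sample_metadata`.
#' @export
sample_metadata <- function(df) {
  missing_cols <- setdiff(.meta_required_cols, colnames(df))
  if (length(missing_cols) > 0L)
    stop("metadata is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifiers in metadata")
  if (any(is.na(df$age)) || any(df$age <= 0))
    stop("age must be positive for every sample")
  if (!all(df$sex %in% c(0, 1)))
    stop("unknown sex code (expected 0/1): ",
         paste(unique(df$sex[!df$sex %in% c(0, 1)]), collapse = ", "))
  if (!all(df$diagnosis %in% c("CD", "UC")))
    stop("unknown diagnosis code (expected CD/UC): ",
         paste(unique(df$diagnosis[!df$diagnosis %in% c("CD", "UC")]),
               collapse = ", "))
  for (fl in .meta_binary_flags)
    if (any(is.na(df[[fl]])) || !all(df[[fl]] %in% c(0, 1)))
      stop(sprintf("medication flag '%s' must be 0/1", fl))
  if (any(is.na(df$hads_d)) || any(df$hads_d < 0 | df$hads_d > 21))
    stop("hads_d outside [0, 21]")
  if (any(is.na(df$weimus)) || any(df$weimus < 0 | df$weimus > 68))
    stop("weimus outside [0, 68]")
  if (any(!is.na(df$crp) & df$crp < 0) || any(!is.na(df$fcal) & df$fcal < 0))
    stop("crp and fcal must be non-negative where present")
  df$sample_id <- as.character(df$sample_id)
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Read per-sample metadata from a tab-separated file
#'
#' Empty cells are allowed only for `crp` and `fcal` and become `NA`.
#'
#' @param path Path to a TSV file with the columns listed in
#'   [sample_metadata()].
#' @return A `sample_metadata` data frame.
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = "")
  sample_metadata(df)
}

#' Write per-sample metadata to a tab-separated file
#'
#' @param meta A `sample_metadata` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  stopifnot(inherits(meta, "sample_metadata"))
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

# --- module definitions -----------------------------------------------------

#' Construct a set of module definitions
#'
#' A module definition maps a functional module identifier to the set of KEGG
#' Orthology (KO) groups whose read counts it aggregates. Definitions come
#' either from the curated KEGG module database (`source = "kegg"`) or from a
#' short-chain fatty acid production extension (`source = "scfa_extension"`).
#'
#' @param module_id Character vector of unique module identifiers.
#' @param label Character vector of free-text labels.
#' @param kos List of character vectors, one non-empty KO set per module.
#' @param source `"kegg"` or `"scfa_extension"` (recycled).
#' @return A data frame of class `module_definitions` with a list-column
#'   `kos`.
#' @export
module_definitions <- function(module_id, label, kos,
                               source = c("kegg", "scfa_extension")) {
  source <- match.arg(source)
  if (anyDuplicated(module_id))
    stop("duplicate module_id: ",
         paste(unique(module_id[duplicated(module_id)]), collapse = ", "))
  kos <- lapply(kos, function(k) unique(trimws(k)))
  empty <- lengths(kos) == 0L | vapply(kos, function(k) all(!nzchar(k)), TRUE)
  if (any(empty))
    stop("empty KO list for module(s): ",
         paste(module_id[empty], collapse = ", "))
  df <- data.frame(module_id = as.character(module_id),
                   label = as.character(label),
                   source = rep_len(source, length(module_id)),
                   stringsAsFactors = FALSE)
  df$kos <- kos
  class(df) <- c("module_definitions", "data.frame")
  df
}

#' Read module definitions from a tab-separated file
#'
#' Each line holds `module_id<TAB>label<TAB>KO1,KO2,...` with no header.
#'
#' @param path Path to the definition file.
#' @param source Definition source tag, `"kegg"` (default) or
#'   `"scfa_extension"`.
#' @return A `module_definitions` data frame.
#' @export
read_module_definitions <- function(path, source = c("kegg", "scfa_extension")) {
  source <- match.arg(source)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(raw) != 3L)
    stop("module definition file must have 3 tab-separated fields per line")
  kos <- strsplit(raw[[3L]], ",", fixed = TRUE)
  module_definitions(raw[[1L]], raw[[2L]], kos, source = source)
}

#' Merge curated KEGG definitions with an SCFA extension
#'
#' The manually curated KEGG module database carries no modules for the
#' production of short-chain fatty acids, so the definition set is extended
#' with dedicated SCFA pathway modules. On a module-ID collision the KEGG
#' version is kept and a warning is emitted.
#'
#' @param kegg,scfa `module_definitions` data frames.
#' @return A merged `module_definitions` data frame; source labels are
#'   preserved.
#' @export
merge_module_definitions <- function(kegg, scfa) {
  stopifnot(inherits(kegg, "module_definitions"),
            inherits(scfa, "module_definitions"))
  clash <- intersect(kegg$module_id, scfa$module_id)
  if (length(clash) > 0L) {
    warning("module_id collision resolved in favour of KEGG: ",
            paste(clash, collapse = ", "))
    scfa <- scfa[!scfa$module_id %in% clash, , drop = FALSE]
  }
  out <- rbind.data.frame(kegg, scfa, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("module_definitions", "data.frame")
  out
}

#' Aggregate KO-level counts into module abundances
#'
#' The abundance of a functional module is the sum of read counts across its
#' member KOs. KOs listed in a definition but absent from the table contribute
#' zero; modules whose members are all absent yield an all-zero column (they
#' are removed later by prevalence filtering, not here). One KO may belong to
#' several modules and is counted in each.
#'
#' @param ko_table An `abundance_table` with `unit = "count"` whose features
#'   are KO identifiers.
#' @param defs A `module_definitions` data frame.
#' @return An `abundance_table` with `modality = "module"`, one column per
#'   definition, annotated with the definition labels.
#' @export
aggregate_ko_counts <- function(ko_table, defs) {
  stopifnot(inherits(ko_table, "abundance_table"),
            inherits(defs, "module_definitions"))
  if (ko_table$unit != "count")
    stop("KO aggregation is defined on count tables")
  if (nrow(defs) == 0L)
    stop("empty module definition set")
  kos_present <- colnames(ko_table$values)
  out <- matrix(0, nrow(ko_table$values), nrow(defs),
                dimnames = list(rownames(ko_table$values), defs$module_id))
  for (i in seq_len(nrow(defs))) {
    members <- intersect(defs$kos[[i]], kos_present)
    if (length(members) > 0L)
      out[, i] <- rowSums(ko_table$values[, members, drop = FALSE])
  }
  ann <- stats::setNames(defs$label, defs$module_id)
  abundance_table(out, modality = "module", unit = "count",
                  feature_annotation = ann)
}
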