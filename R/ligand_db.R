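#' Default column-name aliases for activity tables
#'
#' Deposited collections and database exports name their columns differently;
#' the reader resolves each required field through this alias table
#' (case-insensitive). Override or extend entries to adapt to a new file.
#'
#' @return named list mapping field names to accepted column headers.
#' @export
activity_column_aliases <- function() {
  list(
    record_id      = c("record_id", "id", "row_id"),
    structure      = c("structure", "smiles", "canonical_smiles", "smiles_string"),
    parameter      = c("parameter", "standard_type", "type", "activity_type"),
    relation       = c("relation", "standard_relation", "rel"),
    value          = c("value", "standard_value", "value_nm", "activity_value"),
    unit           = c("unit", "units", "standard_units"),
    source         = c("source", "src", "database", "data_source"),
    compound_label = c("compound_label", "label", "name", "compound_id",
                       "molecule_chembl_id", "chembl_id")
  )
}

ACTIVITY_PARAMETERS <- c("Ki", "IC50", "EC50")
RELATIONS <- c("=", "<", ">")
SOURCES <- c("chembl", "patent", "pdsp", "other")

normalize_parameter <- function(x) {
  x <- gsub("[ _]", "", as.character(x))
  m <- match(toupper(x), toupper(ACTIVITY_PARAMETERS))
  ACTIVITY_PARAMETERS[m]
}

# unit multipliers to nM
UNIT_TO_NM <- c(nm = 1, um = 1e3, "µm" = 1e3, mm = 1e6, pm = 1e-3, m = 1e9)

#' Read and validate a bioactivity table
#'
#' Reads a CSV or XLSX activity table, resolves column names through an alias
#' table, normalizes units to nM, validates every row (positive value, known
#' parameter and relation, parseable SMILES) and canonicalizes structures.
#' Rows failing validation are not dropped silently: they are returned in a
#' `rejects` table with a reason each.
#'
#' @param path path to the table.
#' @param format `"auto"` (by extension), `"csv"` or `"xlsx"` (needs readxl).
#' @param aliases alias table, see [activity_column_aliases()].
#' @return list with elements `records` (validated activity records with a
#'   `canonical_key` column) and `rejects` (failed rows with `reason`).
#' @export
read_activity_table <- function(path, format = c("auto", "csv", "xlsx"),
                                aliases = activity_column_aliases()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_arg("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "xlsx" else "csv"
  }
  raw <- if (format == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop_arg("reading xlsx requires the readxl package")
    as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  validate_activity_records(resolve_columns(raw, aliases))
}

resolve_columns <- function(raw, aliases) {
  lower <- tolower(names(raw))
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(aliases)) {
    hit <- which(lower %in% tolower(aliases[[field]]))
    out[[field]] <- if (length(hit)) raw[[hit[1]]] else NA
  }
  required <- c("structure", "parameter", "relation", "value", "source")
  missing <- required[vapply(required, function(f) all(is.na(out[[f]])) &&
                               !any(tolower(aliases[[f]]) %in% lower),
                             logical(1))]
  # relation and source may be genuinely absent: default them
  missing <- setdiff(missing, c("relation", "source"))
  if (length(missing))
    stop_arg("missing required column(s): ", paste(missing, collapse = ", "))
  out
}

#' Validate raw activity rows into records
#'
#' @param df data frame with columns `structure`, `parameter`, `relation`,
#'   `value`, and optionally `unit`, `source`, `record_id`, `compound_label`.
#' @return list with `records` and `rejects` (see [read_activity_table()]).
#' @export
validate_activity_records <- function(df) {
  n <- nrow(df)
  if (is.null(df$record_id) || all(is.na(df$record_id)))
    df$record_id <- sprintf("R%05d", seq_len(n))
  rel <- trimws(as.character(df$relation %||% rep("=", n)))
  df$relation <- ifelse(is.na(rel) | !nzchar(rel), "=", rel)
  src <- tolower(as.character(df$source %||% rep("other", n)))
  df$source <- ifelse(is.na(src) | !src %in% SOURCES, "other", src)
  if (is.null(df$compound_label)) df$compound_label <- rep(NA_character_, n)

  value <- suppressWarnings(as.numeric(df$value))
  unit <- tolower(trimws(as.character(df$unit %||% rep("nm", n))))
  unit[is.na(unit) | !nzchar(unit)] <- "nm"
  mult <- UNIT_TO_NM[unit]
  value_nM <- value * as.numeric(mult)

  parameter <- normalize_parameter(df$parameter)
  reason <- rep(NA_character_, n)
  reason[is.na(parameter)] <- "unknown parameter"
  reason[is.na(reason) & !df$relation %in% RELATIONS] <- "unknown relation"
  reason[is.na(reason) & is.na(mult)] <- "unknown unit"
  reason[is.na(reason) & (is.na(value_nM))] <- "non-numeric value"
  reason[is.na(reason) & value_nM <= 0] <- "nonpositive value"

  canon <- rep(NA_character_, n)
  todo <- which(is.na(reason))
  canon[todo] <- canonical_smiles(df$structure[todo])
  reason[is.na(reason) & is.na(canon)] <- "unparseable structure"

  records <- data.frame(
    record_id = as.character(df$record_id),
    structure = as.character(df$structure),
    canonical_key = canon,
    parameter = parameter,
    relation = as.character(df$relation),
    value_nM = value_nM,
    source = df$source,
    compound_label = as.character(df$compound_label),
    stringsAsFactors = FALSE
  )
  keep <- is.na(reason)
  rejects <- records[!keep, c("record_id", "structure", "parameter", "relation",
                              "value_nM", "source")]
  rejects$reason <- reason[!keep]
  list(records = records[keep, , drop = FALSE], rejects = rejects)
}

#' Merge activity records into unique compounds
#'
#' Groups validated records by canonical structure. Per compound and per
#' parameter the best determined value is the minimum (or median) over
#' `=`-relation records; censored bounds (`<`, `>`) are carried separately so
#' that [classify_activity()] can use them as activity evidence. The
#' operation is idempotent: re-merging the records of the output reproduces it.
#'
#' @param records validated records (from [read_activity_table()]).
#' @param best `"min"` (default) or `"median"` aggregation of `=` values.
#' @return a `compound_set` data frame, one row per unique compound, with
#'   per-parameter `best_*_nM`, `lt_*_nM` (tightest `<` bound) and `gt_*_nM`
#'   (largest `>` bound) columns, a `records` list-column, and an attribute
#'   `rejects` holding records whose structure failed canonicalization.
#' @export
merge_compounds <- function(records, best = c("min", "median")) {
  best <- match.arg(best)
  stopifnot(is.data.frame(records))
  if (is.null(records$canonical_key))
    records$canonical_key <- canonical_smiles(records$structure)
  bad <- is.na(records$canonical_key)
  rejects <- records[bad, , drop = FALSE]
  if (nrow(rejects)) rejects$reason <- "canonicalization failure"
  records <- records[!bad, , drop = FALSE]
  if (!nrow(records)) {
    out <- empty_compound_set()
    attr(out, "rejects") <- rejects
    return(out)
  }
  agg <- if (best == "min") function(x) min(x) else function(x) stats::median(x)
  groups <- split(records, records$canonical_key)
  rows <- lapply(groups, function(g) {
    row <- list(canonical_key = g$canonical_key[1], n_records = nrow(g))
    for (p in ACTIVITY_PARAMETERS) {
      eq <- g$value_nM[g$parameter == p & g$relation == "="]
      lt <- g$value_nM[g$parameter == p & g$relation == "<"]
      gt <- g$value_nM[g$parameter == p & g$relation == ">"]
      row[[paste0("best_", p, "_nM")]] <- if (length(eq)) agg(eq) else NA_real_
      row[[paste0("lt_", p, "_nM")]] <- if (length(lt)) min(lt) else NA_real_
      row[[paste0("gt_", p, "_nM")]] <- if (length(gt)) max(gt) else NA_real_
    }
    row
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out$canonical_key), , drop = FALSE]
  rownames(out) <- NULL
  out$chemotype <- NA_character_
  out$records <- I(unname(groups[out$canonical_key]))
  class(out) <- c("compound_set", "data.frame")
  attr(out, "rejects") <- rejects
  out
}

empty_compound_set <- function() {
  cols <- c("canonical_key", "n_records",
            as.vector(outer(c("best_", "lt_", "gt_"), ACTIVITY_PARAMETERS,
                            function(a, b) paste0(a, b, "_nM"))),
            "chemotype")
  out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  out$n_records <- integer(0)
  out$records <- I(list())
  class(out) <- c("compound_set", "data.frame")
  out
}

#' Classify compounds as active / inactive / undetermined
#'
#' A compound is active for a parameter when its best determined value is
#' strictly below the threshold, inactive when at or above it. The boundary
#' value (exactly at the threshold) is classified inactive. Censored records
#' contribute when no determined value exists: a `<` bound below the
#' threshold is active evidence, a `>` bound at or above it is inactive
#' evidence; otherwise the compound is undetermined for that parameter.
#'
#' @param entries a `compound_set` from [merge_compounds()].
#' @param parameter one of `"Ki"`, `"IC50"`, `"EC50"`.
#' @param threshold_nM activity threshold in nM (default 1000).
#' @return factor with levels active, inactive, undetermined.
#' @export
classify_activity <- function(entries, parameter, threshold_nM = 1000) {
  if (!is_scalar_number(threshold_nM) || threshold_nM <= 0)
    stop_arg("threshold_nM must be a positive number")
  parameter <- match_parameter(parameter)
  best <- entries[[paste0("best_", parameter, "_nM")]]
  lt <- entries[[paste0("lt_", parameter, "_nM")]]
  gt <- entries[[paste0("gt_", parameter, "_nM")]]
  out <- rep("undetermined", nrow(entries))
  out[!is.na(best)] <- ifelse(best[!is.na(best)] < threshold_nM, "active", "inactive")
  cens <- is.na(best)
  out[cens & !is.na(lt) & lt < threshold_nM] <- "active"
  out[cens & out == "undetermined" & !is.na(gt) & gt >= threshold_nM] <- "inactive"
  factor(out, levels = c("active", "inactive", "undetermined"))
}

match_parameter <- function(parameter) {
  p <- normalize_parameter(parameter)
  if (length(p) != 1L || is.na(p))
    stop_arg("unknown parameter: ", paste(parameter, collapse = ", "))
  p
}

#' Venn counts of determined activity parameters
#'
#' Each compound with at least one determined (`=`-relation) parameter value
#' is counted in exactly one cell of the Ki / IC50 / EC50 Venn diagram.
#'
#' @param entries a `compound_set`.
#' @return named integer vector over the 7 nonempty parameter subsets
#'   (class `venn_counts`), e.g. `"Ki"`, `"Ki+EC50"`, `"Ki+IC50+EC50"`.
#' @export
parameter_overlap <- function(entries) {
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(ACTIVITY_PARAMETERS, k, paste, collapse = "+")))
  counts <- setNames(integer(length(subsets)), subsets)
  if (nrow(entries) > 0L) {
    has <- vapply(ACTIVITY_PARAMETERS, function(p)
      !is.na(entries[[paste0("best_", p, "_nM")]]), logical(nrow(entries)))
    has <- matrix(has, nrow = nrow(entries),
                  dimnames = list(NULL, ACTIVITY_PARAMETERS))
    labels <- apply(has, 1, function(r) paste(ACTIVITY_PARAMETERS[r], collapse = "+"))
    tab <- table(labels[nzchar(labels)])
    counts[names(tab)] <- as.integer(tab)
  }
  structure(counts, class = "venn_counts")
}

#' Count compounds below an activity cutoff
#'
#' @param entries a `compound_set`.
#' @param parameter activity parameter.
#' @param cutoff_nM strict upper cutoff in nM.
#' @param chemotype optional chemotype name to restrict the count to.
#' @return number of compounds with best determined value `< cutoff_nM`.
#' @export
threshold_count <- function(entries, parameter, cutoff_nM, chemotype = NULL) {
  parameter <- match_parameter(parameter)
  best <- entries[[paste0("best_", parameter, "_nM")]]
  keep <- !is.na(best) & best < cutoff_nM
  if (!is.null(chemotype))
    keep <- keep & !is.na(entries$chemotype) & entries$chemotype == chemotype
  sum(keep)
}

#' Histogram of activity values
#'
#' Bins best determined values into left-closed, right-open bins.
#'
#' @param entries a `compound_set`.
#' @param parameter activity parameter.
#' @param bin_edges_nM strictly increasing bin edges in nM.
#' @return named integer vector of bin counts (`[a,b)` labels) with
#'   attributes `n_total` (compounds with a determined value) and
#'   `n_outside` (values outside the edge range).
#' @export
activity_distribution <- function(entries, parameter, bin_edges_nM) {
  parameter <- match_parameter(parameter)
  if (length(bin_edges_nM) < 2L || any(diff(bin_edges_nM) <= 0))
    stop_arg("bin_edges_nM must be strictly increasing with >= 2 edges")
  x <- entries[[paste0("best_", parameter, "_nM")]]
  x <- x[!is.na(x)]
  idx <- findInterval(x, bin_edges_nM)
  inside <- idx >= 1L & idx < length(bin_edges_nM)
  counts <- tabulate(idx[inside], nbins = length(bin_edges_nM) - 1L)
  names(counts) <- sprintf("[%g,%g)", head(bin_edges_nM, -1), bin_edges_nM[-1])
  structure(counts, n_total = length(x), n_outside = sum(!inside))
}

#' Summarize a curated collection
#'
#' Convenience wrapper producing the headline counts of a curated collection:
#' total compounds, unique compounds per determined parameter, Venn cells,
#' and sub-threshold counts.
#'
#' @param entries a `compound_set`.
#' @param threshold_nM activity threshold for the active/inactive split.
#' @return list of summary quantities.
#' @export
collection_summary <- function(entries, threshold_nM = 1000) {
  venn <- parameter_overlap(entries)
  per_param <- sapply(ACTIVITY_PARAMETERS, function(p)
    sum(!is.na(entries[[paste0("best_", p, "_nM")]])))
  list(
    n_compounds = nrow(entries),
    n_with_parameter = per_param,
    venn = venn,
    n_Ki_below_100 = threshold_count(entries, "Ki", 100),
    n_IC50_below_100 = threshold_count(entries, "IC50", 100),
    min_EC50_nM = if (any(!is.na(entries$best_EC50_nM)))
      min(entries$best_EC50_nM, na.rm = TRUE) else NA_real_,
    n_active_Ki = sum(classify_activity(entries, "Ki", threshold_nM) == "active")
  )
}
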