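#' Construct a feature table
#'
#' A feature table holds a numeric samples-by-features matrix of radiomics
#' (or other tabular) feature values together with unique sample identifiers
#' and unique feature names. All values must be finite: missing or
#' non-finite values are rejected rather than imputed.
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#' @param sample_ids Character vector of unique sample identifiers,
#'   length `nrow(values)`.
#' @param feature_names Character vector of unique feature names,
#'   length `ncol(values)`.
#' @return An object of class `feature_table`: the numeric matrix with
#'   `sample_ids` as row names and `feature_names` as column names.
#' @examples
#' ft <- feature_table(matrix(rnorm(12), 4, 3),
#'                     sample_ids = paste0("s", 1:4),
#'                     feature_names = paste0("f", 1:3))
#' dim(ft)
#' @export
feature_table <- function(values, sample_ids = rownames(values),
                          feature_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(feature_names))
    stop("feature_table needs sample_ids and feature_names")
  sample_ids <- as.character(sample_ids)
  feature_names <- as.character(feature_names)
  if (nrow(values) != length(sample_ids))
    stop("values has ", nrow(values), " rows but ", length(sample_ids),
         " sample_ids were given")
  if (ncol(values) != length(feature_names))
    stop("values has ", ncol(values), " columns but ", length(feature_names),
         " feature_names were given")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(feature_names))
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop("non-finite feature value at sample '", sample_ids[bad[1]],
         "', feature '", feature_names[bad[2]],
         "' (missing values are rejected, not imputed)")
  }
  dimnames(values) <- list(sample_ids, feature_names)
  class(values) <- c("feature_table", class(values))
  values
}

#' Construct cohort metadata
#'
#' Per-sample acquisition environment (e.g. contributing hospital/center)
#' and binary outcome labels, with an explicit positive-class designation.
#' At least two environments are required because the invariance analysis
#' compares model fits across environments.
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param environment Per-sample environment (center) label; coerced to factor.
#' @param outcome Per-sample binary outcome label; coerced to factor with
#'   exactly two levels.
#' @param positive_class The outcome level treated as "positive" in all
#'   confusion-matrix-derived metrics. Defaults to the second factor level.
#'   For IDH1/2 cohorts the convention throughout this package is
#'   wild-type positive.
#' @return A `cohort_metadata` data frame with columns `sample_id`,
#'   `environment`, `outcome` and attribute `positive_class`.
#' @export
cohort_metadata <- function(sample_ids, environment, outcome,
                            positive_class = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in metadata")
  n <- length(sample_ids)
  if (length(environment) != n || length(outcome) != n)
    stop("sample_ids, environment and outcome must have equal length")
  if (anyNA(environment) || anyNA(outcome))
    stop("missing environment or outcome labels are not allowed")
  environment <- factor(environment)
  environment <- droplevels(environment)
  if (nlevels(environment) < 2)
    stop("at least 2 environments are required for invariance analysis (got ",
         nlevels(environment), ")")
  outcome <- factor(outcome)
  outcome <- droplevels(outcome)
  if (nlevels(outcome) != 2)
    stop("outcome must be binary; got levels: ",
         paste(levels(outcome), collapse = ", "))
  if (is.null(positive_class)) positive_class <- levels(outcome)[2]
  positive_class <- as.character(positive_class)
  if (!positive_class %in% levels(outcome))
    stop("positive_class '", positive_class, "' is not an outcome level")
  md <- data.frame(sample_id = sample_ids, environment = environment,
                   outcome = outcome, stringsAsFactors = FALSE)
  attr(md, "positive_class") <- positive_class
  class(md) <- c("cohort_metadata", class(md))
  md
}

#' Positive-class designation of a metadata object
#' @param metadata A [cohort_metadata()] object.
#' @return The positive outcome level, as a string.
#' @export
positive_class <- function(metadata) attr(metadata, "positive_class")

#' Binary outcome as 0/1 with 1 = positive class
#' @param metadata A [cohort_metadata()] object.
#' @return Integer vector of 0/1.
#' @keywords internal
outcome01 <- function(metadata) {
  as.integer(metadata$outcome == positive_class(metadata))
}

## vocabularies of the feature-name grammar
.sequences <- c("T1", "cT1", "T2", "FLAIR")
.regions <- c("L1", "L2", "L3")

#' Parse a radiomics feature name
#'
#' Feature names follow the convention
#' `<filter>_<class>_<name>_<sequence>_<region>`, e.g.
#' `wavelet.HL_firstorder_Mean_cT1_L2`. The image-filter token may contain
#' dots (`log.sigma.2.mm.3D`) but never underscores, so a valid name splits
#' into exactly five underscore-delimited fields. The sequence must be one
#' of `r paste(.sequences, collapse = ", ")` and the region one of L1
#' (enhancing tumor), L2 (nonenhancing tumor/necrosis) or L3 (edema).
#'
#' @param name Character vector of feature names.
#' @return A data frame with one row per name and columns `image_filter`,
#'   `feature_class`, `feature_name`, `sequence`, `region`, plus the
#'   original string in `name`. Joining the five components with `_`
#'   reproduces the input exactly.
#' @examples
#' parse_feature_name("wavelet.HL_firstorder_Mean_cT1_L2")
#' @export
parse_feature_name <- function(name) {
  name <- as.character(name)
  parts <- strsplit(name, "_", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5)) {
    bad <- name[nf != 5][1]
    stop("malformed feature name '", bad, "': expected 5 underscore-delimited ",
         "fields, got ", nf[nf != 5][1])
  }
  m <- do.call(rbind, parts)
  seqs <- m[, 4]
  regs <- m[, 5]
  if (!all(seqs %in% .sequences))
    stop("unknown sequence token '", seqs[!seqs %in% .sequences][1],
         "' in feature name '", name[!seqs %in% .sequences][1],
         "' (expected one of ", paste(.sequences, collapse = ", "), ")")
  if (!all(regs %in% .regions))
    stop("unknown region token '", regs[!regs %in% .regions][1],
         "' in feature name '", name[!regs %in% .regions][1],
         "' (expected one of ", paste(.regions, collapse = ", "), ")")
  data.frame(image_filter = m[, 1], feature_class = m[, 2],
             feature_name = m[, 3], sequence = seqs, region = regs,
             name = name, stringsAsFactors = FALSE)
}

#' Reassemble a parsed feature name
#'
#' Inverse of [parse_feature_name()]: joins the five components with `_`.
#'
#' @param parsed Data frame as returned by [parse_feature_name()].
#' @return Character vector of feature names.
#' @export
unparse_feature_name <- function(parsed) {
  paste(parsed$image_filter, parsed$feature_class, parsed$feature_name,
        parsed$sequence, parsed$region, sep = "_")
}

#' Read a feature table and cohort metadata from delimited text
#'
#' Reads a feature file (sample ID in the first column, one numeric column
#' per feature, header row) and a metadata file (sample ID in the first
#' column plus environment and outcome columns), and aligns them by sample
#' ID. Samples present in only one of the two files are dropped with a
#' warning giving the count.
#'
#' @param path Path to the feature CSV/TSV.
#' @param metadata_path Path to the metadata CSV/TSV.
#' @param environment_col,outcome_col Names of the metadata columns holding
#'   the center label and the binary outcome.
#' @param positive_class Outcome level treated as positive; default the
#'   second sorted level.
#' @param sep Field delimiter, `","` by default; pass `"\t"` for TSV.
#' @return A list with elements `table` ([feature_table()]) and
#'   `metadata` ([cohort_metadata()]), row-aligned.
#' @export
read_feature_table <- function(path, metadata_path,
                               environment_col = "environment",
                               outcome_col = "outcome",
                               positive_class = NULL, sep = ",") {
  feats <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
  md <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(feats) < 2) stop("feature file has no feature columns")
  ids_f <- as.character(feats[[1]])
  if (anyDuplicated(ids_f))
    stop("duplicate sample ID in feature file: ",
         ids_f[duplicated(ids_f)][1])
  for (j in seq(2, ncol(feats))) {
    v <- feats[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric feature value in column '", names(feats)[j],
           "', row ", bad)
    }
  }
  ids_m <- as.character(md[[1]])
  if (anyDuplicated(ids_m))
    stop("duplicate sample ID in metadata file: ", ids_m[duplicated(ids_m)][1])
  for (col in c(environment_col, outcome_col))
    if (!col %in% names(md))
      stop("metadata file lacks column '", col, "'")
  common <- intersect(ids_f, ids_m)
  dropped <- (length(ids_f) - length(common)) + (length(ids_m) - length(common))
  if (dropped > 0)
    warning(dropped, " sample(s) present in only one file were dropped")
  if (length(common) == 0) stop("no samples shared between the two files")
  feats <- feats[match(common, ids_f), , drop = FALSE]
  md <- md[match(common, ids_m), , drop = FALSE]
  tab <- feature_table(as.matrix(feats[, -1, drop = FALSE]),
                       sample_ids = common,
                       feature_names = names(feats)[-1])
  meta <- cohort_metadata(common, md[[environment_col]], md[[outcome_col]],
                          positive_class = positive_class)
  list(table = tab, metadata = meta)
}

#' Write an evaluation report to structured text (JSON)
#'
#' Serializes an [evaluation report][evaluate_predictions] (or any nested
#' list of numeric/character fields) as JSON with stable key order and full
#' numeric precision, so that two runs with identical seed and configuration
#' produce byte-identical files.
#'
#' @param report The report object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(report, path) {
  report <- unclass_recursive(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "string")
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path Path to the JSON report.
#' @return The report as nested lists.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_recursive)
    attributes(x) <- list(names = names(x))
    x
  } else if (is.matrix(x)) {
    # keep dimnames through JSON as a named list of rows
    rows <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    names(rows) <- rownames(x)
    rows
  } else {
    attributes(x) <- if (!is.null(names(x))) list(names = names(x)) else NULL
    x
  }
}
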