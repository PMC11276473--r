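#' Z-score the columns of a matrix
#'
#' Centers every column to mean 0 and scales it to sample standard
#' deviation 1 (divisor `n - 1`). All indicator variables are z-scored
#' before profile analysis so that profile means are directly
#' interpretable as deviations from the sample average in SD units.
#'
#' @param raw Numeric matrix (participants in rows, variables in columns).
#' @return Matrix of the same shape with standardized columns.
#' @examples
#' standardize_columns(cbind(a = c(1, 2, 3)))
#' @export
standardize_columns <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("`raw` must be a numeric matrix")
  if (anyNA(raw)) stop("missing values are not allowed; filter to complete cases upstream")
  if (nrow(raw) < 2L) stop("need at least 2 rows to standardize")
  sds <- apply(raw, 2L, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(raw)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  scale(raw, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Construct an indicator matrix
#'
#' Wraps a participants x indicators score matrix, optionally z-scoring
#' the columns (the default, and what every fitting function expects).
#'
#' @param values Numeric matrix of scores.
#' @param participant_ids Optional row labels; defaults to row numbers.
#' @param indicator_names Optional column labels; defaults to existing
#'   column names or `V1..Vm`.
#' @param standardize Z-score the columns? Default `TRUE`.
#' @return An object of class `indicator_matrix` with elements `values`,
#'   `participant_ids`, `indicator_names`.
#' @export
indicator_matrix <- function(values, participant_ids = NULL,
                             indicator_names = NULL, standardize = TRUE) {
  values <- as.matrix(values)
  n <- nrow(values); m <- ncol(values)
  if (n < 2L || m < 1L) stop("need n >= 2 participants and m >= 1 indicators")
  if (anyNA(values)) stop("indicator values must be fully observed; filter to complete cases upstream")
  if (is.null(indicator_names)) {
    indicator_names <- colnames(values)
    if (is.null(indicator_names)) indicator_names <- paste0("V", seq_len(m))
  }
  if (is.null(participant_ids)) {
    participant_ids <- rownames(values)
    if (is.null(participant_ids)) participant_ids <- as.character(seq_len(n))
  }
  if (standardize) values <- standardize_columns(values)
  dimnames(values) <- NULL
  structure(list(values = values,
                 participant_ids = as.character(participant_ids),
                 indicator_names = as.character(indicator_names)),
            class = "indicator_matrix")
}

#' @export
print.indicator_matrix <- function(x, ...) {
  cat("indicator_matrix:", nrow(x$values), "participants x",
      ncol(x$values), "indicators\n")
  cat("indicators:", paste(x$indicator_names, collapse = ", "), "\n")
  invisible(x)
}

#' Construct an outcome vector
#'
#' Holds one outcome variable, z-scored over its observed entries.
#' Participants may be missing an outcome without being dropped from the
#' indicator analysis; missing entries are excluded per outcome.
#'
#' @param values Numeric vector (may contain `NA`).
#' @param name Optional outcome name.
#' @param standardize Z-score over non-missing entries? Default `TRUE`.
#' @return An object of class `outcome_vector` with elements `values`
#'   (standardized, `NA` where missing), `missing_mask`, `name`.
#' @export
outcome_vector <- function(values, name = "outcome", standardize = TRUE) {
  values <- as.numeric(values)
  miss <- is.na(values)
  n_obs <- sum(!miss)
  if (n_obs < 2L) stop("outcome '", name, "' has fewer than 2 observed values")
  if (standardize) {
    obs <- values[!miss]
    s <- stats::sd(obs)
    if (s == 0) stop("outcome '", name, "' has zero variance")
    values[!miss] <- (obs - mean(obs)) / s
  }
  structure(list(values = values, missing_mask = miss, name = name),
            class = "outcome_vector")
}

#' Load a participants x variables CSV
#'
#' Reads a UTF-8 CSV with a header row and one row per participant,
#' splits it into a standardized indicator matrix and standardized
#' outcome vectors. Indicator columns must be fully observed; outcomes
#' may be missing per participant.
#'
#' @param path CSV file path.
#' @param indicator_columns Character vector of indicator column names.
#' @param outcome_columns Character vector of outcome column names
#'   (may be empty).
#' @param id_column Optional name of a participant-id column.
#' @return List with `indicators` (an [indicator_matrix]) and `outcomes`
#'   (named list of [outcome_vector]s).
#' @export
load_table <- function(path, indicator_columns, outcome_columns = character(),
                       id_column = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want <- c(indicator_columns, outcome_columns, id_column)
  missing_cols <- setdiff(want, names(df))
  if (length(missing_cols))
    stop("column(s) not present in ", path, ": ", paste(missing_cols, collapse = ", "))
  ind_raw <- as.matrix(df[indicator_columns])
  storage.mode(ind_raw) <- "double"
  if (anyNA(ind_raw)) {
    bad <- indicator_columns[colSums(is.na(ind_raw)) > 0]
    stop("missing values in indicator column(s) ", paste(bad, collapse = ", "),
         "; filter to complete cases upstream")
  }
  ids <- if (is.null(id_column)) as.character(seq_len(nrow(df))) else as.character(df[[id_column]])
  ind <- indicator_matrix(ind_raw, participant_ids = ids,
                          indicator_names = indicator_columns)
  outs <- lapply(outcome_columns, function(cl) outcome_vector(df[[cl]], name = cl))
  names(outs) <- outcome_columns
  list(indicators = ind, outcomes = outs)
}

#' Read a run configuration file
#'
#' Plain YAML key-value file selecting indicator/outcome columns, priors,
#' truncation level and seeds for reproducible runs.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}
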