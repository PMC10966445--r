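#' Construct a binary cohort matrix
#'
#' A cohort holds presence/absence indicators for `P` long-term conditions
#' (LTCs) across `N` patients, optionally with a per-patient stratum label
#' (e.g. `"men"` / `"women"`).
#'
#' @param presence Matrix or data frame of 0/1 (or logical) indicators, one
#'   row per patient and one named column per condition.
#' @param strata Optional character/factor vector of per-patient stratum
#'   labels, length `N`.
#' @return An object of class `abc_cohort`: a list with elements
#'   `presence` (integer matrix with condition names as column names) and
#'   `strata` (character vector or `NULL`).
#' @examples
#' coh <- cohort(cbind(A = c(1, 0, 1), B = c(0, 0, 1)))
#' coh
#' @export
cohort <- function(presence, strata = NULL) {
  if (is.data.frame(presence)) presence <- as.matrix(presence)
  if (!is.matrix(presence)) stop("`presence` must be a matrix or data frame")
  if (is.logical(presence)) storage.mode(presence) <- "integer"
  if (nrow(presence) < 1L) stop("cohort is empty: N must be >= 1")
  if (ncol(presence) < 2L) stop("a cohort needs at least two conditions")
  labels <- colnames(presence)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("condition columns must have non-empty names")
  }
  if (anyDuplicated(labels)) {
    stop("duplicate condition names: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (anyNA(presence)) {
    bad <- which(is.na(presence), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in condition '%s' (row %d); %s",
                 labels[bad[2L]], bad[1L],
                 "missing indicators are rejected, not imputed"))
  }
  suppressWarnings(storage.mode(presence) <- "integer")
  bad <- which(!(presence %in% c(0L, 1L)))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], dim(presence))
    stop(sprintf("non-binary value in condition '%s' (row %d): all %s",
                 labels[idx[2L]], idx[1L],
                 "indicators must be 0/1 or TRUE/FALSE"))
  }
  if (!is.null(strata)) {
    strata <- as.character(strata)
    if (length(strata) != nrow(presence)) {
      stop("`strata` must have one label per patient")
    }
  }
  empty <- labels[colSums(presence) == 0L]
  if (length(empty)) {
    message("conditions with zero prevalence retained: ",
            paste(empty, collapse = ", "))
  }
  structure(list(presence = presence, strata = strata),
            class = "abc_cohort")
}

#' @export
print.abc_cohort <- function(x, ...) {
  cat(sprintf("<abc_cohort> %d patients x %d conditions\n",
              nrow(x$presence), ncol(x$presence)))
  if (!is.null(x$strata)) {
    tab <- table(x$strata)
    cat("strata:", paste(sprintf("%s (%d)", names(tab), tab),
                         collapse = ", "), "\n")
  }
  prev <- colMeans(x$presence)
  cat(sprintf("prevalence range: %.4f (%s) to %.4f (%s)\n",
              min(prev), names(which.min(prev)),
              max(prev), names(which.max(prev))))
  invisible(x)
}

#' Number of patients / conditions in a cohort
#' @param cohort An `abc_cohort`.
#' @return Integer count.
#' @export
n_patients <- function(cohort) nrow(cohort$presence)

#' @rdname n_patients
#' @export
n_conditions <- function(cohort) ncol(cohort$presence)

#' @rdname n_patients
#' @export
condition_names <- function(cohort) colnames(cohort$presence)

#' Read a cohort from a wide CSV file
#'
#' Expects one row per patient and one 0/1 (or true/false) column per
#' condition; an optional stratum column (e.g. sex) is named via
#' `stratum_col`. Column order is preserved as the condition panel order.
#'
#' @param path Path to a CSV file.
#' @param condition_cols Character vector naming the condition columns;
#'   default: every column except `stratum_col`.
#' @param stratum_col Optional name of the stratum column.
#' @return An `abc_cohort`.
#' @export
read_cohort <- function(path, condition_cols = NULL, stratum_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!is.null(stratum_col) && !stratum_col %in% names(df)) {
    stop("stratum column '", stratum_col, "' not found")
  }
  if (is.null(condition_cols)) {
    condition_cols <- setdiff(names(df), stratum_col)
  }
  missing_cols <- setdiff(condition_cols, names(df))
  if (length(missing_cols)) {
    stop("condition columns not found: ",
         paste(missing_cols, collapse = ", "))
  }
  sub <- df[condition_cols]
  for (cn in condition_cols) {
    v <- sub[[cn]]
    if (is.character(v)) {
      v <- tolower(trimws(v))
      v <- ifelse(v %in% c("true", "t"), "1",
                  ifelse(v %in% c("false", "f"), "0", v))
      sub[[cn]] <- suppressWarnings(as.numeric(v))
    }
    bad <- which(is.na(sub[[cn]]) | !(sub[[cn]] %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-binary value '%s' in column '%s', row %d",
                   df[[cn]][bad[1L]], cn, bad[1L]))
    }
  }
  cohort(as.matrix(sub),
         strata = if (!is.null(stratum_col)) df[[stratum_col]])
}

#' Convert long-format diagnosis records to a cohort
#'
#' Convenience converter for "one row per (patient, condition) diagnosis"
#' data. Patients appearing in `records` with no diagnoses must be listed in
#' `patients` to be included as all-zero rows.
#'
#' @param records Data frame with columns `patient` and `condition`.
#' @param patients Optional vector of all patient ids (supplies all-zero
#'   rows); default: the patients present in `records`.
#' @param conditions Optional vector fixing the condition panel and its
#'   order; default: sorted unique conditions in `records`.
#' @param strata Optional named vector mapping patient id to stratum label.
#' @return An `abc_cohort`.
#' @export
cohort_from_long <- function(records, patients = NULL, conditions = NULL,
                             strata = NULL) {
  stopifnot(all(c("patient", "condition") %in% names(records)))
  if (is.null(patients)) patients <- unique(records$patient)
  if (is.null(conditions)) conditions <- sort(unique(records$condition))
  unknown <- setdiff(unique(records$condition), conditions)
  if (length(unknown)) {
    stop("conditions in records but not in panel: ",
         paste(unknown, collapse = ", "))
  }
  X <- matrix(0L, length(patients), length(conditions),
              dimnames = list(NULL, conditions))
  ri <- match(records$patient, patients)
  if (anyNA(ri)) stop("records contain patients not in `patients`")
  X[cbind(ri, match(records$condition, conditions))] <- 1L
  cohort(X, strata = if (!is.null(strata)) unname(strata[as.character(patients)]))
}

#' Write a cohort to a wide CSV file
#' @param cohort An `abc_cohort`.
#' @param path Output CSV path.
#' @param stratum_col Column name used for strata, if present.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, stratum_col = "stratum") {
  df <- as.data.frame(cohort$presence)
  if (!is.null(cohort$strata)) {
    df <- cbind(stats::setNames(data.frame(cohort$strata,
                                           stringsAsFactors = FALSE),
                                stratum_col), df)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a cohort to one stratum
#'
#' @param cohort An `abc_cohort` with strata.
#' @param stratum Stratum label to keep.
#' @return An `abc_cohort` containing only the matching patients; the
#'   condition panel is unchanged.
#' @export
stratify <- function(cohort, stratum) {
  if (is.null(cohort$strata)) stop("cohort has no strata")
  if (!stratum %in% cohort$strata) {
    stop("unknown stratum '", stratum, "'; available: ",
         paste(unique(cohort$strata), collapse = ", "))
  }
  keep <- cohort$strata == stratum
  suppressMessages(
    cohort(cohort$presence[keep, , drop = FALSE],
           strata = cohort$strata[keep])
  )
}

#' Stack stratified sub-cohorts into one cohort
#' @param cohorts Named list of `abc_cohort`s sharing one condition panel;
#'   names become the stratum labels.
#' @return An `abc_cohort` with strata.
#' @export
bind_cohorts <- function(cohorts) {
  stopifnot(is.list(cohorts), !is.null(names(cohorts)))
  panel <- condition_names(cohorts[[1L]])
  for (coh in cohorts) {
    if (!identical(condition_names(coh), panel)) {
      stop("all cohorts must share the same condition panel")
    }
  }
  suppressMessages(cohort(
    do.call(rbind, lapply(cohorts, function(c) c$presence)),
    strata = rep(names(cohorts),
                 vapply(cohorts, n_patients, integer(1L)))
  ))
}

#' All pairwise 2x2 contingency counts
#'
#' For each unordered condition pair (i, j) returns the cohort size `N`, the
#' marginal counts `N_i`, `N_j`, and the co-occurrence count `N_ij`, from
#' which the 2x2 cells are `a = N_ij`, `b = N_i - N_ij`, `c = N_j - N_ij`,
#' `d = N - N_i - N_j + N_ij`.
#'
#' @param cohort An `abc_cohort`.
#' @return A data frame with one row per unordered pair (`P*(P-1)/2` rows)
#'   and columns `i`, `j` (panel indices, `i < j`), `cond_i`, `cond_j`, `N`,
#'   `N_i`, `N_j`, `N_ij`.
#' @examples
#' coh <- cohort(cbind(A = c(1, 1, 1, 0, 0), B = c(0, 0, 1, 1, 1)))
#' pairwise_counts(coh)
#' @export
pairwise_counts <- function(cohort) {
  X <- cohort$presence
  P <- ncol(X)
  marg <- colSums(X)
  co <- crossprod(X)          # co[i, j] = N_ij
  idx <- which(upper.tri(co), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  out <- data.frame(
    i = idx[, 1L], j = idx[, 2L],
    cond_i = colnames(X)[idx[, 1L]], cond_j = colnames(X)[idx[, 2L]],
    N = nrow(X),
    N_i = marg[idx[, 1L]], N_j = marg[idx[, 2L]],
    N_ij = co[idx],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$N_i <- as.integer(out$N_i); out$N_j <- as.integer(out$N_j)
  out$N_ij <- as.integer(out$N_ij)
  out
}

#' Expand pair counts into 2x2 cells
#' @param tables Data frame from [pairwise_counts()].
#' @return The input with columns `a`, `b`, `c`, `d` appended.
#' @export
pair_cells <- function(tables) {
  tables$a <- tables$N_ij
  tables$b <- tables$N_i - tables$N_ij
  tables$c <- tables$N_j - tables$N_ij
  tables$d <- tables$N - tables$N_i - tables$N_j + tables$N_ij
  tables
}

#' Distribution of per-patient condition counts
#'
#' Standard multimorbidity descriptor: how many patients carry 0, 1, 2, ...
#' conditions, with the mean and SD of the per-patient count.
#'
#' @param cohort An `abc_cohort`.
#' @return A list with `histogram` (named integer vector over observed
#'   counts, summing to `N`), `mean` and `sd`.
#' @export
condition_count_histogram <- function(cohort) {
  k <- rowSums(cohort$presence)
  tab <- table(factor(k, levels = 0:max(k)))
  list(histogram = stats::setNames(as.integer(tab), names(tab)),
       mean = mean(k),
       sd = stats::sd(k))
}

#' Per-condition prevalence table
#' @param cohort An `abc_cohort`.
#' @return Data frame with `condition`, `count`, `prevalence`.
#' @export
condition_prevalence <- function(cohort) {
  cnt <- colSums(cohort$presence)
  data.frame(condition = colnames(cohort$presence),
             count = as.integer(cnt),
             prevalence = cnt / nrow(cohort$presence),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write prevalence and condition-count summaries as JSON
#' @param cohort An `abc_cohort`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(cohort, path) {
  h <- condition_count_histogram(cohort)
  jsonlite::write_json(
    list(n_patients = n_patients(cohort),
         n_conditions = n_conditions(cohort),
         prevalence = condition_prevalence(cohort),
         condition_count = list(histogram = as.list(h$histogram),
                                mean = h$mean, sd = h$sd)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
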