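#' Subject-level results of a multi-modality diagnostic trial
#'
#' Container for the binary outcomes of `M` diagnostic modalities (or
#' flattened reader-by-method cells) applied to every subject of a trial,
#' together with an error-free gold-standard disease label. Missing cells
#' are rejected: the sampling model assumes every subject is examined by
#' all `M` tests, and silently dropping or imputing cells would change the
#' covariance structure of the accuracy estimators.
#'
#' @param subject_id character vector of unique subject identifiers.
#' @param gold integer vector of gold-standard labels, 1 = diseased,
#'   0 = non-diseased.
#' @param results integer matrix (subjects x modalities) of binary test
#'   outcomes, 1 = positive.
#' @param modality_labels optional character vector of modality names;
#'   defaults to the column names of `results` or `"mod1"`, ...
#'
#' @return An object of class `trial_data` with components `subject_id`,
#'   `gold`, `results` and `modality_labels`.
#' @seealso [read_trial_csv()], [estimate_accuracy()], [generate_trial()]
#' @export
#' @examples
#' trial_data(c("a", "b"), c(1, 0), matrix(c(1, 0, 1, 1), 2, 2))
trial_data <- function(subject_id, gold, results, modality_labels = NULL) {
  results <- as.matrix(results)
  if (is.null(modality_labels)) {
    modality_labels <- colnames(results)
    if (is.null(modality_labels)) {
      modality_labels <- paste0("mod", seq_len(ncol(results)))
    }
  }
  subject_id <- as.character(subject_id)
  storage.mode(results) <- "integer"
  gold <- as.integer(gold)
  rownames(results) <- NULL
  colnames(results) <- modality_labels
  x <- structure(
    list(subject_id = subject_id, gold = gold, results = results,
         modality_labels = modality_labels),
    class = "trial_data"
  )
  validate_trial_data(x)
}

validate_trial_data <- function(x) {
  n <- length(x$subject_id)
  if (n == 0L) stop("trial contains no subjects", call. = FALSE)
  if (anyDuplicated(x$subject_id)) {
    stop("duplicated subject identifiers: ",
         paste(unique(x$subject_id[duplicated(x$subject_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(x$gold) != n || nrow(x$results) != n) {
    stop("subject_id, gold and results must agree in length", call. = FALSE)
  }
  if (anyNA(x$gold) || !all(x$gold %in% c(0L, 1L))) {
    stop("gold-standard labels must be 0 or 1 for every subject", call. = FALSE)
  }
  if (anyNA(x$results)) {
    stop("missing test outcomes are not allowed: every subject must be ",
         "examined by all modalities (complete-case design)", call. = FALSE)
  }
  if (!all(x$results %in% c(0L, 1L))) {
    stop("test outcomes must be binary (0/1)", call. = FALSE)
  }
  if (length(x$modality_labels) != ncol(x$results)) {
    stop("modality_labels must name every results column", call. = FALSE)
  }
  if (sum(x$gold == 1L) < 1L || sum(x$gold == 0L) < 1L) {
    stop("need at least one diseased and one non-diseased subject",
         call. = FALSE)
  }
  x
}

#' @export
print.trial_data <- function(x, ...) {
  n1 <- sum(x$gold == 1L)
  n0 <- sum(x$gold == 0L)
  cat(sprintf("Diagnostic trial: %d subjects (n1 = %d diseased, n0 = %d non-diseased)\n",
              length(x$subject_id), n1, n0))
  cat(sprintf("Modalities (M = %d): %s\n", ncol(x$results),
              paste(x$modality_labels, collapse = ", ")))
  invisible(x)
}

#' Number of modalities of a trial
#' @param x a `trial_data` object.
#' @return Integer count of modality slots.
#' @export
n_modalities <- function(x) {
  stopifnot(inherits(x, "trial_data"))
  ncol(x$results)
}

#' Read subject-level trial data from CSV
#'
#' Wide format has one row per subject: an identifier column, the gold
#' standard column and one 0/1 column per modality. Long format has one
#' row per (subject, modality) pair with columns for the modality label and
#' the result, and is pivoted to wide on read; each pair must occur exactly
#' once and a subject's gold label must be consistent across rows.
#'
#' @param path path to a CSV file (RFC 4180).
#' @param format `"wide"` or `"long"`.
#' @param id_col,gold_col column names of the subject identifier and the
#'   gold-standard label.
#' @param modality_cols for wide input, the names of the modality columns;
#'   defaults to every column other than `id_col` and `gold_col`.
#' @param modality_col,result_col for long input, the names of the modality
#'   and result columns.
#'
#' @return A validated [trial_data()] object.
#' @export
read_trial_csv <- function(path, format = c("wide", "long"),
                           id_col = "subject_id", gold_col = "gold",
                           modality_cols = NULL,
                           modality_col = "modality", result_col = "result") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("cannot read '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(df) == 0L) stop("'", path, "' contains no data rows", call. = FALSE)
  need <- if (format == "wide") c(id_col, gold_col) else
    c(id_col, gold_col, modality_col, result_col)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (format == "wide") {
    if (is.null(modality_cols)) {
      modality_cols <- setdiff(names(df), c(id_col, gold_col))
    }
    if (length(modality_cols) == 0L) {
      stop("no modality columns found", call. = FALSE)
    }
    res <- as.matrix(df[modality_cols])
    if (!is.numeric(res)) stop("modality columns must be numeric 0/1",
                               call. = FALSE)
    return(trial_data(df[[id_col]], df[[gold_col]], res,
                      modality_labels = modality_cols))
  }
  # long -> wide pivot
  id <- as.character(df[[id_col]])
  mods <- as.character(df[[modality_col]])
  if (anyDuplicated(paste(id, mods, sep = "\r"))) {
    stop("duplicate (subject, modality) pairs in long input", call. = FALSE)
  }
  gold_by_subj <- tapply(df[[gold_col]], id, function(g) {
    u <- unique(g)
    if (length(u) > 1L) NA else u
  })
  if (anyNA(gold_by_subj)) {
    stop("inconsistent gold labels for subject(s): ",
         paste(names(gold_by_subj)[is.na(gold_by_subj)], collapse = ", "),
         call. = FALSE)
  }
  subjects <- unique(id)
  labels <- unique(mods)
  res <- matrix(NA_integer_, length(subjects), length(labels),
                dimnames = list(subjects, labels))
  res[cbind(match(id, subjects), match(mods, labels))] <-
    as.integer(df[[result_col]])
  if (anyNA(res)) {
    stop("incomplete long input: every subject needs a result for every ",
         "modality", call. = FALSE)
  }
  trial_data(subjects, gold_by_subj[subjects], res, modality_labels = labels)
}

#' Write subject-level trial data to CSV
#'
#' @param x a `trial_data` object.
#' @param path output file path.
#' @param format `"wide"` (default) or `"long"`; both round-trip through
#'   [read_trial_csv()].
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "trial_data"))
  if (format == "wide") {
    df <- data.frame(subject_id = x$subject_id, gold = x$gold,
                     x$results, check.names = FALSE)
  } else {
    M <- ncol(x$results)
    df <- data.frame(
      subject_id = rep(x$subject_id, each = M),
      gold = rep(x$gold, each = M),
      modality = rep(x$modality_labels, times = length(x$subject_id)),
      result = as.vector(t(x$results))
    )
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
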