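#' Prepare a three-class diagnostic dataset for bias-corrected analysis
#'
#' Validates a subject-level table, encodes the three disease classes as
#' integers 1/2/3 (1 = least severe), and builds the n x 3 disease
#' indicator matrix consumed by the estimators.  Subjects with
#' `verified == 0` keep missing disease fields: the bias-corrected
#' estimators, not sentinel codes, decide how unverified subjects enter
#' downstream computations.
#'
#' Class codes are assigned from `class_order` when given.  Otherwise
#' numeric labels keep their natural order (so a reversed labeling is
#' surfaced by [check_ordering()] rather than silently remapped), and
#' non-numeric labels are ranked by the class-conditional mean of the
#' test among verified subjects, matching the monotone-ordering
#' assumption that test values increase with disease severity.
#'
#' @param data a data.frame of subjects.
#' @param test name of the continuous diagnostic test column (no missing
#'   values allowed).
#' @param disease name of the disease-status column; must be non-missing
#'   for every verified subject and carry exactly three distinct labels
#'   among them.
#' @param verified name of the binary verification-status column
#'   (1 = disease status observed). If `NULL`, all subjects are treated
#'   as verified.
#' @param covariates character vector of numeric auxiliary covariate
#'   columns (fully observed), or `NULL`.
#' @param class_order optional length-3 vector giving the disease labels
#'   in increasing severity; overrides the mean-based default ordering.
#' @return an object of class `roc3_data`: a list with elements `test`,
#'   `verified`, `disease` (integer codes, `NA` for unverified), `dmat`
#'   (n x 3 indicator matrix, `NA` rows for unverified), `frame` (test +
#'   covariate columns), `mapping` (label -> code), `test_name`,
#'   `covariate_names` and `n`.
#' @examples
#' d <- simulate_roc3(200, seed = 1)
#' x <- prepare_roc3(d, test = "T", disease = "D", verified = "V",
#'                   covariates = "A")
#' x
#' @export
prepare_roc3 <- function(data, test, disease, verified = NULL,
                         covariates = NULL, class_order = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1L)
  for (col in c(test, disease, verified, covariates))
    if (!col %in% names(data))
      stop("column '", col, "' not found in `data`", call. = FALSE)

  t_val <- data[[test]]
  if (!is.numeric(t_val)) stop("test column must be numeric", call. = FALSE)
  if (anyNA(t_val))
    stop("missing values in test column are not allowed; rows with missing ",
         "test results must be resolved upstream, not dropped", call. = FALSE)

  if (is.null(verified)) {
    v <- rep(1L, nrow(data))
  } else {
    v <- data[[verified]]
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("verification status must be 0/1 with no missing values",
           call. = FALSE)
    v <- as.integer(v)
  }
  if (!any(v == 1L)) stop("no verified subjects", call. = FALSE)

  cov_frame <- data[, covariates, drop = FALSE]
  for (nm in covariates) {
    if (!is.numeric(cov_frame[[nm]]))
      stop("covariate '", nm, "' must be numeric", call. = FALSE)
    if (anyNA(cov_frame[[nm]]))
      stop("missing values in covariate '", nm, "' are not allowed",
           call. = FALSE)
  }

  lab <- data[[disease]]
  if (anyNA(lab[v == 1L]))
    stop("disease status is missing for a verified subject", call. = FALSE)
  obs_labels <- unique(lab[v == 1L])
  if (length(obs_labels) != 3L)
    stop("expected exactly three distinct disease classes among verified ",
         "subjects, found ", length(obs_labels), call. = FALSE)

  if (!is.null(class_order)) {
    if (length(class_order) != 3L ||
        !setequal(as.character(class_order), as.character(obs_labels)))
      stop("`class_order` must list the three observed disease labels",
           call. = FALSE)
    ordered_labels <- as.character(class_order)
  } else if (is.numeric(lab)) {
    # numeric codes keep their natural order, so a reversed labeling is
    # surfaced by check_ordering() instead of being silently remapped
    ordered_labels <- as.character(sort(obs_labels))
  } else {
    m <- vapply(obs_labels,
                function(l) mean(t_val[v == 1L & lab == l]), numeric(1))
    ordered_labels <- as.character(obs_labels[order(m)])
  }
  mapping <- setNames(1:3, ordered_labels)

  code <- rep(NA_integer_, nrow(data))
  code[v == 1L] <- mapping[as.character(lab[v == 1L])]
  dmat <- matrix(NA_real_, nrow(data), 3L,
                 dimnames = list(NULL, paste0("D", 1:3)))
  for (k in 1:3) dmat[v == 1L, k] <- as.numeric(code[v == 1L] == k)

  structure(list(test = t_val, verified = v, disease = code, dmat = dmat,
                 frame = cbind(setNames(data.frame(t_val), test), cov_frame),
                 mapping = mapping, test_name = test,
                 covariate_names = covariates %||% character(0),
                 n = nrow(data)),
            class = "roc3_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.roc3_data <- function(x, ...) {
  cat("Three-class diagnostic dataset:", x$n, "subjects,",
      sum(x$verified), "verified\n")
  cat("Verified class counts:",
      paste(table(factor(x$disease, 1:3)), collapse = " / "), "\n")
  cat("Class coding:",
      paste(names(x$mapping), "->", x$mapping, collapse = ", "), "\n")
  invisible(x)
}

#' Check the monotone ordering of the three disease classes
#'
#' Computes the class-conditional means of the diagnostic test among
#' verified subjects and checks that they are strictly increasing in the
#' class code.  Monotone ordering -- class 3 subjects tending to higher
#' test values than class 2, and class 2 higher than class 1 -- is the
#' working assumption of the ROC-surface analysis; a failed check is
#' reported, never raised, so that a user who knows the labels are
#' misordered can relabel and proceed.
#'
#' @param x a `roc3_data` object from [prepare_roc3()].
#' @return an object of class `roc3_ordering` with elements
#'   `class_means`, `satisfied` and `message`.
#' @examples
#' x <- prepare_roc3(simulate_roc3(200, seed = 1), "T", "D", "V", "A")
#' check_ordering(x)
#' @export
check_ordering <- function(x) {
  stopifnot(inherits(x, "roc3_data"))
  counts <- table(factor(x$disease, 1:3))
  if (any(counts == 0))
    stop("class-conditional means are undefined: no verified subject in ",
         "class ", paste(which(counts == 0), collapse = ", "), call. = FALSE)
  m <- vapply(1:3, function(k) {
    mean(x$test[x$verified == 1L & x$disease == k])
  }, numeric(1))
  ok <- m[1] < m[2] && m[2] < m[3]
  msg <- if (ok) {
    "Monotone ordering satisfied: class-conditional test means are strictly increasing."
  } else {
    paste0("Monotone ordering NOT satisfied: class-conditional test means (",
           paste(sprintf("%.4g", m), collapse = ", "),
           ") are not strictly increasing. Consider relabeling the classes ",
           "(e.g. via `class_order`) so that severity increases with the test.")
  }
  structure(list(class_means = m, satisfied = ok, message = msg),
            class = "roc3_ordering")
}

#' @export
print.roc3_ordering <- function(x, ...) {
  cat(x$message, "\n")
  cat("Class means:", paste(sprintf("%.4f", x$class_means), collapse = ", "),
      "\n")
  invisible(x)
}

# Resample/subset a prepared dataset by row index (bootstrap support).
roc3_subset <- function(x, idx) {
  out <- x
  out$test <- x$test[idx]
  out$verified <- x$verified[idx]
  out$disease <- x$disease[idx]
  out$dmat <- x$dmat[idx, , drop = FALSE]
  out$frame <- x$frame[idx, , drop = FALSE]
  rownames(out$frame) <- NULL
  out$n <- length(idx)
  out
}
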