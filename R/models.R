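#' Fit the verification-probability model
#'
#' Binary regression of the verification status on the diagnostic test
#' and auxiliary covariates, giving the verification probabilities
#' \eqn{\hat\pi_i = \Pr(V_i = 1 \mid T_i, A_i)} needed by the IPW and SPE
#' estimators.  Under missing at random, verification may depend on the
#' test and covariates but not on the unobserved disease status, so this
#' model is fit on all subjects.
#'
#' Fitted probabilities are floored at `pi_floor` before use as inverse
#' weights; near-zero verification probabilities otherwise make IPW/SPE
#' numerically explosive.  The number of floored values is recorded in
#' the returned object.
#'
#' @param x a `roc3_data` object.
#' @param predictors character vector of predictor columns (default: the
#'   test plus all covariates).
#' @param link `"logit"` (default), `"probit"`, or `"threshold"`.  The
#'   threshold option is accepted as an alias for the complementary
#'   log-log link; see the package vignette for the rationale.
#' @param pi_floor lower floor applied to fitted probabilities
#'   (default `1e-6`); set to 0 to disable.
#' @return an object of class `verif_fit`: list with `link`,
#'   `coefficients`, `pi` (floored, length n), `pi_raw`, `n_floored`,
#'   `predictors` and the underlying `glm` fit.
#' @examples
#' x <- prepare_roc3(simulate_roc3(300, seed = 1), "T", "D", "V", "A")
#' pi_fit <- fit_verification(x)
#' coef(pi_fit$fit)
#' @export
fit_verification <- function(x, predictors = NULL,
                             link = c("logit", "probit", "threshold"),
                             pi_floor = 1e-6) {
  stopifnot(inherits(x, "roc3_data"))
  link <- match.arg(link)
  glm_link <- c(logit = "logit", probit = "probit",
                threshold = "cloglog")[[link]]
  predictors <- predictors %||% names(x$frame)
  missing_p <- setdiff(predictors, names(x$frame))
  if (length(missing_p))
    stop("unknown predictor(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  if (length(unique(x$verified)) < 2L)
    stop("verification status must contain both 0 and 1", call. = FALSE)

  df <- cbind(.V = x$verified, x$frame[, predictors, drop = FALSE])
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.V ~ ., data = df, family = binomial(link = glm_link)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated) {
    # Extreme fitted probabilities alone are not separation: with strong
    # true effects |eta| legitimately exceeds the double-precision logit
    # range.  Separation makes the MLE diverge, so flag only coefficients
    # whose standardized magnitude is implausibly large.
    cf <- coef(fit)[-1]
    sds <- vapply(x$frame[, predictors, drop = FALSE], sd, numeric(1))
    std_cf <- abs(cf) * sds
    if (any(std_cf > 15)) {
      worst <- names(cf)[which.max(std_cf)]
      stop("(quasi-)perfect separation detected in the verification model; ",
           "offending predictor: ", worst, call. = FALSE)
    }
  }
  pi_raw <- as.numeric(predict(fit, type = "response"))
  pi <- pmax(pi_raw, pi_floor)
  structure(list(link = link, coefficients = coef(fit), pi = pi,
                 pi_raw = pi_raw, n_floored = sum(pi_raw < pi_floor),
                 pi_floor = pi_floor, predictors = predictors, fit = fit),
            class = "verif_fit")
}

#' @export
print.verif_fit <- function(x, ...) {
  cat("Verification model (", x$link, " link)\n", sep = "")
  print(round(x$coefficients, 4))
  if (x$n_floored > 0)
    cat(x$n_floored, "fitted probabilities floored at", x$pi_floor, "\n")
  invisible(x)
}

#' Fit disease-class probabilities by multinomial logistic regression
#'
#' Multinomial logit model for the three-class disease status given the
#' test and covariates, fit on verified subjects only (valid under
#' missing at random) with class 1 as the baseline category.  The fitted
#' probabilities \eqn{\hat\rho_k(T_i, A_i)} are predicted for every
#' subject, verified or not; they drive the FI, MSI and SPE estimators.
#'
#' @param x a `roc3_data` object.
#' @param predictors character vector of predictor columns (default: the
#'   test plus all covariates).
#' @param maxit maximum optimizer iterations passed to
#'   [nnet::multinom()].
#' @return an object of class `rho_fit`: list with `method = "mlogit"`,
#'   `rho` (n x 3, rows sum to 1), `coefficients` (class-vs-baseline),
#'   `predictors` and the underlying `multinom` fit.
#' @examples
#' x <- prepare_roc3(simulate_roc3(300, seed = 1), "T", "D", "V", "A")
#' rho <- fit_rho_mlogit(x)
#' head(rho$rho)
#' @export
fit_rho_mlogit <- function(x, predictors = NULL, maxit = 500) {
  stopifnot(inherits(x, "roc3_data"))
  predictors <- predictors %||% names(x$frame)
  missing_p <- setdiff(predictors, names(x$frame))
  if (length(missing_p))
    stop("unknown predictor(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  ver <- x$verified == 1L
  counts <- table(factor(x$disease[ver], 1:3))
  if (any(counts == 0))
    stop("class ", paste(which(counts == 0), collapse = ", "),
         " has no verified subjects; cannot fit the disease model",
         call. = FALSE)

  df <- cbind(.D = factor(x$disease, levels = 1:3),
              x$frame[, predictors, drop = FALSE])
  fit <- nnet::multinom(.D ~ ., data = df[ver, , drop = FALSE],
                        trace = FALSE, maxit = maxit)
  if (fit$convergence != 0)
    stop("multinomial logistic fit did not converge within ", maxit,
         " iterations", call. = FALSE)
  rho <- predict(fit, newdata = df, type = "probs")
  rho <- matrix(as.numeric(rho), ncol = 3,
                dimnames = list(NULL, paste0("rho", 1:3)))
  structure(list(method = "mlogit", rho = rho, coefficients = coef(fit),
                 predictors = predictors, fit = fit),
            class = "rho_fit")
}

#' Fit disease-class probabilities by K nearest-neighbor regression
#'
#' Nonparametric alternative to the multinomial logit disease model: for
#' each subject, \eqn{\hat\rho_k} is the average of the class-k
#' indicators over the K verified subjects nearest in standardized
#' predictor space (Euclidean distance; predictors centred and scaled by
#' the verified-subject mean and standard deviation).  Ties at the K-th
#' distance are broken by lowest subject index, so the fit is fully
#' deterministic.
#'
#' @param x a `roc3_data` object.
#' @param k number of neighbors, `1 <= k <=` number of verified subjects.
#' @param predictors character vector of predictor columns (default: the
#'   test plus all covariates).
#' @param loo if `TRUE`, a verified subject is excluded from its own
#'   neighbor set (leave-one-out prediction); default `FALSE`.
#' @return an object of class `rho_fit` with `method = "knn"`, `rho`
#'   (n x 3), `k` and `distance = "euclidean"`.
#' @seealso [choose_k()] for cross-validated selection of `k`.
#' @examples
#' x <- prepare_roc3(simulate_roc3(300, seed = 1), "T", "D", "V", "A")
#' rho <- fit_rho_knn(x, k = 15)
#' @export
fit_rho_knn <- function(x, k, predictors = NULL, loo = FALSE) {
  stopifnot(inherits(x, "roc3_data"))
  predictors <- predictors %||% names(x$frame)
  missing_p <- setdiff(predictors, names(x$frame))
  if (length(missing_p))
    stop("unknown predictor(s): ", paste(missing_p, collapse = ", "),
         call. = FALSE)
  ver_idx <- which(x$verified == 1L)
  nv <- length(ver_idx)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  if (k > nv - as.integer(loo))
    stop("k (", k, ") exceeds the number of available verified neighbors (",
         nv - as.integer(loo), ")", call. = FALSE)

  X <- as.matrix(x$frame[, predictors, drop = FALSE])
  ctr <- colMeans(X[ver_idx, , drop = FALSE])
  scl <- apply(X[ver_idx, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)

  rho <- knn_average(Xs, Xs[ver_idx, , drop = FALSE],
                     x$dmat[ver_idx, , drop = FALSE], k,
                     ref_index = ver_idx,
                     self_index = if (loo) seq_len(x$n) else NULL)
  colnames(rho) <- paste0("rho", 1:3)
  structure(list(method = "knn", rho = rho, k = k,
                 distance = "euclidean", predictors = predictors,
                 loo = loo),
            class = "rho_fit")
}

# KNN class-indicator averaging.  Xq: query matrix; Xr: reference matrix
# (rows = verified subjects); Dr: reference indicator rows; ref_index:
# original subject index of each reference row (tie-break key);
# self_index: original index of each query row, used to drop a query's
# own reference row (leave-one-out) when non-NULL.
knn_average <- function(Xq, Xr, Dr, k, ref_index, self_index = NULL) {
  nq <- nrow(Xq)
  rho <- matrix(0, nq, 3)
  for (i in seq_len(nq)) {
    d2 <- colSums((t(Xr) - Xq[i, ])^2)
    if (!is.null(self_index)) {
      drop_row <- which(ref_index == self_index[i])
      if (length(drop_row)) d2[drop_row] <- Inf
    }
    nb <- order(d2, ref_index)[seq_len(k)]
    rho[i, ] <- colMeans(Dr[nb, , drop = FALSE])
  }
  rho
}

#' @export
print.rho_fit <- function(x, ...) {
  if (x$method == "mlogit") {
    cat("Disease model: multinomial logit (baseline class 1)\n")
    print(round(x$coefficients, 4))
  } else {
    cat("Disease model: ", x$k, "-nearest-neighbor (",
        x$distance, " distance)\n", sep = "")
  }
  invisible(x)
}

#' Choose K for the nearest-neighbor disease model by cross-validation
#'
#' V-fold cross-validation on the verified subjects: each held-out
#' subject's disease indicator row is predicted by KNN averaging over the
#' training verified subjects, and the score for a candidate K is the
#' mean squared error between held-out indicator rows and predictions.
#' The K minimizing the score wins; ties go to the smaller K.
#'
#' @param x a `roc3_data` object.
#' @param predictors predictor columns (default: test plus covariates).
#' @param k_grid candidate K values; default the odd numbers
#'   `1, 3, 5, ...` up to `ceiling(sqrt(n_verified))` rounded up to odd.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `k` (selected) and `table` (data.frame of `k`,
#'   `score`).
#' @examples
#' x <- prepare_roc3(simulate_roc3(300, seed = 1), "T", "D", "V", "A")
#' choose_k(x, seed = 7)$k
#' @export
choose_k <- function(x, predictors = NULL, k_grid = NULL, folds = 10,
                     seed = NULL) {
  stopifnot(inherits(x, "roc3_data"))
  predictors <- predictors %||% names(x$frame)
  ver_idx <- which(x$verified == 1L)
  nv <- length(ver_idx)
  if (folds < 2) stop("folds must be at least 2", call. = FALSE)
  if (folds > nv) stop("folds exceeds the number of verified subjects",
                       call. = FALSE)
  if (is.null(k_grid)) {
    kmax <- ceiling(sqrt(nv))
    if (kmax %% 2 == 0) kmax <- kmax + 1
    k_grid <- seq(1L, kmax, by = 2L)
  }
  if (!length(k_grid)) stop("k_grid is empty", call. = FALSE)
  max_train <- nv - ceiling(nv / folds)
  if (any(k_grid > max_train))
    stop("k_grid contains values larger than the training-fold size (",
         max_train, ")", call. = FALSE)

  X <- as.matrix(x$frame[, predictors, drop = FALSE])
  ctr <- colMeans(X[ver_idx, , drop = FALSE])
  scl <- apply(X[ver_idx, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)[ver_idx, , drop = FALSE]
  D <- x$dmat[ver_idx, , drop = FALSE]

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fold_id <- sample(rep_len(seq_len(folds), nv))

  scores <- vapply(k_grid, function(k) {
    se <- 0
    for (f in seq_len(folds)) {
      hold <- fold_id == f
      pred <- knn_average(Xs[hold, , drop = FALSE],
                          Xs[!hold, , drop = FALSE],
                          D[!hold, , drop = FALSE], k,
                          ref_index = ver_idx[!hold])
      se <- se + sum((D[hold, , drop = FALSE] - pred)^2)
    }
    se / (3 * nv)
  }, numeric(1))

  tab <- data.frame(k = k_grid, score = scores)
  list(k = k_grid[which.min(scores)], table = tab)
}
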