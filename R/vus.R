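#' VUS point estimate from a bias-corrected disease matrix
#'
#' Tie-weighted trivariate Mann-Whitney statistic: with weights
#' \eqn{w(a,b,c)} equal to 1 for \eqn{a<b<c}, 1/2 for one adjacent tie
#' (\eqn{a=b<c} or \eqn{a<b=c}), 1/6 for a triple tie and 0 otherwise,
#' the estimate is
#' \deqn{\widehat{VUS} = \frac{\sum_i \sum_j \sum_l w(T_i,T_j,T_l)
#'   \hat D_{1i} \hat D_{2j} \hat D_{3l}}
#'   {(\sum_i \hat D_{1i})(\sum_j \hat D_{2j})(\sum_l \hat D_{3l})}.}
#' The ratio normalisation makes the IPW variant a Hajek-style estimator
#' and leaves the statistic invariant to rescaling of \eqn{\hat D}
#' columns.  The sum is evaluated by an O(n log n) sorted
#' cumulative-sum kernel that is exactly equal to the naive triple loop.
#'
#' The estimate depends on the test values only through their ordering
#' and ties, so it is invariant under strictly increasing transformations
#' of the test.  It equals 1 for a test that separates the three classes
#' perfectly and 1/6 for a useless test (e.g. all test values tied).
#'
#' @param dhat an n x 3 `disease_hat` matrix (or any numeric n x 3
#'   matrix of disease values).
#' @param test length-n numeric vector of diagnostic test values.
#' @return the VUS estimate (scalar).
#' @examples
#' ## perfectly separated classes
#' t <- c(1, 2, 3, 4, 5, 6)
#' d <- diag(3)[rep(1:3, each = 2), ]
#' vus_point(d, t)  # 1
#' @export
vus_point <- function(dhat, test) {
  dhat <- as_dhat_matrix(dhat)
  if (length(test) != nrow(dhat))
    stop("`test` and `dhat` must have matching length", call. = FALSE)
  if (anyNA(test) || anyNA(dhat))
    stop("missing values in `test` or `dhat`", call. = FALSE)
  cs <- colSums(dhat)
  if (any(cs <= 0))
    stop("non-positive column sum in `dhat` (class ",
         paste(which(cs <= 0), collapse = ", "),
         " carries no estimated mass)", call. = FALSE)
  cpp_vus(as.numeric(test), dhat)
}

as_dhat_matrix <- function(dhat) {
  m <- unclass(dhat)
  if (!is.matrix(m) || ncol(m) != 3L || !is.numeric(m))
    stop("`dhat` must be a numeric n x 3 matrix", call. = FALSE)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

#' Jackknife variance of the VUS estimate
#'
#' Leave-one-out jackknife over subjects: the VUS is recomputed with
#' subject i removed, keeping the fitted disease/verification
#' probabilities of the remaining subjects fixed (models are not refit),
#' and the variance is \eqn{\frac{n-1}{n}\sum_i (\widehat{VUS}_{(-i)} -
#' \overline{\widehat{VUS}_{(\cdot)}})^2}.  This is the package's
#' asymptotic-variance route; [vus_variance_bootstrap()] additionally
#' propagates model-refitting variability.
#'
#' @param dhat an n x 3 `disease_hat` matrix.
#' @param test length-n numeric vector of test values.
#' @return the jackknife variance estimate (scalar, nonnegative).
#' @export
vus_variance_jackknife <- function(dhat, test) {
  dhat <- as_dhat_matrix(dhat)
  n <- nrow(dhat)
  if (n < 10) stop("jackknife variance requires at least 10 subjects",
                   call. = FALSE)
  loo <- cpp_vus_loo(as.numeric(test), dhat)
  if (anyNA(loo))
    stop("a leave-one-out replicate leaves a class with no estimated mass",
         call. = FALSE)
  (n - 1) / n * sum((loo - mean(loo))^2)
}

#' Bootstrap variance of the VUS estimate
#'
#' Nonparametric bootstrap over subjects: each replicate resamples
#' subjects with replacement, refits the verification and disease models
#' required by `method`, and recomputes the VUS.  Replicate r uses seed
#' `seed + r`, and parallelism distributes whole replicates, so the
#' result is identical for any `workers` count.  A replicate whose
#' verified subjects lose an entire disease class is redrawn (up to
#' `100 * B` attempts in total).
#'
#' @param x a `roc3_data` object.
#' @param method estimation method (see [disease_hat()]).
#' @param B number of bootstrap replicates (at least 2).
#' @param seed integer base seed.
#' @param workers number of parallel workers (forked; 1 = serial).
#' @param verif_predictors,disease_predictors,link,k,pi_floor model
#'   options, as in [vus()].
#' @return the bootstrap variance (scalar) with the replicate estimates
#'   in attribute `"replicates"`.
#' @export
vus_variance_bootstrap <- function(x, method, B = 250, seed = 1,
                                   workers = 1,
                                   verif_predictors = NULL,
                                   disease_predictors = NULL,
                                   link = "logit", k = NULL,
                                   pi_floor = 1e-6) {
  stopifnot(inherits(x, "roc3_data"))
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  reps <- boot_replicates(x, method, B, seed, workers,
                          stat = function(xb) {
                            fits <- fit_for_method(xb, method,
                                                   verif_predictors,
                                                   disease_predictors,
                                                   link, k, pi_floor)
                            vus_point(disease_hat(xb, method,
                                                  rho = fits$rho,
                                                  verif = fits$verif),
                                      xb$test)
                          })
  reps <- unlist(reps)
  structure(var(reps), replicates = reps)
}

# Draw B bootstrap resamples of x (redrawing resamples that lose a
# verified class), apply stat() to each, distributing replicates over
# forked workers.  Replicate r is driven entirely by seed + r.
boot_replicates <- function(x, method, B, seed, workers, stat) {
  one <- function(r) {
    for (attempt in seq_len(100L)) {
      set.seed(seed + r + (attempt - 1L) * 1000003L)
      idx <- sample.int(x$n, x$n, replace = TRUE)
      xb <- roc3_subset(x, idx)
      counts <- table(factor(xb$disease[xb$verified == 1L], 1:3))
      if (any(counts == 0)) next
      # a replicate on which the estimator is undefined (a class left
      # with no estimated mass, e.g. SPE with an extreme inverse weight)
      # or whose disease model degenerates (quasi-separation in the
      # resample) is redrawn like a replicate that lost a verified class
      val <- tryCatch(stat(xb), error = function(e) {
        if (grepl("non-positive column sum|did not converge",
                  conditionMessage(e))) NULL
        else stop(e)
      })
      if (!is.null(val)) return(val)
    }
    stop("bootstrap replicate ", r, " repeatedly lost an entire verified ",
         "class or yielded an undefined estimate; the sample cannot be ",
         "bootstrapped", call. = FALSE)
  }
  if (workers > 1 && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(seq_len(B), one, mc.cores = workers)
    err <- vapply(res, inherits, logical(1), "try-error")
    if (any(err)) stop(attr(res[[which(err)[1]]], "condition"))
    res
  } else {
    lapply(seq_len(B), one)
  }
}

# Fit whatever models `method` needs on dataset x.
fit_for_method <- function(x, method, verif_predictors, disease_predictors,
                           link, k, pi_floor) {
  rho <- verif <- NULL
  if (method %in% c("fi", "msi", "spe")) {
    rho <- fit_rho_mlogit(x, disease_predictors)
  } else if (method == "knn") {
    if (is.null(k)) {
      nv <- sum(x$verified)
      k <- ceiling(sqrt(nv))
      if (k %% 2 == 0) k <- k + 1
      k <- min(k, nv)
    }
    rho <- fit_rho_knn(x, k = k, predictors = disease_predictors)
  }
  if (method %in% c("ipw", "spe"))
    verif <- fit_verification(x, verif_predictors, link = link,
                              pi_floor = pi_floor)
  list(rho = rho, verif = verif)
}

#' Confidence interval for the VUS
#'
#' Normal scale: `estimate +/- z * se`.  Logit scale: the interval is
#' built for `logit(estimate)` with the delta-method standard error
#' `se / (estimate * (1 - estimate))` and mapped back, which keeps the
#' bounds strictly inside (0, 1).
#'
#' @param estimate VUS point estimate.
#' @param se standard error (nonnegative).
#' @param level confidence level in (0, 1); default 0.95.
#' @param scale `"normal"` or `"logit"`.
#' @return named numeric `c(lower, upper)`.
#' @examples
#' vus_ci(0.5150, 0.0404, scale = "logit")
#' @export
vus_ci <- function(estimate, se, level = 0.95,
                   scale = c("normal", "logit")) {
  scale <- match.arg(scale)
  stopifnot(level > 0, level < 1, se >= 0)
  z <- qnorm((1 + level) / 2)
  if (scale == "normal") {
    out <- c(estimate - z * se, estimate + z * se)
  } else {
    if (estimate <= 0 || estimate >= 1)
      stop("logit-scale interval requires an estimate strictly inside ",
           "(0, 1)", call. = FALSE)
    se_l <- se / (estimate * (1 - estimate))
    out <- plogis(qlogis(estimate) + c(-1, 1) * z * se_l)
  }
  setNames(out, c("lower", "upper"))
}

#' Test the useless-test null VUS = 1/6
#'
#' One-sided asymptotic test of H0: VUS = 1/6 against H1: VUS > 1/6
#' using \eqn{t = (\widehat{VUS} - 1/6)/\sqrt{\widehat{Var}}}, referred
#' to the standard normal upper tail.
#'
#' @param estimate VUS point estimate.
#' @param variance positive variance estimate.
#' @return list with `statistic` and `p.value`.
#' @examples
#' vus_test(0.5150, 0.0404^2)
#' @export
vus_test <- function(estimate, variance) {
  if (!is.numeric(variance) || variance <= 0)
    stop("variance must be positive", call. = FALSE)
  t_stat <- (estimate - 1 / 6) / sqrt(variance)
  list(statistic = t_stat, p.value = pnorm(t_stat, lower.tail = FALSE))
}

#' Bias-corrected VUS estimation with variance, intervals and test
#'
#' End-to-end inference for one estimation method: fits the models the
#' method needs, builds the bias-corrected disease matrix, computes the
#' VUS, its variance (jackknife or bootstrap), confidence intervals on
#' the normal and logit scales, and the test of H0: VUS = 1/6.
#'
#' @param x a `roc3_data` object.
#' @param method `"full"`, `"fi"`, `"msi"`, `"ipw"`, `"spe"` or
#'   `"knn"`.
#' @param variance `"jackknife"` (default) or `"bootstrap"`.
#' @param verif_predictors,disease_predictors predictor columns for the
#'   verification / disease models (default: test plus all covariates).
#' @param link verification-model link (see [fit_verification()]).
#' @param k neighbor count for `method = "knn"`; default
#'   `sqrt(n_verified)` rounded up to odd.
#' @param B bootstrap replicates when `variance = "bootstrap"`.
#' @param seed base seed for the bootstrap.
#' @param workers parallel workers for the bootstrap.
#' @param level confidence level (default 0.95).
#' @param pi_floor floor for fitted verification probabilities.
#' @return an object of class `vus_result`: list with `estimate`,
#'   `variance`, `se`, `ci_normal`, `ci_logit` (NA with a warning when
#'   the estimate falls outside (0, 1)), `t_stat`, `p_value`, `level`,
#'   `method`, `variance_method`, `n` and the fitted model objects.
#' @examples
#' x <- prepare_roc3(simulate_roc3(400, seed = 2), "T", "D", "V", "A")
#' vus(x, "spe")
#' @export
vus <- function(x, method = c("full", "fi", "msi", "ipw", "spe", "knn"),
                variance = c("jackknife", "bootstrap"),
                verif_predictors = NULL, disease_predictors = NULL,
                link = "logit", k = NULL, B = 250, seed = 1,
                workers = 1, level = 0.95, pi_floor = 1e-6) {
  stopifnot(inherits(x, "roc3_data"))
  method <- match.arg(method)
  variance <- match.arg(variance)

  fits <- fit_for_method(x, method, verif_predictors, disease_predictors,
                         link, k, pi_floor)
  dh <- disease_hat(x, method, rho = fits$rho, verif = fits$verif)
  est <- vus_point(dh, x$test)

  v <- if (variance == "jackknife") {
    vus_variance_jackknife(dh, x$test)
  } else {
    as.numeric(vus_variance_bootstrap(x, method, B = B, seed = seed,
                                      workers = workers,
                                      verif_predictors = verif_predictors,
                                      disease_predictors = disease_predictors,
                                      link = link, k = k,
                                      pi_floor = pi_floor))
  }
  se <- sqrt(v)
  ci_n <- vus_ci(est, se, level, "normal")
  ci_l <- if (est > 0 && est < 1) {
    vus_ci(est, se, level, "logit")
  } else {
    warning("estimate outside (0, 1): logit-scale interval unavailable",
            call. = FALSE)
    c(lower = NA_real_, upper = NA_real_)
  }
  tst <- vus_test(est, v)

  structure(list(estimate = est, variance = v, se = se,
                 ci_normal = ci_n, ci_logit = ci_l, level = level,
                 t_stat = tst$statistic, p_value = tst$p.value,
                 method = method, variance_method = variance,
                 n = x$n, rho = fits$rho, verif = fits$verif),
            class = "vus_result")
}

format_pval <- function(p) if (p < 1e-4) "< 0.0001" else sprintf("%.4f", p)

#' @export
print.vus_result <- function(x, ...) {
  cat("Bias-corrected VUS estimate (method: ", x$method, ", variance: ",
      x$variance_method, ")\n", sep = "")
  cat(sprintf("  Estimate: %.4f   Std.Err: %.4f\n", x$estimate, x$se))
  cat(sprintf("  %g%% CI (normal): [%.4f, %.4f]\n", 100 * x$level,
              x$ci_normal[1], x$ci_normal[2]))
  if (!anyNA(x$ci_logit))
    cat(sprintf("  %g%% CI (logit) : [%.4f, %.4f]\n", 100 * x$level,
                x$ci_logit[1], x$ci_logit[2]))
  cat(sprintf("  H0: VUS = 1/6 vs H1: VUS > 1/6:  t = %.4f, p %s\n",
              x$t_stat,
              if (x$p_value < 1e-4) format_pval(x$p_value)
              else paste("=", format_pval(x$p_value))))
  invisible(x)
}
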