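#' True class fractions at a cut-point pair
#'
#' For cut-points \eqn{c_1 \le c_2}, the three true class fractions are
#' the bias-corrected analogues of
#' TCF1 = P(T <= c1 | class 1), TCF2 = P(c1 < T <= c2 | class 2),
#' TCF3 = P(T > c2 | class 3), estimated as ratios of
#' \eqn{\hat D}-weighted indicator sums to the \eqn{\hat D} column sums.
#' The interval convention is half-open, right-closed: class-2 mass
#' exactly at \eqn{c_2} counts as correctly classified.
#'
#' @param dhat an n x 3 `disease_hat` matrix.
#' @param test length-n numeric test values.
#' @param c1,c2 cut-points with `c1 <= c2`.
#' @return named numeric `c(tcf1, tcf2, tcf3)` with attribute `cuts`.
#'   FI/MSI/KNN/full values lie in \[0, 1\]; IPW/SPE values may exit.
#' @examples
#' t <- 1:6
#' d <- diag(3)[rep(1:3, each = 2), ]
#' tcf_at(d, t, 2.5, 4.5)  # (1, 1, 1): perfectly separating cuts
#' @export
tcf_at <- function(dhat, test, c1, c2) {
  if (c1 > c2) stop("c1 must not exceed c2", call. = FALSE)
  dhat <- as_dhat_matrix(dhat)
  cs <- colSums(dhat)
  if (any(cs <= 0))
    stop("non-positive column sum in `dhat`", call. = FALSE)
  out <- c(tcf1 = sum(dhat[, 1] * (test <= c1)) / cs[1],
           tcf2 = sum(dhat[, 2] * (test > c1 & test <= c2)) / cs[2],
           tcf3 = sum(dhat[, 3] * (test > c2)) / cs[3])
  attr(out, "cuts") <- c(c1 = c1, c2 = c2)
  out
}

#' Bias-corrected ROC surface over a cut-point grid
#'
#' Evaluates the true class fractions on every admissible pair
#' (`c1 <= c2`) of grid cut-points.  The default grid is the set of
#' unique observed test values augmented with -Inf/+Inf sentinels, so
#' the surface attains the corner vertices (1,0,0), (0,1,0) and
#' (0,0,1) exactly.
#'
#' @param dhat an n x 3 `disease_hat` matrix.
#' @param test length-n numeric test values.
#' @param grid either `NULL` (default grid), a single integer giving the
#'   number of equally spaced interior cut-points, or a sorted numeric
#'   vector of cut-points (sentinels are appended in all cases).
#' @return an object of class `roc3_surface`: list with `points` (a
#'   data.frame with columns `c1`, `c2`, `tcf1`, `tcf2`, `tcf3`), `grid`
#'   and `method`.
#' @seealso [surface_volume()] for the grid-integrated volume.
#' @export
roc_surface <- function(dhat, test, grid = NULL) {
  method <- attr(dhat, "method") %||% "unknown"
  dhat <- as_dhat_matrix(dhat)
  cs <- colSums(dhat)
  if (any(cs <= 0)) stop("non-positive column sum in `dhat`", call. = FALSE)
  if (is.null(grid)) {
    g <- sort(unique(test))
  } else if (length(grid) == 1L && grid == round(grid)) {
    if (grid < 2) stop("grid size must be at least 2", call. = FALSE)
    g <- seq(min(test), max(test), length.out = grid)
  } else {
    if (!length(grid)) stop("empty cut-point grid", call. = FALSE)
    if (is.unsorted(grid)) stop("explicit grid must be sorted", call. = FALSE)
    g <- unique(as.numeric(grid))
  }
  g <- c(-Inf, g, Inf)
  ng <- length(g)

  # cumulative D-hat mass at or below each grid value, per class
  Fk <- vapply(1:3, function(k) {
    vapply(g, function(c) sum(dhat[, k] * (test <= c)), numeric(1)) / cs[k]
  }, numeric(ng))

  pairs <- which(outer(seq_len(ng), seq_len(ng), "<="), arr.ind = TRUE)
  i1 <- pairs[, 1]; i2 <- pairs[, 2]
  pts <- data.frame(c1 = g[i1], c2 = g[i2],
                    tcf1 = Fk[i1, 1],
                    tcf2 = Fk[i2, 2] - Fk[i1, 2],
                    tcf3 = 1 - Fk[i2, 3])
  structure(list(points = pts, grid = g, method = method,
                 Fk = Fk),
            class = "roc3_surface")
}

#' @export
print.roc3_surface <- function(x, ...) {
  cat("ROC surface (method:", x$method, ") on",
      length(x$grid), "cut-points,", nrow(x$points), "admissible pairs\n")
  invisible(x)
}

#' Grid-integrated volume under a ROC surface
#'
#' Integrates TCF2 over the (TCF1, TCF3) footprint of the surface as a
#' Riemann sum over grid cells.  When the grid contains all unique test
#' values and the test values are distinct, this reproduces the
#' tie-free VUS point estimate exactly; on coarser grids it is an
#' approximation.
#'
#' @param surface a `roc3_surface` object.
#' @return the integrated volume (scalar).
#' @export
surface_volume <- function(surface) {
  stopifnot(inherits(surface, "roc3_surface"))
  g <- surface$grid
  Fk <- surface$Fk
  ng <- length(g)
  d1 <- diff(c(0, Fk[, 1]))       # class-1 mass arriving at each grid value
  d3 <- diff(c(0, Fk[, 3]))       # class-3 mass arriving at each grid value
  vol <- 0
  for (i in seq_len(ng)) {        # c1 at grid value i (class-1 atom)
    if (d1[i] == 0) next
    j <- i:ng
    vol <- vol + d1[i] * sum(d3[j] * (Fk[j, 2] - Fk[i, 2]))
  }
  vol
}

#' Ellipsoidal confidence region for the true class fractions
#'
#' At a fixed cut-point pair, the sampling variability of the estimated
#' TCF 3-vector is summarised by a bootstrap covariance matrix, and the
#' confidence region is the ellipsoid
#' \eqn{\{x : (x - \hat c)^\top \Sigma^{-1} (x - \hat c) \le
#' \chi^2_{3}(level)\}} centred at the point estimate.  Bootstrap
#' replicates follow the same resampling and seeding contract as
#' [vus_variance_bootstrap()].
#'
#' @param x a `roc3_data` object.
#' @param method estimation method (see [disease_hat()]).
#' @param c1,c2 cut-points with `c1 <= c2`.
#' @param level confidence level in (0, 1).
#' @param B bootstrap replicates.
#' @param seed base seed.
#' @param workers parallel workers.
#' @param verif_predictors,disease_predictors,link,k,pi_floor model
#'   options as in [vus()].
#' @return an object of class `tcf_region`: list with `center`,
#'   `covariance`, `precision` (inverse, pseudo-inverse when the
#'   covariance is singular, flagged by `degenerate`), `radius2`
#'   (chi-square 3-df quantile), `level`, `cuts` and `replicates`.
#' @export
tcf_ellipsoid <- function(x, method, c1, c2, level = 0.95, B = 250,
                          seed = 1, workers = 1,
                          verif_predictors = NULL,
                          disease_predictors = NULL, link = "logit",
                          k = NULL, pi_floor = 1e-6) {
  stopifnot(inherits(x, "roc3_data"), level > 0, level < 1)
  if (c1 > c2) stop("c1 must not exceed c2", call. = FALSE)

  fits <- fit_for_method(x, method, verif_predictors, disease_predictors,
                         link, k, pi_floor)
  center <- tcf_at(disease_hat(x, method, rho = fits$rho,
                               verif = fits$verif), x$test, c1, c2)

  reps <- boot_replicates(x, method, B, seed, workers,
                          stat = function(xb) {
                            fb <- fit_for_method(xb, method,
                                                 verif_predictors,
                                                 disease_predictors,
                                                 link, k, pi_floor)
                            as.numeric(tcf_at(disease_hat(xb, method,
                                                          rho = fb$rho,
                                                          verif = fb$verif),
                                              xb$test, c1, c2))
                          })
  reps <- do.call(rbind, reps)
  colnames(reps) <- c("tcf1", "tcf2", "tcf3")
  covm <- cov(reps)
  degenerate <- FALSE
  prec <- tryCatch(solve(covm), error = function(e) {
    degenerate <<- TRUE
    MASS::ginv(covm)
  })
  if (!degenerate && rcond(covm) < 1e-12) {
    degenerate <- TRUE
    prec <- MASS::ginv(covm)
  }

  structure(list(center = center, covariance = covm, precision = prec,
                 radius2 = qchisq(level, df = 3), level = level,
                 cuts = c(c1 = c1, c2 = c2), method = method,
                 degenerate = degenerate, replicates = reps),
            class = "tcf_region")
}

#' Test whether a TCF vector lies inside an ellipsoidal region
#'
#' @param region a `tcf_region` object.
#' @param tcf numeric 3-vector (tcf1, tcf2, tcf3).
#' @return logical.
#' @export
in_region <- function(region, tcf) {
  stopifnot(inherits(region, "tcf_region"), length(tcf) == 3L)
  d <- as.numeric(tcf) - as.numeric(region$center)
  drop(t(d) %*% region$precision %*% d) <= region$radius2
}

#' @export
print.tcf_region <- function(x, ...) {
  cat(sprintf("%g%% ellipsoidal confidence region at cuts (%.4g, %.4g), method %s\n",
              100 * x$level, x$cuts[1], x$cuts[2], x$method))
  cat("  Center (TCF1, TCF2, TCF3):",
      paste(sprintf("%.4f", x$center), collapse = ", "), "\n")
  if (x$degenerate)
    cat("  NOTE: singular bootstrap covariance; pseudo-inverse used\n")
  invisible(x)
}
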