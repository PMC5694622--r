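#' Configuration of the synthetic three-class verification-bias design
#'
#' The generator emulates a verification-biased diagnostic study: the
#' disease class is trinomial with probabilities `theta`; given class k
#' the test and one auxiliary covariate are bivariate normal with mean
#' `k * mean_base` and common covariance `sigma`; and verification is
#' Bernoulli with success probability
#' `plogis(verif_coef[1] + verif_coef[2] * T + verif_coef[3] * A)`,
#' which depends only on observables (missing at random).  The defaults
#' give a moderately informative marker with partial overlap between
#' adjacent classes and roughly 55% overall verification.
#'
#' @param theta class probabilities (positive, summing to 1); default
#'   `c(0.40, 0.35, 0.25)`.
#' @param mean_base class-mean base 2-vector for (test, covariate);
#'   class k has mean `k * mean_base`; default `c(2, 1)`.
#' @param sigma common 2 x 2 covariance of (test, covariate) within
#'   class, symmetric positive semi-definite; default
#'   `matrix(c(1.75, 0.1, 0.1, 2.5), 2)`.
#' @param verif_coef (intercept, test, covariate) coefficients of the
#'   logistic verification model; default `c(1, -2.2, 4)`.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(theta = c(0.40, 0.35, 0.25),
                       mean_base = c(2, 1),
                       sigma = matrix(c(1.75, 0.1, 0.1, 2.5), 2),
                       verif_coef = c(1, -2.2, 4)) {
  stopifnot(length(theta) == 3L, all(theta > 0),
            abs(sum(theta) - 1) < 1e-12,
            length(mean_base) == 2L,
            is.matrix(sigma), all(dim(sigma) == 2L),
            isTRUE(all.equal(sigma, t(sigma))),
            length(verif_coef) == 3L)
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10))
    stop("sigma must be positive semi-definite", call. = FALSE)
  structure(list(theta = theta, mean_base = mean_base, sigma = sigma,
                 verif_coef = verif_coef),
            class = "sim_config")
}

#' Simulate a three-class diagnostic study with MAR verification
#'
#' Draws `n` subjects from the design described in [sim_config()].  The
#' returned data.frame has columns `T` (test), `A` (covariate), `D`
#' (disease label, `NA` for unverified subjects), `V` (verification
#' status) and `D_true` (the generating label for every subject).
#' `D_true` exists only so that simulation studies can measure bias
#' against the truth; analyses must use `D`, whose missingness is
#' exactly the verification draw.
#'
#' @param n number of subjects.
#' @param config a `sim_config` (default: [sim_config()] defaults).
#' @param seed optional integer seed.
#' @return a data.frame with columns `T`, `A`, `D`, `V`, `D_true`.
#' @examples
#' d <- simulate_roc3(500, seed = 42)
#' table(d$D_true); mean(d$V)
#' @export
simulate_roc3 <- function(n, config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  cls <- sample.int(3L, n, replace = TRUE, prob = config$theta)
  Z <- matrix(rnorm(2 * n), n, 2)
  R <- msqrt(config$sigma)
  TA <- Z %*% R +
    outer(cls, rep(1, 2)) * matrix(config$mean_base, n, 2, byrow = TRUE)
  tt <- TA[, 1]; aa <- TA[, 2]
  eta <- config$verif_coef[1] + config$verif_coef[2] * tt +
    config$verif_coef[3] * aa
  v <- rbinom(n, 1L, plogis(eta))
  data.frame(T = tt, A = aa,
             D = ifelse(v == 1L, cls, NA_integer_),
             V = v, D_true = cls)
}

# symmetric matrix square root (tolerates semi-definite sigma)
msqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors)
}

#' Monte-Carlo truth oracle for the VUS of a simulation design
#'
#' Draws `m` independent triples, one test value from each
#' class-conditional marginal, and averages the tie-handling concordance
#' weight (1 for a strictly increasing triple, 1/2 for one adjacent tie,
#' 1/6 for a triple tie).  Under the generating model the class-k test
#' marginal is normal with mean `k * mean_base[1]` and variance
#' `sigma[1, 1]`.
#'
#' @param config a `sim_config`.
#' @param m number of Monte-Carlo triples (at least 1000).
#' @param seed optional integer seed.
#' @return list with `value` (the true VUS) and `se` (Monte-Carlo
#'   standard error).
#' @examples
#' true_vus(sim_config(), m = 1e5, seed = 1)
#' @export
true_vus <- function(config = sim_config(), m = 1e6, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), m >= 1000)
  if (!is.null(seed)) set.seed(seed)
  mu <- config$mean_base[1]
  s <- sqrt(config$sigma[1, 1])
  t1 <- rnorm(m, 1 * mu, s)
  t2 <- rnorm(m, 2 * mu, s)
  t3 <- rnorm(m, 3 * mu, s)
  w <- ifelse(t1 < t2 & t2 < t3, 1,
       ifelse((t1 == t2 & t2 < t3) | (t1 < t2 & t2 == t3), 0.5,
       ifelse(t1 == t2 & t2 == t3, 1 / 6, 0)))
  list(value = mean(w), se = sd(w) / sqrt(m))
}

#' Exact true class fractions of a simulation design
#'
#' Closed-form normal-CDF evaluation of the three class-conditional
#' probabilities TCF1 = P(T <= c1 | 1), TCF2 = P(c1 < T <= c2 | 2),
#' TCF3 = P(T > c2 | 3) under the generating model.
#'
#' @param config a `sim_config`.
#' @param c1,c2 cut-points with `c1 <= c2`.
#' @return named numeric `c(tcf1, tcf2, tcf3)`.
#' @examples
#' true_tcf(sim_config(), 3, 5)
#' @export
true_tcf <- function(config = sim_config(), c1, c2) {
  stopifnot(inherits(config, "sim_config"))
  if (c1 > c2) stop("c1 must not exceed c2", call. = FALSE)
  mu <- config$mean_base[1]
  s <- sqrt(config$sigma[1, 1])
  c(tcf1 = pnorm(c1, 1 * mu, s),
    tcf2 = pnorm(c2, 2 * mu, s) - pnorm(c1, 2 * mu, s),
    tcf3 = pnorm(c2, 3 * mu, s, lower.tail = FALSE))
}
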