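#' Bias-corrected disease matrix for a chosen estimator
#'
#' Builds the n x 3 matrix \eqn{\hat D} whose column-k entries play the
#' role of the class-k disease indicators in the VUS and TCF estimators.
#' With `rho` the fitted disease probabilities, `pi` the fitted
#' verification probabilities, `V` the verification indicator and `D` the
#' observed indicators:
#'
#' * `full`: \eqn{\hat D_{ki} = D_{ki}} (requires complete verification);
#' * `fi`  : \eqn{\hat D_{ki} = \hat\rho_{ki}} for every subject;
#' * `msi` : \eqn{\hat D_{ki} = V_i D_{ki} + (1 - V_i)\hat\rho_{ki}};
#' * `ipw` : \eqn{\hat D_{ki} = V_i D_{ki} / \hat\pi_i} (zero rows for
#'   unverified subjects; downstream ratio normalisation makes this a
#'   Hajek-style estimator);
#' * `spe` : \eqn{\hat D_{ki} = V_i D_{ki}/\hat\pi_i -
#'   (V_i - \hat\pi_i)\hat\rho_{ki}/\hat\pi_i} (doubly robust;
#'   consistent when either the disease or the verification model is
#'   correct);
#' * `knn` : as `msi`, with `rho` from [fit_rho_knn()].
#'
#' SPE entries may fall outside \[0, 1\]; they are deliberately not
#' clipped, since clipping would destroy the unbiasedness that defines
#' the estimator.  Downstream consumers tolerate out-of-range values.
#'
#' @param x a `roc3_data` object.
#' @param method one of `"full"`, `"fi"`, `"msi"`, `"ipw"`, `"spe"`,
#'   `"knn"`.
#' @param rho a `rho_fit` (required for fi/msi/spe/knn; `knn` requires a
#'   nearest-neighbor fit).
#' @param verif a `verif_fit` (required for ipw/spe).
#' @return an object of class `disease_hat`: the n x 3 numeric matrix
#'   with attributes `method`, `rho_method` and `verif_link`.
#' @examples
#' x <- prepare_roc3(simulate_roc3(300, seed = 1), "T", "D", "V", "A")
#' rho <- fit_rho_mlogit(x)
#' pi_fit <- fit_verification(x)
#' dh <- disease_hat(x, "spe", rho = rho, verif = pi_fit)
#' colMeans(dh)
#' @export
disease_hat <- function(x, method = c("full", "fi", "msi", "ipw", "spe",
                                      "knn"),
                        rho = NULL, verif = NULL) {
  stopifnot(inherits(x, "roc3_data"))
  method <- match.arg(method)
  needs_rho <- method %in% c("fi", "msi", "spe", "knn")
  needs_pi <- method %in% c("ipw", "spe")
  if (needs_rho) {
    if (is.null(rho) || !inherits(rho, "rho_fit"))
      stop("method '", method, "' requires a fitted disease model (`rho`)",
           call. = FALSE)
    if (method == "knn" && rho$method != "knn")
      stop("method 'knn' requires `rho` from fit_rho_knn()", call. = FALSE)
    if (nrow(rho$rho) != x$n)
      stop("`rho` was fitted on a dataset of different size", call. = FALSE)
  }
  if (needs_pi) {
    if (is.null(verif) || !inherits(verif, "verif_fit"))
      stop("method '", method,
           "' requires a fitted verification model (`verif`)", call. = FALSE)
    if (length(verif$pi) != x$n)
      stop("`verif` was fitted on a dataset of different size", call. = FALSE)
  }

  v <- x$verified
  D <- x$dmat
  D0 <- D
  D0[v == 0L, ] <- 0  # V_i * D_ki with the NA rows zeroed

  dh <- switch(method,
    full = {
      if (any(v == 0L))
        stop("method 'full' requires every subject to be verified; ",
             sum(v == 0L), " subjects have V = 0", call. = FALSE)
      D
    },
    fi  = rho$rho,
    msi = ,
    knn = D0 + (1 - v) * rho$rho,
    ipw = D0 / verif$pi,
    spe = D0 / verif$pi - ((v - verif$pi) / verif$pi) * rho$rho
  )
  dimnames(dh) <- list(NULL, paste0("D", 1:3))
  structure(dh, class = c("disease_hat", class(dh)),
            method = method,
            rho_method = if (needs_rho) rho$method else NA_character_,
            verif_link = if (needs_pi) verif$link else NA_character_)
}

#' @export
print.disease_hat <- function(x, ...) {
  cat("Bias-corrected disease matrix (method:", attr(x, "method"), ")\n")
  cat("Column means:", paste(sprintf("%.4f", colMeans(x)), collapse = ", "),
      "\n")
  invisible(x)
}
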