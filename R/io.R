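#' Read a subject-level table from delimited text
#'
#' Thin wrapper around [utils::read.table()] exposing the separator and
#' quote options; column roles are assigned later by [prepare_roc3()].
#'
#' @param path file path.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @param quote quote character (default `"\""`).
#' @param header logical; default `TRUE`.
#' @return a data.frame.
#' @export
read_subjects <- function(path, sep = ",", quote = "\"", header = TRUE) {
  read.table(path, sep = sep, quote = quote, header = header,
             stringsAsFactors = FALSE)
}

#' Summary tables for a set of VUS results
#'
#' `vus_table()` lays out estimates, standard errors and both interval
#' types with columns `Estimate`, `Std.Err`, `Lower.Normal`,
#' `Upper.Normal`, `Lower.Logit`, `Upper.Logit`; `vus_test_table()`
#' collects the t statistics and p-values of the useless-test null.
#'
#' @param results a list of `vus_result` objects (names become row
#'   names; unnamed lists use the method labels).
#' @return a data.frame.
#' @export
vus_table <- function(results) {
  if (inherits(results, "vus_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(Estimate = r$estimate, Std.Err = r$se,
               Lower.Normal = r$ci_normal[["lower"]],
               Upper.Normal = r$ci_normal[["upper"]],
               Lower.Logit = r$ci_logit[["lower"]],
               Upper.Logit = r$ci_logit[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(results) %||%
    vapply(results, function(r) toupper(r$method), character(1))
  out
}

#' @rdname vus_table
#' @export
vus_test_table <- function(results) {
  if (inherits(results, "vus_result")) results <- list(results)
  out <- data.frame(
    t.stat = vapply(results, function(r) r$t_stat, numeric(1)),
    p.value = vapply(results, function(r) r$p_value, numeric(1)))
  rownames(out) <- names(results) %||%
    vapply(results, function(r) toupper(r$method), character(1))
  out
}

# Round a summary table to display precision and write it as CSV.
write_summary_csv <- function(tab, path, digits = 4) {
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  write.csv(tab, path, row.names = TRUE)
  invisible(path)
}

#' Export a ROC surface as CSV and a triangulated OBJ mesh
#'
#' The CSV holds the long-format grid (`c1`, `c2`, `tcf1`, `tcf2`,
#' `tcf3`).  The OBJ mesh places vertices at the (TCF1, TCF2, TCF3)
#' coordinates of finite grid points and triangulates adjacent
#' admissible cells, so any standard mesh viewer renders the surface.
#'
#' @param surface a `roc3_surface` object.
#' @param csv file path for the CSV (or `NULL` to skip).
#' @param obj file path for the OBJ mesh (or `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
export_surface <- function(surface, csv = NULL, obj = NULL) {
  stopifnot(inherits(surface, "roc3_surface"))
  written <- character(0)
  if (!is.null(csv)) {
    write.csv(surface$points, csv, row.names = FALSE)
    written <- c(written, csv)
  }
  if (!is.null(obj)) {
    g <- surface$grid
    ng <- length(g)
    pts <- surface$points
    key <- function(i, j) paste(i, j)
    idx <- setNames(seq_len(nrow(pts)),
                    key(match(pts$c1, g), match(pts$c2, g)))
    lines <- sprintf("v %.6f %.6f %.6f", pts$tcf1, pts$tcf2, pts$tcf3)
    faces <- character(0)
    for (i in seq_len(ng - 1)) {
      for (j in i:(ng - 1)) {
        a <- idx[key(i, j)]; b <- idx[key(i + 1, j)]
        c_ <- idx[key(i, j + 1)]; d <- idx[key(i + 1, j + 1)]
        if (!anyNA(c(a, b, d))) faces <- c(faces,
                                           sprintf("f %d %d %d", a, b, d))
        if (!anyNA(c(a, d, c_))) faces <- c(faces,
                                            sprintf("f %d %d %d", a, d, c_))
      }
    }
    writeLines(c("# ROC surface mesh (TCF1, TCF2, TCF3)", lines, faces), obj)
    written <- c(written, obj)
  }
  invisible(written)
}

#' Run the full three-step analysis pipeline
#'
#' Data preparation, modeling and inference in one call, mirroring the
#' interactive workflow: read (or accept) a subject table, prepare and
#' check it, estimate the VUS with the requested method and variance
#' route, optionally evaluate the ROC surface and an ellipsoidal TCF
#' confidence region, and write JSON/CSV artifacts to `outdir`.
#'
#' @param input a data.frame or a path to a delimited file.
#' @param columns named list with entries `test`, `disease`, `verified`
#'   and optionally `covariates`.
#' @param method estimation method (see [disease_hat()]).
#' @param variance `"jackknife"` or `"bootstrap"`.
#' @param outdir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param surface logical: also evaluate the ROC surface grid?
#' @param cuts optional `c(c1, c2)`: also build the ellipsoid TCF
#'   region at this cut-point pair.
#' @param sep,quote input parsing options when `input` is a path.
#' @param allow_nonmonotone proceed despite a failed monotone-ordering
#'   check (default `FALSE`: the failure is an error naming the check).
#' @param B,seed,workers,level,link,k,pi_floor passed to [vus()] /
#'   [tcf_ellipsoid()].
#' @param verbose print progress and warnings to stderr.
#' @return invisibly, a list with `data`, `ordering`, `vus`, and (when
#'   requested) `surface` and `region`.
#' @export
run_pipeline <- function(input, columns, method = "spe",
                         variance = "jackknife", outdir = NULL,
                         surface = FALSE, cuts = NULL,
                         sep = ",", quote = "\"",
                         allow_nonmonotone = FALSE,
                         B = 250, seed = 1, workers = 1, level = 0.95,
                         link = "logit", k = NULL, pi_floor = 1e-6,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  df <- if (is.character(input)) {
    read_subjects(input, sep = sep, quote = quote)
  } else input

  x <- prepare_roc3(df, test = columns$test, disease = columns$disease,
                    verified = columns$verified,
                    covariates = columns$covariates)
  ord <- check_ordering(x)
  if (!ord$satisfied) {
    if (!allow_nonmonotone)
      stop(ord$message, " (set allow_nonmonotone = TRUE to proceed)",
           call. = FALSE)
    say("WARNING: ", ord$message)
  }
  say("Prepared ", x$n, " subjects (", sum(x$verified), " verified); ",
      "estimating VUS by method '", method, "'")

  res <- vus(x, method = method, variance = variance, link = link, k = k,
             B = B, seed = seed, workers = workers, level = level,
             pi_floor = pi_floor)
  bundle <- list(data = x, ordering = ord, vus = res)

  if (surface || !is.null(cuts)) {
    fits <- fit_for_method(x, method, NULL, NULL, link, k, pi_floor)
    dh <- disease_hat(x, method, rho = fits$rho, verif = fits$verif)
    if (surface) bundle$surface <- roc_surface(dh, x$test)
    if (!is.null(cuts))
      bundle$region <- tcf_ellipsoid(x, method, cuts[1], cuts[2],
                                     level = level, B = B, seed = seed,
                                     workers = workers, link = link,
                                     k = k, pi_floor = pi_floor)
  }

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_summary_csv(vus_table(list(res)),
                      file.path(outdir, "vus_estimates.csv"))
    write_summary_csv(vus_test_table(list(res)),
                      file.path(outdir, "vus_tests.csv"))
    jsonlite::write_json(result_json(bundle),
                         file.path(outdir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(bundle$surface))
      export_surface(bundle$surface,
                     csv = file.path(outdir, "surface.csv"),
                     obj = file.path(outdir, "surface.obj"))
    say("Wrote results to ", outdir)
  }
  invisible(bundle)
}

# JSON-serializable view of a pipeline result bundle (full precision).
result_json <- function(bundle) {
  r <- bundle$vus
  out <- list(
    n = bundle$data$n,
    n_verified = sum(bundle$data$verified),
    ordering = list(class_means = bundle$ordering$class_means,
                    satisfied = bundle$ordering$satisfied),
    vus = list(method = r$method, estimate = r$estimate,
               variance = r$variance, se = r$se,
               variance_method = r$variance_method, level = r$level,
               ci_normal = as.list(r$ci_normal),
               ci_logit = as.list(r$ci_logit),
               t_stat = r$t_stat, p_value = r$p_value,
               p_display = format_pval(r$p_value)))
  if (!is.null(r$verif))
    out$verification_model <- list(link = r$verif$link,
                                   coefficients = as.list(r$verif$coefficients),
                                   n_floored = r$verif$n_floored)
  if (!is.null(r$rho)) {
    out$disease_model <- if (r$rho$method == "mlogit") {
      list(method = "mlogit",
           coefficients = as.data.frame(r$rho$coefficients))
    } else {
      list(method = "knn", k = r$rho$k, distance = r$rho$distance)
    }
  }
  if (!is.null(bundle$region))
    out$tcf_region <- list(cuts = as.list(bundle$region$cuts),
                           center = as.list(bundle$region$center[1:3]),
                           covariance = bundle$region$covariance,
                           radius2 = bundle$region$radius2,
                           degenerate = bundle$region$degenerate)
  out
}
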