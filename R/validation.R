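#' Pair predicted map CPUE with monitoring observations
#'
#' Looks up the predicted CPUE at each monitoring site's cell and pairs it
#' with the observed CPUE. Sites that fall on nodata cells (land, or outside
#' a species' depth range) are dropped with a warning naming them; sites
#' outside the grid are an error.
#'
#' @param cpue_map A [raster_grid()] of predicted CPUE.
#' @param sites data.frame with columns `site_id`, `row`, `col`,
#'   `observed_cpue` (as written by [generate_monitoring()]).
#' @param exclude Optional character vector of `site_id`s to leave out
#'   (e.g. sites no longer representative due to a fishing ban).
#' @return data.frame with columns `site_id`, `predicted`, `observed`.
#' @export
extract_predictions <- function(cpue_map, sites, exclude = NULL) {
  if (!is_raster_grid(cpue_map)) stop("`cpue_map` must be a raster_grid", call. = FALSE)
  need <- c("site_id", "row", "col", "observed_cpue")
  if (!all(need %in% names(sites)))
    stop("`sites` must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (!is.null(exclude)) sites <- sites[!sites$site_id %in% exclude, , drop = FALSE]
  d <- dim(cpue_map$values)
  if (any(sites$row < 1 | sites$row > d[1] | sites$col < 1 | sites$col > d[2]))
    stop("monitoring sites fall outside the raster grid", call. = FALSE)
  pred <- cpue_map$values[cbind(sites$row, sites$col)]
  on_nodata <- is.na(pred)
  if (any(on_nodata))
    warning("dropping ", sum(on_nodata), " site(s) on nodata cells: ",
            paste(sites$site_id[on_nodata], collapse = ", "), call. = FALSE)
  keep <- !on_nodata
  if (!any(keep)) stop("all monitoring sites fall on nodata cells", call. = FALSE)
  data.frame(site_id = sites$site_id[keep], predicted = pred[keep],
             observed = sites$observed_cpue[keep])
}

#' Regress observed on predicted CPUE
#'
#' Ordinary least squares of observed monitoring CPUE on map-predicted CPUE
#' (`observed = a * predicted + b`), the orientation used to evaluate the
#' habitat productivity predictions. Reports the slope and intercept with
#' standard errors, r-squared, the overall F statistic on (1, n - 2) degrees
#' of freedom and its two-sided p value.
#'
#' @param pairs data.frame with columns `predicted` and `observed` (as from
#'   [extract_predictions()]).
#' @return An object of class `validation_fit`: list with `slope`,
#'   `slope_se`, `intercept`, `intercept_se`, `r2`, `f`, `df1`, `df2`, `p`,
#'   `n`.
#' @examples
#' fit_obs_vs_pred(data.frame(predicted = 0:2, observed = c(0.1, 1, 2.1)))
#' @export
fit_obs_vs_pred <- function(pairs) {
  if (!all(c("predicted", "observed") %in% names(pairs)))
    stop("`pairs` needs columns `predicted` and `observed`", call. = FALSE)
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 sites for the validation regression", call. = FALSE)
  if (stats::var(pairs$predicted) == 0)
    stop("predicted CPUE is constant across sites; regression is degenerate",
         call. = FALSE)
  if (stats::var(pairs$observed) == 0) {
    # flat response: slope 0, no variation to explain
    return(structure(list(
      slope = 0, slope_se = 0,
      intercept = pairs$observed[1], intercept_se = 0,
      r2 = 0, f = 0, df1 = 1L, df2 = n - 2L, p = NA_real_, n = n),
      class = "validation_fit"))
  }
  fit <- stats::lm(observed ~ predicted, data = pairs)
  # suppress the "essentially perfect fit" notice for exact linear inputs
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  fstat <- s$fstatistic
  structure(list(
    slope = co["predicted", "Estimate"], slope_se = co["predicted", "Std. Error"],
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = co["(Intercept)", "Std. Error"],
    r2 = s$r.squared,
    f = unname(fstat["value"]), df1 = unname(fstat["numdf"]),
    df2 = unname(fstat["dendf"]),
    p = unname(stats::pf(fstat["value"], fstat["numdf"], fstat["dendf"],
                         lower.tail = FALSE)),
    n = n), class = "validation_fit")
}

#' @export
print.validation_fit <- function(x, ...) {
  cat(sprintf(
    "<validation_fit> observed = %.3g (+/- %.2g SE) * predicted + %.3g (+/- %.2g SE)\n",
    x$slope, x$slope_se, x$intercept, x$intercept_se))
  cat(sprintf("  r2 = %.3f, F(%d, %d) = %.2f, p = %.3g, n = %d\n",
              x$r2, x$df1, x$df2, x$f, x$p, x$n))
  invisible(x)
}
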