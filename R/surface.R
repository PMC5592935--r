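# Full response-surface enumeration and summaries, plus the deterministic
# two-factor yield demonstration surface.

#' Default factor levels of the genomic-prediction surface
#'
#' Three levels each for progeny, markers, QTL and heritability and five
#' for the epistatic share: 3 x 3 x 3 x 5 x 3 = 405 combinations.
#'
#' @return named list of level vectors.
#' @export
gp_grid_levels <- function() {
  list(ind = c(200, 1000, 2000),
       m = c(100, 400, 1000),
       qtl = c(10, 50, 100),
       epi = c(0, 0.2, 0.5, 0.8, 1),
       h = c(0.2, 0.5, 0.8))
}

#' Enumerate a full factor grid
#'
#' Cartesian product of the per-factor level lists, in `expand.grid` order
#' (first factor varying fastest); exhaustive and duplicate-free.
#'
#' @param levels named list of level vectors (default [gp_grid_levels()]).
#' @return data.frame with one row per design point.
#' @export
enumerate_grid <- function(levels = gp_grid_levels()) {
  if (length(levels) == 0 || any(lengths(levels) == 0))
    stop_config("every factor needs at least one level")
  out <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a response surface
#'
#' Maximum and argmax, fraction of combinations exceeding each threshold,
#' and histogram counts of the mean responses.
#'
#' @param grid_results data.frame of design points with a response column.
#' @param response name of the response column.
#' @param thresholds numeric thresholds for exceedance fractions.
#' @param bin_width histogram bin width (default 0.05).
#' @return object of class `surface_summary`.
#' @export
summarize_surface <- function(grid_results, response,
                              thresholds = c(0.2, 0.8),
                              bin_width = 0.05) {
  y <- grid_results[[response]]
  if (is.null(y)) stop_config("no column '%s' in grid results", response)
  breaks <- seq(floor(min(y) / bin_width) * bin_width,
                ceiling(max(y) / bin_width) * bin_width + bin_width / 2,
                by = bin_width)
  hg <- graphics::hist(y, breaks = breaks, plot = FALSE)
  fr <- vapply(thresholds, function(t) mean(y > t), numeric(1))
  names(fr) <- thresholds
  structure(list(
    n = length(y), response = response,
    max_response = max(y),
    argmax = grid_results[which.max(y), , drop = FALSE],
    threshold_fractions = fr,
    histogram = list(breaks = hg$breaks, counts = hg$counts)),
    class = "surface_summary")
}

#' @export
print.surface_summary <- function(x, ...) {
  cat(sprintf("Surface summary of '%s' over %d combinations\n",
              x$response, x$n))
  cat(sprintf("  max = %.4g at:\n", x$max_response))
  print(x$argmax)
  for (i in seq_along(x$threshold_fractions))
    cat(sprintf("  fraction > %s: %.3f\n",
                names(x$threshold_fractions)[i], x$threshold_fractions[i]))
  invisible(x)
}

#' Evaluate the response surface over a factor grid
#'
#' Runs [estimate_accuracy()] at every grid point and returns one row per
#' point with the mean accuracies, their replicate standard deviations and
#' the per-point seed (the full-surface table analogue).
#'
#' @param grid data.frame from [enumerate_grid()].
#' @param method,n_datasets,n_splits,seed forwarded to
#'   [estimate_accuracy()]; each point gets a derived seed.
#' @param ... further arguments to [estimate_accuracy()].
#' @return data.frame of per-point results.
#' @export
evaluate_grid <- function(grid, method = "both", n_datasets = 20,
                          n_splits = 25, seed = 1, ...) {
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    est <- estimate_accuracy(as.list(grid[i, , drop = FALSE]),
                             method = method, n_datasets = n_datasets,
                             n_splits = n_splits,
                             seed = seed_stream(seed, "grid", i), ...)
    as.data.frame(est)
  })
  do.call(rbind, rows)
}

#' Deterministic yield demonstration surface
#'
#' `yield = 110 + cos(0.25 * drought)^2 + sin(0.15 * temperature)^2 +
#' 0.0024375 * drought * temperature`, trigonometric arguments in radians.
#' Over temperature 64-80 degrees F and drought -4 to 4 SPI the surface is
#' maximized at a temperature between 73 and 74.
#'
#' @param temperature degrees Fahrenheit (vectorized).
#' @param drought standard precipitation index (vectorized).
#' @return yield value(s).
#' @export
yield_surface <- function(temperature, drought) {
  110 + cos(0.25 * drought)^2 + sin(0.15 * temperature)^2 +
    0.0024375 * drought * temperature
}

#' Grid argmax of the yield demonstration surface
#'
#' Exhaustive evaluation on a regular grid.
#'
#' @param resolution grid spacing in both coordinates (default 0.01).
#' @param temperature_range,drought_range evaluation window.
#' @return list with `temperature`, `drought` and `yield` at the argmax.
#' @export
yield_grid_argmax <- function(resolution = 0.01,
                              temperature_range = c(64, 80),
                              drought_range = c(-4, 4)) {
  temps <- seq(temperature_range[1], temperature_range[2], by = resolution)
  drts <- seq(drought_range[1], drought_range[2], by = resolution)
  Y <- outer(temps, drts, yield_surface)
  ij <- arrayInd(which.max(Y), dim(Y))
  list(temperature = temps[ij[1]], drought = drts[ij[2]],
       yield = Y[ij[1], ij[2]])
}
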