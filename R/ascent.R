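# Steepest ascent: turn a first-order fit on coded variables into a path
# of factor combinations to evaluate next.
#
# A basis factor (by default the one with the largest |slope|) anchors the
# move: its coded step is the user-chosen natural step divided by the
# factor's half-range, carrying the sign of its fitted coefficient; every
# other factor steps in proportion to its coefficient ratio,
#   step_i = (b_i / b_basis) * step_basis.
# Natural increments are Delta_i = half_range_i * coded_step_i; coordinates
# base + k * Delta are rounded (counts to integers, fractions to two
# decimals) and clamped to each factor's operability region.

#' Choose the basis factor for steepest ascent
#'
#' The factor with the largest absolute fitted slope, unless overridden.
#'
#' @param fit a `first_order_fit`.
#' @param override optional factor name to force.
#' @return the basis factor's name.
#' @export
choose_basis <- function(fit, override = NULL) {
  slopes <- stats::coef(fit)[-1]
  if (!is.null(override)) {
    if (!override %in% names(slopes))
      stop_config("unknown factor '%s'", override)
    return(override)
  }
  if (all(slopes == 0))
    stop_config("all slopes are zero: no direction of improvement")
  names(slopes)[which.max(abs(slopes))]
}

#' Coded step sizes along the ascent direction
#'
#' The basis coded step is `|basis_step| / half_range(basis)` signed by the
#' basis coefficient (so a negative coefficient moves the basis downward on
#' an ascent); for descent the sign is reversed. All other steps follow the
#' coefficient ratios `b_i / b_basis`.
#'
#' @param fit a `first_order_fit`.
#' @param factors named list of [rsm_factor()]s covering the slopes.
#' @param basis basis factor name; defaults to [choose_basis()].
#' @param basis_step step magnitude of the basis in natural units
#'   (default 0.25, a natural choice for fraction-type factors).
#' @param direction `"ascent"` (maximize) or `"descent"` (minimize).
#' @param digits optional rounding of the coded steps (half away from
#'   zero), matching the precision printed in path tables.
#' @return named vector of coded steps with attribute `basis`.
#' @export
coded_step_sizes <- function(fit, factors, basis = NULL, basis_step = 0.25,
                             direction = c("ascent", "descent"),
                             digits = NULL) {
  direction <- match.arg(direction)
  slopes <- stats::coef(fit)[-1]
  basis <- basis %||% choose_basis(fit)
  if (!basis %in% names(slopes)) stop_config("unknown basis '%s'", basis)
  if (slopes[[basis]] == 0) stop_config("zero basis coefficient")
  bf <- factors[[basis]]
  if (is.null(bf) || bf$half_range <= 0)
    stop_config("basis factor '%s' missing or degenerate", basis)
  dir_sign <- if (direction == "ascent") 1 else -1
  step_basis <- dir_sign * sign(slopes[[basis]]) *
    abs(basis_step) / bf$half_range
  steps <- slopes / slopes[[basis]] * step_basis
  if (!is.null(digits)) steps <- round_half_up(steps, digits)
  structure(steps, basis = basis, basis_step_coded = step_basis)
}

#' Natural-unit increments from coded steps
#'
#' `Delta_i = half_range_i * coded_step_i`. With `compat = TRUE` each
#' increment is rounded to two significant figures but never finer than
#' whole units (296 stays 296, 91.2 becomes 91, -4.35 becomes -4.4,
#' 0.117 becomes 0.12), the convention used in printed path tables; the
#' full-precision default is recommended for new analyses.
#'
#' @param coded_steps vector from [coded_step_sizes()].
#' @param factors named factor list.
#' @param compat apply the table-compatible increment rounding?
#' @return named vector of per-factor increments in natural units.
#' @export
natural_increments <- function(coded_steps, factors, compat = FALSE) {
  hr <- vapply(factors[names(coded_steps)], `[[`, numeric(1), "half_range")
  deltas <- hr * as.numeric(coded_steps)
  names(deltas) <- names(coded_steps)
  if (compat) deltas <- round_increment(deltas)
  deltas
}

#' Coordinates of the steepest-ascent path
#'
#' Computes `base + k * Delta` for `k = 1..k_max` (accumulating from the
#' base, not from previously rounded coordinates), rounds integer factors
#' to whole numbers and fraction factors to two decimals, and clamps every
#' coordinate to the factor's operability region.
#'
#' @param base named vector of natural-unit base values (factor bases).
#' @param deltas named increment vector from [natural_increments()].
#' @param k_max number of path points.
#' @param factors named factor list.
#' @return data.frame with column `k` and one column per factor.
#' @export
path_coordinates <- function(base, deltas, k_max, factors) {
  if (k_max < 1) stop_config("k_max must be >= 1")
  nm <- names(deltas)
  rows <- lapply(seq_len(k_max), function(k) {
    z <- base[nm] + k * deltas
    z <- mapply(function(zi, f) {
      zi <- if (f$integer_valued) round_half_up(zi, 0) else
        round_half_up(zi, 2)
      min(max(zi, f$operability_min), f$operability_max)
    }, z, factors[nm])
    as.data.frame(as.list(z))
  })
  out <- cbind(k = seq_len(k_max), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Build a steepest-ascent path from a first-order fit
#'
#' Convenience wrapper chaining [choose_basis()], [coded_step_sizes()],
#' [natural_increments()] and [path_coordinates()].
#'
#' @inheritParams coded_step_sizes
#' @inheritParams natural_increments
#' @param k_max number of path points (default 9).
#' @param base optional named base point; defaults to the factor bases.
#' @return object of class `ascent_path`: base, coded steps, increments,
#'   basis, and the coordinate table (responses unset until
#'   [evaluate_path()]).
#' @examples
#' fit <- first_order_fit(c("(Intercept)" = -0.130, ind = 0.019,
#'                          m = -0.004, qtl = -0.003, epi = 0.043,
#'                          h = 0.020))
#' steepest_ascent(fit, gp_factors(), basis_step = 0.25, digits = 2,
#'                 compat = TRUE)
#' @export
steepest_ascent <- function(fit, factors, basis = NULL, basis_step = 0.25,
                            direction = c("ascent", "descent"),
                            k_max = 9, digits = NULL, compat = FALSE,
                            base = NULL) {
  direction <- match.arg(direction)
  steps <- coded_step_sizes(fit, factors, basis, basis_step, direction,
                            digits)
  basis <- attr(steps, "basis")
  deltas <- natural_increments(steps, factors, compat)
  base <- base %||% vapply(factors[names(deltas)], `[[`, numeric(1), "base")
  coords <- path_coordinates(base, deltas, k_max, factors)
  structure(
    list(base = base, coded_steps = steps, deltas = deltas,
         basis = basis,
         basis_step_natural = deltas[[basis]],
         direction = direction, coordinates = coords, responses = NULL),
    class = "ascent_path")
}

#' @export
print.ascent_path <- function(x, ...) {
  cat(sprintf("Steepest %s path (basis: %s)\n", x$direction, x$basis))
  tab <- rbind(Base = x$base, Delta = x$deltas)
  print(tab)
  coords <- x$coordinates
  rownames(coords) <- paste0("Base+", coords$k, "D")
  print(coords[, -1, drop = FALSE])
  if (!is.null(x$responses)) {
    cat("Responses along the path:\n")
    print(x$responses)
  }
  invisible(x)
}

#' @export
as.data.frame.ascent_path <- function(x, ...) {
  base_row <- cbind(k = 0, as.data.frame(as.list(x$base)))
  out <- rbind(base_row, x$coordinates)
  if (!is.null(x$responses))
    out$response <- c(NA, x$responses)
  out
}

#' Evaluate responses along an ascent path
#'
#' Applies `response_fn` to every coordinate (as a named list of factor
#' values). Errors at a coordinate are caught and recorded as `NA` without
#' aborting the remaining path.
#'
#' @param path an `ascent_path`.
#' @param response_fn function of a named design point returning a scalar
#'   response (typically a cross-validated accuracy or a difference of
#'   accuracies).
#' @param ... forwarded to `response_fn`.
#' @return the path with `$responses` filled in.
#' @export
evaluate_path <- function(path, response_fn, ...) {
  coords <- path$coordinates
  resp <- vapply(seq_len(nrow(coords)), function(i) {
    pt <- as.list(coords[i, -1, drop = FALSE])
    tryCatch(as.numeric(response_fn(pt, ...)),
             error = function(e) {
               warning(sprintf("path point %d failed: %s", i,
                               conditionMessage(e)))
               NA_real_
             })
  }, numeric(1))
  path$responses <- resp
  path
}

#' Run the full iterative steepest-ascent procedure
#'
#' Repeats design -> fit -> path -> relocate: evaluates the response on a
#' two-level design over the current region (a resolution-V half fraction
#' for four or more factors, the full factorial otherwise), fits the
#' first-order model, walks the steepest-ascent path, and recenters the
#' region on the best path point. Stops when the best response fails to
#' improve on the previous iteration's best by more than `min_improve`, when
#' all slopes vanish, or after `max_iterations`.
#'
#' @param factors named list of [rsm_factor()]s defining the initial
#'   region.
#' @param response_fn function of a named design point (natural units)
#'   returning a scalar response to maximize (or minimize for descent).
#' @param basis_step basis step magnitude in natural units.
#' @param k_max path points per iteration.
#' @param max_iterations iteration cap.
#' @param min_improve minimal improvement to continue (default 0).
#' @param direction `"ascent"` or `"descent"`.
#' @param compat use the printed-table increment rounding.
#' @param digits optional coded-step rounding.
#' @param fraction_sign sign of the defining relation used for the half
#'   fraction (default -1).
#' @param ... forwarded to `response_fn`.
#' @return object of class `ascent_run`: `best_point`, `best_response`,
#'   `n_evaluations`, convergence flag and an `iterations` audit trail of
#'   every design, fit and path.
#' @export
run_ascent <- function(factors, response_fn, basis_step = 0.25, k_max = 9,
                       max_iterations = 5, min_improve = 0,
                       direction = c("ascent", "descent"), compat = FALSE,
                       digits = NULL, fraction_sign = -1, ...) {
  direction <- match.arg(direction)
  better <- if (direction == "ascent") function(a, b) a > b + min_improve
            else function(a, b) a < b - min_improve
  best_of <- if (direction == "ascent") which.max else which.min
  trail <- list()
  n_eval <- 0L
  best_point <- NULL
  best_response <- if (direction == "ascent") -Inf else Inf
  converged <- FALSE
  for (iter in seq_len(max_iterations)) {
    design <- if (length(factors) >= 4)
      half_fraction(factors, sign = fraction_sign)
    else full_factorial(factors)
    natural <- decode_design(design)
    y <- vapply(seq_len(nrow(natural)), function(i)
      as.numeric(response_fn(as.list(natural[i, , drop = FALSE]), ...)),
      numeric(1))
    n_eval <- n_eval + length(y)
    fit <- fit_first_order(design, y)
    slopes <- stats::coef(fit)[-1]
    it_rec <- list(factors = factors, design = natural, responses = y,
                   fit = fit)
    des_best <- best_of(y)
    if (better(y[des_best], best_response)) {
      best_response <- y[des_best]
      best_point <- as.list(natural[des_best, , drop = FALSE])
    }
    if (all(slopes == 0)) {
      trail[[iter]] <- it_rec
      converged <- TRUE
      break
    }
    path <- steepest_ascent(fit, factors, basis_step = basis_step,
                            direction = direction, k_max = k_max,
                            digits = digits, compat = compat)
    path <- evaluate_path(path, response_fn, ...)
    n_eval <- n_eval + sum(!is.na(path$responses))
    it_rec$path <- path
    trail[[iter]] <- it_rec
    ok <- which(!is.na(path$responses))
    if (length(ok) == 0) { converged <- TRUE; break }
    pb <- ok[best_of(path$responses[ok])]
    if (!better(path$responses[pb], best_response)) {
      converged <- TRUE
      break
    }
    best_response <- path$responses[pb]
    best_point <- as.list(path$coordinates[pb, -1, drop = FALSE])
    factors <- recenter_region(factors, best_point)
  }
  structure(list(best_point = best_point, best_response = best_response,
                 n_evaluations = n_eval, converged = converged,
                 iterations = trail, direction = direction),
            class = "ascent_run")
}

# Decode a coded design into natural units, one column per factor.
decode_design <- function(design) {
  out <- mapply(function(col, f) {
    z <- decode_value(f, design$runs[, col])
    if (f$integer_valued) round_half_up(z, 0) else z
  }, colnames(design$runs), design$factors[colnames(design$runs)],
  SIMPLIFY = FALSE)
  as.data.frame(out)
}

# Move the two-level region so it is centered on a point, keeping each
# factor's half-range and clamping to the operability region.
recenter_region <- function(factors, point) {
  out <- lapply(factors, function(f) {
    ctr <- as.numeric(point[[f$name]])
    hr <- f$half_range
    lo <- max(ctr - hr, f$operability_min)
    hi <- min(ctr + hr, f$operability_max)
    if (f$integer_valued) { lo <- round_half_up(lo, 0); hi <- round_half_up(hi, 0) }
    if (!(lo < hi)) { # pinned at a boundary: keep a minimal two-level span
      if (f$integer_valued) {
        if (lo >= f$operability_max) lo <- hi - 1 else hi <- lo + 1
      } else {
        eps <- hr * 0.01
        if (lo >= f$operability_max) lo <- hi - eps else hi <- lo + eps
      }
    }
    rsm_factor(f$name, lo, hi, f$integer_valued, f$operability_min,
               f$operability_max)
  })
  names(out) <- names(factors)
  out
}

#' @export
print.ascent_run <- function(x, ...) {
  cat(sprintf("Steepest %s: %d iterations, %d response evaluations%s\n",
              x$direction, length(x$iterations), x$n_evaluations,
              if (x$converged) " (converged)" else ""))
  cat(sprintf("Best response: %.4g at\n", x$best_response))
  print(as.data.frame(x$best_point))
  invisible(x)
}

#' Write a path table in the printed-table layout
#'
#' CSV with a base row, an increment row, and one `Base+kD` row per path
#' point, plus evaluated responses when present.
#'
#' @param path an `ascent_path`.
#' @param file output CSV path.
#' @return invisibly, `file`.
#' @export
write_path_table <- function(path, file) {
  nm <- names(path$deltas)
  head <- data.frame(row = c("Base", "Increment"),
                     rbind(path$base[nm], path$deltas[nm]))
  body <- data.frame(row = paste0("Base+", path$coordinates$k, "D"),
                     path$coordinates[, nm, drop = FALSE])
  out <- rbind(head, body)
  if (!is.null(path$responses)) out$response <- c(NA, NA, path$responses)
  utils::write.csv(out, file, row.names = FALSE)
  invisible(file)
}
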