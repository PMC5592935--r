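# Two-level factorial machinery on coded variables: factor coding, full
# and regular half-fraction designs with defining relations and alias
# structure, first-order OLS fits, and the Box-Cox response transform.

#' Define a design factor with its operability region
#'
#' A factor has a low and a high level in natural units (coded -1 and +1)
#' inside an operability region, the attainable range of the factor. The
#' coding base is `(low + high)/2` and the half-range `base - low`.
#'
#' @param name factor name.
#' @param low,high the two design levels in natural units, `low < high`.
#' @param integer_valued is the factor integral (counts such as lines,
#'   markers, QTL)?
#' @param operability_min,operability_max attainable range; must contain
#'   `[low, high]`.
#' @return object of class `rsm_factor`.
#' @examples
#' f <- rsm_factor("ind", 200, 1000, integer_valued = TRUE,
#'                 operability_min = 1)
#' code_value(f, 600)  # 0
#' @export
rsm_factor <- function(name, low, high, integer_valued = FALSE,
                       operability_min = -Inf, operability_max = Inf) {
  if (!(low < high)) stop_config("factor %s: low must be < high", name)
  if (low < operability_min || high > operability_max)
    stop_config("factor %s: [low, high] outside the operability region",
                name)
  structure(
    list(name = name, low = low, high = high,
         integer_valued = integer_valued,
         operability_min = operability_min,
         operability_max = operability_max,
         base = (low + high) / 2, half_range = (high - low) / 2),
    class = "rsm_factor")
}

#' @export
print.rsm_factor <- function(x, ...) {
  cat(sprintf("Factor %s: levels [%g, %g], base %g, half-range %g%s\n",
              x$name, x$low, x$high, x$base, x$half_range,
              if (x$integer_valued) " (integer)" else ""))
  invisible(x)
}

#' The five genomic-prediction design factors
#'
#' Returns the standard starting region for exploring genomic prediction
#' accuracy: progeny 200/1000, markers 100/400, QTL 10/100, epistatic
#' share 0.2/0.5, heritability 0.2/0.5, with operability regions of
#' positive integers for the counts and `[0, 1]` for the fractions.
#'
#' @return named list of five [rsm_factor()] objects
#'   (`ind`, `m`, `qtl`, `epi`, `h`).
#' @export
gp_factors <- function() {
  list(
    ind = rsm_factor("ind", 200, 1000, TRUE, 1, Inf),
    m   = rsm_factor("m", 100, 400, TRUE, 1, Inf),
    qtl = rsm_factor("qtl", 10, 100, TRUE, 1, Inf),
    epi = rsm_factor("epi", 0.2, 0.5, FALSE, 0, 1),
    h   = rsm_factor("h", 0.2, 0.5, FALSE, 0, 1)
  )
}

#' Code and decode factor values
#'
#' Linear map between natural and coded units: the low level codes to -1,
#' the high level to +1; values outside `[low, high]` are mapped linearly.
#'
#' @param factor an [rsm_factor()].
#' @param z value in natural units.
#' @param x value in coded units.
#' @return the transformed value(s).
#' @export
code_value <- function(factor, z) {
  if (factor$half_range == 0) stop_config("degenerate factor %s", factor$name)
  (z - factor$base) / factor$half_range
}

#' @rdname code_value
#' @export
decode_value <- function(factor, x) {
  factor$base + x * factor$half_range
}

#' Full two-level factorial in coded units
#'
#' All `2^p` sign combinations, ordered lexicographically with -1 before
#' +1 and the last factor varying fastest.
#'
#' @param factors named list of [rsm_factor()]s, or an integer `p` (factors
#'   are then lettered A, B, C, ...).
#' @return object of class `coded_design` with the `runs` matrix and the
#'   factor list.
#' @export
full_factorial <- function(factors) {
  factors <- as_factor_list(factors)
  p <- length(factors)
  if (p < 1 || p > 20) stop_config("p must be between 1 and 20")
  # expand.grid varies its first column fastest; reversing the columns
  # yields lexicographic order with the last factor fastest
  runs <- as.matrix(expand.grid(rep(list(c(-1, 1)), p)))[, p:1, drop = FALSE]
  colnames(runs) <- names(factors)
  rownames(runs) <- NULL
  structure(list(factors = factors, runs = runs, defining_relation = NULL),
            class = "coded_design")
}

as_factor_list <- function(factors) {
  if (is.numeric(factors) && length(factors) == 1) {
    p <- as.integer(factors)
    factors <- lapply(LETTERS[seq_len(p)], function(nm)
      rsm_factor(nm, -1, 1))
  }
  if (is.null(names(factors)) || any(names(factors) == ""))
    names(factors) <- vapply(factors, `[[`, "", "name")
  factors
}

#' Regular half-fraction of a two-level factorial
#'
#' Keeps the `2^(p-1)` runs of the full factorial whose product over the
#' columns named in the generator word equals `sign`: the defining relation
#' is `I = sign * word`.
#'
#' @param factors as in [full_factorial()].
#' @param generator word over the factor letters (e.g. `"ABC"` or
#'   `"ABCDE"`); defaults to the word using all factors.
#' @param sign `+1` or `-1`.
#' @return a `coded_design` with `defining_relation` set.
#' @examples
#' d <- half_fraction(3, "ABC", +1)  # runs a, b, c, abc
#' @export
half_fraction <- function(factors, generator = NULL, sign = +1) {
  full <- full_factorial(factors)
  p <- length(full$factors)
  generator <- generator %||% paste(LETTERS[seq_len(p)], collapse = "")
  gi <- generator_indices(generator, full)
  if (!sign %in% c(-1, 1)) stop_config("sign must be +1 or -1")
  prod_col <- apply(full$runs[, gi, drop = FALSE], 1, prod)
  runs <- full$runs[prod_col == sign, , drop = FALSE]
  structure(list(factors = full$factors, runs = runs,
                 defining_relation = list(word = toupper(generator),
                                          sign = sign)),
            class = "coded_design")
}

# Resolve a generator word ("ABC") to column indices; letters index the
# factor list positionally (A = first factor).
generator_indices <- function(word, design) {
  letters_used <- strsplit(toupper(word), "")[[1]]
  idx <- match(letters_used, LETTERS)
  if (any(is.na(idx)) || any(idx > length(design$factors)) ||
      anyDuplicated(letters_used))
    stop_config("malformed generator word '%s'", word)
  idx
}

#' @export
print.coded_design <- function(x, ...) {
  cat(sprintf("Coded design: %d runs x %d factors", nrow(x$runs),
              length(x$factors)))
  if (!is.null(x$defining_relation))
    cat(sprintf(" (I = %s%s)",
                if (x$defining_relation$sign < 0) "-" else "+",
                x$defining_relation$word))
  cat("\n")
  print(x$runs)
  invisible(x)
}

#' Alias structure of a regular half fraction
#'
#' Each effect word is multiplied by the defining relation with squared
#' letters cancelled (symmetric difference of the letter sets), giving the
#' effect it is confounded with. The identity maps to the full defining
#' word.
#'
#' @param design a `coded_design` with a defining relation, or the
#'   generator word itself.
#' @param effects character vector of effect words; defaults to all
#'   non-identity effects of the design.
#' @return data.frame with columns `effect` and `alias`.
#' @examples
#' alias_structure(half_fraction(3, "ABC"))  # C aliased with AB, etc.
#' @export
alias_structure <- function(design, effects = NULL) {
  if (inherits(design, "coded_design")) {
    if (is.null(design$defining_relation))
      stop_config("design has no defining relation")
    word <- design$defining_relation$word
    p <- length(design$factors)
  } else {
    word <- toupper(design)
    p <- max(match(strsplit(word, "")[[1]], LETTERS))
  }
  if (is.null(effects)) {
    sets <- unlist(lapply(seq_len(p), function(k)
      utils::combn(LETTERS[seq_len(p)], k, paste, collapse = "")),
      use.names = FALSE)
    effects <- c("I", sets)
  }
  alias <- vapply(effects, function(e) word_multiply(e, word), "")
  data.frame(effect = effects, alias = alias, row.names = NULL)
}

# Word multiplication with x^2 = I: symmetric difference of letter sets.
word_multiply <- function(a, b) {
  la <- if (identical(a, "I")) character(0) else strsplit(a, "")[[1]]
  lb <- if (identical(b, "I")) character(0) else strsplit(b, "")[[1]]
  res <- sort(c(setdiff(la, lb), setdiff(lb, la)))
  if (length(res) == 0) "I" else paste(res, collapse = "")
}

#' Fit a first-order model on coded variables
#'
#' Ordinary least squares of the response on an intercept and the main
#' effects of the coded variables. On an orthogonal two-level design each
#' slope equals half the difference between the mean response at the high
#' and the low level of that factor.
#'
#' @param design a `coded_design` (or a numeric matrix of coded runs).
#' @param responses one response per run.
#' @param response_name label carried into reports.
#' @return object of class `first_order_fit` with `coefficients`
#'   (intercept first), `fitted`, `residuals`, `sigma2` and the factor
#'   names.
#' @export
fit_first_order <- function(design, responses, response_name = "y") {
  X <- if (inherits(design, "coded_design")) design$runs else as.matrix(design)
  y <- as.numeric(responses)
  if (length(y) != nrow(X))
    stop_config("need one response per run (%d runs, %d responses)",
                nrow(X), length(y))
  if (nrow(X) < ncol(X) + 1)
    stop_config("need at least p + 1 runs to fit p slopes")
  Xf <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    bad <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop_config("singular design; collinear columns: %s",
                paste(bad, collapse = ", "))
  }
  b <- qr.coef(qrX, y)
  fitted <- drop(Xf %*% b)
  res <- y - fitted
  dfres <- nrow(Xf) - ncol(Xf)
  first_order_fit(b, sigma2 = if (dfres > 0) sum(res^2) / dfres else NA_real_,
                  response_name = response_name, fitted = fitted,
                  residuals = res)
}

#' Construct a first-order fit from known coefficients
#'
#' Low-level constructor, also used to carry printed coefficient vectors
#' (e.g. from a previously reported fit) into the steepest-ascent stage.
#'
#' @param coefficients named numeric vector; the first element is the
#'   intercept, the rest are slopes in coded units named after factors.
#' @param sigma2 residual variance estimate, if any.
#' @param response_name label.
#' @param fitted,residuals optional vectors from an actual fit.
#' @return object of class `first_order_fit`.
#' @examples
#' # slopes of a reported SVM-minus-BLUP fit
#' first_order_fit(c("(Intercept)" = -0.130, ind = 0.019, m = -0.004,
#'                   qtl = -0.003, epi = 0.043, h = 0.020))
#' @export
first_order_fit <- function(coefficients, sigma2 = NA_real_,
                            response_name = "y", fitted = NULL,
                            residuals = NULL) {
  if (is.null(names(coefficients)))
    stop_config("coefficients must be named (intercept first)")
  structure(list(coefficients = coefficients, sigma2 = sigma2,
                 response_name = response_name, fitted = fitted,
                 residuals = residuals),
            class = "first_order_fit")
}

#' @export
coef.first_order_fit <- function(object, ...) object$coefficients

#' @export
residuals.first_order_fit <- function(object, ...) object$residuals

#' @export
print.first_order_fit <- function(x, ...) {
  b <- x$coefficients
  terms <- paste(sprintf("%+.4g %s", b[-1], names(b)[-1]), collapse = " ")
  cat(sprintf("First-order fit: %s = %.4g %s\n", x$response_name,
              b[1], terms))
  invisible(x)
}

#' @export
summary.first_order_fit <- function(object, ...) {
  cat(sprintf("First-order model for response '%s'\n",
              object$response_name))
  print(object$coefficients)
  if (!is.na(object$sigma2))
    cat(sprintf("Residual variance: %.5g\n", object$sigma2))
  invisible(object)
}

#' @export
predict.first_order_fit <- function(object, newdata, ...) {
  b <- object$coefficients
  X <- as.matrix(newdata)[, names(b)[-1], drop = FALSE]
  drop(b[1] + X %*% b[-1])
}

#' Box-Cox power transformation
#'
#' `w = (y^lambda - 1) / lambda` for `lambda != 0` and `w = log(y)` at
#' `lambda = 0`; rank-preserving for any `lambda`, defined for positive
#' responses only.
#'
#' @param y positive numeric vector.
#' @param lambda power parameter.
#' @return transformed vector.
#' @export
box_cox <- function(y, lambda) {
  if (any(y <= 0)) stop_config("Box-Cox requires positive values")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' @rdname box_cox
#' @param lambda_grid grid over which the profile likelihood is maximized.
#' @return for `box_cox_mle`, the maximizing `lambda`.
#' @export
box_cox_mle <- function(y, lambda_grid = seq(-2, 2, by = 0.01)) {
  if (any(y <= 0)) stop_config("Box-Cox requires positive values")
  df <- data.frame(.response = y)
  fit <- stats::lm(.response ~ 1, data = df, y = TRUE, qr = TRUE)
  prof <- MASS::boxcox(fit, lambda = lambda_grid, plotit = FALSE)
  prof$x[which.max(prof$y)]
}
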