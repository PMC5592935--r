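# Quantitative trait model on DH genotypes.
#
# Phenotypes follow Pheno = mu + Xa a + Xe epi + e, where Xa holds the
# -1/+1 codes at the QTL, Xe holds additive-by-additive products of paired
# neighboring QTL, a and epi are common scalar effects, and e is normal
# noise scaled so that broad-sense heritability VG/(VG+Ve) equals h.
# The genetic variance decomposes as
#   VG = a^2 Va + epi^2 Vepi + 2 a epi Cov,
# with Va/Vepi/Cov the empirical (co)variances of the additive and
# epistatic row sums.

#' Build additive and epistatic incidence matrices
#'
#' `Xa` restricts the genotype codes to the QTL columns. Epistasis is
#' additive-by-additive between pairs of neighboring QTL: with
#' `pairing = "disjoint"` (default) the QTL are paired (1,2), (3,4), ... in
#' genome order giving `floor(q/2)` product columns; `"chain"` uses the
#' sliding pairs (1,2), (2,3), ... giving `q - 1` columns.
#'
#' @param pop a `dh_pop` with `qtl_indices` set (see [place_qtl()]).
#' @param pairing neighboring-pair scheme.
#' @return list with matrices `Xa` (`n x q`) and `Xe` (`n x p`).
#' @export
build_incidence_matrices <- function(pop, pairing = c("disjoint", "chain")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(pop, "dh_pop"))
  if (is.null(pop$qtl_indices))
    stop_config("qtl_indices not set; call place_qtl() first")
  Xa <- pop$genotypes[, pop$qtl_indices, drop = FALSE]
  q <- ncol(Xa)
  if (q >= 2) {
    if (pairing == "disjoint") {
      i1 <- seq(1L, q - 1L, by = 2L)
    } else {
      i1 <- seq_len(q - 1L)
    }
    i2 <- i1 + 1L
    Xe <- Xa[, i1, drop = FALSE] * Xa[, i2, drop = FALSE]
    colnames(Xe) <- paste0(colnames(Xa)[i1], "x", colnames(Xa)[i2])
  } else {
    Xe <- matrix(numeric(0), nrow(Xa), 0)
  }
  list(Xa = Xa, Xe = Xe)
}

#' Empirical variance components of the trait architecture
#'
#' `Va` is the sample variance over lines of the additive row sum
#' (effects are a common scalar, so the genetic value is `a * rowSums(Xa) +
#' epi * rowSums(Xe)`), `Vepi` that of the epistatic row sum, and `Cov`
#' their sample covariance.
#'
#' @param Xa,Xe incidence matrices from [build_incidence_matrices()].
#' @return list with `Va`, `Vepi`, `Cov`.
#' @export
empirical_variance_components <- function(Xa, Xe) {
  if (nrow(Xa) < 2) stop_config("need at least 2 lines for a variance")
  sa <- rowSums(Xa)
  se <- if (ncol(Xe) > 0) rowSums(Xe) else rep(0, nrow(Xa))
  list(Va = stats::var(sa),
       Vepi = if (ncol(Xe) > 0) stats::var(se) else 0,
       Cov = if (ncol(Xe) > 0) stats::cov(sa, se) else 0)
}

#' Solve effect scalars for a target epistatic share
#'
#' Chooses `a` and `epi` so that `a^2 Va + epi^2 Vepi = 1` with
#' `epi^2 Vepi` equal to the target share. The share definition excludes
#' the `2 a epi Cov` cross-term (which is near zero under disjoint pairing);
#' the cross-term is still included in VG when scaling the error variance.
#'
#' @param target_epi_proportion fraction of genetic variance that is
#'   epistatic, in `[0, 1]`.
#' @param Va,Vepi variance components (see
#'   [empirical_variance_components()]).
#' @return list with scalars `a` and `epi`.
#' @examples
#' solve_effect_scalars(0.5, 1, 1)  # a = epi = 1/sqrt(2)
#' @export
solve_effect_scalars <- function(target_epi_proportion, Va, Vepi) {
  t <- target_epi_proportion
  if (!is.finite(t) || t < 0 || t > 1)
    stop_config("target epistatic proportion must be in [0, 1]")
  if (t < 1 && Va <= 0)
    stop_config("additive variance is zero but target proportion < 1")
  if (t > 0 && Vepi <= 0)
    stop_config("epistatic variance is zero but target proportion > 0")
  list(a = if (t < 1) sqrt((1 - t) / Va) else 0,
       epi = if (t > 0) sqrt(t / Vepi) else 0)
}

#' Construct a trait architecture on a population
#'
#' Builds incidence matrices, solves the effect scalars for the requested
#' epistatic share, and computes the variance decomposition
#' `VG = a^2 Va + epi^2 Vepi + 2 a epi Cov` and the error variance
#' `Ve = VG (1 - h) / h`.
#'
#' @param pop a `dh_pop` with QTL placed.
#' @param epi_proportion target fraction of genetic variance due to
#'   epistasis, in `[0, 1]`.
#' @param h broad-sense heritability, in `(0, 1]`.
#' @param mu phenotype intercept (default 0; prediction accuracy is
#'   translation-invariant).
#' @param pairing neighboring-QTL pairing scheme, see
#'   [build_incidence_matrices()].
#' @return object of class `trait_arch` carrying the effect scalars, the
#'   variance decomposition, and the per-line genetic values.
#' @export
trait_architecture <- function(pop, epi_proportion, h, mu = 0,
                               pairing = c("disjoint", "chain")) {
  pairing <- match.arg(pairing)
  if (!is.finite(h) || h <= 0 || h > 1)
    stop_config("heritability h must be in (0, 1]")
  if (epi_proportion > 0 && length(pop$qtl_indices) < 2)
    stop_config("epistasis requested but fewer than 2 QTL are placed")
  inc <- build_incidence_matrices(pop, pairing)
  vc <- empirical_variance_components(inc$Xa, inc$Xe)
  eff <- solve_effect_scalars(epi_proportion, vc$Va, vc$Vepi)
  VG <- eff$a^2 * vc$Va + eff$epi^2 * vc$Vepi +
    2 * eff$a * eff$epi * vc$Cov
  Ve <- VG * (1 - h) / h
  sa <- rowSums(inc$Xa)
  se <- if (ncol(inc$Xe) > 0) rowSums(inc$Xe) else rep(0, nrow(inc$Xa))
  structure(
    list(a = eff$a, epi = eff$epi, epi_proportion = epi_proportion,
         h = h, mu = mu, pairing = pairing,
         Va = vc$Va, Vepi = vc$Vepi, Cov = vc$Cov, VG = VG, Ve = Ve,
         genetic_values = mu + eff$a * sa + eff$epi * se,
         n_epistatic_pairs = ncol(inc$Xe)),
    class = "trait_arch"
  )
}

#' @export
print.trait_arch <- function(x, ...) {
  cat(sprintf(
    "Trait architecture: epi share %.2f, h %.2f (%s pairing, %d pairs)\n",
    x$epi_proportion, x$h, x$pairing, x$n_epistatic_pairs))
  cat(sprintf("  a = %.4f, epi = %.4f; Va %.3f, Vepi %.3f, Cov %.3f\n",
              x$a, x$epi, x$Va, x$Vepi, x$Cov))
  cat(sprintf("  VG = %.4f, Ve = %.4f\n", x$VG, x$Ve))
  invisible(x)
}

#' Simulate phenotypes at the target heritability
#'
#' Adds i.i.d. normal noise with variance `Ve = VG (1 - h) / h` to the
#' genetic values; at `h = 1` the phenotypes equal the genetic values
#' exactly.
#'
#' @param pop the `dh_pop` the architecture was built on (used for line
#'   names and a size check).
#' @param arch a `trait_arch`.
#' @param seed integer seed for the noise draw.
#' @return object of class `phenotype_set` with `values`,
#'   `genetic_values` and the `seed`.
#' @export
simulate_phenotypes <- function(pop, arch, seed) {
  stopifnot(inherits(arch, "trait_arch"))
  n <- length(arch$genetic_values)
  if (nrow(pop$genotypes) != n)
    stop_config("architecture was built on a different population size")
  set.seed(as.integer(seed))
  eps <- if (arch$Ve > 0) stats::rnorm(n, 0, sqrt(arch$Ve)) else numeric(n)
  structure(
    list(values = arch$genetic_values + eps,
         genetic_values = arch$genetic_values,
         Ve = arch$Ve, h = arch$h, seed = as.integer(seed)),
    class = "phenotype_set"
  )
}

#' @export
print.phenotype_set <- function(x, ...) {
  cat(sprintf("Phenotypes: %d lines, Ve = %.4f (h = %.2f)\n",
              length(x$values), x$Ve, x$h))
  invisible(x)
}

#' Export phenotypes and report the architecture
#'
#' @param ph a `phenotype_set`.
#' @param file two-column CSV path (`line_id`, `phenotype`).
#' @return invisibly, `file`.
#' @export
write_phenotypes <- function(ph, file) {
  utils::write.csv(
    data.frame(line_id = seq_along(ph$values), phenotype = ph$values),
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_phenotypes
#' @param arch a `trait_arch`.
#' @param realized_h optional realized heritability to record.
#' @export
architecture_report <- function(arch, file, realized_h = NULL) {
  rep <- list(a = arch$a, epi = arch$epi,
              epi_proportion = arch$epi_proportion,
              Va = arch$Va, Vepi = arch$Vepi, Cov = arch$Cov,
              VG = arch$VG, Ve = arch$Ve, h = arch$h)
  if (!is.null(realized_h)) rep$realized_h <- realized_h
  jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
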