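# Genomic prediction: ridge-regression BLUP and support-vector regression,
# with independently drawn 80/20 cross-validation splits and Pearson
# accuracy r(pheno, predicted) on held-out lines.

#' Fit ridge-regression BLUP marker effects and predict test lines
#'
#' Solves the mixed model `y = 1 mu + Z u + e` with `u ~ N(0, sigma_u^2 I)`
#' by ridge regression, the shrinkage parameter `lambda =
#' sigma_e^2 / sigma_u^2` estimated by REML via a spectral decomposition of
#' the centered marker cross-product (the smaller of `Z'Z` and `ZZ'` is
#' decomposed). `lambda` is floored at 1e-8 so a vanishing error variance
#' stays numerically solvable.
#'
#' @param train_genotypes,train_phenotypes training marker matrix
#'   (lines x markers) and phenotype vector.
#' @param test_genotypes marker matrix of the lines to predict; columns
#'   must match the training matrix.
#' @param lambda optional fixed shrinkage parameter; skips REML. The fixed
#'   solution equals the direct ridge solution
#'   `(Zc'Zc + lambda I)^{-1} Zc' yc` on centered data.
#' @return list of class `gp_fit`: `predictions`, `method = "BLUP"`,
#'   `hyperparameters` (lambda, variance components, degeneracy flag),
#'   `effects` and `intercept`.
#' @export
fit_rrblup <- function(train_genotypes, train_phenotypes, test_genotypes,
                       lambda = NULL) {
  Z <- as.matrix(train_genotypes)
  y <- as.numeric(train_phenotypes)
  Zt <- as.matrix(test_genotypes)
  n <- nrow(Z)
  if (n < 2) stop_config("need at least 2 training lines")
  if (ncol(Zt) != ncol(Z))
    stop_config("train and test marker columns differ")
  mu <- mean(y)
  if (stats::sd(y) == 0) {
    warning("constant training phenotypes; falling back to mean prediction")
    return(structure(list(
      predictions = rep(mu, nrow(Zt)), method = "BLUP",
      hyperparameters = list(lambda = NA_real_, degenerate = TRUE),
      effects = rep(0, ncol(Z)), intercept = mu), class = "gp_fit"))
  }
  cm <- colMeans(Z)
  Zc <- sweep(Z, 2, cm)
  yc <- y - mu
  df <- n - 1  # intercept absorbed by centering

  if (ncol(Z) <= n) {
    # primal route: eigendecompose Zc'Zc (m x m)
    E <- eigen(crossprod(Zc), symmetric = TRUE)
    d <- pmax(E$values, 0)
    keep <- d > max(d, 1e-12) * 1e-10
    w <- drop(crossprod(E$vectors, crossprod(Zc, yc)))
    eta2 <- w[keep]^2 / d[keep]  # squared projections onto the
    # unit eigenvectors of ZcZc'
    R0 <- max(sum(yc^2) - sum(eta2), 0)
    r <- sum(keep)
    lam <- lambda %||% reml_lambda(d[keep], eta2, R0, df, r)
    u <- drop(E$vectors %*% (w / (d + lam)))
  } else {
    # dual route: eigendecompose ZcZc' (n x n)
    E <- eigen(tcrossprod(Zc), symmetric = TRUE)
    d <- pmax(E$values, 0)
    keep <- d > max(d, 1e-12) * 1e-10
    eta <- drop(crossprod(E$vectors, yc))
    eta2 <- eta[keep]^2
    R0 <- max(sum(yc^2) - sum(eta2), 0)
    r <- sum(keep)
    lam <- lambda %||% reml_lambda(d[keep], eta2, R0, df, r)
    u <- drop(crossprod(Zc, E$vectors %*% (eta / (d + lam))))
  }
  sigma_u2 <- if (is.null(lambda)) attr(lam, "sigma_u2") else NA_real_
  lam <- as.numeric(lam)
  preds <- drop(sweep(Zt, 2, cm) %*% u) + mu
  structure(list(
    predictions = preds, method = "BLUP",
    hyperparameters = list(lambda = lam, sigma_u2 = sigma_u2,
                           sigma_e2 = if (is.na(sigma_u2)) NA_real_
                                      else lam * sigma_u2,
                           degenerate = FALSE),
    effects = u, intercept = mu), class = "gp_fit")
}

# REML profile over log(lambda), lambda = sigma_e^2 / sigma_u^2. In the
# rotated basis of the centered marker cross-product each direction with
# eigenvalue d_i has variance sigma_u^2 (d_i + lambda); the df - r null
# directions have variance sigma_e^2. d: nonzero eigenvalues; eta2:
# squared projections of the centered response on the unit eigenvectors;
# R0: residual sum of squares over the null directions; df = n - 1.
reml_lambda <- function(d, eta2, R0, df, r) {
  nzero <- max(df - r, 0)
  profile_sigma_u2 <- function(lam) {
    S <- sum(eta2 / (d + lam))
    if (nzero > 0) S <- S + R0 / lam
    S / df
  }
  negll <- function(loglam) {
    lam <- exp(loglam)
    0.5 * (sum(log(d + lam)) + nzero * loglam +
             df * log(profile_sigma_u2(lam)))
  }
  opt <- stats::optimize(negll, interval = c(log(1e-8), log(1e10)))
  lam <- max(exp(opt$minimum), 1e-8)
  structure(lam, sigma_u2 = profile_sigma_u2(lam))
}

#' Fit epsilon-insensitive support-vector regression and predict
#'
#' Radial-basis kernel by default with cost 1, `gamma = 1/m` and
#' `epsilon = 0.1`; genotype codes are already on a common -1/+1 scale so
#' no input scaling is applied.
#'
#' @inheritParams fit_rrblup
#' @param cost,gamma,epsilon,kernel SVR hyperparameters; `gamma` defaults
#'   to `1/ncol(train_genotypes)`.
#' @return list of class `gp_fit` with `method = "SVM"`.
#' @export
fit_svr <- function(train_genotypes, train_phenotypes, test_genotypes,
                    cost = 1, gamma = NULL, epsilon = 0.1,
                    kernel = "radial") {
  Z <- as.matrix(train_genotypes)
  y <- as.numeric(train_phenotypes)
  Zt <- as.matrix(test_genotypes)
  if (nrow(Z) < 2) stop_config("need at least 2 training lines")
  gamma <- gamma %||% (1 / ncol(Z))
  if (stats::sd(y) == 0) {
    return(structure(list(
      predictions = rep(mean(y), nrow(Zt)), method = "SVM",
      hyperparameters = list(degenerate = TRUE),
      intercept = mean(y)), class = "gp_fit"))
  }
  fit <- e1071::svm(x = Z, y = y, type = "eps-regression", kernel = kernel,
                    cost = cost, gamma = gamma, epsilon = epsilon,
                    scale = FALSE)
  structure(list(
    predictions = as.numeric(stats::predict(fit, Zt)), method = "SVM",
    hyperparameters = list(cost = cost, gamma = gamma, epsilon = epsilon,
                           kernel = kernel, degenerate = FALSE)),
    class = "gp_fit")
}

#' Draw independent random 80/20 train/test splits
#'
#' Each split is an independent random partition (not a rotation-fold
#' scheme): `round(test_fraction * n)` lines form the testing set, the rest
#' the training set.
#'
#' @param n number of lines.
#' @param test_fraction fraction held out (default 0.2).
#' @param n_splits number of splits.
#' @param seed integer seed; the full split list is reproducible.
#' @return list of `n_splits` elements, each `list(train, test)` of
#'   indices.
#' @export
make_cv_splits <- function(n, test_fraction = 0.2, n_splits, seed) {
  if (n < 5) stop_config("n must be at least 5 for a nonempty test set")
  n_test <- max(1L, round(test_fraction * n))
  set.seed(as.integer(seed))
  lapply(seq_len(n_splits), function(i) {
    test <- sort(sample.int(n, n_test))
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

# Pearson accuracy with a degeneracy flag: a zero-variance prediction (or
# response) is recorded as 0 so replicate averaging stays total.
pearson_accuracy <- function(obs, pred) {
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0)
    return(list(r = 0, degenerate = TRUE))
  list(r = stats::cor(obs, pred), degenerate = FALSE)
}

#' Estimate cross-validated prediction accuracy at a design point
#'
#' Simulates `n_datasets` independent genotype/phenotype data sets at the
#' factor combination, draws `n_splits` random 80/20 splits within each
#' (paper defaults: 20 x 25 = 500 replicates), fits the predictor(s) on
#' the training lines, and records the Pearson correlation between
#' held-out phenotypes and predictions. BLUP and SVR consume identical
#' splits, so the SVM-minus-BLUP difference is computed replicate-wise on
#' shared data.
#'
#' @param design_point named list or vector with `ind` (lines), `m`
#'   (markers), `qtl`, `epi` (epistatic share) and `h` (heritability).
#' @param method `"both"`, `"blup"` or `"svm"`.
#' @param n_datasets,n_splits replication counts (defaults 20 and 25).
#' @param seed master seed; dataset, phenotype and split streams are
#'   derived deterministically from it.
#' @param n_chromosomes,map_length genome settings passed to
#'   [genome_spec()].
#' @param svr_args list of arguments forwarded to [fit_svr()].
#' @param qtl_rule QTL placement rule (see [place_qtl()]).
#' @return object of class `accuracy_estimate`: per-replicate accuracies,
#'   means, degenerate-replicate counts, and the design point.
#' @export
estimate_accuracy <- function(design_point, method = c("both", "blup", "svm"),
                              n_datasets = 20, n_splits = 25, seed = 1,
                              n_chromosomes = 10, map_length = 1,
                              svr_args = list(),
                              qtl_rule = "evenly_spaced") {
  method <- match.arg(method)
  dp <- as.list(design_point)
  required <- c("ind", "m", "qtl", "epi", "h")
  if (!all(required %in% names(dp)))
    stop_config("design point needs fields: %s",
                paste(required, collapse = ", "))
  if (dp$qtl > dp$m)
    stop_config("design point violates the constraint qtl <= m")
  do_blup <- method %in% c("both", "blup")
  do_svm <- method %in% c("both", "svm")
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    gs <- genome_spec(dp$m, n_chromosomes, map_length)
    pop <- simulate_dh_genotypes(gs, dp$ind,
                                 seed = seed_stream(seed, "genotypes", i))
    pop <- place_qtl(pop, dp$qtl, rule = qtl_rule,
                     seed = seed_stream(seed, "qtl", i))
    arch <- trait_architecture(pop, dp$epi, dp$h)
    ph <- simulate_phenotypes(pop, arch,
                              seed = seed_stream(seed, "phenotypes", i))
    splits <- make_cv_splits(dp$ind, 0.2, n_splits,
                             seed = seed_stream(seed, "splits", i))
    res <- lapply(seq_along(splits), function(j) {
      sp <- splits[[j]]
      Ztr <- pop$genotypes[sp$train, , drop = FALSE]
      Zte <- pop$genotypes[sp$test, , drop = FALSE]
      ytr <- ph$values[sp$train]
      yte <- ph$values[sp$test]
      r_blup <- r_svm <- NA_real_
      deg_blup <- deg_svm <- NA
      if (do_blup) {
        fb <- suppressWarnings(fit_rrblup(Ztr, ytr, Zte))
        ab <- pearson_accuracy(yte, fb$predictions)
        r_blup <- ab$r; deg_blup <- ab$degenerate
      }
      if (do_svm) {
        fs <- do.call(fit_svr, c(list(Ztr, ytr, Zte), svr_args))
        as_ <- pearson_accuracy(yte, fs$predictions)
        r_svm <- as_$r; deg_svm <- as_$degenerate
      }
      data.frame(dataset = i, split = j, r_blup = r_blup, r_svm = r_svm,
                 diff = r_svm - r_blup, degenerate_blup = deg_blup,
                 degenerate_svm = deg_svm)
    })
    rows[[i]] <- do.call(rbind, res)
  }
  per <- do.call(rbind, rows)
  structure(list(
    design_point = dp, method = method,
    per_replicate = per,
    n_datasets = n_datasets, n_splits_per_dataset = n_splits,
    n_replicates = nrow(per),
    mean_r_blup = if (do_blup) mean(per$r_blup) else NA_real_,
    mean_r_svm = if (do_svm) mean(per$r_svm) else NA_real_,
    mean_diff = if (do_blup && do_svm) mean(per$diff) else NA_real_,
    sd_r_blup = if (do_blup) stats::sd(per$r_blup) else NA_real_,
    sd_r_svm = if (do_svm) stats::sd(per$r_svm) else NA_real_,
    n_degenerate = sum(per$degenerate_blup, per$degenerate_svm,
                       na.rm = TRUE),
    seed = seed), class = "accuracy_estimate")
}

#' @export
print.accuracy_estimate <- function(x, ...) {
  dp <- x$design_point
  cat(sprintf(
    "Accuracy at (%g ind, %g m, %g QTL, %.2g epi, %.2g h), %d replicates:\n",
    dp$ind, dp$m, dp$qtl, dp$epi, dp$h, x$n_replicates))
  if (!is.na(x$mean_r_blup))
    cat(sprintf("  BLUP  mean r = %.3f (sd %.3f)\n",
                x$mean_r_blup, x$sd_r_blup))
  if (!is.na(x$mean_r_svm))
    cat(sprintf("  SVM   mean r = %.3f (sd %.3f)\n",
                x$mean_r_svm, x$sd_r_svm))
  if (!is.na(x$mean_diff))
    cat(sprintf("  SVM - BLUP   = %.3f\n", x$mean_diff))
  if (x$n_degenerate > 0)
    cat(sprintf("  (%d degenerate replicates recorded as 0)\n",
                x$n_degenerate))
  invisible(x)
}

#' @export
as.data.frame.accuracy_estimate <- function(x, ...) {
  dp <- x$design_point
  data.frame(ind = dp$ind, m = dp$m, qtl = dp$qtl, epi = dp$epi, h = dp$h,
             method = x$method, n_replicates = x$n_replicates,
             mean_r_blup = x$mean_r_blup, mean_r_svm = x$mean_r_svm,
             mean_diff = x$mean_diff, sd_r_blup = x$sd_r_blup,
             sd_r_svm = x$sd_r_svm, n_degenerate = x$n_degenerate,
             seed = x$seed)
}
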