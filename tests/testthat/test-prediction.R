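test_that("fixed-shrinkage BLUP equals the direct ridge solution", {
  set.seed(41)
  Z <- matrix(sample(c(-1, 1), 5 * 3, TRUE), 5, 3)
  y <- rnorm(5)
  Zt <- matrix(sample(c(-1, 1), 4 * 3, TRUE), 4, 3)
  for (lam in c(0.1, 1, 10)) {
    fit <- fit_rrblup(Z, y, Zt, lambda = lam)
    # independent brute-force oracle: centered ridge by matrix inversion
    Zc <- scale(Z, scale = FALSE)
    u <- solve(crossprod(Zc) + lam * diag(3), crossprod(Zc, y - mean(y)))
    pred <- mean(y) + drop(scale(Zt, center = attr(Zc, "scaled:center"),
                                 scale = FALSE) %*% u)
    expect_equal(fit$predictions, pred, tolerance = 1e-10)
  }
})

test_that("primal and dual BLUP routes agree", {
  set.seed(42)
  Z <- matrix(sample(c(-1, 1), 10 * 25, TRUE), 10, 25)  # m > n: dual
  y <- rnorm(10)
  Zt <- matrix(sample(c(-1, 1), 3 * 25, TRUE), 3, 25)
  f_dual <- fit_rrblup(Z, y, Zt, lambda = 2)
  # force the primal route through the same matrices padded by zero rows?
  # simpler: direct kernel-form oracle
  Zc <- scale(Z, scale = FALSE)
  u <- drop(crossprod(Zc, solve(tcrossprod(Zc) + 2 * diag(10), y - mean(y))))
  pred <- mean(y) + drop(scale(Zt, center = attr(Zc, "scaled:center"),
                               scale = FALSE) %*% u)
  expect_equal(f_dual$predictions, pred, tolerance = 1e-10)
})

test_that("REML BLUP approaches perfect accuracy on a noiseless additive trait", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(50, 10), 300,
                                         seed = 43), 50)
  arch <- trait_architecture(pop, 0, h = 1)
  ph <- simulate_phenotypes(pop, arch, seed = 44)
  fit <- fit_rrblup(pop$genotypes, ph$values, pop$genotypes)
  expect_gt(cor(fit$predictions, ph$values), 0.99)
  expect_gt(fit$hyperparameters$lambda, 0)
})

test_that("constant training phenotypes fall back to mean prediction", {
  Z <- matrix(sample(c(-1, 1), 20, TRUE), 5, 4)
  expect_warning(fit <- fit_rrblup(Z, rep(2, 5), Z), "constant")
  expect_equal(fit$predictions, rep(2, 5))
  expect_true(fit$hyperparameters$degenerate)
  fs <- fit_svr(Z, rep(2, 5), Z)
  expect_equal(fs$predictions, rep(2, 5))
  expect_true(fs$hyperparameters$degenerate)
})

test_that("SVR learns a linear marker signal", {
  set.seed(45)
  Z <- matrix(sample(c(-1, 1), 200 * 3, TRUE), 200, 3)
  y <- rowSums(Z)
  Zt <- matrix(sample(c(-1, 1), 100 * 3, TRUE), 100, 3)
  fit <- fit_svr(Z, y, Zt)
  expect_gt(cor(fit$predictions, rowSums(Zt)), 0.9)
  expect_equal(fit$hyperparameters$gamma, 1 / 3)
  # minimal smoke contract
  f2 <- fit_svr(Z[1:2, ], y[1:2], Zt)
  expect_length(f2$predictions, 100)
})

test_that("SVR far outperforms BLUP on a purely epistatic trait", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(20, 10), 800,
                                         seed = 46), 4)
  arch <- trait_architecture(pop, 1, h = 1)
  ph <- simulate_phenotypes(pop, arch, seed = 47)
  tr <- 1:600; te <- 601:800
  fb <- fit_rrblup(pop$genotypes[tr, ], ph$values[tr],
                   pop$genotypes[te, ])
  fs <- fit_svr(pop$genotypes[tr, ], ph$values[tr], pop$genotypes[te, ])
  r_blup <- cor(ph$values[te], fb$predictions)
  r_svm <- cor(ph$values[te], fs$predictions)
  expect_lt(abs(r_blup), 0.25)
  expect_gt(r_svm, r_blup + 0.3)
})

test_that("cross-validation splits are random 20/80 partitions", {
  sp <- make_cv_splits(10, 0.2, 4, seed = 48)
  expect_length(sp, 4)
  for (s in sp) {
    expect_length(s$test, 2)
    expect_length(s$train, 8)
    expect_setequal(c(s$train, s$test), 1:10)
  }
  sp1k <- make_cv_splits(1000, 0.2, 2, seed = 49)
  expect_length(sp1k[[1]]$test, 200)
  expect_length(sp1k[[1]]$train, 800)
  expect_identical(make_cv_splits(50, 0.2, 3, seed = 50),
                   make_cv_splits(50, 0.2, 3, seed = 50))
  # independent draws, not a rotation: same index may recur across tests
  expect_false(identical(sp1k[[1]]$test, sp1k[[2]]$test))
  expect_error(make_cv_splits(4, 0.2, 1, seed = 1), "at least 5")
})

test_that("accuracy replicates are bookkept on shared splits", {
  est <- estimate_accuracy(list(ind = 100, m = 20, qtl = 4, epi = 0.2,
                                h = 0.8),
                           n_datasets = 3, n_splits = 4, seed = 51)
  expect_equal(est$n_replicates, 12L)
  expect_equal(nrow(est$per_replicate), 12L)
  # the difference response is computed replicate-wise on shared data
  expect_equal(est$per_replicate$diff,
               est$per_replicate$r_svm - est$per_replicate$r_blup)
  expect_equal(est$mean_diff, mean(est$per_replicate$diff))
  expect_true(all(abs(est$per_replicate$r_blup) <= 1))
  # identical seed reproduces the whole table
  est2 <- estimate_accuracy(list(ind = 100, m = 20, qtl = 4, epi = 0.2,
                                 h = 0.8),
                            n_datasets = 3, n_splits = 4, seed = 51)
  expect_identical(est$per_replicate, est2$per_replicate)
  expect_error(
    estimate_accuracy(list(ind = 50, m = 10, qtl = 20, epi = 0, h = 0.5),
                      n_datasets = 1, n_splits = 1, seed = 1),
    "qtl <= m")
})

test_that("degenerate predictions are recorded as zero accuracy", {
  r <- gpascent:::pearson_accuracy(c(1, 2, 3), c(5, 5, 5))
  expect_equal(r$r, 0)
  expect_true(r$degenerate)
  r2 <- gpascent:::pearson_accuracy(c(1, 2, 3), c(1, 2, 2.5))
  expect_false(r2$degenerate)
})
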