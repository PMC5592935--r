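test_that("the basis is the factor with the largest absolute slope", {
  expect_equal(choose_basis(svm_minus_blup_fit()), "epi")
  expect_equal(choose_basis(blup_fit()), "epi")
  expect_equal(choose_basis(blup_fit(), override = "h"), "h")
  single <- first_order_fit(c("(Intercept)" = 0, temp = 0.3))
  expect_equal(choose_basis(single), "temp")
  flat <- first_order_fit(c("(Intercept)" = 1, a = 0, b = 0))
  expect_error(choose_basis(flat), "no direction")
})

test_that("coded steps follow the coefficient ratios from the basis", {
  facs <- gp_factors()
  s1 <- coded_step_sizes(svm_minus_blup_fit(), facs, basis_step = 0.25,
                         digits = 2)
  expect_equal(unname(s1[c("ind", "m", "qtl", "h")]),
               c(0.74, -0.16, -0.12, 0.78))
  expect_equal(attr(s1, "basis"), "epi")
  expect_equal(attr(s1, "basis_step_coded"), 0.25 / 0.15)

  s2 <- coded_step_sizes(blup_fit(), facs, basis_step = 0.25, digits = 3)
  expect_equal(unname(s2[c("ind", "m", "qtl", "h")]),
               c(0.228, -0.029, 0.146, 0.842))
  # basis coded step carries the sign of the basis coefficient
  expect_equal(attr(s2, "basis_step_coded"), -0.25 / 0.15)

  # exact ratio property before any rounding
  raw <- coded_step_sizes(svm_minus_blup_fit(), facs)
  b <- coef(svm_minus_blup_fit())[-1]
  expect_equal(as.numeric(raw / raw[["epi"]]), as.numeric(b / b[["epi"]]),
               tolerance = 1e-14)
  zf <- first_order_fit(c("(Intercept)" = 0, ind = 0, m = 0, qtl = 0,
                          epi = 0.04, h = 0))
  expect_equal(unname(coded_step_sizes(zf, facs)[c("ind", "m")]), c(0, 0))
})

test_that("natural increments reproduce the printed path tables", {
  facs <- gp_factors()
  s1 <- coded_step_sizes(svm_minus_blup_fit(), facs, basis_step = 0.25, digits = 2)
  d1 <- natural_increments(s1, facs, compat = TRUE)
  expect_equal(unname(d1), c(296, -24, -5.4, 0.25, 0.12))

  s2 <- coded_step_sizes(blup_fit(), facs, basis_step = 0.25, digits = 3)
  d2 <- natural_increments(s2, facs, compat = TRUE)
  expect_equal(unname(d2), c(91, -4.4, 6.6, -0.25, 0.13))

  expect_equal(unname(natural_increments(c(ind = 0), facs)), 0)
})

test_that("path coordinates accumulate from the base with rounding and clamping", {
  facs <- gp_factors()
  p1 <- steepest_ascent(svm_minus_blup_fit(), facs, basis_step = 0.25,
                        digits = 2, compat = TRUE)
  co <- p1$coordinates
  expect_equal(unlist(co[co$k == 3, -1], use.names = FALSE),
               c(1488, 178, 39, 1, 0.71))
  expect_equal(unlist(co[co$k == 9, -1], use.names = FALSE),
               c(3264, 34, 6, 1, 1))
  # epistasis pinned at 1 from the third step onward, h from the sixth
  expect_true(all(co$epi[co$k >= 3] == 1))
  expect_true(all(co$h[co$k >= 6] == 1))
  expect_true(all(co$epi[co$k < 3] < 1))

  p2 <- steepest_ascent(blup_fit(), facs, basis_step = 0.25, digits = 3,
                        compat = TRUE, k_max = 5)
  co2 <- p2$coordinates
  expect_equal(unlist(co2[co2$k == 1, -1], use.names = FALSE),
               c(691, 246, 62, 0.10, 0.48))
  expect_equal(unlist(co2[co2$k == 2, -1], use.names = FALSE),
               c(782, 241, 68, 0, 0.61))
  # epistasis clamped at its lower operability bound 0
  expect_true(all(co2$epi >= 0))
})

test_that("coordinates never leave the operability region", {
  set.seed(71)
  facs <- gp_factors()
  for (i in 1:1000) {
    b <- rnorm(5)
    if (all(b == 0)) next
    names(b) <- c("ind", "m", "qtl", "epi", "h")
    fit <- first_order_fit(c("(Intercept)" = rnorm(1), b))
    p <- steepest_ascent(fit, facs, basis_step = runif(1, 0.05, 2),
                         k_max = sample(3:12, 1),
                         compat = sample(c(TRUE, FALSE), 1))
    co <- p$coordinates
    expect_true(all(co$epi >= 0 & co$epi <= 1))
    expect_true(all(co$h >= 0 & co$h <= 1))
    expect_true(all(co$ind >= 1 & co$m >= 1 & co$qtl >= 1))
    expect_true(all(co$ind == round(co$ind)))
    expect_true(all(co$qtl == round(co$qtl)))
  }
})

test_that("rescaling a factor's natural units leaves the coded path unchanged", {
  facs <- gp_factors()
  fit <- svm_minus_blup_fit()
  p <- steepest_ascent(fit, facs, basis_step = 0.25)
  # express markers in hundreds instead of counts
  facs2 <- facs
  facs2$m <- rsm_factor("m", 1, 4, FALSE, 0.01, Inf)
  p2 <- steepest_ascent(fit, facs2, basis_step = 0.25)
  expect_equal(p2$coded_steps, p$coded_steps, tolerance = 1e-12)
  expect_equal(unname(p2$deltas["m"] * 100), unname(p$deltas["m"]),
               tolerance = 1e-12)
})

test_that("descent is ascent on the negated response", {
  facs <- gp_factors()
  fit <- blup_fit()
  neg <- first_order_fit(-coef(fit))
  s_desc <- coded_step_sizes(fit, facs, basis_step = 0.25, direction = "descent")
  s_asc_neg <- coded_step_sizes(neg, facs, basis_step = 0.25, direction = "ascent")
  expect_equal(unname(s_desc), unname(s_asc_neg), tolerance = 1e-14)
})

test_that("path evaluation attaches responses and survives point failures", {
  facs <- gp_factors()
  p <- steepest_ascent(svm_minus_blup_fit(), facs, basis_step = 0.25,
                       k_max = 5)
  flat <- evaluate_path(p, function(pt) 1.5)
  expect_equal(flat$responses, rep(1.5, 5))

  # deterministic quadratic toy: rises then falls, interior maximum
  peak <- evaluate_path(p, function(pt) -(pt$ind - 1500)^2)
  expect_equal(which.max(peak$responses), 3)  # ind path crosses 1500
  expect_true(all(diff(peak$responses[1:3]) > 0))
  expect_true(all(diff(peak$responses[3:5]) < 0))

  expect_warning(
    bad <- evaluate_path(p, function(pt)
      if (pt$ind > 2000) stop("boom") else 1),
    "failed")
  expect_true(any(is.na(bad$responses)))
  expect_true(any(!is.na(bad$responses)))
})

test_that("iterative ascent on the yield surface reaches the optimal temperature", {
  facs <- list(
    temperature = rsm_factor("temperature", 64, 68, FALSE, 64, 80),
    drought = rsm_factor("drought", -4, -2, FALSE, -4, 4))
  run <- run_ascent(facs, function(pt)
    yield_surface(pt$temperature, pt$drought),
    basis_step = 1, k_max = 8, max_iterations = 8)
  # grid argmax oracle: temperature 73.39, drought 1.59
  expect_gt(run$best_point$temperature, 71)
  expect_lt(run$best_point$temperature, 76)
  expect_gt(run$best_response, 112)
  expect_lt(run$n_evaluations, 200)
})

test_that("a flat response converges immediately", {
  facs <- list(a = rsm_factor("a", 0, 1), b = rsm_factor("b", 0, 1))
  run <- run_ascent(facs, function(pt) 3, max_iterations = 4)
  expect_true(run$converged)
  expect_equal(run$best_response, 3)
  expect_length(run$iterations, 1)
})
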