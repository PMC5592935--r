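test_that("epistatic incidence columns are products of paired QTL codes", {
  G <- rbind(c(1, 1, -1, 1), c(1, -1, 1, 1), c(-1, -1, -1, -1))
  pop <- place_qtl(manual_pop(G), 4)
  inc <- build_incidence_matrices(pop)
  expect_identical(inc$Xa, pop$genotypes)
  expect_equal(unname(inc$Xe[, 1]), c(1, -1, 1))   # products (1,2)
  expect_equal(unname(inc$Xe[, 2]), c(-1, 1, 1))   # products (3,4)
})

test_that("pair counts follow the pairing scheme", {
  pop <- simulate_dh_genotypes(genome_spec(20, 2), 30, seed = 8)
  pop <- place_qtl(pop, 10)
  expect_equal(ncol(build_incidence_matrices(pop)$Xe), 5L)
  expect_equal(ncol(build_incidence_matrices(pop, "chain")$Xe), 9L)
  pop1 <- place_qtl(pop, 1)
  expect_equal(ncol(build_incidence_matrices(pop1)$Xe), 0L)
})

test_that("unlinked product columns have unit variance and Va approaches q", {
  # QTL on different chromosomes: codes independent, products of two
  # independent +/-1 variables take each sign with probability 1/2, so
  # the population variance is exactly 1 (enumeration over 4 outcomes)
  pop <- simulate_dh_genotypes(genome_spec(10, 10), 5000, seed = 21)
  pop <- place_qtl(pop, 10)
  inc <- build_incidence_matrices(pop)
  expect_true(all(abs(apply(inc$Xe, 2, var) - 1) < 0.1))
  vc <- empirical_variance_components(inc$Xa, inc$Xe)
  expect_lt(abs(vc$Va - 10) / 10, 0.15)

  pop2 <- place_qtl(simulate_dh_genotypes(genome_spec(2, 2), 5000,
                                          seed = 22), 2)
  vc2 <- empirical_variance_components(
    build_incidence_matrices(pop2)$Xa,
    build_incidence_matrices(pop2)$Xe)
  expect_lt(abs(vc2$Va - 2), 0.2)
})

test_that("degenerate variance components are handled", {
  G <- matrix(1, 4, 3)
  vc <- empirical_variance_components(G, matrix(numeric(0), 4, 0))
  expect_equal(vc$Va, 0)
  expect_equal(vc$Vepi, 0)
  expect_equal(vc$Cov, 0)
  expect_error(empirical_variance_components(G[1, , drop = FALSE],
                                             matrix(numeric(0), 1, 0)),
               "at least 2")
})

test_that("effect scalars hit the target epistatic share", {
  expect_equal(solve_effect_scalars(0, 4, 2), list(a = 0.5, epi = 0))
  s1 <- solve_effect_scalars(1, 4, 2)
  expect_equal(s1$a, 0)
  expect_equal(s1$epi^2 * 2, 1)
  s5 <- solve_effect_scalars(0.5, 1, 1)
  expect_equal(s5$a, 1 / sqrt(2))
  expect_equal(s5$epi, 1 / sqrt(2))
  expect_equal(s5$a^2 * 1, 0.5)
  expect_error(solve_effect_scalars(1.2, 1, 1), "\\[0, 1\\]")
  expect_error(solve_effect_scalars(0.5, 1, 0), "epistatic variance")
  expect_error(solve_effect_scalars(0.5, 0, 1), "additive variance")
})

test_that("genetic variance identity holds to machine precision", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(40, 4), 300,
                                         seed = 31), 12)
  for (t in c(0, 0.3, 0.8, 1)) {
    arch <- trait_architecture(pop, t, h = 0.5)
    expect_equal(var(arch$genetic_values), arch$VG, tolerance = 1e-12)
  }
})

test_that("phenotype noise is scaled by heritability", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(40, 4), 2000,
                                         seed = 32), 20)
  arch1 <- trait_architecture(pop, 0.2, h = 1)
  ph1 <- simulate_phenotypes(pop, arch1, seed = 33)
  expect_identical(ph1$values, ph1$genetic_values)  # Ve = 0 at h = 1

  arch5 <- trait_architecture(pop, 0.2, h = 0.5)
  ph5 <- simulate_phenotypes(pop, arch5, seed = 33)
  realized <- var(ph5$genetic_values) / var(ph5$values)
  expect_lt(abs(realized - 0.5), 0.05)

  # Ve strictly decreasing in h on fixed genotypes
  ve <- vapply(c(0.2, 0.4, 0.6, 0.8, 1),
               function(h) trait_architecture(pop, 0.2, h)$Ve, numeric(1))
  expect_true(all(diff(ve) < 0))
})

test_that("a purely additive trait is linear in the QTL codes", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(30, 3), 200,
                                         seed = 35), 9)
  arch <- trait_architecture(pop, 0, h = 1)
  inc <- build_incidence_matrices(pop)
  expect_equal(arch$genetic_values,
               arch$mu + arch$a * rowSums(inc$Xa), tolerance = 1e-12)
  expect_equal(arch$epi, 0)
})

test_that("architecture errors are raised for impossible requests", {
  pop <- place_qtl(simulate_dh_genotypes(genome_spec(10, 1), 50,
                                         seed = 36), 1)
  expect_error(trait_architecture(pop, 0.5, h = 0.5), "fewer than 2 QTL")
  pop2 <- place_qtl(simulate_dh_genotypes(genome_spec(10, 1), 50,
                                          seed = 36), 4)
  expect_error(trait_architecture(pop2, 0.5, h = 0), "heritability")
  expect_error(trait_architecture(pop2, 0.5, h = 1.2), "heritability")
})
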