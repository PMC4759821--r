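# Shared fixture: one moderately sized backcross dataset with a strong
# eQTL, plus fits at the true position, reused across the test blocks.
scan_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- sim_design(n = 80, m = 90, L = 3, rho_cM = 24, seed = 55,
                      effect = 1.2)
      sim <- simulate_dataset(d)
      pr <- genotype_prior(sim$map, sim$geno, "1", 24)
      full <- fit_em(sim$x, pr, L = 3, n_starts = 3, seed = 1)
      null <- fit_em(sim$x, matrix(1, d$n, 1), K = 1, L = 3, n_starts = 3,
                     seed = 1)
      cache <<- list(d = d, sim = sim, pr = pr, full = full, null = null)
    }
    cache
  }
})

test_that("scan locates a strong simulated eQTL and is deterministic", {
  fx <- scan_fixture()
  sc1 <- scan_genome(fx$sim$x, fx$sim$map, fx$sim$geno, L = 3, step = 2,
                     n_starts = 2, seed = 9)
  sc2 <- scan_genome(fx$sim$x, fx$sim$map, fx$sim$geno, L = 3, step = 2,
                     n_starts = 2, seed = 9)
  expect_identical(sc1$table, sc2$table)
  expect_true(all(sc1$table$clr >= -1e-6))
  expect_lte(abs(sc1$peak$pos_cM - 24), 6)
  expect_gt(sc1$peak$clr, 30)
})

test_that("single-marker map degenerates to a one-position scan", {
  fx <- scan_fixture()
  map1 <- genetic_map("m3", "1", 20)
  geno1 <- fx$sim$geno[, "m3", drop = FALSE]
  sc <- scan_genome(fx$sim$x, map1, geno1, L = 3, n_starts = 2, seed = 2)
  expect_equal(nrow(sc$table), 1L)
  expect_equal(sc$peak$pos_cM, 20)
  expect_gt(sc$peak$clr, 0)
})

test_that("any-cluster test equals the scan statistic and vanishes under no effect", {
  fx <- scan_fixture()
  tt <- test_any_cluster(fx$full, fx$null)
  expect_equal(tt$clr, 2 * (fx$full$logcl - fx$null$logcl))
  expect_length(tt$effects, 3)

  # data with no genotype effect: CLR near zero relative to data scale
  mu0 <- rbind(c(-2, 2), c(-2, 2))
  dat0 <- make_block_data(60, 50, mu0, sigma = 1, seed = 8)
  pr0 <- matrix(0.5, 60, 2)
  f0 <- fit_em(dat0$x, pr0, L = 2, n_starts = 2, seed = 3)
  n0 <- fit_em(dat0$x, matrix(1, 60, 1), K = 1, L = 2, n_starts = 2, seed = 3)
  t0 <- test_any_cluster(f0, n0)
  expect_lt(t0$clr, 15)
  expect_gt(tt$clr, 10 * max(t0$clr, 1))
})

test_that("constrained refits are nested within the full fit", {
  fx <- scan_fixture()
  for (l in 1:3) {
    tl <- test_per_cluster(fx$sim$x, fx$pr, fx$full, cluster = l)
    expect_gte(tl$clr, -1e-6)
  }
  ti <- test_interaction(fx$sim$x, fx$pr, fx$full)
  expect_gte(ti$clr, -1e-6)
  ts <- test_cluster_structure(fx$sim$x, fx$pr, fx$full)
  expect_gte(ts$clr, -1e-6)
  expect_error(test_per_cluster(fx$sim$x, fx$pr, fx$full, cluster = 9),
               "out of range")
})

test_that("per-cluster test separates affected from unaffected clusters", {
  # cluster 2 carries no genotype effect; clusters 1 and 3 a 3 sigma effect
  mu <- rbind(c(-4.5, 0, 4.5), c(-1.5, 0, 7.5))
  dat <- make_block_data(80, 90, mu, sigma = 1, seed = 23)
  pr <- cbind(as.numeric(dat$z == 1), as.numeric(dat$z == 2)) * 0.9 + 0.05
  full <- fit_em(dat$x, pr, L = 3, n_starts = 3, seed = 1)
  tab <- test_per_cluster(dat$x, pr, full, n_perm = 30, seed = 2)
  expect_equal(dim(tab), c(3L, 5L))
  expect_lt(tab$clr[2], 10)
  expect_gt(tab$clr[1], 50)
  expect_gt(tab$clr[3], 50)
  expect_lte(tab$p_value[1], 0.05)
  expect_gt(tab$p_value[2], 0.05)  # zero-effect cluster: no rejection
  expect_true(all(tab$p_adj >= tab$p_value - 1e-12))
})

test_that("interaction test classifies magnitude- and direction-varying pairs", {
  fx <- scan_fixture()
  ti <- test_interaction(fx$sim$x, fx$pr, fx$full)
  # generating effects alternate sign with distinct magnitudes
  true_d <- fx$d$mu[1, ] - fx$d$mu[2, ]
  cls <- ti$classification
  for (a in 1:2) for (b in (a + 1):3) {
    want <- if (true_d[a] * true_d[b] < 0) "direction" else "magnitude"
    expect_equal(cls[a, b], want)
  }
  expect_gt(ti$clr, 20)

  # pure +delta/-delta two-cluster design -> direction-varying
  mu2 <- rbind(c(-2.5, 2.5), c(-3.5, 3.5))
  dat2 <- make_block_data(60, 60, mu2, sigma = 1, seed = 12)
  pr2 <- cbind(as.numeric(dat2$z == 1), as.numeric(dat2$z == 2)) * 0.9 + 0.05
  full2 <- fit_em(dat2$x, pr2, L = 2, n_starts = 2, seed = 1)
  ti2 <- test_interaction(dat2$x, pr2, full2)
  expect_equal(ti2$classification[1, 2], "direction")
})

test_that("structure test accepts parallel profiles and rejects swapped ones", {
  # genotype 2 profile = genotype 1 profile + constant: additive, CLR ~ 0
  mu_add <- rbind(c(-3, 0, 3), c(-2, 1, 4))
  dat <- make_block_data(70, 60, mu_add, sigma = 1, seed = 33)
  pr <- cbind(as.numeric(dat$z == 1), as.numeric(dat$z == 2)) * 0.9 + 0.05
  full <- fit_em(dat$x, pr, L = 3, n_starts = 2, seed = 1)
  ts <- test_cluster_structure(dat$x, pr, full)
  expect_lt(ts$clr, 15)
  expect_true(all(abs(ts$profile_contrast) < 0.4))

  # swapped cluster ordering between genotypes -> strong rejection
  mu_swap <- rbind(c(-3, 0, 3), c(3, 0, -3))
  dat2 <- make_block_data(70, 60, mu_swap, sigma = 1, seed = 34)
  pr2 <- cbind(as.numeric(dat2$z == 1), as.numeric(dat2$z == 2)) * 0.9 + 0.05
  full2 <- fit_em(dat2$x, pr2, L = 3, n_starts = 2, seed = 1)
  ts2 <- test_cluster_structure(dat2$x, pr2, full2)
  expect_gt(ts2$clr, 100)
})

test_that("permutation threshold is deterministic with quantile edge cases", {
  nd <- null_scan_data(n = 40, m = 24, seed = 3)
  th1 <- permutation_threshold(nd$x, nd$map, nd$geno, L = 2, n_perm = 25,
                               alpha = 0.05, seed = 7, step = 5,
                               n_starts = 2)
  th2 <- permutation_threshold(nd$x, nd$map, nd$geno, L = 2, n_perm = 25,
                               alpha = 0.05, seed = 7, step = 5,
                               n_starts = 2)
  expect_identical(th1$max_clr, th2$max_clr)
  expect_identical(th1$threshold, th2$threshold)
  expect_gt(th1$threshold, 0)
  # alpha = 1 returns the minimum permuted maximum
  tha <- permutation_threshold(nd$x, nd$map, nd$geno, L = 2, n_perm = 25,
                               alpha = 1, seed = 7, step = 5, n_starts = 2)
  expect_equal(tha$threshold, min(tha$max_clr))
  expect_error(permutation_threshold(nd$x, nd$map, nd$geno, L = 2,
                                     n_perm = 10, seed = 1), ">= 20")
})

test_that("a strong eQTL clears the permutation threshold", {
  fx <- scan_fixture()
  sc <- scan_genome(fx$sim$x, fx$sim$map, fx$sim$geno, L = 3, step = 5,
                    n_starts = 2, seed = 9)
  th <- permutation_threshold(fx$sim$x, fx$sim$map, fx$sim$geno, L = 3,
                              n_perm = 20, alpha = 0.05, seed = 11, step = 5,
                              n_starts = 2, scan = sc)
  expect_gt(sc$peak$clr, th$threshold)
})
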