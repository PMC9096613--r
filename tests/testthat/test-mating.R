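# Mixed-mating likelihood, outcrossing-rate recovery, grid-search optimality,
# bootstrap behaviour and correlated paternity.

test_that("family log-likelihood handles degenerate selfing terms", {
  freqs <- c(0.3, 0.4)
  mom <- c(0L, 1L)
  # a heterozygous offspring of a dosage-0 mother is impossible when selfed
  # (both selfing gametes carry allele 0) but fine under outcrossing
  off <- matrix(c(1L, 1L), 1, 2,
                dimnames = list("p1", c("l1", "l2")))
  ll <- family_log_likelihood(off, mom, s = 0.4, freqs, error_rate = 0)
  out_only <- family_log_likelihood(off, mom, s = 0, freqs, error_rate = 0)
  expect_equal(ll, log(0.6) + out_only)
  # s = 0 equals the outcross-only model exactly (full trio error mixture,
  # matching trio_genotype_prob's treatment of the mother call)
  off2 <- matrix(c(0L, 1L), 1, 2, dimnames = list("p1", c("l1", "l2")))
  l0 <- family_log_likelihood(off2, mom, s = 0, freqs, error_rate = 0.02,
                              known_mother = FALSE)
  direct <- sum(log(trio_genotype_prob(c(0L, 1L), mom, NULL, freqs, 0.02)))
  expect_equal(l0, direct, tolerance = 1e-9)
})

test_that("family log-likelihood equals exhaustive mixture enumeration", {
  # small family, two loci, known-mother error model enumerated by hand
  e <- 0.05
  freqs <- c(0.25, 0.6)
  mom <- c(1L, 1L)
  off <- rbind(p1 = c(0L, 2L), p2 = c(1L, 1L))
  colnames(off) <- c("l1", "l2")
  s <- 0.3
  orc_self <- function(o, m) {
    sum(sapply(0:2, function(to) .orc_mendel(to, m, m) * .orc_err(o, to, e)))
  }
  orc_out <- function(o, m, p) {
    acc <- 0
    pm <- c(1 - m / 2, m / 2)
    for (to in 0:2) {
      pr <- 0
      for (ma in 0:1) for (pa in 0:1) {
        if (ma + pa == to) pr <- pr + pm[ma + 1] * (if (pa == 1) p else 1 - p)
      }
      acc <- acc + pr * .orc_err(o, to, e)
    }
    acc
  }
  expected <- 0
  for (i in 1:2) {
    pself <- prod(sapply(1:2, function(l) orc_self(off[i, l], mom[l])))
    pout <- prod(sapply(1:2, function(l) orc_out(off[i, l], mom[l], freqs[l])))
    expected <- expected + log(s * pself + (1 - s) * pout)
  }
  got <- family_log_likelihood(off, mom, s, freqs, error_rate = e,
                               known_mother = TRUE)
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("outcrossing rates are recovered from simulated nurseries", {
  sim0 <- tiny_nursery(seed = 41, n_candidates = 120, n_families = 20,
                       family_size = 6, n_mothers = 8, progeny = 25,
                       n_loci = 400, selfing_rate = 0)
  ms0 <- estimate_outcrossing(sim0$progeny, sim0$families,
                              sim0$founders$genotypes, n_bootstrap = 0)
  expect_gte(ms0$t_m, 0.9)
  expect_lte(ms0$t_m, 1.1)
  sim3 <- tiny_nursery(seed = 42, n_candidates = 120, n_families = 20,
                       family_size = 6, n_mothers = 8, progeny = 25,
                       n_loci = 400, selfing_rate = 0.3)
  ms3 <- estimate_outcrossing(sim3$progeny, sim3$families,
                              sim3$founders$genotypes, n_bootstrap = 0)
  expect_lt(abs(ms3$t_m - 0.7), 0.08)
})

test_that("returned selfing rate beats a grid search on [0, 1]", {
  sim <- tiny_nursery(seed = 43, n_mothers = 4, progeny = 15, n_loci = 150,
                      selfing_rate = 0.2)
  ms <- estimate_outcrossing(sim$progeny, sim$families,
                             sim$founders$genotypes, n_bootstrap = 0)
  freqs <- pollen_pool_frequencies(sim$founders$genotypes)
  ll_at <- function(s) {
    sum(sapply(split(sim$families$progeny_id, sim$families$mother_id),
               function(pids) {
                 mom <- sim$families$mother_id[match(pids[1],
                                                     sim$families$progeny_id)]
                 family_log_likelihood(
                   sim$progeny[pids, , drop = FALSE],
                   sim$founders$genotypes[mom, ], s,
                   freqs, error_rate = 0.01
                 )
               }))
  }
  grid <- seq(0, 1, length.out = 1000)
  grid_best <- max(sapply(grid, ll_at))
  expect_gte(ll_at(ms$s) + 1e-6, grid_best)
  # the profile is smooth and unimodal on the grid
  vals <- sapply(seq(0.01, 0.99, length.out = 50), ll_at)
  expect_equal(sum(diff(sign(diff(vals))) != 0), 1)
})

test_that("family bootstrap is deterministic with positive spread", {
  sim <- tiny_nursery(seed = 44, n_mothers = 6, progeny = 15, n_loci = 200,
                      selfing_rate = 0.15)
  a <- estimate_outcrossing(sim$progeny, sim$families,
                            sim$founders$genotypes, n_bootstrap = 30, seed = 5)
  b <- estimate_outcrossing(sim$progeny, sim$families,
                            sim$founders$genotypes, n_bootstrap = 30, seed = 5)
  expect_identical(a$bootstrap, b$bootstrap)
  expect_gt(a$t_m_sd, 0)
  expect_gt(a$t_s_sd, 0)
})

test_that("multilocus beats single-locus recovery on average", {
  # biparental-inbreeding-free matings (uniform kernel) in the near-complete
  # outcrossing regime the estimator targets
  err_tm <- err_ts <- numeric(50)
  for (r in seq_len(50)) {
    sim <- tiny_nursery(seed = 800 + r, n_candidates = 96, n_families = 16,
                        family_size = 6, n_mothers = 6, progeny = 25,
                        n_loci = 100, selfing_rate = 0.05,
                        kernel = list(family = "uniform", scale_m = 1,
                                      shape = 1))
    ms <- estimate_outcrossing(sim$progeny, sim$families,
                               sim$founders$genotypes, n_bootstrap = 0)
    err_tm[r] <- abs(ms$t_m - 0.95)
    err_ts[r] <- abs(ms$t_s - 0.95)
  }
  expect_lte(mean(err_tm), mean(err_ts))
})

test_that("correlated paternity: degenerate, uniform-father and cross-method cases", {
  # all sibs share one father: place a single candidate next to each mother
  # and everyone else far outside the kernel range
  cfg1 <- sim_config(n_candidates = 60, n_families = 10, family_size = 6,
                     n_mothers_sampled = 2, progeny_per_mother = c(12, 12),
                     n_loci = 200, maf_range = c(0.1, 0.4),
                     kernel = list(family = "exponential", scale_m = 1,
                                   shape = 1),
                     selfing_rate = 0, genotyping_error = 0.01,
                     missing_rate = 0.02, seed = 45)
  f1 <- simulate_founders(cfg1)
  f1$map$x_m <- 100 * seq_len(nrow(f1$map)) # everyone isolated
  f1$map$y_m <- 0
  moms <- f1$map$genet_id[c(10, 30)]
  f1$map$x_m[11] <- f1$map$x_m[10] + 0.5 # one nearby donor per mother
  f1$map$x_m[31] <- f1$map$x_m[30] + 0.5
  m1 <- simulate_matings(f1, cfg1, mothers = moms)
  shared <- tapply(m1$truth$true_father, m1$families$mother_id,
                   function(f) max(table(f)) / length(f))
  expect_true(all(shared == 1))
  rp1 <- correlated_paternity(m1$genotypes, m1$families, f1$genotypes,
                              n_bootstrap = 0)
  expect_gt(rp1$rp_ml, 0.8)

  # uniform fathers over K candidates: direct estimate near 1/K
  set.seed(8)
  K <- 25
  fathers <- sample(sprintf("F%02d", 1:K), 4000, replace = TRUE)
  pt <- data.frame(progeny_id = sprintf("p%04d", 1:4000),
                   mother_id = rep(sprintf("M%d", 1:4), each = 1000),
                   father_id = fathers, confidence = "strict95",
                   stringsAsFactors = FALSE)
  direct <- tapply(pt$father_id, pt$mother_id, function(f) {
    x <- table(f)
    n <- sum(x)
    sum(x * (x - 1)) / (n * (n - 1))
  })
  expect_lt(abs(mean(direct) - 1 / K) / (1 / K), 0.25)

  # ML and direct estimates agree on a simulated nursery
  sim2 <- tiny_nursery(seed = 46, n_mothers = 5, progeny = 30, n_loci = 300,
                       kernel = list(family = "exponential", scale_m = 1.2,
                                     shape = 1))
  ptab <- assign_paternity(sim2$progeny, sim2$families,
                           sim2$founders$genotypes,
                           lod_model(error_rate = 0.05, min_loci = 100),
                           thresholds = NULL)
  rp2 <- correlated_paternity(sim2$progeny, sim2$families,
                              sim2$founders$genotypes, paternity = ptab,
                              n_bootstrap = 40, seed = 3)
  expect_lt(abs(rp2$rp_ml - rp2$rp_direct), max(3 * rp2$rp_sd, 0.05))
  expect_identical(
    rp2$bootstrap,
    correlated_paternity(sim2$progeny, sim2$families,
                         sim2$founders$genotypes, paternity = ptab,
                         n_bootstrap = 40, seed = 3)$bootstrap
  )
})
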