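# Diversity statistics against closed forms, enumerations and null
# calibrations.

test_that("heterozygosity matches a brute-force per-locus computation", {
  gm <- matrix(1L, 5, 3, dimnames = list(letters[1:5], c("A", "B", "C")))
  expect_equal(heterozygosity(gm)$H_o, 1)

  set.seed(7)
  gm2 <- matrix(rbinom(20 * 40, 2, 0.35), 20, 40,
                dimnames = list(sprintf("i%02d", 1:20), sprintf("l%02d", 1:40)))
  gm2[sample(length(gm2), 60)] <- NA
  het <- heterozygosity(gm2)
  ho <- he <- numeric(40)
  for (l in 1:40) {
    x <- gm2[, l]
    x <- x[!is.na(x)]
    n <- length(x)
    ho[l] <- mean(x == 1)
    p <- sum(x) / (2 * n)
    he[l] <- 2 * p * (1 - p) * n / (n - 1)
  }
  expect_equal(het$H_o, mean(ho))
  expect_equal(het$H_e, mean(he))
})

test_that("PIC follows the biallelic closed form", {
  expect_equal(pic(0.5), 0.375)
  expect_equal(pic(0), 0)
  p <- 0.1
  expect_equal(pic(p), 1 - (p^2 + (1 - p)^2) - 2 * p^2 * (1 - p)^2)
})

test_that("PIC and expected heterozygosity bounds hold over a frequency grid", {
  p <- seq(0.01, 0.99, by = 0.01)
  he <- 2 * p * (1 - p)
  expect_true(all(pic(p) < he))
  expect_true(all(he < 2 * pic(p)))
})

test_that("HWE chi-square flags the right loci and calibrates at alpha", {
  # exact HW proportions: never deviating
  gm <- matrix(c(rep(0L, 25), rep(1L, 50), rep(2L, 25)), ncol = 1,
               dimnames = list(sprintf("i%03d", 1:100), "hw"))
  expect_equal(hwe_test(gm)$deviating, 0)
  # all heterozygotes at p = 0.5: chi-square = n, far past alpha
  gm2 <- matrix(1L, 100, 1, dimnames = list(sprintf("i%03d", 1:100), "het"))
  res2 <- hwe_test(gm2)
  expect_equal(res2$per_locus$chisq, 100)
  expect_equal(res2$deviating, 1)
  # null calibration: HW data deviates at ~alpha
  set.seed(42)
  L <- 2500
  p <- runif(L, 0.2, 0.5)
  gm3 <- matrix(rbinom(200 * L, 2, rep(p, each = 200)), 200, L,
                dimnames = list(sprintf("i%03d", 1:200), sprintf("l%04d", 1:L)))
  frac <- hwe_test(gm3, alpha = 0.05)$fraction
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("second-parent non-exclusion matches full trio enumeration", {
  # monomorphic locus excludes no one
  expect_equal(non_exclusion_second_parent(1e-12)$NE_combined, 1,
               tolerance = 1e-6)
  # independence: combined value is the product of per-locus values
  ne <- non_exclusion_second_parent(c(0.3, 0.4))
  expect_equal(ne$NE_combined,
               prod(non_exclusion_second_parent(0.3)$NE_combined,
                    non_exclusion_second_parent(0.4)$NE_combined))
  # exhaustive enumeration oracle at p = 0.5: average over mother x true
  # father x offspring of the probability that a random male is excluded
  p <- 0.5
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  excl <- 0
  for (m in 0:2) for (d in 0:2) for (o in 0:2) {
    pr <- hw[m + 1] * hw[d + 1] * .orc_mendel(o, m, d)
    if (pr == 0) next
    # a male is excluded iff he cannot supply any allele completing o given m
    excl_male <- 0
    for (male in 0:2) {
      can <- FALSE
      for (ma in 0:1) for (pa in 0:1) {
        pm <- c(1 - m / 2, m / 2)[ma + 1]
        pd <- c(1 - male / 2, male / 2)[pa + 1]
        if (pm > 0 && pd > 0 && ma + pa == o) can <- TRUE
      }
      if (!can) excl_male <- excl_male + hw[male + 1]
    }
    excl <- excl + pr * excl_male
  }
  got <- non_exclusion_second_parent(p)
  expect_equal(got$per_locus_exclusion, excl)
  expect_equal(got$per_locus_exclusion, p * (1 - p) * (1 - p * (1 - p)))
})

test_that("Weir-Cockerham theta: fixed difference, null, and scalar re-derivation", {
  g1 <- matrix(2L, 20, 5)
  g2 <- matrix(0L, 20, 5)
  gm <- rbind(g1, g2)
  dimnames(gm) <- list(sprintf("i%02d", 1:40), sprintf("l%d", 1:5))
  res <- weir_cockerham_fst(gm, rep(c("A", "B"), each = 20))
  expect_equal(unname(res$per_locus$theta), rep(1, 5))
  expect_equal(res$theta_mean, 1)

  set.seed(10)
  L <- 1000
  p <- runif(L, 0.1, 0.5)
  null_gm <- matrix(rbinom(400 * L, 2, rep(p, each = 400)), 400, L,
                    dimnames = list(sprintf("i%03d", 1:400),
                                    sprintf("l%04d", 1:L)))
  null_res <- weir_cockerham_fst(null_gm, rep(c("A", "B"), each = 200))
  expect_lt(abs(null_res$theta_mean), 0.01)

  # scalar re-derivation of the variance components on a small instance
  set.seed(11)
  small <- matrix(rbinom(24 * 4, 2, 0.4), 24, 4,
                  dimnames = list(sprintf("i%02d", 1:24), sprintf("l%d", 1:4)))
  grp <- rep(c("A", "B", "C"), each = 8)
  got <- weir_cockerham_fst(small, grp)
  for (l in 1:4) {
    x <- split(small[, l], grp)
    ni <- sapply(x, length)
    pi <- sapply(x, function(v) sum(v) / (2 * length(v)))
    hi <- sapply(x, function(v) mean(v == 1))
    r <- 3
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    pbar <- sum(ni * pi) / (r * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (pbar > 0 && pbar < 1) {
      expect_equal(got$per_locus$theta[l], a / (a + b + cc))
    }
  }
})

test_that("Nei distance is zero for identical groups, symmetric, and matches arithmetic", {
  set.seed(3)
  gm <- matrix(rbinom(20 * 10, 2, 0.4), 20, 10,
               dimnames = list(sprintf("i%02d", 1:20), sprintf("l%02d", 1:10)))
  expect_equal(nei_distance(gm, 1:10, 1:10), 0)
  expect_equal(nei_distance(gm, 1:10, 11:20), nei_distance(gm, 11:20, 1:10))
  # two-locus toy: direct evaluation of the identity terms
  gA <- rbind(c(0L, 2L), c(2L, 2L), c(0L, 2L), c(0L, 2L), c(0L, 0L))
  gB <- rbind(c(2L, 2L), c(2L, 0L), c(0L, 2L), c(0L, 0L), c(0L, 1L))
  gm2 <- rbind(gA, gB)
  rownames(gm2) <- sprintf("i%02d", 1:10)
  colnames(gm2) <- c("x", "y")
  fa <- allele_frequencies(gm2, 1:5)
  fb <- allele_frequencies(gm2, 6:10)
  expjab <- mean(fa * fb + (1 - fa) * (1 - fb))
  expja <- mean(fa^2 + (1 - fa)^2)
  expjb <- mean(fb^2 + (1 - fb)^2)
  expect_equal(nei_distance(gm2, 1:5, 6:10), -log(expjab / sqrt(expja * expjb)))
})

test_that("Shannon index matches direct evaluation and vegan", {
  expect_equal(shannon_index(5), 0)
  expect_equal(shannon_index(rep(3, 7)), log(7))
  counts <- c(5, 3, 2)
  p <- counts / sum(counts)
  expect_equal(shannon_index(counts), -sum(p * log(p)))
  expect_equal(shannon_index(counts),
               unname(vegan::diversity(counts, index = "shannon")))
  expect_error(shannon_index(c(0, 0)), "positive")
})

test_that("rarefaction equals exhaustive subsample enumeration", {
  expect_equal(rarefaction_richness(c(4, 3, 1), 1), 1)
  expect_equal(rarefaction_richness(c(4, 3, 1), 8), 3)
  # enumeration over all C(8, 4) subsamples of the labelled community
  items <- rep(1:3, c(4, 3, 1))
  combos <- combn(8, 4)
  expected <- mean(apply(combos, 2, function(ix) length(unique(items[ix]))))
  expect_equal(rarefaction_richness(c(4, 3, 1), 4), expected)
  expect_equal(rarefaction_richness(c(4, 3, 1), 4),
               as.numeric(vegan::rarefy(c(4, 3, 1), 4)))
  expect_error(rarefaction_richness(c(4, 3, 1), 9), "depth")
})

test_that("VanRaden relationships and IBS dissimilarity behave as expected", {
  set.seed(6)
  gm <- matrix(rbinom(8 * 50, 2, 0.4), 8, 50,
               dimnames = list(sprintf("i%d", 1:8), sprintf("l%02d", 1:50)))
  gm <- rbind(gm, dup = gm[1, ]) # duplicated individual
  rownames(gm)[9] <- "i1dup"
  K <- grm_vanraden(gm)
  expect_equal(K, t(K))
  expect_equal(K["i1", "i1dup"], K["i1", "i1"])

  toy <- rbind(a = c(0L, 1L, 2L), b = c(2L, 1L, 0L), c = c(0L, 1L, 2L),
               d = c(1L, 1L, 1L))
  colnames(toy) <- c("x", "y", "z")
  # hand count: |d_i - d_j| / 2 averaged over loci, then over the 6 pairs
  pairs <- combn(4, 2)
  hand <- mean(apply(pairs, 2, function(ix) {
    mean(abs(toy[ix[1], ] - toy[ix[2], ]) / 2)
  }))
  expect_equal(ibs_dissimilarity(toy), hand)
  expect_error(grm_vanraden(matrix(0L, 4, 3,
                                   dimnames = list(letters[1:4], c("a", "b", "c")))),
               "monomorphic")
})

test_that("PCA scores are orthogonal and match an independent decomposition", {
  set.seed(8)
  base <- rbinom(30, 2, 0.5)
  rank1 <- outer(c(1, 1, 1, 0, 0, 0), base) # two clusters, rank-1 signal
  rownames(rank1) <- sprintf("i%d", 1:6)
  colnames(rank1) <- sprintf("l%02d", 1:30)
  res <- pca_scores(rank1, k = 2)
  expect_gt(res$var_explained[1], 0.999)

  gm <- matrix(rbinom(15 * 40, 2, 0.3), 15, 40,
               dimnames = list(sprintf("i%02d", 1:15), sprintf("l%02d", 1:40)))
  res2 <- pca_scores(gm, k = 3)
  cp <- crossprod(res2$scores)
  expect_equal(cp[upper.tri(cp)], rep(0, 3), tolerance = 1e-8)
  ev <- eigen(cov(scale(gm, scale = FALSE)), symmetric = TRUE)$values
  expect_equal(res2$eigenvalues[1:3], ev[1:3])
})

test_that("group statistics are invariant to individual ordering", {
  sim <- tiny_nursery(seed = 14, progeny = 10)
  gm <- sim$founders$genotypes
  perm <- sample(nrow(gm))
  expect_equal(heterozygosity(gm)$H_e, heterozygosity(gm[perm, ])$H_e)
  expect_equal(ibs_dissimilarity(gm), ibs_dissimilarity(gm[perm, ]))
  expect_equal(diversity_summary(gm)$PIC, diversity_summary(gm[perm, ])$PIC)
})
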