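# Population-genetic summary statistics: heterozygosity, PIC, HWE tests,
# second-parent non-exclusion, Weir-Cockerham fixation index, Nei's distance,
# Shannon diversity, rarefaction richness, VanRaden relationships, PCA.

.subset_rows <- function(gm, group) {
  if (is.null(group)) gm else gm[group, , drop = FALSE]
}

#' Observed and expected heterozygosity
#'
#' Per-locus observed heterozygosity is the fraction of heterozygous calls
#' among non-missing genotypes; expected heterozygosity is `2p(1-p)` with the
#' small-sample correction `n/(n-1)` (n = genotyped individuals at the locus).
#' Reported summary values are means over loci.
#'
#' @param gm dosage matrix.
#' @param group optional subset of individuals (ids or indices).
#' @return list with `H_o`, `H_e` (means over loci) and `per_locus` data frame.
#' @export
heterozygosity <- function(gm, group = NULL) {
  g <- .subset_rows(gm, group)
  if (nrow(g) == 0) stop("empty group")
  n <- colSums(!is.na(g))
  ho <- colSums(g == 1, na.rm = TRUE) / n
  p <- colMeans(g, na.rm = TRUE) / 2
  corr <- ifelse(n > 1, n / (n - 1), NA_real_)
  he <- 2 * p * (1 - p) * corr
  list(H_o = mean(ho, na.rm = TRUE), H_e = mean(he, na.rm = TRUE),
       per_locus = data.frame(locus = colnames(g), n = n, H_o = ho, H_e = he,
                              row.names = NULL))
}

#' Mean number of alleles observed per locus
#'
#' For biallelic data this is 2 at polymorphic loci and 1 at loci monomorphic
#' in the group.
#' @inheritParams heterozygosity
#' @return mean alleles per locus.
#' @export
alleles_per_locus <- function(gm, group = NULL) {
  g <- .subset_rows(gm, group)
  p <- colMeans(g, na.rm = TRUE) / 2
  mean(ifelse(is.na(p), NA_real_, 1 + (p > 0 & p < 1)), na.rm = TRUE)
}

#' Polymorphism information content of a biallelic locus
#'
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`.
#'
#' @param freqs allele frequencies.
#' @return vector of per-locus PIC values.
#' @export
pic <- function(freqs) {
  stopifnot(all(freqs >= 0 & freqs <= 1, na.rm = TRUE))
  q <- 1 - freqs
  1 - (freqs^2 + q^2) - 2 * freqs^2 * q^2
}

#' Per-locus chi-square test for Hardy-Weinberg equilibrium
#'
#' One-degree-of-freedom goodness of fit of the three genotype counts against
#' Hardy-Weinberg expectations at the estimated allele frequency. Loci with
#' fewer than `min_n` genotyped individuals are skipped (NA).
#'
#' @inheritParams heterozygosity
#' @param alpha significance level for the "deviating" flag.
#' @param min_n minimum genotyped individuals per locus.
#' @return list with `deviating` count, `fraction`, and `per_locus` data frame
#'   (chisq, p_value, deviating flag).
#' @export
hwe_test <- function(gm, group = NULL, alpha = 0.05, min_n = 5) {
  g <- .subset_rows(gm, group)
  n0 <- colSums(g == 0, na.rm = TRUE)
  n1 <- colSums(g == 1, na.rm = TRUE)
  n2 <- colSums(g == 2, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e0 <- n * (1 - p)^2
  e1 <- n * 2 * p * (1 - p)
  e2 <- n * p^2
  chisq <- (n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 + (n2 - e2)^2 / e2
  chisq[p == 0 | p == 1] <- 0 # monomorphic: fits trivially
  pval <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  skip <- n < min_n
  chisq[skip] <- NA
  pval[skip] <- NA
  dev <- !is.na(pval) & pval < alpha
  list(deviating = sum(dev), fraction = mean(dev[!skip]),
       per_locus = data.frame(locus = colnames(g), n = n, chisq = chisq,
                              p_value = pval, deviating = dev,
                              row.names = NULL))
}

#' Second-parent non-exclusion probability
#'
#' With the mother known, a random non-father is excluded at a biallelic locus
#' with probability `p q (1 - p q)` (derived by enumerating all mother x true
#' father x offspring genotype combinations at Hardy-Weinberg proportions).
#' The combined non-exclusion probability over a locus panel is the product of
#' the per-locus non-exclusion probabilities.
#'
#' @param freqs per-locus allele frequencies of the analyzed panel.
#' @return list with `NE_combined` and `per_locus` exclusion probabilities.
#' @export
non_exclusion_second_parent <- function(freqs) {
  stopifnot(all(freqs >= 0 & freqs <= 1))
  pq <- freqs * (1 - freqs)
  excl <- pq * (1 - pq)
  list(NE_combined = prod(1 - excl), per_locus_exclusion = excl)
}

#' Weir-Cockerham fixation index
#'
#' Variance-components estimator of theta for diploid biallelic loci with
#' missing data; the mean over loci is the ratio of summed components. Loci at
#' which any group has fewer than two genotyped individuals, or which are
#' monomorphic across groups, are excluded.
#'
#' @param gm dosage matrix.
#' @param groups factor (or coercible) of group membership, one per row.
#' @return list with `theta_mean` (ratio of sums), `per_locus` theta, and the
#'   per-locus variance components `a`, `b`, `c`.
#' @export
weir_cockerham_fst <- function(gm, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("at least two groups are required")
  typed <- !is.na(gm)
  storage.mode(typed) <- "double"
  cnt <- rowsum(typed, groups) # groups x loci genotyped counts
  gs <- gm
  gs[is.na(gs)] <- 0
  sums <- rowsum(gs * 1.0, groups)
  het <- rowsum((gm == 1) * 1.0, groups, na.rm = TRUE)
  pbar_ok <- cnt >= 2
  valid <- colSums(pbar_ok) == nlevels(groups)
  p <- sums / (2 * cnt)
  h <- het / cnt
  r <- nlevels(groups)
  nbar <- colMeans(cnt)
  nc <- (r * nbar - colSums(cnt^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(cnt * p) / (r * nbar)
  s2 <- colSums(cnt * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(cnt * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  use <- valid & !mono
  theta <- ifelse(use, a / (a + b + cc), NA_real_)
  theta_mean <- sum(a[use]) / sum((a + b + cc)[use])
  list(theta_mean = theta_mean,
       per_locus = data.frame(locus = colnames(gm), theta = theta,
                              a = ifelse(use, a, NA), b = ifelse(use, b, NA),
                              c = ifelse(use, cc, NA), row.names = NULL))
}

.nei_from_freqs <- function(pa, pb) {
  ok <- !is.na(pa) & !is.na(pb)
  pa <- pa[ok]
  pb <- pb[ok]
  jab <- mean(pa * pb + (1 - pa) * (1 - pb))
  ja <- mean(pa^2 + (1 - pa)^2)
  jb <- mean(pb^2 + (1 - pb)^2)
  i <- jab / sqrt(ja * jb)
  if (i <= 0) return(Inf)
  -log(i)
}

#' Nei's standard genetic distance between two groups
#'
#' `D = -ln( J_AB / sqrt(J_A J_B) )` with the identity terms summed over loci.
#'
#' @param gm dosage matrix.
#' @param groupA,groupB individual ids or indices.
#' @return scalar distance (`Inf`, flagged by a warning, when the normalized
#'   identity is zero).
#' @export
nei_distance <- function(gm, groupA, groupB) {
  pa <- allele_frequencies(gm, groupA)
  pb <- allele_frequencies(gm, groupB)
  d <- .nei_from_freqs(pa, pb)
  if (is.infinite(d)) warning("zero genetic identity: infinite Nei distance")
  d
}

#' Mean pairwise Nei distance among individuals of a group
#'
#' Treats each individual as a population with allele frequency dosage/2;
#' used for distance-bin diversity tables.
#'
#' @param gm dosage matrix.
#' @param group individual ids or indices (at least 2).
#' @return mean over unordered pairs.
#' @export
nei_pairwise_mean <- function(gm, group = NULL) {
  g <- .subset_rows(gm, group)
  n <- nrow(g)
  if (n < 2) return(NA_real_)
  x <- g / 2
  miss <- is.na(x)
  x0 <- x
  x0[miss] <- 0
  ok <- (!miss) * 1.0
  jab <- (x0 %*% t(x0) + (1 - x0 - miss) %*% t(1 - x0 - miss))
  nshare <- ok %*% t(ok)
  jab <- jab / nshare
  jii <- rowSums(x0^2 + (1 - x0 - miss)^2) / rowSums(ok)
  # per-pair self identities restricted to shared loci are approximated by the
  # full-locus identities; exact when missingness is absent
  denom <- sqrt(outer(jii, jii))
  d <- -log(pmax(jab / denom, .Machine$double.xmin))
  mean(d[upper.tri(d)])
}

#' Shannon diversity index
#'
#' `H = -sum p_i ln p_i` over categories with positive counts.
#'
#' @param counts non-negative category counts (e.g. progeny per father).
#' @return scalar H.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("at least one positive count is required")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Rarefaction: expected category richness at a reference depth
#'
#' Hypergeometric expectation
#' `E[S] = sum_i 1 - choose(N - N_i, depth) / choose(N, depth)`.
#'
#' @param counts non-negative category counts.
#' @param depth subsample size (at most `sum(counts)`).
#' @return expected number of distinct categories.
#' @export
rarefaction_richness <- function(counts, depth) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N) stop("depth exceeds the total count")
  if (depth < 1) stop("depth must be at least 1")
  term <- ifelse(N - counts < depth, 0,
                 exp(lchoose(N - counts, depth) - lchoose(N, depth)))
  sum(1 - term)
}

#' VanRaden genomic relationship matrix (method 1)
#'
#' `K = W W' / (2 sum p(1-p))` with `W` the dosage matrix centered at twice
#' the reference allele frequencies. Missing calls are treated as the locus
#' mean (zero after centering).
#'
#' @param gm dosage matrix.
#' @param group optional subset of individuals.
#' @param freqs reference allele frequencies (default: computed from the
#'   subset itself).
#' @return relationship matrix.
#' @export
grm_vanraden <- function(gm, group = NULL, freqs = NULL) {
  g <- .subset_rows(gm, group)
  if (is.null(freqs)) freqs <- allele_frequencies(g)
  ok <- !is.na(freqs) & freqs > 0 & freqs < 1
  if (!any(ok)) stop("all loci are monomorphic: zero denominator")
  w <- sweep(g[, ok, drop = FALSE], 2, 2 * freqs[ok])
  w[is.na(w)] <- 0
  denom <- 2 * sum(freqs[ok] * (1 - freqs[ok]))
  tcrossprod(w) / denom
}

#' Mean pairwise identity-by-state dissimilarity
#'
#' Per pair of individuals the IBS allele-sharing dissimilarity at a locus is
#' `|d_i - d_j| / 2`; the statistic is its mean over shared typed loci,
#' averaged over all unordered pairs in the group. This is the "genetic
#' distance" reported in distance-bin diversity tables.
#'
#' @param gm dosage matrix.
#' @param group optional subset (at least 2 individuals).
#' @return scalar mean dissimilarity.
#' @export
ibs_dissimilarity <- function(gm, group = NULL) {
  g <- .subset_rows(gm, group)
  n <- nrow(g)
  if (n < 2) return(NA_real_)
  ok <- (!is.na(g)) * 1.0
  x <- g
  x[is.na(x)] <- 0
  # sum over loci of |di - dj| via dosage-class indicators
  i0 <- (g == 0 & !is.na(g)) * 1.0
  i1 <- (g == 1 & !is.na(g)) * 1.0
  i2 <- (g == 2 & !is.na(g)) * 1.0
  absdiff <- i0 %*% t(i1) + i1 %*% t(i0) + i1 %*% t(i2) + i2 %*% t(i1) +
    2 * (i0 %*% t(i2) + i2 %*% t(i0))
  nshare <- ok %*% t(ok)
  d <- absdiff / (2 * nshare)
  mean(d[upper.tri(d)])
}

#' Principal component scores of centered dosages
#'
#' Missing calls are imputed at the locus mean before centering.
#'
#' @param gm dosage matrix.
#' @param k number of axes.
#' @return list with `scores` (individuals x k), `var_explained` fractions and
#'   the full eigenvalue spectrum.
#' @export
pca_scores <- function(gm, k = 2) {
  if (nrow(gm) < k) stop("need at least k individuals")
  x <- gm * 1.0
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(k), drop = FALSE],
       var_explained = ve[seq_len(k)], eigenvalues = pr$sdev^2)
}

#' Bundle of diversity summaries for one group
#'
#' @param gm dosage matrix.
#' @param group optional subset of individuals.
#' @param alpha HWE significance level.
#' @return data frame with A, H_o, H_e, PIC, N_E and HWE-deviating counts.
#' @export
diversity_summary <- function(gm, group = NULL, alpha = 0.05) {
  g <- .subset_rows(gm, group)
  het <- heterozygosity(g)
  p <- allele_frequencies(g)
  hwe <- hwe_test(g, alpha = alpha)
  data.frame(
    n = nrow(g),
    A = alleles_per_locus(g),
    H_o = het$H_o,
    H_e = het$H_e,
    PIC = mean(pic(p), na.rm = TRUE),
    N_E = non_exclusion_second_parent(p[!is.na(p)])$NE_combined,
    hwe_deviating = hwe$deviating,
    hwe_fraction = hwe$fraction
  )
}
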