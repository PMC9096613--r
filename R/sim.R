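# Forward simulator of a wind-pollinated spaced-plant breeding nursery.
# Produces candidate-parent genotypes with half-sib family structure, a grid
# field map, progeny from sampled mothers under a distance-decaying pollen
# kernel, and a ground-truth record enabling parameter-recovery tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# derived sub-stage seeds, kept below 2^31 - 1
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483647)
}

#' Simulation configuration for a spaced-plant nursery
#'
#' Defaults emulate a recurrent-selection nursery of 749 candidate parents:
#' 73 half-sib families of 9 planted adjacently on a 0.91 m grid plus
#' bi-parental F1 genets filling the remainder, 15 sampled mothers with 44-72
#' progeny each, 2,500 biallelic SNPs with founder minor-allele frequencies
#' uniform on 0.04-0.25, near-complete outcrossing, and an exponential
#' pollen-dispersal kernel with 3.5 m scale.
#'
#' @param n_candidates number of candidate parents planted and genotyped.
#' @param n_families number of half-sib families among the candidates.
#' @param family_size genets per half-sib family (planted adjacently).
#' @param grid_spacing_m planting distance in meters between neighbours.
#' @param n_mothers_sampled mothers sampled for progeny arrays (away from the
#'   nursery borders).
#' @param progeny_per_mother integer range `c(lo, hi)`; each mother's progeny
#'   count is drawn uniformly from it (a single value fixes the count).
#' @param n_loci number of biallelic loci.
#' @param maf_range founder allele-frequency law: uniform on this interval.
#' @param kernel list with `family` ("exponential", "exponential-power" or
#'   "uniform"), `scale_m` (> 0, meters) and `shape` (dimensionless, used by
#'   the exponential-power family).
#' @param selfing_rate probability that a progeny is selfed.
#' @param genotyping_error per-call probability of a symmetric dosage flip in
#'   the progeny genotypes.
#' @param missing_rate per-call probability that a progeny genotype is missing.
#' @param trait_h2 narrow-sense heritability of simulated traits.
#' @param seed integer seed; all sub-stage seeds are derived from it.
#' @param grid_ncol optional number of grid columns (default: near-square).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_candidates = 749, n_families = 73, family_size = 9,
                       grid_spacing_m = 0.91, n_mothers_sampled = 15,
                       progeny_per_mother = c(44, 72), n_loci = 2500,
                       maf_range = c(0.04, 0.25),
                       kernel = list(family = "exponential", scale_m = 3.5,
                                     shape = 1),
                       selfing_rate = 0, genotyping_error = 0.01,
                       missing_rate = 0.05, trait_h2 = 0.5, seed = 1,
                       grid_ncol = NULL) {
  cfg <- list(n_candidates = as.integer(n_candidates),
              n_families = as.integer(n_families),
              family_size = as.integer(family_size),
              grid_spacing_m = grid_spacing_m,
              n_mothers_sampled = as.integer(n_mothers_sampled),
              progeny_per_mother = as.integer(range(progeny_per_mother)),
              n_loci = as.integer(n_loci), maf_range = maf_range,
              kernel = kernel, selfing_rate = selfing_rate,
              genotyping_error = genotyping_error,
              missing_rate = missing_rate, trait_h2 = trait_h2,
              seed = as.integer(seed), grid_ncol = grid_ncol)
  probs <- c(selfing = cfg$selfing_rate, error = cfg$genotyping_error,
             missing = cfg$missing_rate, h2 = cfg$trait_h2)
  if (any(probs < 0 | probs > 1)) {
    stop("selfing_rate, genotyping_error, missing_rate and trait_h2 must lie in [0, 1]")
  }
  if (cfg$grid_spacing_m <= 0) stop("grid_spacing_m must be positive")
  if (cfg$n_loci < 1) stop("n_loci must be at least 1")
  if (!kernel$family %in% c("exponential", "exponential-power", "uniform")) {
    stop("unknown kernel family: ", kernel$family)
  }
  if (kernel$family != "uniform" && (is.null(kernel$scale_m) || kernel$scale_m <= 0)) {
    stop("kernel scale_m must be positive")
  }
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range >= 1)) {
    stop("maf_range must lie strictly inside (0, 1)")
  }
  if (cfg$n_families * cfg$family_size > cfg$n_candidates) {
    stop("n_families * family_size exceeds n_candidates")
  }
  class(cfg) <- "sim_config"
  cfg
}

.kernel_weight <- function(d, kernel) {
  switch(kernel$family,
    exponential = exp(-d / kernel$scale_m),
    `exponential-power` = exp(-(d / kernel$scale_m)^(kernel$shape %||% 1)),
    uniform = rep(1, length(d)),
    stop("unknown kernel family: ", kernel$family)
  )
}

.locus_names <- function(L, n_chrom = 21) {
  chrom <- rep(seq_len(n_chrom), length.out = L)
  chrom <- sort(chrom)
  pos <- stats::ave(seq_len(L), chrom, FUN = seq_along) * 1000L
  sprintf("C%02d_%07d", chrom, pos)
}

# draw one gamete (0/1 allele) per locus from each row of a dosage matrix
.gametes <- function(dos) {
  matrix(stats::rbinom(length(dos), 1L, dos / 2), nrow(dos), ncol(dos))
}

#' Simulate the founder candidates of a nursery
#'
#' Draws per-locus founder allele frequencies from the configured law, builds
#' half-sib families that share one simulated dam (with independent sires
#' drawn from the population pollen cloud) plus bi-parental F1 genets for any
#' remainder, and lays all candidates out row-major on the planting grid with
#' family members adjacent.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes` (candidates x loci dosage matrix), `map`
#'   (field map data frame: genet_id, family_id, role, grid_row, grid_col,
#'   x_m, y_m), `families` (genet_id -> family_id), and `founder_freqs`.
#' @export
simulate_founders <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 1L))
  L <- cfg$n_loci
  n <- cfg$n_candidates
  p <- stats::runif(L, cfg$maf_range[1], cfg$maf_range[2])
  nhs <- cfg$n_families * cfg$family_size

  dams <- matrix(stats::rbinom(cfg$n_families * L, 2L, rep(p, each = cfg$n_families)),
                 cfg$n_families, L)
  fam_of <- rep(seq_len(cfg$n_families), each = cfg$family_size)
  dam_gam <- .gametes(dams[fam_of, , drop = FALSE])
  sire_gam <- matrix(stats::rbinom(nhs * L, 1L, rep(p, each = nhs)), nhs, L)
  G <- dam_gam + sire_gam
  family_id <- sprintf("FAM%03d", fam_of)

  n_f1 <- n - nhs
  if (n_f1 > 0) {
    n_par <- min(8L, max(2L, n_f1))
    elite <- matrix(stats::rbinom(n_par * L, 2L, rep(p, each = n_par)), n_par, L)
    n_cross <- min(12L, n_f1, choose(n_par, 2))
    pairs <- utils::combn(n_par, 2)
    pairs <- pairs[, sample(ncol(pairs), n_cross), drop = FALSE]
    cross_of <- rep_len(seq_len(n_cross), n_f1)
    g1 <- .gametes(elite[pairs[1, cross_of], , drop = FALSE])
    g2 <- .gametes(elite[pairs[2, cross_of], , drop = FALSE])
    G <- rbind(G, g1 + g2)
    family_id <- c(family_id, sprintf("F1X%02d", cross_of))
  }

  ids <- sprintf("G%04d", seq_len(n))
  rownames(G) <- ids
  colnames(G) <- .locus_names(L)
  storage.mode(G) <- "integer"

  ncol_grid <- cfg$grid_ncol %||% ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  if (nrow_grid * ncol_grid < n) stop("grid too small for n_candidates")
  idx <- seq_len(n) - 1L
  map <- data.frame(
    genet_id = ids, family_id = family_id, role = "candidate",
    grid_row = idx %/% ncol_grid, grid_col = idx %% ncol_grid,
    stringsAsFactors = FALSE
  )
  map$x_m <- map$grid_col * cfg$grid_spacing_m
  map$y_m <- map$grid_row * cfg$grid_spacing_m

  list(genotypes = G, map = map,
       families = data.frame(genet_id = ids, family_id = family_id,
                             stringsAsFactors = FALSE),
       founder_freqs = p)
}

#' Simulate progeny arrays from sampled mothers
#'
#' Samples mothers away from the grid borders, then for each mother draws each
#' progeny's father: the mother herself (selfing) with probability
#' `selfing_rate`, otherwise a candidate with probability proportional to the
#' dispersal kernel evaluated at the mother-candidate distance. Progeny
#' genotypes are Mendelian gamete draws; each observed call is then flipped to
#' a uniformly chosen different dosage with probability `genotyping_error` and
#' set missing with probability `missing_rate`.
#'
#' @param founders output of [simulate_founders()].
#' @param cfg the same [sim_config()].
#' @param mothers optional character vector of mother genet ids (default:
#'   sampled among interior half-sib candidates).
#' @return list with `genotypes` (observed progeny dosages), `families`
#'   (progeny_id -> mother_id) and `truth` (true fathers incl. "SELF",
#'   realized distances, true pre-error genotypes, kernel parameters, selfing
#'   event count, founder frequencies).
#' @export
simulate_matings <- function(founders, cfg, mothers = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.derive_seed(cfg$seed, 2L))
  map <- founders$map
  G <- founders$genotypes
  if (is.null(mothers)) {
    interior <- map$grid_row > min(map$grid_row) & map$grid_row < max(map$grid_row) &
      map$grid_col > min(map$grid_col) & map$grid_col < max(map$grid_col)
    halfsib <- startsWith(map$family_id, "FAM")
    pool <- map$genet_id[interior & halfsib]
    if (length(pool) < cfg$n_mothers_sampled) pool <- map$genet_id[halfsib]
    mothers <- sort(sample(pool, cfg$n_mothers_sampled))
  }
  if (!all(mothers %in% map$genet_id)) {
    stop("mother absent from the field map: ",
         paste(setdiff(mothers, map$genet_id), collapse = ", "))
  }

  L <- ncol(G)
  rng <- cfg$progeny_per_mother
  out_g <- list()
  out_true <- list()
  fam <- list()
  father <- list()
  dist_m <- list()
  for (mom in mothers) {
    mrow <- match(mom, map$genet_id)
    npro <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    d <- sqrt((map$x_m - map$x_m[mrow])^2 + (map$y_m - map$y_m[mrow])^2)
    w <- .kernel_weight(d, cfg$kernel)
    w[mrow] <- 0 # selfing handled by selfing_rate, not by the kernel
    dads <- sample.int(nrow(map), npro, replace = TRUE, prob = w)
    is_self <- stats::runif(npro) < cfg$selfing_rate
    dads[is_self] <- mrow
    gm <- .gametes(G[rep(mrow, npro), , drop = FALSE])
    gf <- .gametes(G[dads, , drop = FALSE])
    off <- gm + gf
    ids <- sprintf("%s_P%03d", mom, seq_len(npro))
    rownames(off) <- ids
    colnames(off) <- colnames(G)
    out_true[[mom]] <- off

    obs <- off
    flip <- matrix(stats::runif(length(obs)) < cfg$genotyping_error,
                   npro, L)
    if (any(flip)) {
      shift <- sample(1:2, sum(flip), replace = TRUE)
      obs[flip] <- (obs[flip] + shift) %% 3L
    }
    obs[matrix(stats::runif(length(obs)) < cfg$missing_rate, npro, L)] <- NA
    storage.mode(obs) <- "integer"
    out_g[[mom]] <- obs
    fam[[mom]] <- data.frame(progeny_id = ids, mother_id = mom,
                             stringsAsFactors = FALSE)
    father[[mom]] <- ifelse(is_self, "SELF", map$genet_id[dads])
    dist_m[[mom]] <- ifelse(is_self, 0, d[dads])
  }

  families <- do.call(rbind, unname(fam))
  truth <- list(
    true_father = stats::setNames(unlist(unname(father)), families$progeny_id),
    realized_distance_m = stats::setNames(unlist(unname(dist_m)),
                                          families$progeny_id),
    true_genotypes = do.call(rbind, unname(out_true)),
    kernel_params = cfg$kernel,
    selfing_events = sum(unlist(father) == "SELF"),
    founder_freqs = founders$founder_freqs,
    mothers = mothers
  )
  list(genotypes = do.call(rbind, unname(out_g)), families = families,
       truth = truth)
}

#' Simulate additive traits with a target heritability
#'
#' Additive genetic value is the dosage-weighted sum of i.i.d. standard-normal
#' marker effects; Gaussian noise is scaled so the phenotypic variance yields
#' the configured heritability (`h2 = 1` gives the genetic value exactly;
#' `h2 = 0` gives unit-variance noise uncorrelated with the genotype).
#'
#' @param genotypes dosage matrix without missing calls (use the simulator's
#'   true genotypes for progeny).
#' @param cfg a [sim_config()]; `trait_h2` is used.
#' @param n_traits number of independent traits to simulate.
#' @param effects optional loci x traits matrix of marker effects (default:
#'   i.i.d. standard normal draws).
#' @return list with `phenotypes` (individuals x traits), `genetic_values`,
#'   and `effects` (loci x traits).
#' @export
simulate_traits <- function(genotypes, cfg, n_traits = 1, effects = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  h2 <- cfg$trait_h2
  if (h2 < 0 || h2 > 1) stop("trait_h2 must lie in [0, 1]")
  set.seed(.derive_seed(cfg$seed, 3L))
  if (anyNA(genotypes)) stop("simulate_traits requires complete genotypes")
  L <- ncol(genotypes)
  eff <- if (is.null(effects)) {
    matrix(stats::rnorm(L * n_traits), L, n_traits)
  } else {
    matrix(effects, L, n_traits)
  }
  g <- genotypes %*% eff
  if (h2 == 0) {
    y <- matrix(stats::rnorm(length(g)), nrow(g), n_traits)
  } else {
    sd_e <- sqrt(apply(g, 2, stats::var) * (1 - h2) / h2)
    noise <- matrix(stats::rnorm(length(g)), nrow(g), n_traits)
    y <- g + sweep(noise, 2, sd_e, `*`)
  }
  dimnames(y) <- dimnames(g) <- list(rownames(genotypes),
                                     sprintf("trait%02d", seq_len(n_traits)))
  list(phenotypes = y, genetic_values = g, effects = eff)
}

#' Simulate a full nursery: founders, progeny arrays and traits
#'
#' @param cfg a [sim_config()].
#' @param n_traits traits to simulate on founders and (true) progeny genotypes.
#' @return object of class `nursery_sim`: founders, progeny, families, truth,
#'   traits and the config.
#' @export
simulate_nursery <- function(cfg = sim_config(), n_traits = 1) {
  founders <- simulate_founders(cfg)
  mat <- simulate_matings(founders, cfg)
  all_true <- rbind(founders$genotypes, mat$truth$true_genotypes)
  traits <- simulate_traits(all_true, cfg, n_traits = n_traits)
  out <- list(cfg = cfg, founders = founders, progeny = mat$genotypes,
              families = mat$families, truth = mat$truth, traits = traits)
  class(out) <- "nursery_sim"
  out
}

#' @export
print.nursery_sim <- function(x, ...) {
  cat("Simulated spaced-plant nursery\n")
  cat(sprintf("  candidates: %d (%d families of %d), grid spacing %.2f m\n",
              x$cfg$n_candidates, x$cfg$n_families, x$cfg$family_size,
              x$cfg$grid_spacing_m))
  cat(sprintf("  progeny: %d from %d mothers; selfing events: %d\n",
              nrow(x$progeny), length(x$truth$mothers),
              x$truth$selfing_events))
  cat(sprintf("  loci: %d; kernel: %s (scale %.2f m)\n", x$cfg$n_loci,
              x$cfg$kernel$family, x$cfg$kernel$scale_m %||% NA))
  invisible(x)
}

#' Availability-weighted kernel fraction within a distance cutoff
#'
#' The theoretical probability that an outcross pollination event falls within
#' `cutoff_m` of a mother, i.e. the dispersal-kernel mass restricted to the
#' actual candidate positions, averaged over the given mothers. This is the
#' "kernel truth" against which pipeline estimates of the fraction of
#' short-range pollinations are compared.
#'
#' @param map field map (as from [simulate_founders()]).
#' @param mothers character vector of mother genet ids.
#' @param kernel kernel specification (`family`, `scale_m`, `shape`).
#' @param cutoff_m distance cutoff in meters.
#' @return scalar probability.
#' @export
kernel_fraction_within <- function(map, mothers, kernel, cutoff_m = 10) {
  sapply(mothers, function(mom) {
    mrow <- match(mom, map$genet_id)
    if (is.na(mrow)) stop("mother absent from the field map: ", mom)
    d <- sqrt((map$x_m - map$x_m[mrow])^2 + (map$y_m - map$y_m[mrow])^2)
    w <- .kernel_weight(d, kernel)
    w[mrow] <- 0
    sum(w[d <= cutoff_m]) / sum(w)
  }) |> mean()
}
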