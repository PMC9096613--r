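# Test-side oracles, written independently of the package internals: plain
# loops and direct arithmetic only.

# error-mixture weights: observed call is true w.p. 1 - e, each wrong dosage
# w.p. e / 2
.orc_err <- function(obs, true, e) {
  if (obs == true) 1 - e else e / 2
}

# Mendelian transmission P(off | mom, dad) for dosages
.orc_mendel <- function(off, mom, dad) {
  pm <- c(1 - mom / 2, mom / 2)
  pd <- c(1 - dad / 2, dad / 2)
  probs <- c(pm[1] * pd[1], pm[1] * pd[2] + pm[2] * pd[1], pm[2] * pd[2])
  probs[off + 1]
}

# exhaustive enumeration over all true-genotype configurations
orc_trio_named <- function(o, m, d, e) {
  acc <- 0
  for (tm in 0:2) for (td in 0:2) for (to in 0:2) {
    acc <- acc + .orc_err(m, tm, e) * .orc_err(d, td, e) *
      .orc_mendel(to, tm, td) * .orc_err(o, to, e)
  }
  acc
}

orc_trio_pool <- function(o, m, p, e) {
  acc <- 0
  for (tm in 0:2) for (to in 0:2) {
    # paternal allele drawn from the pool at frequency p
    pr_to <- 0
    pm <- c(1 - tm / 2, tm / 2)
    for (ma in 0:1) for (pa in 0:1) {
      w <- pm[ma + 1] * (if (pa == 1) p else 1 - p)
      if (ma + pa == to) pr_to <- pr_to + w
    }
    acc <- acc + .orc_err(m, tm, e) * pr_to * .orc_err(o, to, e)
  }
  acc
}

# brute-force two-sample Kolmogorov-Smirnov D over all data points
orc_ks_d <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 1.0)))
}

# a small simulated nursery used across tests
tiny_nursery <- function(seed = 5, n_candidates = 96, n_families = 16,
                         family_size = 6, n_mothers = 3, progeny = 25,
                         n_loci = 300, selfing_rate = 0,
                         genotyping_error = 0.01, missing_rate = 0.02,
                         kernel = list(family = "exponential", scale_m = 3.5,
                                       shape = 1)) {
  cfg <- sim_config(
    n_candidates = n_candidates, n_families = n_families,
    family_size = family_size, n_mothers_sampled = n_mothers,
    progeny_per_mother = c(progeny, progeny), n_loci = n_loci,
    maf_range = c(0.1, 0.4), kernel = kernel, selfing_rate = selfing_rate,
    genotyping_error = genotyping_error, missing_rate = missing_rate,
    seed = seed
  )
  simulate_nursery(cfg)
}

# truth vector aligned to a paternity table, selfing coded as the mother
truth_fathers <- function(sim, pt) {
  tf <- sim$truth$true_father[pt$progeny_id]
  tf[tf == "SELF"] <- pt$mother_id[tf == "SELF"]
  unname(tf)
}
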