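# Mixed-mating maximum-likelihood estimation of outcrossing rates and
# correlated paternity, with family bootstrap.
#
# Model: a progeny of a known mother is selfed with probability s, otherwise
# outcrossed to a father drawn from the pollen pool at the candidate allele
# frequencies. Per progeny,
#   P = s * prod_l T_self(g_l | mom_l) + (1 - s) * prod_l T_out(g_l | mom_l, p_l)
# with the same symmetric genotyping-error mixture as the paternity module;
# the selfing indicator is shared across loci, which is what makes the
# multilocus rate t_m = 1 - s robust to single-locus noise.

#' Pollen-pool allele frequencies
#'
#' Plug-in allele frequencies of the candidate (pollen donor) population.
#' @param candidates candidate dosage matrix.
#' @param subset optional subset of candidate ids or indices.
#' @return per-locus frequencies.
#' @export
pollen_pool_frequencies <- function(candidates, subset = NULL) {
  allele_frequencies(candidates, subset)
}

# per-family likelihood components: per-progeny selfing / outcross
# probabilities per locus (skipped loci contribute 1). With known_mother the
# maternal genotype is taken as true; otherwise her call also gets the error
# mixture (the trio model used for paternity LOD scores).
.mating_components <- function(off, g_mom, freqs, error_rate,
                               known_mother = TRUE) {
  tabs <- .trio_tables(error_rate)
  n <- nrow(off)
  L <- ncol(off)
  pool <- .pool_table(tabs, freqs, known_mother = known_mother) # 3 x 3 x L
  self_tab <- if (known_mother) tabs$self_known else tabs$self
  momm <- matrix(rep(as.integer(g_mom), each = n), n, L)
  ok <- !is.na(off) & !is.na(momm)
  o <- off
  o[!ok] <- 0L
  m <- momm
  m[!ok] <- 0L
  base <- o + 3L * m
  a <- matrix(self_tab[as.vector(base) + 1L], n, L)
  b <- matrix(pool[as.vector(base + rep(9L * (seq_len(L) - 1L), each = n)) + 1L],
              n, L)
  a[!ok] <- 1
  b[!ok] <- 1
  list(self = a, out = b, ok = ok)
}

#' Family log-likelihood of the mixed-mating model
#'
#' @param off progeny dosage matrix of one maternal family.
#' @param g_mom the mother's dosage vector.
#' @param s selfing probability at which to evaluate.
#' @param freqs pollen-pool allele frequencies.
#' @param error_rate per-call mistyping probability.
#' @param known_mother take the maternal genotype as true (the default for
#'   known-mother designs); `FALSE` applies the error mixture to her call as
#'   in the paternity trio model.
#' @return log-likelihood; progeny impossible under both hypotheses (only
#'   possible at `error_rate = 0`) raise an error naming them.
#' @export
family_log_likelihood <- function(off, g_mom, s, freqs, error_rate = 0.01,
                                  known_mother = TRUE) {
  stopifnot(s >= 0, s <= 1)
  cmp <- .mating_components(off, g_mom, freqs, error_rate, known_mother)
  la <- rowSums(log(cmp$self))
  lb <- rowSums(log(cmp$out))
  bad <- is.infinite(la) & is.infinite(lb)
  if (any(bad)) {
    stop("progeny inconsistent with the mother under both hypotheses at error_rate = 0: ",
         paste(rownames(off)[bad], collapse = ", "))
  }
  m <- pmax(la, lb)
  sum(m + log(s * exp(la - m) + (1 - s) * exp(lb - m)))
}

# safeguarded Newton-Raphson for the concave 1-D mixture log-likelihood
# sum log(b + s * (a - b)) given scaled per-observation (a, b)
.mle_mix_scalar <- function(at, bt, lower, upper, tol = 1e-12, maxit = 200) {
  d <- at - bt
  lo <- lower
  hi <- upper
  grad <- function(s) sum(d / (bt + s * d))
  if (grad(lo) <= 0) return(list(s = lo, boundary = TRUE))
  if (grad(hi) >= 0) return(list(s = hi, boundary = TRUE))
  s <- min(max(0.05, lo + 1e-6), hi - 1e-6)
  for (it in seq_len(maxit)) {
    r <- d / (bt + s * d)
    g <- sum(r)
    h <- sum(r^2)
    step <- g / h
    s_new <- min(max(s + step, lo + 1e-12), hi - 1e-12)
    if (g > 0) lo <- max(lo, s) else hi <- min(hi, s)
    if (s_new <= lo || s_new >= hi) s_new <- (lo + hi) / 2 # bisection fallback
    if (abs(s_new - s) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  list(s = s, boundary = FALSE)
}

# vectorised Newton-Raphson across loci; a, b are n x L, s bounds per locus
.mle_mix_loci <- function(a, b, lo, hi, init, maxit = 40, tol = 1e-9) {
  d <- a - b
  s <- pmin(pmax(init, lo + 1e-9), hi - 1e-9)
  n <- nrow(a)
  for (it in seq_len(maxit)) {
    P <- b + d * rep(s, each = n)
    r <- d / P
    g <- colSums(r)
    h <- colSums(r^2)
    step <- ifelse(h > 0, g / h, 0)
    step <- pmin(pmax(step, -0.25), 0.25) # damp early oscillation
    s_new <- pmin(pmax(s + step, lo + 1e-9), hi - 1e-9)
    if (max(abs(s_new - s)) < tol) {
      s <- s_new
      break
    }
    s <- s_new
  }
  s
}

#' Estimate outcrossing rates by maximum likelihood
#'
#' Multilocus outcrossing rate `t_m = 1 - s` with `s` maximizing the
#' multilocus mixture likelihood (Newton-Raphson on the concave 1-D
#' log-likelihood, safeguarded by bisection); single-locus rate `t_s` is one
#' minus the mean of per-locus maximum-likelihood selfing rates. The
#' multilocus s is constrained to \[0, 1\] by default because with plug-in
#' pollen-pool frequencies its likelihood is monotone at the boundary when no
#' progeny supports selfing; `constrain = FALSE` lifts the lower bound to the
#' positivity limit of the likelihood, allowing `t_m > 1`. The per-locus
#' estimates are always unconstrained within the positivity region (so their
#' mean, hence `t_s`, is approximately unbiased and may exceed 1). Spread is
#' obtained by resampling maternal families with replacement.
#'
#' @param progeny progeny dosage matrix.
#' @param families data frame (progeny_id, mother_id).
#' @param candidates candidate dosage matrix containing the mothers.
#' @param freqs pollen-pool allele frequencies (default: from candidates).
#' @param error_rate per-call mistyping probability of the mating model.
#' @param n_bootstrap family bootstrap replicates (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap.
#' @param constrain restrict the multilocus s to \[0, 1\] (default).
#' @param known_mother take maternal genotypes as true (known-mother design);
#'   `FALSE` applies the error mixture to mother calls as well.
#' @return object of class `mating_fit` with estimates `t_m`, `t_s`,
#'   `biparental` (= t_m - t_s), bootstrap standard deviations, and the
#'   bootstrap draws.
#' @export
estimate_outcrossing <- function(progeny, families, candidates, freqs = NULL,
                                 error_rate = 0.01, n_bootstrap = 1000,
                                 seed = 1, constrain = TRUE,
                                 known_mother = TRUE) {
  if (is.null(freqs)) freqs <- pollen_pool_frequencies(candidates)
  mothers <- unique(families$mother_id)
  if (n_bootstrap > 0 && length(mothers) < 2) {
    stop("at least two maternal families are required for the bootstrap")
  }
  keep <- !is.na(freqs) & freqs > 0 & freqs < 1
  fr <- freqs[keep]

  fam_rows <- split(families$progeny_id, families$mother_id)
  la <- list()
  lb <- list()
  amat <- list()
  bmat <- list()
  for (mom in names(fam_rows)) {
    off <- progeny[fam_rows[[mom]], keep, drop = FALSE]
    cmp <- .mating_components(off, candidates[mom, keep], fr, error_rate,
                              known_mother)
    la[[mom]] <- rowSums(log(pmax(cmp$self, 1e-300)))
    lb[[mom]] <- rowSums(log(pmax(cmp$out, 1e-300)))
    amat[[mom]] <- cmp$self
    bmat[[mom]] <- cmp$out
  }
  fam_id <- rep(names(fam_rows), vapply(fam_rows, length, 1L))
  la <- unlist(unname(la))
  lb <- unlist(unname(lb))
  A <- do.call(rbind, unname(amat))
  B <- do.call(rbind, unname(bmat))

  scl <- pmax(la, lb)
  at <- exp(la - scl)
  bt <- exp(lb - scl)

  mix_bounds <- function(at, bt, constrain) {
    d <- at - bt
    lo <- suppressWarnings(max(-0.5, max(-bt[d > 0] / d[d > 0])))
    hi <- suppressWarnings(min(1, min(bt[d < 0] / (bt[d < 0] - at[d < 0]))))
    if (constrain) lo <- max(lo, 0)
    c(max(lo, -0.5) + 1e-9, min(hi, 1) - 1e-9)
  }
  bnd <- mix_bounds(at, bt, constrain)
  s_hat <- .mle_mix_scalar(at, bt, bnd[1], bnd[2])$s

  # per-locus bounds computed once on the full data (valid for any subset);
  # per-locus estimates stay unconstrained within the positivity region so
  # their noise averages out in t_s
  d <- A - B
  lo_l <- apply(ifelse(d > 0, -B / d, -Inf), 2, max)
  hi_l <- apply(ifelse(d < 0, B / (B - A), Inf), 2, min)
  lo_l <- pmax(lo_l, -0.5)
  hi_l <- pmin(hi_l, 1.5)
  informative <- colSums(abs(d) > 1e-12) > 0 & hi_l - lo_l > 1e-6
  s_loc <- rep(NA_real_, ncol(A))
  init0 <- pmin(pmax(s_hat, lo_l + 1e-6), hi_l - 1e-6)
  s_loc[informative] <- .mle_mix_loci(
    A[, informative, drop = FALSE], B[, informative, drop = FALSE],
    lo_l[informative], hi_l[informative],
    init0[informative]
  )
  t_m <- 1 - s_hat
  t_s <- 1 - mean(s_loc, na.rm = TRUE)

  boot <- NULL
  if (n_bootstrap > 0) {
    set.seed(.derive_seed(seed, 11L))
    moms <- names(fam_rows)
    rows_of <- split(seq_along(fam_id), fam_id)
    boot <- matrix(NA_real_, n_bootstrap, 3,
                   dimnames = list(NULL, c("t_m", "t_s", "biparental")))
    for (r in seq_len(n_bootstrap)) {
      pick <- sample(moms, length(moms), replace = TRUE)
      rows <- unlist(rows_of[pick], use.names = FALSE)
      bb <- mix_bounds(at[rows], bt[rows], constrain)
      sb <- .mle_mix_scalar(at[rows], bt[rows], bb[1], bb[2])$s
      slb <- rep(NA_real_, ncol(A))
      slb[informative] <- .mle_mix_loci(
        A[rows, informative, drop = FALSE], B[rows, informative, drop = FALSE],
        lo_l[informative], hi_l[informative], s_loc[informative],
        maxit = 8
      )
      tmb <- 1 - sb
      tsb <- 1 - mean(slb, na.rm = TRUE)
      boot[r, ] <- c(tmb, tsb, tmb - tsb)
    }
  }
  out <- list(
    t_m = t_m, t_s = t_s, biparental = t_m - t_s, s = s_hat,
    t_m_sd = if (is.null(boot)) NA_real_ else stats::sd(boot[, "t_m"]),
    t_s_sd = if (is.null(boot)) NA_real_ else stats::sd(boot[, "t_s"]),
    biparental_sd = if (is.null(boot)) NA_real_ else stats::sd(boot[, "biparental"]),
    n_bootstrap = n_bootstrap, bootstrap = boot,
    per_locus_s = s_loc, error_rate = error_rate, constrain = constrain,
    n_progeny = nrow(progeny), n_families = length(fam_rows)
  )
  class(out) <- "mating_fit"
  out
}

#' @export
print.mating_fit <- function(x, ...) {
  cat("Mixed-mating model fit (maximum likelihood)\n")
  cat(sprintf("  families: %d, progeny: %d, error rate: %.3f\n",
              x$n_families, x$n_progeny, x$error_rate))
  fmt <- function(v, s) {
    if (is.na(s)) sprintf("%.3f", v) else sprintf("%.3f (%.3f)", v, s)
  }
  cat("  multilocus outcrossing rate t_m:  ", fmt(x$t_m, x$t_m_sd), "\n")
  cat("  single-locus outcrossing rate t_s:", fmt(x$t_s, x$t_s_sd), "\n")
  cat("  biparental inbreeding t_m - t_s:  ",
      fmt(x$biparental, x$biparental_sd), "\n")
  invisible(x)
}

#' @export
coef.mating_fit <- function(object, ...) {
  c(t_m = object$t_m, t_s = object$t_s, biparental = object$biparental)
}

#' @export
summary.mating_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$bootstrap)) {
    cat(sprintf("  bootstrap (n = %d) quantiles of t_m:\n", object$n_bootstrap))
    print(round(stats::quantile(object$bootstrap[, "t_m"],
                                c(0.025, 0.5, 0.975)), 4))
  }
  invisible(object)
}

# per-family correlated-paternity pair components: log P(pair | full sibs)
# and log P(pair | half sibs) for every unordered pair of progeny
.pair_components <- function(off, g_mom, freqs, error_rate, max_pairs = Inf,
                             pair_seed = NULL, known_mother = TRUE) {
  tabs <- .trio_tables(error_rate)
  n <- nrow(off)
  if (n < 2) return(NULL)
  L <- ncol(off)
  hw <- rbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2)
  momm <- matrix(rep(as.integer(g_mom), each = n), n, L)
  ok <- !is.na(off) & !is.na(momm)
  o <- off
  o[!ok] <- 0L
  m <- momm
  m[!ok] <- 0L
  base <- o + 3L * m
  dt <- if (known_mother) tabs$dad_true_known else tabs$dad_true
  w <- lapply(0:2, function(k) {
    wk <- matrix(dt[as.vector(base) + 9L * k + 1L], n, L)
    wk[!ok] <- 1 # skipped locus: no information, cancels in the ratio
    wk
  })
  u <- lapply(0:2, function(k) {
    w[[k + 1]] * matrix(rep(sqrt(hw[k + 1, ]), each = n), n, L)
  })
  hmarg <- u[[1]] * matrix(rep(sqrt(hw[1, ]), each = n), n, L) +
    u[[2]] * matrix(rep(sqrt(hw[2, ]), each = n), n, L) +
    u[[3]] * matrix(rep(sqrt(hw[3, ]), each = n), n, L)
  lh <- rowSums(log(pmax(hmarg, 1e-300)))
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > max_pairs) {
    if (!is.null(pair_seed)) set.seed(pair_seed)
    pairs <- pairs[, sample(ncol(pairs), max_pairs), drop = FALSE]
  }
  i <- pairs[1, ]
  j <- pairs[2, ]
  full <- u[[1]][i, , drop = FALSE] * u[[1]][j, , drop = FALSE] +
    u[[2]][i, , drop = FALSE] * u[[2]][j, , drop = FALSE] +
    u[[3]][i, , drop = FALSE] * u[[3]][j, , drop = FALSE]
  logF <- rowSums(log(pmax(full, 1e-300)))
  logH <- lh[i] + lh[j]
  data.frame(logF = logF, logH = logH)
}

#' Correlated paternity
#'
#' Probability that two outcrossed maternal sibs share a father. Estimated by
#' maximum likelihood on sib pairs under the mixture
#' `P(pair) = r_p P(full sibs) + (1 - r_p) P(half sibs with independent
#' pollen-pool fathers)` (a composite likelihood over pairs). When a paternity
#' table is supplied, the direct identity-probability estimate
#' `sum x_i (x_i - 1) / (n (n - 1))` per family (mean over families) is also
#' reported, and its family bootstrap yields a percentile test of `r_p > 0`.
#'
#' @inheritParams estimate_outcrossing
#' @param paternity optional [assign_paternity()] table for the direct
#'   estimate.
#' @param max_pairs_per_family cap on sib pairs per family used in the ML fit.
#' @param known_mother take maternal genotypes as true (known-mother design).
#' @return object of class `correlated_paternity` with `rp_ml`, `rp_direct`,
#'   bootstrap sd and a percentile p-value for `r_p > 0`.
#' @export
correlated_paternity <- function(progeny, families, candidates, freqs = NULL,
                                 error_rate = 0.01, paternity = NULL,
                                 n_bootstrap = 1000, seed = 1,
                                 max_pairs_per_family = 3000,
                                 known_mother = TRUE) {
  if (is.null(freqs)) freqs <- pollen_pool_frequencies(candidates)
  keep <- !is.na(freqs) & freqs > 0 & freqs < 1
  fr <- freqs[keep]
  fam_rows <- split(families$progeny_id, families$mother_id)
  comp <- list()
  for (mom in names(fam_rows)) {
    pids <- fam_rows[[mom]]
    if (length(pids) < 2) next
    comp[[mom]] <- .pair_components(
      progeny[pids, keep, drop = FALSE], candidates[mom, keep], fr, error_rate,
      max_pairs = max_pairs_per_family,
      pair_seed = .derive_seed(seed, 13L), known_mother = known_mother
    )
  }
  if (!length(comp)) stop("no family with at least two progeny")

  rp_from <- function(moms) {
    cc <- do.call(rbind, comp[moms])
    scl <- pmax(cc$logF, cc$logH)
    ft <- exp(cc$logF - scl)
    ht <- exp(cc$logH - scl)
    .mle_mix_scalar(ft, ht, 1e-9, 1 - 1e-9)$s
  }
  rp_ml <- rp_from(names(comp))

  rp_direct <- NA_real_
  direct_of <- NULL
  if (!is.null(paternity)) {
    asg <- paternity[!is.na(paternity$father_id) &
                       paternity$father_id != paternity$mother_id, ,
                     drop = FALSE]
    direct_of <- tapply(asg$father_id, asg$mother_id, function(f) {
      x <- table(f)
      n <- sum(x)
      if (n < 2) return(NA_real_)
      sum(x * (x - 1)) / (n * (n - 1))
    })
    rp_direct <- mean(direct_of, na.rm = TRUE)
  }

  boot <- NULL
  p_gt0 <- NA_real_
  rp_sd <- NA_real_
  if (n_bootstrap > 0 && length(comp) > 1) {
    set.seed(.derive_seed(seed, 17L))
    boot <- numeric(n_bootstrap)
    for (r in seq_len(n_bootstrap)) {
      boot[r] <- rp_from(sample(names(comp), length(comp), replace = TRUE))
    }
    rp_sd <- stats::sd(boot)
    p_gt0 <- (1 + sum(boot <= 1e-6)) / (n_bootstrap + 1)
  }
  out <- list(rp_ml = rp_ml, rp_direct = rp_direct, rp_sd = rp_sd,
              p_value_gt0 = p_gt0, bootstrap = boot,
              per_family_direct = direct_of, n_families = length(comp))
  class(out) <- "correlated_paternity"
  out
}

#' @export
print.correlated_paternity <- function(x, ...) {
  cat("Correlated paternity\n")
  cat(sprintf("  r_p (ML on sib pairs):   %.3f (sd %.3f)\n", x$rp_ml, x$rp_sd))
  if (!is.na(x$rp_direct)) {
    cat(sprintf("  r_p (direct, paternity): %.3f\n", x$rp_direct))
  }
  if (!is.na(x$p_value_gt0)) {
    cat(sprintf("  bootstrap percentile test of r_p > 0: p = %.3g\n",
                x$p_value_gt0))
  }
  invisible(x)
}
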