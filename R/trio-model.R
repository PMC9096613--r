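# Trio genotype likelihood machinery shared by the paternity and mating-system
# modules. Genotypes are diploid biallelic dosages (count of the "1" allele,
# values 0/1/2, NA = missing). The genotyping-error model is a symmetric dosage
# flip: an observed call is the true genotype with probability 1 - e and each
# of the two wrong dosages with probability e/2.

# floor used inside the dense-matrix LOD path so log(0) stays BLAS-safe
.LOG_TINY <- log(1e-300)

.check_dosage <- function(g, what = "dosage") {
  bad <- !is.na(g) & !(g %in% c(0L, 1L, 2L))
  if (any(bad)) stop(what, " must be 0, 1, 2 or NA", call. = FALSE)
  invisible(g)
}

#' @keywords internal
.trio_tables <- function(error_rate) {
  stopifnot(error_rate >= 0, error_rate < 0.5)
  e <- error_rate
  E <- matrix(e / 2, 3, 3)
  diag(E) <- 1 - e # E[true + 1, obs + 1]
  mend <- array(0, c(3, 3, 3)) # P(true off | true mom, true dad)
  for (m in 0:2) {
    for (d in 0:2) {
      pm <- c(1 - m / 2, m / 2)
      pd <- c(1 - d / 2, d / 2)
      mend[, m + 1, d + 1] <- c(
        pm[1] * pd[1],
        pm[1] * pd[2] + pm[2] * pd[1],
        pm[2] * pd[2]
      )
    }
  }
  # P(obs off | obs mom, TRUE dad genotype k): error mixture on mother and
  # offspring only (used for pollen-pool and sib-pair likelihoods)
  dad_true <- array(0, c(3, 3, 3))
  for (o in 0:2) {
    for (m in 0:2) {
      for (k in 0:2) {
        acc <- 0
        for (tm in 0:2) {
          for (to in 0:2) {
            acc <- acc + E[tm + 1, m + 1] * mend[to + 1, tm + 1, k + 1] *
              E[to + 1, o + 1]
          }
        }
        dad_true[o + 1, m + 1, k + 1] <- acc
      }
    }
  }
  # P(obs off | obs mom, obs dad): error mixture on all three calls
  dad_obs <- array(0, c(3, 3, 3))
  for (d in 0:2) {
    dad_obs[, , d + 1] <-
      dad_true[, , 1] * E[1, d + 1] +
      dad_true[, , 2] * E[2, d + 1] +
      dad_true[, , 3] * E[3, d + 1]
  }
  # selfing: father IS the mother, one true genotype drawn once
  self <- matrix(0, 3, 3) # [obs off + 1, obs mom + 1]
  for (o in 0:2) {
    for (m in 0:2) {
      acc <- 0
      for (tm in 0:2) {
        for (to in 0:2) {
          acc <- acc + E[tm + 1, m + 1] * mend[to + 1, tm + 1, tm + 1] *
            E[to + 1, o + 1]
        }
      }
      self[o + 1, m + 1] <- acc
    }
  }
  # known-mother variants: the maternal genotype is taken as true (no error
  # mixture on her call); the offspring mixture is retained
  dad_true_known <- array(0, c(3, 3, 3))
  self_known <- matrix(0, 3, 3)
  for (o in 0:2) {
    for (m in 0:2) {
      for (k in 0:2) {
        dad_true_known[o + 1, m + 1, k + 1] <-
          sum(mend[, m + 1, k + 1] * E[, o + 1])
      }
      self_known[o + 1, m + 1] <- sum(mend[, m + 1, m + 1] * E[, o + 1])
    }
  }
  list(error_rate = e, E = E, mendel = mend, dad_obs = dad_obs,
       dad_true = dad_true, self = self,
       dad_true_known = dad_true_known, self_known = self_known)
}

# P(obs off | mom, father = random draw from the pollen pool at allele
# frequency p), per locus; returns a 3 x 3 x L array
.pool_table <- function(tabs, freqs, known_mother = FALSE) {
  dt <- if (known_mother) tabs$dad_true_known else tabs$dad_true
  hw <- rbind((1 - freqs)^2, 2 * freqs * (1 - freqs), freqs^2)
  out <- outer(dt[, , 1], hw[1, ])
  out <- out + outer(dt[, , 2], hw[2, ])
  out + outer(dt[, , 3], hw[3, ])
}

#' Trio genotype probability under the symmetric genotyping-error model
#'
#' Probability of an observed offspring dosage given the mother's observed
#' dosage and either a named father's observed dosage or a random father drawn
#' from the pollen pool (paternal allele sampled at the locus frequency). Each
#' observed call is taken to be the true genotype with probability
#' `1 - error_rate` and each of the two other dosages with probability
#' `error_rate / 2`. Missing calls (NA in any of the three genotypes)
#' contribute probability 1, i.e. the locus is skipped.
#'
#' @param g_off,g_mom offspring and mother dosages (0/1/2/NA), vectorised over
#'   loci.
#' @param g_dad father dosages, or `NULL` for the random pollen-pool father.
#' @param freq frequency of the counted allele at each locus, in (0, 1).
#'   Required only for the pollen-pool father.
#' @param error_rate per-call mistyping probability, in \[0, 0.5).
#' @return numeric vector of probabilities, one per locus.
#' @examples
#' trio_genotype_prob(1, 1, 1, freq = 0.5, error_rate = 0) # Mendelian 0.5
#' trio_genotype_prob(2, 0, 0, freq = 0.5, error_rate = 0) # impossible, 0
#' @export
trio_genotype_prob <- function(g_off, g_mom, g_dad = NULL, freq = NULL,
                               error_rate = 0) {
  n <- max(length(g_off), length(g_mom),
           if (is.null(g_dad)) 0L else length(g_dad),
           if (is.null(freq)) 0L else length(freq))
  g_off <- rep_len(as.integer(g_off), n)
  g_mom <- rep_len(as.integer(g_mom), n)
  .check_dosage(g_off, "offspring dosage")
  .check_dosage(g_mom, "mother dosage")
  tabs <- .trio_tables(error_rate)
  out <- rep(1, n)
  if (is.null(g_dad)) {
    if (is.null(freq)) stop("freq is required for a pollen-pool father")
    freq <- rep_len(freq, n)
    stopifnot(all(freq > 0 & freq < 1))
    den <- .pool_table(tabs, freq)
    ok <- !is.na(g_off) & !is.na(g_mom)
    idx <- cbind(g_off + 1L, g_mom + 1L, seq_len(n))
    out[ok] <- den[idx[ok, , drop = FALSE]]
  } else {
    g_dad <- rep_len(as.integer(g_dad), n)
    .check_dosage(g_dad, "father dosage")
    ok <- !is.na(g_off) & !is.na(g_mom) & !is.na(g_dad)
    idx <- cbind(g_off + 1L, g_mom + 1L, g_dad + 1L)
    out[ok] <- tabs$dad_obs[idx[ok, , drop = FALSE]]
  }
  out
}

#' Paternity LOD score for one progeny-mother-candidate trio
#'
#' Natural-log likelihood ratio of "candidate is the father" versus "father is
#' a random draw from the pollen pool", summed over the loci at which all
#' three individuals are typed.
#'
#' @param g_off,g_mom,g_dad dosage vectors over loci (0/1/2/NA).
#' @param freqs pollen-pool allele frequencies per locus.
#' @param error_rate assumed per-call mistyping probability.
#' @return list with `lod` (natural-log units; `-Inf` possible at
#'   `error_rate = 0`, `NA` when no locus is shared) and `n_loci` compared.
#' @export
lod_score <- function(g_off, g_mom, g_dad, freqs, error_rate = 0.1) {
  ok <- !is.na(g_off) & !is.na(g_mom) & !is.na(g_dad)
  if (!any(ok)) {
    return(list(lod = NA_real_, n_loci = 0L))
  }
  num <- trio_genotype_prob(g_off, g_mom, g_dad, freqs, error_rate)
  den <- trio_genotype_prob(g_off, g_mom, NULL, freqs, error_rate)
  list(lod = sum(log(num[ok]) - log(den[ok])), n_loci = sum(ok))
}

# Candidate dosage indicators used by the dense LOD engine: list of three
# C x L numeric matrices (dosage == k) plus the typed indicator.
.cand_indicators <- function(cand) {
  typed <- !is.na(cand)
  ind <- lapply(0:2, function(k) {
    m <- (cand == k)
    m[!typed] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  storage.mode(typed) <- "double"
  list(ind = ind, typed = typed)
}

# Dense LOD computation: progeny (n x L) against every candidate (C x L).
# mom_idx gives, per progeny, the row of `cand` holding its mother.
# Returns LOD (n x C) and the per-pair count of loci where offspring, mother
# and candidate are all typed. Loci missing in offspring or mother are
# skipped; candidate missingness enters through the indicator matrices.
.lod_matrix <- function(off, mom_idx, cand, freqs, error_rate,
                        indicators = NULL, tabs = NULL) {
  if (is.null(tabs)) tabs <- .trio_tables(error_rate)
  if (is.null(indicators)) indicators <- .cand_indicators(cand)
  n <- nrow(off)
  L <- ncol(off)
  lnum <- log(pmax(tabs$dad_obs, 1e-300)) # 3 x 3 x 3
  lden <- log(pmax(.pool_table(tabs, freqs), 1e-300)) # 3 x 3 x L
  mom <- cand[mom_idx, , drop = FALSE]
  ok <- !is.na(off) & !is.na(mom)
  o <- off
  o[!ok] <- 0L
  m <- mom
  m[!ok] <- 0L
  base <- o + 3L * m # 0..8 index into the (off, mom) slice
  # flatten index matrices: a matrix index whose width equals the array
  # dimensionality would otherwise be read as coordinate rows
  den_idx <- as.vector(base + rep(9L * (seq_len(L) - 1L), each = n)) + 1L
  vden <- matrix(lden[den_idx], n, L)
  lod <- matrix(0, n, nrow(cand))
  for (k in 0:2) {
    vk <- matrix(lnum[as.vector(base) + 9L * k + 1L], n, L) - vden
    vk[!ok] <- 0
    lod <- lod + vk %*% t(indicators$ind[[k + 1]])
  }
  okn <- ok
  storage.mode(okn) <- "double"
  nloci <- okn %*% t(indicators$typed)
  dimnames(lod) <- list(rownames(off), rownames(cand))
  list(lod = lod, n_loci = nloci)
}
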