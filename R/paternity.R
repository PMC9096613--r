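# Categorical LOD-based paternity assignment with known mothers,
# simulation-calibrated confidence thresholds, and paternal-contribution
# summaries.

#' LOD model configuration
#'
#' @param error_rate assumed per-call mistyping probability used in the trio
#'   likelihoods (the analysis default of 0.10 matches the maximum missing
#'   proportion allowed during SNP filtering; it deliberately conflates
#'   mistyping with missingness and is configurable).
#' @param min_loci minimum number of loci at which progeny, mother and
#'   candidate must all be typed for an assignment.
#' @return list of class `lod_model`.
#' @export
lod_model <- function(error_rate = 0.10, min_loci = 300) {
  stopifnot(error_rate >= 0, error_rate < 0.5, min_loci >= 1)
  structure(list(error_rate = error_rate, min_loci = as.integer(min_loci)),
            class = "lod_model")
}

#' Simulation-calibrated LOD confidence thresholds
#'
#' Simulates offspring from random mother x father pairs drawn from the
#' candidate pool under the genotyping-error/typing model, computes each
#' offspring's best-candidate LOD with the true father present in the
#' evaluated candidate set with probability `prop_candidates_sampled`, and
#' returns the lowest LOD thresholds at which assignments are correct at the
#' strict (95%) and relaxed (80%) rates.
#'
#' @param candidates candidate dosage matrix (the pollen pool).
#' @param model a [lod_model()].
#' @param freqs pollen-pool allele frequencies (default: from `candidates`).
#' @param n_offspring simulated offspring count.
#' @param prop_candidates_sampled probability the true father is in the
#'   evaluated candidate set (default 749/771, the genotyped fraction of
#'   planted genets).
#' @param prop_loci_typed per-call typing rate applied to simulated offspring
#'   (default: the observed typing rate of the candidates).
#' @param strict,relaxed target assignment-accuracy levels.
#' @param seed integer seed (thresholds are deterministic given it).
#' @param chunk offspring block size for the dense LOD computation.
#' @return object of class `confidence_thresholds` with `lod_strict`,
#'   `lod_relaxed` and simulation diagnostics.
#' @export
calibrate_confidence <- function(candidates, model = lod_model(),
                                 freqs = NULL, n_offspring = 10000,
                                 prop_candidates_sampled = 749 / 771,
                                 prop_loci_typed = NULL,
                                 strict = 0.95, relaxed = 0.80,
                                 seed = 1, chunk = 500) {
  .validate_gm(candidates)
  nC <- nrow(candidates)
  if (nC < 3) stop("insufficient candidates for calibration")
  L <- ncol(candidates)
  if (is.null(freqs)) freqs <- allele_frequencies(candidates)
  if (is.null(prop_loci_typed)) prop_loci_typed <- mean(!is.na(candidates))
  set.seed(as.integer(seed))
  tabs <- .trio_tables(model$error_rate)
  indicators <- .cand_indicators(candidates)
  pfill <- ifelse(is.na(freqs) | freqs <= 0 | freqs >= 1, 0.5, freqs)

  best_lod <- numeric(n_offspring)
  best_n <- numeric(n_offspring)
  correct <- logical(n_offspring)
  father_present <- stats::runif(n_offspring) < prop_candidates_sampled
  done <- 0L
  while (done < n_offspring) {
    nb <- min(chunk, n_offspring - done)
    rows <- done + seq_len(nb)
    mom_i <- sample.int(nC, nb, replace = TRUE)
    dad_i <- sample.int(nC, nb, replace = TRUE)
    clash <- dad_i == mom_i
    while (any(clash)) {
      dad_i[clash] <- sample.int(nC, sum(clash), replace = TRUE)
      clash <- dad_i == mom_i
    }
    gam <- function(idx) {
      dos <- candidates[idx, , drop = FALSE] * 1.0
      miss <- is.na(dos)
      if (any(miss)) {
        dos[miss] <- 2 * rep(pfill, each = nb)[miss] # population draw
      }
      matrix(stats::rbinom(nb * L, 1L, dos / 2), nb, L)
    }
    off <- gam(mom_i) + gam(dad_i)
    flip <- matrix(stats::runif(nb * L) < model$error_rate, nb, L)
    if (any(flip)) {
      off[flip] <- (off[flip] + sample(1:2, sum(flip), replace = TRUE)) %% 3L
    }
    off[matrix(stats::runif(nb * L) > prop_loci_typed, nb, L)] <- NA
    res <- .lod_matrix(off, mom_i, candidates, freqs, model$error_rate,
                       indicators = indicators, tabs = tabs)
    lod <- res$lod
    # mother is not a candidate for her own simulated outcross offspring
    lod[cbind(seq_len(nb), mom_i)] <- -Inf
    absent <- !father_present[rows]
    if (any(absent)) lod[cbind(which(absent), dad_i[absent])] <- -Inf
    bi <- max.col(lod, ties.method = "first")
    best_lod[rows] <- lod[cbind(seq_len(nb), bi)]
    best_n[rows] <- res$n_loci[cbind(seq_len(nb), bi)]
    correct[rows] <- bi == dad_i & father_present[rows]
    done <- done + nb
  }
  eligible <- best_n >= model$min_loci
  thr <- function(level) {
    lod <- best_lod[eligible]
    corr <- correct[eligible]
    o <- order(lod, decreasing = TRUE)
    prec <- cumsum(corr[o]) / seq_along(o)
    i <- which(prec >= level)
    if (!length(i)) return(Inf)
    lod[o][max(i)]
  }
  lod_strict <- thr(strict)
  lod_relaxed <- min(thr(relaxed), lod_strict)
  structure(list(
    lod_strict = lod_strict, lod_relaxed = max(lod_relaxed, -Inf),
    sim = list(n_offspring = n_offspring, n_candidates = nC,
               prop_candidates_sampled = prop_candidates_sampled,
               prop_loci_typed = prop_loci_typed,
               error_rate = model$error_rate, seed = seed,
               assignment_rate_strict = mean(best_lod >= lod_strict & eligible),
               assignment_rate_relaxed = mean(best_lod >= lod_relaxed & eligible))
  ), class = "confidence_thresholds")
}

#' @export
print.confidence_thresholds <- function(x, ...) {
  cat(sprintf("LOD confidence thresholds (simulated, n = %d offspring)\n",
              x$sim$n_offspring))
  cat(sprintf("  strict (95%%): %.3f   relaxed (80%%): %.3f\n",
              x$lod_strict, x$lod_relaxed))
  cat(sprintf("  expected assignment rate at strict threshold: %.1f%%\n",
              100 * x$sim$assignment_rate_strict))
  invisible(x)
}

#' Assign paternity to progeny with known mothers
#'
#' For every progeny, the LOD score against every candidate (including the
#' mother herself, so selfing is detectable) is computed over the loci at
#' which progeny, mother and candidate are all typed. The best candidate is
#' assigned at strict or relaxed confidence if its LOD reaches the calibrated
#' threshold and at least `min_loci` loci were compared. LOD ties are broken
#' by the larger locus count; remaining ties are left unassigned and flagged.
#'
#' @param progeny progeny dosage matrix.
#' @param families data frame (progeny_id, mother_id); progeny without a known
#'   mother are skipped with a warning.
#' @param candidates candidate dosage matrix; mothers must be rows of it.
#' @param model a [lod_model()].
#' @param thresholds a [calibrate_confidence()] result, or `NULL` for the
#'   uncalibrated rule "best candidate with LOD > 0" (labelled relaxed).
#' @param freqs pollen-pool allele frequencies (default: from `candidates`).
#' @return data frame of class `paternity_table`: progeny_id, mother_id,
#'   father_id (NA when unassigned), lod, delta (LOD gap to the second-best
#'   candidate — reported for inspection but deliberately never used for
#'   assignment, since adjacently planted half-sib candidates make near-ties
#'   expected), n_loci_compared, confidence (strict95 / relaxed80 /
#'   unassigned), tie flag.
#' @export
assign_paternity <- function(progeny, families, candidates,
                             model = lod_model(), thresholds = NULL,
                             freqs = NULL) {
  .validate_gm(progeny)
  .validate_gm(candidates)
  if (is.null(freqs)) freqs <- allele_frequencies(candidates)
  known <- families$progeny_id %in% rownames(progeny) &
    families$mother_id %in% rownames(candidates)
  miss_mom <- setdiff(rownames(progeny), families$progeny_id[known])
  if (length(miss_mom)) {
    warning(length(miss_mom), " progeny without a known genotyped mother were skipped")
  }
  fam <- families[known, , drop = FALSE]
  tabs <- .trio_tables(model$error_rate)
  indicators <- .cand_indicators(candidates)
  lod_strict <- if (is.null(thresholds)) 0 else thresholds$lod_strict
  lod_relaxed <- if (is.null(thresholds)) 0 else thresholds$lod_relaxed

  res <- lapply(split(fam$progeny_id, fam$mother_id), function(pids) {
    mom <- fam$mother_id[match(pids[1], fam$progeny_id)]
    off <- progeny[pids, , drop = FALSE]
    mrow <- match(mom, rownames(candidates))
    lm <- .lod_matrix(off, rep(mrow, length(pids)), candidates, freqs,
                      model$error_rate, indicators = indicators, tabs = tabs)
    n <- length(pids)
    best <- integer(n)
    tie <- logical(n)
    delta <- numeric(n)
    for (i in seq_len(n)) {
      l <- lm$lod[i, ]
      top <- max(l)
      cand <- which(l >= top - 1e-9)
      if (length(cand) > 1) {
        nl <- lm$n_loci[i, cand]
        cand <- cand[nl == max(nl)]
        if (length(cand) > 1) tie[i] <- TRUE
      }
      best[i] <- cand[1]
      delta[i] <- top - max(l[-best[i]])
    }
    lod <- lm$lod[cbind(seq_len(n), best)]
    nlc <- lm$n_loci[cbind(seq_len(n), best)]
    conf <- rep("unassigned", n)
    ok <- nlc >= model$min_loci & !tie & is.finite(lod)
    conf[ok & lod >= lod_relaxed] <- "relaxed80"
    conf[ok & lod >= lod_strict] <- "strict95"
    data.frame(progeny_id = pids, mother_id = mom,
               father_id = ifelse(conf == "unassigned", NA_character_,
                                  rownames(candidates)[best]),
               lod = lod, delta = delta, n_loci_compared = as.integer(nlc),
               confidence = conf, tie = tie, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(res))
  rownames(out) <- NULL
  class(out) <- c("paternity_table", "data.frame")
  out
}

#' @export
print.paternity_table <- function(x, ...) {
  cat(sprintf("Paternity table: %d progeny, %d mothers\n", nrow(x),
              length(unique(x$mother_id))))
  print(table(confidence = x$confidence))
  NextMethod(x, ...)
}

#' Summaries of paternal contribution
#'
#' Per-mother father counts, unique fathers, unique parent pairs, progeny per
#' pair and per father, assigned/unassigned counts and the fraction of
#' father events that are half-sibs of the mother (same family).
#'
#' @param pt a [assign_paternity()] table.
#' @param candidate_families optional data frame (genet_id, family_id) for the
#'   half-sib flag.
#' @param confidence confidence classes counted as assigned.
#' @return list of summary statistics (class `paternity_summary`).
#' @export
paternity_summary <- function(pt, candidate_families = NULL,
                              confidence = c("strict95")) {
  if (nrow(pt) == 0) stop("empty paternity table")
  asg <- pt[pt$confidence %in% confidence & !is.na(pt$father_id), , drop = FALSE]
  n_mothers <- length(unique(pt$mother_id))
  pair <- paste(asg$mother_id, asg$father_id, sep = "|")
  pair_counts <- table(pair)
  per_mother_fathers <- tapply(asg$father_id, asg$mother_id,
                               function(f) length(unique(f)))
  father_counts <- table(asg$father_id)
  half_sib_fraction <- NA_real_
  if (!is.null(candidate_families)) {
    fam_of <- stats::setNames(candidate_families$family_id,
                              candidate_families$genet_id)
    pairs_df <- unique(asg[, c("mother_id", "father_id")])
    selfed <- pairs_df$mother_id == pairs_df$father_id
    hs <- fam_of[pairs_df$mother_id] == fam_of[pairs_df$father_id] & !selfed
    half_sib_fraction <- mean(hs, na.rm = TRUE)
  }
  out <- list(
    n_progeny = nrow(pt),
    n_assigned = nrow(asg),
    n_unassigned = nrow(pt) - nrow(asg),
    assigned_fraction = nrow(asg) / nrow(pt),
    mean_assigned_per_mother = nrow(asg) / n_mothers,
    mean_unassigned_per_mother = (nrow(pt) - nrow(asg)) / n_mothers,
    total_father_events = length(pair_counts),
    unique_fathers = length(father_counts),
    mean_fathers_per_mother = mean(per_mother_fathers),
    per_mother_fathers = per_mother_fathers,
    mean_progeny_per_pair = mean(pair_counts),
    max_progeny_per_pair = max(pair_counts),
    mean_progeny_per_father = mean(father_counts),
    selfing_assignments = sum(asg$mother_id == asg$father_id),
    half_sib_father_fraction = half_sib_fraction
  )
  class(out) <- "paternity_summary"
  out
}

#' @export
print.paternity_summary <- function(x, ...) {
  cat("Paternal contribution summary\n")
  cat(sprintf("  progeny assigned: %d / %d (%.1f%%)\n", x$n_assigned,
              x$n_progeny, 100 * x$assigned_fraction))
  cat(sprintf("  parent pairs: %d; unique fathers: %d; mean fathers/mother: %.1f\n",
              x$total_father_events, x$unique_fathers,
              x$mean_fathers_per_mother))
  cat(sprintf("  progeny per pair: mean %.2f, max %d\n",
              x$mean_progeny_per_pair, x$max_progeny_per_pair))
  invisible(x)
}

#' Aggregate nursery ratios from headline counts
#'
#' Derives the per-mother and per-pair summary ratios (assignment percentage,
#' mean assigned/unassigned per mother, progeny per parent pair, progeny per
#' father, fathers per mother) from the raw counts a parentage study reports.
#'
#' @param n_mothers mothers sampled.
#' @param n_progeny progeny genotyped.
#' @param n_assigned progeny with assigned paternity.
#' @param n_parent_pairs unique mother-father pairs.
#' @param n_unique_fathers unique paternal genets.
#' @return list of ratios.
#' @export
nursery_summary_ratios <- function(n_mothers, n_progeny, n_assigned,
                                   n_parent_pairs, n_unique_fathers) {
  list(
    assigned_pct = 100 * n_assigned / n_progeny,
    mean_progeny_per_mother = n_progeny / n_mothers,
    mean_assigned_per_mother = n_assigned / n_mothers,
    mean_unassigned_per_mother = (n_progeny - n_assigned) / n_mothers,
    mean_fathers_per_mother = n_parent_pairs / n_mothers,
    mean_progeny_per_pair = n_assigned / n_parent_pairs,
    mean_progeny_per_father = n_assigned / n_unique_fathers
  )
}

#' Nielsen unbiased effective number of fathers
#'
#' Moment estimator of the probability of paternal identity for one mother's
#' progeny array, `Q = sum x_i (x_i - 1) / (n (n - 1))`; the effective father
#' number is `1 / Q`. A non-positive `Q` is reported as unbounded (`Inf`) with
#' a flag.
#'
#' @param counts per-father progeny counts for one mother.
#' @return list with `Q`, `effective_fathers` and `unbounded` flag.
#' @export
nielsen_effective_fathers <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("at least two progeny are required")
  q <- sum(counts * (counts - 1)) / (n * (n - 1))
  list(Q = q, effective_fathers = if (q > 0) 1 / q else Inf, unbounded = q <= 0)
}

#' Kolmogorov-Smirnov test: realized versus available pollination distances
#'
#' Two-sample K-S test comparing the distances of realized pollination events
#' with the distances of all available pollen donors, pooled across mothers.
#'
#' @param realized distances of assigned father-mother pairs (meters).
#' @param available distances of all candidate donors from the mothers.
#' @return list with `D` statistic and asymptotic `p_value`.
#' @export
ks_progeny_vs_distance <- function(realized, available) {
  if (!length(realized) || !length(available)) stop("both samples must be nonempty")
  kt <- suppressWarnings(stats::ks.test(realized, available))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
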