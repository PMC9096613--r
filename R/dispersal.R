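# Distance and direction statistics of realized pollination events, distance
# bins, per-bin diversity, protected LSD tests and paternal trait
# correlations.

.SECTORS <- c("N", "NNE", "NE", "ENE", "E", "ESE", "SE", "SSE",
              "S", "SSW", "SW", "WSW", "W", "WNW", "NW", "NNW")

#' Build dispersal records from assigned paternity
#'
#' One record per assigned progeny: Euclidean mother-father distance in
#' meters, bearing from mother to father (degrees clockwise from North), the
#' 22.5-degree compass sector, and a half-sib flag (father belongs to the
#' mother's family). Selfing assignments (father = mother) are excluded by
#' default since their zero distance would distort dispersal moments; their
#' count is kept in the `n_selfing` attribute.
#'
#' @param pt a [assign_paternity()] table.
#' @param map field map with genet coordinates.
#' @param candidate_families data frame (genet_id, family_id).
#' @param confidence confidence classes to keep.
#' @param include_self keep selfing records (distance 0).
#' @return data frame of class `dispersal_records`.
#' @export
build_dispersal_records <- function(pt, map, candidate_families = NULL,
                                    confidence = "strict95",
                                    include_self = FALSE) {
  asg <- pt[pt$confidence %in% confidence & !is.na(pt$father_id), , drop = FALSE]
  n_self <- sum(asg$father_id == asg$mother_id)
  if (!include_self) asg <- asg[asg$father_id != asg$mother_id, , drop = FALSE]
  mi <- match(asg$mother_id, map$genet_id)
  fi <- match(asg$father_id, map$genet_id)
  drop <- is.na(mi) | is.na(fi)
  if (any(drop)) {
    warning(sum(drop), " records skipped: parent missing from the field map")
    asg <- asg[!drop, , drop = FALSE]
    mi <- mi[!drop]
    fi <- fi[!drop]
  }
  dx <- map$x_m[fi] - map$x_m[mi]
  dy <- map$y_m[fi] - map$y_m[mi]
  dist <- sqrt(dx^2 + dy^2)
  bearing <- (atan2(dx, dy) * 180 / pi) %% 360
  sector <- .SECTORS[(floor(((bearing + 11.25) %% 360) / 22.5) %% 16) + 1]
  is_hs <- rep(NA, nrow(asg))
  if (!is.null(candidate_families)) {
    fam_of <- stats::setNames(candidate_families$family_id,
                              candidate_families$genet_id)
    is_hs <- unname(fam_of[asg$mother_id] == fam_of[asg$father_id]) &
      asg$mother_id != asg$father_id
  }
  out <- data.frame(progeny_id = asg$progeny_id, mother_id = asg$mother_id,
                    father_id = asg$father_id, distance_m = dist,
                    bearing_deg = bearing, sector = sector,
                    is_half_sib_father = is_hs, stringsAsFactors = FALSE)
  attr(out, "n_selfing") <- n_self
  class(out) <- c("dispersal_records", "data.frame")
  out
}

#' Axial dispersal standard deviation
#'
#' `M` is the mean squared mother-father distance and the axial standard
#' deviation of pollen dispersal is `sigma = sqrt(M / 2)`.
#'
#' @param distances realized pollination distances in meters.
#' @return list with `M` (m^2) and `sigma_pollen_m`.
#' @export
axial_sigma <- function(distances) {
  if (!length(distances)) stop("at least one distance is required")
  m <- mean(distances^2)
  list(M = m, sigma_pollen_m = sqrt(m / 2))
}

#' Compass-sector analysis of pollination direction
#'
#' Counts unique mother-father pairs per 22.5-degree compass sector and
#' reports the Pearson correlation between sector index and pollination
#' distance.
#'
#' @param records a [build_dispersal_records()] table.
#' @return list with `sector_counts` (named, all 16 sectors), the modal
#'   sector, and `distance_direction_cor` (estimate, p_value).
#' @export
sector_analysis <- function(records) {
  if (!nrow(records)) stop("no dispersal records")
  pairs <- records[!duplicated(paste(records$mother_id, records$father_id)), ,
                   drop = FALSE]
  counts <- table(factor(pairs$sector, levels = .SECTORS))
  ddc <- c(r = NA_real_, p_value = NA_real_)
  if (nrow(pairs) >= 3 && stats::sd(pairs$distance_m) > 0 &&
      length(unique(pairs$sector)) > 1) {
    ct <- suppressWarnings(
      stats::cor.test(match(pairs$sector, .SECTORS), pairs$distance_m)
    )
    ddc <- c(r = unname(ct$estimate), p_value = ct$p.value)
  }
  list(sector_counts = counts,
       modal_sector = names(counts)[which.max(counts)],
       distance_direction_cor = ddc)
}

#' Bin dispersal records by distance
#'
#' Left-closed, right-open bins of `width_m` meters starting at zero
#' (`[0, 3), [3, 6), ...`).
#'
#' @param records a [build_dispersal_records()] table.
#' @param width_m bin width in meters.
#' @return list with `bin` (factor per record), `levels` labels and `counts`.
#' @export
bin_by_distance <- function(records, width_m = 3) {
  if (width_m <= 0) stop("bin width must be positive")
  top <- max(records$distance_m)
  breaks <- seq(0, (floor(top / width_m) + 1) * width_m, by = width_m)
  labels <- sprintf("%g-%g", breaks[-length(breaks)], breaks[-1])
  bin <- cut(records$distance_m, breaks = breaks, labels = labels,
             right = FALSE, include.lowest = FALSE)
  list(bin = bin, levels = labels, counts = table(bin))
}

#' Per-bin diversity table
#'
#' For each distance bin: progeny count, mean pairwise IBS genetic distance,
#' mean pairwise Nei distance among progeny, and Shannon diversity plus
#' rarefaction richness of the per-father progeny-count community. Bins with
#' fewer than two progeny get NA statistics.
#'
#' @param records a [build_dispersal_records()] table.
#' @param progeny progeny dosage matrix.
#' @param width_m bin width in meters.
#' @param rarefaction_depth reference depth (default: the smallest bin count,
#'   but at least 2).
#' @return data frame of class `distance_bin_table`.
#' @export
per_bin_diversity <- function(records, progeny, width_m = 3,
                              rarefaction_depth = NULL) {
  bins <- bin_by_distance(records, width_m)
  counts <- as.integer(bins$counts)
  if (is.null(rarefaction_depth)) {
    rarefaction_depth <- max(2L, min(counts[counts > 0]))
  }
  rows <- lapply(seq_along(bins$levels), function(i) {
    lab <- bins$levels[i]
    rec <- records[which(bins$bin == lab), , drop = FALSE]
    n <- nrow(rec)
    fathers <- table(rec$father_id)
    if (n >= 2) {
      ids <- intersect(rec$progeny_id, rownames(progeny))
      gd <- ibs_dissimilarity(progeny, ids)
      nd <- nei_pairwise_mean(progeny, ids)
      sh <- shannon_index(as.numeric(fathers))
      rf <- rarefaction_richness(as.numeric(fathers),
                                 min(rarefaction_depth, n))
    } else {
      gd <- nd <- sh <- rf <- NA_real_
    }
    data.frame(bin = lab, n_progeny = n, n_fathers = length(fathers),
               genetic_distance = gd, nei_d = nd, shannon_h = sh,
               rarefaction = rf, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rarefaction_depth") <- rarefaction_depth
  class(out) <- c("distance_bin_table", "data.frame")
  out
}

# compact letter display from a logical "not significantly different" matrix
# over groups sorted by decreasing mean
.cld <- function(nonsig) {
  k <- nrow(nonsig)
  runs <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nonsig[i:j, j + 1])) j <- j + 1
    runs[[i]] <- i:j
  }
  keep <- rep(TRUE, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j && keep[j] && all(runs[[i]] %in% runs[[j]]) &&
          (length(runs[[i]]) < length(runs[[j]]) || i > j)) {
        keep[i] <- FALSE
      }
    }
  }
  runs <- runs[keep]
  lab <- rep("", k)
  for (r in seq_along(runs)) {
    lab[runs[[r]]] <- paste0(lab[runs[[r]]], letters[r])
  }
  lab
}

#' Fisher's protected LSD test with compact letter display
#'
#' One-way analysis of variance followed by pairwise least-significant-
#' difference comparisons at level `alpha`. By default the pairwise
#' comparisons are protected: they are declared only when the ANOVA F test is
#' itself significant at `alpha`, which keeps the null rejection rate at the
#' nominal level; `protected = FALSE` gives the unprotected variant. Groups
#' sharing a letter are not significantly different.
#'
#' @param values numeric observations.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level.
#' @param protected gate the pairwise comparisons on the ANOVA F test.
#' @return list with per-group means, letter groups, the pairwise significance
#'   matrix, the ANOVA p-value and the residual mean square.
#' @export
lsd_test <- function(values, groups, alpha = 0.05, protected = TRUE) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(as.factor(groups[ok]))
  k <- nlevels(groups)
  if (k < 2) stop("at least two groups are required")
  ni <- table(groups)
  if (all(ni < 2)) stop("at least one group needs two observations")
  fit <- stats::aov(values ~ groups)
  an <- suppressWarnings(stats::anova(fit)) # zero-residual fits are handled below
  mse <- an[["Mean Sq"]][2]
  dfe <- an[["Df"]][2]
  p_f <- an[["Pr(>F)"]][1]
  means <- tapply(values, groups, mean)
  ord <- order(means, decreasing = TRUE)
  means <- means[ord]
  ni <- ni[ord]
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  sig <- matrix(FALSE, k, k, dimnames = list(names(means), names(means)))
  if (mse > 0) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        lsd <- tcrit * sqrt(mse * (1 / ni[i] + 1 / ni[j]))
        sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) > lsd
      }
    }
  } else {
    # zero residual variance: groups differ exactly when their means differ
    sig <- abs(outer(means, means, `-`)) > 1e-12
  }
  if (protected && !is.na(p_f) && p_f >= alpha) sig[] <- FALSE
  letters_out <- .cld(!sig)
  list(
    groups = data.frame(group = names(means), mean = as.numeric(means),
                        n = as.integer(ni), letters = letters_out,
                        singleton = as.integer(ni) < 2, row.names = NULL),
    significant = sig, anova_p = p_f, mse = mse, alpha = alpha,
    any_difference = any(sig)
  )
}

#' Correlations between paternal traits and pollination success
#'
#' Pearson correlations (with p-values) between each paternal trait and (i)
#' the number of progeny fathered and (ii) the mean pollination distance.
#'
#' @param records a [build_dispersal_records()] table.
#' @param phenotypes data frame with a `genet_id` column and one column per
#'   trait.
#' @return data frame (trait, statistic, r, p_value); constant vectors yield
#'   NA with a flag.
#' @export
father_trait_correlations <- function(records, phenotypes) {
  cnt <- table(records$father_id)
  dst <- tapply(records$distance_m, records$father_id, mean)
  ids <- intersect(names(cnt), phenotypes$genet_id)
  if (length(ids) < 3) stop("at least three fathers with phenotypes are required")
  ph <- phenotypes[match(ids, phenotypes$genet_id), , drop = FALSE]
  traits <- setdiff(names(ph), "genet_id")
  rows <- list()
  for (tr in traits) {
    for (stat in c("progeny_count", "mean_distance_m")) {
      x <- if (stat == "progeny_count") as.numeric(cnt[ids]) else as.numeric(dst[ids])
      y <- ph[[tr]]
      if (stats::sd(x) == 0 || stats::sd(y, na.rm = TRUE) == 0) {
        rows[[length(rows) + 1]] <- data.frame(trait = tr, statistic = stat,
                                               r = NA_real_, p_value = NA_real_,
                                               constant = TRUE)
      } else {
        ct <- stats::cor.test(x, y)
        rows[[length(rows) + 1]] <- data.frame(trait = tr, statistic = stat,
                                               r = unname(ct$estimate),
                                               p_value = ct$p.value,
                                               constant = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Distance profile of half-sib versus unrelated fathers
#'
#' @param records a [build_dispersal_records()] table carrying half-sib flags.
#' @param cutoffs_m distances at which cumulative fractions are reported.
#' @return list with the overall half-sib father fraction, per-class distance
#'   summaries and, per class, the fraction of events within each cutoff.
#' @export
half_sib_profile <- function(records, cutoffs_m = c(0.92, 1.8, 5, 10)) {
  if (all(is.na(records$is_half_sib_father))) {
    stop("records carry no half-sib flags; supply candidate_families when building them")
  }
  hs <- records$is_half_sib_father
  frac_within <- function(d) {
    sapply(cutoffs_m, function(cc) mean(d <= cc))
  }
  by_class <- lapply(split(records$distance_m, hs), function(d) {
    list(n = length(d), mean_m = mean(d), median_m = stats::median(d),
         within = stats::setNames(frac_within(d), paste0("<=", cutoffs_m, "m")))
  })
  list(half_sib_fraction = mean(hs, na.rm = TRUE),
       n_half_sib = sum(hs, na.rm = TRUE),
       n_other = sum(!hs, na.rm = TRUE),
       by_class = by_class)
}

#' Dispersal summary
#'
#' Mean/median/min/max pollination distance, mean squared distance `M`, the
#' axial standard deviation, the K-S test of realized versus available donor
#' distances, per-sector father counts and the fraction of events within the
#' given cutoffs.
#'
#' @param records a [build_dispersal_records()] table.
#' @param map field map (used for the available-donor distance distribution).
#' @param cutoffs_m distance cutoffs for cumulative fractions.
#' @return list of class `dispersal_summary`.
#' @export
dispersal_summary <- function(records, map = NULL, cutoffs_m = c(5, 10)) {
  d <- records$distance_m
  ax <- axial_sigma(d)
  ks <- NULL
  if (!is.null(map)) {
    avail <- unlist(lapply(unique(records$mother_id), function(mom) {
      mrow <- match(mom, map$genet_id)
      dd <- sqrt((map$x_m - map$x_m[mrow])^2 + (map$y_m - map$y_m[mrow])^2)
      dd[-mrow]
    }))
    ks <- ks_progeny_vs_distance(d, avail)
  }
  out <- list(
    n = length(d), mean_m = mean(d), median_m = stats::median(d),
    min_m = min(d), max_m = max(d), M = ax$M,
    sigma_pollen_m = ax$sigma_pollen_m, ks = ks,
    fraction_within = stats::setNames(
      sapply(cutoffs_m, function(cc) mean(d <= cc)),
      paste0("<=", cutoffs_m, "m")
    ),
    sectors = sector_analysis(records)$sector_counts
  )
  class(out) <- "dispersal_summary"
  out
}

#' @export
print.dispersal_summary <- function(x, ...) {
  cat("Pollen dispersal summary\n")
  cat(sprintf("  events: %d; distance mean %.2f m, median %.2f m, range %.2f-%.2f m\n",
              x$n, x$mean_m, x$median_m, x$min_m, x$max_m))
  cat(sprintf("  sigma_pollen = sqrt(M/2) = %.2f m (M = %.2f m^2)\n",
              x$sigma_pollen_m, x$M))
  for (nm in names(x$fraction_within)) {
    cat(sprintf("  fraction %s: %.1f%%\n", nm, 100 * x$fraction_within[nm]))
  }
  if (!is.null(x$ks)) {
    cat(sprintf("  K-S realized vs available: D = %.4f, p = %.3g\n",
                x$ks$D, x$ks$p_value))
  }
  invisible(x)
}

#' @export
plot.dispersal_records <- function(x, breaks = 20, ...) {
  graphics::hist(x$distance_m, breaks = breaks,
                 main = "Realized pollination distances",
                 xlab = "mother-father distance (m)", ...)
  graphics::abline(v = mean(x$distance_m), lwd = 2)
  graphics::abline(v = stats::median(x$distance_m), lty = 2)
  invisible(x)
}
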