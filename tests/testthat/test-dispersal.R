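# Dispersal records, axial sigma, sectors, distance bins, protected LSD and
# half-sib profiles.

toy_setup <- function() {
  map <- data.frame(
    genet_id = c("M", "N", "E", "FAR", "HS"),
    family_id = c("F1", "F2", "F3", "F4", "F1"),
    role = "candidate",
    grid_row = 0, grid_col = 0,
    x_m = c(0, 0, 3, 9, 0),
    y_m = c(0, 4, 0, 12, 0.91)
  )
  pt <- data.frame(
    progeny_id = sprintf("p%d", 1:4),
    mother_id = "M",
    father_id = c("N", "E", "FAR", "HS"),
    lod = 10, n_loci_compared = 400L,
    confidence = "strict95", tie = FALSE,
    stringsAsFactors = FALSE
  )
  class(pt) <- c("paternity_table", "data.frame")
  list(map = map, pt = pt)
}

test_that("dispersal records carry exact distances, bearings and flags", {
  ts <- toy_setup()
  rec <- build_dispersal_records(ts$pt, ts$map,
                                 ts$map[, c("genet_id", "family_id")])
  expect_equal(rec$distance_m[rec$father_id == "N"], 4) # due North
  expect_equal(rec$bearing_deg[rec$father_id == "N"], 0)
  expect_equal(rec$bearing_deg[rec$father_id == "E"], 90)
  expect_equal(rec$distance_m[rec$father_id == "FAR"], sqrt(9^2 + 12^2))
  expect_equal(rec$distance_m[rec$father_id == "HS"], 0.91)
  expect_true(rec$is_half_sib_father[rec$father_id == "HS"])
  expect_false(any(rec$is_half_sib_father[rec$father_id != "HS"]))
  expect_equal(rec$sector[rec$father_id == "N"], "N")
  expect_equal(rec$sector[rec$father_id == "E"], "E")
})

test_that("selfing assignments are excluded from distance records by default", {
  ts <- toy_setup()
  ts$pt$father_id[1] <- "M"
  rec <- build_dispersal_records(ts$pt, ts$map)
  expect_equal(nrow(rec), 3)
  expect_equal(attr(rec, "n_selfing"), 1)
  with_self <- build_dispersal_records(ts$pt, ts$map, include_self = TRUE)
  expect_equal(nrow(with_self), 4)
  expect_equal(min(with_self$distance_m), 0)
})

test_that("axial sigma follows the closed form", {
  expect_equal(axial_sigma(c(3, 4))$M, 12.5)
  expect_equal(axial_sigma(c(3, 4))$sigma_pollen_m, 2.5)
  d <- 7.3
  expect_equal(axial_sigma(rep(d, 10))$sigma_pollen_m, d / sqrt(2))
  base <- axial_sigma(c(1, 2, 5))$sigma_pollen_m
  expect_equal(axial_sigma(3 * c(1, 2, 5))$sigma_pollen_m, 3 * base)
  expect_error(axial_sigma(numeric(0)), "at least one")
})

test_that("sector analysis counts parent pairs and correlates with distance", {
  ts <- toy_setup()
  rec <- build_dispersal_records(ts$pt, ts$map)
  sa <- sector_analysis(rec)
  expect_equal(sum(sa$sector_counts), nrow(rec))
  north_only <- rec[rec$father_id == "N", ]
  expect_equal(unname(sector_analysis(north_only)$sector_counts["N"]), 1)
  # correlation oracle on constructed records
  rec2 <- rec
  rec2$distance_m <- match(rec2$sector, pollenkin:::.SECTORS) * 2 # perfect rank link
  expect_equal(unname(sector_analysis(rec2)$distance_direction_cor["r"]), 1)
})

test_that("distance bins are left-closed right-open and conserve counts", {
  rec <- data.frame(progeny_id = sprintf("p%d", 1:5), mother_id = "M",
                    father_id = sprintf("f%d", 1:5),
                    distance_m = c(0.5, 3, 5.999, 6, 14.2))
  bins <- bin_by_distance(rec, 3)
  expect_equal(as.character(bins$bin),
               c("0-3", "3-6", "3-6", "6-9", "12-15"))
  expect_equal(sum(bins$counts), 5)
  # brute-force comparison loop
  for (i in seq_len(5)) {
    lo <- 3 * (match(as.character(bins$bin[i]), bins$levels) - 1)
    expect_true(rec$distance_m[i] >= lo && rec$distance_m[i] < lo + 3)
  }
})

test_that("per-bin diversity composes the diversity-module statistics", {
  sim <- tiny_nursery(seed = 51, n_mothers = 3, progeny = 25, n_loci = 200)
  pt <- assign_paternity(sim$progeny, sim$families, sim$founders$genotypes,
                         lod_model(error_rate = 0.05, min_loci = 50),
                         thresholds = NULL)
  rec <- build_dispersal_records(pt, sim$founders$map,
                                 sim$founders$families)
  tab <- per_bin_diversity(rec, sim$progeny, width_m = 3)
  expect_equal(sum(tab$n_progeny), nrow(rec))
  bins <- bin_by_distance(rec, 3)
  busy <- which(tab$n_progeny >= 2)[1]
  ids <- rec$progeny_id[which(bins$bin == tab$bin[busy])]
  fathers <- table(rec$father_id[which(bins$bin == tab$bin[busy])])
  expect_equal(tab$genetic_distance[busy], ibs_dissimilarity(sim$progeny, ids))
  expect_equal(tab$shannon_h[busy], shannon_index(as.numeric(fathers)))
  expect_equal(tab$rarefaction[busy],
               rarefaction_richness(as.numeric(fathers),
                                    min(attr(tab, "rarefaction_depth"),
                                        length(ids))))
  # a bin fathered by a single donor has zero community diversity
  one <- rec[rec$father_id == rec$father_id[1], ][1, , drop = FALSE]
  one <- rbind(one, one)
  one$progeny_id <- c("x1", "x2")
  rownames(sim$progeny)[1:2] <- c("x1", "x2")
  tab1 <- per_bin_diversity(one, sim$progeny, width_m = 3)
  busy1 <- which(tab1$n_progeny == 2)
  expect_equal(tab1$shannon_h[busy1], 0)
  expect_equal(tab1$rarefaction[busy1], 1)
})

test_that("protected LSD separates what it should and letters are consistent", {
  set.seed(2)
  same <- c(rnorm(10, 0), rnorm(10, 0))
  g <- rep(c("a", "b"), each = 10)
  res_same <- lsd_test(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3) ,
                       alpha = 0.05)
  # identical group values: same letter
  res_eq <- lsd_test(rep(c(5, 5), each = 4), rep(c("a", "b"), each = 4))
  expect_equal(res_eq$groups$letters, c("a", "a"))
  # strongly separated groups: different letters
  far <- lsd_test(c(rnorm(8, 0, 0.1), rnorm(8, 10, 0.1)),
                  rep(c("a", "b"), each = 8))
  expect_false(any(far$groups$letters[1] == far$groups$letters[2]))
  # pairwise decisions match t statistics computed independently
  set.seed(3)
  vals <- c(rnorm(6, 0), rnorm(6, 1.1), rnorm(6, 5))
  grp <- rep(c("a", "b", "c"), each = 6)
  res <- lsd_test(vals, grp, alpha = 0.05, protected = FALSE)
  fit <- aov(vals ~ grp)
  mse <- anova(fit)[["Mean Sq"]][2]
  dfe <- anova(fit)[["Df"]][2]
  for (i in 1:2) for (j in (i + 1):3) {
    gi <- res$groups$group[i]
    gj <- res$groups$group[j]
    tstat <- abs(mean(vals[grp == gi]) - mean(vals[grp == gj])) /
      sqrt(mse * (1 / 6 + 1 / 6))
    expect_equal(unname(res$significant[gi, gj]),
                 tstat > qt(0.975, dfe))
  }
})

test_that("LSD null rejection rate calibrates at the nominal level", {
  set.seed(9)
  rejections <- replicate(400, {
    vals <- rnorm(36)
    lsd_test(vals, rep(letters[1:4], each = 9), alpha = 0.05)$any_difference
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.03)
})

test_that("father trait correlations match direct covariance arithmetic", {
  ts <- toy_setup()
  rec <- build_dispersal_records(ts$pt, ts$map)
  rec <- rbind(rec, rec, rec) # three progeny per father
  rec$progeny_id <- sprintf("p%d", seq_len(nrow(rec)))
  cnt <- table(rec$father_id)
  set.seed(4)
  # progeny counts vary across fathers: drop one record of one father
  rec <- rec[-1, ]
  cnt <- table(rec$father_id)
  ph <- data.frame(genet_id = names(cnt),
                   height = as.numeric(cnt), # trait equals progeny count
                   other = rnorm(length(cnt)))
  res <- father_trait_correlations(rec, ph)
  expect_equal(res$r[res$trait == "height" &
                       res$statistic == "progeny_count"], 1)
  other_r <- res$r[res$trait == "other" & res$statistic == "mean_distance_m"]
  dst <- tapply(rec$distance_m, rec$father_id, mean)
  expect_equal(other_r, unname(cor(as.numeric(dst[names(cnt)]), ph$other)))
  ph$flat <- 1
  res_flat <- father_trait_correlations(rec, ph)
  expect_true(all(is.na(res_flat$r[res_flat$trait == "flat"])))
  expect_true(all(res_flat$constant[res_flat$trait == "flat"]))
})

test_that("half-sib profile fractions equal brute-force filtering", {
  ts <- toy_setup()
  rec <- build_dispersal_records(ts$pt, ts$map,
                                 ts$map[, c("genet_id", "family_id")])
  prof <- half_sib_profile(rec, cutoffs_m = c(1, 5))
  expect_equal(prof$half_sib_fraction, mean(rec$is_half_sib_father))
  expect_equal(prof$n_half_sib + prof$n_other, nrow(rec))
  hs_d <- rec$distance_m[rec$is_half_sib_father]
  expect_equal(unname(prof$by_class$`TRUE`$within["<=1m"]), mean(hs_d <= 1))
  none <- rec
  none$is_half_sib_father <- FALSE
  expect_equal(half_sib_profile(none)$half_sib_fraction, 0)
})

test_that("estimated sigma_pollen rises monotonically with the kernel scale", {
  scales <- c(1, 2, 3.5, 5, 7)
  sig <- matrix(NA_real_, length(scales), 10)
  for (i in seq_along(scales)) {
    for (r in 1:10) {
      sim <- tiny_nursery(seed = 900 + 37 * i + r, n_candidates = 144,
                          n_families = 24, family_size = 6, n_mothers = 3,
                          progeny = 25, n_loci = 300,
                          kernel = list(family = "exponential",
                                        scale_m = scales[i], shape = 1))
      pt <- assign_paternity(sim$progeny, sim$families,
                             sim$founders$genotypes,
                             lod_model(error_rate = 0.05, min_loci = 100),
                             thresholds = NULL)
      rec <- build_dispersal_records(pt, sim$founders$map)
      sig[i, r] <- axial_sigma(rec$distance_m)$sigma_pollen_m
    }
  }
  rho <- cor(rep(scales, 10), as.vector(sig), method = "spearman")
  expect_gt(rho, 0.9)
})
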