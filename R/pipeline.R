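# End-to-end orchestration: simulate (or load) -> filter -> subsample ->
# calibrate + assign -> mating system -> dispersal -> trait prediction ->
# JSON report. Every intermediate table is persisted; stage progress is
# logged to standard error.

.log_stage <- function(fmt, ...) {
  message(sprintf("[pollenkin] %s %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param stages character vector of enabled stages among "simulate",
#'   "filter", "assign", "mating", "dispersal", "traits".
#' @param maf_min,max_missing locus filters.
#' @param n_subsample loci retained for parentage (NULL keeps all).
#' @param error_rate_lod assumed mistyping rate of the LOD model.
#' @param min_loci minimum compared loci for an assignment.
#' @param n_calibration simulated offspring for threshold calibration.
#' @param prop_candidates_sampled calibration sampling fraction of fathers.
#' @param error_rate_mating mistyping rate of the mating model (independent of
#'   the LOD model's).
#' @param n_bootstrap family bootstrap replicates.
#' @param bin_width_m distance-bin width.
#' @param alpha significance level for LSD tests.
#' @param inputs optional list of file paths (genotypes_candidates,
#'   genotypes_progeny, field_map, family_table, phenotypes) used instead of
#'   the simulator when "simulate" is disabled.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = sim_config(seed = seed),
                       stages = c("simulate", "filter", "assign", "mating",
                                  "dispersal", "traits"),
                       maf_min = 0.03, max_missing = 0.10,
                       n_subsample = NULL, error_rate_lod = 0.10,
                       min_loci = 300, n_calibration = 10000,
                       prop_candidates_sampled = 749 / 771,
                       error_rate_mating = 0.01, n_bootstrap = 1000,
                       bin_width_m = 3, alpha = 0.05, inputs = NULL) {
  sim$seed <- as.integer(seed)
  cfg <- list(seed = as.integer(seed), sim = sim, stages = stages,
              maf_min = maf_min, max_missing = max_missing,
              n_subsample = n_subsample, error_rate_lod = error_rate_lod,
              min_loci = min_loci, n_calibration = n_calibration,
              prop_candidates_sampled = prop_candidates_sampled,
              error_rate_mating = error_rate_mating,
              n_bootstrap = n_bootstrap, bin_width_m = bin_width_m,
              alpha = alpha, inputs = inputs)
  known <- c("simulate", "filter", "assign", "mating", "dispersal", "traits")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  if ("dispersal" %in% stages && !"assign" %in% stages) {
    stop("the dispersal stage requires the assign stage")
  }
  if ("traits" %in% stages && !"dispersal" %in% stages) {
    stop("the traits stage requires the dispersal stage")
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full nursery analysis pipeline
#'
#' Executes the enabled stages in dependency order, persists every
#' intermediate table under `out_dir`, and writes a single JSON report with
#' the mating-system estimates, paternity and dispersal summaries and the
#' distance-bin tables. Reruns with the same configuration are byte-identical.
#'
#' @param config a [run_config()] (or a YAML file path holding one).
#' @param out_dir output directory (created; NULL skips persistence).
#' @return the report, invisibly (class `pipeline_report`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (is.character(config)) {
    raw <- yaml::read_yaml(config)
    sim_args <- raw$sim %||% list()
    raw$sim <- do.call(sim_config, sim_args)
    config <- do.call(run_config, raw)
  }
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  persist <- function(obj, name, writer = utils::write.csv) {
    if (is.null(out_dir)) return(invisible(NULL))
    writer(obj, file.path(out_dir, name))
  }
  report <- list(package = "pollenkin", schema_version = "1.0",
                 seed = config$seed)
  sim <- NULL
  truth <- NULL

  if ("simulate" %in% config$stages) {
    .log_stage("simulate: %d candidates, %d loci", config$sim$n_candidates,
               config$sim$n_loci)
    sim <- simulate_nursery(config$sim, n_traits = 1)
    candidates <- sim$founders$genotypes
    progeny <- sim$progeny
    map <- sim$founders$map
    fam <- sim$families
    cand_fam <- sim$founders$families
    truth <- sim$truth
    phen <- data.frame(genet_id = rownames(candidates),
                       trait01 = sim$traits$phenotypes[rownames(candidates), 1])
    if (!is.null(out_dir)) {
      write_genotypes(candidates, file.path(out_dir, "candidates.tsv"), "tsv")
      write_genotypes(progeny, file.path(out_dir, "progeny.tsv"), "tsv")
      write_field_map(map, file.path(out_dir, "field_map.csv"))
      write_family_table(fam, file.path(out_dir, "families.csv"))
      jsonlite::write_json(
        list(true_father = as.list(truth$true_father),
             realized_distance_m = as.list(truth$realized_distance_m),
             kernel = truth$kernel_params,
             selfing_events = truth$selfing_events),
        file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA
      )
    }
  } else {
    inp <- config$inputs
    if (is.null(inp)) stop("no inputs configured and the simulate stage is disabled")
    .log_stage("load inputs")
    candidates <- read_genotypes(inp$genotypes_candidates)
    progeny <- read_genotypes(inp$genotypes_progeny)
    map <- read_field_map(inp$field_map)
    fam <- read_family_table(inp$family_table, map)
    cand_fam <- map[, c("genet_id", "family_id")]
    phen <- if (!is.null(inp$phenotypes)) {
      utils::read.csv(inp$phenotypes, stringsAsFactors = FALSE)
    } else {
      NULL
    }
  }

  if ("filter" %in% config$stages) {
    .log_stage("filter: MAF >= %.2f, missing <= %.2f", config$maf_min,
               config$max_missing)
    pooled <- rbind(candidates, progeny)
    filt <- filter_loci(pooled, config$maf_min, config$max_missing)
    keep <- colnames(filt)
    report$filter <- as.list(attr(filt, "filter_report"))
    if (!is.null(config$n_subsample) && config$n_subsample < length(keep)) {
      sub <- subsample_loci(filt, config$n_subsample,
                            seed = .derive_seed(config$seed, 23L))
      keep <- colnames(sub)
    }
    candidates <- candidates[, keep, drop = FALSE]
    progeny <- progeny[, keep, drop = FALSE]
    report$n_loci_used <- length(keep)
  }

  freqs <- allele_frequencies(rbind(candidates, progeny))
  report$diversity <- as.list(diversity_summary(progeny))

  pt <- NULL
  if ("assign" %in% config$stages) {
    model <- lod_model(config$error_rate_lod, config$min_loci)
    .log_stage("calibrate confidence: %d offspring", config$n_calibration)
    thr <- calibrate_confidence(
      candidates, model, freqs = freqs,
      n_offspring = config$n_calibration,
      prop_candidates_sampled = config$prop_candidates_sampled,
      seed = .derive_seed(config$seed, 29L)
    )
    .log_stage("assign paternity: %d progeny x %d candidates", nrow(progeny),
               nrow(candidates))
    pt <- assign_paternity(progeny, fam, candidates, model, thr, freqs = freqs)
    persist(pt, "paternity.csv",
            function(x, f) utils::write.csv(as.data.frame(x), f, row.names = FALSE))
    ps <- paternity_summary(pt, cand_fam)
    nielsen <- tapply(pt$father_id[!is.na(pt$father_id)],
                      pt$mother_id[!is.na(pt$father_id)], function(f) {
                        nielsen_effective_fathers(table(f))$effective_fathers
                      })
    report$thresholds <- list(lod_strict = thr$lod_strict,
                              lod_relaxed = thr$lod_relaxed)
    report$paternity <- list(
      n_progeny = ps$n_progeny, n_assigned = ps$n_assigned,
      assigned_pct = 100 * ps$assigned_fraction,
      mean_assigned_per_mother = ps$mean_assigned_per_mother,
      mean_unassigned_per_mother = ps$mean_unassigned_per_mother,
      total_fathers = ps$total_father_events,
      unique_fathers = ps$unique_fathers,
      mean_fathers_per_mother = ps$mean_fathers_per_mother,
      mean_progeny_per_pair = ps$mean_progeny_per_pair,
      max_progeny_per_pair = ps$max_progeny_per_pair,
      half_sib_father_fraction = ps$half_sib_father_fraction,
      nielsen_effective_fathers_mean = mean(nielsen, na.rm = TRUE),
      selfing_assignments = ps$selfing_assignments
    )
    if (!is.null(truth)) {
      asg <- pt[pt$confidence == "strict95", ]
      tf <- truth$true_father[asg$progeny_id]
      tf[tf == "SELF"] <- asg$mother_id[tf == "SELF"]
      report$paternity$recovery_accuracy <- mean(asg$father_id == tf)
    }
  }

  if ("mating" %in% config$stages) {
    .log_stage("mating system: %d bootstrap replicates", config$n_bootstrap)
    ms <- estimate_outcrossing(progeny, fam, candidates, freqs = freqs,
                               error_rate = config$error_rate_mating,
                               n_bootstrap = config$n_bootstrap,
                               seed = .derive_seed(config$seed, 31L))
    rp <- correlated_paternity(progeny, fam, candidates, freqs = freqs,
                               error_rate = config$error_rate_mating,
                               paternity = pt,
                               n_bootstrap = config$n_bootstrap,
                               seed = .derive_seed(config$seed, 37L))
    report$mating <- list(
      t_m = ms$t_m, t_m_sd = ms$t_m_sd, t_s = ms$t_s, t_s_sd = ms$t_s_sd,
      biparental = ms$biparental, biparental_sd = ms$biparental_sd,
      r_p = rp$rp_ml, r_p_sd = rp$rp_sd, r_p_direct = rp$rp_direct,
      r_p_p_gt0 = rp$p_value_gt0
    )
  }

  records <- NULL
  if ("dispersal" %in% config$stages) {
    if (is.null(pt)) stop("the dispersal stage requires paternity assignments")
    .log_stage("dispersal analysis")
    records <- build_dispersal_records(pt, map, cand_fam)
    persist(as.data.frame(records), "dispersal_records.csv",
            function(x, f) utils::write.csv(x, f, row.names = FALSE))
    ds <- dispersal_summary(records, map)
    bt <- per_bin_diversity(records, progeny, config$bin_width_m)
    persist(as.data.frame(bt), "distance_bins.csv",
            function(x, f) utils::write.csv(x, f, row.names = FALSE))
    report$dispersal <- list(
      n_events = ds$n, mean_distance_m = ds$mean_m,
      median_distance_m = ds$median_m, min_distance_m = ds$min_m,
      max_distance_m = ds$max_m, M = ds$M,
      sigma_pollen_m = ds$sigma_pollen_m,
      fraction_within = as.list(ds$fraction_within),
      ks_D = ds$ks$D, ks_p = ds$ks$p_value,
      sector_counts = as.list(ds$sectors)
    )
    report$distance_bins <- bt
  }

  if ("traits" %in% config$stages) {
    if (is.null(records)) stop("the traits stage requires dispersal records")
    if (is.null(phen)) {
      .log_stage("traits: no phenotypes available, stage skipped")
    } else {
      .log_stage("traits: GBLUP prediction")
      traits <- setdiff(names(phen), "genet_id")
      train <- candidates[intersect(rownames(candidates), phen$genet_id), ,
                          drop = FALSE]
      preds <- sapply(traits, function(tr) {
        fit <- fit_gblup(train,
                         stats::setNames(phen[[tr]], phen$genet_id)[rownames(train)])
        predict(fit, progeny)
      })
      rownames(preds) <- rownames(progeny)
      tab <- per_bin_trait_table(preds, records, config$bin_width_m,
                                 config$alpha)
      persist(tab, "trait_bins.csv",
              function(x, f) utils::write.csv(x, f, row.names = FALSE))
      report$trait_bins <- tab
    }
  }

  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    yaml::write_yaml(
      list(seed = config$seed, stages = config$stages,
           sim = unclass(config$sim)),
      file.path(out_dir, "run_config.yaml")
    )
  }
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pollenkin pipeline report (seed", x$seed, ")\n")
  if (!is.null(x$paternity)) {
    cat(sprintf("  paternity: %.1f%% assigned, %.1f fathers/mother\n",
                x$paternity$assigned_pct, x$paternity$mean_fathers_per_mother))
  }
  if (!is.null(x$mating)) {
    cat(sprintf("  mating: t_m %.3f, t_s %.3f, r_p %.3f\n", x$mating$t_m,
                x$mating$t_s, x$mating$r_p))
  }
  if (!is.null(x$dispersal)) {
    cat(sprintf("  dispersal: mean %.2f m, sigma_pollen %.2f m\n",
                x$dispersal$mean_distance_m, x$dispersal$sigma_pollen_m))
  }
  invisible(x)
}

#' Deterministic miniature nursery fixture
#'
#' A small error-free nursery (48 candidates in 8 families, 200 loci, 4
#' mothers with 12 progeny each) used in tests and documentation; paternity
#' recovery on it is exact at zero genotyping error.
#'
#' @param seed integer seed.
#' @param dir optional directory: when given, all tables are written there in
#'   the package's standard formats.
#' @return a `nursery_sim` object.
#' @export
make_fixtures <- function(seed = 42, dir = NULL) {
  cfg <- sim_config(n_candidates = 48, n_families = 8, family_size = 6,
                    n_mothers_sampled = 4, progeny_per_mother = c(12, 12),
                    n_loci = 200, maf_range = c(0.1, 0.4),
                    kernel = list(family = "exponential", scale_m = 2,
                                  shape = 1),
                    selfing_rate = 0, genotyping_error = 0,
                    missing_rate = 0, seed = seed)
  sim <- simulate_nursery(cfg)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_genotypes(sim$founders$genotypes, file.path(dir, "candidates.vcf"))
    write_genotypes(sim$progeny, file.path(dir, "progeny.vcf"))
    write_field_map(sim$founders$map, file.path(dir, "field_map.csv"))
    write_family_table(sim$families, file.path(dir, "families.csv"))
    jsonlite::write_json(list(true_father = as.list(sim$truth$true_father)),
                         file.path(dir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  sim
}
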