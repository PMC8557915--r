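.CONFIG_KEYS <- c("seed", "output_dir", "vials_file", "intervals_file",
                  "contamination_file", "og_matrix_file", "annotations_file",
                  "simulate", "n_contaminated", "alpha", "extrapolation",
                  "censoring", "permutation_traits", "permutation_factors",
                  "permutation_classes", "exclude_treatments",
                  "mgwa_exclude_strains", "mgwa_mean_mode")

#' Read and validate a pipeline configuration
#'
#' A single declarative YAML or JSON file drives [runPipeline()].  Unknown
#' keys are rejected.  Recognised keys: \code{seed}, \code{output_dir},
#' input paths (\code{vials_file}, \code{intervals_file},
#' \code{contamination_file}, \code{og_matrix_file},
#' \code{annotations_file}) or \code{simulate: true}; \code{alpha},
#' \code{extrapolation} (\code{rate}/\code{raw}), \code{censoring}
#' (\code{exclude}/\code{deaths}), \code{permutation_traits},
#' \code{permutation_factors} (denominators, e.g. \code{[2, 10, 100]}),
#' \code{permutation_classes}, \code{exclude_treatments},
#' \code{mgwa_exclude_strains}, \code{mgwa_mean_mode}, \code{n_contaminated}.
#'
#' @param path configuration file (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return named list of settings with defaults filled in.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L, output_dir = "flyfitness_out", simulate = FALSE,
                   n_contaminated = 0L, alpha = 0.05,
                   extrapolation = "rate", censoring = "exclude",
                   permutation_traits = c("survival", "fecundity"),
                   permutation_factors = c(2, 10, 20, 100, 200, 1e3, 1e4, 1e5),
                   permutation_classes = 2L,
                   exclude_treatments = "P_putida_like",
                   mgwa_exclude_strains = "P_putida_like",
                   mgwa_mean_mode = "vial")
  utils::modifyList(defaults, cfg)
}

#' Run the full fitness pipeline
#'
#' Orchestrates the stages end to end: read (or simulate) vial data,
#' contamination filter, survival-record export, per-vial Leslie fitness,
#' treatment statistics (Kruskal-Wallis + Dunn + compact letters on lambda;
#' pairwise log-rank + compact letters on life span), the perturbation grid,
#' and -- when an OG matrix is configured or simulation is on -- the
#' metagenome-wide association.  Each run writes a provenance record
#' (config, seed, package and R versions) beside the outputs, and a rerun
#' with the same configuration is byte-identical.
#'
#' @param config path to a configuration file or a list as returned by
#'   [readPipelineConfig()].
#' @return invisibly, the output directory.  Files written:
#'   \code{vials.csv}, \code{intervals.csv}, \code{contamination.csv},
#'   \code{removed_vials.csv}, \code{survival_records.csv},
#'   \code{fitness.csv}, \code{stats_summary.csv}, \code{permutations.csv},
#'   \code{permutation_summary.csv}, \code{mgwa_results.csv} (when run),
#'   \code{truth.json} (simulation only) and \code{provenance.json}.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- utils::modifyList(readPipelineConfigDefaults(), config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)
  set.seed(as.integer(cfg$seed))

  ogSim <- NULL
  if (isTRUE(cfg$simulate)) {
    design <- studyDesign(seed = as.integer(cfg$seed))
    sim <- simulateStudy(design, nContaminated = cfg$n_contaminated)
    vials <- sim$vials
    contamination <- sim$contamination
    writeVialTable(vials, out("vials.csv"), out("intervals.csv"))
    utils::write.csv(contamination, out("contamination.csv"), row.names = FALSE)
    jsonlite::write_json(sim$truth, out("truth.json"), dataframe = "columns",
                         digits = NA)
    ogSim <- simulateOGMatrix(100L, sim$truth$treatment, effectDelta = 0)
  } else {
    vials <- readVialTable(cfg$vials_file, cfg$intervals_file)
    contamination <- if (!is.null(cfg$contamination_file))
      readContaminationLog(cfg$contamination_file)
    else data.frame(vial_id = character(0), week = integer(0),
                    cfu_per_fly = numeric(0),
                    unexpected_morphology = logical(0))
  }

  flt <- contaminationFilter(vials, contamination)
  utils::write.csv(data.frame(vial_id = flt$removed),
                   out("removed_vials.csv"), row.names = FALSE)
  vials <- flt$kept
  if (length(vials) == 0L) stop("stage 'filter' failed: no vials left")

  surv <- toSurvivalRecords(vials)
  utils::write.csv(surv, out("survival_records.csv"), row.names = FALSE)

  fitness <- vialFitness(vials, extrapolation = cfg$extrapolation,
                         censoring = cfg$censoring)
  utils::write.csv(fitness, out("fitness.csv"), row.names = FALSE)

  statsRows <- .treatmentStats(fitness, surv, cfg$alpha)
  utils::write.csv(statsRows, out("stats_summary.csv"), row.names = FALSE)

  perm <- list()
  for (tr in cfg$permutation_traits)
    perm <- c(perm, permutationGrid(
      vials, trait = tr, factors = 1 / cfg$permutation_factors,
      classes = cfg$permutation_classes,
      excludeTreatments = cfg$exclude_treatments,
      extrapolation = cfg$extrapolation, censoring = cfg$censoring))
  utils::write.csv(permutationSummary(perm, "vials"), out("permutations.csv"),
                   row.names = FALSE)
  utils::write.csv(permutationSummary(perm, "summary"),
                   out("permutation_summary.csv"), row.names = FALSE)

  ranMGWA <- FALSE
  if (!is.null(cfg$og_matrix_file) || !is.null(ogSim)) {
    og <- if (!is.null(ogSim)) ogSim$og else readOGMatrix(cfg$og_matrix_file)
    ann <- if (!is.null(cfg$annotations_file))
      utils::read.csv(cfg$annotations_file, stringsAsFactors = FALSE)
    panel <- data.frame(vial_id = fitness$vial_id,
                        strain_id = fitness$treatment,
                        experiment = fitness$experiment_day,
                        lambda = fitness$lambda)
    mg <- runMGWA(panel, og, annotations = ann,
                  excludeStrains = cfg$mgwa_exclude_strains,
                  meanMode = cfg$mgwa_mean_mode)
    mg$member_ogs <- vapply(mg$member_ogs, paste, character(1), collapse = ";")
    utils::write.csv(mg, out("mgwa_results.csv"), row.names = FALSE)
    ranMGWA <- TRUE
  } else {
    message("no OG matrix configured; association stage skipped")
  }

  prov <- list(config = cfg, seed = cfg$seed,
               package = as.character(utils::packageVersion("flyfitness")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               stages = c("filter", "survival", "fitness", "stats",
                          "permutations", if (ranMGWA) "mgwa"))
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(cfg$output_dir)
}

readPipelineConfigDefaults <- function() {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines("{}", tmp)
  readPipelineConfig(tmp)
}

.treatmentStats <- function(fitness, surv, alpha) {
  rows <- list()
  if (length(unique(fitness$treatment)) >= 2L) {
    kw <- kruskalWallis(fitness$lambda, fitness$treatment)
    dn <- dunnTest(fitness$lambda, fitness$treatment)
    cld <- compactLetterDisplay(dn, alpha)
    rows[["kw"]] <- data.frame(analysis = "fitness", test = "kruskal-wallis",
                               statistic = kw$statistic, df = kw$df,
                               p = kw$p.value, group = NA, letters = NA)
    rows[["cld"]] <- data.frame(analysis = "fitness", test = "cld",
                                statistic = NA, df = NA, p = NA,
                                group = names(cld), letters = unname(cld))
    if (sum(surv$event) > 0) {
      lr <- pairwiseLogrank(surv)
      cldS <- compactLetterDisplay(lr, alpha)
      rows[["lr"]] <- data.frame(analysis = "lifespan", test = "logrank-cld",
                                 statistic = NA, df = NA, p = NA,
                                 group = names(cldS), letters = unname(cldS))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read an OG presence/absence matrix from CSV
#'
#' @param path CSV with an \code{og_id} column and one 0/1 column per
#'   strain.
#' @return an \linkS4class{OGMatrix}.
#' @export
readOGMatrix <- function(path) {
  df <- .readCsvChecked(path, "og_id")
  m <- as.matrix(df[setdiff(names(df), "og_id")])
  rownames(m) <- df$og_id
  OGMatrix(m)
}

#' Write an OG matrix to CSV
#'
#' @param og an \linkS4class{OGMatrix}.
#' @param path output path.
#' @export
writeOGMatrix <- function(og, path) {
  df <- cbind(data.frame(og_id = rownames(og@presence)),
              as.data.frame(og@presence))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
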