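#' Default pipeline configuration
#'
#' @param ... Overrides for any top-level or nested field.
#' @return A validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    simulate = list(n_genotypes = 5, n_trials = 4, n_replicates = 3,
                    organs = c("flag_leaf", "glume", "lemma"),
                    stages = c("anthesis", "grain_filling"),
                    n_metabolites = 80, n_blocks = 8, block_rho = 0.5,
                    n_effects = 10, target_r2 = 0.7, noise_sd = 1,
                    condition_shift = -2),
    input = NULL,                     # list(matrix =, design =, traits =)
    preprocess = list(max_missing_frac = 0.10, k = 10, scale = "raw"),
    resampling = list(n_runs = 100, train_fraction = 0.75, stratify = FALSE),
    lasso = list(n_grid = 100, eps = 1e-3, inner_folds = 5, rule = "min",
                 tol = 1e-8, max_iter = 1e5),
    refit = list(dr_threshold = 0.70, variance_method = "sequential_dr")
  )
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(cfg[[nm]], over[[nm]])
    } else over[[nm]]
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  dr <- cfg$refit$dr_threshold
  if (!is.numeric(dr) || dr <= 0 || dr > 1) {
    abort("`refit$dr_threshold` must be in (0, 1].")
  }
  tf <- cfg$resampling$train_fraction
  if (tf <= 0 || tf >= 1) abort("`resampling$train_fraction` must be in (0, 1).")
  if (!cfg$preprocess$scale %in% c("raw", "log2", "both")) {
    abort("`preprocess$scale` must be 'raw', 'log2' or 'both'.")
  }
  if (cfg$preprocess$max_missing_frac < 0 || cfg$preprocess$max_missing_frac >= 1) {
    abort("`preprocess$max_missing_frac` must be in [0, 1).")
  }
  invisible(cfg)
}

#' Run the full metabolome-to-yield pipeline
#'
#' Simulates (or reads) a metabolome with design and trait tables, then for
#' every organ-stage cell: filters metabolites by missingness, imputes with
#' KNN, optionally log2-transforms, runs the resampling stability engine,
#' selects metabolites at the detection-rate threshold and refits by OLS on
#' the whole cell and on the WS / HY subsets with variance partitioning.
#' Writes, per model, a detection-rate effects TSV, a variance-shares TSV
#' and refit/stability JSON summaries, plus a preprocessing report per cell
#' and a manifest recording the config, all derived seeds and the package
#' version. Everything is deterministic given the config: re-running yields
#' byte-identical files.
#'
#' @param config A config list from [pipeline_config()], or a YAML/JSON path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results and output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  if (is.character(config)) {
    cfg_in <- if (grepl("\\.json$", config, TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
    config <- do.call(pipeline_config, cfg_in)
  }
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  if (!is.null(config$input)) {
    mat <- read_matrix(config$input$matrix, design = config$input$design)
    traits <- readr::read_tsv(config$input$traits, show_col_types = FALSE,
                              progress = FALSE)
    truth <- NULL
  } else {
    sp <- config$simulate
    design <- build_design(sp$n_genotypes, sp$n_trials, sp$n_replicates,
                           sp$organs, sp$stages)
    sim <- simulate_metabolome(design, n_metabolites = sp$n_metabolites,
                               n_blocks = sp$n_blocks,
                               block_rho = sp$block_rho,
                               seed = derive_seed(seed, "sim"),
                               n_effects = sp$n_effects,
                               target_r2 = sp$target_r2,
                               noise_sd = sp$noise_sd,
                               condition_shift = sp$condition_shift)
    truth <- sim$truth
    mat <- inject_missing(sim$matrix, truth$missing_rates,
                          seed = derive_seed(seed, "missing"))
    traits <- simulate_traits(sim$matrix, truth,
                              seed = derive_seed(seed, "traits"))
    write_ground_truth(truth, file.path(out_dir, "ground_truth.json"))
  }
  y_all <- traits$GY[match(mat$design$sample_id, traits$sample_id)]

  cells <- dplyr::distinct(mat$design, .data$organ, .data$stage)
  scales <- if (config$preprocess$scale == "both") c("raw", "log2")
            else config$preprocess$scale
  models <- list(); seeds_used <- list(sim = derive_seed(seed, "sim"))
  for (ci in seq_len(nrow(cells))) {
    organ <- cells$organ[ci]; stage <- cells$stage[ci]
    idx <- which(mat$design$organ == organ & mat$design$stage == stage)
    cell_mat <- subset_samples(mat, idx)
    y <- y_all[idx]
    tag <- paste(organ, stage, sep = "_")

    pre <- filter_by_missingness(cell_mat, config$preprocess$max_missing_frac)
    pre <- knn_impute(pre, k = config$preprocess$k)
    jsonlite::write_json(preprocess_report(pre),
                         file.path(out_dir, paste0("preprocess_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA)

    for (scl in scales) {
      m <- if (scl == "log2") log2_transform(pre) else pre
      mtag <- paste(tag, scl, sep = "_")
      split_seed <- derive_seed(seed, paste0("splits_", mtag))
      seeds_used[[paste0("splits_", mtag)]] <- split_seed
      plan <- make_splits(
        length(idx), n_runs = config$resampling$n_runs,
        train_fraction = config$resampling$train_fraction,
        seed = split_seed,
        stratify_by = if (isTRUE(config$resampling$stratify) &&
                          "condition" %in% names(m$design)) {
          m$design$condition
        } else NULL
      )
      stab <- run_stability(m, y, plan, config$lasso)
      feats <- suppressWarnings(
        select_by_dr(stab, config$refit$dr_threshold))

      effects_out <- dplyr::mutate(stab$effects, organ = organ, stage = stage,
                                   scale = scl)
      readr::write_tsv(effects_out,
                       file.path(out_dir, paste0("effects_", mtag, ".tsv")),
                       progress = FALSE)
      jsonlite::write_json(as.list(stab$summary),
                           file.path(out_dir, paste0("stability_", mtag, ".json")),
                           auto_unbox = TRUE, digits = NA)

      subsets <- "all"
      if ("condition" %in% names(m$design) &&
          all(c("WS", "HY") %in% m$design$condition)) {
        subsets <- c("all", "WS", "HY")
      }
      refits <- list(); shares <- list()
      for (ss in subsets) {
        if (length(feats) >= (if (ss == "all") length(idx) else
                              sum(m$design$condition == ss)) - 1) next
        rf <- fit_refit(m, y, feats, subset = ss)
        refits[[ss]] <- rf
        if (length(rf$features) > 0) {
          sh <- partition_variance(rf, method = config$refit$variance_method)
          sh$subset <- ss
          shares[[ss]] <- sh
        }
      }
      if (length(shares) > 0) {
        readr::write_tsv(dplyr::bind_rows(shares),
                         file.path(out_dir, paste0("shares_", mtag, ".tsv")),
                         progress = FALSE)
      }
      jsonlite::write_json(
        lapply(refits, function(rf) {
          list(subset = rf$subset, features = rf$features,
               coefficients = as.list(rf$coefficients),
               r2 = rf$r2, adj_r2 = rf$adj_r2, overall_p = rf$overall_p,
               n = rf$n)
        }),
        file.path(out_dir, paste0("refit_", mtag, ".json")),
        auto_unbox = TRUE, digits = NA)
      models[[mtag]] <- list(stability = stab, refits = refits,
                             dr_features = feats)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("metayield")),
    config = config, seeds = seeds_used
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(models = models, truth = truth, out_dir = out_dir,
                 traits = traits))
}
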