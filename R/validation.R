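# Comparison of simulated and observed integrative traits (Pearson r, RMSE,
# nRMSE, bias) and the end-to-end pipeline: estimate parameters, fit the
# genomic prediction model, predict parameters, simulate the population
# under two climates, and score the simulations.

#' Validation metrics for paired observed/simulated values
#'
#' `RMSE = sqrt(mean((O - S)^2))`, `nRMSE = RMSE / mean(O)` (stored as a
#' fraction; multiply by 100 for the percentage), `BIAS = mean(S - O)`
#' (positive = overestimation), and Pearson's correlation with its test
#' p-value.
#'
#' @param observed,simulated numeric vectors paired by genotype, length
#'   >= 3.
#' @param trait optional trait label carried into the report.
#' @return An object of class `validation_report`: one-row data frame with
#'   columns `trait`, `n`, `r`, `p`, `rmse`, `nrmse`, `bias`.
#' @export
validation_metrics <- function(observed, simulated, trait = NA_character_) {
  n <- length(observed)
  if (length(simulated) != n) stop("observed and simulated must be paired")
  if (n < 3) stop("need at least 3 pairs")
  if (anyNA(observed) || anyNA(simulated)) stop("missing values in inputs")
  rmse <- sqrt(mean((observed - simulated)^2))
  if (mean(observed) == 0) stop("mean(observed) is zero: nRMSE undefined")
  nrmse <- rmse / mean(observed)
  bias <- mean(simulated - observed)
  if (stats::var(observed) == 0 || stats::var(simulated) == 0) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(observed, simulated)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  out <- data.frame(trait = trait, n = n, r = r, p = p,
                    rmse = rmse, nrmse = nrmse, bias = bias)
  class(out) <- c("validation_report", "data.frame")
  out
}

#' Run the full pipeline on a configuration
#'
#' Executes, in order: synthetic-data generation (or loading of CSV
#' inputs), per-trait RR-BLUP fitting on replicate-level phenotypes,
#' rescaling and per-genotype parameter prediction, population simulation
#' under both climates with the true (genotype-mean) and the predicted
#' parameters, and validation metrics per integrative trait per climate.
#' Every seed and stage is recorded in the report; a stage failure aborts
#' with a stage-tagged error.
#'
#' @param config either a list or a path to a YAML file. Recognized fields:
#'   `seed` (master seed), `synth` (arguments for [synth_config()]), or
#'   `inputs` (paths: `climate_exp1`, `climate_exp2`, `markers`, `map`,
#'   `phenotypes`), `branching` (`r_k`, `n_days`), `n_sim_reps` (replicate
#'   simulations per genotype, default 5), `out_dir` (optional; write
#'   report CSV + JSON there).
#' @return An object of class `pipeline_report`: list with `config_used`,
#'   `gp` (per-parameter fit summaries and within-sample accuracy),
#'   `validation` (data frame over climates x traits), `seeds`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  br <- stage("config", {
    b <- config$branching
    if (is.null(b)) branching_params() else branching_params(b$r_k, b$n_days)
  })
  n_sim_reps <- if (is.null(config$n_sim_reps)) 5L else as.integer(config$n_sim_reps)

  # --- inputs -------------------------------------------------------------
  ds <- stage("inputs", {
    if (!is.null(config$inputs)) {
      inp <- config$inputs
      markers <- read_marker_csv(inp$markers, inp$map)
      list(markers = markers,
           phenotypes = utils::read.csv(inp$phenotypes, stringsAsFactors = FALSE),
           climates = list(exp1 = read_climate_csv(inp$climate_exp1),
                           exp2 = read_climate_csv(inp$climate_exp2)))
    } else {
      sc <- do.call(synth_config, c(config$synth, list(seed = seed)))
      generate_synthetic_dataset(sc)
    }
  })
  param_traits <- c("rle_gdd", "in_length", "leaf_area", "loga_syll")
  miss <- setdiff(param_traits, names(ds$phenotypes))
  if (length(miss)) stop("[stage inputs] phenotype table lacks parameter column(s): ",
                         paste(miss, collapse = ", "))
  tt <- stage("thermal_time", lapply(ds$climates, season_thermal_time))
  W <- ds$markers$W
  gids <- rownames(W)

  # --- genomic prediction of the four parameters --------------------------
  gp <- stage("genomic_prediction", {
    res <- list()
    for (tr in param_traits) {
      y <- ds$phenotypes[[tr]]
      X <- W[as.character(ds$phenotypes$genotype_id), , drop = FALSE]
      fit <- rrblup_fit(y, X)
      fit <- rescale_effects(fit, y, W)
      pred <- predict_phenotypes(fit, W)
      obs_mean <- as.numeric(tapply(y, factor(ds$phenotypes$genotype_id,
                                              levels = gids), mean))
      res[[tr]] <- list(mu = fit$mu, lambda = fit$lambda,
                        sigma_g2 = fit$sigma_g2, sigma_e2 = fit$sigma_e2,
                        predicted = stats::setNames(pred, gids),
                        observed_mean = stats::setNames(obs_mean, gids),
                        accuracy = stats::cor(pred, obs_mean))
    }
    res
  })

  # --- parameter tables: observed (genotype means) and predicted ----------
  make_table <- function(values_by_trait) {
    data.frame(genotype_id = gids,
               rle_gdd = pmax(values_by_trait$rle_gdd, 1e-6),
               in_length = pmax(values_by_trait$in_length, 1e-3),
               leaf_area = pmax(values_by_trait$leaf_area, 1e-3),
               a_syll = exp(values_by_trait$loga_syll))
  }
  obs_params <- make_table(lapply(gp, `[[`, "observed_mean"))
  pred_params <- make_table(lapply(gp, `[[`, "predicted"))

  # --- simulate under both climates, score simulated vs observed ----------
  validation <- stage("simulation", {
    rows <- list()
    for (cl in names(tt)) {
      off <- match(cl, names(tt)) * 1000003L
      pop_obs <- simulate_population(obs_params, br, tt[[cl]],
                                     n_reps = n_sim_reps, seed = seed + off)
      pop_sim <- simulate_population(pred_params, br, tt[[cl]],
                                     n_reps = n_sim_reps, seed = seed + off + 500009L)
      for (trait in c("nb_leaves", "trunk_length", "nb_syll")) {
        vm <- validation_metrics(pop_obs$summary[[trait]],
                                 pop_sim$summary[[trait]], trait = trait)
        vm$climate <- cl
        rows[[paste(cl, trait)]] <- vm
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out[, c("climate", "trait", "n", "r", "p", "rmse", "nrmse", "bias")]
  })

  report <- structure(list(
    seeds = list(master = seed),
    branching = unclass(br),
    n_sim_reps = n_sim_reps,
    gp = lapply(gp, function(x) x[c("mu", "lambda", "sigma_g2", "sigma_e2",
                                    "accuracy")]),
    validation = validation
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    stage("report", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(validation, file.path(config$out_dir, "validation.csv"),
                       row.names = FALSE)
      jsonlite::write_json(.report_as_list(report),
                           file.path(config$out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }
  report
}

.report_as_list <- function(report) {
  list(seeds = report$seeds, branching = report$branching,
       n_sim_reps = report$n_sim_reps, gp = report$gp,
       validation = report$validation)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> master seed ", x$seeds$master, "\n", sep = "")
  cat("Within-sample prediction accuracy (r):\n")
  acc <- vapply(x$gp, `[[`, 0, "accuracy")
  print(round(acc, 3))
  cat("Validation of simulated integrative traits:\n")
  v <- x$validation
  v$nrmse_pct <- round(100 * v$nrmse, 1)
  print(v[, c("climate", "trait", "r", "rmse", "nrmse_pct", "bias")],
        digits = 3, row.names = FALSE)
  invisible(x)
}
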