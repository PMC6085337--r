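#' Pipeline configuration
#'
#' A pipeline config either points at input CSVs (\code{inputs}) or carries a
#' \code{scenario} block for simulation. Per-stage parameters and a global
#' seed complete it; stage seeds are derived deterministically from the
#' global seed. Configs round-trip losslessly through YAML.
#'
#' @param scenario a [scenario_config()] (or list of its arguments), or
#'   \code{NULL} when \code{inputs} are given.
#' @param inputs named list of file paths (per mutualism:
#'   \code{plant_traits}, \code{plant_traits_meta}, \code{animal_traits},
#'   \code{animal_traits_meta}; plus \code{interactions},
#'   \code{covariates}).
#' @param n_perm permutations for the fourth-corner tests.
#' @param model fourth-corner permutation model (2, 4 or 6).
#' @param coverage axis-selection coverage.
#' @param trait_sets trait sets for the FD stage.
#' @param mcmc a [sem_mcmc()] schedule (or list of its arguments).
#' @param seed global seed.
#' @param out_dir output directory.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(scenario = scenario_config(), inputs = NULL,
                            n_perm = 999, model = 6, coverage = 0.99,
                            trait_sets = c("all", "matching", "energy",
                                           "foraging"),
                            mcmc = sem_mcmc(), seed = 1L,
                            out_dir = "mutualinet_out") {
  if (is.list(scenario) && !inherits(scenario, "scenario_config"))
    scenario <- do.call(scenario_config, scenario)
  if (is.list(mcmc) && !inherits(mcmc, "sem_mcmc"))
    mcmc <- do.call(sem_mcmc, mcmc)
  structure(list(scenario = scenario, inputs = inputs, n_perm = n_perm,
                 model = model, coverage = coverage, trait_sets = trait_sets,
                 mcmc = mcmc, seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline config from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, rlq = 23L, fd = 37L, niche = 41L, sem = 53L)
  (config$seed * 101L + offsets[[stage]]) %% 2147483L
}

#' Run the full analysis pipeline
#'
#' Simulates or ingests a dataset, builds the metawebs, runs the RLQ and
#' fourth-corner stage per mutualism, the functional diversity and niche
#' stages, and both structural equation models, writing every artifact plus
#' a manifest (inputs, seeds, checksums) to the output directory. Any stage
#' failure aborts with the stage name; partial outputs are retained next to
#' a \code{FAILED} marker.
#'
#' @param config a [pipeline_config()] or path to its YAML form.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stage_seeds = list(), outputs = list())
  stage <- "setup"
  on.exit({
    writeLines(paste("failed at stage:", stage), file.path(out, "FAILED"))
  })

  stage <- "simulate/ingest"
  if (!is.null(config$inputs)) {
    dataset <- ingest_dataset(config$inputs)
  } else {
    sc <- config$scenario
    sc$seed <- as.integer(stage_seed(config, "simulate"))
    dataset <- simulate_dataset(sc)
    write_dataset(dataset, file.path(out, "dataset"))
    manifest$stage_seeds$simulate <- sc$seed
  }

  stage <- "rlq"
  rlq_rows <- list()
  pvals <- list()
  for (mut in names(dataset$mutualisms)) {
    d <- dataset$mutualisms[[mut]]
    pt <- sqrt_transform(d$plant_traits)
    at <- sqrt_transform(d$animal_traits)
    L <- d$interactions$metaweb
    fit <- rlq(pt, L, at)
    k <- select_axes(fit, config$coverage)
    cors <- trait_axis_correlations(fit, pt, at, axes = seq_len(k))
    test <- fourth_corner_test(pt, L, at, "sum_eigenvalues",
                               n_perm = config$n_perm, model = config$model,
                               seed = as.integer(stage_seed(config, "rlq")))
    rlq_rows[[mut]] <- data.frame(mutualism = mut,
                                  axis = seq_along(fit$eigenvalues),
                                  eigenvalue = fit$eigenvalues,
                                  percent_covariance = fit$percent_covariance)
    cors$mutualism <- mut
    pvals[[mut]] <- list(sum_eigenvalues = test$observed, p = test$p,
                         p_model2 = test$p_model2, p_model4 = test$p_model4,
                         n_axes_selected = k)
    utils::write.csv(cors, file.path(out, paste0("correlations_", mut, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rlq_rows), file.path(out, "eigenvalues.csv"),
                   row.names = FALSE)
  jsonlite::write_json(pvals, file.path(out, "fourth_corner.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$stage_seeds$rlq <- as.integer(stage_seed(config, "rlq"))

  stage <- "fd"
  fd_rows <- list()
  for (mut in names(dataset$mutualisms)) {
    d <- dataset$mutualisms[[mut]]
    pt <- sqrt_transform(d$plant_traits)
    at <- sqrt_transform(d$animal_traits)
    for (ts in config$trait_sets)
      fd_rows[[paste(mut, ts)]] <- fd_pipeline(
        d$interactions$site_networks, pt, at, trait_set = ts,
        mutualism = mut)
  }
  fd_tab <- do.call(rbind, fd_rows)
  rownames(fd_tab) <- NULL
  utils::write.csv(fd_tab, file.path(out, "functional_diversity.csv"),
                   row.names = FALSE)

  stage <- "niche"
  metrics <- niche_pipeline(dataset)
  utils::write.csv(metrics, file.path(out, "site_metrics.csv"),
                   row.names = FALSE)

  stage <- "sem"
  sem_seed <- as.integer(stage_seed(config, "sem"))
  both <- run_both_models(metrics, mcmc = config$mcmc, seed = sem_seed)
  manifest$stage_seeds$sem <- sem_seed
  for (nm in names(both)) {
    utils::write.csv(both[[nm]]$support,
                     file.path(out, paste0("path_support_", nm, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(both[[nm]]$r2,
                         file.path(out, paste0("r2_", nm, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_draws(both[[nm]]$fit,
                file.path(out, paste0("draws_", nm, ".csv")))
  }

  stage <- "manifest"
  produced <- list.files(out, recursive = TRUE, full.names = TRUE)
  produced <- produced[basename(produced) != "FAILED"]
  validate_outputs(out)
  manifest$outputs <- stats::setNames(
    as.list(unname(tools::md5sum(produced))),
    sub(paste0("^", out, "/?"), "", produced))
  manifest$version <- as.character(utils::packageVersion("mutualinet"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  on.exit()
  unlink(file.path(out, "FAILED"))
  invisible(manifest)
}

# columnar text export of posterior draws: parameter, chain, iteration, value
write_draws <- function(fit, path) {
  sm <- fit$samples
  rows <- lapply(seq_along(sm), function(ch) {
    m <- as.matrix(sm[[ch]])
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

ingest_dataset <- function(inputs) {
  need <- c("interactions", "covariates", "mutualisms")
  miss <- setdiff(need, names(inputs))
  if (length(miss))
    stop("inputs lack: ", paste(miss, collapse = ", "))
  for (f in c(inputs$interactions, inputs$covariates))
    if (!file.exists(f)) stop("missing input file: ", f)
  records <- read_interactions(inputs$interactions)
  cov <- read_covariates(inputs$covariates)
  muts <- lapply(inputs$mutualisms, function(mi) {
    for (f in unlist(mi)) if (!file.exists(f)) stop("missing input file: ", f)
    list(plant_traits = read_trait_table(mi$plant_traits,
                                         metadata = mi$plant_traits_meta,
                                         trophic_level = "plant"),
         animal_traits = read_trait_table(mi$animal_traits,
                                          metadata = mi$animal_traits_meta,
                                          trophic_level = "animal"),
         interactions = NULL)
  })
  for (mut in names(muts)) {
    r <- records[records$mutualism == mut, , drop = FALSE]
    if (nrow(r) == 0) stop("no interaction records for mutualism ", mut)
    muts[[mut]]$interactions <- interaction_data(r)
  }
  structure(list(mutualisms = muts, covariates = cov, records = records,
                 truth = NULL),
            class = "mutualism_dataset")
}

# every numeric output file must parse before the manifest is written
validate_outputs <- function(out) {
  for (f in list.files(out, pattern = "\\.csv$", full.names = TRUE,
                       recursive = TRUE)) {
    d <- utils::read.csv(f)
    if (nrow(d) == 0) stop("empty output table: ", f)
  }
  for (f in list.files(out, pattern = "\\.json$", full.names = TRUE,
                       recursive = TRUE))
    jsonlite::read_json(f)
  invisible(TRUE)
}
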