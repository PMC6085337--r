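#' Scenario configuration for the synthetic-data generator
#'
#' Collects every knob of the data-generating process in one validated list.
#' The defaults are the package's reference study conditions: three
#' mutualisms observed on overlapping subsets of 53 sites along an
#' elevational gradient (39, 20 and 19 sites; the third mutualism resampled
#' within sites so the structural-equation table has 126 observations),
#' Gaussian trait-matching interactions, plant community trait dispersion
#' increasing with precipitation and animal dispersion with temperature, and
#' five nonzero structural paths of standardised magnitude 0.6
#' (MAP -> FD_p, MAT -> FD_a, FD_p -> niche_a, FD_a -> niche_p) and 0.3
#' (MAT -> niche_p, MAT -> niche_a), all other paths zero.
#'
#' @param n_mutualisms number of mutualism types (1-3).
#' @param n_sites integer vector: sites per mutualism.
#' @param n_plants,n_animals species-pool sizes per mutualism.
#' @param n_community mean number of species per trophic level sampled into
#'   each site community (actual sizes vary around it).
#' @param sigma_match width of the Gaussian matching kernel in units of the
#'   matching-trait standard deviation; \code{Inf} switches matching off.
#' @param kernel \code{"gaussian"} or \code{"threshold"} (strict forbidden
#'   links: an animal cannot use a plant whose matching trait exceeds its own
#'   by more than \code{sigma_match}).
#' @param energy_slope,foraging_slope log-linear modulation of interaction
#'   intensity by the product of standardised plant and animal energy
#'   (foraging) traits.
#' @param coefficients named numeric vector of true structural path
#'   coefficients (\code{"MAP->FD_p"} etc.); unnamed paths are zero. Use
#'   [sem_paths()] for the full path set.
#' @param fd_driver_plants,fd_driver_animals strength with which site MAP
#'   (MAT) scales the trait dispersion of the sampled plant (animal)
#'   community in [simulate_dataset()].
#' @param sd_site,sd_mut random-intercept standard deviations (site, crossed
#'   with mutualism) shared by every structural equation.
#' @param resid_sd length-4 residual standard deviations (FD_p, FD_a,
#'   niche_p, niche_a).
#' @param resid_cor length-2 residual correlations within the (FD_p, FD_a)
#'   and (niche_p, niche_a) pairs; must lie in (-1, 1).
#' @param interaction_intensity expected total interaction count per site
#'   network.
#' @param overdispersion \code{NULL} for Poisson counts, or a negative
#'   binomial size parameter.
#' @param seed integer seed; every simulation is fully reproducible from it.
#' @return validated list of class \code{scenario_config}.
#' @export
scenario_config <- function(n_mutualisms = 3,
                            n_sites = c(39, 20, 19),
                            n_plants = 40, n_animals = 40,
                            n_community = 12,
                            sigma_match = 0.5,
                            kernel = c("gaussian", "threshold"),
                            energy_slope = 0.2, foraging_slope = 0.1,
                            coefficients = NULL,
                            fd_driver_plants = 0.6, fd_driver_animals = 0.6,
                            sd_site = 0.3, sd_mut = 0.2,
                            resid_sd = c(1, 1, 1, 1),
                            resid_cor = c(0.3, 0.3),
                            interaction_intensity = 300,
                            overdispersion = NULL,
                            seed = 1L) {
  kernel <- match.arg(kernel)
  if (is.null(coefficients)) coefficients <- default_sem_coefficients()
  full <- stats::setNames(numeric(length(sem_paths())), sem_paths())
  unknown <- setdiff(names(coefficients), names(full))
  if (length(unknown))
    stop("unknown path name(s): ", paste(unknown, collapse = ", "))
  full[names(coefficients)] <- coefficients
  n_sites <- rep_len(n_sites, n_mutualisms)
  stopifnot(sd_site >= 0, sd_mut >= 0, all(resid_sd >= 0),
            all(abs(resid_cor) < 1), sigma_match > 0,
            interaction_intensity > 0)
  structure(list(n_mutualisms = n_mutualisms, n_sites = n_sites,
                 n_plants = n_plants, n_animals = n_animals,
                 n_community = n_community, sigma_match = sigma_match,
                 kernel = kernel, energy_slope = energy_slope,
                 foraging_slope = foraging_slope, coefficients = full,
                 fd_driver_plants = fd_driver_plants,
                 fd_driver_animals = fd_driver_animals,
                 sd_site = sd_site, sd_mut = sd_mut,
                 resid_sd = rep_len(resid_sd, 4),
                 resid_cor = rep_len(resid_cor, 2),
                 interaction_intensity = interaction_intensity,
                 overdispersion = overdispersion,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' The full set of structural paths
#'
#' @return character vector of path names: the three abiotic drivers to each
#'   endogenous variable plus the two functional-diversity to niche paths.
#' @export
sem_paths <- function() {
  exo <- c("MAT", "MAP", "LU")
  endo <- c("FD_p", "FD_a", "niche_p", "niche_a")
  c(as.vector(outer(exo, endo, paste, sep = "->")),
    as.vector(outer(c("FD_p", "FD_a"), c("niche_p", "niche_a"),
                    paste, sep = "->")))
}

default_sem_coefficients <- function() {
  c("MAP->FD_p" = 0.6, "MAT->FD_a" = 0.6,
    "FD_p->niche_a" = 0.6, "FD_a->niche_p" = 0.6,
    "MAT->niche_p" = 0.3, "MAT->niche_a" = 0.3)
}

mutualism_names <- function(n)
  c("bird_fruit", "bird_flower", "insect_flower")[seq_len(n)]

# fixed elevation-climate shape of the gradient: temperature falls almost
# linearly with elevation, precipitation peaks mid-slope (~2200 m)
site_gradient <- function(n_sites_total) {
  elev <- seq(870, 4400, length.out = n_sites_total)
  data.frame(
    site_id = sprintf("site%02d", seq_len(n_sites_total)),
    elevation = elev,
    MAT_mean = 25.3 - 0.0056 * elev,
    MAP_mean = 500 + 1800 * exp(-((elev - 2200) / 900)^2),
    stringsAsFactors = FALSE)
}

simulate_covariates <- function(n_sites_total) {
  g <- site_gradient(n_sites_total)
  hab_band <- cut(g$elevation, breaks = c(0, 1150, 2050, 2750, 3000, 3900, Inf),
                  labels = c("savanna", "lower_montane", "ocotea",
                             "podocarpus", "erica", "alpine"))
  lu <- stats::rbinom(n_sites_total, 1, stats::plogis(3 - g$elevation / 700))
  site_covariates(data.frame(
    site_id = g$site_id,
    MAT = g$MAT_mean + stats::rnorm(n_sites_total, 0, 0.3),
    MAP = g$MAP_mean + stats::rnorm(n_sites_total, 0, 50),
    LU = lu, elevation = g$elevation,
    habitat = paste0(as.character(hab_band),
                     ifelse(lu == 1, "_disturbed", "")),
    stringsAsFactors = FALSE))
}

# which of the shared sites each mutualism is observed on
mutualism_site_sets <- function(config, site_ids) {
  n_total <- length(site_ids)
  starts <- c(1, 15, n_total - config$n_sites[min(3, config$n_mutualisms)] + 1)
  lapply(seq_len(config$n_mutualisms), function(m) {
    n <- config$n_sites[m]
    from <- min(starts[m], n_total - n + 1)
    site_ids[seq(from, length.out = n)]
  })
}

species_pool <- function(n, prefix, level) {
  z <- stats::rnorm(n)
  match_sqrt <- pmax(5 + z, 0.2)
  energy <- stats::rlnorm(n, meanlog = 2, sdlog = 0.5)
  foraging <- stats::runif(n, 0.1, 0.9)
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  traits <- data.frame(match_sqrt^2, energy, foraging)
  names(traits) <- paste0(c("matching_", "energy_", "foraging_"), level)
  list(table = trait_table(ids, traits,
                           stats::setNames(c("matching", "energy", "foraging"),
                                           names(traits)),
                           level),
       z = stats::setNames(z, ids),
       match_sqrt = stats::setNames(match_sqrt, ids),
       energy_z = stats::setNames(as.numeric(scale(log(energy))), ids),
       foraging_z = stats::setNames(as.numeric(scale(foraging)), ids))
}

matching_kernel <- function(tp, ta, config) {
  if (config$kernel == "threshold")
    return(outer(tp, ta, function(p, a) as.numeric(a + config$sigma_match >= p)))
  if (!is.finite(config$sigma_match))
    return(matrix(1, length(tp), length(ta)))
  outer(tp, ta, function(p, a)
    exp(-(p - a)^2 / (2 * config$sigma_match^2)))
}

#' Simulate a trait-matching mutualistic network dataset
#'
#' Generates, for each mutualism, plant and animal species pools with
#' positive matching/energy/foraging traits, site communities whose trait
#' dispersion scales with precipitation (plants) and temperature (animals),
#' and per-site interaction counts drawn from a Poisson (optionally negative
#' binomial) law with intensity proportional to log-normal abundances times
#' a Gaussian kernel on the square-root-scale matching-trait difference,
#' modulated by the energy and foraging terms. Site covariates follow the
#' fixed elevation-climate shapes of [scenario_config()].
#'
#' @param config a [scenario_config()].
#' @param trait_independent internal: if \code{TRUE}, interactions ignore
#'   all traits (used by [null_dataset()]).
#' @return object of class \code{mutualism_dataset}: list with
#'   \code{mutualisms} (per mutualism: \code{plant_traits},
#'   \code{animal_traits}, \code{interactions}), \code{covariates},
#'   \code{records} (all mutualisms pooled) and \code{truth} (a
#'   \code{synthetic_truth} list sufficient to re-simulate).
#' @export
simulate_dataset <- function(config = scenario_config(),
                             trait_independent = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n_total <- if (config$n_mutualisms >= 3) max(53, max(config$n_sites)) else
    max(config$n_sites)
  cov <- simulate_covariates(n_total)
  map_z <- as.numeric(scale(cov$MAP))
  mat_z <- as.numeric(scale(cov$MAT))
  names(map_z) <- names(mat_z) <- cov$site_id
  site_sets <- mutualism_site_sets(config, cov$site_id)

  muts <- list()
  all_records <- list()
  for (m in seq_len(config$n_mutualisms)) {
    mut_name <- mutualism_names(config$n_mutualisms)[m]
    pool_p <- species_pool(config$n_plants, paste0("P", m, "_"), "plant")
    pool_a <- species_pool(config$n_animals, paste0("A", m, "_"), "animal")
    recs <- list()
    for (s in site_sets[[m]]) {
      n_cp <- max(3, stats::rpois(1, config$n_community))
      n_ca <- max(3, stats::rpois(1, config$n_community))
      if (trait_independent) {
        comm_p <- sample(names(pool_p$z), min(n_cp, config$n_plants))
        comm_a <- sample(names(pool_a$z), min(n_ca, config$n_animals))
      } else {
        sd_p <- exp(0.4 * config$fd_driver_plants * map_z[s])
        sd_a <- exp(0.4 * config$fd_driver_animals * mat_z[s])
        wp <- stats::dnorm(pool_p$z, 0, sd_p)
        wa <- stats::dnorm(pool_a$z, 0, sd_a)
        comm_p <- sample(names(pool_p$z), min(n_cp, config$n_plants),
                         prob = wp / sum(wp))
        comm_a <- sample(names(pool_a$z), min(n_ca, config$n_animals),
                         prob = wa / sum(wa))
      }
      ab_p <- stats::rlnorm(length(comm_p), 0, 0.7)
      ab_a <- stats::rlnorm(length(comm_a), 0, 0.7)
      K <- if (trait_independent)
        matrix(1, length(comm_p), length(comm_a))
      else {
        K0 <- matching_kernel(pool_p$match_sqrt[comm_p],
                              pool_a$match_sqrt[comm_a], config)
        K0 * exp(config$energy_slope *
                   outer(pool_p$energy_z[comm_p], pool_a$energy_z[comm_a])) *
          exp(config$foraging_slope *
                outer(pool_p$foraging_z[comm_p], pool_a$foraging_z[comm_a]))
      }
      lambda <- outer(ab_p, ab_a) * K
      if (sum(lambda) <= 0)
        stop("configuration implies an empty network at site ", s)
      lambda <- lambda * config$interaction_intensity / sum(lambda)
      counts <- if (is.null(config$overdispersion))
        stats::rpois(length(lambda), lambda)
      else
        stats::rnbinom(length(lambda), size = config$overdispersion,
                       mu = lambda)
      counts <- matrix(counts, nrow(lambda), ncol(lambda))
      idx <- which(counts > 0, arr.ind = TRUE)
      if (nrow(idx))
        recs[[length(recs) + 1L]] <- data.frame(
          site_id = s, mutualism = mut_name,
          plant_id = comm_p[idx[, 1]], animal_id = comm_a[idx[, 2]],
          count = counts[idx], stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    if (is.null(records)) stop("no interactions realised in ", mut_name)
    muts[[mut_name]] <- list(plant_traits = pool_p$table,
                             animal_traits = pool_a$table,
                             interactions = interaction_data(records))
    all_records[[mut_name]] <- records
  }
  truth <- structure(list(config = config,
                          coefficients = config$coefficients,
                          sigma_match = config$sigma_match,
                          fd_driver_plants = config$fd_driver_plants,
                          fd_driver_animals = config$fd_driver_animals,
                          trait_independent = trait_independent,
                          seed = config$seed),
                     class = "synthetic_truth")
  structure(list(mutualisms = muts, covariates = cov,
                 records = do.call(rbind, all_records), truth = truth),
            class = "mutualism_dataset")
}

#' Null dataset: interactions independent of all traits
#'
#' Identical generative process to [simulate_dataset()] except that site
#' communities are uniform random samples of the pools and interaction
#' intensities depend on species abundances only, never on traits. Used for
#' type-I-error studies of the fourth-corner tests.
#'
#' @param config a [scenario_config()].
#' @return a \code{mutualism_dataset}; \code{truth$trait_independent} is
#'   \code{TRUE}.
#' @export
null_dataset <- function(config = scenario_config()) {
  simulate_dataset(config, trait_independent = TRUE)
}

#' Simulate a site-metrics table directly from the structural equations
#'
#' Draws the exact data-generating process the hierarchical SEM assumes:
#' z-scaled MAT, MAP and LU from the elevational gradient, then functional
#' diversities with bivariate-normal residuals, then niche variables with
#' their own correlated residuals, plus equation-specific site and mutualism
#' random intercepts on the crossed (site, mutualism) observation design.
#'
#' @param config a [scenario_config()]; \code{config$coefficients} are the
#'   true standardised path weights.
#' @return list with \code{metrics} (data frame: site_id, mutualism, MAT,
#'   MAP, LU, FD_p, FD_a, niche_p, niche_a) and \code{truth}.
#' @export
simulate_sem_table <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  n_total <- if (config$n_mutualisms >= 3) max(53, max(config$n_sites)) else
    max(config$n_sites)
  cov <- simulate_covariates(n_total)
  site_sets <- mutualism_site_sets(config, cov$site_id)
  # observation design: one row per sampling event; the third mutualism is
  # resampled within sites until 126 observations in the reference scenario
  obs <- do.call(rbind, lapply(seq_len(config$n_mutualisms), function(m) {
    sites <- site_sets[[m]]
    if (config$n_mutualisms >= 3 && m == 3) {
      reps <- rep(sites, length.out = 67)
      data.frame(site_id = reps, mutualism = mutualism_names(3)[m],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(site_id = sites,
                 mutualism = mutualism_names(config$n_mutualisms)[m],
                 stringsAsFactors = FALSE)
    }
  }))
  n <- nrow(obs)
  if (n < 30) stop("n_sites x n_mutualisms must give at least 30 observations")
  i <- match(obs$site_id, cov$site_id)
  X <- cbind(MAT = as.numeric(scale(cov$MAT[i])),
             MAP = as.numeric(scale(cov$MAP[i])),
             LU = as.numeric(scale(cov$LU[i])))
  b <- config$coefficients
  site_f <- factor(obs$site_id)
  mut_f <- factor(obs$mutualism)
  re <- function() {
    u_site <- stats::rnorm(nlevels(site_f), 0, config$sd_site)
    u_mut <- stats::rnorm(nlevels(mut_f), 0, config$sd_mut)
    u_site[site_f] + u_mut[mut_f]
  }
  bvn <- function(sd1, sd2, rho) {
    S <- matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2)
    ev <- eigen(S, symmetric = TRUE)
    if (any(ev$values <= 0))
      stop("residual covariance not positive definite")
    z <- matrix(stats::rnorm(2 * n), n, 2)
    z %*% (ev$vectors %*% diag(sqrt(ev$values)) %*% t(ev$vectors))
  }
  e_fd <- bvn(config$resid_sd[1], config$resid_sd[2], config$resid_cor[1])
  FD_p <- b["MAT->FD_p"] * X[, "MAT"] + b["MAP->FD_p"] * X[, "MAP"] +
    b["LU->FD_p"] * X[, "LU"] + re() + e_fd[, 1]
  FD_a <- b["MAT->FD_a"] * X[, "MAT"] + b["MAP->FD_a"] * X[, "MAP"] +
    b["LU->FD_a"] * X[, "LU"] + re() + e_fd[, 2]
  e_n <- bvn(config$resid_sd[3], config$resid_sd[4], config$resid_cor[2])
  niche_p <- b["MAT->niche_p"] * X[, "MAT"] + b["MAP->niche_p"] * X[, "MAP"] +
    b["LU->niche_p"] * X[, "LU"] + b["FD_p->niche_p"] * FD_p +
    b["FD_a->niche_p"] * FD_a + re() + e_n[, 1]
  niche_a <- b["MAT->niche_a"] * X[, "MAT"] + b["MAP->niche_a"] * X[, "MAP"] +
    b["LU->niche_a"] * X[, "LU"] + b["FD_p->niche_a"] * FD_p +
    b["FD_a->niche_a"] * FD_a + re() + e_n[, 2]
  metrics <- data.frame(obs, MAT = X[, "MAT"], MAP = X[, "MAP"],
                        LU = X[, "LU"], FD_p = FD_p, FD_a = FD_a,
                        niche_p = niche_p, niche_a = niche_a,
                        stringsAsFactors = FALSE)
  truth <- structure(list(config = config, coefficients = b,
                          sd_site = config$sd_site, sd_mut = config$sd_mut,
                          resid_sd = config$resid_sd,
                          resid_cor = config$resid_cor, seed = config$seed),
                     class = "synthetic_truth")
  list(metrics = metrics, truth = truth)
}

#' Write a synthetic dataset to the package's CSV dialects
#'
#' Emits per-mutualism trait CSVs with metadata companions, one pooled
#' interaction CSV, the covariates CSV and a truth JSON (seed, kernel and
#' structural coefficients).
#'
#' @param dataset a \code{mutualism_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (mut in names(dataset$mutualisms)) {
    d <- dataset$mutualisms[[mut]]
    for (lv in c("plant", "animal")) {
      tab <- if (lv == "plant") d$plant_traits else d$animal_traits
      f <- file.path(dir, paste0(mut, "_", lv, "_traits.csv"))
      utils::write.csv(as.data.frame(tab), f, row.names = FALSE)
      md <- data.frame(trait = trait_columns(tab),
                       trait_type = unname(attr(tab, "trait_types")))
      fm <- file.path(dir, paste0(mut, "_", lv, "_traits_meta.csv"))
      utils::write.csv(md, fm, row.names = FALSE)
      files <- c(files, f, fm)
    }
  }
  f <- file.path(dir, "interactions.csv")
  utils::write.csv(dataset$records, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "covariates.csv")
  utils::write.csv(as.data.frame(dataset$covariates), f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  tr <- dataset$truth
  jsonlite::write_json(list(seed = tr$seed, sigma_match = tr$sigma_match,
                            coefficients = as.list(tr$coefficients),
                            trait_independent = isTRUE(tr$trait_independent)),
                       f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}
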