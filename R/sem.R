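#' MCMC schedule for the hierarchical structural equation model
#'
#' The full reference schedule (\code{reference = TRUE}) runs 8 chains of 51,000
#' iterations with 1,000 adaptation iterations and thinning 100, i.e. 4,000
#' retained draws. The default desk schedule (4 chains x 5,000, thinning 10)
#' keeps the same retained sample size at a fraction of the cost and is
#' adequate for the n = 126 reference scenario.
#'
#' @param chains number of parallel chains.
#' @param iter post-adaptation iterations per chain.
#' @param adapt adaptation (burn-in) iterations.
#' @param thin thinning interval.
#' @param pilot_chains,pilot_iter,pilot_adapt schedule of the pilot run used
#'   to adapt the pseudo-priors (see [fit_sem()]).
#' @param reference if \code{TRUE}, use the full reference schedule.
#' @return list of class \code{sem_mcmc}.
#' @export
sem_mcmc <- function(chains = 4, iter = 5000, adapt = 1000, thin = 10,
                     pilot_chains = 1, pilot_iter = 2000, pilot_adapt = 500,
                     reference = FALSE) {
  if (reference) {
    chains <- 8; iter <- 51000; adapt <- 1000; thin <- 100
    pilot_chains <- 2; pilot_iter <- 10000; pilot_adapt <- 1000
  }
  structure(list(chains = chains, iter = iter, adapt = adapt, thin = thin,
                 pilot_chains = pilot_chains, pilot_iter = pilot_iter,
                 pilot_adapt = pilot_adapt),
            class = "sem_mcmc")
}

sem_model_string <- function(selection = TRUE) {
  sel_fd <- if (selection) "
    g_fd[j,k] ~ dbern(0.5)
    theta_fd[j,k] ~ dnorm((1 - g_fd[j,k]) * pm_fd[j,k],
      g_fd[j,k] * slab_prec + (1 - g_fd[j,k]) * pow(ps_fd[j,k], -2))
    beta_fd[j,k] <- g_fd[j,k] * theta_fd[j,k]" else "
    theta_fd[j,k] ~ dnorm(0, slab_prec)
    beta_fd[j,k] <- theta_fd[j,k]"
  sel_n <- if (selection) "
    g_n[j,k] ~ dbern(0.5)
    theta_n[j,k] ~ dnorm((1 - g_n[j,k]) * pm_n[j,k],
      g_n[j,k] * slab_prec + (1 - g_n[j,k]) * pow(ps_n[j,k], -2))
    beta_n[j,k] <- g_n[j,k] * theta_n[j,k]" else "
    theta_n[j,k] ~ dnorm(0, slab_prec)
    beta_n[j,k] <- theta_n[j,k]"
  paste0("
model {
  for (i in 1:N) {
    y_fd[i, 1:2] ~ dmnorm(mu_fd[i, 1:2], Tau_fd)
    y_n[i, 1:2] ~ dmnorm(mu_n[i, 1:2], Tau_n)
    for (k in 1:2) {
      mu_fd[i, k] <- a0_fd[k] + inprod(beta_fd[1:3, k], X[i, 1:3]) +
        u_site_fd[site[i], k] + u_mut_fd[mut[i], k]
      mu_n[i, k] <- a0_n[k] + inprod(beta_n[1:5, k], Z[i, 1:5]) +
        u_site_n[site[i], k] + u_mut_n[mut[i], k]
    }
  }
  for (j in 1:3) { for (k in 1:2) {", sel_fd, "
  }}
  for (j in 1:5) { for (k in 1:2) {", sel_n, "
  }}
  for (k in 1:2) {
    a0_fd[k] ~ dnorm(0, intercept_prec)
    a0_n[k] ~ dnorm(0, intercept_prec)
    sd_fd[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    sd_n[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    sd_site_fd[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    sd_site_n[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    sd_mut_fd[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    sd_mut_n[k] ~ dt(0, pow(2.5, -2), 1) T(0,)
    for (s in 1:NS) {
      u_site_fd[s, k] ~ dnorm(0, pow(sd_site_fd[k], -2))
      u_site_n[s, k] ~ dnorm(0, pow(sd_site_n[k], -2))
    }
    for (g in 1:NM) {
      u_mut_fd[g, k] ~ dnorm(0, pow(sd_mut_fd[k], -2))
      u_mut_n[g, k] ~ dnorm(0, pow(sd_mut_n[k], -2))
    }
  }
  rho_fd ~ dunif(-1, 1)
  rho_n ~ dunif(-1, 1)
  Sigma_fd[1, 1] <- pow(sd_fd[1], 2)
  Sigma_fd[2, 2] <- pow(sd_fd[2], 2)
  Sigma_fd[1, 2] <- rho_fd * sd_fd[1] * sd_fd[2]
  Sigma_fd[2, 1] <- Sigma_fd[1, 2]
  Tau_fd <- inverse(Sigma_fd)
  Sigma_n[1, 1] <- pow(sd_n[1], 2)
  Sigma_n[2, 2] <- pow(sd_n[2], 2)
  Sigma_n[1, 2] <- rho_n * sd_n[1] * sd_n[2]
  Sigma_n[2, 1] <- Sigma_n[1, 2]
  Tau_n <- inverse(Sigma_n)
}
")
}

sem_prepare_data <- function(metrics, niche) {
  if (inherits(metrics, "site_metrics")) metrics <- scale_metrics(metrics)
  cols <- switch(niche,
                 eH = c("ln_eH_p", "ln_eH_a"),
                 dprime = c("dprime_p", "dprime_a"),
                 direct = c("niche_p", "niche_a"))
  need <- c("site_id", "mutualism", "MAT", "MAP", "LU", "FD_p", "FD_a", cols)
  miss <- setdiff(need, colnames(metrics))
  if (length(miss))
    stop("metrics lack column(s): ", paste(miss, collapse = ", "))
  if (anyNA(metrics[need])) stop("metrics contain missing cells")
  z <- function(x) as.numeric(scale(x))
  site <- factor(metrics$site_id)
  mut <- factor(metrics$mutualism)
  if (nlevels(mut) < 2) stop("need at least 2 mutualisms")
  if (nlevels(site) < 10) stop("need at least 10 sites")
  y_fd <- cbind(z(metrics$FD_p), z(metrics$FD_a))
  y_n <- cbind(z(metrics[[cols[1]]]), z(metrics[[cols[2]]]))
  X <- cbind(z(metrics$MAT), z(metrics$MAP), z(metrics$LU))
  list(N = nrow(metrics), NS = nlevels(site), NM = nlevels(mut),
       site = as.integer(site), mut = as.integer(mut),
       X = X, Z = cbind(X, y_fd), y_fd = y_fd, y_n = y_n,
       # weakly informative slab on z-scale path coefficients: an over-diffuse
       # slab penalises inclusion through the prior-odds (Lindley) effect and
       # cripples the indicator selection; 2.5 matches the half-Cauchy scale
       slab_prec = 1 / 2.5^2, intercept_prec = 1 / 100)
}

sem_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed * 1000L + ch) %% 2147483L + 1L))
}

sem_path_names <- function() {
  exo <- c("MAT", "MAP", "LU")
  list(fd = outer(exo, c("FD_p", "FD_a"), paste, sep = "->"),
       n = outer(c(exo, "FD_p", "FD_a"), c("niche_p", "niche_a"),
                 paste, sep = "->"))
}

run_jags <- function(model_string, data, monitors, chains, iter, adapt, thin,
                     seed) {
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          n.chains = chains, n.adapt = adapt,
                          inits = sem_inits(chains, seed), quiet = TRUE)
  rjags::coda.samples(jm, variable.names = monitors, n.iter = iter,
                      thin = thin)
}

#' Fit the Bayesian hierarchical structural equation model
#'
#' Two bivariate-Gaussian structural blocks on z-scaled data: functional
#' diversities (FD_p, FD_a) regressed on MAT, MAP and LU, and the niche pair
#' regressed on MAT, MAP, LU, FD_p and FD_a, each with correlated residuals
#' within the pair and equation-specific random intercepts for study site
#' and mutualism type (crossed). Every directed path carries a stochastic
#' selection indicator (prior inclusion probability 1/2): the effective
#' coefficient is \eqn{\beta_k = \gamma_k \theta_k}. When a path is excluded
#' its free coefficient follows a pseudo-prior centred on the posterior
#' obtained from a pilot run without selection ("global adaptation"), which
#' keeps the Gibbs sampler mixing across models. Priors: weakly informative
#' Normal(0, 2.5^2) slab on the (z-scale) path coefficients -- a more
#' diffuse slab would penalise inclusion through the prior odds and blunt
#' the selection -- Normal(0, 10^2) on intercepts, half-Cauchy(2.5) on all
#' standard deviations, Uniform(-1, 1) on residual correlations.
#'
#' @param metrics a [niche_pipeline()] table, a [scale_metrics()] frame, or
#'   a table from [simulate_sem_table()] (use \code{niche = "direct"}).
#' @param niche which niche metric pair forms the second block:
#'   \code{"eH"} (log effective partners), \code{"dprime"}, or
#'   \code{"direct"} (columns named \code{niche_p}, \code{niche_a}).
#' @param mcmc a [sem_mcmc()] schedule.
#' @param seed integer; all chain RNGs derive from it.
#' @param selection set \code{FALSE} to fit without indicator selection
#'   (all paths included), e.g. for maximum-likelihood comparisons.
#' @return object of class \code{sem_fit}: \code{samples} (a
#'   \code{coda::mcmc.list}), path name tables, pseudo-prior table,
#'   convergence diagnostics (\code{rhat}, \code{ess}, \code{converged}),
#'   and the prepared data.
#' @export
fit_sem <- function(metrics, niche = c("eH", "dprime", "direct"),
                    mcmc = sem_mcmc(), seed = 1L, selection = TRUE) {
  niche <- match.arg(niche)
  dat <- sem_prepare_data(metrics, niche)
  base_monitors <- c("theta_fd", "theta_n", "a0_fd", "a0_n",
                     "sd_fd", "sd_n", "rho_fd", "rho_n",
                     "sd_site_fd", "sd_site_n", "sd_mut_fd", "sd_mut_n")
  if (!selection) {
    samples <- run_jags(sem_model_string(selection = FALSE), dat,
                        base_monitors, mcmc$chains, mcmc$iter, mcmc$adapt,
                        mcmc$thin, seed)
    pseudo <- NULL
  } else {
    # pilot run without selection tunes the pseudo-priors
    pilot <- run_jags(sem_model_string(selection = FALSE), dat,
                      c("theta_fd", "theta_n"), mcmc$pilot_chains,
                      mcmc$pilot_iter, mcmc$pilot_adapt,
                      max(1L, mcmc$thin %/% 2L), seed + 7L)
    pm <- as.matrix(pilot)
    pil_mean <- colMeans(pm)
    pil_sd <- apply(pm, 2, stats::sd)
    get_mat <- function(stat, prefix, nr, nc) {
      out <- matrix(NA_real_, nr, nc)
      for (j in seq_len(nr)) for (k in seq_len(nc))
        out[j, k] <- stat[paste0(prefix, "[", j, ",", k, "]")]
      out
    }
    dat$pm_fd <- get_mat(pil_mean, "theta_fd", 3, 2)
    dat$ps_fd <- pmax(get_mat(pil_sd, "theta_fd", 3, 2), 1e-3)
    dat$pm_n <- get_mat(pil_mean, "theta_n", 5, 2)
    dat$ps_n <- pmax(get_mat(pil_sd, "theta_n", 5, 2), 1e-3)
    pseudo <- list(pm_fd = dat$pm_fd, ps_fd = dat$ps_fd,
                   pm_n = dat$pm_n, ps_n = dat$ps_n)
    samples <- run_jags(sem_model_string(selection = TRUE), dat,
                        c(base_monitors, "g_fd", "g_n"),
                        mcmc$chains, mcmc$iter, mcmc$adapt, mcmc$thin, seed)
  }
  diag <- sem_convergence(samples)
  structure(list(samples = samples, niche = niche, selection = selection,
                 paths = sem_path_names(), data = dat, mcmc = mcmc,
                 seed = seed, pseudo_priors = pseudo,
                 rhat = diag$rhat, ess = diag$ess,
                 converged = diag$converged),
            class = "sem_fit")
}

sem_convergence <- function(samples, rhat_limit = 1.05) {
  ess <- coda::effectiveSize(samples)
  rhat <- NULL
  converged <- NA
  if (coda::nchain(samples) >= 2) {
    keep <- colnames(samples[[1]])
    # indicators and their conditional coefficients are bimodal by design;
    # R-hat applies to the continuous non-selection parameters
    keep <- keep[!grepl("^(g_fd|g_n|theta_fd|theta_n)\\[", keep)]
    gd <- try(coda::gelman.diag(samples[, keep, drop = FALSE],
                                multivariate = FALSE, autoburnin = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) {
      rhat <- gd$psrf[, 1]
      converged <- all(is.finite(rhat[rhat > 0])) && max(rhat, na.rm = TRUE) < rhat_limit
    }
  }
  list(rhat = rhat, ess = ess, converged = converged)
}

sem_draws <- function(fit) as.matrix(fit$samples)

#' Path support from posterior inclusion frequencies
#'
#' Converts the posterior inclusion frequency \eqn{p_k} of each selection
#' indicator into a Bayes factor against its prior inclusion odds,
#' \eqn{BF_k = \frac{p_k/(1-p_k)}{\pi/(1-\pi)}}, and reports
#' \eqn{2\ln BF} with the conventional support categories: < 2 none,
#' 2-6 positive, 6-10 strong, > 10 decisive. Inclusion frequencies of
#' exactly 0 or 1 are clipped to the resolution of the posterior sample
#' (1/(n_draws+1)) and flagged saturated. The conditional posterior of each
#' coefficient given inclusion is summarised alongside.
#'
#' @param fit a [fit_sem()] result (with selection).
#' @param prior_inclusion prior inclusion probability (default 0.5).
#' @return data frame of class \code{path_support}: path, inclusion_prob,
#'   two_ln_bf, category, saturated, beta_mean, beta_lo, beta_hi (95\%
#'   conditional credible interval).
#' @export
bayes_factors <- function(fit, prior_inclusion = 0.5) {
  stopifnot(inherits(fit, "sem_fit"))
  if (!fit$selection) stop("fit has no selection indicators")
  draws <- sem_draws(fit)
  n_draws <- nrow(draws)
  eps <- 1 / (n_draws + 1)
  prior_odds <- prior_inclusion / (1 - prior_inclusion)
  rows <- list()
  for (block in c("fd", "n")) {
    pn <- fit$paths[[block]]
    for (j in seq_len(nrow(pn))) for (k in seq_len(ncol(pn))) {
      gcol <- paste0("g_", block, "[", j, ",", k, "]")
      tcol <- paste0("theta_", block, "[", j, ",", k, "]")
      g <- draws[, gcol]
      p_raw <- mean(g)
      saturated <- p_raw %in% c(0, 1)
      p <- min(max(p_raw, eps), 1 - eps)
      two_ln_bf <- 2 * log((p / (1 - p)) / prior_odds)
      incl <- draws[g == 1, tcol]
      rows[[length(rows) + 1L]] <- data.frame(
        path = pn[j, k], inclusion_prob = p_raw, two_ln_bf = two_ln_bf,
        category = as.character(cut(two_ln_bf, c(-Inf, 2, 6, 10, Inf),
                                    labels = c("none", "positive", "strong",
                                               "decisive"))),
        saturated = saturated,
        beta_mean = if (length(incl)) mean(incl) else NA_real_,
        beta_sd = if (length(incl) > 1) stats::sd(incl) else NA_real_,
        beta_lo = if (length(incl) > 1)
          unname(stats::quantile(incl, 0.025)) else NA_real_,
        beta_hi = if (length(incl) > 1)
          unname(stats::quantile(incl, 0.975)) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$category <- ifelse(out$saturated & out$inclusion_prob == 1,
                         "decisive (saturated)", out$category)
  class(out) <- c("path_support", "data.frame")
  out
}

#' Marginal and conditional variance decomposition
#'
#' For each endogenous variable and each posterior draw, the variance of the
#' fixed-effect linear predictor over the observed design is combined with
#' the random-intercept and residual variances:
#' \deqn{r^2_m = \frac{V_f}{V_f + V_{site} + V_{mut} + V_{res}}, \quad
#'       r^2_c = \frac{V_f + V_{site} + V_{mut}}{V_f + V_{site} + V_{mut} +
#'       V_{res}}.}
#' Posterior medians are reported; \eqn{r^2_m \le r^2_c} holds on every
#' draw by construction.
#'
#' @param fit a [fit_sem()] result.
#' @return list with \code{summary} (data frame: variable, r2_marginal,
#'   r2_conditional) and \code{draws} (per-draw matrices).
#' @export
r2_decomposition <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  draws <- sem_draws(fit)
  dat <- fit$data
  endo <- c("FD_p", "FD_a", "niche_p", "niche_a")
  r2m <- r2c <- matrix(NA_real_, nrow(draws), 4,
                       dimnames = list(NULL, endo))
  design <- list(dat$X, dat$X, dat$Z, dat$Z)
  blocks <- c("fd", "fd", "n", "n")
  kk <- c(1, 2, 1, 2)
  for (v in 1:4) {
    blk <- blocks[v]
    k <- kk[v]
    np <- nrow(fit$paths[[blk]])
    bcols <- paste0("theta_", blk, "[", seq_len(np), ",", k, "]")
    B <- draws[, bcols, drop = FALSE]
    if (fit$selection) {
      G <- draws[, paste0("g_", blk, "[", seq_len(np), ",", k, "]"),
                 drop = FALSE]
      B <- B * G
    }
    eta <- B %*% t(design[[v]])
    var_f <- apply(eta, 1, stats::var)
    var_site <- draws[, paste0("sd_site_", blk, "[", k, "]")]^2
    var_mut <- draws[, paste0("sd_mut_", blk, "[", k, "]")]^2
    var_res <- draws[, paste0("sd_", blk, "[", k, "]")]^2
    denom <- var_f + var_site + var_mut + var_res
    r2m[, v] <- var_f / denom
    r2c[, v] <- (var_f + var_site + var_mut) / denom
  }
  list(summary = data.frame(variable = endo,
                            r2_marginal = apply(r2m, 2, stats::median),
                            r2_conditional = apply(r2c, 2, stats::median),
                            row.names = NULL),
       draws = list(r2_marginal = r2m, r2_conditional = r2c))
}

#' Closed-form marginal/conditional r-squared from variance components
#'
#' @param var_fixed variance of the fixed-effect predictor.
#' @param var_random summed random-intercept variance.
#' @param var_residual residual variance.
#' @return named vector \code{c(r2_marginal, r2_conditional)}.
#' @export
r2_from_variances <- function(var_fixed, var_random, var_residual) {
  denom <- var_fixed + var_random + var_residual
  c(r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + var_random) / denom)
}

#' Fit both niche-metric structural equation models
#'
#' Fits the model once with log effective partner numbers and once with d'
#' as the niche block, with identical path topology, and returns the path
#' support and variance decompositions of each.
#'
#' @param metrics a [niche_pipeline()] table containing both niche metric
#'   pairs.
#' @param mcmc a [sem_mcmc()] schedule.
#' @param seed integer seed.
#' @return list with elements \code{eH} and \code{dprime}, each holding
#'   \code{fit}, \code{support} and \code{r2}.
#' @export
run_both_models <- function(metrics, mcmc = sem_mcmc(), seed = 1L) {
  out <- lapply(stats::setNames(c("eH", "dprime"), c("eH", "dprime")),
                function(nm) {
    fit <- fit_sem(metrics, niche = nm, mcmc = mcmc, seed = seed)
    list(fit = fit, support = bayes_factors(fit),
         r2 = r2_decomposition(fit)$summary)
  })
  out
}

#' True path coefficients on the z-scale of a simulated table
#'
#' [simulate_sem_table()] draws data with coefficients on the generator's
#' scale; [fit_sem()] z-scales every variable before fitting. This helper
#' maps the generating coefficients onto the fitted scale,
#' \eqn{\beta' = \beta\, sd(x)/sd(y)}, using the realised sample standard
#' deviations, so posterior summaries can be compared to truth directly.
#'
#' @param sem_table result of [simulate_sem_table()].
#' @return named numeric vector over [sem_paths()].
#' @export
scaled_truth <- function(sem_table) {
  m <- sem_table$metrics
  b <- sem_table$truth$coefficients
  s <- vapply(m[c("MAT", "MAP", "LU", "FD_p", "FD_a", "niche_p", "niche_a")],
              stats::sd, numeric(1))
  out <- b
  for (p in names(b)) {
    xy <- strsplit(p, "->", fixed = TRUE)[[1]]
    out[p] <- b[p] * s[xy[1]] / s[xy[2]]
  }
  out
}

#' @export
print.sem_fit <- function(x, ...) {
  cat("Hierarchical SEM fit (niche = ", x$niche, ", ",
      if (x$selection) "with" else "without", " indicator selection)\n",
      sep = "")
  cat(coda::nchain(x$samples), "chains,", coda::niter(x$samples),
      "retained draws each\n")
  if (!is.null(x$rhat))
    cat("max R-hat:", round(max(x$rhat, na.rm = TRUE), 3),
        if (isTRUE(x$converged)) "(converged)" else "(check convergence)",
        "\n")
  invisible(x)
}
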