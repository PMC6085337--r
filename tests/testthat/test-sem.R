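# one moderately-sized reference fit shared by several tests
sem_fit_cache <- new.env(parent = emptyenv())
get_reference_fit <- function() {
  if (is.null(sem_fit_cache$fit)) {
    sem_fit_cache$table <- simulate_sem_table(scenario_config(seed = 7))
    sem_fit_cache$fit <- fit_sem(sem_fit_cache$table$metrics,
                                 niche = "direct", mcmc = tiny_mcmc(),
                                 seed = 3)
  }
  list(fit = sem_fit_cache$fit, table = sem_fit_cache$table)
}

fake_selection_fit <- function(n_draws = 1000) {
  set.seed(101)
  cols <- list()
  pn <- mutualinet::sem_paths()
  for (j in 1:3) for (k in 1:2) {
    cols[[paste0("g_fd[", j, ",", k, "]")]] <- rep(0, n_draws)
    cols[[paste0("theta_fd[", j, ",", k, "]")]] <- rnorm(n_draws, 0.5, 0.1)
  }
  for (j in 1:5) for (k in 1:2) {
    cols[[paste0("g_n[", j, ",", k, "]")]] <- rep(0, n_draws)
    cols[[paste0("theta_n[", j, ",", k, "]")]] <- rnorm(n_draws, 0.5, 0.1)
  }
  # MAT->FD_p: inclusion 0.9; MAP->FD_p: 0.5; LU->FD_p: saturated at 1
  cols[["g_fd[1,1]"]][1:900] <- 1
  cols[["g_fd[2,1]"]][1:500] <- 1
  cols[["g_fd[3,1]"]][] <- 1
  m <- do.call(cbind, cols)
  structure(list(samples = coda::mcmc.list(coda::mcmc(m)),
                 selection = TRUE,
                 paths = list(fd = outer(c("MAT", "MAP", "LU"),
                                         c("FD_p", "FD_a"), paste, sep = "->"),
                              n = outer(c("MAT", "MAP", "LU", "FD_p", "FD_a"),
                                        c("niche_p", "niche_a"),
                                        paste, sep = "->"))),
            class = "sem_fit")
}

test_that("Bayes factors follow the inclusion-odds formula and categories", {
  fit <- fake_selection_fit()
  bf <- bayes_factors(fit)
  expect_equal(nrow(bf), 16)
  g11 <- bf[bf$path == "MAT->FD_p", ]
  expect_equal(g11$inclusion_prob, 0.9)
  expect_equal(g11$two_ln_bf, 2 * log(9), tolerance = 1e-10)
  expect_equal(round(g11$two_ln_bf, 3), 4.394)
  expect_equal(g11$category, "positive")
  g21 <- bf[bf$path == "MAP->FD_p", ]
  expect_equal(g21$two_ln_bf, 0, tolerance = 1e-10)
  expect_equal(g21$category, "none")
  # saturated inclusion is clipped and flagged
  g31 <- bf[bf$path == "LU->FD_p", ]
  expect_true(g31$saturated)
  expect_equal(g31$category, "decisive (saturated)")
  expect_true(is.finite(g31$two_ln_bf))
  # a different prior inclusion shifts the odds baseline
  bf2 <- bayes_factors(fit, prior_inclusion = 0.9)
  expect_equal(bf2$two_ln_bf[bf2$path == "MAT->FD_p"], 0, tolerance = 1e-10)
})

test_that("r-squared decomposition obeys its algebra", {
  # closed-form fixture: fixed 1, random 1, residual 2
  expect_equal(unname(r2_from_variances(1, 1, 2)), c(0.25, 0.5))
  expect_equal(unname(r2_from_variances(0, 1, 2))[1], 0)
  ref <- get_reference_fit()
  r2 <- r2_decomposition(ref$fit)
  expect_true(all(r2$draws$r2_marginal <= r2$draws$r2_conditional + 1e-12))
  expect_true(all(r2$draws$r2_conditional <= 1 + 1e-12))
  expect_true(all(r2$draws$r2_marginal >= 0))
  # draws in which every path of an equation is excluded explain nothing
  draws <- as.matrix(ref$fit$samples)
  gcols <- paste0("g_fd[", 1:3, ",1]")
  all_off <- rowSums(draws[, gcols]) == 0
  if (any(all_off))
    expect_equal(max(r2$draws$r2_marginal[all_off, "FD_p"]), 0,
                 tolerance = 1e-12)
  expect_equal(r2$summary$variable, c("FD_p", "FD_a", "niche_p", "niche_a"))
})

test_that("identical seeds give identical retained draws", {
  st <- simulate_sem_table(small_scenario(seed = 12, n_mutualisms = 2,
                                          n_sites = c(20, 20)))
  mc <- sem_mcmc(chains = 1, iter = 600, adapt = 200, thin = 3,
                 pilot_chains = 1, pilot_iter = 400, pilot_adapt = 200)
  f1 <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = 5)
  f2 <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = 5)
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
  f3 <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = 6)
  expect_false(identical(as.matrix(f1$samples), as.matrix(f3$samples)))
})

test_that("posterior means agree with a maximum-likelihood mixed model fit", {
  skip_if_not_installed("lme4")
  cfg <- scenario_config(n_mutualisms = 3, n_sites = c(300, 300, 19),
                         seed = 21)
  st <- simulate_sem_table(cfg)
  mc <- sem_mcmc(chains = 1, iter = 1500, adapt = 300, thin = 3)
  fit <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = 9,
                 selection = FALSE)
  draws <- as.matrix(fit$samples)
  # FD_p equation on the z-scale, against lmer on the same prepared data
  dat <- mutualinet:::sem_prepare_data(st$metrics, "direct")
  df <- data.frame(y = dat$y_fd[, 1], MAT = dat$X[, 1], MAP = dat$X[, 2],
                   LU = dat$X[, 3], site = dat$site, mut = dat$mut)
  ml <- lme4::lmer(y ~ MAT + MAP + LU + (1 | site) + (1 | mut), data = df,
                   REML = FALSE)
  ml_beta <- lme4::fixef(ml)[c("MAT", "MAP", "LU")]
  post_beta <- colMeans(draws[, paste0("theta_fd[", 1:3, ",1]")])
  for (j in 1:3) {
    tol <- max(0.05 * abs(ml_beta[j]), 0.03)
    expect_lt(abs(post_beta[j] - ml_beta[j]), tol)
  }
})

test_that("residual correlations are recovered", {
  covered <- 0
  means <- numeric(0)
  for (i in 1:3) {
    cfg <- scenario_config(seed = 400 + i, resid_cor = c(0.5, 0.3))
    st <- simulate_sem_table(cfg)
    mc <- sem_mcmc(chains = 1, iter = 1200, adapt = 300, thin = 3)
    fit <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = i,
                   selection = FALSE)
    rho <- as.matrix(fit$samples)[, "rho_fd"]
    ci <- quantile(rho, c(0.025, 0.975))
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) covered <- covered + 1
    means <- c(means, mean(rho))
  }
  expect_gte(covered, 2)
  expect_lt(abs(mean(means) - 0.5), 0.25)
})

test_that("credible intervals are calibrated on data drawn from the model", {
  # parameters at the reference conditions, refit without selection:
  # pooled 95% interval coverage of the 16 true paths stays near nominal
  hits <- 0; total <- 0
  for (i in 1:5) {
    st <- simulate_sem_table(scenario_config(seed = 700 + i))
    truth <- scaled_truth(st)
    mc <- sem_mcmc(chains = 1, iter = 1000, adapt = 250, thin = 2)
    fit <- fit_sem(st$metrics, niche = "direct", mcmc = mc, seed = i,
                   selection = FALSE)
    draws <- as.matrix(fit$samples)
    pn <- fit$paths
    for (blk in c("fd", "n")) {
      nm <- pn[[blk]]
      for (j in seq_len(nrow(nm))) for (k in 1:2) {
        th <- draws[, paste0("theta_", blk, "[", j, ",", k, "]")]
        ci <- quantile(th, c(0.025, 0.975))
        total <- total + 1
        if (ci[1] <= truth[nm[j, k]] && truth[nm[j, k]] <= ci[2])
          hits <- hits + 1
      }
    }
  }
  expect_gte(hits / total, 0.8)
})

test_that("both niche models fit with identical path topology", {
  cfg <- scenario_config(n_mutualisms = 2, n_sites = c(12, 12),
                         n_plants = 20, n_animals = 20, n_community = 8,
                         interaction_intensity = 150, seed = 31)
  ds <- simulate_dataset(cfg)
  mets <- niche_pipeline(ds)
  mc <- sem_mcmc(chains = 1, iter = 800, adapt = 200, thin = 2,
                 pilot_chains = 1, pilot_iter = 400, pilot_adapt = 200)
  both <- run_both_models(mets, mcmc = mc, seed = 2)
  expect_named(both, c("eH", "dprime"))
  for (nm in names(both)) {
    sup <- both[[nm]]$support
    expect_setequal(sup$path, sem_paths())
    expect_true(all(sup$category %in%
                      c("none", "positive", "strong", "decisive",
                        "decisive (saturated)")))
    expect_equal(nrow(both[[nm]]$r2), 4)
  }
  expect_equal(both$eH$fit$niche, "eH")
  expect_equal(both$dprime$fit$niche, "dprime")
})

test_that("input contracts are enforced", {
  st <- simulate_sem_table(scenario_config(seed = 1))
  m <- st$metrics
  m$FD_p[3] <- NA
  expect_error(fit_sem(m, niche = "direct", mcmc = tiny_mcmc()), "missing")
  one_mut <- st$metrics[st$metrics$mutualism == "bird_fruit", ]
  expect_error(fit_sem(one_mut, niche = "direct", mcmc = tiny_mcmc()),
               "2 mutualisms")
})
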