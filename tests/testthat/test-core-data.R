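test_that("trait table round-trips through CSV and validates labels", {
  tab <- toy_plant_traits(3)
  f <- tempfile(fileext = ".csv")
  write.csv(as.data.frame(tab), f, row.names = FALSE)
  back <- read_trait_table(f, attr(tab, "trait_types"), trophic_level = "plant")
  expect_s3_class(back, "trait_table")
  expect_equal(nrow(back), 3)
  expect_equal(trait_matrix(back), trait_matrix(tab))

  # a table lacking one labelled trait type is a configuration error
  expect_error(
    read_trait_table(f, c(fruit_diameter = "matching", crop_mass = "energy",
                          plant_height = "energy"),
                     trophic_level = "plant"),
    "trait_type")
  # duplicated species are a data error
  expect_error(trait_table(c("x", "x"),
                           data.frame(a = 1:2, b = 1:2, c = 1:2),
                           c(a = "matching", b = "energy", c = "foraging"),
                           "plant"),
               "duplicated")
})

test_that("blank cells become missing-value markers and are counted", {
  df <- as.data.frame(toy_plant_traits(4))
  df$fruit_diameter[2] <- NA
  df$crop_mass[3] <- NA
  f <- tempfile(fileext = ".csv")
  write.csv(df, f, row.names = FALSE)
  expect_warning(tab <- read_trait_table(
    f, c(fruit_diameter = "matching", crop_mass = "energy",
         plant_height = "foraging"), trophic_level = "plant"),
    "2 missing")
  expect_equal(sum(is.na(trait_matrix(tab))), 2)
})

test_that("square-root transform is exact and inverts squaring", {
  tab <- trait_table(c("s1", "s2", "s3"),
                     data.frame(m = c(4, 0, 2.25), e = (1:3)^2,
                                f = c(1, 4, 9)),
                     c(m = "matching", e = "energy", f = "foraging"),
                     "plant")
  out <- sqrt_transform(tab)
  expect_equal(out$m, c(2, 0, 1.5))
  expect_equal(out$e, 1:3)
  expect_equal(attr(out, "trait_types"), attr(tab, "trait_types"))
  # sqrt o square = identity on random non-negative tables
  set.seed(4)
  vals <- matrix(runif(30, 0, 50), 10, 3)
  sq <- trait_table(sprintf("s%02d", 1:10),
                    setNames(as.data.frame(vals^2), c("m", "e", "f")),
                    c(m = "matching", e = "energy", f = "foraging"), "plant")
  expect_equal(unname(trait_matrix(sqrt_transform(sq))), unname(vals))
  neg <- trait_table("s1", data.frame(m = -1, e = 1, f = 1),
                     c(m = "matching", e = "energy", f = "foraging"), "plant")
  expect_error(sqrt_transform(neg), "negative")
})

test_that("metaweb is a binary tally, pruned, and order-invariant", {
  rec <- toy_records()
  L <- build_metaweb(rec)
  # repeated observations of a pair collapse to a single 1
  expect_equal(L["p01", "a01"], 1L)
  expect_true(all(L %in% 0:1))
  expect_equal(sum(L), 4L)  # p01-a01, p02-a01, p01-a02, p02-a02
  # record order and count magnitude do not matter
  rec2 <- rec[sample(nrow(rec)), ]
  rec2$count <- rec2$count * 100
  expect_identical(build_metaweb(rec2), L)
  # a species never observed interacting is absent
  rec3 <- rec[rec$animal_id != "a02", ]
  expect_false("a02" %in% colnames(build_metaweb(rec3)))
  expect_error(build_metaweb(rec[0, ]), "empty")
  rec4 <- rec; rec4$mutualism[1] <- "bird_flower"
  expect_error(build_metaweb(rec4), "one metaweb per mutualism")
})

test_that("site networks preserve marginal record totals", {
  rec <- toy_records()
  nets <- site_networks(rec)
  expect_named(nets, c("s1", "s2"))
  for (s in names(nets))
    expect_equal(sum(nets[[s]]), sum(rec$count[rec$site_id == s]))
  expect_equal(nets$s2["p01", "a01"], 5)
})

test_that("climate imputation recovers a noiseless cubic exactly", {
  n <- 24
  elev <- seq(800, 4000, length.out = n)
  hab <- rep(c("forest", "savanna"), n / 2)
  mat_true <- 28 - 0.005 * elev + 2e-7 * elev^2 - 3e-11 * elev^3 +
    ifelse(hab == "forest", 0, 1.5)
  map_true <- 800 + 0.9 * elev - 2e-4 * elev^2 + 1e-8 * elev^3
  cov <- site_covariates(data.frame(
    site_id = sprintf("s%02d", seq_len(n)), MAT = mat_true, MAP = map_true,
    LU = 0, elevation = elev, habitat = hab))
  miss <- which(cov$site_id == "s07")
  truth <- cov$MAT[miss]
  cov$MAT[miss] <- NA
  imp <- suppressWarnings(impute_climate(cov))
  expect_equal(imp$MAT[miss], truth, tolerance = 1e-8)
  expect_equal(attr(imp, "imputation")$MAT$r_squared, 1, tolerance = 1e-8)
  # only the missing row changed
  expect_equal(imp$MAT[-miss], cov$MAT[-miss])
  expect_equal(imp$MAP, cov$MAP)
})

test_that("noisy imputation matches an independent normal-equations oracle", {
  set.seed(11)
  n <- 52
  elev <- runif(n, 800, 4400)
  hab <- sample(c("a", "b", "c"), n, replace = TRUE)
  mat <- 27 - 0.0055 * elev + 1e-7 * elev^2 - 1e-11 * elev^3 +
    c(a = 0, b = 1, c = -0.5)[hab] + rnorm(n, 0, 0.4)
  cov <- site_covariates(data.frame(
    site_id = sprintf("s%02d", seq_len(n)), MAT = mat, MAP = 1000,
    LU = 0, elevation = elev, habitat = hab))
  ord <- order(sprintf("s%02d", seq_len(n)))
  cov$MAT[1] <- NA
  imp <- impute_climate(cov)
  # oracle: solve the normal equations directly on the complete sites
  # (elevation in km keeps the cubic design well conditioned; the model is
  # identical up to reparameterisation, so fits and R^2 agree exactly)
  comp <- !is.na(cov$MAT)
  ekm <- cov$elevation / 1000
  X <- cbind(1, ekm[comp], ekm[comp]^2, ekm[comp]^3,
             model.matrix(~ habitat, data = cov[comp, ])[, -1])
  beta <- solve(crossprod(X), crossprod(X, cov$MAT[comp]))
  fitted <- X %*% beta
  r2 <- 1 - sum((cov$MAT[comp] - fitted)^2) /
    sum((cov$MAT[comp] - mean(cov$MAT[comp]))^2)
  expect_equal(attr(imp, "imputation")$MAT$r_squared, as.numeric(r2),
               tolerance = 1e-10)
  x_new <- c(1, ekm[1]^(1:3),
             as.numeric(levels(factor(cov$habitat[comp]))[-1] ==
                          cov$habitat[1]))
  expect_equal(imp$MAT[1], as.numeric(x_new %*% beta), tolerance = 1e-6)
})

test_that("allometric prediction evaluates the printed power laws", {
  # bee body length from intertegular distance, at ln(predictor) = 0
  expect_equal(impute_trait_allometric(1, 1.89, 0.518), exp(1.89),
               tolerance = 1e-12)
  expect_equal(round(impute_trait_allometric(1, 1.89, 0.518), 3), 6.619)
  # wasp proboscis length from head width
  expect_equal(round(impute_trait_allometric(1, -1.32, 1.54), 4), 0.2671)
  # positive slope implies strict monotonicity
  x <- sort(runif(20, 0.2, 5))
  y <- impute_trait_allometric(x, 1.89, 0.518)
  expect_true(all(diff(y) > 0))
  expect_error(impute_trait_allometric(-1, 1, 1), "positive")
  # fitting recovers exact coefficients from noiseless pairs
  xs <- c(0.5, 1, 2, 4)
  # noiseless pairs: lm warns about the perfect fit, which is the point
  fit <- suppressWarnings(fit_allometry(xs, exp(1.2 + 0.7 * log(xs))))
  expect_equal(fit$intercept, 1.2, tolerance = 1e-10)
  expect_equal(fit$slope, 0.7, tolerance = 1e-10)
})

test_that("taxonomic imputation fills genus first, then family, then order", {
  tab <- trait_table(c("s1", "s2", "s3", "s4"),
                     data.frame(m = c(NA, 2, 4, 5), e = c(1, 1, 1, NA),
                                f = c(1, 2, 3, 4)),
                     c(m = "matching", e = "energy", f = "foraging"), "plant")
  taxonomy <- data.frame(
    species_id = c("s1", "s2", "s3", "s4"),
    genus = c("g1", "g1", "g1", "g2"),
    family = c("f1", "f1", "f1", "f1"),
    order = "o1", stringsAsFactors = FALSE)
  out <- impute_trait_taxonomic(tab, taxonomy)
  expect_equal(out$m[1], 3)  # mean of the two congeners
  prov <- attr(out, "provenance")
  expect_equal(prov$level[prov$species_id == "s1"], "genus")
  # s4 has no congener with the energy trait: family mean applies
  expect_equal(out$e[4], 1)
  expect_equal(prov$level[prov$species_id == "s4"], "family")
  # idempotence: re-imputing a filled table changes no values
  again <- impute_trait_taxonomic(out, taxonomy)
  expect_equal(trait_matrix(again), trait_matrix(out))
  expect_equal(nrow(attr(again, "provenance")), 0)
})
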