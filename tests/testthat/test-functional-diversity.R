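test_that("Gower distance matches the hand-evaluated formula", {
  # identical rows are at distance zero
  m <- matrix(c(1, 1, 5, 5, 9, 9), 2, 3,
              dimnames = list(c("a", "b"), c("t1", "t2", "t3")))
  expect_equal(gower_distance(rbind(m, c(2, 6, 1)))["a", "b"], 0)
  # two species at the extremes of every trait are at distance one
  ext <- matrix(c(0, 10, 2, 4, 1, 9), 2, 3,
                dimnames = list(c("lo", "hi"), c("t1", "t2", "t3")))
  expect_equal(gower_distance(ext)["lo", "hi"], 1)
  # ranges 10 and 2 with differences 5 and 1 average to 0.5
  mm <- matrix(c(0, 5, 10, 0, 1, 2), 3, 2,
               dimnames = list(c("x", "y", "z"), c("t1", "t2")))
  expect_equal(gower_distance(mm)["x", "y"], 0.5)
  D <- gower_distance(mm)
  expect_equal(unclass(D), t(unclass(D)), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  expect_true(all(diag(D) == 0))
})

test_that("Gower agrees with the community-ecology reference implementation", {
  skip_if_not_installed("vegan")
  set.seed(8)
  m <- matrix(runif(40, 0, 10), 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  ours <- gower_distance(m)
  ref <- as.matrix(vegan::vegdist(m, method = "gower"))
  expect_equal(unclass(ours), ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("zero-range traits are excluded and missing values use pairwise deletion", {
  m <- matrix(c(1, 1, 1, 0, 5, 10), 3, 2,
              dimnames = list(c("a", "b", "c"), c("flat", "t")))
  expect_warning(D <- gower_distance(m), "zero-range")
  expect_equal(D["a", "c"], 1)
  expect_error(gower_distance(m[, 1, drop = FALSE]), "zero range")
  m2 <- matrix(c(0, 5, 10, 0, NA, 2), 3, 2,
               dimnames = list(c("a", "b", "c"), c("t1", "t2")))
  D2 <- gower_distance(m2)
  expect_equal(D2["a", "b"], 0.5)          # only t1 contributes
  expect_equal(D2["a", "c"], 1)            # both traits at full range
})

test_that("PCoA embeds Euclidean configurations exactly", {
  # points on a line: one axis, exact distances
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x))
  emb <- pcoa_embed(D)
  expect_equal(emb$n_axes, 1)
  expect_equal(as.matrix(dist(emb$points)), D, tolerance = 1e-10,
               ignore_attr = TRUE)
  # a 4-point planar configuration is recovered
  set.seed(2)
  pts <- matrix(rnorm(8), 4, 2)
  D2 <- as.matrix(dist(pts))
  emb2 <- pcoa_embed(D2)
  expect_equal(as.matrix(dist(emb2$points)), D2, tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvalue sum equals the trace of the double-centred matrix
  G <- -0.5 * (D2^2 -
                 outer(rowMeans(D2^2), rep(1, 4)) -
                 outer(rep(1, 4), colMeans(D2^2)) + mean(D2^2))
  expect_equal(sum(emb2$eigenvalues), sum(diag(G)), tolerance = 1e-10)
})

test_that("functional dispersion equals the weighted-centroid formula", {
  expect_equal(functional_dispersion(matrix(c(0, 0.4)), c(1, 1)), 0.2)
  # abundances (1,1,2) at coordinates 0,1,2: centroid 1.25, FD 0.75
  expect_equal(functional_dispersion(matrix(c(0, 1, 2)), c(1, 1, 2)), 0.75)
  expect_equal(functional_dispersion(matrix(5), 3), 0)
  # zero-abundance species contribute nothing
  expect_equal(functional_dispersion(matrix(c(0, 1, 2, 99)), c(1, 1, 2, 0)),
               0.75)
  # scale invariance of abundances
  expect_equal(functional_dispersion(matrix(c(0, 1, 2)), 7 * c(1, 1, 2)),
               0.75)
  # duplicating a species and splitting its abundance leaves FD unchanged
  set.seed(14)
  co <- matrix(rnorm(8), 4, 2)
  ab <- c(2, 1, 4, 3)
  fd0 <- functional_dispersion(co, ab)
  co_dup <- rbind(co, co[4, ])
  ab_dup <- c(2, 1, 4, 1.5, 1.5)
  expect_equal(functional_dispersion(co_dup, ab_dup), fd0, tolerance = 1e-10)
  expect_error(functional_dispersion(co, c(1, 2)), "match")
})

test_that("the FD pipeline is order-invariant and zero for uniform communities", {
  pt <- toy_plant_traits(6, seed = 3)
  at <- toy_animal_traits(6, seed = 4)
  set.seed(5)
  net <- matrix(rpois(36, 1.5), 6, 6,
                dimnames = list(pt$species_id, at$species_id))
  net[rowSums(net) == 0, 1] <- 1
  nets <- list(s1 = net)
  fd <- fd_pipeline(nets, pt, at, mutualism = "toy")
  expect_equal(nrow(fd), 2)
  expect_true(all(fd$fd > 0))
  # species order in the network must not matter
  perm <- sample(6)
  fd2 <- fd_pipeline(list(s1 = net[perm, ]), pt, at, mutualism = "toy")
  expect_equal(fd2$fd, fd$fd, tolerance = 1e-10)
  # identical traits give FD zero
  flat <- trait_table(pt$species_id,
                      data.frame(m = rep(2, 6), e = rep(3, 6), f = rep(4, 6)),
                      c(m = "matching", e = "energy", f = "foraging"),
                      "plant")
  fd3 <- fd_pipeline(nets, flat, at, mutualism = "toy")
  expect_equal(fd3$fd[fd3$level == "plant"], 0)
  # a site with fewer than two interacting species is flagged
  tiny <- matrix(5, 1, 1, dimnames = list(pt$species_id[1], at$species_id[1]))
  fd4 <- fd_pipeline(list(s1 = tiny), pt, at, mutualism = "toy")
  expect_true(all(fd4$fd == 0) && all(fd4$flag == "few_species"))
})

test_that("global-range mode matches per-community Gower on the full table", {
  pt <- toy_plant_traits(8, seed = 9)
  at <- toy_animal_traits(8, seed = 10)
  set.seed(11)
  net <- matrix(rpois(64, 1), 8, 8,
                dimnames = list(pt$species_id, at$species_id))
  net[rowSums(net) == 0, 1] <- 1; net[1, colSums(net) == 0] <- 1
  all_sp <- fd_pipeline(list(s1 = net), pt, at, mutualism = "toy",
                        global_ranges = TRUE)
  per_comm <- fd_pipeline(list(s1 = net), pt, at, mutualism = "toy")
  # with every species interacting, the two modes coincide
  expect_equal(all_sp$fd, per_comm$fd, tolerance = 1e-10)
})

test_that("FD is only weakly coupled to species richness in simulations", {
  cfg <- scenario_config(n_mutualisms = 2, n_sites = c(50, 50),
                         n_plants = 40, n_animals = 40, n_community = 12,
                         interaction_intensity = 200, seed = 77)
  ds <- simulate_dataset(cfg)
  fd_rich <- do.call(rbind, lapply(names(ds$mutualisms), function(mut) {
    d <- ds$mutualisms[[mut]]
    fd_pipeline(d$interactions$site_networks, sqrt_transform(d$plant_traits),
                sqrt_transform(d$animal_traits), mutualism = mut)
  }))
  fd_rich <- fd_rich[fd_rich$n_species > 1, ]
  r <- cor(fd_rich$fd, fd_rich$n_species)
  expect_lt(abs(r), 0.6)
})
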