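# Small builders shared across the suite. All fixtures are generated in code.

toy_plant_traits <- function(n = 4, seed = 1) {
  set.seed(seed)
  trait_table(sprintf("p%02d", seq_len(n)),
              data.frame(fruit_diameter = runif(n, 2, 12),
                         crop_mass = rlnorm(n, 3, 0.5),
                         plant_height = runif(n, 1, 20)),
              c(fruit_diameter = "matching", crop_mass = "energy",
                plant_height = "foraging"),
              "plant")
}

toy_animal_traits <- function(n = 4, seed = 2) {
  set.seed(seed)
  trait_table(sprintf("a%02d", seq_len(n)),
              data.frame(bill_width = runif(n, 2, 12),
                         body_mass = rlnorm(n, 3, 0.5),
                         kipps_index = runif(n, 0.1, 0.5)),
              c(bill_width = "matching", body_mass = "energy",
                kipps_index = "foraging"),
              "animal")
}

toy_records <- function() {
  data.frame(site_id = c("s1", "s1", "s2", "s2", "s2"),
             mutualism = "bird_fruit",
             plant_id = c("p01", "p02", "p01", "p02", "p01"),
             animal_id = c("a01", "a01", "a02", "a02", "a01"),
             count = c(3, 1, 2, 4, 5),
             stringsAsFactors = FALSE)
}

# random binary link matrix with no empty rows/columns
random_metaweb <- function(m, n, fill = 0.5) {
  repeat {
    L <- matrix(rbinom(m * n, 1, fill), m, n,
                dimnames = list(paste0("p", seq_len(m)),
                                paste0("a", seq_len(n))))
    if (all(rowSums(L) > 0) && all(colSums(L) > 0)) return(L)
  }
}

# all non-negative integer matrices with the same row and column sums as m
enumerate_marginal_matrices <- function(m) {
  rs <- rowSums(m); cs <- colSums(m)
  out <- list()
  recurse <- function(mat, i, remaining_cols) {
    if (i > length(rs)) {
      if (all(remaining_cols == 0)) out[[length(out) + 1L]] <<- mat
      return(invisible())
    }
    fill_row <- function(row, j, left) {
      if (j == length(cs)) {
        if (left <= remaining_cols[j]) {
          row[j] <- left
          m2 <- mat; m2[i, ] <- row
          recurse(m2, i + 1L, remaining_cols - row)
        }
        return(invisible())
      }
      for (v in 0:min(left, remaining_cols[j]))
        fill_row(`[<-`(row, j, v), j + 1L, left - v)
    }
    fill_row(numeric(length(cs)), 1L, rs[i])
  }
  recurse(matrix(0, nrow(m), ncol(m)), 1L, cs)
  out
}

# reference scenario scaled down for fast simulation tests
small_scenario <- function(seed = 1, ...) {
  defaults <- list(n_mutualisms = 1, n_sites = 8, n_plants = 25,
                   n_animals = 25, n_community = 10,
                   interaction_intensity = 150, seed = seed)
  do.call(scenario_config, utils::modifyList(defaults, list(...)))
}

tiny_mcmc <- function() {
  sem_mcmc(chains = 2, iter = 1500, adapt = 300, thin = 3,
           pilot_chains = 1, pilot_iter = 800, pilot_adapt = 300)
}
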