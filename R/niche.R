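#' Effective number of interaction partners
#'
#' Niche breadth of each species as the exponent of the Shannon entropy of
#' its interaction frequencies: with link proportions
#' \eqn{p_{ij} = a_{ij}/A_i}, \eqn{H_i = -\sum_j p_{ij}\ln p_{ij}} and the
#' effective partner number is \eqn{e^{H_i}} (1 for a pure specialist, the
#' realised degree for a perfectly even generalist). The network-level value
#' is the unweighted arithmetic mean across species with at least one
#' interaction; an abundance-weighted mean is available.
#'
#' @param network weighted plant x animal interaction matrix.
#' @param level \code{"plant"} (rows) or \code{"animal"} (columns).
#' @param weighted if \code{TRUE}, weight the mean by species totals.
#' @return list: \code{species} (named vector of \eqn{e^{H_i}}),
#'   \code{mean}.
#' @export
effective_partners <- function(network, level = c("plant", "animal"),
                               weighted = FALSE) {
  level <- match.arg(level)
  m <- if (level == "plant") as.matrix(network) else t(as.matrix(network))
  tot <- rowSums(m)
  keep <- tot > 0
  m <- m[keep, , drop = FALSE]
  tot <- tot[keep]
  if (nrow(m) == 0) stop("no species with interactions at level ", level)
  eh <- vapply(seq_len(nrow(m)), function(i) {
    p <- m[i, ] / tot[i]
    p <- p[p > 0]
    exp(-sum(p * log(p)))
  }, numeric(1))
  names(eh) <- rownames(m)
  w <- if (weighted) tot / sum(tot) else rep(1 / length(eh), length(eh))
  list(species = eh, mean = sum(w * eh))
}

#' Standardised Kullback-Leibler specialisation d'
#'
#' For each species, the Kullback-Leibler divergence of its realised partner
#' use \eqn{p'_{ij}} from the partner availability \eqn{q_j} (the partners'
#' relative marginal totals),
#' \eqn{d_i = \sum_j p'_{ij} \ln(p'_{ij}/q_j)}, standardised between the
#' minimum and maximum achievable given the integer marginal totals of the
#' network: \eqn{d'_i = (d_i - d_{min})/(d_{max} - d_{min})}, so 0 means
#' partner use proportional to availability and 1 maximal specialisation.
#'
#' \code{d_max} comes from a greedy integer reallocation: species are
#' processed in order of decreasing total and each species' interactions are
#' concentrated on the least-available partners that still have marginal
#' capacity. \code{d_min} uses the integer allocation closest to
#' proportional use (largest-remainder rounding of \eqn{A_i q_j}). The
#' greedy maximum is a heuristic for larger networks; it is exact on small
#' matrices (verifiable by exhaustive enumeration). A species whose bounds
#' coincide (e.g. total of 1) gets \code{d' = 0}.
#'
#' @param network integer-count plant x animal matrix.
#' @param level \code{"plant"} or \code{"animal"}.
#' @param weighted if \code{TRUE}, weight the network mean by species totals.
#' @return list with per-species vectors \code{d}, \code{d_min},
#'   \code{d_max}, \code{d_prime} and the network \code{mean} d'.
#' @export
kl_specialization <- function(network, level = c("plant", "animal"),
                              weighted = FALSE) {
  level <- match.arg(level)
  m <- if (level == "plant") as.matrix(network) else t(as.matrix(network))
  if (any(m != round(m)) || any(m < 0))
    stop("d' requires non-negative integer counts")
  tot <- rowSums(m)
  keep <- tot > 0
  m <- m[keep, , drop = FALSE]
  tot <- tot[keep]
  if (nrow(m) == 0) stop("no species with interactions at level ", level)
  col_tot <- colSums(m)
  q <- col_tot / sum(col_tot)

  kl <- function(alloc) {
    p <- alloc / sum(alloc)
    pos <- p > 0
    sum(p[pos] * log(p[pos] / q[pos]))
  }
  d <- apply(m, 1, kl)

  # d_min: integer allocation closest to proportional use; largest-remainder
  # rounding of A_i * q followed by single-unit descent to the local optimum
  d_min <- vapply(tot, function(A) {
    target <- A * q
    base <- floor(target)
    rem <- A - sum(base)
    if (rem > 0) {
      extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    best <- kl(base)
    repeat {
      improved <- FALSE
      for (from in which(base > 0)) for (to in seq_along(base)) {
        if (from == to) next
        cand <- base
        cand[from] <- cand[from] - 1
        cand[to] <- cand[to] + 1
        v <- kl(cand)
        if (v < best - 1e-12) {
          base <- cand
          best <- v
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    best
  }, numeric(1))

  # d_max: per species, the most specialised allocation of its total across
  # partners capped at their marginal totals. The KL divergence is convex in
  # the allocation, so the maximum sits at an extreme point of the capped
  # simplex: try, for every partner, filling it first and the remainder by
  # ascending availability, then refine by single-unit ascent.
  greedy_fill <- function(A, first = NULL) {
    alloc <- numeric(length(q))
    need <- A
    ordering <- order(q)
    if (!is.null(first)) ordering <- c(first, setdiff(ordering, first))
    for (j in ordering) {
      if (need <= 0) break
      take <- min(need, col_tot[j])
      alloc[j] <- take
      need <- need - take
    }
    alloc
  }
  d_max <- vapply(tot, function(A) {
    starts <- c(list(greedy_fill(A)),
                lapply(seq_along(q), function(j) greedy_fill(A, j)))
    best_alloc <- starts[[which.max(vapply(starts, kl, numeric(1)))]]
    best <- kl(best_alloc)
    repeat {
      improved <- FALSE
      for (from in which(best_alloc > 0)) for (to in seq_along(q)) {
        if (from == to || best_alloc[to] >= col_tot[to]) next
        cand <- best_alloc
        cand[from] <- cand[from] - 1
        cand[to] <- cand[to] + 1
        v <- kl(cand)
        if (v > best + 1e-12) {
          best_alloc <- cand
          best <- v
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    best
  }, numeric(1))

  denom <- d_max - d_min
  d_prime <- ifelse(denom > 1e-12, (d - d_min) / denom, 0)
  d_prime <- pmin(pmax(d_prime, 0), 1)
  names(d) <- names(d_min) <- names(d_max) <- names(d_prime) <- rownames(m)
  w <- if (weighted) tot / sum(tot) else rep(1 / length(d_prime), length(d_prime))
  list(d = d, d_min = d_min, d_max = d_max, d_prime = d_prime,
       mean = sum(w * d_prime))
}

#' Per-site functional diversity, niche metrics and covariates
#'
#' Assembles the modelling table for the structural equation models: one row
#' per site x mutualism with multivariate functional dispersion of plants
#' and animals, mean effective partner numbers, mean d', and the site's MAT,
#' MAP and LU. Sites missing covariates are flagged and excluded.
#'
#' @param dataset a \code{mutualism_dataset} (see [simulate_dataset()]) or a
#'   list with elements \code{mutualisms} (named list holding
#'   \code{plant_traits}, \code{animal_traits}, \code{interactions}) and
#'   \code{covariates}.
#' @param trait_set trait set for the FD columns (default \code{"all"}).
#' @param sqrt_traits square-root transform traits before FD (default TRUE,
#'   the analysis scale).
#' @return data frame of class \code{site_metrics}: site_id, mutualism,
#'   FD_p, FD_a, eH_p, eH_a, dprime_p, dprime_a, MAT, MAP, LU.
#' @export
niche_pipeline <- function(dataset, trait_set = "all", sqrt_traits = TRUE) {
  cov <- dataset$covariates
  rows <- list()
  for (mut in names(dataset$mutualisms)) {
    d <- dataset$mutualisms[[mut]]
    pt <- if (sqrt_traits) sqrt_transform(d$plant_traits) else d$plant_traits
    at <- if (sqrt_traits) sqrt_transform(d$animal_traits) else d$animal_traits
    nets <- d$interactions$site_networks
    fd <- fd_pipeline(nets, pt, at, trait_set = trait_set, mutualism = mut)
    for (s in names(nets)) {
      net <- nets[[s]]
      i <- which(cov$site_id == s)
      covrow <- if (length(i) == 1)
        cov[i, c("MAT", "MAP", "LU")] else
        data.frame(MAT = NA_real_, MAP = NA_real_, LU = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = s, mutualism = mut,
        FD_p = fd$fd[fd$site_id == s & fd$level == "plant"],
        FD_a = fd$fd[fd$site_id == s & fd$level == "animal"],
        eH_p = effective_partners(net, "plant")$mean,
        eH_a = effective_partners(net, "animal")$mean,
        dprime_p = kl_specialization(net, "plant")$mean,
        dprime_a = kl_specialization(net, "animal")$mean,
        MAT = covrow$MAT, MAP = covrow$MAP, LU = covrow$LU,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  missing_cov <- is.na(out$MAT) | is.na(out$MAP) | is.na(out$LU)
  if (any(missing_cov))
    warning(sum(missing_cov), " row(s) lack covariates; flagged for exclusion")
  out$complete <- !missing_cov
  class(out) <- c("site_metrics", "data.frame")
  out
}

#' Scale a site-metrics table for the structural equation model
#'
#' Natural-log transforms the effective partner numbers and z-scales every
#' modelling column to zero mean and unit variance across the pooled table
#' (all mutualisms together, as the SEM pools them with a random factor).
#' Incomplete rows are dropped.
#'
#' @param metrics a [niche_pipeline()] table.
#' @return data frame with z-scaled columns MAT, MAP, LU, FD_p, FD_a,
#'   ln_eH_p, ln_eH_a, dprime_p, dprime_a plus site_id and mutualism.
#' @export
scale_metrics <- function(metrics) {
  m <- metrics[if ("complete" %in% colnames(metrics)) metrics$complete else
    TRUE, , drop = FALSE]
  z <- function(x) as.numeric(scale(x))
  out <- data.frame(site_id = m$site_id, mutualism = m$mutualism,
                    MAT = z(m$MAT), MAP = z(m$MAP), LU = z(m$LU),
                    FD_p = z(m$FD_p), FD_a = z(m$FD_a),
                    ln_eH_p = z(log(m$eH_p)), ln_eH_a = z(log(m$eH_a)),
                    dprime_p = z(m$dprime_p), dprime_a = z(m$dprime_a),
                    stringsAsFactors = FALSE)
  out
}
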