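#' Range-standardised Gower distance between species
#'
#' Pairwise dissimilarity between species equal to the mean absolute trait
#' difference after standardising each trait by its range across the supplied
#' table: \eqn{d(i,j) = \frac{1}{T}\sum_t |x_{it}-x_{jt}|/\mathrm{range}_t}.
#' By construction distances lie in [0, 1], with 1 attained by two species at
#' opposite extremes of every trait's range. Traits with zero range carry no
#' information and are excluded from the mean with a warning; missing values
#' are handled by pairwise deletion (the mean runs over the traits both
#' species have).
#'
#' @param table a [trait_table()] or a numeric matrix with species rownames.
#' @param trait_set \code{"all"} or a subset of
#'   \code{c("matching","energy","foraging")} (trait tables only).
#' @return square symmetric matrix of class \code{c("gower_dist","matrix")}
#'   with zero diagonal and species ids as dimnames.
#' @export
gower_distance <- function(table, trait_set = "all") {
  m <- if (inherits(table, "trait_table")) trait_matrix(table, trait_set)
       else as.matrix(table)
  if (nrow(m) < 2) stop("need at least 2 species")
  rng <- apply(m, 2, function(x) diff(range(x, na.rm = TRUE)))
  zero <- rng <= 0 | !is.finite(rng)
  if (all(zero)) stop("all traits have zero range")
  if (any(zero))
    warning("zero-range trait(s) excluded: ",
            paste(colnames(m)[zero], collapse = ", "))
  m <- m[, !zero, drop = FALSE]
  rng <- rng[!zero]
  ms <- sweep(m, 2, rng, "/")
  n <- nrow(ms)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(ms[i, ] - ms[j, ])
      ok <- !is.na(diffs)
      if (!any(ok)) stop("species pair with no shared trait: ",
                         rownames(m)[i], " / ", rownames(m)[j])
      D[i, j] <- D[j, i] <- mean(diffs[ok])
    }
  }
  class(D) <- c("gower_dist", "matrix")
  D
}

#' Principal coordinates embedding of a distance matrix
#'
#' Classical metric scaling (PCoA) of the dissimilarity matrix, keeping the
#' axes whose eigenvalues exceed \code{tol} times the largest eigenvalue.
#' Axes with negative eigenvalues are dropped: the range-standardised Gower
#' distance on a handful of quantitative traits is near-Euclidean, so no
#' Cailliez or Lingoes correction is applied by default.
#'
#' @param D square symmetric dissimilarity matrix (e.g. from
#'   [gower_distance()]).
#' @param tol relative eigenvalue tolerance for axis retention.
#' @param correction \code{"none"} (default) or \code{"cailliez"} to add the
#'   smallest constant making the distances Euclidean-embeddable.
#' @return list with \code{points} (species x axes), \code{eigenvalues}
#'   (all, including any negative ones) and \code{n_axes}.
#' @export
pcoa_embed <- function(D, tol = 1e-8, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  d <- stats::as.dist(D)
  n <- attr(d, "Size")
  mds <- suppressWarnings(stats::cmdscale(d, k = max(n - 1, 1), eig = TRUE,
                                          add = correction == "cailliez"))
  eig <- mds$eig
  pts <- mds$points
  if (max(eig) <= 0)
    return(list(points = matrix(0, n, 1, dimnames = list(rownames(as.matrix(D)),
                                                         NULL)),
                eigenvalues = eig, n_axes = 0L))
  keep <- which(eig[seq_len(ncol(pts))] > tol * max(eig))
  pts <- pts[, keep, drop = FALSE]
  rownames(pts) <- rownames(as.matrix(D))
  list(points = pts, eigenvalues = eig, n_axes = length(keep))
}

#' Abundance-weighted functional dispersion
#'
#' The mean abundance-weighted distance of each species to the
#' abundance-weighted centroid of its community in trait space:
#' \deqn{c = \sum_i a_i x_i / \sum_i a_i, \quad
#'       FD = \sum_i a_i \lVert x_i - c\rVert / \sum_i a_i.}
#' Species with zero abundance contribute nothing; a community of one
#' species (or fewer) has dispersion zero. The measure is invariant to
#' rescaling of the abundances and to duplicating a species while splitting
#' its abundance.
#'
#' @param coords numeric matrix of species coordinates (rows) in trait
#'   space, e.g. from [pcoa_embed()].
#' @param abundances non-negative weights, one per row of \code{coords};
#'   here the marginal interaction totals of the species in its network.
#' @return the dispersion value (>= 0).
#' @export
functional_dispersion <- function(coords, abundances) {
  coords <- as.matrix(coords)
  if (length(abundances) != nrow(coords))
    stop("abundances must match rows of coords")
  if (any(abundances < 0)) stop("abundances must be >= 0")
  A <- sum(abundances)
  if (A <= 0) stop("abundances must not be all zero")
  pos <- abundances > 0
  if (sum(pos) <= 1) return(0)
  a <- abundances[pos] / sum(abundances[pos])
  x <- coords[pos, , drop = FALSE]
  centroid <- colSums(x * a)
  dist_c <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  sum(a * dist_c)
}

#' Functional dispersion of every site network
#'
#' For each site network of a mutualism and each trophic level: subset the
#' trait table to the interacting species, compute range-standardised Gower
#' distances, embed by PCoA and return the abundance-weighted dispersion
#' with marginal interaction totals as abundances. Run once with
#' \code{trait_set = "all"} for multivariate FD and once per trait type for
#' the univariate versions.
#'
#' @param networks named list of weighted site networks (plants x animals),
#'   e.g. \code{interaction_data$site_networks}.
#' @param plant_traits,animal_traits [trait_table()]s on the analysis scale.
#' @param trait_set \code{"all"}, \code{"matching"}, \code{"energy"} or
#'   \code{"foraging"}.
#' @param mutualism label copied into the output.
#' @param global_ranges if \code{TRUE}, Gower ranges are computed across the
#'   whole trait table of the mutualism instead of per site community.
#' @return data frame: site_id, mutualism, level, trait_set, fd, n_species,
#'   flag (\code{"few_species"} when fewer than two interacting species).
#' @export
fd_pipeline <- function(networks, plant_traits, animal_traits,
                        trait_set = "all", mutualism = NA_character_,
                        global_ranges = FALSE) {
  one <- function(site, net, level) {
    traits <- if (level == "plant") plant_traits else animal_traits
    ab <- if (level == "plant") rowSums(net) else colSums(net)
    ab <- ab[ab > 0]
    ids <- names(ab)
    if (length(ids) < 2)
      return(data.frame(site_id = site, mutualism = mutualism, level = level,
                        trait_set = trait_set, fd = 0,
                        n_species = length(ids), flag = "few_species",
                        stringsAsFactors = FALSE))
    tm <- trait_matrix(traits, trait_set)
    miss <- setdiff(ids, rownames(tm))
    if (length(miss))
      stop("species without traits in site ", site, ": ",
           paste(miss, collapse = ", "))
    D <- tryCatch(
      if (global_ranges) gower_distance(tm)[ids, ids]
      else suppressWarnings(gower_distance(tm[ids, , drop = FALSE])),
      error = function(e) {
        if (grepl("zero range", conditionMessage(e)))
          matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
        else stop(e)
      })
    fd <- if (all(D == 0)) 0 else {
      emb <- pcoa_embed(D)
      functional_dispersion(emb$points, ab[rownames(emb$points)])
    }
    data.frame(site_id = site, mutualism = mutualism, level = level,
               trait_set = trait_set, fd = fd, n_species = length(ids),
               flag = "", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(names(networks), function(s) {
    rbind(one(s, networks[[s]], "plant"), one(s, networks[[s]], "animal"))
  }))
  rownames(out) <- NULL
  out
}
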