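#' Degree-weighted RLQ co-inertia of plant traits, metaweb and animal traits
#'
#' Links a plant trait table \code{R} (m species x p traits) and an animal
#' trait table \code{Q} (n species x a traits) through a binary metaweb
#' \code{L} (m x n). The metaweb is converted to relative frequencies
#' \code{P = L / sum(L)} whose margins \code{r} (plants) and \code{c}
#' (animals) are proportional to species degree; trait columns are centred
#' and scaled to unit variance under these degree weights. The
#' cross-covariance matrix is
#' \deqn{\Omega = \tilde R^T (P - r c^T) \tilde Q}
#' and its singular value decomposition yields trait coefficient vectors
#' \code{u_k}, \code{v_k} (columns of U, V) and species scores
#' \code{x_k = \tilde R u_k}, \code{y_k = \tilde Q v_k} that maximise the
#' squared cross-covariance \eqn{(x_k^T P y_k)^2 = \lambda_k} subject to
#' orthonormality of the coefficient vectors.
#'
#' Sign convention: within each axis the coefficient of largest magnitude
#' (across plant and animal traits jointly) is made positive, so results are
#' reproducible across BLAS implementations.
#'
#' @param R plant traits: a [trait_table()] or numeric matrix with species
#'   rownames matching the rows of \code{L}. Traits should already be on the
#'   analysis scale (see [sqrt_transform()]).
#' @param L binary metaweb from [build_metaweb()]; no all-zero rows/columns.
#' @param Q animal traits, matching the columns of \code{L}.
#' @param k number of axes to retain (default all, \code{min(p, a)}).
#' @return object of class \code{rlq}: list with \code{eigenvalues},
#'   \code{percent_covariance}, coefficient matrices \code{U}, \code{V},
#'   species scores \code{X}, \code{Y}, weights \code{row_weights},
#'   \code{col_weights}, the standardised trait tables and \code{P}.
#' @references The three-table ordination combines a correspondence analysis
#'   of the link table with degree-weighted principal component analyses of
#'   the two trait tables.
#' @export
rlq <- function(R, L, Q, k = NULL) {
  R <- as_rlq_matrix(R, rownames(L), "R (plant traits)")
  Q <- as_rlq_matrix(Q, colnames(L), "Q (animal traits)")
  if (!all(L %in% c(0, 1))) stop("L must be binary")
  if (any(rowSums(L) == 0) || any(colSums(L) == 0))
    stop("L has zero-degree species; prune them (see build_metaweb)")
  P <- L / sum(L)
  r <- rowSums(P)
  c_ <- colSums(P)
  Rs <- weighted_standardize(R, r)
  Qs <- weighted_standardize(Q, c_)
  Omega <- crossprod(Rs, (P - tcrossprod(r, c_)) %*% Qs)
  nax <- min(ncol(Rs), ncol(Qs))
  if (is.null(k)) k <- nax
  if (k > nax) stop("k exceeds min(p, a) = ", nax)
  sv <- svd(Omega, nu = nax, nv = nax)
  lambda <- sv$d[seq_len(nax)]^2
  U <- sv$u
  V <- sv$v
  # deterministic axis orientation
  for (ax in seq_len(nax)) {
    w <- c(U[, ax], V[, ax])
    if (w[which.max(abs(w))] < 0) {
      U[, ax] <- -U[, ax]
      V[, ax] <- -V[, ax]
    }
  }
  dimnames(U) <- list(colnames(R), paste0("axis", seq_len(nax)))
  dimnames(V) <- list(colnames(Q), paste0("axis", seq_len(nax)))
  X <- Rs %*% U
  Y <- Qs %*% V
  keep <- seq_len(k)
  structure(list(
    eigenvalues = lambda[keep],
    percent_covariance = 100 * lambda[keep] / sum(lambda),
    total_inertia = sum(lambda),
    U = U[, keep, drop = FALSE], V = V[, keep, drop = FALSE],
    X = X[, keep, drop = FALSE], Y = Y[, keep, drop = FALSE],
    row_weights = r, col_weights = c_,
    R_std = Rs, Q_std = Qs, P = P), class = "rlq")
}

as_rlq_matrix <- function(x, ids, what) {
  if (inherits(x, "trait_table")) x <- trait_matrix(x)
  x <- as.matrix(x)
  if (!is.null(rownames(x)) && !is.null(ids)) {
    miss <- setdiff(ids, rownames(x))
    if (length(miss))
      stop(what, " lacks species: ", paste(utils::head(miss, 5), collapse = ", "))
    x <- x[ids, , drop = FALSE]
  }
  if (anyNA(x)) stop(what, " contains missing values; impute first")
  x
}

# centre and scale columns to zero weighted mean / unit weighted variance
weighted_standardize <- function(M, w) {
  w <- w / sum(w)
  mu <- colSums(M * w)
  Mc <- sweep(M, 2, mu)
  v <- colSums(Mc^2 * w)
  if (any(v <= .Machine$double.eps))
    stop("constant trait column under weights: ",
         paste(colnames(M)[v <= .Machine$double.eps], collapse = ", "))
  sweep(Mc, 2, sqrt(v), "/")
}

#' Select ordination axes by cross-covariance coverage
#'
#' Returns the smallest number of leading axes whose cumulative percent
#' cross-covariance reaches \code{coverage}, with a floor of two axes when
#' at least two exist (the two-dimensional trait-space representation used
#' throughout downstream summaries).
#'
#' @param result an [rlq()] fit, or a numeric vector of percent covariances.
#' @param coverage target cumulative proportion in (0, 1]; default 0.99.
#' @return integer number of axes.
#' @export
select_axes <- function(result, coverage = 0.99) {
  stopifnot(coverage > 0, coverage <= 1)
  pct <- if (inherits(result, "rlq")) result$percent_covariance else result
  kstar <- which(cumsum(pct) >= 100 * coverage - 1e-9)[1]
  if (is.na(kstar)) kstar <- length(pct)
  max(kstar, min(2L, length(pct)))
}

#' Correlations between traits and RLQ axes
#'
#' Degree-weighted Pearson correlations between each original trait and the
#' species scores on each retained axis: plant traits against \code{X} under
#' the plant weights, animal traits against \code{Y} under the animal
#' weights. Axis orientation is arbitrary, so downstream summaries use the
#' absolute magnitude \code{|r|}.
#'
#' @param result an [rlq()] fit.
#' @param R,Q the trait tables used in the fit (for trait-type labels);
#'   matrices are accepted, in which case trait types are \code{NA}.
#' @param axes integer vector of axes (default all retained).
#' @return data frame: level, trait, trait_type, axis, r.
#' @export
trait_axis_correlations <- function(result, R, Q, axes = NULL) {
  stopifnot(inherits(result, "rlq"))
  if (is.null(axes)) axes <- seq_along(result$eigenvalues)
  if (any(axes > ncol(result$X))) stop("axis index out of range")
  one_side <- function(tab, scores, w, level) {
    m <- if (inherits(tab, "trait_table")) trait_matrix(tab) else as.matrix(tab)
    m <- m[names(w), , drop = FALSE]
    tt <- if (inherits(tab, "trait_table"))
      attr(tab, "trait_types")[colnames(m)] else
        stats::setNames(rep(NA_character_, ncol(m)), colnames(m))
    do.call(rbind, lapply(axes, function(ax) {
      data.frame(level = level, trait = colnames(m),
                 trait_type = unname(tt), axis = ax,
                 r = apply(m, 2, weighted_pearson, y = scores[, ax], w = w),
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  }
  rw <- result$row_weights
  cw <- result$col_weights
  if (is.null(names(rw))) names(rw) <- rownames(result$P)
  if (is.null(names(cw))) names(cw) <- colnames(result$P)
  out <- rbind(one_side(R, result$X, rw, "plant"),
               one_side(Q, result$Y, cw, "animal"))
  rownames(out) <- NULL
  out
}

weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  xc <- x - sum(w * x)
  yc <- y - sum(w * y)
  sum(w * xc * yc) / sqrt(sum(w * xc^2) * sum(w * yc^2))
}

#' Summarise trait-axis correlation magnitudes by trait type
#'
#' Pools the [trait_axis_correlations()] tables of several mutualisms and
#' reports, per trait type and axis, the mean absolute correlation with its
#' standard error, the number of individually significant tests (when
#' permutation p-values are supplied) and Moran's probability of observing
#' that many significant tests by chance.
#'
#' @param cor_tables list of correlation tables (one per mutualism), each as
#'   returned by [trait_axis_correlations()], optionally with a column
#'   \code{p} of permutation p-values.
#' @param alpha significance level for the Moran count (default 0.05).
#' @return data frame: trait_type, axis, n, mean_abs_r, sem_abs_r,
#'   n_significant, moran_p (last two NA without p-values).
#' @export
trait_type_summary <- function(cor_tables, alpha = 0.05) {
  all_tab <- do.call(rbind, cor_tables)
  sp <- split(all_tab, list(all_tab$trait_type, all_tab$axis), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    has_p <- "p" %in% colnames(d) && !anyNA(d$p)
    n_sig <- if (has_p) sum(d$p < alpha) else NA_integer_
    data.frame(trait_type = d$trait_type[1], axis = d$axis[1], n = nrow(d),
               mean_abs_r = mean(abs(d$r)),
               sem_abs_r = stats::sd(abs(d$r)) / sqrt(nrow(d)),
               n_significant = n_sig,
               moran_p = if (has_p) moran_probability(nrow(d), n_sig, alpha)
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$axis, out$trait_type), ]
}

#' @export
print.rlq <- function(x, digits = 4, ...) {
  cat("RLQ ordination:", nrow(x$X), "plants x", nrow(x$Y), "animals,",
      length(x$eigenvalues), "axes\n")
  cat("eigenvalues: ", paste(signif(x$eigenvalues, digits), collapse = ", "),
      "\n")
  cat("% cross-covariance:",
      paste(signif(x$percent_covariance, digits), collapse = ", "), "\n")
  invisible(x)
}
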