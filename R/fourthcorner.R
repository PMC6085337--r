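#' Fourth-corner permutation tests for trait-space association
#'
#' Tests the association between plant and animal trait spaces mediated by
#' the binary metaweb, by permuting species identities. Model 2 permutes
#' plant species (rows of the link table), model 4 permutes animal species
#' (columns), and model 6 runs both sequentially and reports the maximum of
#' the two p-values, the only combination that controls the type I error of
#' the fourth-corner problem.
#'
#' Three statistics are available:
#' \describe{
#'   \item{\code{sum_eigenvalues}}{the total RLQ cross-covariance
#'     \eqn{\sum_k \lambda_k = \|\Omega\|_F^2}, a global multivariate
#'     statistic (upper-tail test);}
#'   \item{\code{axis_correlation}}{the degree-weighted fourth-corner
#'     correlation between the plant and animal species scores of one RLQ
#'     axis, with the observed scores held fixed as variables (two-sided);}
#'   \item{\code{trait_axis_correlation}}{the absolute degree-weighted
#'     Pearson correlation between one original trait and its own side's
#'     axis scores, with the ordination recomputed under each permutation
#'     (axis orientation is arbitrary, hence the absolute value).}
#' }
#'
#' P-values use the add-one permutation formula
#' \code{p = (1 + #extreme) / (n_perm + 1)}; ties count as extreme.
#'
#' @param R,L,Q as in [rlq()].
#' @param statistic one of \code{"sum_eigenvalues"},
#'   \code{"axis_correlation"}, \code{"trait_axis_correlation"}.
#' @param axis axis index for the axis statistics (default 1).
#' @param trait trait column name for \code{trait_axis_correlation}.
#' @param level trophic level of \code{trait} (\code{"plant"} or
#'   \code{"animal"}).
#' @param n_perm number of permutations (>= 99; 9999 for final inference,
#'   999 is a practical default for simulation studies).
#' @param model 2, 4 or 6.
#' @param seed integer seed for reproducible permutations.
#' @return object of class \code{fourth_corner}: statistic name, observed
#'   value, \code{p_model2}, \code{p_model4}, \code{p_model6} (\code{NA} for
#'   models not run), \code{n_perm}, \code{model}, \code{seed} and the count
#'   of degenerate permutations that were redrawn.
#' @export
fourth_corner_test <- function(R, L, Q,
                               statistic = c("sum_eigenvalues",
                                             "axis_correlation",
                                             "trait_axis_correlation"),
                               axis = 1, trait = NULL,
                               level = c("plant", "animal"),
                               n_perm = 999, model = 6, seed = NULL) {
  statistic <- match.arg(statistic)
  level <- match.arg(level)
  if (!model %in% c(2, 4, 6)) stop("model must be 2, 4 or 6")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (!is.null(seed)) set.seed(seed)

  fit <- rlq(R, L, Q)
  Rm <- as_rlq_matrix(R, rownames(L), "R")
  Qm <- as_rlq_matrix(Q, colnames(L), "Q")
  r <- fit$row_weights
  c_ <- fit$col_weights
  Pc <- fit$P - tcrossprod(r, c_)
  two_sided <- statistic != "sum_eigenvalues"
  n_degenerate <- 0L

  if (statistic == "sum_eigenvalues") {
    M2 <- Pc %*% fit$Q_std                      # fixed for row permutations
    M4 <- crossprod(fit$R_std, Pc)              # fixed for column permutations
    observed <- sum(fit$eigenvalues)
    stat_row <- function(perm)
      sum(crossprod(weighted_standardize(Rm[perm, , drop = FALSE], r), M2)^2)
    stat_col <- function(perm)
      sum((M4 %*% weighted_standardize(Qm[perm, , drop = FALSE], c_))^2)
  } else if (statistic == "axis_correlation") {
    if (axis > ncol(fit$X)) stop("axis index out of range")
    xs <- std_vec(fit$X[, axis], r)
    ys <- std_vec(fit$Y[, axis], c_)
    observed <- as.numeric(xs %*% Pc %*% ys)
    stat_row <- function(perm) as.numeric(std_vec(xs[perm], r) %*% Pc %*% ys)
    stat_col <- function(perm) as.numeric(xs %*% Pc %*% std_vec(ys[perm], c_))
  } else {
    if (is.null(trait)) stop("trait_axis_correlation requires a trait name")
    side_m <- if (level == "plant") Rm else Qm
    if (!trait %in% colnames(side_m))
      stop("trait '", trait, "' not found at level ", level)
    tv <- side_m[, trait]
    w <- if (level == "plant") r else c_
    if (axis > ncol(fit$X)) stop("axis index out of range")
    score <- function(f) if (level == "plant") f$X[, axis] else f$Y[, axis]
    observed <- abs(weighted_pearson(tv, score(fit), w))
    # permute trait values against link positions (rownames stay aligned
    # with L so the ordination sees relabelled species)
    permute_rows <- function(M, perm) {
      M[] <- M[perm, , drop = FALSE]
      M
    }
    stat_row <- function(perm)
      abs(weighted_pearson(tv, score(rlq(permute_rows(Rm, perm), L, Qm)), w))
    stat_col <- function(perm)
      abs(weighted_pearson(tv, score(rlq(Rm, L, permute_rows(Qm, perm))), w))
  }

  run_perms <- function(stat_fn, n_items) {
    vapply(seq_len(n_perm), function(i) {
      for (try in 1:100) {
        s <- tryCatch(stat_fn(sample.int(n_items)), error = function(e) NA_real_)
        if (is.finite(s)) return(s)
        n_degenerate <<- n_degenerate + 1L
      }
      stop("degenerate permutation statistic could not be resampled")
    }, numeric(1))
  }
  perm_p <- function(perm_stats) {
    if (two_sided)
      (1 + sum(abs(perm_stats) >= abs(observed) - 1e-12)) / (n_perm + 1)
    else
      (1 + sum(perm_stats >= observed - 1e-12)) / (n_perm + 1)
  }

  p2 <- p4 <- NA_real_
  if (model %in% c(2, 6)) p2 <- perm_p(run_perms(stat_row, nrow(Rm)))
  if (model %in% c(4, 6)) p4 <- perm_p(run_perms(stat_col, nrow(Qm)))
  p6 <- if (model == 6) max(p2, p4) else NA_real_

  structure(list(statistic = statistic, observed = observed,
                 axis = if (statistic != "sum_eigenvalues") axis else NA,
                 trait = trait,
                 p_model2 = p2, p_model4 = p4, p_model6 = p6,
                 p = switch(as.character(model), "2" = p2, "4" = p4, "6" = p6),
                 n_perm = n_perm, model = model, seed = seed,
                 n_degenerate = n_degenerate),
            class = "fourth_corner")
}

std_vec <- function(x, w) {
  w <- w / sum(w)
  xc <- x - sum(w * x)
  s <- sqrt(sum(w * xc^2))
  if (s <= .Machine$double.eps) stop("zero weighted variance")
  xc / s
}

#' @export
print.fourth_corner <- function(x, ...) {
  cat("Fourth-corner permutation test (model ", x$model, ", ",
      x$n_perm, " permutations)\n", sep = "")
  cat("statistic:", x$statistic,
      if (!is.na(x$axis)) paste0("(axis ", x$axis, ")"), "=",
      signif(x$observed, 4), "\n")
  cat("p (model 2):", x$p_model2, " p (model 4):", x$p_model4,
      " p (model 6):", x$p_model6, "\n")
  invisible(x)
}

#' Moran's probability of K significant tests in N trials
#'
#' Exact Bernoulli point probability of observing exactly \code{K} tests
#' significant at level \code{alpha} among \code{N} independent trials under
#' the global null,
#' \deqn{P = \frac{N!}{(N-K)!\,K!}\,\alpha^K (1-\alpha)^{N-K},}
#' used to aggregate evidence across multiple permutation tests (e.g. the
#' per-mutualism trait-axis correlations). Computed in log space so large
#' \code{N} does not overflow the binomial coefficient.
#'
#' @param N number of tests.
#' @param K number of significant tests (0 <= K <= N).
#' @param alpha significance level in (0, 1).
#' @return the point probability.
#' @examples
#' moran_probability(6, 4, 0.05)   # ~ 8.5e-5
#' @export
moran_probability <- function(N, K, alpha = 0.05) {
  if (K < 0 || K > N) stop("K must satisfy 0 <= K <= N")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  exp(lchoose(N, K) + K * log(alpha) + (N - K) * log1p(-alpha))
}
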