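#' Site covariates
#'
#' Per-site abiotic context: mean annual temperature (MAT, degrees C), mean
#' annual precipitation (MAP, mm per year), land use (LU, 0 = near-natural,
#' 1 = anthropogenic), elevation (m a.s.l.) and habitat type. MAT/MAP may be
#' missing for individual sites before [impute_climate()].
#'
#' @param df data frame with columns \code{site_id}, \code{MAT}, \code{MAP},
#'   \code{LU}, \code{elevation}, \code{habitat}.
#' @return data frame of class \code{site_covariates}, sorted by site id.
#' @export
site_covariates <- function(df) {
  need <- c("site_id", "MAT", "MAP", "LU", "elevation", "habitat")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("covariates lack column(s): ", paste(miss, collapse = ", "))
  if (!all(df$LU %in% c(0, 1)))
    stop("LU must be binary (0 = near-natural, 1 = anthropogenic)")
  if (anyDuplicated(df$site_id)) stop("duplicated site_id")
  df$site_id <- as.character(df$site_id)
  df <- df[order(df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("site_covariates", "data.frame")
  df
}

#' Read site covariates from CSV
#'
#' Empty MAT/MAP cells are read as missing.
#'
#' @param path CSV with columns \code{site_id,MAT,MAP,LU,elevation,habitat}.
#' @return a [site_covariates()] data frame.
#' @export
read_covariates <- function(path) {
  site_covariates(utils::read.csv(path, stringsAsFactors = FALSE,
                                  na.strings = c("", "NA")))
}

#' Impute missing site climate from elevation and habitat
#'
#' Sites lacking MAT or MAP get predictions from an ordinary least squares
#' model of the observed values on a third-order polynomial of elevation plus
#' additive habitat-type indicators, fitted across the complete sites.
#' Observed values are never touched.
#'
#' @param covariates a [site_covariates()] table with >= 10 complete sites.
#' @return the covariates with missing MAT/MAP filled in; attribute
#'   \code{imputation} records per-response R squared, the model fits and the
#'   imputed site ids.
#' @export
impute_climate <- function(covariates) {
  stopifnot(inherits(covariates, "site_covariates"))
  res <- covariates
  info <- list()
  for (resp in c("MAT", "MAP")) {
    missing <- is.na(covariates[[resp]])
    complete <- !missing & !is.na(covariates$elevation)
    if (!any(missing)) {
      info[[resp]] <- list(r_squared = NA_real_, imputed = character(0))
      next
    }
    if (sum(complete) < 10)
      stop("need >= 10 complete sites to impute ", resp)
    dat <- covariates[complete, , drop = FALSE]
    dat$habitat <- factor(dat$habitat)
    mm <- stats::model.matrix(~ poly(elevation, 3, raw = TRUE) + habitat,
                              data = dat)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("rank-deficient imputation design; collinear column(s): ",
           paste(dropped, collapse = ", "))
    }
    fit <- stats::lm(stats::reformulate(
      c("poly(elevation, 3, raw = TRUE)", "habitat"), response = resp),
      data = dat)
    newdat <- covariates[missing, , drop = FALSE]
    newhab <- setdiff(unique(newdat$habitat), levels(dat$habitat))
    if (length(newhab))
      stop("cannot impute ", resp, " for unseen habitat type(s): ",
           paste(newhab, collapse = ", "))
    newdat$habitat <- factor(newdat$habitat, levels = levels(dat$habitat))
    res[[resp]][missing] <- unname(stats::predict(fit, newdata = newdat))
    info[[resp]] <- list(r_squared = summary(fit)$r.squared,
                         imputed = covariates$site_id[missing],
                         fit = fit)
  }
  attr(res, "imputation") <- info
  res
}
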