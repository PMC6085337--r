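#' Allometric trait prediction on the log-log scale
#'
#' Predicts a trait from a correlated measurement through a power law
#' \code{ln(trait) = intercept + slope * ln(predictor)}, as used e.g. to
#' estimate bee body length from intertegular distance
#' (intercept 1.89, slope 0.518) or wasp proboscis length from head width
#' (intercept -1.32, slope 1.54).
#'
#' @param predictor strictly positive numeric vector.
#' @param intercept,slope coefficients of the log-log regression.
#' @return predicted trait values, \code{exp(intercept + slope*ln(predictor))}.
#' @seealso [fit_allometry()] to estimate the coefficients from known pairs.
#' @export
impute_trait_allometric <- function(predictor, intercept, slope) {
  if (any(predictor <= 0, na.rm = TRUE))
    stop("allometric predictor must be strictly positive")
  exp(intercept + slope * log(predictor))
}

#' Fit a log-log allometric regression from known trait pairs
#'
#' @param predictor,response strictly positive numeric vectors of equal
#'   length (species with both measurements).
#' @return list with \code{intercept}, \code{slope} and \code{r_squared} of
#'   the least-squares fit of \code{ln(response)} on \code{ln(predictor)}.
#' @export
fit_allometry <- function(predictor, response) {
  if (any(predictor <= 0) || any(response <= 0))
    stop("allometric variables must be strictly positive")
  fit <- stats::lm(log(response) ~ log(predictor))
  list(intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       r_squared = summary(fit)$r.squared)
}

#' Fill missing traits from taxonomic relatives
#'
#' Missing trait values are replaced by the mean across species of the same
#' genus; failing that, the same family; failing that, the same order. The
#' taxonomic level used is recorded per filled cell. Species with no scored
#' relative at any level are flagged unresolved and left missing.
#'
#' @param table a [trait_table()] possibly containing \code{NA} cells.
#' @param taxonomy data frame with columns \code{species_id}, \code{genus},
#'   \code{family}, \code{order} covering all species in \code{table}.
#' @return the filled \code{trait_table}; attribute \code{provenance} is a
#'   data frame (species_id, trait, level, value) of filled cells, attribute
#'   \code{unresolved} lists species x trait combinations left missing.
#' @export
impute_trait_taxonomic <- function(table, taxonomy) {
  stopifnot(inherits(table, "trait_table"))
  need <- c("species_id", "genus", "family", "order")
  if (!all(need %in% colnames(taxonomy)))
    stop("taxonomy needs columns: ", paste(need, collapse = ", "))
  miss_tax <- setdiff(table$species_id, taxonomy$species_id)
  if (length(miss_tax))
    stop("species missing from taxonomy: ", paste(miss_tax, collapse = ", "))
  tax <- taxonomy[match(table$species_id, taxonomy$species_id), ]
  prov <- list()
  unresolved <- list()
  for (cl in trait_columns(table)) {
    v <- table[[cl]]
    for (i in which(is.na(v))) {
      filled <- FALSE
      for (level in c("genus", "family", "order")) {
        rel <- which(tax[[level]] == tax[[level]][i] &
                       seq_along(v) != i & !is.na(v))
        if (length(rel)) {
          v[i] <- mean(v[rel])
          prov[[length(prov) + 1L]] <- data.frame(
            species_id = table$species_id[i], trait = cl,
            level = level, value = v[i], stringsAsFactors = FALSE)
          filled <- TRUE
          break
        }
      }
      if (!filled)
        unresolved[[length(unresolved) + 1L]] <- data.frame(
          species_id = table$species_id[i], trait = cl,
          stringsAsFactors = FALSE)
    }
    table[[cl]] <- v
  }
  attr(table, "provenance") <- if (length(prov)) do.call(rbind, prov) else
    data.frame(species_id = character(0), trait = character(0),
               level = character(0), value = numeric(0))
  attr(table, "unresolved") <- if (length(unresolved))
    do.call(rbind, unresolved) else NULL
  if (length(unresolved))
    warning(length(unresolved),
            " trait value(s) unresolvable at genus/family/order level")
  table
}
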