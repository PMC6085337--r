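#' Interaction records and derived networks
#'
#' Long-format interaction records hold one row per observed (site, plant,
#' animal) combination with a non-negative count of interaction events.
#' From the records of one mutualism two derived objects are built: the
#' binary metaweb \code{L} (was the pair ever observed interacting across
#' all sites) and the per-site weighted networks used for functional
#' diversity and niche metrics.
#'
#' @param records data frame with columns \code{site_id}, \code{mutualism},
#'   \code{plant_id}, \code{animal_id}, \code{count}.
#' @return an object of class \code{interaction_data}: list with elements
#'   \code{records}, \code{metaweb} and \code{site_networks}.
#' @export
interaction_data <- function(records) {
  records <- validate_records(records)
  structure(list(records = records,
                 metaweb = build_metaweb(records),
                 site_networks = site_networks(records)),
            class = "interaction_data")
}

validate_records <- function(records) {
  need <- c("site_id", "mutualism", "plant_id", "animal_id", "count")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("records lack column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0) stop("empty record set")
  if (any(records$count < 0) || any(records$count != round(records$count)))
    stop("count must be a non-negative integer")
  for (cl in c("site_id", "mutualism", "plant_id", "animal_id"))
    records[[cl]] <- as.character(records[[cl]])
  records
}

#' Build the binary metaweb of one mutualism
#'
#' \code{L[i, j] = 1} iff plant i and animal j were observed interacting at
#' least once across all sites. Species that never interact are pruned, so
#' every row and column of \code{L} has degree >= 1. Rows and columns are
#' ordered lexicographically by species id; the result is invariant to
#' record order and to count magnitudes.
#'
#' @param records long-format records of a single mutualism.
#' @return binary matrix, plants as rows, animals as columns.
#' @export
build_metaweb <- function(records) {
  records <- validate_records(records)
  if (length(unique(records$mutualism)) > 1)
    stop("records span more than one mutualism; build one metaweb per mutualism")
  records <- records[records$count > 0, , drop = FALSE]
  if (nrow(records) == 0) stop("no positive interaction counts")
  plants <- sort(unique(records$plant_id))
  animals <- sort(unique(records$animal_id))
  L <- matrix(0L, length(plants), length(animals),
              dimnames = list(plants, animals))
  L[cbind(records$plant_id, records$animal_id)] <- 1L
  L
}

#' Per-site weighted interaction networks
#'
#' @param records long-format records of a single mutualism.
#' @return named list (by site) of weighted plant x animal count matrices;
#'   each network keeps only the species observed at that site.
#' @export
site_networks <- function(records) {
  records <- validate_records(records)
  records <- records[records$count > 0, , drop = FALSE]
  out <- lapply(split(records, records$site_id), function(r) {
    plants <- sort(unique(r$plant_id))
    animals <- sort(unique(r$animal_id))
    w <- matrix(0, length(plants), length(animals),
                dimnames = list(plants, animals))
    for (k in seq_len(nrow(r)))
      w[r$plant_id[k], r$animal_id[k]] <- w[r$plant_id[k], r$animal_id[k]] +
        r$count[k]
    w
  })
  out[sort(names(out))]
}

#' Read long-format interaction records from CSV
#'
#' Expected columns: \code{site_id,mutualism,plant_id,animal_id,count}.
#'
#' @param path CSV path.
#' @return validated records data frame.
#' @export
read_interactions <- function(path) {
  validate_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.interaction_data <- function(x, ...) {
  cat("Interaction data:", nrow(x$records), "records,",
      nrow(x$metaweb), "plants x", ncol(x$metaweb), "animals,",
      length(x$site_networks), "site networks\n")
  invisible(x)
}
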