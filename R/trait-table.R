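#' Construct a trait table
#'
#' A trait table holds quantitative functional traits for the species of one
#' trophic level of a mutualistic network. Each table carries exactly three
#' traits, one per functional trait type: a size-matching trait (e.g. fruit
#' diameter, bill width, corolla depth, proboscis length), an energy trait
#' (e.g. crop mass, body mass, flower number, head width) and a foraging
#' trait (e.g. plant height, Kipp's index, forewing index). Trait values are
#' strictly positive real numbers on their measurement scale (mm, g, counts,
#' dimensionless ratios); ratio traits are computed from their components
#' before any transformation.
#'
#' Rows are always sorted lexicographically by \code{species_id} so that all
#' derived matrices are reproducible.
#'
#' @param species_id character vector of unique species identifiers.
#' @param traits data frame or matrix of numeric trait values, one column per
#'   trait.
#' @param trait_types named character vector mapping each trait column to one
#'   of \code{"matching"}, \code{"energy"}, \code{"foraging"}; exactly one
#'   trait per type.
#' @param trophic_level \code{"plant"} or \code{"animal"}.
#' @return An object of class \code{trait_table}: a data frame with a
#'   \code{species_id} column and one column per trait, plus attributes
#'   \code{trait_types} and \code{trophic_level}.
#' @examples
#' trait_table(c("sp1", "sp2"),
#'             data.frame(fruit_diameter = c(4, 9),
#'                        crop_mass = c(10, 200),
#'                        plant_height = c(2, 15)),
#'             c(fruit_diameter = "matching", crop_mass = "energy",
#'               plant_height = "foraging"),
#'             "plant")
#' @export
trait_table <- function(species_id, traits, trait_types, trophic_level) {
  trophic_level <- match.arg(trophic_level, c("plant", "animal"))
  species_id <- as.character(species_id)
  if (anyDuplicated(species_id))
    stop("duplicated species_id: ",
         paste(unique(species_id[duplicated(species_id)]), collapse = ", "))
  traits <- as.data.frame(traits)
  if (nrow(traits) != length(species_id))
    stop("traits must have one row per species")
  check_trait_types(trait_types, colnames(traits))
  for (cl in colnames(traits)) {
    if (!is.numeric(traits[[cl]]))
      stop("trait column '", cl, "' is not numeric")
  }
  ord <- order(species_id)
  out <- cbind(data.frame(species_id = species_id[ord],
                          stringsAsFactors = FALSE),
               traits[ord, , drop = FALSE])
  rownames(out) <- NULL
  structure(out,
            trait_types = trait_types[colnames(traits)],
            trophic_level = trophic_level,
            class = c("trait_table", "data.frame"))
}

check_trait_types <- function(trait_types, trait_cols) {
  valid <- c("matching", "energy", "foraging")
  if (is.null(names(trait_types)) || !all(trait_cols %in% names(trait_types)))
    stop("trait_types must be named by trait column")
  tt <- trait_types[trait_cols]
  if (!all(tt %in% valid))
    stop("trait_type must be one of: ", paste(valid, collapse = ", "))
  miss <- setdiff(valid, tt)
  if (length(miss))
    stop("missing trait_type label(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tt))
    stop("more than one trait per trait_type: ",
         paste(tt[duplicated(tt)], collapse = ", "))
  invisible(tt)
}

#' Read a trait table from CSV
#'
#' The CSV must have a \code{species_id} column and one column per trait.
#' Trait-type labels come either from \code{trait_type_map} or from a
#' companion metadata CSV with columns \code{trait,trait_type} (and
#' optionally \code{units}). Blank cells become \code{NA} with a warning;
#' they can be filled with [impute_trait_taxonomic()] or
#' [impute_trait_allometric()].
#'
#' @param path path to the trait CSV.
#' @param trait_type_map named character vector, trait column ->
#'   matching/energy/foraging.
#' @param metadata optional path to a metadata CSV (used when
#'   \code{trait_type_map} is \code{NULL}).
#' @param trophic_level \code{"plant"} or \code{"animal"}.
#' @return a [trait_table()].
#' @export
read_trait_table <- function(path, trait_type_map = NULL, metadata = NULL,
                             trophic_level = c("plant", "animal")) {
  trophic_level <- match.arg(trophic_level)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if (!"species_id" %in% colnames(df))
    stop("trait CSV must contain a species_id column: ", path)
  if (is.null(trait_type_map)) {
    if (is.null(metadata))
      stop("either trait_type_map or a metadata CSV is required")
    md <- utils::read.csv(metadata, stringsAsFactors = FALSE)
    if (!all(c("trait", "trait_type") %in% colnames(md)))
      stop("metadata CSV needs columns trait,trait_type: ", metadata)
    trait_type_map <- stats::setNames(md$trait_type, md$trait)
  }
  trait_cols <- setdiff(colnames(df), "species_id")
  bad <- vapply(df[trait_cols], function(x) !is.numeric(x), logical(1))
  if (any(bad)) {
    # report unparseable cells by row/column
    for (cl in trait_cols[bad]) {
      raw <- df[[cl]]
      conv <- suppressWarnings(as.numeric(raw))
      rows <- which(is.na(conv) & !is.na(raw))
      if (length(rows))
        stop("unparseable numeric value(s) in column '", cl, "', row(s) ",
             paste(rows, collapse = ", "))
      df[[cl]] <- conv
    }
  }
  n_missing <- sum(is.na(df[trait_cols]))
  if (n_missing > 0)
    warning(n_missing, " missing trait value(s) in ", basename(path))
  trait_table(df$species_id, df[trait_cols], trait_type_map, trophic_level)
}

#' Square-root transform a trait table
#'
#' All plant and animal traits are square-root transformed before ordination
#' and distance computations; ratio traits are transformed like any other
#' trait. Missing values pass through.
#'
#' @param x a [trait_table()].
#' @return the transformed \code{trait_table}; trait-type labels preserved.
#' @export
sqrt_transform <- function(x) {
  stopifnot(inherits(x, "trait_table"))
  cols <- trait_columns(x)
  for (cl in cols) {
    v <- x[[cl]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative trait value in column '", cl, "'")
    x[[cl]] <- sqrt(v)
  }
  x
}

#' @rdname trait_table
#' @param x a \code{trait_table}.
#' @export
trait_columns <- function(x) setdiff(colnames(x), "species_id")

#' Extract the numeric trait matrix of a trait table
#'
#' @param x a [trait_table()].
#' @param trait_set \code{"all"} or a subset of
#'   \code{c("matching","energy","foraging")}.
#' @return numeric matrix, species as (named) rows.
#' @export
trait_matrix <- function(x, trait_set = "all") {
  stopifnot(inherits(x, "trait_table"))
  tt <- attr(x, "trait_types")
  cols <- trait_columns(x)
  if (!identical(trait_set, "all")) {
    bad <- setdiff(trait_set, c("matching", "energy", "foraging"))
    if (length(bad)) stop("unknown trait_set: ", paste(bad, collapse = ", "))
    cols <- cols[tt[cols] %in% trait_set]
  }
  m <- as.matrix(x[cols])
  rownames(m) <- x$species_id
  m
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table (", attr(x, "trophic_level"), "), ",
      nrow(x), " species\n", sep = "")
  tt <- attr(x, "trait_types")
  cat("traits:", paste0(names(tt), " [", tt, "]", collapse = ", "), "\n")
  print.data.frame(utils::head(x, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
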