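#' Construct and validate a municipality profile table
#'
#' A profile table holds the raw per-municipality attributes from which every
#' model input is derived: population, patient demand for each intervention,
#' estimated substance consumers, sentiment-labelled social-media post counts,
#' crime incidents, the multidimensional poverty index (MPI), the rurality
#' proportion, and centroid coordinates.
#'
#' @param df data.frame with columns `node_id`, `name`, `latitude`,
#'   `longitude`, `population`, `demand_prevention`, `demand_mitigation`,
#'   `consumers`, `posts_negative`, `posts_neutral`, `posts_positive`,
#'   `crime_incidents`, `mpi`, `rurality`.
#' @return the validated data.frame with class `municipality_profiles`.
#' @export
municipality_profiles <- function(df) {
  required <- c(
    "node_id", "name", "latitude", "longitude", "population",
    "demand_prevention", "demand_mitigation", "consumers",
    "posts_negative", "posts_neutral", "posts_positive",
    "crime_incidents", "mpi", "rurality"
  )
  if (!is.data.frame(df) || nrow(df) < 1L) {
    stop("profiles must be a data.frame with at least one row", call. = FALSE)
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("profile table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$node_id <- as.character(df$node_id)
  if (anyDuplicated(df$node_id)) {
    stop("duplicate node_id in profile table", call. = FALSE)
  }
  counts <- c("population", "demand_prevention", "demand_mitigation",
              "consumers", "posts_negative", "posts_neutral",
              "posts_positive", "crime_incidents")
  for (col in counts) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
      stop("column '", col, "' must contain nonnegative integers", call. = FALSE)
    }
  }
  for (col in c("mpi", "rurality")) {
    v <- df[[col]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1)) {
      stop("column '", col, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  if (any(abs(df$latitude) > 90) || any(abs(df$longitude) > 180)) {
    stop("coordinates out of range: |latitude| <= 90, |longitude| <= 180",
         call. = FALSE)
  }
  df <- df[, required]
  class(df) <- c("municipality_profiles", "data.frame")
  df
}

#' Read a municipality profile table from CSV
#'
#' @param path CSV file with the exact column names of
#'   [municipality_profiles()].
#' @return a validated `municipality_profiles` data.frame.
#' @export
read_profiles_csv <- function(path) {
  if (!file.exists(path)) stop("profile CSV not found: ", path, call. = FALSE)
  municipality_profiles(read.csv(path, stringsAsFactors = FALSE))
}

#' Write a municipality profile table to CSV
#'
#' @param profiles a `municipality_profiles` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
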