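#' Distance matrix container
#'
#' @param d numeric `|I| x |J|` matrix of kilometres, dimnames set to node
#'   ids.
#' @param node_ids character vector naming the common node order.
#' @return object of class `distance_matrix`: list with `node_ids`, `d`
#'   (km matrix) and `d_max` (global maximum entry, used to normalise the
#'   distance terms of both objectives).
#' @export
distance_matrix <- function(d, node_ids) {
  node_ids <- as.character(node_ids)
  d <- as.matrix(d)
  if (nrow(d) != length(node_ids) || ncol(d) != length(node_ids)) {
    stop("distance matrix must be square over node_ids", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and nonnegative", call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop("self-distances must be zero", call. = FALSE)
  }
  dimnames(d) <- list(node_ids, node_ids)
  structure(
    list(node_ids = node_ids, d = d, d_max = max(d)),
    class = "distance_matrix"
  )
}

#' Great-circle distance matrix from profile coordinates
#'
#' Haversine distances (Earth radius 6371 km) between municipality centroids.
#' A stand-in for a road-network (driving) matrix, which can be supplied
#' instead via [load_distance_csv()].
#'
#' @param profiles a [municipality_profiles()] table with valid coordinates.
#' @return a [distance_matrix()].
#' @export
haversine_matrix <- function(profiles) {
  pts <- cbind(profiles$longitude, profiles$latitude)
  if (any(!is.finite(pts))) stop("invalid coordinates", call. = FALSE)
  d <- geosphere::distm(pts, fun = function(p1, p2) {
    geosphere::distHaversine(p1, p2, r = 6371000)
  }) / 1000
  diag(d) <- 0
  distance_matrix(d, profiles$node_id)
}

#' Load a distance matrix from CSV
#'
#' Accepts either a square matrix layout (first column and header row are
#' node ids) or a long layout with columns `origin`, `destination`, `km`.
#' The long layout must cover every ordered pair; missing pairs and negative
#' entries are reported by name.
#'
#' @param path CSV file path.
#' @param node_ids optional character vector; when given, the file must cover
#'   exactly these nodes and the result follows this order.
#' @return a [distance_matrix()].
#' @export
load_distance_csv <- function(path, node_ids = NULL) {
  if (!file.exists(path)) stop("distance CSV not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  long <- all(c("origin", "destination", "km") %in% names(df))
  if (long) {
    ids <- if (is.null(node_ids)) {
      unique(c(as.character(df$origin), as.character(df$destination)))
    } else {
      as.character(node_ids)
    }
    unknown <- setdiff(unique(c(df$origin, df$destination)), ids)
    if (length(unknown) > 0L) {
      stop("unknown node in distance CSV: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    d <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
    d[cbind(as.character(df$origin), as.character(df$destination))] <- df$km
    miss <- which(is.na(d), arr.ind = TRUE)
    if (nrow(miss) > 0L) {
      stop("distance CSV missing pair (", ids[miss[1, 1]], ", ",
           ids[miss[1, 2]], ")", call. = FALSE)
    }
  } else {
    ids <- as.character(df[[1]])
    d <- as.matrix(df[, -1, drop = FALSE])
    mode(d) <- "numeric"
    if (ncol(d) != length(ids)) {
      stop("square distance CSV must have one column per node id", call. = FALSE)
    }
    dimnames(d) <- list(ids, colnames(df)[-1])
    if (!identical(ids, colnames(d))) {
      stop("row and column node ids of square distance CSV disagree",
           call. = FALSE)
    }
    if (!is.null(node_ids)) {
      node_ids <- as.character(node_ids)
      missing <- setdiff(node_ids, ids)
      if (length(missing) > 0L) {
        stop("distance CSV missing node: ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
      d <- d[node_ids, node_ids]
      ids <- node_ids
    }
  }
  bad <- which(d < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("negative distance at (", rownames(d)[bad[1, 1]], ", ",
         colnames(d)[bad[1, 2]], ")", call. = FALSE)
  }
  distance_matrix(d, ids)
}

#' Write a distance matrix to CSV (square layout)
#'
#' @param dm a [distance_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  df <- data.frame(node_id = dm$node_ids, dm$d, check.names = FALSE)
  names(df) <- c("node_id", dm$node_ids)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Radius mask over a distance matrix
#'
#' Boolean mask of node pairs within a service radius. The threshold is
#' inclusive: a pair exactly at the radius counts as covered.
#'
#' @param dm a [distance_matrix()].
#' @param radius_km positive radius in kilometres.
#' @return logical matrix with the dimensions of `dm$d`.
#' @export
within_radius <- function(dm, radius_km) {
  stopifnot(inherits(dm, "distance_matrix"))
  if (!is.numeric(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  dm$d <= radius_km
}
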