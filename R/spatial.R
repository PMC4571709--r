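#' Read a station presence table
#'
#' Long-format CSV with header `station,lon,lat,species`: one row per
#' species observed at a station.
#'
#' @param path CSV path.
#' @return data frame with those four columns.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("station file not found: ", path,
                               call. = FALSE)
  st <- read.csv(path, strip.white = TRUE,
                 colClasses = c(station = "character", lon = "numeric",
                                lat = "numeric", species = "character"))
  need <- c("station", "lon", "lat", "species")
  if (!all(need %in% names(st))) {
    stop("station table must have header columns station,lon,lat,species",
         call. = FALSE)
  }
  if (any(!is.finite(st$lon)) || any(!is.finite(st$lat))) {
    stop("station coordinates must be finite", call. = FALSE)
  }
  st
}

#' Station-wise mean degree centrality
#'
#' For each station, the mean meta-web degree (prey + predator links, a
#' self-link counted once) over the species present, optionally restricted
#' to a taxon filter (e.g. the fish list). Species unknown to the meta-web
#' are dropped with a warning; stations with no qualifying species get `NA`.
#'
#' @param stations data frame `station,lon,lat,species` (see
#'   [read_stations]).
#' @param meta the meta-web supplying the degrees.
#' @param taxa_filter optional [species_set] or character vector; must be a
#'   subset of the meta-web's nodes.
#' @return data frame with one row per station: `station`, `lon`, `lat`,
#'   `n_species`, `mean_degree`.
#' @export
station_mean_degree <- function(stations, meta, taxa_filter = NULL) {
  stopifnot(inherits(meta, "food_web"))
  need <- c("station", "lon", "lat", "species")
  if (!all(need %in% names(stations))) {
    stop("station table must have columns station,lon,lat,species",
         call. = FALSE)
  }
  deg <- total_degree(meta)
  coords <- unique(stations[, c("station", "lon", "lat")])
  coords <- coords[!duplicated(coords$station), , drop = FALSE]
  unknown <- setdiff(unique(stations$species), meta$nodes)
  if (length(unknown)) {
    warning("excluding species unknown to the meta-web: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    stations <- stations[!(stations$species %in% unknown), , drop = FALSE]
  }
  if (!is.null(taxa_filter)) {
    taxa <- as_members(taxa_filter)
    miss <- setdiff(taxa, meta$nodes)
    if (length(miss)) {
      stop("taxa filter contains species absent from the meta-web: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    stations <- stations[stations$species %in% taxa, , drop = FALSE]
  }
  split_sp <- split(stations$species, stations$station)
  mean_deg <- vapply(coords$station, function(s) {
    sp <- unique(split_sp[[s]])
    if (is.null(sp) || !length(sp)) NA_real_ else mean(deg[sp])
  }, numeric(1))
  n_sp <- vapply(coords$station, function(s) {
    length(unique(split_sp[[s]]))
  }, integer(1))
  data.frame(station = coords$station, lon = coords$lon, lat = coords$lat,
             n_species = n_sp, mean_degree = unname(mean_deg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate station values on a regular km grid
#'
#' Projects stations with a local equirectangular projection about their
#' centroid (x = east, y = north, in km), bins them into square cells of
#' side `cell_km`, and returns the per-cell mean of the station values.
#' Cells containing no station are simply absent (never reported as 0);
#' stations with missing values are excluded.
#'
#' @param values data frame with columns `lon`, `lat` and a value column.
#' @param cell_km cell size in km (> 0); 50 km mirrors typical survey
#'   resolution of about one station per cell.
#' @param value_col name of the value column (default `"mean_degree"`).
#' @return data frame of class `degree_field`: `cell_x`, `cell_y` (cell
#'   centre coordinates, km), `mean_value`, `n_stations`; attributes carry
#'   the projection origin and cell size.
#' @export
grid_aggregate <- function(values, cell_km = 50,
                           value_col = "mean_degree") {
  stopifnot(cell_km > 0)
  if (!all(c("lon", "lat", value_col) %in% names(values))) {
    stop("values must have columns lon, lat and ", value_col, call. = FALSE)
  }
  v <- values[is.finite(values[[value_col]]), , drop = FALSE]
  if (!nrow(v)) {
    out <- data.frame(cell_x = numeric(), cell_y = numeric(),
                      mean_value = numeric(), n_stations = integer())
    class(out) <- c("degree_field", "data.frame")
    return(out)
  }
  lon0 <- mean(values$lon)
  lat0 <- mean(values$lat)
  km_per_deg <- 6371 * pi / 180
  x <- (v$lon - lon0) * km_per_deg * cos(lat0 * pi / 180)
  y <- (v$lat - lat0) * km_per_deg
  ix <- floor(x / cell_km)
  iy <- floor(y / cell_km)
  key <- paste(ix, iy)
  agg <- aggregate(v[[value_col]], by = list(key = key), FUN = mean)
  cnt <- as.data.frame(table(key), stringsAsFactors = FALSE)
  ij <- do.call(rbind, strsplit(agg$key, " ", fixed = TRUE))
  out <- data.frame(
    cell_x = (as.numeric(ij[, 1]) + 0.5) * cell_km,
    cell_y = (as.numeric(ij[, 2]) + 0.5) * cell_km,
    mean_value = agg$x,
    n_stations = cnt$Freq[match(agg$key, cnt$key)])
  out <- out[order(out$cell_x, out$cell_y), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "origin") <- c(lon = lon0, lat = lat0)
  attr(out, "cell_km") <- cell_km
  class(out) <- c("degree_field", "data.frame")
  out
}
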