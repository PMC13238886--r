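#' Construct and validate a site table
#'
#' A site table describes the sampling design: one row per site with a unique
#' short identifier, decimal-degree coordinates, and the ocean basin the site
#' belongs to. All downstream pairwise analyses (genetic differentiation,
#' community dissimilarity, in-water distance) are keyed on `site_id`.
#'
#' @param x data.frame with columns `site_id`, `name`, `lon`, `lat`, `basin`
#'   (`name` is optional and defaults to `site_id`).
#' @return data.frame of class `site_table`.
#' @examples
#' site_table(data.frame(
#'   site_id = c("A", "B"), lon = c(45, 55), lat = c(-4, -12),
#'   basin = "WIO"))
#' @export
site_table <- function(x) {
  x <- as.data.frame(x)
  required <- c("site_id", "lon", "lat", "basin")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("site table is missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"name" %in% names(x)) x$name <- x$site_id
  x$site_id <- as.character(x$site_id)
  x$basin <- as.character(x$basin)
  if (anyDuplicated(x$site_id))
    stop("duplicated site_id: ",
         paste(unique(x$site_id[duplicated(x$site_id)]), collapse = ", "))
  if (any(!is.finite(x$lon)) || any(x$lon < -180 | x$lon > 180))
    stop("lon must be finite and within [-180, 180]")
  if (any(!is.finite(x$lat)) || any(x$lat < -90 | x$lat > 90))
    stop("lat must be finite and within [-90, 90]")
  x <- x[, c("site_id", "name", "lon", "lat", "basin")]
  class(x) <- c("site_table", "data.frame")
  x
}

#' Read a site table from CSV
#'
#' Expects a header `site_id,name,lon,lat,basin` (column order free).
#'
#' @param path CSV file path.
#' @return `site_table` data.frame.
#' @export
read_sites <- function(path) {
  site_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @export
print.site_table <- function(x, ...) {
  cat("Site table:", nrow(x), "sites in",
      length(unique(x$basin)), "basin(s)\n")
  NextMethod()
  invisible(x)
}
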