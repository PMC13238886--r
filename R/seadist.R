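#' Construct a gridded seascape (land/sea mask)
#'
#' Regular lon/lat grid with a binary traversability mask. Cells are sea
#' (traversable) or land. When built from an elevation grid, cells with
#' elevation at or above `land_threshold` are land; depth itself is ignored.
#'
#' @param lon,lat vectors of cell-center coordinates (regular spacing,
#'   increasing).
#' @param mask logical matrix `length(lat)` x `length(lon)`, TRUE = sea.
#'   Row 1 corresponds to `lat[1]`.
#' @return object of class `seascape_grid`.
#' @export
seascape_grid <- function(lon, lat, mask) {
  mask <- as.matrix(mask)
  if (nrow(mask) != length(lat) || ncol(mask) != length(lon))
    stop("mask must be length(lat) x length(lon)")
  if (!is.logical(mask)) stop("mask must be logical (TRUE = sea)")
  step_ok <- function(v) length(v) < 2 ||
    max(abs(diff(diff(v)))) < 1e-6 * abs(mean(diff(v)))
  if (!step_ok(lon) || !step_ok(lat))
    stop("lon/lat must be regularly spaced")
  if (!any(mask)) stop("grid has no sea cells")
  structure(list(lon = lon, lat = lat, mask = mask,
                 res = c(lon = if (length(lon) > 1) diff(lon[1:2]) else NA,
                         lat = if (length(lat) > 1) diff(lat[1:2]) else NA)),
            class = "seascape_grid")
}

#' @export
print.seascape_grid <- function(x, ...) {
  cat(sprintf(
    "Seascape grid: %d x %d cells (%.3f deg), %.1f%% sea\n",
    length(x$lat), length(x$lon), abs(x$res["lon"]), 100 * mean(x$mask)))
  invisible(x)
}

#' Read a seascape grid from an ESRI ASCII raster
#'
#' Single-band elevation or mask grid in `.asc` format. Cells with value
#' `>= land_threshold` become land (default 0: elevation at or above sea
#' level), so either a bathymetry grid (negative = depth) or a 0/1 land mask
#' works directly.
#'
#' @param path `.asc` file.
#' @param land_threshold numeric; cells with values `>= land_threshold` are
#'   land.
#' @return `seascape_grid`.
#' @export
read_seascape_asc <- function(path, land_threshold = 0) {
  hdr <- list()
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    pos <- seek(con)
    line <- readLines(con, 1)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (suppressWarnings(is.na(as.numeric(parts[1])))) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else { seek(con, pos); break }
  }
  vals <- scan(con, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cs <- hdr$cellsize
  x0 <- if (!is.null(hdr$xllcorner)) hdr$xllcorner + cs / 2 else hdr$xllcenter
  y0 <- if (!is.null(hdr$yllcorner)) hdr$yllcorner + cs / 2 else hdr$yllcenter
  lon <- x0 + (0:(nc - 1)) * cs
  lat <- y0 + (0:(nr - 1)) * cs
  # .asc rows run north -> south; store with row 1 = lat[1] (south)
  m <- m[nr:1, , drop = FALSE]
  sea <- is.na(m) | m < land_threshold
  sea[is.na(m)] <- FALSE   # nodata treated as land (not traversable)
  seascape_grid(lon, lat, sea)
}

#' Write a seascape grid to an ESRI ASCII raster
#'
#' Sea cells are written as -10 (in-water), land cells as 10, so the file
#' reads back with the default `land_threshold = 0`.
#'
#' @param grid `seascape_grid`.
#' @param path output `.asc` path.
#' @export
write_seascape_asc <- function(grid, path) {
  nr <- length(grid$lat); nc <- length(grid$lon)
  cs <- abs(grid$res["lon"])
  hdr <- c(sprintf("ncols %d", nc), sprintf("nrows %d", nr),
           sprintf("xllcorner %.6f", grid$lon[1] - cs / 2),
           sprintf("yllcorner %.6f", grid$lat[1] - cs / 2),
           sprintf("cellsize %.6f", cs), "NODATA_value -9999")
  m <- ifelse(grid$mask, -10, 10)
  m <- m[nr:1, , drop = FALSE]   # write north -> south
  body <- apply(m, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

# haversine great-circle distance in km, Earth radius 6371 km
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Build the sea-traversal graph of a gridded seascape
#'
#' Nodes are sea cells; edges connect neighbouring sea cells, weighted by
#' the great-circle (haversine) distance between cell centres. The default
#' 16-cell neighbourhood (rook + bishop + knight moves) reduces lattice
#' anisotropy relative to the 8-cell one. Moves never cut corners through
#' land: a diagonal step is blocked when both flanking orthogonal cells are
#' land, and a knight step requires the two cells adjacent to its long axis
#' to be sea.
#'
#' @param grid `seascape_grid`.
#' @param neighborhood 8 or 16 (default 16).
#' @return object of class `sea_graph`: the igraph, the grid, and the
#'   node index matrix.
#' @export
build_sea_graph <- function(grid, neighborhood = 16) {
  stopifnot(neighborhood %in% c(8, 16))
  mask <- grid$mask
  nr <- nrow(mask); nc <- ncol(mask)
  node_id <- matrix(NA_integer_, nr, nc)
  node_id[mask] <- seq_len(sum(mask))
  idx <- which(mask, arr.ind = TRUE)   # (row=lat, col=lon) of each node

  moves <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  if (neighborhood == 16)
    moves <- rbind(moves, c(1, 2), c(2, 1), c(2, -1), c(1, -2))

  edges_from <- integer(0); edges_to <- integer(0); wt <- numeric(0)
  sea_at <- function(r, c) r >= 1 & r <= nr & c >= 1 & c <= nc &
    mask[cbind(pmin(pmax(r, 1), nr), pmin(pmax(c, 1), nc))]
  for (k in seq_len(nrow(moves))) {
    dr <- moves[k, 1]; dc <- moves[k, 2]
    r1 <- idx[, 1]; c1 <- idx[, 2]
    r2 <- r1 + dr; c2 <- c1 + dc
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- mask[cbind(r2[ok], c2[ok])]
    if (abs(dr) == 1 && abs(dc) == 1) {
      # block diagonals squeezing between two diagonally-adjacent land cells
      pass <- sea_at(r1, c1 + dc) | sea_at(r1 + dr, c1)
      ok <- ok & pass
    } else if (abs(dr) + abs(dc) == 3) {
      # knight moves must pass two sea cells along the move corridor
      if (abs(dr) == 2) {
        pass <- sea_at(r1 + sign(dr), c1) & sea_at(r1 + sign(dr), c1 + dc)
      } else {
        pass <- sea_at(r1, c1 + sign(dc)) & sea_at(r1 + dr, c1 + sign(dc))
      }
      ok <- ok & pass
    }
    if (!any(ok)) next
    from <- node_id[cbind(r1[ok], c1[ok])]
    to <- node_id[cbind(r2[ok], c2[ok])]
    w <- haversine_km(grid$lon[c1[ok]], grid$lat[r1[ok]],
                      grid$lon[c2[ok]], grid$lat[r2[ok]])
    edges_from <- c(edges_from, from); edges_to <- c(edges_to, to)
    wt <- c(wt, w)
  }
  g <- igraph::make_empty_graph(n = nrow(idx), directed = FALSE)
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(edges_from, edges_to),
                           weight = wt)
  structure(list(graph = g, grid = grid, node_id = node_id, cells = idx,
                 neighborhood = neighborhood),
            class = "sea_graph")
}

#' @export
print.sea_graph <- function(x, ...) {
  cat("Sea graph:", igraph::vcount(x$graph), "sea cells,",
      igraph::ecount(x$graph), "edges (",
      x$neighborhood, "-neighbourhood)\n")
  invisible(x)
}

# snap sites to nearest sea cell within `snap_radius` cells; errors naming
# unsnappable sites
snap_sites <- function(sg, sites, snap_radius = 2) {
  grid <- sg$grid
  cell_lon <- grid$lon[sg$cells[, 2]]
  cell_lat <- grid$lat[sg$cells[, 1]]
  max_km <- snap_radius * haversine_km(0, 0, abs(grid$res["lon"]), 0) * 1.5
  vapply(seq_len(nrow(sites)), function(i) {
    d <- haversine_km(sites$lon[i], sites$lat[i], cell_lon, cell_lat)
    j <- which.min(d)
    if (d[j] > max_km)
      stop("site '", sites$site_id[i], "' is farther than the snap radius (",
           snap_radius, " cells) from any sea cell")
    j
  }, integer(1))
}

#' Least-cost in-water distances between sites
#'
#' Each site snaps to its nearest sea cell (within `snap_radius` cells);
#' shortest in-water path lengths between the snapped cells are computed by
#' Dijkstra's algorithm on the sea graph. Site pairs in disconnected
#' components get `Inf` (flagged, not dropped).
#'
#' @param sg `sea_graph` from [build_sea_graph()].
#' @param sites `site_table`.
#' @param snap_radius snap tolerance in cells (default 2).
#' @return `pairwise_matrix` with metric `"distance_km"`.
#' @export
least_cost_distance <- function(sg, sites, snap_radius = 2) {
  nodes <- snap_sites(sg, sites, snap_radius)
  d <- igraph::distances(sg$graph, v = nodes, to = nodes,
                         weights = igraph::E(sg$graph)$weight,
                         algorithm = "dijkstra")
  dimnames(d) <- list(sites$site_id, sites$site_id)
  pairwise_matrix(d, sites$site_id, "distance_km")
}
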