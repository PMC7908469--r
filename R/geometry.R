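#' @useDynLib spfrail, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dist optim dnorm rnorm runif quantile median var sd
#'   rbinom rexp density acf integrate uniroot setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

EARTH_RADIUS_M <- 6371008.8

# ---- ring / polygon primitives -------------------------------------------

#' Signed area of a closed ring (shoelace), in squared coordinate units
#' @keywords internal
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Area-weighted centroid of a closed ring
#' @keywords internal
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x[-n]), mean(y[-n])))
  cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
  cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  c(cx, cy)
}

# Repair a ring cheaply: drop consecutive duplicate vertices, force closure.
repair_ring <- function(ring) {
  ring <- as.matrix(ring)
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 0)
  ring <- ring[keep, , drop = FALSE]
  if (nrow(ring) >= 1 && any(ring[1, ] != ring[nrow(ring), ]))
    ring <- rbind(ring, ring[1, ])
  ring
}

# O(k^2) proper-crossing test between non-adjacent edges.
ring_self_intersects <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(FALSE)
  seg <- function(i) list(p = ring[i, ], q = ring[i + 1L, ])
  orient <- function(a, b, c)
    sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  for (i in seq_len(n - 2L)) {
    si <- seg(i)
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      sj <- seg(j)
      if (orient(si$p, si$q, sj$p) * orient(si$p, si$q, sj$q) < 0 &&
          orient(sj$p, sj$q, si$p) * orient(sj$p, sj$q, si$q) < 0)
        return(TRUE)
    }
  }
  FALSE
}

# Multi-part geometry helpers: a geometry is a list of "parts"; each part is a
# list of rings (first outer, rest holes); each ring an (k x 2) matrix.
geometry_centroid <- function(parts) {
  totA <- 0; cx <- 0; cy <- 0
  for (part in parts) {
    for (r in seq_along(part)) {
      a <- abs(ring_area(part[[r]])) * if (r == 1L) 1 else -1
      ctr <- ring_centroid(part[[r]])
      totA <- totA + a
      cx <- cx + a * ctr[1]; cy <- cy + a * ctr[2]
    }
  }
  if (totA <= 0) stop("geometry has nonpositive area")
  c(cx / totA, cy / totA)
}

geometry_area <- function(parts) {
  a <- 0
  for (part in parts)
    for (r in seq_along(part))
      a <- a + abs(ring_area(part[[r]])) * if (r == 1L) 1 else -1
  a
}

# ---- local metric projection ---------------------------------------------

#' Project geographic (lon, lat in degrees) to local metric coordinates
#'
#' Sinusoidal projection about a local origin: equal-area, with distances
#' accurate to well under 1\% at regional (sub-500 km) scales. Used because
#' the spatial correlation range is interpreted in metres.
#'
#' @param lonlat two-column matrix of longitude/latitude in decimal degrees
#' @param origin projection origin `c(lon0, lat0)` in degrees
#' @return two-column matrix of (x, y) in metres
#' @export
project_lonlat <- function(lonlat, origin) {
  lonlat <- rbind(lonlat)
  rad <- pi / 180
  x <- EARTH_RADIUS_M * rad * (lonlat[, 1] - origin[1]) * cos(lonlat[, 2] * rad)
  y <- EARTH_RADIUS_M * rad * (lonlat[, 2] - origin[2])
  cbind(x, y)
}

#' Great-circle (haversine) distance in metres
#' @param p1,p2 length-2 vectors `c(lon, lat)` in degrees
#' @export
haversine_distance <- function(p1, p2) {
  rad <- pi / 180
  dphi <- (p2[2] - p1[2]) * rad
  dlam <- (p2[1] - p1[1]) * rad
  a <- sin(dphi / 2)^2 + cos(p1[2] * rad) * cos(p2[2] * rad) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_M * asin(sqrt(pmin(1, a)))
}

is_geographic_crs <- function(crs) {
  !is.null(crs) && toupper(crs) %in%
    c("EPSG:4326", "WGS84", "CRS84", "OGC:CRS84", "GEOGRAPHIC", "LONLAT")
}

# ---- district map ---------------------------------------------------------

#' Construct a district map
#'
#' A `district_map` holds, for one region, district identifiers, names, the
#' polygon geometry in a projected planar coordinate system (metres), and
#' area-weighted centroids.
#'
#' @param district_id character vector of unique short keys
#' @param name free-text district names (defaults to the ids)
#' @param region single region label shared by all districts
#' @param geometry list (one element per district) of multi-part polygon
#'   geometry: each element a list of parts, each part a list of rings,
#'   each ring a closed (k x 2) coordinate matrix in metres
#' @return object of class `district_map` (a data.frame with a `geometry`
#'   attribute): columns `district_id`, `name`, `region`, `cx`, `cy`,
#'   `area_km2`
#' @export
district_map <- function(district_id, name = district_id, region, geometry) {
  district_id <- as.character(district_id)
  if (anyDuplicated(district_id))
    stop("duplicate district_id values: ",
         paste(unique(district_id[duplicated(district_id)]), collapse = ", "))
  if (length(unique(region)) != 1L)
    stop("all districts in a district_map must share one region label")
  stopifnot(length(geometry) == length(district_id))
  cent <- t(vapply(geometry, geometry_centroid, numeric(2)))
  area <- vapply(geometry, geometry_area, numeric(1)) / 1e6
  out <- data.frame(district_id = district_id, name = as.character(name),
                    region = rep(region[1], length(district_id)),
                    cx = cent[, 1], cy = cent[, 2], area_km2 = area,
                    stringsAsFactors = FALSE)
  attr(out, "geometry") <- geometry
  class(out) <- c("district_map", "data.frame")
  out
}

#' @export
print.district_map <- function(x, ...) {
  cat(sprintf("district_map: %d districts, region '%s'\n", nrow(x), x$region[1]))
  print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Load district polygons from GeoJSON, split by region
#'
#' Reads a GeoJSON FeatureCollection of district polygons, repairs cheap
#' geometry defects (duplicate vertices, unclosed rings), rejects districts
#' whose outer ring still self-intersects or has zero area, reprojects
#' geographic coordinates to a local metric (sinusoidal) projection per
#' region, and returns one [district_map] per region value.
#'
#' Only GeoJSON input is supported: no shapefile reader is bundled, and
#' GeoJSON round-trips losslessly as text.
#'
#' @param path GeoJSON file
#' @param region_field property naming the region of each feature
#' @param id_field,name_field property names for id and display name
#' @param crs declared CRS when the file has no `crs` member. GeoJSON is
#'   geographic (WGS84) by specification; pass `"projected"` (or any
#'   non-geographic label) if coordinates are already planar metres.
#' @param regions optional expected region labels; an unknown region value
#'   triggers an error listing the values found
#' @return named list of [district_map], one per region, with a
#'   `rejected` attribute (data.frame of rejected features and reasons)
#' @export
load_district_map <- function(path, region_field = "region",
                              id_field = "district_id", name_field = "name",
                              crs = NULL, regions = NULL) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  file_crs <- tryCatch(gj$crs$properties$name, error = function(e) NULL)
  eff_crs <- if (!is.null(file_crs)) file_crs else crs
  if (is.null(eff_crs))
    stop("no coordinate reference system declared for '", path,
         "': pass crs= (GeoJSON defaults to EPSG:4326)")

  feats <- gj$features
  getprop <- function(f, k) {
    v <- f$properties[[k]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  ids <- vapply(feats, getprop, "", k = id_field)
  nms <- vapply(feats, getprop, "", k = name_field)
  nms[is.na(nms)] <- ids[is.na(nms)]
  regs <- vapply(feats, getprop, "", k = region_field)
  if (anyNA(regs) || (!is.null(regions) && !all(regs %in% regions)))
    stop("unknown region value(s) in '", region_field, "'; values found: ",
         paste(unique(regs), collapse = ", "))

  to_ring <- function(coords)
    repair_ring(do.call(rbind, lapply(coords, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]])))))
  parse_geom <- function(g) {
    if (g$type == "Polygon") list(lapply(g$coordinates, to_ring))
    else if (g$type == "MultiPolygon")
      lapply(g$coordinates, function(poly) lapply(poly, to_ring))
    else stop("unsupported geometry type: ", g$type)
  }
  geoms <- lapply(feats, function(f) parse_geom(f$geometry))

  rejected <- data.frame(district_id = character(), reason = character())
  ok <- rep(TRUE, length(geoms))
  for (i in seq_along(geoms)) {
    reason <- NULL
    for (part in geoms[[i]]) {
      outer <- part[[1]]
      if (nrow(outer) < 4L) reason <- "degenerate ring (<3 vertices)"
      else if (ring_self_intersects(outer)) reason <- "self-intersecting ring"
      else if (abs(ring_area(outer)) == 0) reason <- "zero-area ring"
      if (!is.null(reason)) break
    }
    if (!is.null(reason)) {
      ok[i] <- FALSE
      rejected <- rbind(rejected,
                        data.frame(district_id = ids[i], reason = reason))
    }
  }

  out <- list()
  for (rg in unique(regs)) {
    sel <- which(regs == rg & ok)
    if (!length(sel)) next
    g <- geoms[sel]
    if (is_geographic_crs(eff_crs)) {
      allxy <- do.call(rbind, lapply(g, function(parts)
        do.call(rbind, lapply(parts, function(p) do.call(rbind, p)))))
      origin <- colMeans(allxy)
      g <- lapply(g, function(parts) lapply(parts, function(p)
        lapply(p, project_lonlat, origin = origin)))
    }
    out[[rg]] <- district_map(ids[sel], nms[sel], rg, g)
  }
  attr(out, "rejected") <- rejected
  out
}

#' Pairwise centroid distance matrix
#'
#' Euclidean distances between district centroids, in metres, with district
#' ids as dimnames. This matrix drives the exponential spatial correlation.
#'
#' @param map a [district_map]
#' @return symmetric matrix with zero diagonal
#' @export
centroid_distances <- function(map) {
  stopifnot(inherits(map, "district_map"), nrow(map) >= 1)
  d <- as.matrix(dist(cbind(map$cx, map$cy)))
  dimnames(d) <- list(map$district_id, map$district_id)
  d
}

# ---- town -> district assignment -----------------------------------------

#' Normalise a free-text town name
#'
#' Trim, case-fold and collapse internal whitespace, so registry spellings
#' like `"  Kota  BHARU "` and `"kota bharu"` coincide.
#' @param x character vector
#' @export
normalise_town <- function(x) {
  gsub("\\s+", " ", trimws(tolower(as.character(x))))
}

#' Build a town -> district lookup
#'
#' @param town character vector of town names (normalised internally)
#' @param district_id character vector of district ids, recycled against town
#' @param map optional [district_map] (or character id vector) used to check
#'   that every mapped district exists
#' @return named character vector of class `town_lookup`
#' @export
town_lookup <- function(town, district_id, map = NULL) {
  if (!length(town)) stop("empty town lookup")
  key <- normalise_town(town)
  if (anyDuplicated(key))
    stop("duplicate town keys after normalisation: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  val <- as.character(district_id)
  if (!is.null(map)) {
    known <- if (inherits(map, "district_map")) map$district_id else as.character(map)
    bad <- setdiff(val, known)
    if (length(bad)) stop("lookup maps to unknown district(s): ",
                          paste(bad, collapse = ", "))
  }
  structure(setNames(val, key), class = "town_lookup")
}

#' Assign towns to districts
#'
#' Unmapped towns yield the sentinel `"unassigned"`; this is a data
#' condition, not an error, and the count is reported via the
#' `n_unassigned` attribute.
#'
#' @param town character vector of raw town names
#' @param lookup a [town_lookup]
#' @return character vector of district ids with attribute `n_unassigned`
#' @export
assign_district <- function(town, lookup) {
  if (!length(lookup)) stop("lookup non-empty required")
  key <- normalise_town(town)
  out <- unname(lookup[key])
  out[is.na(out)] <- "unassigned"
  attr(out, "n_unassigned") <- sum(out == "unassigned")
  out
}

# ---- summaries and exports ------------------------------------------------

#' District summary table
#'
#' @param map a [district_map]
#' @param patient_districts optional character vector of per-patient district
#'   ids, tabulated into a `n_patients` column
#' @return data.frame (id, region, centroid x/y, patient count)
#' @export
district_summary <- function(map, patient_districts = NULL) {
  out <- data.frame(district_id = map$district_id, region = map$region,
                    centroid_x = map$cx, centroid_y = map$cy)
  if (!is.null(patient_districts)) {
    tab <- table(factor(patient_districts, levels = map$district_id))
    out$n_patients <- as.integer(tab)
  }
  out
}

#' Write a district summary as tab-delimited text
#' @param map a [district_map]
#' @param path output file
#' @param patient_districts see [district_summary]
#' @export
write_district_summary <- function(map, path, patient_districts = NULL) {
  write.table(district_summary(map, patient_districts), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a district map (plus optional per-district properties) as GeoJSON
#'
#' @param map a [district_map]
#' @param path output file
#' @param properties optional data.frame keyed by `district_id` whose extra
#'   columns are attached as feature properties
#' @export
write_district_geojson <- function(map, path, properties = NULL) {
  geom <- attr(map, "geometry")
  feats <- lapply(seq_len(nrow(map)), function(i) {
    props <- list(district_id = map$district_id[i], name = map$name[i],
                  region = map$region[i])
    if (!is.null(properties)) {
      row <- properties[match(map$district_id[i], properties$district_id), ,
                        drop = FALSE]
      for (cl in setdiff(names(properties), "district_id"))
        props[[cl]] <- row[[cl]]
    }
    coords <- lapply(geom[[i]], function(part)
      lapply(part, function(ring)
        lapply(seq_len(nrow(ring)), function(k) c(ring[k, 1], ring[k, 2]))))
    list(type = "Feature", properties = props,
         geometry = list(type = "MultiPolygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name",
                        properties = list(name = "local-metric")),
             features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Rectangular grid district map
#'
#' Builds an `nx` by `ny` grid of square districts of side `cell` metres —
#' the default synthetic geography (real administrative boundaries are an
#' input, not a dependency).
#'
#' @param nx,ny grid dimensions
#' @param cell cell side length in metres
#' @param region region label
#' @param origin lower-left corner `c(x, y)` in metres
#' @param id_prefix prefix for district ids
#' @param n_keep optionally keep only the first `n_keep` cells (row-major),
#'   for non-rectangular district counts
#' @return a [district_map]
#' @export
make_grid_map <- function(nx, ny, cell = 1000, region = "west",
                          origin = c(0, 0), id_prefix = "D",
                          n_keep = nx * ny) {
  stopifnot(n_keep >= 1, n_keep <= nx * ny)
  ids <- character(n_keep); geoms <- vector("list", n_keep)
  k <- 0L
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      k <- k + 1L
      if (k > n_keep) break
      x0 <- origin[1] + (ix - 1) * cell; y0 <- origin[2] + (iy - 1) * cell
      ring <- rbind(c(x0, y0), c(x0 + cell, y0), c(x0 + cell, y0 + cell),
                    c(x0, y0 + cell), c(x0, y0))
      ids[k] <- sprintf("%s%03d", id_prefix, k)
      geoms[[k]] <- list(list(ring))
    }
  }
  district_map(ids, region = region, geometry = geoms)
}
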