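# Range metrics, endemism classes, richness accounting, syntopy and the
# endemism-by-distinctness conservation ranks.

EARTH_RADIUS_KM <- 6371.0

#' Great-circle (haversine) distance in km
#'
#' @param lat1,lon1,lat2,lon2 WGS84 decimal degrees (vectorised).
#' @param radius Earth radius in km (default 6371.0).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2,
                         radius = EARTH_RADIUS_KM) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * radius * asin(pmin(1, sqrt(a)))
}

#' Maximum range diameter (greatest pairwise great-circle distance)
#'
#' @param lat,lon Coordinate vectors (>= 1 point).
#' @return Kilometres; 0 for a single point.
#' @export
max_diameter <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1L)
  pts <- unique(data.frame(lat = lat, lon = lon))
  n <- nrow(pts)
  if (n < 2L) return(0)
  best <- 0
  for (i in seq_len(n - 1L)) {
    d <- haversine_km(pts$lat[i], pts$lon[i],
                      pts$lat[(i + 1L):n], pts$lon[(i + 1L):n])
    best <- max(best, d)
  }
  best
}

# Lambert azimuthal equal-area projection about (lat0, lon0), km units
laea_project <- function(lat, lon, lat0, lon0, radius = EARTH_RADIUS_KM) {
  to_rad <- pi / 180
  phi <- lat * to_rad; lam <- lon * to_rad
  phi0 <- lat0 * to_rad; lam0 <- lon0 * to_rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  k <- sqrt(2 / pmax(1e-15, 1 + cosc))
  data.frame(
    x = radius * k * cos(phi) * sin(lam - lam0),
    y = radius * k * (cos(phi0) * sin(phi) -
                        sin(phi0) * cos(phi) * cos(lam - lam0)))
}

#' Minimum convex polygon range area
#'
#' Points are projected with a Lambert azimuthal equal-area projection
#' centred on their centroid; the convex hull area (shoelace formula) is
#' returned in km². Fewer than 3 non-collinear points give 0.
#'
#' @param lat,lon Coordinate vectors (>= 1 point).
#' @return Area in km².
#' @export
mcp_area <- function(lat, lon) {
  stopifnot(length(lat) == length(lon), length(lat) >= 1L)
  pts <- unique(data.frame(lat = lat, lon = lon))
  if (nrow(pts) < 3L) return(0)
  xy <- laea_project(pts$lat, pts$lon, mean(pts$lat), mean(pts$lon))
  h <- chull(xy$x, xy$y)
  if (length(h) < 3L) return(0)
  x <- xy$x[h]; y <- xy$y[h]
  0.5 * abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y))
}

#' Per-species range summary from occurrence records
#'
#' @param occurrences Occurrence data frame (see [as_occurrences()]).
#' @return Data frame (species, n_sites, area_km2, max_diameter_km).
#' @export
range_summary <- function(occurrences) {
  sp <- sort(unique(occurrences$species))
  out <- lapply(sp, function(s) {
    rec <- occurrences[occurrences$species == s, , drop = FALSE]
    sites <- !duplicated(rec$site_id)
    data.frame(species = s, n_sites = sum(sites),
               area_km2 = mcp_area(rec$lat[sites], rec$lon[sites]),
               max_diameter_km = max_diameter(rec$lat[sites],
                                              rec$lon[sites]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Endemism class of a range summary
#'
#' Single-site and two-site species are classed by site count; species
#' with more sites fall into IUCN-style area bins with left-inclusive
#' edges (area 500 km² is "500-5000 km2"; below 5000 km² a species
#' qualifies as range-restricted under Red List criterion B thinking).
#'
#' @param n_sites Distinct site count (may be NA when only the area is
#'   known for a multi-site species).
#' @param area_km2 MCP area.
#' @return One of "single-site", "two-site", "<500 km2", "500-5000 km2",
#'   ">5000 km2" (vectorised).
#' @export
endemism_class <- function(n_sites, area_km2) {
  mapply(function(n, a) {
    if (!is.na(n) && n == 1L) return("single-site")
    if (!is.na(n) && n == 2L) return("two-site")
    if (a < 500) "<500 km2" else if (a < 5000) "500-5000 km2"
    else ">5000 km2"
  }, n_sites, area_km2, USE.NAMES = FALSE)
}

#' Conservation rank from endemism and evolutionary distinctness
#'
#' Quadrant rule: (1) high endemism and high ED; (2a) low endemism, high
#' ED; (2b) high endemism, low ED; (3) low endemism and ED. Endemism is
#' high when a species is known from at most `sites_high` sites or its
#' range is below `area_high` km². ED above `ed_high` is high, below
#' `ed_low` low; intermediate values are resolved by the binary split at
#' `ed_mid`.
#'
#' @param ed ED value(s).
#' @param n_sites,area_km2 Range summary values (vectorised).
#' @param thresholds Named list overriding `ed_high` (0.075), `ed_low`
#'   (0.045), `ed_mid` (0.060), `area_high` (500), `sites_high` (2).
#' @return Character rank(s): "1", "2a", "2b" or "3".
#' @export
conservation_rank <- function(ed, n_sites, area_km2, thresholds = list()) {
  th <- modifyList(list(ed_high = 0.075, ed_low = 0.045, ed_mid = 0.060,
                        area_high = 500, sites_high = 2), thresholds)
  mapply(function(e, n, a) {
    if (is.na(e)) stop("missing ED value")
    endem_high <- (!is.na(n) && n <= th$sites_high) || a < th$area_high
    ed_high <- if (e > th$ed_high) TRUE else if (e < th$ed_low) FALSE
    else e >= th$ed_mid
    if (endem_high && ed_high) "1"
    else if (!endem_high && ed_high) "2a"
    else if (endem_high && !ed_high) "2b"
    else "3"
  }, ed, n_sites, area_km2, USE.NAMES = FALSE)
}

#' Assemble a conservation table (published Table-1 analogue)
#'
#' @param ranges Data frame from [range_summary()] (or equivalent with
#'   species, n_sites, area_km2, max_diameter_km).
#' @param ed Named ED vector or data frame (tip/species, ED) aligned to
#'   species names.
#' @param thresholds Rank thresholds, see [conservation_rank()].
#' @return Data frame with endemism class and rank per species.
#' @export
conservation_table <- function(ranges, ed, thresholds = list()) {
  if (is.data.frame(ed)) {
    ed <- setNames(ed[[2L]], ed[[1L]])
  }
  e <- ed[ranges$species]
  if (anyNA(e)) stop("missing ED for: ",
                     ranges$species[which(is.na(e))[1L]])
  data.frame(ranges,
             ED = unname(e),
             endemism_class = endemism_class(ranges$n_sites,
                                             ranges$area_km2),
             rank = conservation_rank(unname(e), ranges$n_sites,
                                      ranges$area_km2, thresholds),
             stringsAsFactors = FALSE)
}

#' Detect syntopic sites (two or more species co-occurring)
#'
#' @param occurrences Occurrence data frame.
#' @param partition Optional `stygo_partition`; when supplied, specimens
#'   are relabelled by their block before screening.
#' @return Data frame (site_id, species_a, species_b), one row per
#'   species pair per site; zero rows when all species are allopatric.
#' @export
detect_syntopy <- function(occurrences, partition = NULL) {
  sp <- occurrences$species
  if (!is.null(partition)) {
    lab <- partition_labels(partition)
    missing <- setdiff(occurrences$specimen_id, names(lab))
    if (length(missing)) stop("specimen '", missing[1L],
                              "' not in partition")
    sp <- unname(lab[occurrences$specimen_id])
  }
  tab <- unique(data.frame(site_id = occurrences$site_id, species = sp,
                           stringsAsFactors = FALSE))
  out <- list()
  for (site in sort(unique(tab$site_id))) {
    spp <- sort(tab$species[tab$site_id == site])
    if (length(spp) < 2L) next
    prs <- combn(spp, 2L)
    out[[length(out) + 1L]] <- data.frame(
      site_id = site, species_a = prs[1L, ], species_b = prs[2L, ],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(site_id = character(), species_a = character(),
                      species_b = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Species richness accounting under nominal vs revised taxonomy
#'
#' Computes alpha diversity per site and species counts per country and
#' drainage basin under both the nominal (pre-revision) and the revised
#' taxonomy, with after/before ratios and the list of sites whose alpha
#' increased (exactly the syntopic sites).
#'
#' @param occurrences Occurrence data frame whose `species` column holds
#'   revised species labels.
#' @param taxonomy_map Data frame (nominal, revised) mapping every revised
#'   species back to its nominal name.
#' @return List of class `stygo_richness` with elements `site`, `country`,
#'   `basin` (data frames) and `increased_sites`.
#' @export
richness_accounting <- function(occurrences, taxonomy_map) {
  nominal <- setNames(taxonomy_map$nominal, taxonomy_map$revised)
  unmapped <- setdiff(occurrences$species, names(nominal))
  if (length(unmapped)) stop("unmapped species label: ", unmapped[1L])
  occ <- occurrences
  occ$nominal <- unname(nominal[occ$species])

  per_level <- function(key) {
    lv <- sort(unique(occ[[key]]))
    before <- vapply(lv, function(k)
      length(unique(occ$nominal[occ[[key]] == k])), integer(1))
    after <- vapply(lv, function(k)
      length(unique(occ$species[occ[[key]] == k])), integer(1))
    df <- data.frame(lv, n_nominal = before, n_revised = after,
                     ratio = after / before, stringsAsFactors = FALSE,
                     row.names = NULL)
    names(df)[1L] <- key
    df
  }
  site <- per_level("site_id")
  names(site) <- c("site_id", "alpha_nominal", "alpha_revised", "ratio")
  structure(list(
    site = site,
    country = per_level("country"),
    basin = per_level("basin"),
    increased_sites = site$site_id[site$alpha_revised >
                                     site$alpha_nominal]),
    class = "stygo_richness")
}

#' @export
print.stygo_richness <- function(x, ...) {
  cat("Richness accounting: ", nrow(x$site), " sites, ",
      length(x$increased_sites), " with increased alpha\n", sep = "")
  print(x$country)
  invisible(x)
}
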