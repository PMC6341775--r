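## Spherical range centroids, great-circle distances and the clinal
## log distance-ratio statistic linking floral extremity to geography.

deg2rad <- function(x) x * pi / 180

#' Spherical centroid of specimen coordinates
#'
#' Coordinates (degrees) are converted to radians (phi = latitude, theta =
#' longitude) and to unit Cartesian vectors `x = cos(theta) cos(phi)`,
#' `y = cos(phi) sin(theta)`, `z = sin(phi)`; the arithmetic mean vector is
#' back-projected with `latitude = asin(z / |v|)` and the full-quadrant
#' arctangent `longitude = atan2(y, x)` (the two-argument form is required
#' for western-hemisphere longitudes, where a plain `atan(y/x)` is
#' ambiguous). An antipodally balanced set (mean vector near zero) has no
#' defined centroid and is an error.
#'
#' @param lat_deg,lon_deg numeric vectors of coordinates in decimal degrees
#'   (west negative); alternatively `lat_deg` may be a [geo_table()].
#' @return list of class `centroid_result`: `lat_deg`, `lon_deg`, `n`,
#'   `mean_vector_norm`.
#' @export
range_centroid <- function(lat_deg, lon_deg = NULL) {
  if (inherits(lat_deg, "geo_table") || is.data.frame(lat_deg)) {
    lon_deg <- lat_deg$lon_deg
    lat_deg <- lat_deg$lat_deg
  }
  stopifnot(length(lat_deg) >= 1, length(lat_deg) == length(lon_deg))
  phi <- deg2rad(lat_deg); theta <- deg2rad(lon_deg)
  v <- c(x = mean(cos(theta) * cos(phi)),
         y = mean(cos(phi) * sin(theta)),
         z = mean(sin(phi)))
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-9)
    stop("degenerate centroid: antipodally balanced coordinates")
  structure(list(lat_deg = asin(v["z"] / nrm) * 180 / pi,
                 lon_deg = atan2(v["y"], v["x"]) * 180 / pi,
                 n = length(lat_deg), mean_vector_norm = nrm),
            class = "centroid_result")
}

#' @export
print.centroid_result <- function(x, ...) {
  cat(sprintf("<centroid> (%.4f, %.4f) from %d points (|v| = %.3f)\n",
              x$lat_deg, x$lon_deg, x$n, x$mean_vector_norm))
  invisible(x)
}

as_latlon <- function(p) {
  if (inherits(p, "centroid_result")) c(p$lat_deg, p$lon_deg)
  else as.numeric(p)
}

#' Great-circle (haversine) distance in km
#'
#' Haversine distance on a sphere of radius `radius_km` (default 6371 km,
#' the conventional mean Earth radius).
#'
#' @param a,b points as `c(lat_deg, lon_deg)` or `centroid_result` objects.
#' @param radius_km sphere radius in km.
#' @return distance in km.
#' @export
haversine_km <- function(a, b, radius_km = 6371) {
  a <- as_latlon(a); b <- as_latlon(b)
  geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                           r = radius_km * 1000) / 1000
}

#' Log ratio of distances to conspecific and heterospecific range centroids
#'
#' `log(d_con / d_het)`: positive values indicate a specimen closer to the
#' centroid of the alternative species than to its own species' centroid.
#'
#' @param point specimen coordinates `c(lat_deg, lon_deg)`.
#' @param con_centroid,het_centroid centroids of the specimen's own and the
#'   alternative species.
#' @param radius_km sphere radius in km.
#' @return the log distance ratio (finite; coincidence with a centroid is
#'   an error).
#' @export
log_distance_ratio <- function(point, con_centroid, het_centroid,
                               radius_km = 6371) {
  d_con <- haversine_km(point, con_centroid, radius_km)
  d_het <- haversine_km(point, het_centroid, radius_km)
  if (d_con == 0 || d_het == 0)
    stop("specimen coincides with a range centroid")
  log(d_con / d_het)
}

#' Build per-specimen cline records from scores and coordinates
#'
#' Joins discriminant scores to specimen coordinates, computes each
#' species' range centroid from its own specimens, and derives per-specimen
#' distances and the log conspecific/heterospecific distance ratio. The
#' stored `ld_score` is centred at the midpoint of the two species' mean
#' scores, so that zero marks the between-species boundary and the absolute
#' value measures floral extremity (a raw `weights . x` projection carries
#' an arbitrary offset).
#'
#' @param scores data.frame with `id` and `score` (discriminant axis
#'   values, e.g. from [predict_lda()]).
#' @param geo a [geo_table()] with known species labels.
#' @param radius_km sphere radius in km.
#' @return data.frame of class `cline_records`: `id`, `species`,
#'   `ld_score`, `d_con`, `d_het`, `log_ratio`.
#' @export
cline_records <- function(scores, geo, radius_km = 6371) {
  geo <- as.data.frame(geo)
  geo <- geo[geo$species != UNKNOWN_LABEL, , drop = FALSE]
  sp <- unique(geo$species)
  stopifnot(length(sp) == 2)
  cents <- lapply(sp, function(s)
    range_centroid(geo[geo$species == s, , drop = FALSE]))
  names(cents) <- sp
  m <- match(geo$id, scores$id)
  keep <- !is.na(m)
  geo <- geo[keep, , drop = FALSE]; m <- m[keep]
  centre <- mean(tapply(scores$score[m], geo$species, mean))
  scores$score <- scores$score - centre
  rows <- lapply(seq_len(nrow(geo)), function(i) {
    own <- geo$species[i]; other <- setdiff(sp, own)
    p <- c(geo$lat_deg[i], geo$lon_deg[i])
    d_con <- haversine_km(p, cents[[own]], radius_km)
    d_het <- haversine_km(p, cents[[other]], radius_km)
    data.frame(id = geo$id[i], species = own, ld_score = scores$score[m[i]],
               d_con = d_con, d_het = d_het,
               log_ratio = log(d_con / d_het), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cline_records", "data.frame")
  out
}

#' Association between floral extremity and proximity to the other species
#'
#' Correlates the absolute discriminant score (floral extremity) with the
#' log conspecific/heterospecific distance ratio, per species and pooled. A
#' negative correlation means specimens nearer the alternative species'
#' range centre are less well discriminated -- the signature of clinal
#' introgression.
#'
#' @param records a `cline_records` data.frame (see [cline_records()]).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: `group` (species or `"pooled"`), `n`, `r`,
#'   `p_value`, `slope` (least-squares slope of `|ld_score|` on
#'   `log_ratio`; NA for Spearman).
#' @export
clinal_association <- function(records, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  one <- function(df, label) {
    if (nrow(df) < 3) stop("need at least 3 records per group")
    x <- df$log_ratio; y <- abs(df$ld_score)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(data.frame(group = label, n = nrow(df), r = NA_real_,
                        p_value = NA_real_, slope = NA_real_))
    ct <- stats::cor.test(x, y, method = method, exact = FALSE)
    slope <- if (method == "pearson")
      unname(stats::coef(stats::lm(y ~ x))[2]) else NA_real_
    data.frame(group = label, n = nrow(df), r = unname(ct$estimate),
               p_value = ct$p.value, slope = slope)
  }
  sp <- unique(records$species)
  out <- do.call(rbind, lapply(sp, function(s)
    one(records[records$species == s, , drop = FALSE], s)))
  rbind(out, one(records, "pooled"))
}
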