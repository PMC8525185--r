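`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws
#' @param alpha concentration vector
#' @return an `n x length(alpha)` matrix of probability vectors
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  # guard against all-zero rows at tiny concentrations
  z <- rowSums(x)
  bad <- z <= 0
  if (any(bad)) {
    x[bad, ] <- 0
    x[cbind(which(bad), sample.int(k, sum(bad), replace = TRUE))] <- 1
    z[bad] <- 1
  }
  x / z
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && abs(x - round(x)) < 1e-8
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param lat1,lon1 coordinates of the first point(s), decimal degrees
#' @param lat2,lon2 coordinates of the second point(s), decimal degrees
#' @return distance(s) in km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  as.numeric(geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                                      r = 6371))
}

#' Normalize longitudes to (-180, 180]
#' @param lon longitudes in degrees
#' @return normalized longitudes
#' @keywords internal
normalize_longitude <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}
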