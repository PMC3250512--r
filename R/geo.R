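#' Longitude encoding schemes
#'
#' Treating latitude and longitude as Cartesian constraint variables makes
#' tree splits sensitive to where the longitude axis is cut. Three encodings
#' of the same circle are supported:
#' \describe{
#'   \item{`greenwich_pm180`}{-180 to +180 degrees, cut at the antimeridian
#'     (the conventional representation).}
#'   \item{`east_of_60W`}{0 to 360 degrees eastwards from 60 W, cut through
#'     the Atlantic at -60.}
#'   \item{`east_of_greenwich`}{0 to 360 degrees eastwards from Greenwich,
#'     cut at 0.}
#' }
#'
#' @return character vector of scheme names.
#' @export
encoding_schemes <- function() {
  c("greenwich_pm180", "east_of_60W", "east_of_greenwich")
}

scheme_origin <- function(scheme) {
  switch(scheme,
         greenwich_pm180 = -180,
         east_of_60W = -60,
         east_of_greenwich = 0,
         stop("unknown encoding scheme: ", scheme))
}

#' Encode a longitude under a named scheme
#'
#' A bijection on the circle: `greenwich_pm180` is the identity on
#' \[-180, 180); the other schemes return degrees east of their origin in
#' \[0, 360).
#'
#' @param longitude_deg numeric longitude(s) in \[-180, 180).
#' @param scheme one of [encoding_schemes()].
#' @return encoded value(s) in degrees.
#' @seealso [decode_longitude()] for the inverse map.
#' @export
encode_longitude <- function(longitude_deg, scheme = "greenwich_pm180") {
  if (any(longitude_deg < -180 | longitude_deg >= 180))
    stop("longitude out of [-180, 180)")
  origin <- scheme_origin(scheme)
  if (scheme == "greenwich_pm180") return(longitude_deg)
  (longitude_deg - origin) %% 360
}

#' @rdname encode_longitude
#' @param encoded encoded value(s) as returned by [encode_longitude()].
#' @export
decode_longitude <- function(encoded, scheme = "greenwich_pm180") {
  origin <- scheme_origin(scheme)
  if (scheme == "greenwich_pm180") return(encoded)
  ((encoded + origin) + 180) %% 360 - 180
}

#' Build the geographic constraint table for a site set
#'
#' Returns the two-column numeric table (latitude, encoded longitude) used as
#' explanatory variables by [grow_mrt()]. Latitude is never re-encoded.
#'
#' @param sites site-record data frame with `site_id`, `latitude_deg`,
#'   `longitude_deg`.
#' @param scheme longitude encoding, one of [encoding_schemes()].
#' @param site_order optional character vector giving the row order (e.g. the
#'   site order of the community matrix); defaults to the order of `sites`.
#' @return numeric matrix with columns `latitude` and `longitude`, rownames =
#'   site ids.
#' @export
build_constraints <- function(sites, scheme = "greenwich_pm180",
                              site_order = NULL) {
  if (nrow(sites) == 0)
    return(matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("latitude", "longitude"))))
  sites <- validate_site_records(sites)
  if (is.null(site_order)) site_order <- sites$site_id
  idx <- match(site_order, sites$site_id)
  if (anyNA(idx))
    stop("missing coordinates for site(s): ",
         paste(site_order[is.na(idx)], collapse = ", "))
  out <- cbind(latitude = sites$latitude_deg[idx],
               longitude = encode_longitude(sites$longitude_deg[idx], scheme))
  rownames(out) <- site_order
  out
}
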