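#' Simulate a province-structured metacommunity
#'
#' Bernoulli occupancy model standing in for a global species occurrence
#' matrix with biogeographic structure. Each province has its own endemic
#' species pool; a site carries each endemic of its own province with
#' probability `endemicity * detection_prob`, each endemic of another
#' province with probability `(1 - endemicity) * detection_prob`, and each
#' cosmopolitan species with probability `detection_prob`. Province centroids
#' are placed at distinct coordinates (longitudinally separable by default)
#' and sites are jittered around them.
#'
#' @param K number of provinces.
#' @param sites_per_province sites per province.
#' @param endemics_per_province endemic species per province.
#' @param cosmopolitan_species species present everywhere at the detection
#'   rate.
#' @param endemicity in \[0, 1\]; 1 = endemics never leave their province.
#' @param detection_prob in (0, 1\]; per-species sampling effort.
#' @param coordinate_spread_deg uniform jitter half-width around the province
#'   centroid, degrees.
#' @param centroid_longitudes optional length-`K` vector of province centroid
#'   longitudes in \[-180, 180) (e.g. to straddle the antimeridian); default
#'   spreads provinces evenly between -120 and 120.
#' @param centroid_latitudes optional length-`K` vector of centroid latitudes;
#'   default alternates around the equator.
#' @param seed integer seed; identical parameters and seed give identical
#'   output.
#' @return an object of class `synthetic_metacommunity`: `matrix` (binary
#'   [community_matrix()]), `sites` (site records), `true_labels` (named
#'   province index per site), `params`, `seed`.
#' @export
generate_metacommunity <- function(K = 3, sites_per_province = 10,
                                   endemics_per_province = 15,
                                   cosmopolitan_species = 5,
                                   endemicity = 0.9, detection_prob = 0.9,
                                   coordinate_spread_deg = 2,
                                   centroid_longitudes = NULL,
                                   centroid_latitudes = NULL,
                                   seed = 1) {
  if (K < 1) stop("K must be >= 1")
  if (endemicity < 0 || endemicity > 1) stop("endemicity must be in [0, 1]")
  if (detection_prob <= 0 || detection_prob > 1)
    stop("detection_prob must be in (0, 1]")
  n <- K * sites_per_province
  if (n < 2) stop("need at least 2 sites in total")
  if (is.null(centroid_longitudes))
    centroid_longitudes <- if (K == 1) 0 else seq(-120, 120, length.out = K)
  if (is.null(centroid_latitudes))
    centroid_latitudes <- rep_len(c(-20, 20, 0, -40, 40), K)
  stopifnot(length(centroid_longitudes) == K, length(centroid_latitudes) == K)

  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  set.seed(seed)

  province <- rep(seq_len(K), each = sites_per_province)
  site_ids <- sprintf("P%02d_S%02d", province,
                      sequence(rep(sites_per_province, K)))
  n_spec <- K * endemics_per_province + cosmopolitan_species
  species_ids <- c(sprintf("end_P%02d_%02d", rep(seq_len(K),
                                                 each = endemics_per_province),
                           sequence(rep(endemics_per_province, K))),
                   if (cosmopolitan_species > 0)
                     sprintf("cosmo_%02d", seq_len(cosmopolitan_species)))
  # per-cell presence probability
  prob <- matrix(detection_prob, n, n_spec)
  for (k in seq_len(K)) {
    cols <- (k - 1) * endemics_per_province + seq_len(endemics_per_province)
    prob[, cols] <- (1 - endemicity) * detection_prob
    prob[province == k, cols] <- endemicity * detection_prob
  }
  occ <- matrix(rbinom(n * n_spec, 1, as.vector(prob)), n, n_spec,
                dimnames = list(site_ids, species_ids))

  lon <- centroid_longitudes[province] +
    runif(n, -coordinate_spread_deg, coordinate_spread_deg)
  lon <- (lon + 180) %% 360 - 180          # wrap around the antimeridian
  lat <- centroid_latitudes[province] +
    runif(n, -coordinate_spread_deg, coordinate_spread_deg)
  lat <- pmax(pmin(lat, 90), -90)
  sites <- data.frame(site_id = site_ids, latitude_deg = lat,
                      longitude_deg = lon,
                      region_label = sprintf("province_%02d", province),
                      stringsAsFactors = FALSE)
  true_labels <- stats::setNames(province, site_ids)
  structure(list(
    matrix = suppressWarnings(community_matrix(occ, binary = TRUE)),
    sites = validate_site_records(sites),
    true_labels = true_labels,
    params = list(K = K, sites_per_province = sites_per_province,
                  endemics_per_province = endemics_per_province,
                  cosmopolitan_species = cosmopolitan_species,
                  endemicity = endemicity, detection_prob = detection_prob,
                  coordinate_spread_deg = coordinate_spread_deg,
                  centroid_longitudes = centroid_longitudes,
                  centroid_latitudes = centroid_latitudes),
    seed = seed), class = "synthetic_metacommunity")
}

#' @export
print.synthetic_metacommunity <- function(x, ...) {
  cat(sprintf("synthetic metacommunity: %d provinces, %d sites, %d species (seed %d)\n",
              x$params$K, nrow(x$matrix$occurrences),
              ncol(x$matrix$occurrences), x$seed))
  invisible(x)
}

# TN93 instantaneous rate matrix, scaled to one expected substitution per
# site per unit time.
tn93_rate_matrix <- function(freq, alpha1 = 2, alpha2 = 2, beta = 1) {
  bases <- c("A", "C", "G", "T")
  stopifnot(abs(sum(freq) - 1) < 1e-9, all(freq > 0))
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  rate <- function(i, j) {
    tr_pur <- (i %in% c("A", "G")) && (j %in% c("A", "G"))
    tr_pyr <- (i %in% c("C", "T")) && (j %in% c("C", "T"))
    r <- if (tr_pur) alpha1 else if (tr_pyr) alpha2 else beta
    r * freq[[j]]
  }
  for (i in bases) for (j in bases) if (i != j) Q[i, j] <- rate(i, j)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freq * diag(Q))
  Q / mu
}

#' Simulate a two-sequence alignment at a target TN93 distance
#'
#' Draws an ancestor from the stationary base frequencies and evolves a copy
#' under the TN93 substitution process for an expected `target_distance`
#' substitutions per site, so [tamura_nei()] applied to the pair estimates
#' `target_distance`.
#'
#' @param length alignment length (>= 100).
#' @param target_distance expected substitutions per site (>= 0).
#' @param freq stationary base frequencies (named `A`, `C`, `G`, `T`).
#' @param alpha1,alpha2,beta relative purine-transition,
#'   pyrimidine-transition and transversion rates.
#' @param ids sequence labels.
#' @param seed integer seed.
#' @return an `aligned_set` character matrix of two rows.
#' @export
generate_pair_alignment <- function(length = 1000, target_distance = 0.05,
                                    freq = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                                    alpha1 = 2, alpha2 = 2, beta = 1,
                                    ids = c("anc", "der"), seed = 1) {
  if (length < 100) stop("length must be >= 100")
  if (target_distance < 0) stop("target_distance must be >= 0")
  if (abs(sum(freq) - 1) > 1e-9 || any(freq <= 0))
    stop("invalid base frequencies")
  rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(rng_state))
    assign(".Random.seed", rng_state, envir = globalenv()), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, length, replace = TRUE, prob = freq)
  if (target_distance == 0) {
    der <- anc
  } else {
    Q <- tn93_rate_matrix(freq, alpha1, alpha2, beta)
    P <- as.matrix(Matrix::expm(Q * target_distance))
    P <- pmax(P, 0)
    der <- vapply(anc, function(b)
      sample(bases, 1, prob = P[b, ]), character(1))
  }
  m <- rbind(anc, der)
  rownames(m) <- ids
  aligned_set(m)
}
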