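#' East Scotia Ridge E2/E9 faunal fixture
#'
#' Presence/absence of the dominant fauna recorded at the two East Scotia
#' Ridge vent fields E2 and E9, one column per lowest-level taxon (taxa
#' identified only to a higher level, e.g. "Octopodidae" or "Zoarcid fish",
#' are kept as single columns; vent-periphery records count as presences).
#' Site coordinates are the midpoints of the published position ranges.
#'
#' @return a list with elements `matrix` (a 2-site [community_matrix()]) and
#'   `sites` (a site-record data frame with decimal-degree coordinates).
#' @export
esr_fixture <- function() {
  # taxon, at E2, at E9
  taxa <- list(
    c("Cladorhiza n. sp. 1",                     1, 1),
    c("Abyssocladia n. sp. 1",                   0, 1),
    c("Chondrophellia sp. or Hormathia spinosa", 0, 1),
    c("Actinostolidae n. sp. 1",                 0, 1),
    c("Actinostolidae n. sp. 2",                 1, 1),
    c("Actinostolidae n. sp. 3",                 1, 1),
    c("Actinostolidae n. sp. 4",                 1, 0),
    c("Polynoidae sp. 1",                        1, 0),
    c("Polynoidae sp. 2",                        0, 1),
    c("Polynoidae sp. 3",                        0, 1),
    c("Polynoidae sp. 4",                        0, 1),
    c("Peltospiroidea n. sp.",                   1, 1),
    c("cf. Protolira sp.",                       1, 1),
    c("Lepetodrilus n. sp. 1",                   1, 1),
    c("Provannid sp. 1",                         1, 1),
    c("Provannid sp. 2",                         0, 1),
    c("Octopodidae",                             0, 1),
    c("Vulcanolepas n. sp.",                     1, 1),
    c("Kiwa n. sp.",                             1, 1),
    c("Sericosura sp. 1",                        1, 1),
    c("Sericosura sp. 2",                        1, 1),
    c("Sericosura sp. 3",                        0, 1),
    c("Colossendeis cf. concedis",               1, 1),
    c("Colossendeis cf. elephantis",             1, 1),
    c("Stichasteridae n. sp.",                   1, 1),
    c("Freyella cf. fragilissima",               1, 1),
    c("Zoarcid fish",                            0, 1))
  occ <- rbind(E2 = as.numeric(vapply(taxa, `[`, "", 2)),
               E9 = as.numeric(vapply(taxa, `[`, "", 3)))
  colnames(occ) <- vapply(taxa, `[`, "", 1)
  # E2: 56° 5.2'-5.4' S, 30° 19'-19.35' W; E9: 60° 02.5'-03.00' S,
  # 29° 59'-58.6' W (midpoints of the ranges)
  sites <- data.frame(
    site_id = c("E2", "E9"),
    latitude_deg = c(-(56 + 5.3 / 60), -(60 + 2.75 / 60)),
    longitude_deg = c(-(30 + 19.175 / 60), -(29 + 58.8 / 60)),
    region_label = c("East Scotia Ridge", "East Scotia Ridge"),
    stringsAsFactors = FALSE)
  list(matrix = community_matrix(occ, binary = TRUE),
       sites = validate_site_records(sites))
}
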