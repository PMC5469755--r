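# Packaged transcriptions of the published summary tables, so the
# conservation / richness / diagnosis-formatting stages can be exercised
# without downloading the original alignments.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "stygodelim")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' Load the packaged paper-table fixtures
#'
#' Returns transcriptions of the published tables for the
#' \emph{Niphargus stygius} complex:
#' \describe{
#'   \item{table1}{range sizes, ED and conservation ranks (16 species);
#'     multi-site rows carry `n_sites = NA` because the printed table
#'     reports only the area for them.}
#'   \item{table2}{molecular diagnoses, type localities and vouchers
#'     (17 rows: 8 newly described species, 9 reference specimens);
#'     diagnosis strings are verbatim, including the printed
#'     typographic anomalies, and can be parsed with
#'     [parse_diagnosis()].}
#'   \item{occurrences}{a synthetic occurrence fixture over the published
#'     sampling effort of 64 caves and springs: one record per species at
#'     its (approximately geocoded) type locality, synthetic extra sites
#'     for the multi-site species, and the five published syntopies,
#'     three of which pair \emph{N. podpecanus} with
#'     \emph{N. gottscheeanensis}.}
#'   \item{taxonomy_map}{nominal-to-revised map filing all sixteen
#'     species under the single nominal \emph{N. stygius}.}
#' }
#'
#' @return Named list of validated data frames.
#' @export
paper_fixtures <- function() {
  table1 <- read.csv(fixture_path("table1_ranges.csv"),
                     stringsAsFactors = FALSE, comment.char = "#")
  table2 <- read.csv(fixture_path("table2_diagnoses.csv"),
                     stringsAsFactors = FALSE, comment.char = "#")
  occ <- read_occurrences(fixture_path("occurrences_paper_synthetic.csv"))
  taxmap <- read_taxonomy_map(fixture_path("taxonomy_map_paper.csv"))

  # schema / content validation of the transcriptions
  if (nrow(table1) != 16L) stop("table1 fixture: expected 16 rows")
  stopifnot(all(c("species", "n_sites", "area_km2", "max_diameter_km",
                  "ED", "rank") %in% names(table1)))
  if (nrow(table2) != 17L) stop("table2 fixture: expected 17 rows")
  if (sum(table2$status == "new") != 8L) {
    stop("table2 fixture: expected 8 newly described species")
  }
  if (!setequal(taxmap$revised, table1$species)) {
    stop("taxonomy map does not cover the 16 delimited species")
  }
  if (length(setdiff(unique(occ$species), table1$species))) {
    stop("occurrence fixture contains species outside the complex")
  }
  if (length(unique(occ$site_id)) != 64L) {
    stop("occurrence fixture: expected 64 distinct sites")
  }
  list(table1 = table1, table2 = table2, occurrences = occ,
       taxonomy_map = taxmap)
}
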