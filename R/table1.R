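# The published 40-species measurement table, packaged verbatim: relative
# fill volume (mm^3), relative structural complexity (mm^2), elastic modulus
# (MPa), and relative maximum compressive strength (N) per species.

TABLE1_MD5 <- "29d5b8c48173ce399a243e7379adaad3"

#' Load the packaged 40-species morphology/mechanics table
#'
#' Reads the fixture shipped in `inst/extdata/table1_morphomech.csv`,
#' verifying its MD5 checksum against the pinned transcription.
#'
#' @return Data frame with columns `species`, `specimen`, `volume_mm3`,
#'   `structural_complexity_mm2`, `elastic_modulus_MPa`,
#'   `max_compressive_strength_N`, with a `units` attribute.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_morphomech.csv",
                      package = "condylocore", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, TABLE1_MD5))
    stop("checksum mismatch on packaged measurement table (got ", sum,
         "); the fixture has been altered")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) != 40) stop("measurement table must have exactly 40 species")
  attr(df, "units") <- c(volume_mm3 = "mm^3",
                         structural_complexity_mm2 = "mm^2",
                         elastic_modulus_MPa = "MPa",
                         max_compressive_strength_N = "N")
  df
}

#' Per-column extrema of the measurement table
#'
#' @param fixture Table from [load_table1()] (default loads it).
#' @return Data frame with one row per measurement column: minimum and
#'   maximum values and the species attaining them (ties joined with `;`).
#' @export
summarize_extrema <- function(fixture = load_table1()) {
  cols <- c("volume_mm3", "structural_complexity_mm2",
            "elastic_modulus_MPa", "max_compressive_strength_N")
  rows <- lapply(cols, function(cl) {
    x <- fixture[[cl]]
    mn <- min(x); mx <- max(x)
    data.frame(measurement = cl,
               min_value = mn,
               min_species = paste(fixture$species[x == mn], collapse = ";"),
               max_value = mx,
               max_species = paste(fixture$species[x == mx], collapse = ";"))
  })
  do.call(rbind, rows)
}
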