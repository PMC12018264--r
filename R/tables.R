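#' @include climate.R
NULL

#' The default warming-level table
#'
#' Four global warming levels (anomalies vs the 1850-1900 pre-industrial
#' period), each represented by the first scenario to cross it: the IPCC
#' central-estimate crossing year x and the centre years x0 < x1 of the two
#' period climatologies that bracket it and feed the linear interpolation.
#' Users may override any row.
#'
#' @param path optional CSV with columns level, ssp, x, x0, x1; defaults to
#'   the shipped table
#' @return data.frame of warming-level rows (each row valid per
#'   [warmingLevelSpec()])
#' @export
warmingLevelTable <- function(path = system.file("extdata",
                                                 "warming_levels.csv",
                                                 package = "cropSCS",
                                                 mustWork = TRUE)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab)))
    warmingLevelSpec(tab$level[i], tab$ssp[i], tab$x[i], tab$x0[i], tab$x1[i])
  tab
}

#' The crop classification table
#'
#' A reconstruction of the 46-type crop list of the gridded production data:
#' 30 types flagged as food crops, classified into five groups (cereals,
#' pulses, starchy roots, oil crops, fruits and vegetables), with tomato,
#' onion and citrus among fruits and vegetables. Non-food types carry no
#' group.
#'
#' @param path optional CSV with columns crop_id, crop_name, food_crop,
#'   group; defaults to the shipped table
#' @return data.frame
#' @export
cropClassificationTable <- function(path = system.file("extdata",
                                                       "crop_classification.csv",
                                                       package = "cropSCS",
                                                       mustWork = TRUE)) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  tab$food_crop <- as.logical(tab$food_crop)
  tab
}
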