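FIXTURE_INFO <- list(
  phantom = list(
    file = "phantom_cases.csv",
    md5 = "cc6498a08467239a463cb536372ff136",
    n = 36L,
    provenance = "bundled phantom study table (36 reconstruction cases of a thorax phantom with an LVAD implant)"
  ),
  patient = list(
    file = "patient_cases.csv",
    md5 = "7ae7224e2c8a896f4ee6a4ff47983a40",
    n = 27L,
    provenance = "bundled in-vivo study table (27 reconstructions of one LVAD patient acquisition at 120 kVp, IQ 80)"
  )
)

#' Load a bundled per-case study table
#'
#' Loads and validates one of the two study fixtures shipped with the
#' package: `"phantom"` (36 reconstruction cases of a thorax phantom with an
#' implanted LVAD) or `"patient"` (27 reconstructions of one in-vivo LVAD
#' acquisition). File checksums are pinned in the package, so a corrupted or
#' edited fixture is a hard error. Exactly one phantom case has a missing
#' blooming volume (the segmentation was not available for that case);
#' downstream statistics use pairwise deletion.
#'
#' @param name `"phantom"` or `"patient"`.
#' @param path override the packaged file location (used to validate
#'   external copies against the pinned checksum).
#' @return An object of class `study_fixture`: list with `name`, `records`
#'   (a validated [read_case_table()] data frame) and `provenance`.
#' @export
load_fixture <- function(name = c("phantom", "patient"), path = NULL) {
  name <- match.arg(name)
  info <- FIXTURE_INFO[[name]]
  if (is.null(path))
    path <- system.file("extdata", info$file, package = "metartiq",
                        mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, info$md5))
    stop("fixture checksum mismatch for ", name, " (", md5,
         "): file corrupted or modified")
  records <- read_case_table(path)
  if (nrow(records) != info$n)
    stop("fixture ", name, " must have ", info$n, " records")
  n_missing_bloom <- sum(is.na(records$bloom_vol))
  if (name == "phantom" && n_missing_bloom != 1L)
    stop("phantom fixture must have exactly one missing bloom_vol")
  if (name == "patient" && n_missing_bloom != 0L)
    stop("patient fixture must have no missing bloom_vol")
  structure(
    list(name = name, records = records, provenance = info$provenance),
    class = "study_fixture"
  )
}

#' @export
print.study_fixture <- function(x, ...) {
  cat(sprintf("<study_fixture> %s: %d cases\n  %s\n",
              x$name, nrow(x$records), x$provenance))
  invisible(x)
}
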