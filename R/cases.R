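# Enumerated levels of the reconstruction covariates.
KERNEL_LEVELS <- c("Qr36f", "Qr40f", "Qr44f", "Qr56f",
                   "Bv36f", "Bv40f", "Bv44f", "Bv56f", "Bl56f")
IMAR_LEVELS <- c("None", "Pacemaker", "ThoracicCoils", "HipImplants",
                 "ExtremityImplants")
VMI_LEVELS <- c("40", "62", "67", "70", "90", "110", "190", "SPP-70", "T3D")

# Abbreviations used in the printed study tables ("SSP-70" is a table typo
# for the spectral post-processing 70 keV level).
IMAR_ABBREV <- c(Pa = "Pacemaker", Th = "ThoracicCoils", Tc = "ThoracicCoils",
                 Hi = "HipImplants", Ex = "ExtremityImplants",
                 Ei = "ExtremityImplants", None = "None")
VMI_ALIAS <- c("SSP-70" = "SPP-70")

CASE_TABLE_COLUMNS <- c("case_id", "kvp", "iq", "kernel", "imar", "vmi",
                        "slice_mm", "diff_hu", "sd_artifact", "bloom_vol",
                        "amplitude_low_freq", "cv",
                        paste0("q", 1:6), "vg_sum")

#' Read a per-case study table
#'
#' Reads a delimited per-case table (one row per reconstruction case:
#' acquisition/reconstruction covariates, the four artifact metrics, the
#' per-question tallies q1..q6 and their sum) and validates it: factor
#' columns must use the enumerated kernel/iMAR/keV levels (printed
#' abbreviations such as `Pa` or `Tc` are expanded), tallies must lie in
#' 0..6, and `vg_sum` must equal `q1 + ... + q6`. Missing values are empty
#' fields; only `bloom_vol` may be missing.
#'
#' @param path CSV file with header row and the documented column schema.
#' @return A validated data frame of class `case_table` with `kernel`,
#'   `imar` and `vmi` as factors over the full enumerated level sets.
#' @export
read_case_table <- function(path) {
  if (!file.exists(path)) stop("case table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(vmi = "character"))
  missing_cols <- setdiff(CASE_TABLE_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop("case table misses columns: ", paste(missing_cols, collapse = ", "))

  expand <- function(x, map) ifelse(x %in% names(map), unname(map[x]), x)
  df$imar <- expand(df$imar, IMAR_ABBREV)
  df$vmi <- expand(df$vmi, VMI_ALIAS)

  check_levels <- function(x, levels, what) {
    bad <- setdiff(unique(x), levels)
    if (length(bad) > 0)
      stop("unknown ", what, " level(s) ", paste(bad, collapse = ", "),
           "; allowed: ", paste(levels, collapse = ", "))
    factor(x, levels = levels)
  }
  df$kernel <- check_levels(df$kernel, KERNEL_LEVELS, "kernel")
  df$imar <- check_levels(df$imar, IMAR_LEVELS, "iMAR")
  df$vmi <- check_levels(df$vmi, VMI_LEVELS, "keV/VMI")

  num_cols <- c("kvp", "iq", "slice_mm", "diff_hu", "sd_artifact",
                "bloom_vol", "amplitude_low_freq", "cv")
  for (v in num_cols) df[[v]] <- as.numeric(df[[v]])
  req <- setdiff(num_cols, "bloom_vol")
  for (v in req)
    if (any(is.na(df[[v]])))
      stop("missing values in required column ", v)

  qmat <- as.matrix(df[paste0("q", 1:6)])
  if (any(is.na(qmat)) || any(qmat < 0) || any(qmat > 6) ||
      any(qmat != round(qmat)))
    stop("q1..q6 must be integer tallies in 0..6")
  bad_sum <- which(df$vg_sum != rowSums(qmat))
  if (length(bad_sum) > 0)
    stop("vg_sum does not equal q1 + ... + q6 for case_id ",
         paste(df$case_id[bad_sum], collapse = ", "))
  if (any(df$slice_mm <= 0) || any(df$kvp <= 0))
    stop("kvp and slice_mm must be positive")

  class(df) <- c("case_table", "data.frame")
  df
}
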