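# Canonical column layout of a CNV call set. One row per platform call.
CALL_COLS <- c("call_id", "sample_id", "family_id", "role", "cohort",
               "platform", "chrom", "start", "end", "cnv_type", "quality",
               "support")

ROLES <- c("proband", "mother", "father", "sibling", "unrelated_control")
COHORTS <- c("discovery", "rep_wes", "rep_array", "rep_wgs")
PLATFORMS <- c("wes", "array", "wgs")

#' Build a validated CNV call set
#'
#' A call set is a plain data.frame, one row per call, with columns
#' `call_id` (unique), `sample_id`, `family_id`, `role` (proband / mother /
#' father / sibling / unrelated_control), `cohort` (discovery / rep_wes /
#' rep_array / rep_wgs), `platform` (wes / array / wgs), `chrom`, `start`,
#' `end` (1-based inclusive), `cnv_type` (DEL / DUP), `quality` (numeric or
#' NA) and `support` (free-form provenance, e.g. the WGS read-support
#' fraction).
#'
#' @param df data.frame carrying at least `call_id`, `sample_id`, `chrom`,
#'   `start`, `end`, `cnv_type`; missing annotation columns are filled with NA.
#' @return validated call-set data.frame with canonical column order.
#' @export
as_cnv_calls <- function(df) {
  for (col in setdiff(CALL_COLS, names(df))) df[[col]] <- rep(NA, nrow(df))
  df <- df[, CALL_COLS]
  df$chrom <- normalize_chrom(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$quality <- as.numeric(df$quality)
  for (col in c("call_id", "sample_id", "family_id", "role", "cohort",
                "platform", "cnv_type", "support")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (anyDuplicated(df$call_id)) {
    stop("duplicate call_id in call set: ",
         paste(unique(df$call_id[duplicated(df$call_id)]), collapse = ", "))
  }
  if (!all(df$cnv_type %in% c("DEL", "DUP"))) {
    stop("cnv_type must be DEL or DUP")
  }
  if (any(df$start < 1L) || any(df$end < df$start)) {
    stop("invalid call coordinates (need 1 <= start <= end)")
  }
  bad_role <- !is.na(df$role) & !(df$role %in% ROLES)
  if (any(bad_role)) stop("unknown role: ", paste(unique(df$role[bad_role]), collapse = ", "))
  bad_cohort <- !is.na(df$cohort) & !(df$cohort %in% COHORTS)
  if (any(bad_cohort)) stop("unknown cohort: ", paste(unique(df$cohort[bad_cohort]), collapse = ", "))
  rownames(df) <- NULL
  df
}

# Empty call set with the canonical columns.
empty_calls <- function() {
  as_cnv_calls(data.frame(call_id = character(0), sample_id = character(0),
                          chrom = character(0), start = integer(0),
                          end = integer(0), cnv_type = character(0),
                          stringsAsFactors = FALSE))
}

# Deterministic call-set ordering: position, then type, then id.
sort_calls <- function(calls) {
  o <- order(chrom_rank(calls$chrom), calls$chrom, calls$start, calls$end,
             calls$cnv_type, calls$call_id)
  rownames(calls) <- NULL
  calls[o, , drop = FALSE]
}
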