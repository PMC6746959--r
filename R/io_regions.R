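# Canonical column layout of the regions table (Supplementary-style output).
REGION_COLS <- c("region_id", "chrom", "start", "end", "cnv_types",
                 "n_case_carriers", "n_control_carriers", "member_call_ids",
                 "de_novo", "supported", "rep_wes_support", "rep_array_support",
                 "rep_wgs_support", "veto_calls", "genes", "expressed_gene",
                 "novel_vs_chd", "absent_from_dgv", "relevant",
                 "p_carrier", "p_exact", "se_mc", "n_perm", "seed")

REGION_INT_COLS <- c("start", "end", "n_case_carriers", "n_control_carriers",
                     "n_perm", "seed")
REGION_LGL_COLS <- c("de_novo", "supported", "expressed_gene", "novel_vs_chd",
                     "absent_from_dgv", "relevant")
REGION_NUM_COLS <- c("p_carrier", "p_exact", "se_mc")

fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
fmt_int <- function(x) ifelse(is.na(x), "NA", sprintf("%d", as.integer(x)))
fmt_lgl <- function(x) ifelse(is.na(x), "NA", ifelse(x, "TRUE", "FALSE"))
fmt_str <- function(x) ifelse(is.na(x) | !nzchar(x), ".", x)

# Pad a region frame with NA/defaults for any missing canonical column.
complete_regions <- function(regions) {
  for (col in setdiff(REGION_COLS, names(regions))) {
    fill <- if (col %in% REGION_INT_COLS) NA_integer_
      else if (col %in% REGION_LGL_COLS) NA
      else if (col %in% REGION_NUM_COLS) NA_real_
      else NA_character_
    regions[[col]] <- rep(fill, nrow(regions))
  }
  regions[, REGION_COLS]
}

#' Write the canonical regions table
#'
#' Deterministic TSV: a `#` provenance line carrying the genome build tag,
#' then a header, then one row per region sorted by (chrom, start, end,
#' region_id). Writing, re-reading with [read_regions()] and writing again is
#' bit-exact; tests rely on this for diff-based comparisons.
#'
#' @param regions regions data.frame (any subset of the canonical columns;
#'   the rest are filled with NA).
#' @param path output file.
#' @param build free-text genome build tag recorded in the header line.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, build = "unspecified") {
  regions <- complete_regions(as.data.frame(regions))
  o <- order(chrom_rank(regions$chrom), regions$chrom, regions$start,
             regions$end, regions$region_id)
  regions <- regions[o, , drop = FALSE]
  cells <- lapply(REGION_COLS, function(col) {
    x <- regions[[col]]
    if (col %in% REGION_INT_COLS) fmt_int(x)
    else if (col %in% REGION_LGL_COLS) fmt_lgl(x)
    else if (col %in% REGION_NUM_COLS) fmt_num(x)
    else fmt_str(as.character(x))
  })
  body <- do.call(paste, c(cells, sep = "\t"))
  writeLines(c(sprintf("#cnvtrio_regions\tbuild=%s", build),
               paste(REGION_COLS, collapse = "\t"), body), path)
  invisible(path)
}

#' Read a regions table written by [write_regions()]
#'
#' @param path input file.
#' @return regions data.frame with attribute `build`.
#' @export
read_regions <- function(path) {
  lines <- readLines(path)
  build <- "unspecified"
  if (length(lines) && startsWith(lines[1L], "#")) {
    build <- sub("^.*\tbuild=", "", lines[1L])
    lines <- lines[-1L]
  }
  if (!length(lines)) stop("regions file has no header: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1]]
  if (!identical(header, REGION_COLS)) stop("unexpected regions header in ", path)
  body <- lines[-1L]
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  regions <- stats::setNames(
    as.data.frame(lapply(seq_along(REGION_COLS), function(i) {
      col <- REGION_COLS[i]
      x <- if (length(f)) get(i) else character(0)
      if (col %in% REGION_INT_COLS) as.integer(ifelse(x == "NA", NA, x))
      else if (col %in% REGION_LGL_COLS) as.logical(ifelse(x == "NA", NA, x))
      else if (col %in% REGION_NUM_COLS) as.numeric(ifelse(x == "NA", NA, x))
      else ifelse(x == "NA", NA_character_, x)
    }), stringsAsFactors = FALSE), REGION_COLS)
  attr(regions, "build") <- build
  regions
}

TRACE_COLS <- c("call_id", "stage", "decision", "reason", "evidence")

#' Write / read the filter trace
#'
#' The trace is the pipeline's audit spine: one row per (call, stage) with
#' decision `pass` or `drop`, a reason code, and the comma-joined IDs of the
#' evidence calls behind the decision. Every proband call parsed appears at
#' every stage it reached; a dropped call appears in no later stage.
#'
#' @param trace trace data.frame (call_id, stage, decision, reason, evidence).
#' @param path file path.
#' @return `write_trace`: `path` invisibly; `read_trace`: the trace
#'   data.frame.
#' @export
write_trace <- function(trace, path) {
  trace <- as.data.frame(trace)[, TRACE_COLS]
  body <- sprintf("%s\t%s\t%s\t%s\t%s", trace$call_id, trace$stage,
                  trace$decision, trace$reason, fmt_str(trace$evidence))
  writeLines(c(paste(TRACE_COLS, collapse = "\t"), body), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!identical(names(df), TRACE_COLS)) stop("unexpected trace header in ", path)
  df
}

# Append trace rows; evidence vectors are comma-joined, "." when empty.
trace_rows <- function(call_id, stage, decision, reason, evidence = "") {
  n <- length(call_id)
  evidence <- rep_len(as.character(evidence), n)
  data.frame(call_id = call_id, stage = rep_len(stage, n),
             decision = rep_len(decision, n), reason = rep_len(reason, n),
             evidence = ifelse(nzchar(evidence), evidence, "."),
             stringsAsFactors = FALSE)
}

join_ids <- function(x) if (length(x)) paste(sort(x), collapse = ",") else "."
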