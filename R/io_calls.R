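#' Read platform CNV calls in one of three dialects
#'
#' Supported dialects:
#' \describe{
#'   \item{`xcnv`}{exome read-depth caller output, tab-separated with header
#'     `SAMPLE CNV INTERVAL ...`; only SAMPLE, CNV (DEL/DUP) and INTERVAL
#'     (`chr:start-end`, 1-based inclusive) are required, a trailing numeric
#'     quality column (`Q_EXACT`) is kept when present.}
#'   \item{`rawcnv`}{array caller text, whitespace-separated tokens:
#'     `chr:start-end numsnp=N length=L stateK,cn=C samplefile startsnp= endsnp=`.
#'     Copy number 0/1 maps to DEL, 3+ to DUP; cn=2 (diploid) is rejected as a
#'     record-level error.}
#'   \item{`svbed`}{WGS structural-variant table, tab-separated:
#'     chrom, start (0-based), end, sample_id, type (DEL/DUP),
#'     support_fraction. Calls with read support below `min_support` are
#'     dropped at parse time (reason `low_read_support`).}
#' }
#'
#' Malformed lines are rejected, never fatal: the returned call set carries a
#' `rejected` attribute, a data.frame of (line, reason). For every dialect,
#' `nrow(calls) + nrow(rejected)` equals the number of non-header, non-blank
#' input lines.
#'
#' @param path input file.
#' @param dialect one of `"xcnv"`, `"rawcnv"`, `"svbed"`.
#' @param cohort cohort label stamped on every call (one of discovery /
#'   rep_wes / rep_array / rep_wgs).
#' @param platform platform label; defaults by dialect (xcnv = wes,
#'   rawcnv = array, svbed = wgs).
#' @param pedigree optional [read_pedigree()] object used to fill `family_id`
#'   and `role` per sample; samples absent from the pedigree keep NA.
#' @param min_support minimum WGS read-support fraction (svbed only).
#' @return call-set data.frame (see [as_cnv_calls()]) with attribute
#'   `rejected`.
#' @export
read_calls <- function(path, dialect = c("xcnv", "rawcnv", "svbed"),
                       cohort, platform = NULL, pedigree = NULL,
                       min_support = 0.5) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(platform)) {
    platform <- c(xcnv = "wes", rawcnv = "array", svbed = "wgs")[[dialect]]
  }
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  line_no <- seq_along(lines)[keep]
  lines <- lines[keep]
  # header detection
  if (length(lines) && dialect == "xcnv" && startsWith(lines[1L], "SAMPLE")) {
    lines <- lines[-1L]; line_no <- line_no[-1L]
  }
  if (length(lines) && dialect == "svbed" && startsWith(lines[1L], "#")) {
    lines <- lines[-1L]; line_no <- line_no[-1L]
  }
  parse_one <- switch(dialect,
    xcnv = parse_xcnv_line, rawcnv = parse_rawcnv_line,
    svbed = function(x) parse_svbed_line(x, min_support))
  rows <- vector("list", length(lines))
  rej <- list()
  for (i in seq_along(lines)) {
    p <- parse_one(lines[i])
    if (is.character(p)) {
      rej[[length(rej) + 1L]] <- data.frame(line = line_no[i], reason = p,
                                            stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- p
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(line = integer(0), reason = character(0))
  if (!length(rows)) {
    if (!length(lines)) warning("empty call file: ", path)
    calls <- empty_calls()
  } else {
    df <- do.call(rbind, rows)
    df$call_id <- sprintf("%s_%05d", cohort, seq_len(nrow(df)))
    df$cohort <- cohort
    df$platform <- platform
    calls <- as_cnv_calls(df)
  }
  if (!is.null(pedigree)) {
    m <- match(calls$sample_id, pedigree$members$sample_id)
    calls$family_id <- pedigree$members$family_id[m]
    calls$role <- pedigree$members$role[m]
  }
  attr(calls, "rejected") <- rejected
  calls
}

parse_interval_token <- function(tok) {
  m <- regmatches(tok, regexec("^(\\S+):([0-9]+)-([0-9]+)$", tok))[[1]]
  if (length(m) != 4L) return(NULL)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (is.na(start) || is.na(end) || start < 1L || end < start) return(NULL)
  list(chrom = m[2], start = start, end = end)
}

parse_xcnv_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 3L) return("too_few_fields")
  if (!(f[2] %in% c("DEL", "DUP"))) return("bad_cnv_type")
  iv <- parse_interval_token(f[3])
  if (is.null(iv)) return("bad_interval")
  q <- if (length(f) >= 9L) suppressWarnings(as.numeric(f[9])) else NA_real_
  data.frame(call_id = NA_character_, sample_id = f[1], chrom = iv$chrom,
             start = iv$start, end = iv$end, cnv_type = f[2], quality = q,
             support = NA_character_, stringsAsFactors = FALSE)
}

parse_rawcnv_line <- function(line) {
  f <- strsplit(trimws(line), "\\s+")[[1]]
  if (length(f) < 5L) return("too_few_fields")
  iv <- parse_interval_token(f[1])
  if (is.null(iv)) return("bad_interval")
  state <- grep("^state[0-9]+,cn=[0-9]+$", f, value = TRUE)
  if (!length(state)) return("missing_copy_number_state")
  cn <- as.integer(sub("^state[0-9]+,cn=", "", state[1]))
  if (cn == 2L) return("neutral_copy_number")
  cnv_type <- if (cn <= 1L) "DEL" else "DUP"
  sample_tok <- f[5]
  sample_id <- sub("\\.[A-Za-z0-9]+$", "", basename(sample_tok))
  data.frame(call_id = NA_character_, sample_id = sample_id, chrom = iv$chrom,
             start = iv$start, end = iv$end, cnv_type = cnv_type,
             quality = NA_real_, support = NA_character_,
             stringsAsFactors = FALSE)
}

parse_svbed_line <- function(line, min_support) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 6L) return("too_few_fields")
  start0 <- suppressWarnings(as.integer(f[2]))
  end <- suppressWarnings(as.integer(f[3]))
  if (is.na(start0) || is.na(end) || start0 < 0L || end <= start0) {
    return("bad_interval")
  }
  if (!(f[5] %in% c("DEL", "DUP"))) return("bad_cnv_type")
  supp <- suppressWarnings(as.numeric(f[6]))
  if (is.na(supp) || supp < 0 || supp > 1) return("bad_support_fraction")
  if (supp < min_support) return("low_read_support")
  data.frame(call_id = NA_character_, sample_id = f[4], chrom = f[1],
             start = start0 + 1L, end = end, cnv_type = f[5],
             quality = NA_real_, support = sprintf("%.3f", supp),
             stringsAsFactors = FALSE)
}

#' Write a call set in a platform dialect
#'
#' Canonical writers for the three dialects read by [read_calls()]. Writing
#' then re-reading reproduces the call coordinates, types, samples, quality
#' and (svbed) support fractions; re-writing the re-read set is bit-exact.
#'
#' @param calls call-set data.frame.
#' @param path output file.
#' @param dialect one of `"xcnv"`, `"rawcnv"`, `"svbed"`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path, dialect = c("xcnv", "rawcnv", "svbed")) {
  dialect <- match.arg(dialect)
  len <- interval_length(calls)
  lines <- switch(dialect,
    xcnv = {
      q <- ifelse(is.na(calls$quality), ".", sprintf("%.2f", calls$quality))
      body <- sprintf("%s\t%s\t%s:%d-%d\t%.2f\t%s\t%d\t.\t.\t%s",
                      calls$sample_id, calls$cnv_type, calls$chrom,
                      calls$start, calls$end, len / 1000, calls$chrom,
                      as.integer(floor((calls$start + calls$end) / 2)), q)
      c("SAMPLE\tCNV\tINTERVAL\tKB\tCHR\tMID_BP\tTARGETS\tNUM_TARG\tQ_EXACT",
        body)
    },
    rawcnv = {
      cn <- ifelse(calls$cnv_type == "DEL", 1L, 3L)
      state <- ifelse(calls$cnv_type == "DEL", 2L, 5L)
      numsnp <- pmax(3L, as.integer(round(len / 5000)))
      sprintf("%s:%d-%d numsnp=%d length=%d state%d,cn=%d %s.txt startsnp=rs%d endsnp=rs%d",
              calls$chrom, calls$start, calls$end, numsnp, len, state, cn,
              calls$sample_id, calls$start, calls$end)
    },
    svbed = {
      supp <- suppressWarnings(as.numeric(calls$support))
      supp[is.na(supp)] <- 1
      sprintf("%s\t%d\t%d\t%s\t%s\t%.3f", calls$chrom, calls$start - 1L,
              calls$end, calls$sample_id, calls$cnv_type, supp)
    })
  writeLines(lines, path)
  invisible(path)
}
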