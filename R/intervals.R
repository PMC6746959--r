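#' Normalize chromosome labels
#'
#' Callers disagree on chromosome naming ("2", "chr2", "23" for X). All
#' coordinates in the package are compared after normalization to a canonical
#' "chr"-prefixed form; numeric sex-chromosome codes 23/24/25 map to X/Y/M.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of canonical labels ("chr1", ..., "chrX").
#' @export
#' @examples
#' normalize_chrom(c("2", "chr2", "23", "X"))
normalize_chrom <- function(x) {
  if (!length(x)) return(character(0))
  x <- trimws(as.character(x))
  x <- sub("^[Cc][Hh][Rr]", "", x)
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x == "25"] <- "M"
  paste0("chr", x)
}

# Sort rank for canonical chromosome ordering (chr1..chr22, chrX, chrY, chrM;
# anything else after, tie-broken lexicographically by the caller).
chrom_rank <- function(x) {
  m <- match(sub("^chr", "", x), c(as.character(1:22), "X", "Y", "M"))
  ifelse(is.na(m), 99L, m)
}

#' Construct a set of genomic intervals
#'
#' Coordinates are 1-based and inclusive on both ends, matching the
#' "chrN:start-end" convention used for printed CNV loci. BED-style 0-based
#' half-open inputs must be converted at the parser boundary (see
#' [read_knowledge_base()]).
#'
#' @param chrom chromosome labels (normalized via [normalize_chrom()]).
#' @param start,end integer positions, `1 <= start <= end`.
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
#' @examples
#' genomic_interval("chr2", 109363161, 109371723)
genomic_interval <- function(chrom, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (anyNA(start) || anyNA(end)) stop("interval coordinates must be numeric")
  if (any(start < 1L)) stop("interval start must be >= 1")
  if (any(end < start)) stop("interval end must be >= start")
  data.frame(chrom = normalize_chrom(chrom), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Interval length in base pairs
#'
#' @param iv interval data.frame (columns `chrom`, `start`, `end`).
#' @return integer vector, `end - start + 1`.
#' @export
#' @examples
#' interval_length(genomic_interval("chr2", 109363161, 109371723)) # 8563
interval_length <- function(iv) {
  iv$end - iv$start + 1L
}

# Recycle two interval frames to a common row count.
recycle2 <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 0L || nrow(b) == 0L) n <- 0L
  list(ia = rep_len(seq_len(max(nrow(a), 1L)), n),
       ib = rep_len(seq_len(max(nrow(b), 1L)), n), n = n)
}

#' Overlap between two intervals in base pairs
#'
#' Vectorized over rows with recycling. Zero when the chromosomes differ or
#' the intervals are disjoint.
#'
#' @param a,b interval data.frames.
#' @return nonnegative integer vector.
#' @export
overlap_bp <- function(a, b) {
  r <- recycle2(a, b)
  if (r$n == 0L) return(integer(0))
  same <- a$chrom[r$ia] == b$chrom[r$ib]
  ov <- pmin(a$end[r$ia], b$end[r$ib]) - pmax(a$start[r$ia], b$start[r$ib]) + 1L
  as.integer(ifelse(same, pmax(ov, 0L), 0L))
}

#' Reciprocal overlap fraction
#'
#' The standard CNV-matching statistic: the smaller of the two mutual coverage
#' fractions, `min(overlap/len(a), overlap/len(b))`. Symmetric in its
#' arguments; 1 for identical intervals, 0 for disjoint ones.
#'
#' @param a,b interval data.frames.
#' @return numeric vector in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  r <- recycle2(a, b)
  if (r$n == 0L) return(numeric(0))
  ov <- overlap_bp(a, b)
  pmin(ov / interval_length(a)[r$ia], ov / interval_length(b)[r$ib])
}

#' One-way coverage fraction
#'
#' Fraction of interval `a` covered by interval `b` (`overlap/len(a)`). Not
#' symmetric; used for knowledge-base screens where a small candidate inside a
#' megabase catalogue record should count as fully covered.
#'
#' @param a,b interval data.frames.
#' @return numeric vector in \[0, 1\].
#' @export
fraction_of_a_covered <- function(a, b) {
  r <- recycle2(a, b)
  if (r$n == 0L) return(numeric(0))
  overlap_bp(a, b) / interval_length(a)[r$ia]
}

# All-pairs overlap search between two interval frames.
#
# Returns a data.frame (q, s, frac, ov) of index pairs with ov > 0 and
# frac >= min_frac. mode "reciprocal" uses reciprocal_overlap; mode "query"
# uses fraction_of_a_covered(query, subject). min_frac = 0 means any overlap.
# Quadratic per chromosome, fine at pipeline scale (thousands of calls).
overlap_pairs <- function(query, subject, min_frac = 0,
                          mode = c("reciprocal", "query")) {
  mode <- match.arg(mode)
  empty <- data.frame(q = integer(0), s = integer(0),
                      frac = numeric(0), ov = integer(0))
  if (nrow(query) == 0L || nrow(subject) == 0L) return(empty)
  out <- list()
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    ov <- outer(query$end[qi], subject$end[si], pmin) -
      outer(query$start[qi], subject$start[si], pmax) + 1
    ov[ov < 0] <- 0
    ql <- query$end[qi] - query$start[qi] + 1
    sl <- subject$end[si] - subject$start[si] + 1
    frac <- switch(mode,
      reciprocal = pmin(ov / ql, sweep(ov, 2L, sl, "/")),
      query = ov / ql)
    keep <- which(ov > 0 & frac >= min_frac, arr.ind = TRUE)
    if (nrow(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        q = qi[keep[, 1L]], s = si[keep[, 2L]],
        frac = frac[keep], ov = as.integer(ov[keep]))
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(res$q, res$s), , drop = FALSE]
}
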