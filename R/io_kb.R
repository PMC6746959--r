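# Read a BED4 file (0-based half-open) into 1-based inclusive intervals.
# Converting [s, e) yields [s+1, e]; length is preserved.
read_bed4 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 3L)) stop("BED line with fewer than 3 fields in ", path)
  df <- data.frame(
    chrom = normalize_chrom(vapply(f, `[[`, "", 1L)),
    start = as.integer(vapply(f, `[[`, "", 2L)) + 1L,
    end = as.integer(vapply(f, `[[`, "", 3L)),
    name = vapply(f, function(x) if (length(x) >= 4L) x[[4L]] else ".", ""),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$end < df$start)) {
    stop("invalid BED coordinates in ", path)
  }
  df
}

#' Read the knowledge bases used for relevance screening
#'
#' Four flat local files: known disease-associated CNV regions (BED),
#' common-CNV catalogue regions in healthy individuals (DGV-style BED), gene
#' models (BED4, gene symbol in column 4), and a one-symbol-per-line list of
#' genes highly expressed in embryonic/adult heart. BED coordinates (0-based
#' half-open) are converted to the package's 1-based inclusive convention.
#'
#' @param chd_bed BED of previously reported disease-associated CNV regions.
#' @param dgv_bed BED of common CNVs in healthy individuals.
#' @param genes_bed BED4 gene models.
#' @param expressed_list text file, one gene symbol per line.
#' @return object of class `knowledge_base`: list with `chd_known_regions`,
#'   `dgv_common_regions`, `gene_models` (data.frame gene/chrom/start/end)
#'   and `heart_expressed_genes` (character).
#' @export
read_knowledge_base <- function(chd_bed, dgv_bed, genes_bed, expressed_list) {
  genes <- read_bed4(genes_bed)
  if (anyDuplicated(genes$name)) stop("duplicate gene symbol in ", genes_bed)
  expressed <- character(0)
  if (!is.null(expressed_list)) {
    expressed <- readLines(expressed_list)
    expressed <- trimws(expressed[nzchar(trimws(expressed))])
    if (anyDuplicated(expressed)) expressed <- unique(expressed)
    missing <- setdiff(expressed, genes$name)
    if (length(missing)) {
      warning("expressed genes absent from gene models (kept for symbol matching): ",
              paste(missing, collapse = ", "))
    }
  }
  kb <- list(
    chd_known_regions = read_bed4(chd_bed)[, c("chrom", "start", "end", "name")],
    dgv_common_regions = read_bed4(dgv_bed)[, c("chrom", "start", "end", "name")],
    gene_models = data.frame(gene = genes$name, chrom = genes$chrom,
                             start = genes$start, end = genes$end,
                             stringsAsFactors = FALSE),
    heart_expressed_genes = expressed)
  structure(kb, class = "knowledge_base")
}
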