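#' Construct an expression matrix object
#'
#' @param fpkm numeric matrix, genes in rows (rownames = symbols), samples in
#'   columns (colnames = sample IDs); nonnegative, no missing cells.
#' @param tissue named character vector mapping sample ID to tissue label.
#' @param housekeeping gene symbols used as the normalization baseline.
#' @return object of class `expr_matrix`.
#' @export
expression_matrix <- function(fpkm, tissue,
                              housekeeping = c("G6PD", "ACTB")) {
  fpkm <- as.matrix(fpkm)
  if (anyNA(fpkm)) {
    idx <- which(is.na(fpkm), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing FPKM at gene %s, sample %s",
                 rownames(fpkm)[idx[1]], colnames(fpkm)[idx[2]]))
  }
  if (any(fpkm < 0)) {
    idx <- which(fpkm < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative FPKM at gene %s, sample %s",
                 rownames(fpkm)[idx[1]], colnames(fpkm)[idx[2]]))
  }
  if (is.null(rownames(fpkm)) || is.null(colnames(fpkm))) {
    stop("fpkm matrix needs gene rownames and sample colnames")
  }
  tissue <- tissue[colnames(fpkm)]
  if (anyNA(tissue)) stop("tissue label missing for some samples")
  structure(list(fpkm = fpkm, tissue = tissue,
                 housekeeping = housekeeping), class = "expr_matrix")
}

#' Read an FPKM expression matrix with tissue labels
#'
#' The matrix file is TSV: first column `gene`, remaining columns one per
#' sample. The companion tissue map is two-column TSV (`sample`, `tissue`).
#' Negative or missing cells are fatal, with the offending cell named.
#'
#' @param path expression matrix TSV.
#' @param tissue_path tissue map TSV.
#' @param housekeeping housekeeping gene symbols (normalization baseline).
#' @return an `expr_matrix` object.
#' @export
read_expression <- function(path, tissue_path,
                            housekeeping = c("G6PD", "ACTB")) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column of ", path, " must be 'gene'")
  fpkm <- as.matrix(df[, -1, drop = FALSE])
  rownames(fpkm) <- df$gene
  tm <- utils::read.delim(tissue_path, stringsAsFactors = FALSE)
  tissue <- stats::setNames(tm$tissue, tm$sample)
  expression_matrix(fpkm, tissue, housekeeping)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, %d tissue(s); housekeeping: %s\n",
              nrow(x$fpkm), ncol(x$fpkm), length(unique(x$tissue)),
              paste(x$housekeeping, collapse = ", ")))
  invisible(x)
}

#' Write an expression matrix and tissue map
#'
#' @param em `expr_matrix` object.
#' @param path output matrix TSV.
#' @param tissue_path output tissue map TSV.
#' @return `path`, invisibly.
#' @export
write_expression <- function(em, path, tissue_path) {
  body <- apply(em$fpkm, 1L, function(r) paste(sprintf("%.4f", r), collapse = "\t"))
  writeLines(c(paste(c("gene", colnames(em$fpkm)), collapse = "\t"),
               paste(rownames(em$fpkm), body, sep = "\t")), path)
  writeLines(c("sample\ttissue",
               sprintf("%s\t%s", colnames(em$fpkm), em$tissue)), tissue_path)
  invisible(path)
}
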