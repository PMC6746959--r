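#' Normalize an FPKM matrix against housekeeping genes
#'
#' Each sample column is rescaled by
#' `reference / (sample geometric mean of housekeeping FPKM)`, so that after
#' scaling every sample has exactly the reference housekeeping level. The
#' default reference is the cohort geometric mean of the housekeeping FPKM,
#' which keeps values on an interpretable FPKM scale; the value actually
#' used is recorded in the returned object (`$reference`). Carrying that
#' recorded reference across re-analyses makes contrasts exactly invariant
#' to a global rescaling of the raw matrix (a change of unit convention),
#' since the reference pins the housekeeping baseline rather than the unit.
#' Samples with a zero housekeeping value admit no geometric mean and are
#' excluded with a warning. The operation is idempotent.
#'
#' @param em `expr_matrix` object whose housekeeping genes are all present
#'   in the matrix.
#' @param reference target housekeeping geometric mean; NULL (default) uses
#'   the cohort geometric mean.
#' @return normalized `expr_matrix` with `$reference` set.
#' @export
housekeeping_normalize <- function(em, reference = NULL) {
  hk <- em$housekeeping
  missing <- setdiff(hk, rownames(em$fpkm))
  if (length(missing)) {
    stop("housekeeping gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  hk_mat <- em$fpkm[hk, , drop = FALSE]
  zero <- colSums(hk_mat <= 0) > 0
  if (any(zero)) {
    warning("excluding sample(s) with zero housekeeping FPKM: ",
            paste(colnames(em$fpkm)[zero], collapse = ", "))
    em$fpkm <- em$fpkm[, !zero, drop = FALSE]
    em$tissue <- em$tissue[!zero]
    hk_mat <- hk_mat[, !zero, drop = FALSE]
  }
  gm <- exp(colMeans(log(hk_mat)))
  ref <- if (is.null(reference)) exp(mean(log(gm))) else reference
  em$fpkm <- sweep(em$fpkm, 2L, ref / gm, "*")
  em$reference <- ref
  em
}

#' Contrast gene expression between carrier and non-carrier samples
#'
#' Within one tissue, compares FPKM of `gene` between probands carrying a
#' CNV region and all other probands of that tissue. Group means are
#' reported on the FPKM scale; the fold change is
#' `log2((mean_carrier + 1) / (mean_noncarrier + 1))` (unit pseudocount for
#' bounded behavior near zero). With at least 3 samples per group the
#' p-value is a two-sided Welch t-test on `log2(FPKM + 1)`; with 1-2
#' carriers it is a one-sample z-score of the carrier mean against the
#' non-carrier `log2` distribution (method `"z_outlier"`, never pooled with
#' Welch results); it is NA when the non-carrier group has fewer than 3
#' samples.
#'
#' @param gene gene symbol (must be in the matrix).
#' @param tissue tissue label; only samples of this tissue enter the
#'   contrast.
#' @param carriers sample IDs of region carriers.
#' @param em normalized `expr_matrix`.
#' @return list of class `expr_contrast`: gene, tissue, carrier_samples,
#'   noncarrier_samples, mean_fpkm_carrier, mean_fpkm_noncarrier,
#'   log2_fold_change, p_value, method.
#' @export
compare_expression <- function(gene, tissue, carriers, em) {
  if (!(gene %in% rownames(em$fpkm))) stop("gene absent from matrix: ", gene)
  in_tissue <- colnames(em$fpkm)[em$tissue == tissue]
  car <- intersect(in_tissue, carriers)
  non <- setdiff(in_tissue, carriers)
  if (!length(non)) stop("empty non-carrier group for ", gene, " in ", tissue)
  if (!length(car)) stop("no carrier samples present in tissue ", tissue)
  x_car <- em$fpkm[gene, car]
  x_non <- em$fpkm[gene, non]
  l_car <- log2(x_car + 1)
  l_non <- log2(x_non + 1)
  p <- NA_real_
  method <- "none"
  if (length(non) >= 3L) {
    if (length(car) >= 3L) {
      # constant groups carry no evidence against the null
      p <- tryCatch(stats::t.test(l_car, l_non)$p.value,
                    error = function(e) 1)
      method <- "welch_t"
    } else {
      z <- (mean(l_car) - mean(l_non)) /
        (stats::sd(l_non) / sqrt(length(car)))
      p <- 2 * stats::pnorm(-abs(z))
      method <- "z_outlier"
    }
  }
  structure(list(gene = gene, tissue = tissue, carrier_samples = sort(car),
                 noncarrier_samples = sort(non),
                 mean_fpkm_carrier = mean(x_car),
                 mean_fpkm_noncarrier = mean(x_non),
                 log2_fold_change = log2((mean(x_car) + 1) / (mean(x_non) + 1)),
                 p_value = p, method = method),
            class = "expr_contrast")
}

#' @export
print.expr_contrast <- function(x, ...) {
  cat(sprintf(
    "%s [%s]: carrier FPKM %.2f (n=%d) vs non-carrier %.2f (n=%d), log2FC %.2f, p %s (%s)\n",
    x$gene, x$tissue, x$mean_fpkm_carrier, length(x$carrier_samples),
    x$mean_fpkm_noncarrier, length(x$noncarrier_samples),
    x$log2_fold_change,
    if (is.na(x$p_value)) "NA" else sprintf("%.4g", x$p_value), x$method))
  invisible(x)
}

# Flatten a list of expr_contrast objects into the contrasts TSV layout.
contrasts_table <- function(contrasts, region_ids = NULL) {
  if (!length(contrasts)) {
    return(data.frame(region_id = character(0), gene = character(0),
                      tissue = character(0), n_carrier = integer(0),
                      n_noncarrier = integer(0), mean_fpkm_carrier = numeric(0),
                      mean_fpkm_noncarrier = numeric(0), log2fc = numeric(0),
                      p_value = numeric(0), method = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(region_ids)) region_ids <- rep(".", length(contrasts))
  do.call(rbind, Map(function(ct, rid) {
    data.frame(region_id = rid, gene = ct$gene, tissue = ct$tissue,
               n_carrier = length(ct$carrier_samples),
               n_noncarrier = length(ct$noncarrier_samples),
               mean_fpkm_carrier = ct$mean_fpkm_carrier,
               mean_fpkm_noncarrier = ct$mean_fpkm_noncarrier,
               log2fc = ct$log2_fold_change, p_value = ct$p_value,
               method = ct$method, stringsAsFactors = FALSE)
  }, contrasts, region_ids))
}

write_contrasts <- function(tab, path) {
  header <- paste(names(tab), collapse = "\t")
  body <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s\t%s",
                  tab$region_id, tab$gene, tab$tissue, tab$n_carrier,
                  tab$n_noncarrier, fmt_num(tab$mean_fpkm_carrier),
                  fmt_num(tab$mean_fpkm_noncarrier), fmt_num(tab$log2fc),
                  fmt_num(tab$p_value), tab$method)
  writeLines(c(header, body), path)
  invisible(path)
}
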