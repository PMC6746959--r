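#' Map a region to the genes it overlaps
#'
#' Genes whose model interval shares at least one base with the region,
#' sorted by genomic position (then symbol). Abutting models (region ends
#' where the gene starts) do not count.
#'
#' @param region one-row regions data.frame (or any interval row).
#' @param kb [read_knowledge_base()] object.
#' @return character vector of gene symbols.
#' @export
map_genes <- function(region, kb) {
  gm <- kb$gene_models
  iv <- genomic_interval(gm$chrom, gm$start, gm$end)
  hits <- overlap_pairs(region[, c("chrom", "start", "end")], iv, min_frac = 0)
  g <- gm[hits$s, , drop = FALSE]
  g$gene[order(chrom_rank(g$chrom), g$start, g$end, g$gene)]
}

#' Knowledge-based relevance flags for a region
#'
#' The three relevance criteria, any one of which qualifies a region for the
#' high-confidence target list:
#' \enumerate{
#'   \item `expressed_gene`: a mapped gene is on the embryonic/adult heart
#'     expressed-gene list;
#'   \item `novel_vs_chd`: no previously reported disease-associated CNV
#'     region covers at least `f_kb` of the candidate (taken literally:
#'     novelty counts toward relevance; set `invert_criterion2 = TRUE` to
#'     count known-locus overlap instead);
#'   \item `absent_from_dgv`: no common-CNV catalogue record covers at least
#'     `f_kb` of the candidate.
#' }
#' Coverage is one-way, of the candidate by the knowledge-base record, so a
#' small candidate inside a megabase syndromic record counts as covered.
#' `f_kb = 0` means any overlap counts.
#'
#' @param region one-row regions data.frame.
#' @param kb knowledge base.
#' @param f_kb coverage fraction threshold in \[0, 1\]; default 0.5.
#' @param genes mapped gene symbols; computed via [map_genes()] when NULL.
#' @param invert_criterion2 flip the direction of criterion 2 in the
#'   `relevant` OR (the reported `novel_vs_chd` flag keeps its literal value).
#' @return list: `expressed_gene`, `novel_vs_chd`, `absent_from_dgv`,
#'   `relevant`, `genes`.
#' @export
relevance_flags <- function(region, kb, f_kb = 0.5, genes = NULL,
                            invert_criterion2 = FALSE) {
  stopifnot(f_kb >= 0, f_kb <= 1)
  if (is.null(genes)) genes <- map_genes(region, kb)
  covered_by <- function(records) {
    if (!nrow(records)) return(FALSE)
    iv <- genomic_interval(records$chrom, records$start, records$end)
    hits <- overlap_pairs(region[, c("chrom", "start", "end")], iv,
                          min_frac = 0, mode = "query")
    if (!nrow(hits)) return(FALSE)
    if (f_kb > 0) any(hits$frac >= f_kb) else TRUE
  }
  expressed <- length(genes) > 0 && any(genes %in% kb$heart_expressed_genes)
  chd_covered <- covered_by(kb$chd_known_regions)
  dgv_covered <- covered_by(kb$dgv_common_regions)
  crit2 <- if (invert_criterion2) chd_covered else !chd_covered
  list(expressed_gene = expressed,
       novel_vs_chd = !chd_covered,
       absent_from_dgv = !dgv_covered,
       relevant = expressed || crit2 || !dgv_covered,
       genes = genes)
}

#' Annotate a regions table with genes and relevance flags
#'
#' @param regions regions data.frame from [merge_recurrent()].
#' @param kb knowledge base.
#' @param f_kb coverage threshold (see [relevance_flags()]).
#' @param invert_criterion2 see [relevance_flags()].
#' @return regions with `genes`, `expressed_gene`, `novel_vs_chd`,
#'   `absent_from_dgv`, `relevant` columns filled.
#' @export
annotate_regions <- function(regions, kb, f_kb = 0.5,
                             invert_criterion2 = FALSE) {
  n <- nrow(regions)
  regions$genes <- character(n)
  regions$expressed_gene <- logical(n)
  regions$novel_vs_chd <- logical(n)
  regions$absent_from_dgv <- logical(n)
  regions$relevant <- logical(n)
  for (i in seq_len(n)) {
    fl <- relevance_flags(regions[i, , drop = FALSE], kb, f_kb = f_kb,
                          invert_criterion2 = invert_criterion2)
    regions$genes[i] <- if (length(fl$genes)) paste(fl$genes, collapse = ",") else "."
    regions$expressed_gene[i] <- fl$expressed_gene
    regions$novel_vs_chd[i] <- fl$novel_vs_chd
    regions$absent_from_dgv[i] <- fl$absent_from_dgv
    regions$relevant[i] <- fl$relevant
  }
  regions
}

#' De novo regions never reported in the common-CNV catalogue
#'
#' Subset of de novo regions with `absent_from_dgv` true (the novel de novo
#' list); the `recurrent` column additionally marks regions carried by at
#' least two distinct case samples.
#'
#' @param regions annotated regions table carrying de novo membership (a
#'   logical `de_novo` column; when absent, all rows are assumed de novo).
#' @param kb knowledge base (used to compute `absent_from_dgv` if missing).
#' @param f_kb coverage threshold.
#' @return regions subset with a `recurrent` logical column.
#' @export
dgv_novel_de_novo <- function(regions, kb, f_kb = 0.5) {
  if (is.null(regions$absent_from_dgv) || anyNA(regions$absent_from_dgv)) {
    regions <- annotate_regions(regions, kb, f_kb = f_kb)
  }
  dn <- if (!is.null(regions$de_novo)) regions$de_novo %in% TRUE else
    rep(TRUE, nrow(regions))
  out <- regions[dn & regions$absent_from_dgv, , drop = FALSE]
  out$recurrent <- out$n_case_carriers >= 2L
  rownames(out) <- NULL
  out
}
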