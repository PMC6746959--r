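lims1_kb <- function() {
  mk_kb(gene_models = data.frame(
    gene = c("GCC2", "LIMS1", "RANBP2"),
    chrom = "chr2",
    start = c(109105000L, 109154000L, 109335000L),
    end = c(109135000L, 109246000L, 109402000L), stringsAsFactors = FALSE),
    expressed = c("LIMS1", "RANBP2"))
}

test_that("gene mapping returns position-sorted overlapping genes", {
  kb <- lims1_kb()
  r <- mk_region("chr2", 109113426, 109287320)
  expect_equal(map_genes(r, kb), c("GCC2", "LIMS1"))
  expect_equal(map_genes(mk_region("chr7", 1, 1000), kb), character(0))
})

test_that("an abutting gene model does not map", {
  kb <- mk_kb(gene_models = data.frame(gene = "G1", chrom = "chr1",
                                       start = 201L, end = 300L,
                                       stringsAsFactors = FALSE))
  expect_equal(map_genes(mk_region("chr1", 100, 200), kb), character(0))
  expect_equal(map_genes(mk_region("chr1", 100, 201), kb), "G1")
})

test_that("relevance criteria: expressed gene, novelty, catalogue absence", {
  kb <- lims1_kb()
  r <- mk_region("chr2", 109113426, 109287320)
  fl <- relevance_flags(r, kb)
  expect_true(fl$expressed_gene)     # LIMS1 is on the expressed list
  expect_true(fl$novel_vs_chd)       # no known region loaded
  expect_true(fl$absent_from_dgv)    # empty catalogue
  expect_true(fl$relevant)
  # with the region fully inside a common-catalogue record it loses criterion 3
  kb2 <- lims1_kb()
  kb2$dgv_common_regions <- data.frame(chrom = "chr2", start = 109000000L,
                                       end = 109400000L, name = "dgv1",
                                       stringsAsFactors = FALSE)
  fl2 <- relevance_flags(r, kb2)
  expect_false(fl2$absent_from_dgv)
  expect_true(fl2$relevant)          # still expressed + novel
})

test_that("a region failing all three criteria is not relevant", {
  kb <- mk_kb(
    chd = data.frame(chrom = "chr1", start = 1L, end = 10000000L,
                     name = "known", stringsAsFactors = FALSE),
    dgv = data.frame(chrom = "chr1", start = 1L, end = 10000000L,
                     name = "common", stringsAsFactors = FALSE),
    gene_models = data.frame(gene = "G1", chrom = "chr1", start = 100L,
                             end = 5000L, stringsAsFactors = FALSE),
    expressed = character(0))
  fl <- relevance_flags(mk_region("chr1", 1000, 2000), kb)
  expect_false(fl$expressed_gene)
  expect_false(fl$novel_vs_chd)
  expect_false(fl$absent_from_dgv)
  expect_false(fl$relevant)
})

test_that("partial knowledge-base coverage respects the f_kb threshold", {
  kb <- mk_kb(dgv = data.frame(chrom = "chr1", start = 1L, end = 140L,
                               name = "d", stringsAsFactors = FALSE))
  r <- mk_region("chr1", 101, 200)  # covered 40/100
  expect_true(relevance_flags(r, kb, f_kb = 0.5)$absent_from_dgv)
  expect_false(relevance_flags(r, kb, f_kb = 0.3)$absent_from_dgv)
  # f_kb = 0 means any overlap counts
  expect_false(relevance_flags(r, kb, f_kb = 0)$absent_from_dgv)
})

test_that("criterion 2 direction can be inverted without changing the flag", {
  kb <- mk_kb(chd = data.frame(chrom = "chr1", start = 1L, end = 1000L,
                               name = "k", stringsAsFactors = FALSE),
              dgv = data.frame(chrom = "chr1", start = 1L, end = 1000L,
                               name = "d", stringsAsFactors = FALSE))
  r <- mk_region("chr1", 100, 200)
  lit <- relevance_flags(r, kb)
  inv <- relevance_flags(r, kb, invert_criterion2 = TRUE)
  expect_false(lit$novel_vs_chd)
  expect_false(inv$novel_vs_chd)     # reported flag keeps literal value
  expect_false(lit$relevant)         # not novel, in catalogue, not expressed
  expect_true(inv$relevant)          # known-locus overlap now counts
})

test_that("with empty knowledge bases every region is novel and unexpressed", {
  kb <- mk_kb()
  fl <- relevance_flags(mk_region("chr5", 100, 2000), kb)
  expect_true(fl$novel_vs_chd)
  expect_true(fl$absent_from_dgv)
  expect_false(fl$expressed_gene)
})

test_that("widening the common-CNV catalogue only shrinks the novel de novo list", {
  set.seed(401)
  iv <- random_ivs(30, max_coord = 100000, chroms = "chr1")
  regions <- do.call(rbind, lapply(seq_len(30), function(i)
    mk_region("chr1", iv$start[i], iv$end[i],
              region_id = sprintf("r%02d", i))))
  regions$de_novo <- TRUE
  sizes <- integer(0)
  dgv_all <- data.frame(chrom = "chr1",
                        start = as.integer(seq(1, 90000, by = 10000)),
                        end = as.integer(seq(1, 90000, by = 10000) + 15000),
                        name = sprintf("d%d", 1:9), stringsAsFactors = FALSE)
  for (k in c(0, 3, 6, 9)) {
    kb <- mk_kb(dgv = dgv_all[seq_len(k), , drop = FALSE])
    sizes <- c(sizes, nrow(dgv_novel_de_novo(regions, kb)))
  }
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[1], 30L)
})

test_that("planted catalogue-known regions are excluded, novel ones kept", {
  known <- do.call(rbind, lapply(1:10, function(i)
    mk_region("chr1", i * 10000, i * 10000 + 5000,
              region_id = sprintf("k%02d", i))))
  novel <- do.call(rbind, lapply(1:5, function(i)
    mk_region("chr2", i * 10000, i * 10000 + 5000,
              region_id = sprintf("n%02d", i), n_case_carriers = i)))
  regions <- rbind(known, novel)
  regions$de_novo <- TRUE
  kb <- mk_kb(dgv = data.frame(chrom = known$chrom, start = known$start,
                               end = known$end, name = known$region_id,
                               stringsAsFactors = FALSE))
  out <- dgv_novel_de_novo(regions, kb)
  expect_equal(sort(out$region_id), sort(novel$region_id))
  # recurrent sub-list needs at least two case carriers
  expect_equal(sum(out$recurrent), 4L)
})

test_that("relevance_flags is a pure function of region and knowledge base", {
  kb <- lims1_kb()
  r <- mk_region("chr2", 109113426, 109287320)
  expect_identical(relevance_flags(r, kb), relevance_flags(r, kb))
})
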