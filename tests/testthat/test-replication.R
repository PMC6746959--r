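test_that("partial-span opposite-type replication matches at rho 0.25 but not 0.5", {
  disc <- mk_calls("chr2", 109363161, 109371723, cnv_type = "DEL",
                   sample_id = "D1-01", family_id = "D1", call_id = "d1")
  rep_wes <- mk_calls("chr2", 109365376, 109389041, cnv_type = "DUP",
                      sample_id = "R1-01", family_id = "R1",
                      cohort = "rep_wes", call_id = "r1")
  ev <- match_replication(disc, list(rep_wes = rep_wes), rho_rep = 0.25)
  expect_equal(ev$supporting$rep_wes, "r1")
  expect_true(ev$supported)
  ev2 <- match_replication(disc, list(rep_wes = rep_wes), rho_rep = 0.5)
  expect_equal(ev2$supporting$rep_wes, character(0))
  expect_false(ev2$supported)
})

test_that("a control carrying the interval vetoes support", {
  disc <- mk_calls("chr1", 1e6, 2e6, sample_id = "D1-01", family_id = "D1",
                   call_id = "d1")
  rep_calls <- rbind(
    mk_calls("chr1", 1e6, 2e6, sample_id = "R1-01", family_id = "R1",
             cohort = "rep_wes", call_id = "r1"),
    mk_calls("chr1", 1e6, 2e6, sample_id = "R2-02", family_id = "R2",
             role = "father", cohort = "rep_wes", call_id = "r2"))
  ev <- match_replication(disc, list(rep_wes = rep_calls))
  expect_false(ev$supported)
  expect_equal(ev$veto, "r2")
  expect_equal(ev$supporting$rep_wes, "r1")
})

test_that("a replication sample shared with discovery is fatal", {
  disc <- mk_calls("chr1", 1e6, 2e6, sample_id = "S1", call_id = "d1")
  rep_wes <- mk_calls("chr1", 5e6, 6e6, sample_id = "S1", cohort = "rep_wes",
                      call_id = "r1")
  expect_error(
    match_replication(disc, list(rep_wes = rep_wes),
                      discovery_samples = "S1"),
    "mutually exclusive")
})

test_that("merging reproduces the multi-platform recurrent locus example", {
  calls <- rbind(
    mk_calls("chr2", 109113426, 109287320, sample_id = c("D1-01", "D2-01", "D3-01"),
             family_id = c("D1", "D2", "D3"), call_id = c("a", "b", "c")),
    mk_calls("chr2", 109173930, 109301074, sample_id = "PCGC0043294",
             family_id = "PCGC0043294", cohort = "rep_array",
             platform = "array", call_id = "d"))
  regions <- merge_recurrent(calls)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$region_id, "chr2:109113426-109301074")
  expect_gte(regions$n_case_carriers, 4L)
})

test_that("calls on different chromosomes stay separate regions", {
  calls <- mk_calls(c("chr1", "chr2"), c(100, 100), c(200, 200),
                    sample_id = c("a", "b"), call_id = c("x", "y"))
  expect_equal(nrow(merge_recurrent(calls)), 2L)
})

test_that("single linkage is transitive: a-b and b-c overlap chains into one region", {
  calls <- mk_calls("chr1", c(100, 180, 260), c(200, 280, 360),
                    sample_id = c("s1", "s2", "s3"),
                    call_id = c("a", "b", "c"))
  # a-c are disjoint (200 < 260) but both link through b
  expect_equal(overlap_bp(calls[1, ], calls[3, ]), 0L)
  regions <- merge_recurrent(calls)
  expect_equal(nrow(regions), 1L)
  expect_equal(regions$start, 100L)
  expect_equal(regions$end, 360L)
})

test_that("merge partitions calls, spans never overlap, order does not matter", {
  set.seed(301)
  for (rep in 1:8) {
    n <- 15
    iv <- random_ivs(n, max_coord = 800)
    calls <- mk_calls(iv$chrom, iv$start, iv$end,
                      sample_id = sprintf("s%02d", sample(1:8, n, TRUE)),
                      call_id = sprintf("c%02d", 1:n))
    regions <- merge_recurrent(calls)
    # partition: every call in exactly one region
    members <- unlist(strsplit(regions$member_call_ids, ","))
    expect_setequal(members, calls$call_id)
    expect_equal(length(members), n)
    # same-chromosome spans are disjoint
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, ]
      if (nrow(r) > 1) {
        r <- r[order(r$start), ]
        expect_true(all(r$start[-1] > r$end[-nrow(r)]))
      }
    }
    # connected-components oracle
    want <- bf_components(calls)
    got <- strsplit(regions$member_call_ids, ",")
    norm <- function(part) sort(vapply(part, function(x)
      paste(sort(x), collapse = "+"), ""))
    expect_equal(norm(got), unname(norm(want)))
    # order invariance
    regions2 <- merge_recurrent(calls[sample(n), ])
    expect_equal(regions2$region_id, regions$region_id)
    expect_equal(regions2$member_call_ids, regions$member_call_ids)
  }
})

test_that("merge against an independent interval-tree implementation", {
  skip_if_not_installed("IRanges")
  set.seed(302)
  iv <- random_ivs(60, max_coord = 5000, chroms = "chr1")
  calls <- mk_calls(iv$chrom, iv$start, iv$end,
                    sample_id = sprintf("s%02d", 1:60),
                    call_id = sprintf("c%02d", 1:60))
  regions <- merge_recurrent(calls)
  red <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  expect_equal(regions$start, IRanges::start(red))
  expect_equal(regions$end, IRanges::end(red))
})

test_that("carriers are counted as distinct samples, not calls", {
  calls <- mk_calls("chr1", c(100, 150, 120), c(300, 350, 310),
                    sample_id = c("p1", "p1", "c1"),
                    role = c("proband", "proband", "father"),
                    family_id = c("F1", "F1", "F2"),
                    call_id = c("a", "b", "c"))
  regions <- merge_recurrent(calls)
  expect_equal(regions$n_case_carriers, 1L)
  expect_equal(regions$n_control_carriers, 1L)
})

test_that("replicate_calls aggregates evidence and traces vetoed calls", {
  disc <- rbind(
    mk_calls("chr1", 1e6, 2e6, sample_id = "D1-01", family_id = "D1",
             call_id = "d1"),
    mk_calls("chr2", 1e6, 2e6, sample_id = "D2-01", family_id = "D2",
             call_id = "d2"),
    mk_calls("chr3", 1e6, 2e6, sample_id = "D3-01", family_id = "D3",
             call_id = "d3"))
  rep_wes <- rbind(
    mk_calls("chr1", 1e6, 2e6, sample_id = "R1-01", family_id = "R1",
             cohort = "rep_wes", call_id = "rw1"),
    mk_calls("chr2", 1e6, 2e6, sample_id = "R2-03", family_id = "R2",
             role = "mother", cohort = "rep_wes", call_id = "rw2"))
  res <- replicate_calls(disc, list(rep_wes = rep_wes))
  expect_equal(res$supported$call_id, "d1")
  expect_equal(res$support_calls$call_id, "rw1")
  tr <- res$trace
  expect_equal(tr$reason[tr$call_id == "d2"], "replication_control_veto")
  expect_equal(tr$reason[tr$call_id == "d3"], "no_replication_support")
})
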