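small_config <- function(seed = 11,
                         planted_regions = transform(
                           default_planted_regions(),
                           n_discovery = pmin(n_discovery, 3L),
                           n_rep_wes = pmin(n_rep_wes, 3L)), ...) {
  simulation_config(
    seed = seed,
    n_trios = c(discovery = 30L, rep_wes = 40L, rep_wgs = 5L),
    n_array = c(case = 20L, control = 20L),
    n_polymorphic_loci = 5L,
    planted_regions = planted_regions, ...)
}

emit_key <- function(df) {
  sort(paste(df$dataset, df$sample_id, df$chrom, df$start, df$end,
             df$cnv_type))
}

test_that("noiseless emission equals the genotyped truth exactly", {
  cfg <- noiseless_config(small_config(seed = 12))
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  truth_geno <- sim$truth$events[sim$truth$events$genotyped, ]
  expect_equal(emit_key(sim$truth$emitted), emit_key(truth_geno))
  expect_false(any(sim$truth$emitted$origin == "false_positive"))
  # and the written files parse back to the same intervals
  ped <- read_pedigree(sim$paths$pedigree)
  disc <- read_calls(sim$paths$discovery, "xcnv", cohort = "discovery",
                     pedigree = ped)
  disc_truth <- truth_geno[truth_geno$dataset == "discovery", ]
  expect_equal(sort(paste(disc$sample_id, disc$chrom, disc$start, disc$end)),
               sort(paste(disc_truth$sample_id, disc_truth$chrom,
                          disc_truth$start, disc_truth$end)))
})

test_that("zero de novo rate and empty rosters yield no de novo calls", {
  planted0 <- default_planted_regions()
  planted0[, c("n_discovery", "n_rep_wes", "n_rep_array", "n_rep_wgs")] <- 0L
  cfg <- noiseless_config(small_config(seed = 13, de_novo_rate = 0,
                                       planted_regions = planted0))
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  expect_false(any(sim$truth$events$de_novo))
  ped <- read_pedigree(sim$paths$pedigree)
  disc <- read_calls(sim$paths$discovery, "xcnv", cohort = "discovery",
                     pedigree = ped)
  res <- filter_inherited(disc, ped)
  expect_equal(nrow(res$de_novo), 0L)
})

test_that("background de novo counts match the rate (500 trios at 0.1)", {
  planted0 <- default_planted_regions()
  planted0[, c("n_discovery", "n_rep_wes", "n_rep_array", "n_rep_wgs")] <- 0L
  cfg <- simulation_config(
    seed = 14, n_trios = c(discovery = 500L, rep_wes = 0L, rep_wgs = 0L),
    n_array = c(case = 0L, control = 0L), n_polymorphic_loci = 0L,
    de_novo_rate = 0.1, planted_regions = planted0)
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  n_dn <- sum(sim$truth$events$origin == "de_novo_background")
  expect_lt(abs(n_dn - 50), 3 * sqrt(50))
})

test_that("identical config and seed give byte-identical output files", {
  cfg <- small_config(seed = 15)
  d1 <- tempfile("sim_a_"); d2 <- tempfile("sim_b_")
  s1 <- simulate_cohort(cfg, d1)
  s2 <- simulate_cohort(cfg, d2)
  for (nm in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[nm]]), readLines(s2$paths[[nm]]),
                     label = nm)
  }
  e1 <- simulate_expression(cfg, s1$truth, d1)
  e2 <- simulate_expression(cfg, s2$truth, d2)
  expect_identical(readLines(e1$paths$matrix), readLines(e2$paths$matrix))
})

test_that("every inherited proband call has a same-locus parental allele", {
  cfg <- noiseless_config(small_config(seed = 16))
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  ev <- sim$truth$events
  inh <- ev[ev$role == "proband" & !ev$de_novo, ]
  for (i in seq_len(nrow(inh))) {
    parents <- ev[ev$family_id == inh$family_id[i] &
                    ev$role %in% c("father", "mother") &
                    ev$chrom == inh$chrom[i] & ev$start == inh$start[i], ]
    expect_gte(nrow(parents), 1L)
  }
})

test_that("sample IDs are disjoint across datasets", {
  cfg <- small_config(seed = 17)
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  m <- sim$pedigree$members
  expect_equal(anyDuplicated(m$sample_id), 0L)
  by_ds <- split(m$sample_id, m$dataset)
  for (i in seq_along(by_ds)) {
    for (j in seq_len(i - 1L)) {
      expect_equal(length(intersect(by_ds[[i]], by_ds[[j]])), 0L)
    }
  }
})

test_that("planted regions never overlap polymorphic loci", {
  cfg <- small_config(seed = 18)
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  loci <- sim$truth$polymorphic_loci
  planted <- cfg$planted_regions
  for (i in seq_len(nrow(planted))) {
    expect_true(all(overlap_bp(loci[, c("chrom", "start", "end")],
                               planted[i, c("chrom", "start", "end")]) == 0L))
  }
})

test_that("noise-free dosage 0.5 halves carrier FPKM exactly", {
  cfg <- small_config(seed = 19, expression = list(sigma_log2 = 0,
                                                   n_samples = 30L))
  sim <- simulate_cohort(noiseless_config(cfg), tempfile("sim_"))
  ex <- simulate_expression(cfg, sim$truth, tempfile("expr_"))
  for (g in c("LIMS1", "RANBP2", "TTC3", "MAP3K7CL")) {
    car <- ex$carriers[[g]]
    non <- setdiff(colnames(ex$em$fpkm), car)
    if (!length(car)) next
    expect_equal(unname(ex$em$fpkm[g, car]),
                 rep(unname(ex$em$fpkm[g, non][1]) * 0.5, length(car)),
                 tolerance = 1e-9)
  }
  # duplication gene rises 1.5x
  car <- ex$carriers[["SYNDUP1"]]
  if (length(car)) {
    non <- setdiff(colnames(ex$em$fpkm), car)
    expect_equal(unname(ex$em$fpkm["SYNDUP1", car[1]]),
                 unname(ex$em$fpkm["SYNDUP1", non[1]]) * 1.5,
                 tolerance = 1e-9)
  }
})

test_that("simulated dialects parse with zero rejected lines when noiseless", {
  cfg <- noiseless_config(small_config(seed = 20))
  sim <- simulate_cohort(cfg, tempfile("sim_"))
  for (ds in c("discovery", "rep_wes", "rep_array", "rep_wgs")) {
    dialect <- c(discovery = "xcnv", rep_wes = "xcnv", rep_array = "rawcnv",
                 rep_wgs = "svbed")[[ds]]
    calls <- read_calls(sim$paths[[ds]], dialect, cohort = ds)
    expect_equal(nrow(attr(calls, "rejected")), 0L, label = ds)
  }
})
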