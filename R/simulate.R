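default_genome <- function() {
  data.frame(chrom = c("chr1", "chr2", "chr3", "chr21"),
             length = c(120e6, 150e6, 100e6, 48e6),
             stringsAsFactors = FALSE)
}

# Scaled-down platform behavior per dataset: detection sensitivity,
# breakpoint jitter (Gaussian sd, bp), false calls per sample, and the
# probability of reporting the wrong CNV type.
default_platform_params <- function() {
  list(
    discovery = list(sensitivity = 0.95, jitter_sd = 100, false_rate = 0.01,
                     miscall_prob = 0.02),
    rep_wes = list(sensitivity = 0.95, jitter_sd = 100, false_rate = 0.01,
                   miscall_prob = 0.02),
    rep_array = list(sensitivity = 0.85, jitter_sd = 1000, false_rate = 0.02,
                     miscall_prob = 0.02),
    rep_wgs = list(sensitivity = 0.90, jitter_sd = 50, false_rate = 0.005,
                   miscall_prob = 0.01))
}

# Planted case-only recurrent regions with known carrier rosters per dataset
# and a dosage-affected expression gene each. Loci mirror the coordinate
# scale of real recurrent CNV targets; the fifth is a synthetic duplication.
default_planted_regions <- function() {
  data.frame(
    planted_id = paste0("P", 1:5),
    chrom = c("chr2", "chr2", "chr21", "chr21", "chr3"),
    start = c(109113426L, 109363161L, 38461093L, 30400216L, 15000000L),
    end = c(109287320L, 109371723L, 38523202L, 30547213L, 15080000L),
    cnv_type = c("DEL", "DEL", "DEL", "DEL", "DUP"),
    gene = c("LIMS1", "RANBP2", "TTC3", "MAP3K7CL", "SYNDUP1"),
    dosage = c(0.5, 0.5, 0.5, 0.5, 1.5),
    n_discovery = c(3L, 4L, 1L, 1L, 2L),
    n_rep_wes = c(2L, 2L, 3L, 1L, 2L),
    n_rep_array = c(1L, 0L, 0L, 1L, 1L),
    n_rep_wgs = c(0L, 0L, 0L, 1L, 0L),
    stringsAsFactors = FALSE)
}

# Gene models written to the synthetic knowledge base (all coordinates
# 1-based inclusive; converted to BED on write).
default_gene_models <- function() {
  data.frame(
    gene = c("GCC2", "LIMS1", "RANBP2", "TTC3", "MAP3K7CL", "SYNDUP1",
             "G6PD", "ACTB", sprintf("GENE%03d", 1:10)),
    chrom = c("chr2", "chr2", "chr2", "chr21", "chr21", "chr3",
              "chr1", "chr1",
              rep(c("chr1", "chr3"), 5)),
    start = c(109105000L, 109154000L, 109335000L, 38445000L, 30400216L,
              15010000L, 5000001L, 6000001L,
              as.integer(1e7 + (1:10) * 2e6)),
    end = c(109135000L, 109246000L, 109402000L, 38575000L, 30547213L,
            15060000L, 5020000L, 6010000L,
            as.integer(1e7 + (1:10) * 2e6 + 50000L)),
    stringsAsFactors = FALSE)
}

#' Build a simulation configuration
#'
#' Defaults define the scaled-down study conditions used throughout the test
#' suite: 100 discovery trios, 200 exome-replication trios, 150 unrelated
#' array samples (75 affected / 75 control), 10 genome-replication trios; 10
#' polymorphic (benign, inherited) CNV loci at population frequencies
#' U(0.05, 0.30); a background de novo rate of 0.05 per proband; and 5
#' planted case-only recurrent regions with rostered carriers across
#' datasets and a dosage effect on one gene each.
#'
#' @param seed master seed; the whole simulation is deterministic given it.
#' @param n_trios named integer vector (discovery, rep_wes, rep_wgs).
#' @param n_array named integer vector (case, control).
#' @param frac_with_relative fraction of discovery / exome-replication
#'   families with at least one genotyped relative (genome-replication trios
#'   are always complete).
#' @param sibling_prob probability a complete family also has an unaffected
#'   genotyped sibling.
#' @param n_polymorphic_loci,polymorphic_freq_range,polymorphic_len_range
#'   benign polymorphic CNV loci: count, allele-frequency range, length
#'   range (bp).
#' @param de_novo_rate expected background de novo CNVs per proband.
#' @param de_novo_len_range background de novo length range (bp).
#' @param planted_regions data.frame as [default_planted_regions()].
#' @param platform per-dataset degradation parameters, as
#'   [default_platform_params()].
#' @param genome chromosome map (chrom, length).
#' @param expression list: `n_samples` (RNA cohort size, default 55),
#'   `sigma_log2` (expression noise sd on the log2 scale), `tissues`
#'   (labels recycled over samples), `housekeeping_baseline` (named FPKM),
#'   `n_background_genes`.
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_trios = c(discovery = 100L, rep_wes = 200L,
                                          rep_wgs = 10L),
                              n_array = c(case = 75L, control = 75L),
                              frac_with_relative = 0.86,
                              sibling_prob = 0.1,
                              n_polymorphic_loci = 10L,
                              polymorphic_freq_range = c(0.05, 0.30),
                              polymorphic_len_range = c(2e4, 2e5),
                              de_novo_rate = 0.05,
                              de_novo_len_range = c(1e4, 5e5),
                              planted_regions = default_planted_regions(),
                              platform = default_platform_params(),
                              genome = default_genome(),
                              expression = list()) {
  expr_defaults <- list(n_samples = 55L, sigma_log2 = 0.5, tissues = "aorta",
                        housekeeping_baseline = c(G6PD = 40, ACTB = 1500),
                        n_background_genes = 10L)
  expression <- utils::modifyList(expr_defaults, expression)
  cfg <- list(seed = as.integer(seed), n_trios = n_trios, n_array = n_array,
              frac_with_relative = frac_with_relative,
              sibling_prob = sibling_prob,
              n_polymorphic_loci = as.integer(n_polymorphic_loci),
              polymorphic_freq_range = polymorphic_freq_range,
              polymorphic_len_range = polymorphic_len_range,
              de_novo_rate = de_novo_rate,
              de_novo_len_range = de_novo_len_range,
              planted_regions = planted_regions, platform = platform,
              genome = genome, expression = expression)
  probs <- c(frac_with_relative, sibling_prob, de_novo_rate,
             polymorphic_freq_range,
             unlist(lapply(platform, function(p)
               c(p$sensitivity, p$miscall_prob))))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(vapply(platform, `[[`, 0, "jitter_sd") < 0)) {
    stop("jitter sd must be nonnegative")
  }
  structure(cfg, class = "sim_config")
}

#' Noiseless variant of a simulation configuration
#'
#' Sets sensitivity 1, jitter 0, false-call rate 0 and miscall probability 0
#' on every dataset, so emitted calls equal the truth genotypes exactly.
#'
#' @param config a `sim_config` (default [simulation_config()] with `...`
#'   passed through).
#' @param ... forwarded to [simulation_config()].
#' @return modified `sim_config`.
#' @export
noiseless_config <- function(config = simulation_config(...), ...) {
  config$platform <- lapply(config$platform, function(p) {
    p$sensitivity <- 1; p$jitter_sd <- 0; p$false_rate <- 0
    p$miscall_prob <- 0; p
  })
  config
}

# Draw a random interval on the genome (length in bp range, log-uniform when
# log_len). Rejects overlap with `avoid` intervals.
random_interval <- function(genome, len_range, avoid = NULL, log_len = FALSE,
                            max_tries = 50L) {
  for (i in seq_len(max_tries)) {
    len <- if (log_len) {
      round(10^stats::runif(1, log10(len_range[1]), log10(len_range[2])))
    } else {
      round(stats::runif(1, len_range[1], len_range[2]))
    }
    ch <- sample(genome$chrom, 1L, prob = genome$length)
    maxs <- genome$length[genome$chrom == ch] - len
    if (maxs < 1) next
    s <- floor(stats::runif(1, 1, maxs))
    iv <- data.frame(chrom = ch, start = as.integer(s),
                     end = as.integer(s + len - 1L), stringsAsFactors = FALSE)
    if (is.null(avoid) || !nrow(avoid) || all(overlap_bp(avoid, iv) == 0L)) {
      return(iv)
    }
  }
  stop("could not place a random interval avoiding existing loci")
}

build_trio_members <- function(prefix, n, dataset, frac_with_relative,
                               sibling_prob) {
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fam <- sprintf("%s%04d", prefix, i)
    with_rel <- stats::runif(1) < frac_with_relative
    sib <- with_rel && stats::runif(1) < sibling_prob
    pro <- data.frame(family_id = fam, sample_id = paste0(fam, "-01"),
                      father_id = if (with_rel) paste0(fam, "-02") else "0",
                      mother_id = if (with_rel) paste0(fam, "-03") else "0",
                      sex = as.character(sample(1:2, 1L)), affected = 2L,
                      dataset = dataset, stringsAsFactors = FALSE)
    out <- pro
    if (with_rel) {
      out <- rbind(out,
        data.frame(family_id = fam, sample_id = paste0(fam, "-02"),
                   father_id = "0", mother_id = "0", sex = "1", affected = 1L,
                   dataset = dataset, stringsAsFactors = FALSE),
        data.frame(family_id = fam, sample_id = paste0(fam, "-03"),
                   father_id = "0", mother_id = "0", sex = "2", affected = 1L,
                   dataset = dataset, stringsAsFactors = FALSE))
      if (sib) {
        out <- rbind(out,
          data.frame(family_id = fam, sample_id = paste0(fam, "-04"),
                     father_id = paste0(fam, "-02"),
                     mother_id = paste0(fam, "-03"),
                     sex = as.character(sample(1:2, 1L)), affected = 1L,
                     dataset = dataset, stringsAsFactors = FALSE))
      }
    }
    rows[[i]] <- out
  }
  do.call(rbind, rows)
}

#' Simulate a multi-platform trio cohort with known truth
#'
#' Generates pedigrees for every dataset, transmits polymorphic CNV alleles
#' Mendelianly (each parental allele passed with probability 0.5), draws
#' background de novo events per proband, assigns planted-region carriers to
#' their rosters, degrades each dataset's calls per its platform parameters
#' (dropout, breakpoint jitter, type miscalls, injected false calls), and
#' writes call files in the dialect of each platform plus the pedigree,
#' knowledge-base and truth files. Deterministic given `config$seed`.
#'
#' @param config `sim_config` object.
#' @param out_dir output directory (created if needed).
#' @return list: `paths` (named: calls per dataset, pedigree, kb files,
#'   truth files), `truth` (list `events` = true genotype events incl.
#'   ungenotyped family members, `emitted` = per emitted call provenance
#'   with origin or `false_positive`), `pedigree`, `config`.
#' @export
simulate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(config$seed, simulate_cohort_impl(config, out_dir))
}

simulate_cohort_impl <- function(config, out_dir) {
  planted <- config$planted_regions
  planted_iv <- planted[, c("chrom", "start", "end")]

  ## pedigree ---------------------------------------------------------------
  members <- rbind(
    build_trio_members("D", config$n_trios[["discovery"]], "discovery",
                       config$frac_with_relative, config$sibling_prob),
    build_trio_members("R", config$n_trios[["rep_wes"]], "rep_wes",
                       config$frac_with_relative, config$sibling_prob),
    build_trio_members("W", config$n_trios[["rep_wgs"]], "rep_wgs",
                       1.0, 0.0))
  n_ac <- config$n_array[["case"]]; n_au <- config$n_array[["control"]]
  array_members <- if (n_ac + n_au == 0L) NULL else data.frame(
    family_id = sprintf("A%04d", seq_len(n_ac + n_au)),
    sample_id = sprintf("A%04d", seq_len(n_ac + n_au)),
    father_id = "0", mother_id = "0",
    sex = as.character(sample(1:2, n_ac + n_au, replace = TRUE)),
    affected = rep(c(2L, 1L), c(n_ac, n_au)),
    dataset = "rep_array", stringsAsFactors = FALSE)
  members <- rbind(members, array_members)

  ## polymorphic loci -------------------------------------------------------
  loci <- list()
  for (i in seq_len(config$n_polymorphic_loci)) {
    avoid <- rbind(planted_iv,
                   if (length(loci)) do.call(rbind, lapply(loci, `[`,
                     c("chrom", "start", "end"))))
    iv <- random_interval(config$genome, config$polymorphic_len_range,
                          avoid = avoid)
    iv$locus_id <- sprintf("L%02d", i)
    iv$freq <- stats::runif(1, config$polymorphic_freq_range[1],
                            config$polymorphic_freq_range[2])
    iv$cnv_type <- sample(c("DEL", "DUP"), 1L)
    loci[[i]] <- iv
  }
  loci <- if (length(loci)) do.call(rbind, loci) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               locus_id = character(0), freq = numeric(0),
               cnv_type = character(0))

  ## true genotype events ---------------------------------------------------
  events <- list()
  add_event <- function(dataset, family_id, sample_id, role, genotyped,
                        chrom, start, end, cnv_type, origin, de_novo) {
    events[[length(events) + 1L]] <<- data.frame(
      dataset = dataset, family_id = family_id, sample_id = sample_id,
      role = role, genotyped = genotyped, chrom = chrom, start = start,
      end = end, cnv_type = cnv_type, origin = origin, de_novo = de_novo,
      stringsAsFactors = FALSE)
  }

  # polymorphic transmission, family by family
  fams <- unique(members$family_id)
  member_by_fam <- split(members, members$family_id)[fams]
  for (fam in fams) {
    fm <- member_by_fam[[fam]]
    ds <- fm$dataset[1L]
    for (j in seq_len(nrow(loci))) {
      f <- loci$freq[j]
      if (startsWith(fam, "A")) {
        a <- stats::rbinom(1L, 2L, f)
        if (a >= 1L) add_event(ds, fam, fm$sample_id[1L], "founder", TRUE,
                               loci$chrom[j], loci$start[j], loci$end[j],
                               loci$cnv_type[j], paste0("polymorphic:",
                               loci$locus_id[j]), FALSE)
        next
      }
      # trio family: parents always exist genetically; emit their events
      # only if genotyped
      a_f <- stats::rbinom(1L, 2L, f)
      a_m <- stats::rbinom(1L, 2L, f)
      father_id <- paste0(fam, "-02"); mother_id <- paste0(fam, "-03")
      genotyped_parents <- father_id %in% fm$sample_id
      if (a_f >= 1L) add_event(ds, fam, father_id, "father",
                               genotyped_parents, loci$chrom[j],
                               loci$start[j], loci$end[j], loci$cnv_type[j],
                               paste0("polymorphic:", loci$locus_id[j]), FALSE)
      if (a_m >= 1L) add_event(ds, fam, mother_id, "mother",
                               genotyped_parents, loci$chrom[j],
                               loci$start[j], loci$end[j], loci$cnv_type[j],
                               paste0("polymorphic:", loci$locus_id[j]), FALSE)
      children <- fm$sample_id[!(fm$sample_id %in% c(father_id, mother_id))]
      for (child in children) {
        a_c <- stats::rbinom(1L, a_f, 0.5) + stats::rbinom(1L, a_m, 0.5)
        if (a_c >= 1L) {
          role <- if (endsWith(child, "-01")) "proband" else "sibling"
          add_event(ds, fam, child, role, TRUE, loci$chrom[j], loci$start[j],
                    loci$end[j], loci$cnv_type[j],
                    paste0("polymorphic:", loci$locus_id[j]), FALSE)
        }
      }
    }
  }

  # background de novo events per affected proband
  probands <- members[members$affected == 2L, , drop = FALSE]
  avoid_all <- rbind(planted_iv, loci[, c("chrom", "start", "end")])
  for (i in seq_len(nrow(probands))) {
    n_ev <- stats::rpois(1L, config$de_novo_rate)
    for (e in seq_len(n_ev)) {
      iv <- random_interval(config$genome, config$de_novo_len_range,
                            avoid = avoid_all, log_len = TRUE)
      add_event(probands$dataset[i], probands$family_id[i],
                probands$sample_id[i], "proband", TRUE, iv$chrom, iv$start,
                iv$end, sample(c("DEL", "DUP"), 1L), "de_novo_background",
                TRUE)
    }
  }

  # planted case-only regions with rostered carriers
  for (r in seq_len(nrow(planted))) {
    for (ds in COHORTS) {
      n_car <- planted[[paste0("n_", ds)]][r]
      if (is.null(n_car) || n_car == 0L) next
      pool <- probands$sample_id[probands$dataset == ds]
      if (n_car > length(pool)) stop("planted carrier roster exceeds cohort")
      carriers <- sort(sample(pool, n_car))
      for (s in carriers) {
        add_event(ds, members$family_id[members$sample_id == s], s,
                  "proband", TRUE, planted$chrom[r], planted$start[r],
                  planted$end[r], planted$cnv_type[r],
                  paste0("planted:", planted$planted_id[r]), TRUE)
      }
    }
  }

  events <- do.call(rbind, events)
  o <- order(events$dataset, events$sample_id, chrom_rank(events$chrom),
             events$start, events$end, events$origin)
  events <- events[o, , drop = FALSE]
  rownames(events) <- NULL

  ## platform degradation and emission --------------------------------------
  emitted <- list()
  calls_by_ds <- list()
  for (ds in COHORTS) {
    pp <- config$platform[[ds]]
    ev <- events[events$dataset == ds & events$genotyped, , drop = FALSE]
    keep <- stats::runif(nrow(ev)) < pp$sensitivity
    ev <- ev[keep, , drop = FALSE]
    n <- nrow(ev)
    if (n) {
      if (pp$jitter_sd > 0) {
        s2 <- ev$start + as.integer(round(stats::rnorm(n, 0, pp$jitter_sd)))
        e2 <- ev$end + as.integer(round(stats::rnorm(n, 0, pp$jitter_sd)))
        s2 <- pmax(1L, s2)
        e2 <- pmax(e2, s2 + 1L)
        ev$start <- s2; ev$end <- e2
      }
      flip <- stats::runif(n) < pp$miscall_prob
      ev$cnv_type[flip] <- ifelse(ev$cnv_type[flip] == "DEL", "DUP", "DEL")
    }
    # injected false calls
    ds_samples <- members$sample_id[members$dataset == ds]
    fp <- list()
    for (s in ds_samples) {
      for (e in seq_len(stats::rpois(1L, pp$false_rate))) {
        iv <- random_interval(config$genome, c(1e3, 1e6), log_len = TRUE)
        fp[[length(fp) + 1L]] <- data.frame(
          dataset = ds, family_id = members$family_id[members$sample_id == s],
          sample_id = s, role = NA_character_, genotyped = TRUE,
          chrom = iv$chrom, start = iv$start, end = iv$end,
          cnv_type = sample(c("DEL", "DUP"), 1L), origin = "false_positive",
          de_novo = FALSE, stringsAsFactors = FALSE)
      }
    }
    ev <- rbind(ev, if (length(fp)) do.call(rbind, fp))
    if (nrow(ev)) {
      o <- order(ev$sample_id, chrom_rank(ev$chrom), ev$start, ev$end,
                 ev$cnv_type, ev$origin)
      ev <- ev[o, , drop = FALSE]
      # de-duplicate on the emitted join key so truth joins are unambiguous
      key <- paste(ev$sample_id, ev$chrom, ev$start, ev$end, ev$cnv_type)
      ev <- ev[!duplicated(key), , drop = FALSE]
    }
    quality <- if (nrow(ev)) round(stats::runif(nrow(ev), 60, 99), 2) else numeric(0)
    support <- if (nrow(ev)) {
      ifelse(ev$origin == "false_positive",
             sprintf("%.3f", stats::runif(nrow(ev), 0.3, 1)),
             sprintf("%.3f", stats::runif(nrow(ev), 0.5, 1)))
    } else character(0)
    calls_by_ds[[ds]] <- data.frame(
      call_id = if (nrow(ev)) sprintf("%s_tmp%05d", ds, seq_len(nrow(ev)))
                else character(0),
      sample_id = ev$sample_id, chrom = ev$chrom, start = ev$start,
      end = ev$end, cnv_type = ev$cnv_type, quality = quality,
      support = support, stringsAsFactors = FALSE)
    emitted[[ds]] <- ev
  }
  emitted <- do.call(rbind, emitted)
  rownames(emitted) <- NULL

  ## write files ------------------------------------------------------------
  paths <- list(
    discovery = file.path(out_dir, "discovery.xcnv"),
    rep_wes = file.path(out_dir, "rep_wes.xcnv"),
    rep_array = file.path(out_dir, "rep_array.rawcnv"),
    rep_wgs = file.path(out_dir, "rep_wgs.svbed"),
    pedigree = file.path(out_dir, "pedigree.ped"),
    chd_bed = file.path(out_dir, "kb_chd.bed"),
    dgv_bed = file.path(out_dir, "kb_dgv.bed"),
    genes_bed = file.path(out_dir, "genes.bed"),
    expressed_list = file.path(out_dir, "heart_genes.txt"),
    truth_events = file.path(out_dir, "truth_events.tsv"),
    truth_emitted = file.path(out_dir, "truth_emitted.tsv"))

  dialects <- c(discovery = "xcnv", rep_wes = "xcnv", rep_array = "rawcnv",
                rep_wgs = "svbed")
  for (ds in COHORTS) {
    df <- calls_by_ds[[ds]]
    df$cohort <- rep(ds, nrow(df))
    df$platform <- rep(c(xcnv = "wes", rawcnv = "array",
                         svbed = "wgs")[[dialects[[ds]]]], nrow(df))
    write_calls(as_cnv_calls(df), paths[[ds]], dialects[[ds]])
  }
  ped <- structure(list(members = members), class = "pedigree")
  write_pedigree(ped, paths$pedigree)

  # knowledge bases: common catalogue = polymorphic loci + spares; known
  # disease loci kept off the planted regions; heart list = planted genes
  write_bed4 <- function(df, names, path) {
    writeLines(sprintf("%s\t%d\t%d\t%s", df$chrom, df$start - 1L, df$end,
                       names), path)
  }
  chd <- data.frame(chrom = c("chr1", "chr3"),
                    start = c(30000001L, 40000001L),
                    end = c(32000000L, 41000000L), stringsAsFactors = FALSE)
  write_bed4(chd, sprintf("CHD_KNOWN_%02d", seq_len(nrow(chd))), paths$chd_bed)
  dgv_extra <- data.frame(chrom = c("chr1", "chr2", "chr3"),
                          start = c(80000001L, 1000001L, 60000001L),
                          end = c(80500000L, 1500000L, 60500000L),
                          stringsAsFactors = FALSE)
  dgv <- rbind(loci[, c("chrom", "start", "end")], dgv_extra)
  write_bed4(dgv, sprintf("DGV_%02d", seq_len(nrow(dgv))), paths$dgv_bed)
  gm <- default_gene_models()
  write_bed4(gm[, c("chrom", "start", "end")], gm$gene, paths$genes_bed)
  writeLines(sort(unique(planted$gene)), paths$expressed_list)

  fmt_truth <- function(df) {
    c(paste(names(df), collapse = "\t"),
      do.call(paste, c(lapply(df, as.character), sep = "\t")))
  }
  writeLines(fmt_truth(events), paths$truth_events)
  writeLines(fmt_truth(emitted), paths$truth_emitted)

  list(paths = paths, truth = list(events = events, emitted = emitted,
                                   polymorphic_loci = loci),
       pedigree = ped, config = config)
}

#' Simulate the RNA validation dataset
#'
#' Expression for the planted genes is dosage-dependent:
#' `log2 FPKM ~ Normal(log2(baseline * dosage^carrier), sigma_log2)` per
#' sample, with housekeeping genes at fixed baselines and a quarter of the
#' noise. Samples are the first `n_samples` discovery probands; carrier
#' status comes from the simulation truth.
#'
#' @param config `sim_config`.
#' @param truth truth list from [simulate_cohort()].
#' @param out_dir output directory.
#' @return list: `paths` (matrix, tissue_map), `em` (`expr_matrix`),
#'   `carriers` (named list gene -> carrier sample IDs among RNA samples).
#' @export
simulate_expression <- function(config, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(derive_seed(config$seed, "expression"), {
    ex <- config$expression
    ev <- truth$events
    # RNA roster: the first n_samples discovery probands (deterministic IDs)
    n_rna <- min(ex$n_samples, config$n_trios[["discovery"]])
    samples <- sprintf("D%04d-01", seq_len(n_rna))
    planted <- config$planted_regions
    genes <- c(planted$gene, names(ex$housekeeping_baseline),
               sprintf("BG%03d", seq_len(ex$n_background_genes)))
    baseline <- c(2^stats::runif(nrow(planted), 3, 6),
                  unname(ex$housekeeping_baseline),
                  2^stats::runif(ex$n_background_genes, 2, 7))
    names(baseline) <- genes
    sigma <- rep(ex$sigma_log2, length(genes))
    names(sigma) <- genes
    sigma[names(ex$housekeeping_baseline)] <- ex$sigma_log2 / 4
    carriers <- lapply(seq_len(nrow(planted)), function(r) {
      id <- paste0("planted:", planted$planted_id[r])
      intersect(samples, ev$sample_id[ev$origin == id])
    })
    names(carriers) <- planted$gene
    fpkm <- matrix(0, nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
    for (g in genes) {
      dose <- rep(1, length(samples))
      r <- match(g, planted$gene)
      if (!is.na(r)) dose[samples %in% carriers[[g]]] <- planted$dosage[r]
      mu <- log2(baseline[[g]] * dose)
      fpkm[g, ] <- 2^(mu + stats::rnorm(length(samples), 0, sigma[[g]]))
    }
    tissue <- stats::setNames(rep_len(ex$tissues, length(samples)), samples)
    em <- expression_matrix(fpkm, tissue,
                            housekeeping = names(ex$housekeeping_baseline))
    paths <- list(matrix = file.path(out_dir, "expression_fpkm.tsv"),
                  tissue_map = file.path(out_dir, "tissue_map.tsv"))
    write_expression(em, paths$matrix, paths$tissue_map)
    list(paths = paths, em = em, carriers = carriers)
  })
}
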