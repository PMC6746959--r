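#' Build a pipeline configuration
#'
#' @param calls named list per dataset (`discovery`, `rep_wes`, `rep_array`,
#'   `rep_wgs`), each a list with `path` and `dialect`; `discovery` is
#'   required.
#' @param pedigree path to the pedigree file.
#' @param kb named list of knowledge-base paths: `chd_bed`, `dgv_bed`,
#'   `genes_bed`, `expressed_list`.
#' @param expression optional list with `matrix` and `tissue_map` paths;
#'   NULL disables the expression stage.
#' @param rho reciprocal-overlap threshold for the de novo / control screens
#'   (default 0.5).
#' @param rho_rep reciprocal-overlap threshold for replication matching
#'   (default 0.25, looser: replication platforms differ in breakpoint
#'   resolution and may call the opposite type at a shared locus).
#' @param f_kb one-way coverage threshold for the knowledge screens.
#' @param n_perm permutations per region.
#' @param seed master seed (per-region streams are derived from it).
#' @param build free-text genome build tag echoed into outputs.
#' @param out_dir output directory.
#' @param invert_criterion2 see [relevance_flags()].
#' @param quiet suppress stderr progress lines.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(calls, pedigree, kb, expression = NULL,
                            rho = 0.5, rho_rep = 0.25, f_kb = 0.5,
                            n_perm = 2000L, seed = 1L, build = "unspecified",
                            out_dir = tempfile("cnvtrio_run_"),
                            invert_criterion2 = FALSE, quiet = TRUE) {
  stopifnot(rho > 0, rho <= 1, rho_rep > 0, rho_rep <= 1,
            f_kb >= 0, f_kb <= 1, n_perm >= 1)
  if (is.null(calls$discovery)) stop("a discovery call set is required")
  structure(list(calls = calls, pedigree = pedigree, kb = kb,
                 expression = expression, rho = rho, rho_rep = rho_rep,
                 f_kb = f_kb, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), build = build, out_dir = out_dir,
                 invert_criterion2 = invert_criterion2, quiet = quiet),
            class = "pipeline_config")
}

#' Pipeline configuration for a simulated cohort
#'
#' Convenience wrapper wiring the file paths produced by
#' [simulate_cohort()] (and optionally [simulate_expression()]) into a
#' [pipeline_config()].
#'
#' @param sim result of [simulate_cohort()].
#' @param expr optional result of [simulate_expression()].
#' @param ... further arguments to [pipeline_config()].
#' @return `pipeline_config` object.
#' @export
pipeline_config_from_simulation <- function(sim, expr = NULL, ...) {
  p <- sim$paths
  pipeline_config(
    calls = list(discovery = list(path = p$discovery, dialect = "xcnv"),
                 rep_wes = list(path = p$rep_wes, dialect = "xcnv"),
                 rep_array = list(path = p$rep_array, dialect = "rawcnv"),
                 rep_wgs = list(path = p$rep_wgs, dialect = "svbed")),
    pedigree = p$pedigree,
    kb = list(chd_bed = p$chd_bed, dgv_bed = p$dgv_bed,
              genes_bed = p$genes_bed, expressed_list = p$expressed_list),
    expression = if (!is.null(expr)) list(matrix = expr$paths$matrix,
                                          tissue_map = expr$paths$tissue_map),
    build = "synthetic-1", ...)
}

# Deterministic run log: no wall-clock content, so reruns are byte-identical.
make_logger <- function(path, quiet) {
  lines <- character(0)
  log <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    lines[[length(lines) + 1L]] <<- line
    if (!quiet) message(line)
  }
  flush <- function() writeLines(unlist(lines), path)
  list(log = log, flush = flush)
}

#' Run the four-layer CNV target-discovery pipeline
#'
#' Stages, in order: parse all inputs; layer 1, de novo classification
#' against genotyped relatives and removal of calls present in independent
#' family controls; layer 2, replication matching across the independent
#' datasets with control veto; single-linkage merging into recurrent
#' regions; layer 3, gene mapping and knowledge-base relevance flags (plus
#' the catalogue-novel de novo list); carrier-asymmetry permutation tests;
#' layer 4, carrier vs non-carrier expression contrasts for target genes.
#' Surviving call counts are checked to be non-increasing across filter
#' stages, and every proband call receives a terminal pass/drop trace
#' record.
#'
#' @param config [pipeline_config()] object.
#' @return list of class `pipeline_result`: `regions` (all merged de novo
#'   regions with annotation and statistics), `targets` (supported and
#'   relevant subset), `dgv_novel`, `contrasts`, `trace`, `counts` (named
#'   stage counts), `paths` (output files: regions.tsv, targets.tsv,
#'   dgv_novel.tsv, contrasts.tsv, trace.tsv, run.log).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  lg <- make_logger(file.path(config$out_dir, "run.log"), config$quiet)
  lg$log("config", sprintf(
    "rho=%g rho_rep=%g f_kb=%g n_perm=%d seed=%d build=%s invert_criterion2=%s",
    config$rho, config$rho_rep, config$f_kb, config$n_perm, config$seed,
    config$build, config$invert_criterion2))

  ## parse ------------------------------------------------------------------
  ped <- read_pedigree(config$pedigree)
  call_sets <- list()
  trace <- list()
  for (ds in intersect(COHORTS, names(config$calls))) {
    spec <- config$calls[[ds]]
    cs <- read_calls(spec$path, spec$dialect, cohort = ds, pedigree = ped)
    rej <- attr(cs, "rejected")
    lg$log("parse", sprintf("%s: %d calls, %d rejected lines", ds, nrow(cs),
                            nrow(rej)))
    if (nrow(rej)) {
      trace[[paste0("rej_", ds)]] <- trace_rows(
        sprintf("%s_line%d", ds, rej$line), "parse", "drop", rej$reason)
    }
    call_sets[[ds]] <- cs
  }
  kb <- read_knowledge_base(config$kb$chd_bed, config$kb$dgv_bed,
                            config$kb$genes_bed, config$kb$expressed_list)
  disc <- call_sets$discovery
  pro_calls <- disc[!is.na(disc$role) & disc$role == "proband", , drop = FALSE]
  trace[["parsed"]] <- trace_rows(sort_calls(pro_calls)$call_id, "parse",
                                  "pass", "parsed")
  counts <- c(proband_calls = nrow(pro_calls))
  lg$log("parse", sprintf("discovery proband calls: %d", nrow(pro_calls)))

  ## layer 1: de novo + independent controls --------------------------------
  l1 <- filter_inherited(disc, ped, rho = config$rho)
  trace[["inheritance"]] <- l1$trace
  counts["de_novo"] <- nrow(l1$de_novo)
  lg$log("inheritance", sprintf(
    "de novo %d, inherited %d, unclassified %d", nrow(l1$de_novo),
    sum(l1$verdicts$verdict == "inherited"),
    sum(l1$verdicts$verdict == "unclassified")))
  l1c <- filter_controls(l1$de_novo, disc, rho = config$rho)
  trace[["control"]] <- l1c$trace
  counts["after_control_filter"] <- nrow(l1c$surviving)
  lg$log("control_filter", sprintf("surviving %d", nrow(l1c$surviving)))

  ## layer 2: replication with control veto ---------------------------------
  rep_sets <- call_sets[intersect(c("rep_wes", "rep_array", "rep_wgs"),
                                  names(call_sets))]
  l2 <- replicate_calls(l1c$surviving, rep_sets, rho_rep = config$rho_rep,
                        discovery_samples = unique(disc$sample_id))
  trace[["replication"]] <- l2$trace
  counts["supported_calls"] <- nrow(l2$supported)
  lg$log("replication", sprintf("supported %d of %d (+%d supporting calls)",
                                nrow(l2$supported), nrow(l1c$surviving),
                                nrow(l2$support_calls)))

  ## merge: all layer-1 survivors form the de novo region set; supported
  ## regions additionally carry their replication support calls
  regions <- merge_recurrent(rbind(l1c$surviving, l2$support_calls))
  membership <- attr(regions, "membership")
  ev <- l2$evidence
  agg_ev <- function(region_members, col) {
    ids <- unlist(strsplit(ev[[col]][ev$call_id %in% region_members], ","))
    join_ids(unique(ids[ids != "."]))
  }
  mem_list <- strsplit(regions$member_call_ids, ",")
  regions$de_novo <- rep(TRUE, nrow(regions))
  regions$rep_wes_support <- vapply(mem_list, agg_ev, "", col = "rep_wes")
  regions$rep_array_support <- vapply(mem_list, agg_ev, "", col = "rep_array")
  regions$rep_wgs_support <- vapply(mem_list, agg_ev, "", col = "rep_wgs")
  regions$veto_calls <- vapply(mem_list, agg_ev, "", col = "veto")
  has_support <- (regions$rep_wes_support != "." |
                    regions$rep_array_support != "." |
                    regions$rep_wgs_support != ".")
  regions$supported <- has_support & regions$veto_calls == "."
  counts["regions"] <- nrow(regions)
  counts["supported_regions"] <- sum(regions$supported)
  lg$log("merge", sprintf("%d regions, %d supported", nrow(regions),
                          sum(regions$supported)))

  ## layer 3: knowledge-base annotation -------------------------------------
  regions <- annotate_regions(regions, kb, f_kb = config$f_kb,
                              invert_criterion2 = config$invert_criterion2)
  dgv_novel <- dgv_novel_de_novo(regions, kb, f_kb = config$f_kb)
  counts["relevant_supported"] <- sum(regions$supported & regions$relevant)
  counts["dgv_novel"] <- nrow(dgv_novel)
  lg$log("annotate", sprintf(
    "%d supported+relevant targets; %d catalogue-novel de novo regions (%d recurrent)",
    counts[["relevant_supported"]], nrow(dgv_novel), sum(dgv_novel$recurrent)))

  ## permutation tests -------------------------------------------------------
  m <- ped$members
  null_pop <- m[m$dataset %in% c("discovery", "rep_wes"), , drop = FALSE]
  n_case <- sum(null_pop$role == "proband")
  n_control <- sum(null_pop$role != "proband")
  regions <- test_regions(regions, n_case, n_control, n_perm = config$n_perm,
                          seed = config$seed)
  lg$log("test", sprintf("null population %d cases / %d controls, %d perms",
                         n_case, n_control, config$n_perm))

  ## layer 4: expression contrasts ------------------------------------------
  contrasts <- contrasts_table(list())
  if (!is.null(config$expression)) {
    em <- read_expression(config$expression$matrix,
                          config$expression$tissue_map)
    em <- housekeeping_normalize(em)
    targets <- regions[regions$supported & regions$relevant, , drop = FALSE]
    ct_list <- list()
    rid_list <- character(0)
    all_calls <- rbind(disc, do.call(rbind, c(rep_sets, list(empty_calls()))))
    for (i in seq_len(nrow(targets))) {
      mem <- strsplit(targets$member_call_ids[i], ",")[[1]]
      car_samples <- unique(all_calls$sample_id[all_calls$call_id %in% mem])
      car_rna <- intersect(car_samples, colnames(em$fpkm))
      if (!length(car_rna)) next
      genes <- strsplit(targets$genes[i], ",")[[1]]
      genes <- intersect(genes, rownames(em$fpkm))
      for (g in genes) {
        for (ti in unique(em$tissue[car_rna])) {
          non <- setdiff(colnames(em$fpkm)[em$tissue == ti], car_rna)
          if (!length(non)) next
          ct_list[[length(ct_list) + 1L]] <-
            compare_expression(g, ti, car_rna, em)
          rid_list <- c(rid_list, targets$region_id[i])
        }
      }
    }
    contrasts <- contrasts_table(ct_list, rid_list)
    lg$log("express", sprintf("%d contrasts computed", nrow(contrasts)))
  }

  ## assemble, check invariants, write ---------------------------------------
  trace <- do.call(rbind, trace)
  rownames(trace) <- NULL
  stage_counts <- c(counts[["proband_calls"]], counts[["de_novo"]],
                    counts[["after_control_filter"]],
                    counts[["supported_calls"]])
  if (any(diff(stage_counts) > 0)) {
    stop("filter-stage monotonicity violated: ",
         paste(stage_counts, collapse = " -> "))
  }
  pro_ids <- pro_calls$call_id
  tr_pro <- trace[trace$call_id %in% pro_ids, , drop = FALSE]
  terminal <- vapply(split(tr_pro$decision, tr_pro$call_id),
                     function(d) d[length(d)], "")
  if (!setequal(names(terminal), pro_ids)) {
    stop("trace completeness violated: some proband calls have no trace record")
  }
  lg$log("summary", sprintf(
    "counts: %s", paste(sprintf("%s=%d", names(counts), counts),
                        collapse = " ")))

  paths <- list(regions = file.path(config$out_dir, "regions.tsv"),
                targets = file.path(config$out_dir, "targets.tsv"),
                dgv_novel = file.path(config$out_dir, "dgv_novel.tsv"),
                contrasts = file.path(config$out_dir, "contrasts.tsv"),
                trace = file.path(config$out_dir, "trace.tsv"),
                log = file.path(config$out_dir, "run.log"))
  write_regions(regions, paths$regions, build = config$build)
  write_regions(regions[regions$supported & regions$relevant, , drop = FALSE],
                paths$targets, build = config$build)
  write_regions(complete_regions(dgv_novel), paths$dgv_novel,
                build = config$build)
  write_contrasts(contrasts, paths$contrasts)
  write_trace(trace, paths$trace)
  lg$flush()
  structure(list(regions = regions,
                 targets = regions[regions$supported & regions$relevant, ,
                                   drop = FALSE],
                 dgv_novel = dgv_novel, contrasts = contrasts, trace = trace,
                 counts = counts, paths = paths, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("cnvtrio pipeline result\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}
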