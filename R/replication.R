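#' Match a discovery call against the replication datasets
#'
#' Supporting evidence is any replication *proband* call reaching reciprocal
#' overlap `rho_rep` (type-agnostic: a partial-span duplication can replicate
#' a deletion locus). Veto evidence is any replication *control* call
#' (family controls or unrelated array controls) reaching the same threshold,
#' in any replication dataset. A call is `supported` when at least one
#' dataset supports it and nothing vetoes it.
#'
#' @param call one-row call set (a discovery survivor).
#' @param replication_calls named list of call sets, names among `rep_wes`,
#'   `rep_array`, `rep_wgs`.
#' @param rho_rep reciprocal-overlap threshold; default 0.25, looser than the
#'   de novo screen because replication platforms have different breakpoint
#'   resolution.
#' @param discovery_samples optional character vector of discovery sample
#'   IDs; any replication sample also present there violates the
#'   mutual-exclusivity contract and is fatal.
#' @return list: `call_id`, `supporting` (named list of call_id vectors per
#'   dataset), `veto` (character), `supported` (logical).
#' @export
match_replication <- function(call, replication_calls, rho_rep = 0.25,
                              discovery_samples = NULL) {
  stopifnot(nrow(call) == 1L, rho_rep > 0, rho_rep <= 1)
  if (!is.null(discovery_samples)) {
    for (ds in names(replication_calls)) {
      clash <- intersect(replication_calls[[ds]]$sample_id, discovery_samples)
      if (length(clash)) {
        stop("replication dataset ", ds,
             " shares samples with discovery (cohorts must be mutually exclusive): ",
             paste(utils::head(clash, 5), collapse = ", "))
      }
    }
  }
  supporting <- list()
  veto <- character(0)
  for (ds in names(replication_calls)) {
    rc <- replication_calls[[ds]]
    hits <- overlap_pairs(call, rc, min_frac = rho_rep, mode = "reciprocal")
    hit_calls <- rc[hits$s, , drop = FALSE]
    is_pro <- !is.na(hit_calls$role) & hit_calls$role == "proband"
    supporting[[ds]] <- sort(hit_calls$call_id[is_pro])
    veto <- c(veto, hit_calls$call_id[!is_pro])
  }
  list(call_id = call$call_id, supporting = supporting, veto = sort(veto),
       supported = any(lengths(supporting) > 0) && length(veto) == 0L)
}

#' Layer-2 replication screen over the discovery survivors
#'
#' Runs [match_replication()] per call, drops vetoed and unsupported calls
#' (the target list requires support from at least one replication dataset
#' and absence from every replication control), and returns the supporting
#' replication proband calls for region merging.
#'
#' @param calls discovery survivors.
#' @param replication_calls named list of replication call sets.
#' @param rho_rep reciprocal-overlap threshold.
#' @param discovery_samples discovery sample IDs (mutual-exclusivity check).
#' @return list: `supported` (surviving discovery calls), `support_calls`
#'   (replication proband calls backing them), `evidence` (data.frame per
#'   discovery call), `trace` (stage `replication` rows).
#' @export
replicate_calls <- function(calls, replication_calls, rho_rep = 0.25,
                            discovery_samples = NULL) {
  calls <- sort_calls(calls)
  ev <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ev[[i]] <- match_replication(calls[i, , drop = FALSE], replication_calls,
                                 rho_rep = rho_rep,
                                 discovery_samples = discovery_samples)
  }
  get_ds <- function(e, ds) {
    v <- e$supporting[[ds]]
    if (is.null(v)) character(0) else v
  }
  evidence <- data.frame(
    call_id = vapply(ev, `[[`, "", "call_id"),
    rep_wes = vapply(ev, function(e) join_ids(get_ds(e, "rep_wes")), ""),
    rep_array = vapply(ev, function(e) join_ids(get_ds(e, "rep_array")), ""),
    rep_wgs = vapply(ev, function(e) join_ids(get_ds(e, "rep_wgs")), ""),
    veto = vapply(ev, function(e) join_ids(e$veto), ""),
    supported = vapply(ev, `[[`, NA, "supported"),
    stringsAsFactors = FALSE)
  if (!nrow(calls)) {
    evidence <- data.frame(call_id = character(0), rep_wes = character(0),
                           rep_array = character(0), rep_wgs = character(0),
                           veto = character(0), supported = logical(0))
  }
  vetoed <- evidence$veto != "."
  reason <- ifelse(vetoed, "replication_control_veto",
                   ifelse(evidence$supported, "replicated",
                          "no_replication_support"))
  trace <- trace_rows(evidence$call_id, "replication",
                      ifelse(evidence$supported, "pass", "drop"), reason,
                      ifelse(vetoed, evidence$veto, apply(
                        cbind(evidence$rep_wes, evidence$rep_array,
                              evidence$rep_wgs), 1L,
                        function(r) join_ids(unlist(strsplit(r[r != "."], ","))))))
  support_ids <- unique(unlist(lapply(ev[evidence$supported], function(e) {
    unlist(e$supporting, use.names = FALSE)
  })))
  all_rep <- do.call(rbind, replication_calls)
  support_calls <- if (length(support_ids)) {
    sort_calls(all_rep[all_rep$call_id %in% support_ids, , drop = FALSE])
  } else {
    empty_calls()
  }
  rownames(support_calls) <- NULL
  list(supported = calls[evidence$supported, , drop = FALSE],
       support_calls = support_calls, evidence = evidence, trace = trace)
}

#' Merge calls into recurrent regions by single-linkage overlap
#'
#' Calls on the same chromosome sharing at least one base are linked; regions
#' are the connected components (transitive closure) of that relation, with
#' the region interval being the union span of its members. Region IDs are
#' the span itself (`chr:start-end`), so they are deterministic and
#' independent of input order. Carrier counts are distinct samples, never
#' calls: case carriers are probands, control carriers everything else.
#'
#' @param calls call set (typically surviving discovery calls plus their
#'   supporting replication calls).
#' @return regions data.frame: region_id, chrom, start, end, cnv_types
#'   (sorted, "/"-joined), member_call_ids (comma-joined, coordinate-sorted),
#'   n_case_carriers, n_control_carriers; attribute `membership` maps
#'   call_id to region_id.
#' @export
merge_recurrent <- function(calls) {
  calls <- sort_calls(calls)
  if (!nrow(calls)) {
    out <- data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      cnv_types = character(0), member_call_ids = character(0),
                      n_case_carriers = integer(0),
                      n_control_carriers = integer(0),
                      stringsAsFactors = FALSE)
    attr(out, "membership") <- data.frame(call_id = character(0),
                                          region_id = character(0))
    return(out)
  }
  # sweep per chromosome: after coordinate sort, a call starts a new
  # component iff it begins after the running max end (>=1 bp overlap links)
  comp <- integer(nrow(calls))
  comp_n <- 0L
  for (ch in unique(calls$chrom)) {
    idx <- which(calls$chrom == ch)
    max_end <- -1L
    for (i in idx) {
      if (calls$start[i] > max_end) {
        comp_n <- comp_n + 1L
        max_end <- calls$end[i]
      } else {
        max_end <- max(max_end, calls$end[i])
      }
      comp[i] <- comp_n
    }
  }
  comp_ids <- sort(unique(comp))
  rows <- lapply(comp_ids, function(ci) {
    mem <- calls[comp == ci, , drop = FALSE]
    is_case <- !is.na(mem$role) & mem$role == "proband"
    data.frame(
      region_id = sprintf("%s:%d-%d", mem$chrom[1L], min(mem$start), max(mem$end)),
      chrom = mem$chrom[1L], start = min(mem$start), end = max(mem$end),
      cnv_types = paste(sort(unique(mem$cnv_type)), collapse = "/"),
      member_call_ids = paste(mem$call_id, collapse = ","),
      n_case_carriers = length(unique(mem$sample_id[is_case])),
      n_control_carriers = length(unique(mem$sample_id[!is_case])),
      stringsAsFactors = FALSE)
  })
  regions <- do.call(rbind, rows)
  region_by_comp <- stats::setNames(regions$region_id, comp_ids)
  membership <- data.frame(call_id = calls$call_id,
                           region_id = unname(region_by_comp[as.character(comp)]),
                           stringsAsFactors = FALSE)
  o <- order(chrom_rank(regions$chrom), regions$chrom, regions$start, regions$end)
  regions <- regions[o, , drop = FALSE]
  rownames(regions) <- NULL
  attr(regions, "membership") <- membership
  regions
}
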