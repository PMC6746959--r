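#' Classify a proband call as de novo, inherited, or unclassified
#'
#' A proband call is `inherited` when any call from a genotyped first-degree
#' relative (parent or sibling of the same family) reaches reciprocal overlap
#' `rho`, irrespective of DEL/DUP type: an overlapping parental duplication
#' blocks certification of a proband deletion, the conservative choice for a
#' de novo screen. It is `de_novo` when relatives are genotyped and none
#' matches, and `unclassified` when the family has no genotyped relatives at
#' all (such calls are excluded from the de novo channel but kept in the
#' trace).
#'
#' @param proband_call one-row call set.
#' @param relative_calls call set restricted to the proband's own family
#'   (parents/siblings); a call from another family is a contract violation.
#' @param rho reciprocal-overlap threshold in (0, 1\]; default 0.5.
#' @param n_relatives number of genotyped relatives; defaults to the number
#'   of distinct samples in `relative_calls` (callers with pedigree knowledge
#'   should pass the true count so that relatives without calls still yield a
#'   `de_novo` verdict).
#' @return list with `call_id`, `verdict`, `matching_relative_calls`
#'   (character), `max_relative_overlap`.
#' @export
classify_inheritance <- function(proband_call, relative_calls, rho = 0.5,
                                 n_relatives = NULL) {
  stopifnot(nrow(proband_call) == 1L, rho > 0, rho <= 1)
  if (is.null(n_relatives)) {
    n_relatives <- length(unique(relative_calls$sample_id))
  }
  if (nrow(relative_calls) &&
      any(relative_calls$family_id != proband_call$family_id)) {
    stop("relative_calls contains calls from a different family than ",
         proband_call$family_id)
  }
  if (n_relatives == 0L) {
    return(list(call_id = proband_call$call_id, verdict = "unclassified",
                matching_relative_calls = character(0),
                max_relative_overlap = 0))
  }
  if (nrow(relative_calls) == 0L) {
    return(list(call_id = proband_call$call_id, verdict = "de_novo",
                matching_relative_calls = character(0),
                max_relative_overlap = 0))
  }
  ro <- reciprocal_overlap(relative_calls, proband_call)
  hit <- ro >= rho
  list(call_id = proband_call$call_id,
       verdict = if (any(hit)) "inherited" else "de_novo",
       matching_relative_calls = sort(relative_calls$call_id[hit]),
       max_relative_overlap = max(c(0, ro)))
}

#' Layer-1 de novo screen over a discovery cohort
#'
#' Applies [classify_inheritance()] to every proband call in `calls`, using
#' the pedigree to determine each proband's genotyped relatives.
#'
#' @param calls call set for one dataset (probands and relatives).
#' @param pedigree [read_pedigree()] object.
#' @param rho reciprocal-overlap threshold.
#' @return list: `de_novo` (surviving proband calls), `verdicts` (data.frame
#'   call_id/verdict/max_relative_overlap/matching), `trace` (stage
#'   `inheritance` rows).
#' @export
filter_inherited <- function(calls, pedigree, rho = 0.5) {
  pro <- calls[!is.na(calls$role) & calls$role == "proband", , drop = FALSE]
  pro <- sort_calls(pro)
  verdicts <- vector("list", nrow(pro))
  for (i in seq_len(nrow(pro))) {
    rel_ids <- relatives_of(pedigree, pro$sample_id[i])
    rel_calls <- calls[calls$sample_id %in% rel_ids, , drop = FALSE]
    verdicts[[i]] <- classify_inheritance(pro[i, , drop = FALSE], rel_calls,
                                          rho = rho,
                                          n_relatives = length(rel_ids))
  }
  vdf <- data.frame(
    call_id = vapply(verdicts, `[[`, "", "call_id"),
    verdict = vapply(verdicts, `[[`, "", "verdict"),
    max_relative_overlap = vapply(verdicts, `[[`, 0, "max_relative_overlap"),
    matching = vapply(verdicts, function(v) join_ids(v$matching_relative_calls), ""),
    stringsAsFactors = FALSE)
  if (!nrow(vdf)) {
    vdf <- data.frame(call_id = character(0), verdict = character(0),
                      max_relative_overlap = numeric(0),
                      matching = character(0))
  }
  trace <- trace_rows(
    vdf$call_id, "inheritance",
    ifelse(vdf$verdict == "de_novo", "pass", "drop"),
    c(de_novo = "de_novo", inherited = "inherited",
      unclassified = "no_genotyped_relatives")[vdf$verdict],
    ifelse(vdf$matching == ".", ".", vdf$matching))
  list(de_novo = pro[vdf$verdict == "de_novo", , drop = FALSE],
       verdicts = vdf, trace = trace)
}

#' Remove proband calls present in independent family controls
#'
#' A surviving proband call is dropped when any control call (non-proband
#' samples of the same dataset, excluding the proband's own family, which the
#' inheritance screen already consumed) reaches reciprocal overlap `rho`.
#' Matching is type-agnostic, as for inheritance.
#'
#' @param proband_calls call set of de novo candidates.
#' @param control_calls call set of independent controls (caller must already
#'   have excluded each proband's own family; see [filter_controls()]).
#' @param rho reciprocal-overlap threshold.
#' @return list: `surviving` calls and `trace` rows (stage `control_filter`).
#' @export
filter_against_controls <- function(proband_calls, control_calls, rho = 0.5) {
  hits <- overlap_pairs(proband_calls, control_calls, min_frac = rho,
                        mode = "reciprocal")
  ev <- vapply(seq_len(nrow(proband_calls)), function(i) {
    join_ids(control_calls$call_id[hits$s[hits$q == i]])
  }, "")
  dropped <- ev != "."
  trace <- trace_rows(proband_calls$call_id, "control_filter",
                      ifelse(dropped, "drop", "pass"),
                      ifelse(dropped, "present_in_controls", "no_control_match"),
                      ev)
  list(surviving = proband_calls[!dropped, , drop = FALSE], trace = trace)
}

#' Layer-1 control screen with per-family control sets
#'
#' Driver around [filter_against_controls()]: for each proband family, the
#' control set is every non-proband call of the dataset from a different
#' family (parents, siblings, unrelated controls).
#'
#' @param de_novo_calls proband calls surviving the inheritance screen.
#' @param all_calls full call set of the dataset.
#' @param rho reciprocal-overlap threshold.
#' @return list: `surviving` calls and `trace` rows.
#' @export
filter_controls <- function(de_novo_calls, all_calls, rho = 0.5) {
  ctrl <- all_calls[!is.na(all_calls$role) & all_calls$role != "proband", ,
                    drop = FALSE]
  surviving <- list()
  trace <- list()
  de_novo_calls <- sort_calls(de_novo_calls)
  for (fam in unique(de_novo_calls$family_id)) {
    pro_f <- de_novo_calls[de_novo_calls$family_id == fam, , drop = FALSE]
    ctrl_f <- ctrl[ctrl$family_id != fam, , drop = FALSE]
    res <- filter_against_controls(pro_f, ctrl_f, rho = rho)
    surviving[[fam]] <- res$surviving
    trace[[fam]] <- res$trace
  }
  surv <- if (length(surviving)) do.call(rbind, surviving) else empty_calls()
  tr <- if (length(trace)) do.call(rbind, trace) else trace_rows(character(0),
    character(0), character(0), character(0), character(0))
  tr <- tr[order(match(tr$call_id, de_novo_calls$call_id)), , drop = FALSE]
  rownames(surv) <- rownames(tr) <- NULL
  list(surviving = sort_calls(surv), trace = tr)
}
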