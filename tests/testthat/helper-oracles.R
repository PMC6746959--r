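# Fixture builders and independent brute-force oracles shared by the suite.

# Quick call-set builder with sensible defaults.
mk_calls <- function(chrom, start, end, cnv_type = "DEL", sample_id = "S1",
                     family_id = sample_id, role = "proband",
                     cohort = "discovery", platform = "wes", call_id = NULL,
                     quality = NA_real_, support = NA_character_) {
  n <- max(length(chrom), length(start), length(end), length(sample_id))
  df <- data.frame(
    call_id = if (is.null(call_id)) sprintf("c%03d", seq_len(n)) else call_id,
    sample_id = rep_len(sample_id, n), family_id = rep_len(family_id, n),
    role = rep_len(role, n), cohort = rep_len(cohort, n),
    platform = rep_len(platform, n), chrom = rep_len(chrom, n),
    start = rep_len(start, n), end = rep_len(end, n),
    cnv_type = rep_len(cnv_type, n), quality = rep_len(quality, n),
    support = rep_len(support, n), stringsAsFactors = FALSE)
  as_cnv_calls(df)
}

# Random interval frame on a small coordinate range (for enumeration oracles).
random_ivs <- function(n, max_coord = 1000, chroms = c("chr1", "chr2")) {
  s <- sample.int(max_coord, n, replace = TRUE)
  len <- sample.int(max_coord %/% 4, n, replace = TRUE)
  genomic_interval(sample(chroms, n, replace = TRUE), s,
                   pmin(s + len, max_coord))
}

# Base-position enumeration oracle for overlap_bp.
bf_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

# Connected components of the >= 1 bp overlap graph (oracle for
# merge_recurrent), by breadth-first search over the all-pairs adjacency.
bf_components <- function(calls) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- calls$chrom[i] == calls$chrom[j] &&
        min(calls$end[i], calls$end[j]) >= max(calls$start[i], calls$start[j])
    }
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  split(calls$call_id, comp)
}

# Exhaustive-placement oracle for the hypergeometric upper tail: enumerate
# all C(n_total, k) carrier placements and count those with >= k_case in
# the first n_case slots.
bf_hyper_tail <- function(k_case, k, n_case, n_total) {
  placements <- utils::combn(n_total, k)
  mean(colSums(placements <= n_case) >= k_case)
}

# Minimal single-family pedigree builder.
mk_pedigree <- function(members) {
  structure(list(members = members), class = "pedigree")
}

trio_ped_rows <- function(fam, dataset = "discovery", sibling = FALSE,
                          parents = TRUE) {
  rows <- data.frame(
    family_id = fam, sample_id = paste0(fam, "-01"),
    father_id = if (parents) paste0(fam, "-02") else "0",
    mother_id = if (parents) paste0(fam, "-03") else "0",
    sex = "1", affected = 2L, dataset = dataset, stringsAsFactors = FALSE)
  if (parents) {
    rows <- rbind(rows,
      data.frame(family_id = fam, sample_id = paste0(fam, "-02"),
                 father_id = "0", mother_id = "0", sex = "1", affected = 1L,
                 dataset = dataset, stringsAsFactors = FALSE),
      data.frame(family_id = fam, sample_id = paste0(fam, "-03"),
                 father_id = "0", mother_id = "0", sex = "2", affected = 1L,
                 dataset = dataset, stringsAsFactors = FALSE))
  }
  if (sibling) {
    rows <- rbind(rows,
      data.frame(family_id = fam, sample_id = paste0(fam, "-04"),
                 father_id = paste0(fam, "-02"),
                 mother_id = paste0(fam, "-03"), sex = "2", affected = 1L,
                 dataset = dataset, stringsAsFactors = FALSE))
  }
  rows
}

# Assign roles the way read_pedigree would.
finalize_ped <- function(rows) {
  tf <- tempfile(fileext = ".ped")
  on.exit(unlink(tf))
  write_pedigree(mk_pedigree(rows), tf)
  read_pedigree(tf)
}

# A small knowledge base assembled in memory.
mk_kb <- function(chd = NULL, dgv = NULL, gene_models = NULL,
                  expressed = character(0)) {
  empty_iv <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), name = character(0),
                         stringsAsFactors = FALSE)
  if (is.null(chd)) chd <- empty_iv
  if (is.null(dgv)) dgv <- empty_iv
  if (is.null(gene_models)) {
    gene_models <- data.frame(gene = character(0), chrom = character(0),
                              start = integer(0), end = integer(0),
                              stringsAsFactors = FALSE)
  }
  structure(list(chd_known_regions = chd, dgv_common_regions = dgv,
                 gene_models = gene_models,
                 heart_expressed_genes = expressed),
            class = "knowledge_base")
}

mk_region <- function(chrom, start, end, region_id = NULL,
                      n_case_carriers = 1L, n_control_carriers = 0L) {
  data.frame(region_id = if (is.null(region_id))
               sprintf("%s:%d-%d", chrom, start, end) else region_id,
             chrom = chrom, start = as.integer(start), end = as.integer(end),
             cnv_types = "DEL", member_call_ids = ".",
             n_case_carriers = n_case_carriers,
             n_control_carriers = n_control_carriers,
             stringsAsFactors = FALSE)
}
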