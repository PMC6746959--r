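#' Read a pedigree / affection file
#'
#' Seven tab-separated columns, PED-like plus a dataset assignment:
#' `family_id sample_id father_id mother_id sex affected dataset` with
#' `affected` coded 1 (unaffected) / 2 (affected), `dataset` one of
#' discovery / rep_wes / rep_array / rep_wgs. A header line starting with
#' `family_id` or `#` is skipped.
#'
#' Roles are inferred: a sample referenced as a father/mother of another row
#' gets that role; otherwise an affected sample is a proband, an unaffected
#' member of a multi-sample family a sibling, and an unaffected singleton an
#' unrelated_control (its family_id must equal its sample_id). A child whose
#' parent id is not itself a genotyped row simply has fewer available
#' relatives.
#'
#' @param path input file.
#' @return an object of class `pedigree`: a list with `members`, a data.frame
#'   (family_id, sample_id, father_id, mother_id, sex, affected, dataset,
#'   role).
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "family_id")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 7L)
  if (length(bad)) stop("pedigree line(s) with fewer than 7 fields: ",
                        paste(utils::head(bad, 5), collapse = ", "))
  m <- data.frame(
    family_id = vapply(f, `[[`, "", 1L),
    sample_id = vapply(f, `[[`, "", 2L),
    father_id = vapply(f, `[[`, "", 3L),
    mother_id = vapply(f, `[[`, "", 4L),
    sex = vapply(f, `[[`, "", 5L),
    affected = as.integer(vapply(f, `[[`, "", 6L)),
    dataset = vapply(f, `[[`, "", 7L),
    stringsAsFactors = FALSE)
  if (anyDuplicated(m$sample_id)) {
    stop("duplicate sample_id in pedigree: ",
         paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", "))
  }
  if (!all(m$dataset %in% COHORTS)) {
    stop("unknown dataset label in pedigree")
  }
  fam_size <- table(m$family_id)
  role <- character(nrow(m))
  is_father <- m$sample_id %in% m$father_id
  is_mother <- m$sample_id %in% m$mother_id
  role[is_father] <- "father"
  role[is_mother] <- "mother"
  rest <- !is_father & !is_mother
  singleton <- fam_size[m$family_id] == 1L
  role[rest & m$affected == 2L] <- "proband"
  role[rest & m$affected != 2L & !singleton] <- "sibling"
  role[rest & m$affected != 2L & singleton] <- "unrelated_control"
  bad_ctrl <- role == "unrelated_control" & m$family_id != m$sample_id
  if (any(bad_ctrl)) {
    stop("unrelated_control samples must have family_id == sample_id: ",
         paste(m$sample_id[bad_ctrl], collapse = ", "))
  }
  m$role <- role
  structure(list(members = m), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("pedigree: %d samples, %d families\n", nrow(x$members),
              length(unique(x$members$family_id))))
  print(table(x$members$dataset, x$members$role))
  invisible(x)
}

# Genotyped relatives (parents/siblings present in the pedigree) of a sample.
relatives_of <- function(pedigree, sample_id) {
  m <- pedigree$members
  fam <- m$family_id[m$sample_id == sample_id]
  if (!length(fam)) return(character(0))
  rel <- m$sample_id[m$family_id == fam & m$sample_id != sample_id &
                       m$role %in% c("father", "mother", "sibling")]
  rel
}

#' Write a pedigree file
#'
#' Inverse of [read_pedigree()]; writes the canonical seven-column layout
#' with a header line.
#'
#' @param pedigree pedigree object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  m <- pedigree$members
  writeLines(c("family_id\tsample_id\tfather_id\tmother_id\tsex\taffected\tdataset",
               sprintf("%s\t%s\t%s\t%s\t%s\t%d\t%s", m$family_id, m$sample_id,
                       m$father_id, m$mother_id, m$sex, m$affected, m$dataset)),
             path)
  invisible(path)
}
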