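#' Write and read cohort tables
#'
#' Cohort tables are plain CSV with one row per patient and the fixed header
#' `patient_id,age,sex,smoking,alcohol,family_history,ebv_dna,hgb,alb,crp,
#' ldh,t_category,n_category,group,df_time,df_event,dm_time,dm_event,
#' lr_time,lr_event,rr_time,rr_event,censor_time`. Event times are months
#' since end of treatment (empty when no event); event flags are
#' `TRUE`/`FALSE`. `read_cohort()` validates the schema and, by default,
#' re-derives the risk group from T, N and EBV DNA and fails on any mismatch.
#'
#' @param cohort an `npc_cohort` data frame (see [simulate_cohort()]).
#' @param path file path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` returns
#'   an `npc_cohort` data frame.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing)) stop("cohort is missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(cohort[cohort_columns()], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @param validate logical; re-run the grouping rule on load and error on
#'   records whose stored group disagrees.
#' @export
read_cohort <- function(path, validate = TRUE) {
  header <- names(utils::read.csv(path, nrows = 0))
  missing <- setdiff(cohort_columns(), header)
  if (length(missing)) {
    stop("cohort file is missing required column(s): ", paste(missing, collapse = ", "))
  }
  cls <- cohort_colclasses()
  coh <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = cls[intersect(header, names(cls))],
                         na.strings = "")
  coh <- coh[cohort_columns()]
  if (validate && nrow(coh) > 0) {
    expected <- assign_group(coh$t_category, coh$n_category, coh$ebv_dna)
    bad <- which(expected != coh$group)
    if (length(bad)) {
      stop("group inconsistent with T/N/EBV DNA for patient(s): ",
           paste(utils::head(coh$patient_id[bad], 5), collapse = ", "))
    }
  }
  class(coh) <- c("npc_cohort", "data.frame")
  coh
}

cohort_colclasses <- function() {
  c(patient_id = "character", age = "numeric", sex = "character",
    smoking = "logical", alcohol = "logical", family_history = "logical",
    ebv_dna = "numeric", hgb = "numeric", alb = "numeric", crp = "numeric",
    ldh = "numeric", t_category = "character", n_category = "character",
    group = "character", df_time = "numeric", df_event = "logical",
    dm_time = "numeric", dm_event = "logical", lr_time = "numeric",
    lr_event = "logical", rr_time = "numeric", rr_event = "logical",
    censor_time = "numeric")
}
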