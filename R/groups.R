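#' Assign the clinic-molecular risk group
#'
#' Maps TNM category and pre-treatment plasma EBV DNA load onto the four-level
#' clinic-molecular risk grouping used throughout the package:
#'
#' * group I: T1N0;
#' * group II: T2-3N0, T1-3N1, or T1-3N2 with EBV DNA at or below 2000 copies/mL;
#' * group III: T1-3N2 with EBV DNA above 2000 copies/mL, or T4N0-2;
#' * group IV: any T with N3.
#'
#' The rule is total: every valid (T, N, EBV DNA) combination maps to exactly
#' one group.
#'
#' @param t_category character vector of T categories, `"T1"`..`"T4"`.
#' @param n_category character vector of N categories, `"N0"`..`"N3"`.
#' @param ebv_dna numeric vector of plasma EBV DNA loads in copies/mL
#'   (non-negative). The clinically validated cut-off is 2000 copies/mL.
#' @return character vector of group labels `"I"`, `"II"`, `"III"`, `"IV"`.
#' @examples
#' assign_group("T1", "N0", 500)    # "I"
#' assign_group("T3", "N2", 5000)   # "III"
#' assign_group("T2", "N3", 0)      # "IV"
#' assign_group("T1", "N2", 2000)   # "II" (cut-off itself is low-risk)
#' @export
assign_group <- function(t_category, n_category, ebv_dna) {
  t_levels <- paste0("T", 1:4)
  n_levels <- paste0("N", 0:3)
  t_category <- as.character(t_category)
  n_category <- as.character(n_category)
  if (!all(t_category %in% t_levels)) {
    stop("unknown T category: ", paste(unique(setdiff(t_category, t_levels)), collapse = ", "))
  }
  if (!all(n_category %in% n_levels)) {
    stop("unknown N category: ", paste(unique(setdiff(n_category, n_levels)), collapse = ", "))
  }
  if (!is.numeric(ebv_dna) || any(is.na(ebv_dna)) || any(ebv_dna < 0)) {
    stop("ebv_dna must be non-negative and non-missing (copies/mL)")
  }
  n <- max(length(t_category), length(n_category), length(ebv_dna))
  t_category <- rep_len(t_category, n)
  n_category <- rep_len(n_category, n)
  ebv_dna <- rep_len(ebv_dna, n)

  group <- character(n)
  high_ebv <- ebv_dna > 2000
  group[n_category == "N3"] <- "IV"
  group[n_category != "N3" & t_category == "T4"] <- "III"
  t123 <- t_category %in% c("T1", "T2", "T3")
  group[t123 & n_category == "N2" & high_ebv] <- "III"
  group[t123 & n_category == "N2" & !high_ebv] <- "II"
  group[t123 & n_category == "N1"] <- "II"
  group[t_category %in% c("T2", "T3") & n_category == "N0"] <- "II"
  group[t_category == "T1" & n_category == "N0"] <- "I"
  stopifnot(all(group %in% c("I", "II", "III", "IV")))
  group
}

group_levels <- function() c("I", "II", "III", "IV")
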