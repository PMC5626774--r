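#' Canonicalize a drug name
#'
#' Repurposing tools report the same compound with differing case and
#' whitespace. All joins in this package are exact matches on the canonical
#' form: lowercased, trimmed, with internal whitespace runs collapsed to a
#' single space. No synonym or fuzzy resolution is attempted, so distinct
#' spellings remain distinct drugs.
#'
#' @param raw character vector of drug names.
#' @return character vector of canonical names, same length as `raw`.
#' @examples
#' canonicalize_drug_name(c("Thapsigargin ", "NICLOSAMIDE"))
#' @export
canonicalize_drug_name <- function(raw) {
  if (!is.character(raw)) stop("drug names must be character", call. = FALSE)
  out <- tolower(trimws(raw))
  out <- gsub("[[:space:]]+", " ", out)
  if (any(is.na(out) | out == "")) {
    stop("invalid drug name: empty after trimming", call. = FALSE)
  }
  out
}

#' Stage-contrast presets
#'
#' The four disease-stage contrasts used throughout the worked example:
#' advanced disease vs normal, each stage vs normal, and stage 2 vs stage 1.
#' Stage labels are otherwise free strings; these are conveniences only.
#'
#' @return named character vector of the four preset contrast labels.
#' @export
stage_presets <- function() {
  c(ipf_vs_normal    = "IPF_vs_Normal",
    stage1_vs_normal = "Stage1_vs_Normal",
    stage2_vs_normal = "Stage2_vs_Normal",
    stage2_vs_stage1 = "Stage2_vs_Stage1")
}
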