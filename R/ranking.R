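# The CoDReS composite score, per-stage ranking, and re-ranking shifts.

#' Component weights for the composite score
#'
#' The published strategy downgrades the raw inhibition evidence and splits
#' the remaining weight equally across the suitability components:
#' `(0.4, 0.2, 0.2, 0.2)` for inhibition, structural, functional and
#' side-effect scores. Weights must be non-negative and sum to 1, which
#' keeps the composite inside \[0, 1\].
#'
#' @param w_is,w_ss,w_fs,w_ses non-negative weights for the inhibition,
#'   structural, functional and side-effect components.
#' @return numeric vector of the four weights, class `codres_weights`.
#' @export
codres_weights <- function(w_is = 0.4, w_ss = 0.2, w_fs = 0.2, w_ses = 0.2) {
  w <- c(w_is = w_is, w_ss = w_ss, w_fs = w_fs, w_ses = w_ses)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(w, class = "codres_weights")
}

#' Compute the composite drug repurposing score
#'
#' `CoDReS = w_is * inhib + w_ss * struct + w_fs * func + w_ses * side`,
#' an exact weighted sum of the four \[0, 1\] components.
#'
#' @param components data.frame `drug, inhib, struct, func, side` (see
#'   [assemble_components()]).
#' @param weights a [codres_weights()] vector.
#' @return named numeric vector of composite scores in \[0, 1\].
#' @export
compute_codres <- function(components, weights = codres_weights()) {
  stopifnot(inherits(weights, "codres_weights"))
  m <- as.matrix(components[, c("inhib", "struct", "func", "side")])
  if (any(is.na(m))) stop("NaN/NA component", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("components must lie in [0, 1]", call. = FALSE)
  structure(as.numeric(m %*% unclass(weights)), names = components$drug)
}

#' Rank a score map, best first
#'
#' Descending by score; ties break by canonical drug name ascending (the
#' rule that reproduces the published tie ordering). Ranks are 1..N with no
#' gaps.
#'
#' @param scores named numeric vector, no NaN.
#' @return named integer vector of ranks.
#' @export
rank_by_score <- function(scores) {
  if (length(scores) == 0L || is.null(names(scores))) {
    stop("scores must be a nonempty named vector", call. = FALSE)
  }
  if (any(is.na(scores))) stop("NaN score", call. = FALSE)
  o <- order(-scores, names(scores))
  r <- integer(length(scores))
  r[o] <- seq_along(scores)
  structure(r, names = names(scores))
}

#' Re-ranking shifts of the composite vs the inhibition-only ordering
#'
#' `shift = inhib_rank - codres_rank`: positive means the composite score
#' promoted the drug relative to raw inhibition. Shifts always sum to zero.
#'
#' @param inhib named inhibition-score map.
#' @param codres named composite-score map over the same drugs.
#' @return data.frame `drug, codres, codres_rank, inhib_rank, shift` sorted
#'   by composite rank.
#' @export
rank_shifts <- function(inhib, codres) {
  if (!setequal(names(inhib), names(codres)) ||
      length(inhib) != length(codres)) {
    stop("inhibition and composite maps cover different drugs",
         call. = FALSE)
  }
  cr <- rank_by_score(codres)
  ir <- rank_by_score(inhib)[names(cr)]
  out <- data.frame(drug = names(cr), codres = as.numeric(codres[names(cr)]),
                    codres_rank = as.integer(cr),
                    inhib_rank = as.integer(ir),
                    shift = as.integer(ir - cr), stringsAsFactors = FALSE)
  out <- out[order(out$codres_rank), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score and rank one stage
#'
#' Composite score, ranks and re-ranking shifts for a full per-stage
#' component table, sorted by composite score descending.
#'
#' @param components data.frame `drug, inhib, struct, func, side`.
#' @param weights a [codres_weights()] vector.
#' @return data.frame `drug, inhib_score, struct_score, func_score,
#'   side_score, codres, codres_rank, inhib_rank, shift`.
#' @export
score_stage <- function(components, weights = codres_weights()) {
  if (nrow(components) == 0L) stop("empty component table", call. = FALSE)
  codres <- compute_codres(components, weights)
  inhib <- structure(components$inhib, names = components$drug)
  shifts <- rank_shifts(inhib, codres)
  idx <- match(shifts$drug, components$drug)
  data.frame(drug = shifts$drug,
             inhib_score = components$inhib[idx],
             struct_score = components$struct[idx],
             func_score = components$func[idx],
             side_score = components$side[idx],
             codres = shifts$codres,
             codres_rank = shifts$codres_rank,
             inhib_rank = shifts$inhib_rank,
             shift = shifts$shift,
             stringsAsFactors = FALSE)
}
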