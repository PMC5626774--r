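# The three non-inhibition CoDReS components, each normalized within the
# supplied batch of drugs. Normalization is batch-relative by design: adding
# a drug with a heavier penalty changes everyone else's normalized score.

#' Structural druglikeness scores from rule-violation counts
#'
#' Each violated druglikeness rule increments a penalty; penalties are
#' divided by the batch maximum and the score is that value's distance from
#' 1. Drugs with no violations score exactly 1; the worst offender scores
#' exactly 0. A batch with no violations anywhere scores all 1 (no penalty
#' to normalize).
#'
#' @param violations data.frame `drug, violations` ([read_violations()]
#'   layout) or a named non-negative integer vector.
#' @return named numeric vector of structural scores in \[0, 1\].
#' @export
structural_scores <- function(violations) {
  v <- as_named_counts(violations, "violations")
  if (length(v) == 0L) stop("empty violations batch", call. = FALSE)
  if (any(v < 0)) stop("violations must be >= 0", call. = FALSE)
  v_max <- max(v)
  if (v_max == 0) return(structure(rep(1, length(v)), names = names(v)))
  1 - v / v_max
}

as_named_counts <- function(x, col) {
  if (is.data.frame(x)) {
    structure(as.numeric(x[[col]]), names = x$drug)
  } else {
    stopifnot(!is.null(names(x)))
    x
  }
}

#' Functional relevance scores from per-target-gene enrichment lists
#'
#' The functional raw value of a drug is the arithmetic mean of its
#' gene-target enrichment scores (a drug with no targets has mean 0); scores
#' are then divided by the batch maximum. If every mean is 0 all scores stay
#' 0 (no maximum to attain).
#'
#' @param evidence named list mapping drug to a numeric vector of per-gene
#'   scores in \[0, 1\] (possibly empty); see [read_functional()].
#' @return named numeric vector of functional scores in \[0, 1\].
#' @export
functional_scores <- function(evidence) {
  if (length(evidence) == 0L) stop("empty functional batch", call. = FALSE)
  means <- vapply(evidence, function(s) {
    if (length(s) == 0L) return(0)
    if (any(s < 0 | s > 1)) stop("gene scores must lie in [0, 1]",
                                 call. = FALSE)
    mean(s)
  }, numeric(1))
  m <- max(means)
  if (m == 0) means else means / m
}

#' Raw side-effect burden of one profile
#'
#' The count-weighted sum over the eight severity classes, with weight equal
#' to the class index: `S = sum_i counts[i] * i`.
#'
#' @param counts non-negative integer vector of length 8 (class 1..8).
#' @return single non-negative number.
#' @export
side_effect_raw <- function(counts) {
  if (length(counts) != 8L || any(counts < 0)) {
    stop("counts must be 8 non-negative values", call. = FALSE)
  }
  sum(counts * seq_len(8L))
}

#' Side-effect scores for a batch of profiles
#'
#' Known profiles score `1 - S / S_max` where `S_max` is the largest raw
#' burden among known profiles (all 1 if no known drug has any recorded side
#' effect). Drugs flagged `unknown` score exactly 0 -- the worst value --
#' even though a known drug with zero recorded side effects scores 1; the
#' discontinuity penalizes missing safety information deliberately.
#'
#' @param profiles data.frame `drug, c1..c8, unknown`
#'   ([read_side_effects()] layout).
#' @return named numeric vector of side-effect scores in \[0, 1\].
#' @export
side_effect_scores <- function(profiles) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L) {
    stop("empty side-effect batch", call. = FALSE)
  }
  classes <- paste0("c", 1:8)
  raw <- apply(as.matrix(profiles[, classes]), 1L, side_effect_raw)
  known <- !profiles$unknown
  out <- numeric(nrow(profiles))
  if (any(known)) {
    s_max <- max(raw[known])
    out[known] <- if (s_max == 0) 1 else 1 - raw[known] / s_max
  }
  structure(out, names = profiles$drug)
}

#' Join the four component maps over a drug universe
#'
#' Every drug in the universe must carry an inhibition score (there is no
#' sensible default for it); the other three components may fall back to an
#' explicit default when a drug is missing from their map, e.g. `side = 0`
#' for the treat-missing-as-unknown policy. NULL (the default) means a
#' missing entry is an error.
#'
#' @param inhib,struct,func,side named numeric vectors in \[0, 1\].
#' @param universe character vector of canonical drug names; defaults to the
#'   names of `inhib`.
#' @param defaults named list with optional entries `struct`, `func`, `side`.
#' @return data.frame `drug, inhib, struct, func, side`, one row per
#'   universe drug.
#' @export
assemble_components <- function(inhib, struct, func, side,
                                universe = names(inhib),
                                defaults = list()) {
  pick <- function(map, what) {
    default <- defaults[[what]]
    miss <- setdiff(universe, names(map))
    if (length(miss) > 0L && is.null(default)) {
      stop("missing ", what, " score for: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    v <- ifelse(universe %in% names(map), map[universe],
                rep(default %||% NA_real_, length(universe)))
    v <- as.numeric(v)
    if (any(is.na(v) | v < 0 | v > 1)) {
      stop(what, " scores must lie in [0, 1] with no NaN", call. = FALSE)
    }
    v
  }
  if (length(universe) == 0L) stop("empty drug universe", call. = FALSE)
  miss_inhib <- setdiff(universe, names(inhib))
  if (length(miss_inhib) > 0L) {
    stop("missing inhibition score for: ",
         paste(miss_inhib, collapse = ", "), call. = FALSE)
  }
  data.frame(drug = universe,
             inhib = pick(inhib, "inhib"),
             struct = pick(struct, "struct"),
             func = pick(func, "func"),
             side = pick(side, "side"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
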