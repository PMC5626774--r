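# Inhibition threshold + two-of-three tool and dataset consensus, and the
# per-stage normalized inhibition score.

#' Consensus-filter configuration
#'
#' Defaults are the published rule: an inhibiting score of at most -0.5,
#' support from at least 2 of the 3 repurposing tools within a dataset, and
#' presence in at least 2 of the 3 datasets of the same stage. The boundary
#' score (exactly `score_max`) qualifies; set `strict = TRUE` for a strict
#' inequality instead.
#'
#' @param score_max qualification threshold, must be negative (default
#'   -0.5).
#' @param min_tools minimum distinct tools per dataset (default 2).
#' @param min_datasets minimum datasets per stage (default 2).
#' @param strict logical; if TRUE require `score < score_max`.
#' @return list with class `consensus_config`.
#' @export
consensus_config <- function(score_max = -0.5, min_tools = 2L,
                             min_datasets = 2L, strict = FALSE) {
  stopifnot(score_max < 0, min_tools >= 1L, min_datasets >= 1L)
  structure(list(score_max = score_max, min_tools = as.integer(min_tools),
                 min_datasets = as.integer(min_datasets),
                 strict = isTRUE(strict)),
            class = "consensus_config")
}

#' Keep only records at or below the inhibition threshold
#'
#' @param records data.frame of drug-score records ([read_drug_scores()]
#'   layout).
#' @param cfg a [consensus_config()].
#' @return the qualifying rows, input order preserved.
#' @export
filter_qualifying <- function(records, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  keep <- if (cfg$strict) records$score < cfg$score_max
          else records$score <= cfg$score_max
  records[keep, , drop = FALSE]
}

#' Per-dataset tool consensus
#'
#' Within each dataset, a drug qualifies iff it has threshold-passing records
#' from at least `min_tools` distinct tools. The method dimension (e.g.
#' statistical vs network-walk gene selection) is ignored for tool counting:
#' a tool counts once however many methods hit it.
#'
#' @param records threshold-filtered records of a single stage.
#' @param cfg a [consensus_config()].
#' @return named list: dataset -> character vector of qualifying drugs
#'   (sorted).
#' @export
tool_consensus <- function(records, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  if (nrow(records) == 0L) return(structure(list(), names = character()))
  by_ds <- split(records, records$dataset)
  lapply(by_ds, function(r) {
    hits <- unique(r[, c("drug", "tool")])
    counts <- table(hits$drug)
    sort(names(counts)[counts >= cfg$min_tools])
  })
}

#' Cross-dataset consensus for one stage
#'
#' @param dataset_sets named list of per-dataset qualifying drug sets (from
#'   [tool_consensus()]).
#' @param cfg a [consensus_config()].
#' @return data.frame `drug, support` for drugs in at least `min_datasets`
#'   sets, ordered by decreasing support then drug.
#' @export
dataset_consensus <- function(dataset_sets, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  if (length(dataset_sets) < cfg$min_datasets) {
    stop("fewer datasets supplied than min_datasets", call. = FALSE)
  }
  members <- unlist(lapply(dataset_sets, unique), use.names = FALSE)
  if (length(members) == 0L) {
    return(data.frame(drug = character(), support = integer(),
                      stringsAsFactors = FALSE))
  }
  counts <- table(members)
  df <- data.frame(drug = names(counts), support = as.integer(counts),
                   stringsAsFactors = FALSE)
  df <- df[df$support >= cfg$min_datasets, , drop = FALSE]
  rownames(df) <- NULL
  df[order(-df$support, df$drug), , drop = FALSE]
}

#' Aggregate inhibition magnitude per drug within one stage
#'
#' Sums the absolute values of all qualifying (negative) scores of each drug
#' across tools, methods and datasets of the stage, so stronger inhibition
#' yields a larger aggregate. Input must already be threshold-filtered.
#'
#' @param records qualifying records, restricted to one stage (rows with a
#'   different `stage` value are an error).
#' @param stage the stage label the records belong to.
#' @return named numeric vector: drug -> aggregate (> 0).
#' @export
aggregate_inhibition <- function(records, stage) {
  if (nrow(records) > 0L && !all(records$stage == stage)) {
    stop("records from a different stage supplied", call. = FALSE)
  }
  if (nrow(records) == 0L) return(structure(numeric(), names = character()))
  agg <- tapply(abs(records$score), records$drug, sum)
  structure(as.numeric(agg), names = names(agg))
}

#' Normalize per-stage aggregates to (0, 1]
#'
#' Division by the stage maximum; at least one drug scores exactly 1.
#' Normalization is always per stage, never across stages.
#'
#' @param aggregates named numeric vector from [aggregate_inhibition()]; all
#'   values must be positive.
#' @return named numeric vector of inhibition scores in (0, 1].
#' @export
normalize_inhibition <- function(aggregates) {
  if (length(aggregates) == 0L) stop("empty aggregate map", call. = FALSE)
  if (any(aggregates <= 0)) stop("aggregates must be positive", call. = FALSE)
  aggregates / max(aggregates)
}

#' Full consensus + inhibition-score pipeline for one stage
#'
#' Convenience composition: threshold filter, tool consensus per dataset,
#' dataset consensus, and the normalized inhibition score. Consensus
#' membership and the scored universe are decoupled: every drug with at
#' least one qualifying record is scored, and `consensus_flag` marks which
#' of them also pass both consensus filters.
#'
#' @param records raw drug-score records (one or more stages).
#' @param stage stage label to process.
#' @param cfg a [consensus_config()].
#' @return data.frame `drug, aggregate, inhib_score, n_tools, n_datasets,
#'   consensus_flag`, ordered by decreasing inhibition score then drug.
#' @export
stage_inhibition <- function(records, stage, cfg = consensus_config()) {
  stopifnot(inherits(cfg, "consensus_config"))
  r <- records[records$stage == stage, , drop = FALSE]
  q <- filter_qualifying(r, cfg)
  if (nrow(q) == 0L) {
    return(data.frame(drug = character(), aggregate = numeric(),
                      inhib_score = numeric(), n_tools = integer(),
                      n_datasets = integer(), consensus_flag = logical(),
                      stringsAsFactors = FALSE))
  }
  agg <- aggregate_inhibition(q, stage)
  inhib <- normalize_inhibition(agg)
  per_ds <- tool_consensus(q, cfg)
  consensus <- if (length(per_ds) >= cfg$min_datasets) {
    dataset_consensus(per_ds, cfg)$drug
  } else {
    character()
  }
  drugs <- names(agg)
  n_tools <- vapply(drugs, function(d) {
    length(unique(q$tool[q$drug == d]))
  }, integer(1))
  n_datasets <- vapply(drugs, function(d) {
    length(unique(q$dataset[q$drug == d]))
  }, integer(1))
  out <- data.frame(drug = drugs, aggregate = as.numeric(agg),
                    inhib_score = as.numeric(inhib),
                    n_tools = n_tools, n_datasets = n_datasets,
                    consensus_flag = drugs %in% consensus,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$inhib_score, out$drug), , drop = FALSE]
}
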