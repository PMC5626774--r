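# Gene-signature construction and cross-method / cross-dataset consensus.

#' Signature-selection configuration
#'
#' Defaults mirror the published pipeline: the top 150 up- and 150
#' down-regulated genes at p < 0.05 (strict), a size dictated by the input
#' limits of connectivity-map style query tools.
#'
#' @param n_up,n_down maximum number of up-/down-regulated genes kept.
#' @param p_max exclusive p-value cutoff (a gene at exactly `p_max` is
#'   dropped).
#' @return list with class `signature_config`.
#' @export
signature_config <- function(n_up = 150L, n_down = 150L, p_max = 0.05) {
  stopifnot(n_up >= 1L, n_down >= 1L, p_max > 0, p_max <= 1)
  structure(list(n_up = as.integer(n_up), n_down = as.integer(n_down),
                 p_max = p_max), class = "signature_config")
}

#' Select top up/down regulated genes from a DE table
#'
#' Rows with `p_value < p_max` (strict) are kept; a gene appearing on several
#' rows keeps its best-p row (ties by larger absolute fold change, then first
#' occurrence). Up-regulated genes (positive fold change) are ranked by fold
#' change descending, down-regulated (negative) by fold change ascending
#' (most negative first); fold-change ties break alphabetically. Each list is
#' truncated to its configured size. Zero fold change belongs to neither
#' list. An empty result is a valid (empty) signature.
#'
#' @param table data.frame with columns `gene`, `fold_change` (signed,
#'   positive = up), `p_value`; see [read_deg_table()].
#' @param cfg a [signature_config()].
#' @return list with character vectors `up` and `down` (class
#'   `gene_signature`).
#' @export
select_top_genes <- function(table, cfg = signature_config()) {
  stopifnot(inherits(cfg, "signature_config"))
  req <- c("gene", "fold_change", "p_value")
  if (!all(req %in% names(table))) {
    stop("table needs columns gene, fold_change, p_value", call. = FALSE)
  }
  t <- table[!is.na(table$p_value) & table$p_value < cfg$p_max, req,
             drop = FALSE]
  if (nrow(t) > 0L) {
    # best-p deduplication before the top-N cut
    o <- order(t$p_value, -abs(t$fold_change))
    t <- t[o, , drop = FALSE]
    t <- t[!duplicated(t$gene), , drop = FALSE]
  }
  up <- t[t$fold_change > 0, , drop = FALSE]
  up <- up[order(-up$fold_change, up$gene), , drop = FALSE]
  down <- t[t$fold_change < 0, , drop = FALSE]
  down <- down[order(down$fold_change, down$gene), , drop = FALSE]
  gene_signature(utils::head(up$gene, cfg$n_up),
                 utils::head(down$gene, cfg$n_down))
}

#' Construct a gene signature
#'
#' @param up,down ordered character vectors of gene symbols; must be
#'   duplicate-free and disjoint.
#' @return list with elements `up` and `down`, class `gene_signature`.
#' @export
gene_signature <- function(up = character(), down = character()) {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    stop("duplicate genes within a signature list", call. = FALSE)
  }
  both <- intersect(up, down)
  if (length(both) > 0L) {
    stop("genes in both up and down lists: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  structure(list(up = up, down = down), class = "gene_signature")
}

#' Combine the signatures of two gene-selection methods
#'
#' Union per direction (order: genes of `a`, then new genes of `b`). A gene
#' up-regulated under one method and down-regulated under the other is
#' discordant: it is excluded from both lists and reported via a warning and
#' the `discordant` attribute.
#'
#' @param a,b `gene_signature` objects (e.g. statistical vs network-walk
#'   selection on the same dataset).
#' @return combined `gene_signature`; attribute `discordant` holds the
#'   excluded genes.
#' @export
combine_method_lists <- function(a, b) {
  stopifnot(inherits(a, "gene_signature"), inherits(b, "gene_signature"))
  up <- unique(c(a$up, b$up))
  down <- unique(c(a$down, b$down))
  discordant <- intersect(up, down)
  if (length(discordant) > 0L) {
    warning(length(discordant), " discordant gene(s) dropped: ",
            paste(discordant, collapse = ", "), call. = FALSE)
    up <- setdiff(up, discordant)
    down <- setdiff(down, discordant)
  }
  out <- gene_signature(up, down)
  attr(out, "discordant") <- discordant
  out
}

#' Cross-dataset gene consensus for one stage
#'
#' A gene enters the consensus up (resp. down) list iff it appears in the up
#' (resp. down) list of at least `min_datasets` of the supplied per-dataset
#' signatures. Support counts are attached, and genes present in every
#' dataset are flagged.
#'
#' @param signatures list of `gene_signature`, one per dataset.
#' @param min_datasets minimum number of datasets a gene must appear in
#'   (default 2).
#' @return list with `signature` (consensus `gene_signature`), `support`
#'   (data.frame gene/direction/support/in_all), ordered by decreasing
#'   support then gene.
#' @export
stage_consensus_genes <- function(signatures, min_datasets = 2L) {
  if (min_datasets < 1L) stop("min_datasets must be >= 1", call. = FALSE)
  if (length(signatures) < min_datasets) {
    stop("need at least min_datasets signatures", call. = FALSE)
  }
  stopifnot(all(vapply(signatures, inherits, TRUE, "gene_signature")))
  n <- length(signatures)
  tally <- function(dir) {
    counts <- table(unlist(lapply(signatures, `[[`, dir)))
    if (length(counts) == 0L) {
      return(data.frame(gene = character(), support = integer(),
                        stringsAsFactors = FALSE))
    }
    df <- data.frame(gene = names(counts), support = as.integer(counts),
                     stringsAsFactors = FALSE)
    df <- df[df$support >= min_datasets, , drop = FALSE]
    df[order(-df$support, df$gene), , drop = FALSE]
  }
  up <- tally("up"); down <- tally("down")
  discordant <- intersect(up$gene, down$gene)
  if (length(discordant) > 0L) {
    warning(length(discordant),
            " gene(s) reached consensus in both directions, dropped: ",
            paste(discordant, collapse = ", "), call. = FALSE)
    up <- up[!(up$gene %in% discordant), , drop = FALSE]
    down <- down[!(down$gene %in% discordant), , drop = FALSE]
  }
  support <- rbind(
    if (nrow(up) > 0L) cbind(up, direction = "up") else NULL,
    if (nrow(down) > 0L) cbind(down, direction = "down") else NULL)
  if (is.null(support)) {
    support <- data.frame(gene = character(), support = integer(),
                          direction = character(), stringsAsFactors = FALSE)
  }
  support$in_all <- support$support == n
  list(signature = gene_signature(up$gene, down$gene), support = support)
}
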