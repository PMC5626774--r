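# Set-consensus utilities: pathway lists across datasets and stages, and
# common gene targets between repurposed drugs and fibrosis-related
# microRNAs.

normalize_pathways <- function(x) {
  unique(gsub("[[:space:]]+", " ", tolower(trimws(as.character(x)))))
}

#' Pathway consensus across the datasets of one stage
#'
#' Per dataset, the pathway lists of the selection methods are unified;
#' across datasets, a pathway is kept when it appears in at least
#' `min_datasets` of the per-dataset unions. The default (`NULL`) is the
#' full intersection -- pathways use an all-datasets rule, unlike the
#' 2-of-3 gene rule.
#'
#' @param lists list with one element per dataset; each element is either a
#'   character vector or a list of character vectors (one per method, which
#'   are unioned). Names are normalized (lowercase, trimmed).
#' @param min_datasets minimum dataset support; `NULL` means all supplied
#'   datasets.
#' @return character vector of consensus pathways, sorted; attribute
#'   `support` carries the per-pathway dataset counts.
#' @export
pathway_consensus <- function(lists, min_datasets = NULL) {
  if (length(lists) == 0L) stop("no pathway lists supplied", call. = FALSE)
  unions <- lapply(lists, function(x) {
    normalize_pathways(unlist(x, use.names = FALSE))
  })
  if (is.null(min_datasets)) min_datasets <- length(unions)
  if (min_datasets < 1L || min_datasets > length(unions)) {
    stop("min_datasets must be in 1..number of datasets", call. = FALSE)
  }
  counts <- table(unlist(unions, use.names = FALSE))
  keep <- sort(names(counts)[counts >= min_datasets])
  structure(keep, support = counts[keep])
}

#' Exact Venn-region membership of several sets
#'
#' Partitions the union of the input sets into its nonempty Venn regions
#' and reports each region's member set and count. Region labels name the
#' sets a member belongs to, joined by `&`.
#'
#' @param sets named list of >= 2 character vectors.
#' @return list with `regions` (named list of member vectors) and `counts`
#'   (named integer vector); counts sum to the size of the overall union.
#' @export
cross_stage_intersection <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  members <- sort(unique(unlist(sets, use.names = FALSE)))
  sig <- vapply(members, function(m) {
    paste(names(sets)[vapply(sets, function(s) m %in% s, TRUE)],
          collapse = "&")
  }, character(1))
  regions <- split(members, sig)
  list(regions = regions,
       counts = vapply(regions, length, integer(1)))
}

#' Common gene targets of drugs and microRNAs
#'
#' One row per gene targeted by at least one drug and at least one miRNA,
#' with the full targeting sets attached.
#'
#' @param drug_targets,mirna_targets long-format data.frames with columns
#'   `entity, entity_kind, gene` (see [read_target_sets()]); kinds must be
#'   `"drug"` and `"mirna"` respectively.
#' @return data.frame `gene, drugs, mirnas` where `drugs` and `mirnas` are
#'   list columns of character vectors; zero rows when there is no overlap.
#' @export
common_targets <- function(drug_targets, mirna_targets) {
  if (!all(drug_targets$entity_kind == "drug") ||
      !all(mirna_targets$entity_kind == "mirna")) {
    stop("entity kinds do not match the argument roles", call. = FALSE)
  }
  by_gene <- function(df) lapply(split(df$entity, df$gene), unique)
  dg <- by_gene(drug_targets)
  mg <- by_gene(mirna_targets)
  genes <- sort(intersect(names(dg), names(mg)))
  data.frame(gene = genes,
             drugs = I(unname(dg[genes])),
             mirnas = I(unname(mg[genes])),
             stringsAsFactors = FALSE)
}

#' Keep suppressor-miRNA hits on up-regulated genes
#'
#' Retains a (gene, drugs, miRNAs) triple iff the gene is up-regulated in
#' the disease analysis and at least one of its miRNAs is a disease
#' suppressor (`inhibits_disease`); disease-inducing miRNAs are removed
#' from the retained triples. A miRNA without a direction entry triggers a
#' warning and is treated as unknown (excluded).
#'
#' @param triples output of [common_targets()].
#' @param direction named character vector miRNA -> one of
#'   `inhibits_disease`, `induces_disease`, `unknown`.
#' @param upregulated character vector of up-regulated gene symbols.
#' @return filtered triples in the same layout, miRNA lists reduced to the
#'   suppressors.
#' @export
suppressor_filter <- function(triples, direction, upregulated) {
  all_mirnas <- unique(unlist(triples$mirnas, use.names = FALSE))
  missing <- setdiff(all_mirnas, names(direction))
  if (length(missing) > 0L) {
    warning("no direction for miRNA(s), treated as unknown: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- logical(nrow(triples))
  pruned <- vector("list", nrow(triples))
  for (i in seq_len(nrow(triples))) {
    if (!(triples$gene[i] %in% upregulated)) next
    m <- triples$mirnas[[i]]
    suppressors <- m[!is.na(direction[m]) &
                       direction[m] == "inhibits_disease"]
    if (length(suppressors) > 0L) {
      keep[i] <- TRUE
      pruned[[i]] <- suppressors
    }
  }
  out <- triples[keep, , drop = FALSE]
  out$mirnas <- I(pruned[keep])
  rownames(out) <- NULL
  out
}
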