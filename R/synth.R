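# Seeded synthetic-data generators. Each generator is a pure function of
# its arguments: the global RNG state is saved and restored, and a fixed
# seed reproduces the output exactly. The generators plant a known answer
# (consensus membership, cluster labels, top genes) and return it alongside
# the data so pipeline recovery can be asserted.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Synthetic connectivity-score records with planted consensus drugs
#'
#' A planted fraction of drugs receives qualifying scores (drawn uniformly
#' from `qualifying_range`) in exactly `min_tools` distinct tools within
#' each of `min_datasets` datasets, so they pass both consensus filters by
#' construction. The remaining drugs either stay silent or hit a single
#' tool only, which can never pass the tool consensus. All other cells get
#' non-qualifying scores above the threshold.
#'
#' @param n_drugs number of drugs (default 20).
#' @param n_tools,n_datasets grid dimensions (default 3 and 3, the worked
#'   example's layout).
#' @param consensus_fraction fraction of drugs planted into the consensus
#'   (default 0.5).
#' @param stage stage label stamped on every record.
#' @param methods gene-selection method labels (default two, statistical
#'   and network-walk stand-ins).
#' @param qualifying_range score range for qualifying records, within
#'   \[-1, -0.5\].
#' @param cfg [consensus_config()] the plant should satisfy.
#' @param seed RNG seed; fixed seed gives identical output.
#' @return list: `records` (drug-score data.frame), `consensus` (character
#'   vector of planted drugs, sorted).
#' @export
synth_tool_scores <- function(n_drugs = 20L, n_tools = 3L, n_datasets = 3L,
                              consensus_fraction = 0.5,
                              stage = "IPF_vs_Normal",
                              methods = c("limma", "netwalk"),
                              qualifying_range = c(-1, -0.6),
                              cfg = consensus_config(), seed = 1L) {
  stopifnot(n_drugs >= 1L, n_tools >= cfg$min_tools,
            n_datasets >= cfg$min_datasets,
            consensus_fraction >= 0, consensus_fraction <= 1,
            all(qualifying_range <= cfg$score_max))
  with_seed(seed, {
    drugs <- sprintf("drug%02d", seq_len(n_drugs))
    tools <- sprintf("T%d", seq_len(n_tools))
    datasets <- sprintf("D%d", seq_len(n_datasets))
    n_plant <- round(consensus_fraction * n_drugs)
    planted <- drugs[seq_len(n_plant)]
    rows <- list()
    qual <- function(n) stats::runif(n, qualifying_range[1L],
                                     qualifying_range[2L])
    for (d in drugs) {
      if (d %in% planted) {
        ds_hit <- sample(datasets, cfg$min_datasets)
        for (ds in ds_hit) {
          for (tl in sample(tools, cfg$min_tools)) {
            rows[[length(rows) + 1L]] <- data.frame(
              drug = d, tool = tl, method = sample(methods, 1L),
              dataset = ds, stage = stage, score = qual(1L),
              stringsAsFactors = FALSE)
          }
        }
      } else if (stats::runif(1L) < 0.5) {
        # single-tool hitter: qualifies nowhere under min_tools >= 2
        tl <- sample(tools, 1L)
        for (ds in sample(datasets, sample(n_datasets, 1L))) {
          rows[[length(rows) + 1L]] <- data.frame(
            drug = d, tool = tl, method = sample(methods, 1L),
            dataset = ds, stage = stage, score = qual(1L),
            stringsAsFactors = FALSE)
        }
      }
      # background noise above the threshold for every drug
      rows[[length(rows) + 1L]] <- data.frame(
        drug = d, tool = sample(tools, 1L), method = sample(methods, 1L),
        dataset = sample(datasets, 1L), stage = stage,
        score = stats::runif(1L, cfg$score_max + 0.01, 1),
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows)
    records <- records[!duplicated(records[, c("drug", "tool", "method",
                                               "dataset", "stage")]), ]
    rownames(records) <- NULL
    list(records = records, consensus = sort(planted))
  })
}

#' Synthetic binary fingerprints with planted cluster structure
#'
#' Each cluster has a random prototype bitstring; members copy it with
#' independent per-bit flip noise. With the defaults the within-cluster
#' Soergel distance (about 0.05) sits far below the between-cluster
#' distance (about 0.7), so the planted partition is recoverable at the
#' default dendrogram cut.
#'
#' @param n_drugs total fingerprints (default 30).
#' @param n_clusters planted clusters (default 3); must not exceed
#'   `n_drugs`.
#' @param n_bits fingerprint length (default 256).
#' @param flip_prob per-bit flip probability within a cluster (default
#'   0.01; 0 gives identical members).
#' @param seed RNG seed.
#' @return list: `fingerprints` (named list of 0/1 vectors), `labels`
#'   (named integer vector of planted cluster ids).
#' @export
synth_fingerprints <- function(n_drugs = 30L, n_clusters = 3L,
                               n_bits = 256L, flip_prob = 0.01,
                               seed = 1L) {
  stopifnot(n_clusters >= 1L, n_clusters <= n_drugs, n_bits >= 1L,
            flip_prob >= 0, flip_prob < 0.5)
  with_seed(seed, {
    protos <- lapply(seq_len(n_clusters), function(i) {
      stats::rbinom(n_bits, 1L, 0.5)
    })
    labels <- sort(rep_len(seq_len(n_clusters), n_drugs))
    fps <- lapply(seq_len(n_drugs), function(i) {
      fp <- protos[[labels[i]]]
      flip <- stats::runif(n_bits) < flip_prob
      ifelse(flip, 1L - fp, fp)
    })
    names(fps) <- sprintf("drug%02d", seq_len(n_drugs))
    list(fingerprints = fps,
         labels = structure(labels, names = names(fps)))
  })
}

#' Synthetic differential-expression table with a known answer key
#'
#' A planted fraction of genes is significant (p drawn below `p_max`), the
#' rest are not; fold changes are symmetric around zero with planted
#' magnitudes, so the true top-N lists are known by construction.
#'
#' @param n_genes number of genes (default 2000).
#' @param frac_signif fraction of genes with p below the cutoff (default
#'   0.3).
#' @param cfg [signature_config()] the answer key refers to.
#' @param seed RNG seed.
#' @return list: `table` (gene/fold_change/p_value data.frame), `key`
#'   (`gene_signature` with the true top lists).
#' @export
synth_deg_table <- function(n_genes = 2000L, frac_signif = 0.3,
                            cfg = signature_config(), seed = 1L) {
  stopifnot(n_genes >= 1L, frac_signif >= 0, frac_signif <= 1)
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    signif <- stats::runif(n_genes) < frac_signif
    p <- ifelse(signif,
                stats::runif(n_genes, 0, cfg$p_max * 0.999),
                stats::runif(n_genes, cfg$p_max, 1))
    fc <- stats::rnorm(n_genes, 0, 2)
    table <- data.frame(gene = genes, fold_change = fc, p_value = p,
                        stringsAsFactors = FALSE)
    s <- table[signif, ]
    up <- s[s$fold_change > 0, ]
    up <- up[order(-up$fold_change, up$gene), ]
    down <- s[s$fold_change < 0, ]
    down <- down[order(down$fold_change, down$gene), ]
    key <- gene_signature(utils::head(up$gene, cfg$n_up),
                          utils::head(down$gene, cfg$n_down))
    list(table = table, key = key)
  })
}
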