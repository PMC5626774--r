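# Structural clustering of binary fingerprints: Soergel distance, Ward
# linkage via the Lance-Williams recurrence applied directly to the supplied
# distances, a height cut, and top-scored cluster representatives.
#
# Ward's criterion on a non-Euclidean distance (Soergel here) is
# mathematically improper, but it is the procedure of the chemoinformatics
# server being mirrored; fidelity wins over metric purity. The merge order
# is deterministic: the smallest pairwise distance wins, ties broken by the
# (row, column) index of the earlier-created clusters.

#' Clustering configuration
#'
#' @param linkage only `"ward"` is implemented.
#' @param cut_height dendrogram cut height for flat clusters (default 1, the
#'   published threshold).
#' @param fingerprint_kind free-text declaration of the fingerprint type,
#'   carried into outputs for provenance.
#' @return list with class `cluster_config`.
#' @export
cluster_config <- function(linkage = "ward", cut_height = 1.0,
                           fingerprint_kind = "unspecified") {
  linkage <- match.arg(linkage, "ward")
  if (!is.numeric(cut_height) || cut_height <= 0) {
    stop("cut_height must be positive", call. = FALSE)
  }
  structure(list(linkage = linkage, cut_height = cut_height,
                 fingerprint_kind = fingerprint_kind),
            class = "cluster_config")
}

#' Soergel distance between two binary fingerprints
#'
#' For bit vectors this is one minus the Tanimoto coefficient:
#' `1 - |a AND b| / |a OR b|`. It is a proper metric on bit vectors: zero
#' iff the bit sets are identical, symmetric, and triangle-inequality
#' compliant. Two all-zero fingerprints have no defined Tanimoto value; the
#' distance is taken as 0 with a warning.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return distance in \[0, 1\].
#' @export
soergel_distance <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch",
                                   call. = FALSE)
  union_ <- sum(a | b)
  if (union_ == 0L) {
    warning("both fingerprints empty; distance defined as 0", call. = FALSE)
    return(0)
  }
  1 - sum(a & b) / union_
}

#' Pairwise Soergel distance matrix
#'
#' @param fps named list of 0/1 vectors of one shared length (see
#'   [read_fingerprints()]).
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\],
#'   dimnames from `fps`.
#' @export
distance_matrix <- function(fps) {
  n <- length(fps)
  if (n < 2L) stop("need at least 2 fingerprints", call. = FALSE)
  if (length(unique(lengths(fps))) > 1L) {
    stop("fingerprints must share one length", call. = FALSE)
  }
  # vectorized: intersection = crossprod of bit matrix
  m <- do.call(cbind, lapply(fps, as.numeric))
  inter <- crossprod(m)
  ones <- colSums(m)
  union_ <- outer(ones, ones, `+`) - inter
  d <- ifelse(union_ == 0, 0, 1 - inter / union_)
  diag(d) <- 0
  dimnames(d) <- list(names(fps), names(fps))
  d
}

#' Ward-linkage hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with the Ward criterion expressed through the
#' Lance-Williams update on the supplied distances (equivalent to classic
#' Ward when the input is squared Euclidean; applied verbatim to Soergel
#' distances here, matching the mirrored server). Flat clusters come from
#' cutting the tree at `cut_height`; ids are contiguous from 1 in order of
#' each cluster's first drug in input order.
#'
#' @param dm symmetric distance matrix with dimnames (e.g. from
#'   [distance_matrix()]).
#' @param cfg a [cluster_config()].
#' @return list of class `ward_clustering`: `tree` (an `hclust` object),
#'   `clusters` (named integer vector drug -> cluster id), `cut_height`.
#' @export
ward_cluster <- function(dm, cfg = cluster_config()) {
  stopifnot(inherits(cfg, "cluster_config"))
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2L) stop("need at least 2 items to cluster", call. = FALSE)
  if (!isTRUE(all.equal(dm, t(dm))) || any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal",
         call. = FALSE)
  }
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("item", seq_len(n))

  d <- dm
  size <- rep(1L, n)
  id <- -seq_len(n)              # hclust convention: negative = leaf
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); best_d <- Inf
    act <- which(active)
    for (ii in seq_along(act)[-length(act)]) {
      i <- act[ii]
      js <- act[(ii + 1L):length(act)]
      dij <- d[i, js]
      k <- which.min(dij)        # first minimum: index tie-break
      if (dij[k] < best_d) { best_d <- dij[k]; best <- c(i, js[k]) }
    }
    i <- best[1L]; j <- best[2L]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # Lance-Williams Ward update against every other active cluster
    others <- setdiff(act, c(i, j))
    if (length(others) > 0L) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      dnew <- ((ni + nk) * d[i, others] + (nj + nk) * d[j, others] -
                 nk * best_d) / (ni + nj + nk)
      d[i, others] <- dnew; d[others, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    active[j] <- FALSE
  }

  tree <- structure(list(merge = merge, height = height,
                         order = tree_order(merge),
                         labels = labels, method = "ward",
                         dist.method = "soergel", call = match.call()),
                    class = "hclust")
  list(tree = tree,
       clusters = cut_clusters(tree, cfg$cut_height),
       cut_height = cfg$cut_height) |>
    structure(class = "ward_clustering")
}

# leaf order for plotting: left-to-right traversal of the merge matrix
tree_order <- function(merge) {
  walk <- function(node) {
    if (node < 0L) return(-node)
    c(walk(merge[node, 1L]), walk(merge[node, 2L]))
  }
  walk(nrow(merge))
}

#' Cut a merge tree into flat clusters
#'
#' Merges with height at most `h` are applied; the resulting connected
#' groups are the flat clusters, numbered contiguously from 1 by first
#' member in input order. A cut above the root height yields one cluster;
#' below the first merge, all singletons.
#'
#' @param tree `hclust`-structured merge tree (from [ward_cluster()]).
#' @param h cut height.
#' @return named integer vector: label -> cluster id.
#' @export
cut_clusters <- function(tree, h) {
  n <- length(tree$height) + 1L
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  node_rep <- integer(n - 1L)    # leaf representative of each merge node
  for (step in seq_len(n - 1L)) {
    l <- tree$merge[step, 1L]; r <- tree$merge[step, 2L]
    lr <- if (l < 0L) -l else node_rep[l]
    rr <- if (r < 0L) -r else node_rep[r]
    if (tree$height[step] <= h) parent[find(rr)] <- find(lr)
    node_rep[step] <- lr
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ids <- match(roots, unique(roots))
  structure(ids, names = tree$labels)
}

#' Top-scored representative of each structural cluster
#'
#' Within each cluster the member with the highest composite score is the
#' representative; ties break alphabetically. Output is ordered by the
#' representatives' scores, best first.
#'
#' @param assignment named integer vector drug -> cluster id (e.g.
#'   `ward_cluster(...)$clusters`) or a `ward_clustering` object.
#' @param ranking named numeric score map covering every clustered drug.
#' @return data.frame `cluster, drug, score, size`.
#' @export
select_representatives <- function(assignment, ranking) {
  if (inherits(assignment, "ward_clustering")) {
    assignment <- assignment$clusters
  }
  drugs <- names(assignment)
  miss <- setdiff(drugs, names(ranking))
  if (length(miss) > 0L) {
    stop("drugs missing from ranking: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  reps <- lapply(split(drugs, assignment), function(members) {
    s <- ranking[members]
    best <- members[order(-s, members)][1L]
    data.frame(drug = best, score = as.numeric(ranking[best]),
               size = length(members), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, reps)
  out <- data.frame(cluster = as.integer(names(reps)), out,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a merge tree in Newick format
#'
#' Branch lengths are height differences between a node and its parent, so
#' leaf-to-root path length equals the root merge height.
#'
#' @param tree `hclust`-structured merge tree.
#' @return single Newick string terminated by ";".
#' @export
tree_newick <- function(tree) {
  build <- function(node, parent_h) {
    if (node < 0L) {
      sprintf("%s:%.6g", tree$labels[-node], parent_h)
    } else {
      h <- tree$height[node]
      sprintf("(%s,%s):%.6g",
              build(tree$merge[node, 1L], h),
              build(tree$merge[node, 2L], h),
              parent_h - h)
    }
  }
  root <- length(tree$height)
  h <- tree$height[root]
  paste0("(", build(tree$merge[root, 1L], h), ",",
         build(tree$merge[root, 2L], h), ");")
}
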