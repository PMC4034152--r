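#' Euclidean distance matrix of a feature set
#'
#' @param features a `feature_set` (see [extract_feature_set()]) or a
#'   numeric matrix with one column per sample.
#' @return A `dist` object labelled with sample ids.
#' @export
distance_matrix <- function(features) {
  m <- if (inherits(features, "feature_set")) features$values else
    as.matrix(features)
  if (anyNA(m)) stop("features contain NA")
  stats::dist(t(m), method = "euclidean")
}

#' Ward hierarchical clustering of spectra
#'
#' Agglomerative clustering with Ward's minimum-variance criterion on
#' Euclidean distances. The default `"ward_d2"` convention reports merge
#' heights in distance units (height^2 = 2 x the increase in total
#' within-cluster sum of squares), so two singletons at distance d merge at
#' height d. Merge heights are the "heterogeneity" of the groups they
#' create.
#'
#' @param dm a `dist` object (see [distance_matrix()]).
#' @param method `"ward_d2"` (default) or `"ward_d"` (squared-distance
#'   variant, for sensitivity checks).
#' @return Object of class `hca_tree`: list with the underlying `hclust`
#'   fit (`fit`), `leaf_ids`, and `merges` (data frame `node_a`, `node_b`,
#'   `height`, `size`; negative node = leaf index).
#' @export
ward_linkage <- function(dm, method = c("ward_d2", "ward_d")) {
  method <- match.arg(method)
  stopifnot(inherits(dm, "dist"))
  if (anyNA(dm) || any(!is.finite(dm))) stop("distances contain NA/Inf")
  n <- attr(dm, "Size")
  if (n < 2) stop("need at least two samples to cluster")
  fit <- stats::hclust(dm, method = if (method == "ward_d2") "ward.D2"
                       else "ward.D")
  sizes <- cluster_sizes(fit$merge)
  structure(list(fit = fit,
                 leaf_ids = fit$labels %||% as.character(seq_len(n)),
                 merges = data.frame(node_a = fit$merge[, 1],
                                     node_b = fit$merge[, 2],
                                     height = fit$height,
                                     size = sizes)),
            class = "hca_tree")
}

cluster_sizes <- function(merge) {
  sz <- integer(nrow(merge))
  for (i in seq_len(nrow(merge))) {
    sz[i] <- sum(ifelse(merge[i, ] < 0, 1L, sz[pmax(merge[i, ], 1)]))
  }
  sz
}

#' @export
print.hca_tree <- function(x, ...) {
  cat(sprintf("<hca_tree> %d leaves, %d merges, height range %.4g..%.4g\n",
              length(x$leaf_ids), nrow(x$merges),
              min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last `k - 1` merges.
#'
#' @param tree an `hca_tree`.
#' @param k number of clusters, `1 <= k <= n`.
#' @return Named integer vector: cluster index per sample id.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "hca_tree"))
  n <- length(tree$leaf_ids)
  if (k < 1 || k > n) stop("k must be between 1 and the number of leaves")
  cl <- stats::cutree(tree$fit, k = k)
  names(cl) <- tree$leaf_ids
  cl
}

#' Species assignment report for a k-cut
#'
#' Cuts the tree at `k`, labels every cluster with its majority species
#' (ties broken alphabetically, with a warning), counts samples whose true
#' species differs from their cluster's label, and records each cluster's
#' heterogeneity (the height of its last internal merge; 0 for singletons).
#'
#' @param tree an `hca_tree`.
#' @param truth named character vector: species per sample id (must cover
#'   all leaves).
#' @param k number of clusters.
#' @return List of class `cluster_report`: `k`, `assignments` (data frame
#'   `sample_id`, `cluster`, `species`, `assigned_label`, `correct`),
#'   `cluster_label`, `n_misassigned`, `accuracy`,
#'   `per_cluster_heterogeneity`.
#' @export
species_report <- function(tree, truth, k) {
  cl <- cut_tree(tree, k)
  ids <- tree$leaf_ids
  if (!all(ids %in% names(truth)))
    stop("truth lacks species for: ",
         paste(utils::head(setdiff(ids, names(truth))), collapse = ", "))
  sp <- truth[ids]
  labels <- character(k)
  for (g in seq_len(k)) {
    tab <- sort(table(sp[cl == g]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1)
      warning(sprintf("cluster %d: majority tie (%s); using %s", g,
                      paste(top, collapse = ", "), sort(top)[1]))
    labels[g] <- sort(top)[1]
  }
  assigned <- labels[cl]
  miss <- sum(assigned != sp)
  het <- vapply(seq_len(k), function(g)
    subtree_heterogeneity(tree, ids[cl == g]), numeric(1))
  structure(list(k = k,
                 assignments = data.frame(sample_id = ids, cluster = unname(cl),
                                          species = unname(sp),
                                          assigned_label = assigned,
                                          correct = assigned == sp,
                                          stringsAsFactors = FALSE),
                 cluster_label = labels,
                 n_misassigned = miss,
                 accuracy = 1 - miss / length(ids),
                 per_cluster_heterogeneity = het),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d: accuracy %.4f (%d of %d misassigned)\n",
              x$k, x$accuracy, x$n_misassigned, nrow(x$assignments)))
  for (g in seq_len(x$k))
    cat(sprintf("  cluster %d: %-22s n = %3d  heterogeneity %.4g\n", g,
                x$cluster_label[g], sum(x$assignments$cluster == g),
                x$per_cluster_heterogeneity[g]))
  invisible(x)
}

# Height of the last merge entirely inside the given leaf set (0 if the set
# is a singleton). The set need not be a subtree.
subtree_heterogeneity <- function(tree, leaves) {
  sets <- merge_leaf_sets(tree)
  inside <- vapply(sets, function(s) all(s %in% leaves), logical(1))
  if (!any(inside)) 0 else max(tree$merges$height[inside])
}

# leaf-id set below each internal merge node
merge_leaf_sets <- function(tree) {
  m <- tree$fit$merge
  ids <- tree$leaf_ids
  sets <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    grab <- function(x) if (x < 0) ids[-x] else sets[[x]]
    sets[[i]] <- c(grab(m[i, 1]), grab(m[i, 2]))
  }
  sets
}

#' Heterogeneity ratio between two subtrees
#'
#' The heterogeneity of a connected subtree is the height of its root merge
#' (the merge at which all of its leaves, and nothing else, are first
#' together). Each group must be exactly the leaf set of some merge node
#' (or a singleton, heterogeneity 0).
#'
#' @param tree an `hca_tree`.
#' @param group_a,group_b character vectors of leaf ids.
#' @return `heterogeneity(group_a) / heterogeneity(group_b)`.
#' @export
heterogeneity_ratio <- function(tree, group_a, group_b) {
  h <- function(g) {
    g <- unique(g)
    if (!all(g %in% tree$leaf_ids))
      stop("unknown leaves: ",
           paste(utils::head(setdiff(g, tree$leaf_ids)), collapse = ", "))
    if (length(g) == 1) return(0)
    sets <- merge_leaf_sets(tree)
    hit <- which(vapply(sets, function(s)
      length(s) == length(g) && setequal(s, g), logical(1)))
    if (!length(hit)) {
      small <- which(vapply(sets, function(s) all(g %in% s), logical(1)))
      clade <- sets[[small[which.min(lengths(sets)[small])]]]
      stop("group is not a subtree; smallest containing clade also holds: ",
           paste(utils::head(setdiff(clade, g)), collapse = ", "))
    }
    tree$merges$height[hit[1]]
  }
  h(group_a) / h(group_b)
}

#' Export a dendrogram as Newick
#'
#' Branch lengths follow the usual ultrametric convention (leaf branch =
#' parent merge height / 2; internal branch = difference of half-heights),
#' via [ape::as.phylo()]. The file is readable by any standard Newick
#' parser.
#'
#' @param tree an `hca_tree`.
#' @param path output file path.
#' @return Invisibly, the Newick string.
#' @export
export_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hca_tree"))
  fit <- tree$fit
  fit$labels <- tree$leaf_ids
  phy <- ape::as.phylo(fit)
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}
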