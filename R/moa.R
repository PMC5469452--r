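# Mode-of-action assignment by profile clustering ---------------------------
#
# Fraction profiles are clustered together with reference-compound profiles
# on Pearson distance (1 - r); the tree is cut and each fraction inherits
# the majority MoA label of the reference compounds in its cluster.

#' Pearson dissimilarity between profiles
#'
#' `d(i, j) = 1 - r(i, j)` with `r` the (centered) Pearson correlation over
#' the features both profiles have; `d` lies in \[0, 2\], is symmetric and
#' has a zero diagonal. Note 1 - r is not a metric (the triangle inequality
#' can fail); it is used as an agglomeration dissimilarity only.
#'
#' @param mat samples x features matrix (NAs allowed; pairwise-complete
#'   correlation).
#' @param min_shared minimum shared non-missing features per pair.
#' @return symmetric dissimilarity matrix.
#' @export
pearson_distance_matrix <- function(mat, min_shared = 3) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2)
  vars <- apply(mat, 1, stats::var, na.rm = TRUE)
  if (any(vars == 0 | is.na(vars))) {
    bad <- rownames(mat)[which(vars == 0 | is.na(vars))]
    stop("zero-variance profile(s): correlation undefined for ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  shared <- crossprod(t(!is.na(mat)) * 1)
  if (any(shared < min_shared)) {
    i <- which(shared < min_shared, arr.ind = TRUE)[1, ]
    stop("profiles ", rownames(mat)[i[1]], " and ", rownames(mat)[i[2]],
         " share fewer than ", min_shared, " features")
  }
  r <- stats::cor(t(mat), use = "pairwise.complete.obs")
  d <- 1 - r
  diag(d) <- 0
  d[d < 0] <- 0  # numerical guard at r = 1
  d
}

#' Agglomerative clustering of profiles
#'
#' Hierarchical agglomeration of a dissimilarity matrix; average linkage
#' (UPGMA) by default, with complete and single selectable. Leaves are
#' ordered tightest-subtree-first: at every internal node the child merged
#' at the lower height is listed first (leaves count as height 0; ties
#' break on the smaller node index), giving stable heatmap ordering.
#'
#' @param d symmetric non-negative dissimilarity matrix with labelled rows.
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return a `cluster_tree`: list with the underlying `hclust` object,
#'   `labels`, `order` (leaf indices) and `linkage`.
#' @export
hierarchical_cluster <- function(d, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  hc <- stats::hclust(stats::as.dist(d), method = linkage)
  ord <- tightest_first_order(hc$merge, hc$height)
  structure(list(hclust = hc, labels = hc$labels, order = ord,
                 linkage = linkage),
            class = "cluster_tree")
}

# leaf order with the lower-height subtree first at every node
# (leaves count as height 0; ties break on the smallest leaf index inside)
tightest_first_order <- function(merge, height) {
  node_height <- function(k) if (k < 0) 0 else height[k]
  min_leaf <- function(k) if (k < 0) -k else
    min(min_leaf(merge[k, 1]), min_leaf(merge[k, 2]))
  rec <- function(k) {
    if (k < 0) return(-k)
    a <- merge[k, 1]; b <- merge[k, 2]
    ha <- node_height(a); hb <- node_height(b)
    first_a <- ha < hb || (ha == hb && min_leaf(a) < min_leaf(b))
    if (first_a) c(rec(a), rec(b)) else c(rec(b), rec(a))
  }
  rec(nrow(merge))
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree> %d leaves, %s linkage, height range [%.3g, %.3g]\n",
              length(x$labels), x$linkage, min(x$hclust$height),
              max(x$hclust$height)))
  invisible(x)
}

#' Cut a cluster tree
#'
#' @param tree a `cluster_tree`.
#' @param k number of clusters, or
#' @param h cut height (merges above `h` are split).
#' @return named integer cluster membership.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "cluster_tree"), !is.null(k) || !is.null(h))
  stats::cutree(tree$hclust, k = k, h = h)
}

#' Assign modes of action to fractions from a joint cluster tree
#'
#' Cuts the tree built on the union of fraction and reference profiles (by
#' height `h`, default 0.3, i.e. within-cluster r >= 0.7; or by count `k`)
#' and labels each fraction with the majority `moa_label` among the
#' reference compounds in its cluster. Ties take the label of the nearest
#' reference by correlation; clusters without references yield
#' `"unassigned"`. The globally nearest reference and its correlation are
#' always reported.
#'
#' @param tree `cluster_tree` over `rownames(mat)`.
#' @param mat the profile matrix the tree was built on.
#' @param ref_labels named character vector: reference row name ->
#'   moa_label. Rows of `mat` not named here are treated as fractions.
#' @param k,h tree cut (see [cut_tree()]); default `h = 0.3`.
#' @return a data.frame: sample_id, predicted_moa, support (fraction of
#'   cluster references sharing the call), cluster, n_refs_in_cluster,
#'   nearest_reference, nearest_r.
#' @export
assign_moa <- function(tree, mat, ref_labels, k = NULL, h = 0.3) {
  stopifnot(inherits(tree, "cluster_tree"),
            setequal(tree$labels, rownames(mat)))
  if (is.null(names(ref_labels)) || !all(names(ref_labels) %in% rownames(mat)))
    stop("ref_labels must be named by reference rows of the matrix")
  if (!is.null(k)) h <- NULL
  cl <- cut_tree(tree, k = k, h = h)
  if (length(unique(cl)) == 1)
    warning("tree cut yields a single cluster containing everything")
  refs <- names(ref_labels)
  fractions <- setdiff(rownames(mat), refs)
  r_fr <- stats::cor(t(mat[fractions, , drop = FALSE]),
                     t(mat[refs, , drop = FALSE]),
                     use = "pairwise.complete.obs")
  out <- lapply(fractions, function(f) {
    members <- names(cl)[cl == cl[f]]
    cluster_refs <- intersect(members, refs)
    nearest_i <- which.max(r_fr[f, ])
    if (length(cluster_refs) == 0) {
      pred <- "unassigned"; support <- 0
    } else {
      tabs <- sort(table(ref_labels[cluster_refs]), decreasing = TRUE)
      top <- names(tabs)[tabs == tabs[1]]
      pred <- if (length(top) == 1) top[1] else {
        near_in <- cluster_refs[which.max(r_fr[f, cluster_refs])]
        unname(ref_labels[near_in])
      }
      support <- unname(tabs[pred] / length(cluster_refs))
    }
    data.frame(sample_id = f, predicted_moa = pred, support = support,
               cluster = unname(cl[f]),
               n_refs_in_cluster = length(cluster_refs),
               nearest_reference = refs[nearest_i],
               nearest_r = unname(r_fr[f, nearest_i]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# quote a Newick label when it contains structural characters
newick_label <- function(x) {
  ifelse(grepl("[][ \t():;,']", x),
         paste0("'", gsub("'", "''", x), "'"), x)
}

#' Export a cluster tree as Newick text
#'
#' The dendrogram is ultrametric: a node sits at depth `height / 2` so the
#' path length between two leaves equals their merge height (the
#' dissimilarity at which they join). Branch lengths are depth differences
#' between a node and its parent; two leaves merging at height 0.4 export
#' as `(A:0.2,B:0.2);`. Labels containing spaces or Newick syntax
#' characters are quoted.
#'
#' @param tree a `cluster_tree`.
#' @return a single Newick string, terminated by `;`.
#' @export
export_newick <- function(tree) {
  stopifnot(inherits(tree, "cluster_tree"))
  hc <- tree$hclust
  labels <- newick_label(hc$labels)
  node_str <- function(k, parent_depth) {
    if (k < 0)
      return(sprintf("%s:%s", labels[-k], format(parent_depth, digits = 15)))
    d <- hc$height[k] / 2
    sprintf("(%s,%s):%s",
            node_str(hc$merge[k, 1], d), node_str(hc$merge[k, 2], d),
            format(parent_depth - d, digits = 15))
  }
  root <- nrow(hc$merge)
  d <- hc$height[root] / 2
  sprintf("(%s,%s);", node_str(hc$merge[root, 1], d),
          node_str(hc$merge[root, 2], d))
}

#' Render a clustered profile heat map
#'
#' Rows follow the tree's tightest-first leaf order; the diverging color
#' map is centered at 0 and spans \[-1, 1\] (negative scores blue, positive
#' yellow). The ordered matrix is always written/returned so rendering is
#' testable without pixels; pass `file` to also draw a PNG via pheatmap.
#'
#' @param mat profile matrix.
#' @param tree `cluster_tree` over the matrix rows.
#' @param tsv optional path for the row-ordered TSV.
#' @param file optional PNG path.
#' @return the row-ordered matrix, invisibly.
#' @export
render_heatmap <- function(mat, tree, tsv = NULL, file = NULL) {
  stopifnot(setequal(tree$labels, rownames(mat)))
  ordered <- mat[tree$labels[tree$order], , drop = FALSE]
  if (!is.null(tsv))
    data.table::fwrite(data.frame(sample_id = rownames(ordered), ordered,
                                  check.names = FALSE), tsv, sep = "\t")
  if (!is.null(file)) {
    cols <- grDevices::colorRampPalette(c("blue", "black", "yellow"))(101)
    grDevices::png(file, width = 900,
                   height = max(300, 12 * nrow(ordered) + 150))
    pheatmap::pheatmap(ordered, color = cols,
                       breaks = seq(-1, 1, length.out = 102),
                       cluster_rows = FALSE, cluster_cols = FALSE,
                       fontsize_row = 6)
    grDevices::dev.off()
  }
  invisible(ordered)
}
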