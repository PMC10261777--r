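# Hierarchical clustering of treatments by their standardized property
# profiles ("compound correlation" dendrograms).

#' Standardize a treatment feature matrix
#'
#' Transforms every column to mean 0 and standard deviation 1, using the
#' population standard deviation (divisor `n`). Columns with zero variance
#' carry no clustering information and are dropped with a warning. The
#' transform is idempotent.
#'
#' @param x Numeric matrix or data frame; rows are treatments (row names
#'   kept as labels), columns are properties.
#' @return A numeric matrix with the same rows and the surviving columns.
#' @export
standardize_features <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("feature matrix must be numeric", call. = FALSE)
  if (nrow(m) < 2) stop("need at least 2 treatments", call. = FALSE)
  sds <- apply(m, 2, function(col) sqrt(mean((col - mean(col))^2)))
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning(sprintf("dropping zero-variance column(s): %s",
                    paste(colnames(m)[drop], collapse = ", ")), call. = FALSE)
    m <- m[, !drop, drop = FALSE]
    sds <- sds[!drop]
  }
  if (ncol(m) == 0) stop("no columns left after dropping constants", call. = FALSE)
  scale(m, center = colMeans(m), scale = sds)[, , drop = FALSE]
}

#' Cluster treatments into a dendrogram
#'
#' Agglomerative hierarchical clustering of treatment property profiles.
#' `"ward"` uses the Ward minimum-variance criterion on Euclidean distances
#' (`stats::hclust` method `"ward.D2"`); `"average"` and `"complete"`
#' linkage are also available. Merge heights are non-decreasing for all
#' three linkages, and the result is deterministic given the input.
#'
#' @param x Standardized numeric matrix (see [standardize_features()]),
#'   rows = treatments with row-name labels, at least 2 rows.
#' @param distance Distance metric; only `"euclidean"` is supported.
#' @param linkage One of `"ward"`, `"average"`, `"complete"`.
#' @return An object of class `treatment_dendrogram` wrapping the merge
#'   tree: fields `hclust` (the [stats::hclust] object), `labels`,
#'   `linkage`, `distance`.
#' @export
cluster_treatments <- function(x, distance = "euclidean",
                               linkage = c("ward", "average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 treatments to cluster", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- as.character(seq_len(nrow(m)))
  method <- c(ward = "ward.D2", average = "average", complete = "complete")[[linkage]]
  h <- hclust(dist(m, method = "euclidean"), method = method)
  structure(list(hclust = h, labels = h$labels, linkage = linkage,
                 distance = distance),
            class = "treatment_dendrogram")
}

#' @export
print.treatment_dendrogram <- function(x, ...) {
  cat(sprintf("<treatment_dendrogram> %d leaves, %s linkage, root height %.4g\n",
              length(x$labels), x$linkage, max(x$hclust$height)))
  invisible(x)
}

#' Cut a dendrogram at a fraction of its root height
#'
#' Removes every merge whose height exceeds `fraction` times the root
#' (maximum) merge height and returns the resulting flat clusters.
#' `fraction = 1` keeps everything in one cluster; `fraction = 0` leaves
#' each treatment alone (unless treatments coincide exactly).
#'
#' @param tree A [cluster_treatments()] result.
#' @param fraction Cut height as a fraction of the root height, in `[0, 1]`.
#' @return Named integer vector of cluster memberships, one per leaf.
#' @export
cut_tree <- function(tree, fraction) {
  stopifnot(inherits(tree, "treatment_dendrogram"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be a single number in [0, 1]", call. = FALSE)
  cutree(tree$hclust, h = fraction * max(tree$hclust$height))
}

#' Leaves under each side of the root split
#'
#' @param tree A [cluster_treatments()] result.
#' @return A list of two character vectors of leaf labels, the members of
#'   the two clusters merged last.
#' @export
root_split <- function(tree) {
  stopifnot(inherits(tree, "treatment_dendrogram"))
  grp <- cutree(tree$hclust, k = 2)
  split(names(grp), grp)
}

quote_newick_label <- function(lab) {
  bad <- grepl("[][():;,' \t]", lab)
  lab[bad] <- paste0("'", gsub("'", "''", lab[bad]), "'")
  lab
}

#' Serialize a dendrogram to Newick
#'
#' Branch lengths are height differences between a node and its parent, so
#' the root-to-leaf path length equals the root merge height and the tree
#' is ultrametric. Labels containing Newick metacharacters are quoted.
#'
#' @param tree A [cluster_treatments()] result.
#' @param file Optional path; when given, the string is also written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
export_dendrogram <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "treatment_dendrogram"))
  h <- tree$hclust
  labs <- quote_newick_label(h$labels)
  node <- function(i) {  # i: row of the merge matrix
    part <- lapply(h$merge[i, ], function(j) {
      if (j < 0) list(str = labs[-j], height = 0, min_leaf = -j)
      else node(j)
    })
    # deterministic child order: subtree holding the smallest row first
    if (part[[2]]$min_leaf < part[[1]]$min_leaf) part <- part[c(2, 1)]
    str <- paste0("(",
                  part[[1]]$str, ":", format(h$height[i] - part[[1]]$height, digits = 15),
                  ",",
                  part[[2]]$str, ":", format(h$height[i] - part[[2]]$height, digits = 15),
                  ")")
    list(str = str, height = h$height[i],
         min_leaf = min(part[[1]]$min_leaf, part[[2]]$min_leaf))
  }
  nwk <- paste0(node(nrow(h$merge))$str, ";")
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
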