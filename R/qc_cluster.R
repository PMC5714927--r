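# Sample-level QC: distance matrix and hierarchical clustering of normalized
# count profiles. Biological replicates should form one cluster and
# conditions should separate.

#' Pairwise sample distances on normalized count profiles
#'
#' Distances are computed over the union of sites on the RPM matrix (scale
#' invariant: doubling a sample's raw counts leaves it unchanged). Metrics:
#' `"pearson"` gives 1 - Pearson correlation (range 0-2), `"euclidean"` the
#' Euclidean distance on log1p(RPM).
#'
#' @param table A `site_count_table` (normalized on the fly if needed).
#' @param metric `"pearson"` (default) or `"euclidean"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
sample_distance_matrix <- function(table, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  stopifnot(inherits(table, "site_count_table"))
  if (is.null(table$rpm)) table <- normalize_rpm(table)
  rpm <- table$rpm
  if (ncol(rpm) < 2L) stop("need at least two samples")
  if (metric == "pearson") {
    sds <- apply(rpm, 2L, stats::sd)
    if (any(sds == 0)) {
      stop("zero variance under the correlation metric for sample(s): ",
           paste(colnames(rpm)[sds == 0], collapse = ", "))
    }
    d <- 1 - cor(rpm, method = "pearson")
  } else {
    d <- as.matrix(stats::dist(t(log1p(rpm)), method = "euclidean"))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}

#' Average-linkage hierarchical clustering of samples
#'
#' UPGMA clustering of a metric sample-distance matrix; deterministic given
#' the input (samples are ordered lexicographically before clustering so
#' permuting the input leaves the tree unchanged).
#'
#' @param distances Symmetric distance matrix from [sample_distance_matrix()].
#' @param linkage Linkage method (default `"average"`).
#' @return An object of class `msap_dendrogram`: list with `hclust` (the
#'   stats::hclust fit), `merge`, `height`, `labels`, `newick` (serialized
#'   tree text with heights).
#' @export
hierarchical_cluster <- function(distances, linkage = "average") {
  distances <- as.matrix(distances)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  ord <- order(colnames(distances))
  distances <- distances[ord, ord]
  fit <- hclust(as.dist(distances), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(fit))
  structure(
    list(hclust = fit, merge = fit$merge, height = fit$height,
         labels = fit$labels, newick = newick),
    class = "msap_dendrogram"
  )
}

#' @export
print.msap_dendrogram <- function(x, ...) {
  cat("<msap_dendrogram>", length(x$labels), "leaves\n")
  cat(x$newick, "\n")
  invisible(x)
}

#' Top bipartition of a sample dendrogram
#'
#' Cuts the tree into two groups at the last merge; used to check that
#' condition groups separate before replicates do.
#'
#' @param dendro An `msap_dendrogram`.
#' @return Named integer vector (sample -> group 1 or 2).
#' @export
top_bipartition <- function(dendro) {
  cutree(dendro$hclust, k = 2L)
}

#' Write a dendrogram as newick text
#'
#' @param dendro An `msap_dendrogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(dendro, path) {
  writeLines(dendro$newick, path)
  invisible(path)
}
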