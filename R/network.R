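#' Hierarchical clustering of samples by a signature
#'
#' Clusters sample profiles restricted to the signature analytes with
#' average (UPGMA) linkage on the Pearson correlation distance
#' `d = 1 - r`. The clustering itself is unsupervised; the known group
#' labels are only used afterwards to score the cut (each flat cluster is
#' assigned its majority label and the minority samples count as
#' misclassified). Analytes (rows of the heatmap) are clustered the same
#' way.
#'
#' @param table an [analyte_table()]; values are autoscaled internally.
#' @param signature a `progsig_signature` or character vector of analyte
#'   IDs.
#' @param n_clusters integer vector of flat-cut sizes (default `c(2, 4)`).
#' @return A `signature_dendrogram`: the sample `hclust` tree, the analyte
#'   tree, per-cut cluster `assignments`, per-cut `misclassified` counts,
#'   and the group labels used for scoring.
#' @export
hcluster <- function(table, signature, n_clusters = c(2, 4)) {
  stopifnot(inherits(table, "analyte_table"))
  ids <- if (inherits(signature, "progsig_signature"))
    signature$analyte_ids else signature
  if (nrow(table$values) < 3) stop("need >= 3 samples to cluster")
  tab <- subset_table(table, analytes = ids)
  x <- autoscale(tab, on_zero_variance = "drop")$table$values
  d_samples <- as.dist(1 - cor(t(x)))
  hc_samples <- hclust(d_samples, method = "average")
  hc_analytes <- if (ncol(x) >= 3)
    hclust(as.dist(1 - cor(x)), method = "average") else NULL
  groups <- table$sample_meta$group
  assignments <- list()
  misclassified <- integer()
  for (k in n_clusters) {
    cl <- stats::cutree(hc_samples, k = k)
    assignments[[as.character(k)]] <- cl
    wrong <- sum(vapply(split(groups, cl), function(g) {
      length(g) - max(table(g))
    }, numeric(1)))
    misclassified[as.character(k)] <- wrong
  }
  structure(
    list(sample_tree = hc_samples, analyte_tree = hc_analytes,
         assignments = assignments, misclassified = misclassified,
         groups = setNames(groups, rownames(x))),
    class = "signature_dendrogram"
  )
}

#' @export
print.signature_dendrogram <- function(x, ...) {
  cat("signature_dendrogram:", length(x$groups), "samples\n")
  for (k in names(x$assignments)) {
    cat(sprintf("  %s-cluster cut: %d misclassified by majority label\n",
                k, x$misclassified[k]))
  }
  invisible(x)
}

#' Group-wise Pearson correlation network over a signature
#'
#' All pairwise Pearson correlations between signature analytes within one
#' group; edges are kept only when the correlation is significant at
#' `alpha` (raw p from the t transform, the same formula as [pearson()];
#' no multiplicity correction, mirroring the convention for exploratory
#' protein networks). Nodes with at least `hub_degree` retained edges are
#' flagged as hubs.
#'
#' @param table an [analyte_table()] (raw or scaled; correlations are
#'   scale-invariant).
#' @param signature a `progsig_signature` or character vector of analyte
#'   IDs.
#' @param group group label selecting the samples.
#' @param alpha edge significance level (default 0.05).
#' @param hub_degree minimum degree for the hub flag (default 4).
#' @return A `correlation_network`: `edges` (data.frame `analyte_a`,
#'   `analyte_b`, `r`, `p`), `nodes` (data.frame `analyte_id`, `degree`,
#'   `hub`), `hub_ids`, plus the group, alpha and sample count.
#' @export
corr_network <- function(table, signature, group, alpha = 0.05,
                         hub_degree = 4) {
  stopifnot(inherits(table, "analyte_table"))
  ids <- if (inherits(signature, "progsig_signature"))
    signature$analyte_ids else signature
  rows <- which(table$sample_meta$group == group)
  if (length(rows) < 4) stop("need >= 4 samples in group '", group, "'")
  x <- subset_table(table, samples = rows, analytes = ids)$values
  const <- apply(x, 2, var) == 0
  if (any(const)) {
    warning("excluding constant analyte(s) in group '", group, "': ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  n <- nrow(x)
  r <- cor(x)
  p <- .pearson_p(r, n)
  keep <- upper.tri(r) & p < alpha
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(
    analyte_a = colnames(x)[idx[, 1]],
    analyte_b = colnames(x)[idx[, 2]],
    r = r[keep],
    p = p[keep],
    stringsAsFactors = FALSE
  )
  degree <- setNames(integer(ncol(x)), colnames(x))
  if (nrow(edges)) {
    tab <- table(c(edges$analyte_a, edges$analyte_b))
    degree[names(tab)] <- as.integer(tab)
  }
  nodes <- data.frame(analyte_id = names(degree), degree = unname(degree),
                      hub = unname(degree) >= hub_degree,
                      stringsAsFactors = FALSE)
  structure(
    list(edges = edges, nodes = nodes, hub_ids = nodes$analyte_id[nodes$hub],
         group = group, alpha = alpha, n_samples = n,
         analyte_ids = colnames(x)),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("correlation_network (%s, n = %d): %d node(s), %d edge(s) at p < %g\n",
              x$group, x$n_samples, nrow(x$nodes), nrow(x$edges), x$alpha))
  if (length(x$hub_ids))
    cat("  hubs:", paste(x$hub_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Contrast two correlation networks
#'
#' Reports edge and hub counts for each network and a pooled two-sample
#' t-test comparing the absolute correlation strengths of the retained
#' edges, quantifying the "fewer but stronger" pattern. The t-test is
#' skipped (with `NA`s) when either network has fewer than 2 edges.
#'
#' @param net_a,net_b `correlation_network` objects over the same analyte
#'   set.
#' @return List with per-network `edge_count`, `hub_count`, `mean_abs_r`,
#'   and the comparison `t_statistic`, `p_value`.
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "correlation_network"),
            inherits(net_b, "correlation_network"))
  if (!setequal(net_a$analyte_ids, net_b$analyte_ids))
    stop("networks cover different analyte sets")
  abs_a <- abs(net_a$edges$r)
  abs_b <- abs(net_b$edges$r)
  tstat <- p <- NA_real_
  if (length(abs_a) >= 2 && length(abs_b) >= 2) {
    tt <- two_sample_ttest(abs_a, abs_b)
    tstat <- tt$statistic
    p <- tt$p_value
  }
  list(
    edge_count = setNames(c(nrow(net_a$edges), nrow(net_b$edges)),
                          c(net_a$group, net_b$group)),
    hub_count = setNames(c(length(net_a$hub_ids), length(net_b$hub_ids)),
                         c(net_a$group, net_b$group)),
    mean_abs_r = setNames(c(mean(abs_a), mean(abs_b)),
                          c(net_a$group, net_b$group)),
    t_statistic = tstat,
    p_value = p
  )
}
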