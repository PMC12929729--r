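#' Normalize counts by cell area (counts per 100 um^2)
#'
#' Rescales each cell's counts by its segmented area so that expression is
#' reported as transcripts per 100 um^2, removing the size-dependent component
#' of per-cell transcript totals (tumor cells are hypertrophic and would
#' otherwise dominate any abundance comparison): `e[g, c] = 100 * x[g, c] / A_c`.
#' The sparsity pattern is unchanged.
#'
#' @param raw_counts genes x cells matrix (sparse or dense, raw counts).
#' @param cell_areas numeric vector of cell areas in um^2, one per column.
#' @return matrix of the same shape and class family with normalized values.
#' @export
normalize_by_area <- function(raw_counts, cell_areas) {
  if (length(cell_areas) != ncol(raw_counts))
    stop("cell_areas length (", length(cell_areas),
         ") must equal the number of cells (", ncol(raw_counts), ")")
  if (any(!is.finite(cell_areas)) || any(cell_areas <= 0))
    stop("cell areas must be finite and > 0")
  if (inherits(raw_counts, "sparseMatrix")) {
    out <- raw_counts %*% Matrix::Diagonal(x = 100 / cell_areas)
    dimnames(out) <- dimnames(raw_counts)
    out
  } else {
    sweep(raw_counts, 2L, cell_areas / 100, "/")
  }
}

# kNN -> shared-nearest-neighbor Jaccard graph in PCA space
.snn_graph <- function(pcs, k) {
  n <- nrow(pcs)
  nn <- RANN::nn2(pcs, k = min(k + 1L, n))$nn.idx
  idx <- nn[, -1L, drop = FALSE]
  keff <- ncol(idx)
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), keff), j = as.vector(idx),
                              x = 1, dims = c(n, n))
  adj <- adj + Matrix::t(adj)
  adj@x[] <- 1
  shared <- methods::as(adj %*% Matrix::t(adj), "TsparseMatrix")
  deg <- Matrix::rowSums(adj)
  w <- shared@x / (deg[shared@i + 1L] + deg[shared@j + 1L] - shared@x)
  keep <- shared@i < shared@j & w >= 1 / (keff + 1)
  igraph::graph_from_data_frame(
    data.frame(from = shared@i[keep] + 1L, to = shared@j[keep] + 1L,
               weight = w[keep]),
    directed = FALSE, vertices = data.frame(name = seq_len(n)))
}

#' Cluster cells by Leiden community detection in PCA space
#'
#' The clustering contract of the standard imaging-platform pipeline:
#' principal component analysis of the (scaled) normalized expression matrix,
#' a k-nearest-neighbor graph in PC space with shared-nearest-neighbor
#' Jaccard edge weights, then Leiden community detection (modularity
#' objective). Clusters are renumbered in descending order of cell count, so
#' cluster 1 is always the largest. Deterministic for a fixed seed.
#'
#' @param norm_counts genes x cells matrix of area-normalized expression.
#' @param n_pcs number of principal components (reduced with a warning when
#'   fewer cells/genes are available).
#' @param k_neighbors kNN graph degree.
#' @param resolution Leiden resolution parameter.
#' @param seed integer seed.
#' @return integer vector of cluster ids (contiguous from 1, sizes
#'   non-increasing in id), named by cell if `norm_counts` has colnames.
#' @export
cluster_cells <- function(norm_counts, n_pcs = 50L, k_neighbors = 15L,
                          resolution = 1.0, seed = 1L) {
  n <- ncol(norm_counts)
  if (n < k_neighbors + 1L)
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1L, " cells, got ", n)
  x <- t(as.matrix(norm_counts))
  sds <- apply(x, 2L, stats::sd)
  if (all(sds == 0)) {
    # all cells identical: a single community by definition
    cl <- rep(1L, n)
    names(cl) <- colnames(norm_counts)
    return(cl)
  }
  x <- scale(x[, sds > 0, drop = FALSE])
  max_pcs <- min(dim(x)) - 1L
  if (n_pcs > max_pcs) {
    warning("reducing n_pcs from ", n_pcs, " to ", max_pcs)
    n_pcs <- max_pcs
  }
  set.seed(as.integer(seed))
  pcs <- stats::prcomp(x, center = FALSE, scale. = FALSE,
                       rank. = n_pcs)$x
  g <- .snn_graph(pcs, k_neighbors)
  set.seed(as.integer(seed))
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5L)
  memb <- igraph::membership(comm)
  # renumber in descending order of total cell count; ties by first appearance
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  cl <- as.integer(relabel[as.character(memb)])
  names(cl) <- colnames(norm_counts)
  cl
}

#' Per-cluster keratin log2 fold change
#'
#' The keratin score of a cell is the sum of its area-normalized keratin
#' counts (default KRT7 + KRT15, the panel-available stand-in for pan-keratin
#' AE1/AE3 staining). For cluster k the fold change is the mean score over the
#' cluster's cells versus the mean over all other cells, with a pseudocount:
#' `log2((mean_k + eps) / (mean_rest + eps))`.
#'
#' @param norm_counts genes x cells matrix of area-normalized expression.
#' @param clusters integer cluster ids per cell.
#' @param keratin_genes keratin gene names (must be present in the panel).
#' @param eps pseudocount guarding empty complements (default 1e-9).
#' @return named numeric vector of log2 fold changes, one per cluster id.
#' @export
keratin_log2fc <- function(norm_counts, clusters,
                           keratin_genes = c("KRT7", "KRT15"), eps = 1e-9) {
  miss <- setdiff(keratin_genes, rownames(norm_counts))
  if (length(miss))
    stop("keratin gene(s) absent from panel: ", paste(miss, collapse = ", "))
  if (length(clusters) != ncol(norm_counts))
    stop("clusters length must equal number of cells")
  score <- Matrix::colSums(norm_counts[keratin_genes, , drop = FALSE])
  ids <- sort(unique(clusters))
  out <- vapply(ids, function(k) {
    inside <- clusters == k
    m_in <- mean(score[inside])
    m_out <- if (all(inside)) 0 else mean(score[!inside])
    log2((m_in + eps) / (m_out + eps))
  }, numeric(1))
  stats::setNames(out, ids)
}

#' Classify clusters as keratin-positive
#'
#' A cluster is keratin-positive when its keratin log2 fold change is strictly
#' greater than zero; a fold change of exactly zero is negative.
#'
#' @param log2fc named numeric vector from [keratin_log2fc()].
#' @return named logical vector of keratin-positive flags.
#' @export
classify_keratin_clusters <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2fc must be finite for every cluster")
  stats::setNames(log2fc > 0, names(log2fc))
}

#' Estimate tumor content from keratin-positive clusters
#'
#' Tumor content is the proportion of cells assigned to keratin-positive
#' clusters, the operational tumor-purity estimate.
#'
#' @param flags named logical vector of per-cluster keratin-positive flags.
#' @param clusters integer cluster ids per cell.
#' @return fraction in `[0, 1]`.
#' @export
tumor_content <- function(flags, clusters) {
  if (length(clusters) == 0L) stop("empty cell table")
  pos <- as.integer(names(flags)[flags])
  mean(clusters %in% pos)
}

#' Welch's t-test between two groups of cytological values
#'
#' Two-sided unequal-variance t-test, used for comparisons of nuclear/cell
#' areas and transcript totals between keratin-positive and keratin-negative
#' fractions.
#'
#' @param values_a,values_b numeric vectors (each >= 2 values, nonzero
#'   variance).
#' @return list with `statistic`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
compare_cytology <- function(values_a, values_b) {
  for (v in list(values_a, values_b)) {
    if (length(v) < 2L) stop("each group needs at least 2 values")
    if (!all(is.finite(v))) stop("non-finite values in a group")
    if (stats::sd(v) == 0) stop("degenerate group: zero variance")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(values_a), mean_b = mean(values_b))
}
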