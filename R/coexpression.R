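# Biweight midcorrelation coexpression networks, computed per histological
# subtype. bicor downweights observations far from the median via Tukey
# biweights and is therefore robust to the outlying counts common in
# single-cell expression data.

# median-centered, biweight-weighted version of one vector; NULL if MAD = 0
.bicor_transform <- function(x) {
  med <- stats::median(x)
  mad_u <- stats::median(abs(x - med))  # unscaled MAD, no consistency factor
  if (mad_u == 0) return(NULL)
  u <- (x - med) / (9 * mad_u)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  (x - med) * w
}

#' Biweight midcorrelation of two vectors
#'
#' Computes bicor with unscaled median absolute deviation and tuning constant
#' 9: `u_i = (x_i - med_x) / (9 MAD_x)`, weights
#' `w_i = (1 - u_i^2)^2 I(|u_i| < 1)`, and the correlation of the weighted,
#' median-centered vectors. The result is clamped to `[-1, 1]`. When either
#' vector has zero MAD (more than half its values tied at the median) the
#' Pearson correlation is returned instead and flagged via the
#' `"pearson_fallback"` attribute.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return bicor coefficient in `[-1, 1]`, with attribute
#'   `pearson_fallback` (logical).
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4L) stop("bicor needs at least 4 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values")
  a <- .bicor_transform(x)
  b <- .bicor_transform(y)
  if (is.null(a) || is.null(b)) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("constant vector: correlation undefined")
    r <- stats::cor(x, y)
    attr(r, "pearson_fallback") <- TRUE
    return(r)
  }
  r <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  r <- max(-1, min(1, r))
  attr(r, "pearson_fallback") <- FALSE
  r
}

#' Pairwise bicor matrix over the cells of one subtype
#'
#' @param norm_counts genes x cells normalized expression restricted to one
#'   subtype population (>= 4 cells; subtypes may be pooled across samples
#'   beforehand).
#' @param genes genes to correlate (default all rows).
#' @return symmetric genes x genes matrix with unit diagonal and attribute
#'   `pearson_fallback` (logical vector naming genes where the biweight
#'   transform degenerated and Pearson was used).
#' @export
bicor_matrix <- function(norm_counts, genes = NULL) {
  if (ncol(norm_counts) < 4L)
    stop("subtype has ", ncol(norm_counts), " cells; bicor needs >= 4")
  if (is.null(genes)) genes <- rownames(norm_counts)
  miss <- setdiff(genes, rownames(norm_counts))
  if (length(miss)) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  x <- t(as.matrix(norm_counts[genes, , drop = FALSE]))
  consts <- apply(x, 2L, function(v) stats::sd(v) == 0)
  if (any(consts))
    stop("constant gene(s) in subtype: ",
         paste(genes[consts], collapse = ", "))
  cols <- lapply(seq_len(ncol(x)), function(j) .bicor_transform(x[, j]))
  fallback <- vapply(cols, is.null, logical(1))
  for (j in which(fallback)) cols[[j]] <- x[, j] - mean(x[, j])
  m <- do.call(cbind, lapply(cols, function(v) v / sqrt(sum(v^2))))
  r <- crossprod(m)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(genes, genes)
  attr(r, "pearson_fallback") <- stats::setNames(fallback, genes)
  r
}

#' Build a signed coexpression network from a bicor matrix
#'
#' Keeps an undirected edge between two genes when `|bicor| >= threshold`;
#' the sign of the correlation is retained on the edge. Node size is the mean
#' normalized expression of the gene in the subtype.
#'
#' @param mat symmetric bicor matrix from [bicor_matrix()].
#' @param node_sizes named numeric vector of node sizes (mean expression).
#' @param threshold absolute-correlation edge threshold in `(0, 1]`.
#' @param subtype optional subtype label stored on the network.
#' @return list of class `coexpression_network` with `subtype`, `threshold`,
#'   `nodes` (`gene, size`) and `edges` (`gene1, gene2, bicor, sign`).
#' @export
build_network <- function(mat, node_sizes, threshold = 0.2, subtype = NA) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  genes <- rownames(mat)
  if (!all(genes %in% names(node_sizes)))
    stop("node_sizes must name every gene in the matrix")
  idx <- which(upper.tri(mat) & abs(mat) >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene1 = genes[idx[, 1L]], gene2 = genes[idx[, 2L]],
                      bicor = mat[idx],
                      sign = ifelse(mat[idx] >= 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  structure(list(subtype = subtype, threshold = threshold,
                 nodes = data.frame(gene = genes,
                                    size = unname(node_sizes[genes]),
                                    stringsAsFactors = FALSE),
                 edges = edges[order(edges$gene1, edges$gene2), ,
                               drop = FALSE]),
            class = "coexpression_network")
}
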