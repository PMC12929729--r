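# Dropout-rate quadrant screening of tumor-specific marker genes, per-cluster
# z-score summaries, cross-sample intersection and subtype-level positivity.

.dropout_categories <- c("tumor_specific", "normal_specific",
                         "common_negative", "common_positive")

#' Build the tumor-cell mask for dropout screening
#'
#' By default tumor cells are members of keratin-positive clusters and
#' non-tumor cells are everything else. An override table reassigns whole
#' clusters (e.g. keratin-positive clusters histologically identified as
#' normal epithelium can be forced into the non-tumor fraction).
#'
#' @param clusters integer cluster ids per cell.
#' @param keratin_positive named per-cluster flags from
#'   [classify_keratin_clusters()].
#' @param override optional named logical vector, names = cluster ids, value =
#'   treat as tumor.
#' @return logical vector per cell, `TRUE` for tumor.
#' @export
tumor_mask <- function(clusters, keratin_positive, override = NULL) {
  flags <- keratin_positive
  if (!is.null(override)) {
    unknown <- setdiff(names(override), names(flags))
    if (length(unknown))
      stop("override names unknown cluster(s): ",
           paste(unknown, collapse = ", "))
    flags[names(override)] <- override
  }
  unname(flags[as.character(clusters)])
}

#' Per-gene dropout rates in the tumor and non-tumor fractions
#'
#' The dropout rate of a gene in a fraction is the proportion of that
#' fraction's cells in which the gene is undetectable (raw count 0).
#'
#' @param raw_counts genes x cells matrix of raw counts.
#' @param tumor_mask logical per cell, `TRUE` for tumor cells.
#' @return data frame `gene, d_T, d_N, total_tumor_expression` (the latter is
#'   the sum of raw counts over tumor cells, the ranking metric).
#' @export
dropout_rates <- function(raw_counts, tumor_mask) {
  if (length(tumor_mask) != ncol(raw_counts))
    stop("tumor_mask must have one flag per cell")
  if (!any(tumor_mask) || all(tumor_mask))
    stop("both tumor and non-tumor fractions must be non-empty")
  tum <- raw_counts[, tumor_mask, drop = FALSE]
  non <- raw_counts[, !tumor_mask, drop = FALSE]
  data.frame(
    gene = rownames(raw_counts),
    d_T = Matrix::rowSums(tum == 0) / ncol(tum),
    d_N = Matrix::rowSums(non == 0) / ncol(non),
    total_tumor_expression = Matrix::rowSums(tum),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify genes into dropout-rate quadrants
#'
#' With threshold `tau` (default 0.75): tumor-specific when `d_T < tau` and
#' `d_N >= tau`; normal-specific when `d_T >= tau` and `d_N < tau`;
#' common-positive when both `< tau`; common-negative when both `>= tau`.
#' The four categories partition the unit square for any `tau` ("expressed"
#' uses strict `<`, "dropout" uses `>=`).
#'
#' @param d_T,d_N dropout rates in `[0, 1]` (vectorized).
#' @param tau quadrant threshold in `(0, 1)`.
#' @return character vector of categories.
#' @export
classify_dropout <- function(d_T, d_N, tau = 0.75) {
  if (length(tau) != 1L || !is.finite(tau) || tau <= 0 || tau >= 1)
    stop("tau must be a single value in (0, 1)")
  if (any(d_T < 0 | d_T > 1 | d_N < 0 | d_N > 1, na.rm = FALSE) ||
      any(!is.finite(d_T)) || any(!is.finite(d_N)))
    stop("dropout rates must lie in [0, 1]")
  ifelse(d_T < tau,
         ifelse(d_N >= tau, "tumor_specific", "common_positive"),
         ifelse(d_N < tau, "normal_specific", "common_negative"))
}

#' Build the full dropout profile table
#'
#' @param raw_counts genes x cells raw counts.
#' @param tumor_mask logical per cell.
#' @param tau quadrant threshold.
#' @return data frame `gene, d_T, d_N, category, total_tumor_expression`.
#' @export
dropout_profiles <- function(raw_counts, tumor_mask, tau = 0.75) {
  prof <- dropout_rates(raw_counts, tumor_mask)
  prof$category <- classify_dropout(prof$d_T, prof$d_N, tau)
  prof[c("gene", "d_T", "d_N", "category", "total_tumor_expression")]
}

#' Top genes by total tumor expression
#'
#' Ranks genes by their total raw-count expression in tumor cells (descending,
#' ties broken alphabetically) and returns the top `K` with their quadrant
#' categories retained. With `strict = TRUE` the pool is first filtered to
#' tumor-specific genes.
#'
#' @param profiles data frame from [dropout_profiles()].
#' @param K number of genes to return.
#' @param strict restrict the ranking pool to tumor-specific genes.
#' @return data frame of the top `K` rows, ranked.
#' @export
top_tumor_specific <- function(profiles, K = 20L, strict = FALSE) {
  if (K < 1L) stop("K must be >= 1")
  pool <- if (strict) profiles[profiles$category == "tumor_specific", ,
                               drop = FALSE] else profiles
  ord <- order(-pool$total_tumor_expression, pool$gene)
  out <- pool[ord, , drop = FALSE][seq_len(min(K, nrow(pool))), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Gene x cluster z-score matrix
#'
#' Per gene: cluster means of area-normalized expression, then z-scored across
#' clusters (subtract the mean of cluster means, divide by their population
#' SD; a gene with identical cluster means gets all-zero z-scores). This is
#' the representation behind tumor-specific marker heatmaps, where elevation
#' is relative across clusters rather than absolute.
#'
#' @param norm_counts genes x cells normalized expression.
#' @param clusters integer cluster ids per cell (>= 2 distinct).
#' @param genes genes to include (default all).
#' @return genes x clusters numeric matrix of z-scores, with attribute
#'   `sd_convention = "population"`.
#' @export
cluster_zscore_matrix <- function(norm_counts, clusters, genes = NULL) {
  ids <- sort(unique(clusters))
  if (length(ids) < 2L) stop("z-scores need at least 2 clusters")
  if (is.null(genes)) genes <- rownames(norm_counts)
  miss <- setdiff(genes, rownames(norm_counts))
  if (length(miss)) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  means <- sapply(ids, function(k)
    Matrix::rowMeans(norm_counts[genes, clusters == k, drop = FALSE]))
  means <- matrix(means, nrow = length(genes),
                  dimnames = list(genes, as.character(ids)))
  z <- t(apply(means, 1L, function(m) {
    s <- sqrt(mean((m - mean(m))^2))  # population SD across cluster means
    if (s == 0) rep(0, length(m)) else (m - mean(m)) / s
  }))
  dimnames(z) <- dimnames(means)
  attr(z, "sd_convention") <- "population"
  z
}

#' Intersect tumor-specific gene lists across samples
#'
#' @param genes_a,genes_b character vectors of gene names.
#' @return sorted character vector of the shared genes.
#' @export
intersect_samples <- function(genes_a, genes_b) {
  sort(intersect(genes_a, genes_b))
}

#' Annotate tumor cells with histological subtype
#'
#' Labels each cell with the histology of the tumor region containing it
#' (`ADC`, `SCC` or `TTF1neg_p40neg`); cells in no tumor region are `NA` and
#' are dropped from subtype analyses. Overlapping tumor regions with
#' different labels are rejected.
#'
#' @param cells data frame with `cell_id, x, y`.
#' @param regions a `RegionSet`; only tumor-labeled regions are used.
#' @return character vector of subtype labels (`NA` = unlabeled), named by
#'   cell id.
#' @export
annotate_subtypes <- function(cells, regions) {
  tumor_regions <- Filter(function(r) r$label %in% .tumor_labels, regions)
  if (length(tumor_regions) > 1L) {
    for (i in seq_len(length(tumor_regions) - 1L)) {
      for (j in (i + 1L):length(tumor_regions)) {
        if (tumor_regions[[i]]$label != tumor_regions[[j]]$label &&
            polygons_overlap(tumor_regions[[i]]$polygon,
                             tumor_regions[[j]]$polygon))
          stop("overlapping tumor regions with different labels: '",
               tumor_regions[[i]]$region_id, "' (",
               tumor_regions[[i]]$label, ") and '",
               tumor_regions[[j]]$region_id, "' (",
               tumor_regions[[j]]$label, ")")
      }
    }
  }
  out <- rep(NA_character_, nrow(cells))
  for (r in tumor_regions) {
    hit <- is.na(out) & points_in_polygon(cells$x, cells$y, r$polygon)
    out[hit] <- r$label
  }
  stats::setNames(out, cells$cell_id)
}

#' Subtype-level positivity and expression of marker genes
#'
#' Per gene and subtype: the fraction of cells with at least one raw
#' transcript and the mean area-normalized expression; plus the between-
#' subtype differences `delta_ADC_TTF1neg = frac(ADC) - frac(TTF1neg_p40neg)`
#' and `delta_TTF1neg_SCC = frac(TTF1neg_p40neg) - frac(SCC)`. Output is
#' sorted in descending order of positivity in the ADC subtype.
#'
#' @param raw_counts,norm_counts genes x cells matrices (raw and normalized).
#' @param subtype per-cell subtype labels from [annotate_subtypes()]
#'   (`NA` cells are dropped).
#' @param genes genes to report.
#' @return data frame with one row per gene: `gene`,
#'   `frac_<subtype>`, `mean_<subtype>`, `delta_ADC_TTF1neg`,
#'   `delta_TTF1neg_SCC`.
#' @export
subtype_positivity <- function(raw_counts, norm_counts, subtype, genes) {
  subs <- c("ADC", "TTF1neg_p40neg", "SCC")
  keep <- !is.na(subtype)
  subtype <- subtype[keep]
  raw <- raw_counts[, keep, drop = FALSE]
  nrm <- norm_counts[, keep, drop = FALSE]
  missing_sub <- setdiff(subs, unique(subtype))
  if (length(missing_sub))
    stop("subtype(s) not represented: ", paste(missing_sub, collapse = ", "))
  miss <- setdiff(genes, rownames(raw))
  if (length(miss)) stop("gene(s) absent: ", paste(miss, collapse = ", "))
  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (s in subs) {
    sel <- subtype == s
    out[[paste0("frac_", s)]] <-
      Matrix::rowSums(raw[genes, sel, drop = FALSE] >= 1) / sum(sel)
    out[[paste0("mean_", s)]] <-
      Matrix::rowMeans(nrm[genes, sel, drop = FALSE])
  }
  out$delta_ADC_TTF1neg <- out$frac_ADC - out$frac_TTF1neg_p40neg
  out$delta_TTF1neg_SCC <- out$frac_TTF1neg_p40neg - out$frac_SCC
  out <- out[order(-out$frac_ADC, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
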