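# Audit of annotated regions of interest: assign cells to ROIs (boundary
# counts inside), compare marker positivity inside vs outside per cluster
# with Fisher's exact test + BH correction, and exclude histologically
# normal cells from downstream analysis.

#' Assign cells to regions of interest
#'
#' Point-in-polygon membership with the boundary counted as inside. A cell
#' belongs to at most one ROI: regions are tried in file order and the first
#' match wins; geometrically overlapping ROI polygons are rejected.
#'
#' @param cells data frame with `cell_id, x, y`.
#' @param regions a `RegionSet` (list of `region_id`, `label`, `polygon`).
#' @return character vector of ROI ids per cell (`NA` when in no ROI), named
#'   by `cell_id`.
#' @export
assign_rois <- function(cells, regions) {
  if (length(regions) > 1L) {
    for (i in seq_len(length(regions) - 1L)) {
      for (j in (i + 1L):length(regions)) {
        if (polygons_overlap(regions[[i]]$polygon, regions[[j]]$polygon))
          stop("overlapping ROI polygons: '", regions[[i]]$region_id,
               "' and '", regions[[j]]$region_id, "'")
      }
    }
  }
  out <- rep(NA_character_, nrow(cells))
  for (r in regions) {
    hit <- is.na(out) & points_in_polygon(cells$x, cells$y, r$polygon)
    out[hit] <- r$region_id
  }
  stats::setNames(out, cells$cell_id)
}

#' Positivity rate for a gene
#'
#' Fraction of cells with at least one raw transcript of the gene (positivity
#' is a detection statement, consistent with the dropout-rate definition, so
#' it is computed on raw counts and is invariant under area normalization).
#'
#' @param raw_counts genes x cells matrix of raw counts.
#' @param gene gene name.
#' @return fraction in `[0, 1]`.
#' @export
positivity_rate <- function(raw_counts, gene) {
  if (!gene %in% rownames(raw_counts))
    stop("gene '", gene, "' absent from panel")
  if (ncol(raw_counts) == 0L) stop("empty cell subset")
  mean(raw_counts[gene, ] >= 1)
}

#' Compare gene positivity inside vs outside an ROI, per cluster
#'
#' For each cluster represented on both sides, builds the 2x2 table
#' (positive/negative x inside/outside) and applies a two-sided Fisher exact
#' test; p-values are BH-adjusted across the clusters tested. A table with a
#' zero margin on both sides yields p = 1 with a warning. With
#' `pooled = TRUE` a single test over all cells is performed instead.
#'
#' @param raw_counts genes x cells matrix of raw counts.
#' @param gene audit gene name (e.g. `"EPCAM"`).
#' @param clusters integer cluster ids per cell.
#' @param inside logical vector per cell, `TRUE` when inside the ROI.
#' @param clusters_to_test optional subset of cluster ids (default: every
#'   cluster with cells on both sides).
#' @param pooled pool all clusters into one test.
#' @return data frame `cluster, n_inside, n_outside, pos_inside, pos_outside,
#'   odds_ratio, p, q` (one row, cluster `NA`, when pooled).
#' @export
compare_positivity <- function(raw_counts, gene, clusters, inside,
                               clusters_to_test = NULL, pooled = FALSE) {
  if (!gene %in% rownames(raw_counts))
    stop("gene '", gene, "' absent from panel")
  if (length(inside) != ncol(raw_counts) ||
      length(clusters) != ncol(raw_counts))
    stop("clusters and inside must have one entry per cell")
  if (!any(inside) || all(inside))
    stop("both inside and outside groups must be non-empty")
  pos <- as.vector(raw_counts[gene, ] >= 1)

  one_test <- function(sel) {
    tab <- matrix(c(sum(pos[sel] & inside[sel]), sum(!pos[sel] & inside[sel]),
                    sum(pos[sel] & !inside[sel]),
                    sum(!pos[sel] & !inside[sel])), nrow = 2L)
    if (any(colSums(tab) == 0L))
      stop("empty inside or outside group for the tested cells")
    if (all(tab[1L, ] == 0L) || all(tab[2L, ] == 0L)) {
      warning("gene '", gene, "' has a zero margin in both groups; p = 1")
      return(c(or = NA_real_, p = 1))
    }
    ft <- stats::fisher.test(tab)
    c(or = unname(ft$estimate), p = ft$p.value)
  }

  if (pooled) {
    r <- one_test(rep(TRUE, length(pos)))
    return(data.frame(cluster = NA_integer_, n_inside = sum(inside),
                      n_outside = sum(!inside),
                      pos_inside = mean(pos[inside]),
                      pos_outside = mean(pos[!inside]),
                      odds_ratio = r[["or"]], p = r[["p"]], q = r[["p"]]))
  }

  if (is.null(clusters_to_test)) {
    clusters_to_test <- sort(intersect(unique(clusters[inside]),
                                       unique(clusters[!inside])))
  }
  if (length(clusters_to_test) == 0L)
    stop("no cluster has cells both inside and outside the ROI")
  rows <- lapply(clusters_to_test, function(k) {
    sel <- clusters == k
    if (!any(sel & inside) || !any(sel & !inside)) return(NULL)
    r <- one_test(sel)
    data.frame(cluster = k, n_inside = sum(sel & inside),
               n_outside = sum(sel & !inside),
               pos_inside = mean(pos[sel & inside]),
               pos_outside = mean(pos[sel & !inside]),
               odds_ratio = r[["or"]], p = r[["p"]])
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Exclude cells belonging to the listed ROIs
#'
#' Removes every member of the listed ROIs from the dataset (used to drop
#' histologically normal epithelium before marker screening) and logs each
#' excluded cell with its ROI and a reason. Idempotent.
#'
#' @param sim a `spatmark_sim` or any list with `cells` (data frame) and
#'   `counts` (genes x cells matrix).
#' @param roi_assignment named ROI membership from [assign_rois()].
#' @param roi_ids ROI ids to exclude (must exist in the assignment or, when
#'   given, in `regions` — an ROI with zero member cells is legal and leaves
#'   the table unchanged).
#' @param reason free-text reason recorded in the audit log.
#' @param regions optional `RegionSet` whose ids extend the known-ROI set.
#' @return list with `cells`, `counts` (filtered, same classes) and
#'   `excluded` (data frame `cell_id, roi, reason`).
#' @export
exclude_cells <- function(sim, roi_assignment, roi_ids,
                          reason = "histologically normal epithelium",
                          regions = NULL) {
  known <- unique(stats::na.omit(roi_assignment))
  if (!is.null(regions))
    known <- union(known, vapply(regions, `[[`, "", "region_id"))
  unknown <- setdiff(roi_ids, known)
  if (length(unknown))
    stop("unknown ROI id(s): ", paste(unknown, collapse = ", "))
  member <- roi_assignment[sim$cells$cell_id]
  drop <- !is.na(member) & member %in% roi_ids
  excluded <- data.frame(cell_id = sim$cells$cell_id[drop],
                         roi = unname(member[drop]),
                         reason = rep_len(reason, sum(drop)),
                         stringsAsFactors = FALSE)
  out <- sim
  out$cells <- sim$cells[!drop, , drop = FALSE]
  rownames(out$cells) <- NULL
  out$counts <- sim$counts[, !drop, drop = FALSE]
  out$excluded <- excluded
  out
}
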