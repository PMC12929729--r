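# RGB color-space mapping of per-cell transcriptomes: a 3-component nonlinear
# embedding is rescaled channel-wise to 0-255 and overlaid on the tissue so
# transcriptionally similar cells share a color. The embedding is always
# computed within one sample; colors are never comparable across samples.

#' Three-component embedding of tumor-cell expression
#'
#' Reduces the area-normalized expression of keratin-positive cells to three
#' components. Keratin-negative (normal) cells must be excluded by the caller
#' before dimension reduction; the function asserts the flag column. The
#' backend is pluggable: `"umap"` (default; nonlinear, via uwot with a fixed
#' seed and single-threaded optimization for determinism) or `"pca"` (linear,
#' deterministic, useful for fast testing).
#'
#' @param norm_counts genes x cells matrix restricted to keratin-positive
#'   cells.
#' @param keratin_positive logical vector, one entry per cell; all must be
#'   `TRUE`.
#' @param seed integer seed.
#' @param backend `"umap"` or `"pca"`.
#' @param n_neighbors,min_dist UMAP parameters (ignored by the PCA backend).
#' @return cells x 3 numeric matrix of embedding coordinates (`u1,u2,u3`),
#'   rownames = cell ids.
#' @export
embed3 <- function(norm_counts, keratin_positive, seed = 1L,
                   backend = c("umap", "pca"), n_neighbors = 15L,
                   min_dist = 0.1) {
  backend <- match.arg(backend)
  if (length(keratin_positive) != ncol(norm_counts))
    stop("keratin_positive must have one flag per cell")
  if (!all(keratin_positive))
    stop("input contains keratin-negative cells; exclude them before ",
         "dimension reduction")
  n <- ncol(norm_counts)
  if (n < 10L) stop("need at least 10 cells to embed, got ", n)
  x <- t(as.matrix(norm_counts))
  sds <- apply(x, 2L, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (ncol(x) == 0L) stop("all genes constant; nothing to embed")
  x <- scale(x)
  set.seed(as.integer(seed))
  emb <- if (backend == "umap") {
    uwot::umap(x, n_components = 3L,
               n_neighbors = min(n_neighbors, n - 1L), min_dist = min_dist,
               n_threads = 1L, n_sgd_threads = 1L, batch = FALSE)
  } else {
    stats::prcomp(x, center = FALSE, rank. = 3L)$x[, 1:3, drop = FALSE]
  }
  if (any(!is.finite(emb))) stop("embedding produced non-finite coordinates")
  dimnames(emb) <- list(colnames(norm_counts), c("u1", "u2", "u3"))
  emb
}

# nearest integer, half away from zero (round() in R rounds half to even)
.round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rescale a 3-component embedding to 0-255 RGB channels
#'
#' Each component is affinely mapped so its minimum becomes 0 and its maximum
#' 255, rounded to the nearest integer (half away from zero), and assigned to
#' the red, green and blue channels in component order. A degenerate constant
#' component maps to 0.
#'
#' @param embedding cells x 3 matrix of finite coordinates.
#' @return cells x 3 integer matrix with columns `R,G,B`, values in `[0, 255]`.
#' @export
scale_to_rgb <- function(embedding) {
  embedding <- as.matrix(embedding)
  if (ncol(embedding) != 3L) stop("embedding must have exactly 3 components")
  if (nrow(embedding) < 1L) stop("embedding has no cells")
  if (any(!is.finite(embedding))) stop("non-finite embedding coordinates")
  rgb <- apply(embedding, 2L, function(v) {
    rng <- range(v)
    if (rng[1L] == rng[2L]) return(rep(0L, length(v)))
    as.integer(.round_half_away(255 * (v - rng[1L]) / (rng[2L] - rng[1L])))
  })
  rgb <- matrix(rgb, ncol = 3L,
                dimnames = list(rownames(embedding), c("R", "G", "B")))
  rgb
}

#' Join cell coordinates with embedding colors
#'
#' @param cells data frame with `cell_id, x, y`.
#' @param rgb integer matrix from [scale_to_rgb()], rownames = cell ids.
#' @param embedding optional cells x 3 embedding to carry through (`u1..u3`).
#' @return data frame `cell_id, x, y[, u1..u3], R, G, B` in the input cell
#'   order.
#' @export
spatial_rgb_table <- function(cells, rgb, embedding = NULL) {
  if (is.null(rownames(rgb))) stop("rgb must have cell ids as rownames")
  if (!setequal(cells$cell_id, rownames(rgb)))
    stop("cell ids in `cells` and `rgb` do not match")
  m <- match(cells$cell_id, rownames(rgb))
  out <- cells[c("cell_id", "x", "y")]
  if (!is.null(embedding)) {
    if (!setequal(cells$cell_id, rownames(embedding)))
      stop("cell ids in `cells` and `embedding` do not match")
    out <- cbind(out, as.data.frame(embedding[match(cells$cell_id,
                                                    rownames(embedding)), ,
                                              drop = FALSE]))
  }
  out$R <- rgb[m, "R"]; out$G <- rgb[m, "G"]; out$B <- rgb[m, "B"]
  rownames(out) <- NULL
  out
}

#' Render the RGB spatial map to a graphics device
#'
#' Draws one filled marker per cell at its tissue coordinates, colored by its
#' RGB triple; the plotting bounds equal the tissue bounding box and the y
#' axis is flipped to match image orientation.
#'
#' @param rgb_table output of [spatial_rgb_table()].
#' @param cex marker size.
#' @export
plot_spatial_rgb <- function(rgb_table, cex = 0.3) {
  col <- grDevices::rgb(rgb_table$R, rgb_table$G, rgb_table$B,
                        maxColorValue = 255)
  graphics::plot(rgb_table$x, rgb_table$y, pch = 16, cex = cex, col = col,
                 xlim = range(rgb_table$x), ylim = rev(range(rgb_table$y)),
                 xlab = "x (µm)", ylab = "y (µm)", asp = 1)
  invisible(rgb_table)
}

#' Treemap-style block summary of clusters and mean colors
#'
#' Tiles the tissue bounding box into a regular `n_x` x `n_y` grid (or uses
#' explicit block polygons) and reports, per block, each cluster present with
#' its cell count and the channel-wise mean RGB of its cells. Cells on a
#' shared tile edge belong to the tile whose half-open `[lo, hi)` x- then
#' y-interval contains them; the far domain edge is closed so no cell is lost.
#'
#' @param cells data frame with `cell_id, x, y`.
#' @param clusters integer cluster ids, one per cell (same order).
#' @param rgb integer RGB matrix, rownames = cell ids.
#' @param grid integer length-2 `c(n_x, n_y)` (default `c(8, 8)`), or a list
#'   of named block polygons.
#' @return list of class `treemap_summary`: per block `block_id`, `bounds`
#'   (or polygon) and data frame `clusters` (`cluster, n, R, G, B`), plus
#'   `total_cells`.
#' @export
treemap_summary <- function(cells, clusters, rgb, grid = c(8L, 8L)) {
  n <- nrow(cells)
  if (length(clusters) != n) stop("clusters must have one id per cell")
  if (is.null(rownames(rgb)) || !setequal(cells$cell_id, rownames(rgb)))
    stop("rgb rownames must match cell ids")
  rgbm <- rgb[match(cells$cell_id, rownames(rgb)), , drop = FALSE]

  if (is.numeric(grid)) {
    if (length(grid) != 2L || any(grid < 1L)) stop("grid must be c(n_x, n_y)")
    nx <- as.integer(grid[1L]); ny <- as.integer(grid[2L])
    x0 <- min(cells$x); x1 <- max(cells$x)
    y0 <- min(cells$y); y1 <- max(cells$y)
    tile_index <- function(v, lo, hi, nt) {
      if (hi == lo) return(rep(1L, length(v)))  # degenerate extent
      pmin(1L + as.integer(floor((v - lo) / (hi - lo) * nt)), nt)
    }
    ix <- tile_index(cells$x, x0, x1, nx)
    iy <- tile_index(cells$y, y0, y1, ny)
    block <- (iy - 1L) * nx + ix
    bounds <- lapply(seq_len(nx * ny), function(b) {
      bx <- (b - 1L) %% nx; by <- (b - 1L) %/% nx
      c(xmin = x0 + bx * (x1 - x0) / nx, xmax = x0 + (bx + 1L) * (x1 - x0) / nx,
        ymin = y0 + by * (y1 - y0) / ny, ymax = y0 + (by + 1L) * (y1 - y0) / ny)
    })
    block_ids <- sprintf("tile_%02d_%02d",
                         rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  } else if (is.list(grid) && length(grid) > 0L) {
    assigned <- rep(NA_integer_, n)
    for (b in seq_along(grid)) {
      hit <- is.na(assigned) &
        points_in_polygon(cells$x, cells$y, grid[[b]])
      assigned[hit] <- b
    }
    block <- assigned
    bounds <- grid
    block_ids <- if (is.null(names(grid)))
      sprintf("block_%02d", seq_along(grid)) else names(grid)
  } else {
    stop("empty grid specification")
  }

  blocks <- lapply(seq_along(block_ids), function(b) {
    in_b <- which(block == b)
    if (length(in_b) == 0L) return(NULL)
    per <- lapply(sort(unique(clusters[in_b])), function(k) {
      i <- in_b[clusters[in_b] == k]
      data.frame(cluster = k, n = length(i),
                 R = as.integer(.round_half_away(mean(rgbm[i, "R"]))),
                 G = as.integer(.round_half_away(mean(rgbm[i, "G"]))),
                 B = as.integer(.round_half_away(mean(rgbm[i, "B"]))))
    })
    list(block_id = block_ids[b], bounds = bounds[[b]],
         clusters = do.call(rbind, per))
  })
  blocks <- Filter(Negate(is.null), blocks)
  structure(list(blocks = blocks, total_cells = sum(!is.na(block))),
            class = "treemap_summary")
}
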