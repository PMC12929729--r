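# Readers and writers for every on-disk format the pipeline touches.
# Conventions: coordinates in microns with image orientation (y down); CSVs are
# UTF-8, comma-separated, header row required; Matrix Market indices 1-based
# per the standard; gene order is preserved as given, never sorted silently.

.region_labels <- c("ADC", "SCC", "TTF1neg_p40neg", "normal", "non_tumor",
                    "ROI")

#' Read a cell-feature count matrix (Matrix Market + TSV sidecars)
#'
#' Reads the sparse cell-by-gene matrix dialect used by imaging-based spatial
#' platforms: a Matrix Market coordinate file of integer counts with genes in
#' rows and cells in columns, plus `features.tsv` (gene names, first column)
#' and `barcodes.tsv` (cell ids).
#'
#' @param matrix_path path to the `.mtx` file.
#' @param features_path path to the features TSV (first column = gene name).
#' @param barcodes_path path to the barcodes TSV (one cell id per line).
#' @return list with `counts` (sparse dgCMatrix, genes x cells, dimnames set),
#'   `genes`, and `cells`.
#' @export
read_cell_feature_matrix <- function(matrix_path, features_path, barcodes_path) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  cells <- utils::read.delim(barcodes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1L]]
  if (nrow(m) != length(genes))
    stop("dimension mismatch in ", matrix_path, ": matrix has ", nrow(m),
         " rows but ", features_path, " lists ", length(genes), " features")
  if (ncol(m) != length(cells))
    stop("dimension mismatch in ", matrix_path, ": matrix has ", ncol(m),
         " columns but ", barcodes_path, " lists ", length(cells), " barcodes")
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("duplicate gene names in ", features_path, ": ",
         paste(unique(dup), collapse = ", "))
  vals <- methods::as(m, "TsparseMatrix")
  bad <- which(vals@x != round(vals@x) | vals@x < 0)
  if (length(bad))
    stop("non-integer or negative count in ", matrix_path, " at entry ",
         bad[1L], " (gene row ", vals@i[bad[1L]] + 1L, ", cell column ",
         vals@j[bad[1L]] + 1L, ")")
  counts <- methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix")
  dimnames(counts) <- list(genes, cells)
  list(counts = counts, genes = genes, cells = cells)
}

#' Write a cell-feature count matrix (Matrix Market + TSV sidecars)
#'
#' @param counts genes x cells matrix (sparse or dense, integer counts).
#' @param dir output directory; creates `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return invisibly, the three file paths.
#' @export
write_cell_feature_matrix <- function(counts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and cell colnames")
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "TsparseMatrix"), paths[1L])
  writeLines(rownames(counts), paths[2L])
  writeLines(colnames(counts), paths[3L])
  invisible(paths)
}

.check_rows <- function(bad, what, path) {
  if (any(bad))
    stop(what, " in ", path, " at row(s): ",
         paste(utils::head(which(bad), 10L), collapse = ", "),
         if (sum(bad) > 10L) " ..." else "")
}

#' Read per-cell geometry metadata from CSV
#'
#' Required columns: `cell_id, x, y, cell_area, nucleus_area`; optional
#' `total_counts`; unknown columns are preserved as passthrough.
#'
#' @param path CSV path.
#' @return validated data frame.
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("cell_id", "x", "y", "cell_area", "nucleus_area")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id))
    stop("duplicate cell_id in ", path, ": ",
         paste(unique(df$cell_id[duplicated(df$cell_id)]), collapse = ", "))
  .check_rows(!is.finite(df$x) | !is.finite(df$y), "non-finite coordinate", path)
  .check_rows(!is.finite(df$cell_area) | df$cell_area <= 0,
              "non-positive cell_area", path)
  .check_rows(!is.finite(df$nucleus_area) | df$nucleus_area < 0,
              "negative nucleus_area", path)
  .check_rows(df$nucleus_area > df$cell_area,
              "nucleus_area exceeds cell_area", path)
  df
}

#' Write per-cell geometry metadata to CSV
#' @param cells data frame as returned by [read_cells_csv()].
#' @param path output path.
#' @export
write_cells_csv <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read region annotations from GeoJSON
#'
#' Expects a `FeatureCollection` of `Polygon` features with the histology
#' label under `properties.histology` (controlled vocabulary: ADC, SCC,
#' TTF1neg_p40neg, normal, non_tumor, ROI), an optional `properties.region_id`
#' and free-text `properties.note`.
#'
#' @param path GeoJSON path.
#' @return a `RegionSet`: list of `list(region_id, label, polygon, note)`.
#' @export
read_regions_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop(path, " is not a GeoJSON FeatureCollection")
  feats <- gj$features
  out <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom$type) || geom$type != "Polygon")
      stop("feature ", i, " in ", path, " is not a Polygon")
    ring <- geom$coordinates[[1L]]
    if (length(ring) < 3L)
      stop("degenerate polygon in feature ", i, " of ", path,
           ": fewer than 3 vertices")
    p <- do.call(rbind, lapply(ring, function(v) as.numeric(v[1:2])))
    p <- tryCatch(polygon_matrix(p),
                  error = function(e) stop("degenerate polygon in feature ", i,
                                           " of ", path, ": ",
                                           conditionMessage(e)))
    if (!polygon_is_simple(p))
      stop("self-intersecting polygon in feature ", i, " of ", path)
    lab <- f$properties$histology
    if (is.null(lab) || !lab %in% .region_labels)
      stop("feature ", i, " of ", path,
           " has missing or unknown properties.histology (allowed: ",
           paste(.region_labels, collapse = ", "), ")")
    rid <- f$properties$region_id
    if (is.null(rid)) rid <- sprintf("region_%03d", i)
    note <- f$properties$note
    out[[i]] <- list(region_id = rid, label = lab, polygon = p,
                     note = if (is.null(note)) "" else note)
  }
  out
}

#' Write region annotations to GeoJSON
#' @param regions a `RegionSet` (list of `region_id`, `label`, `polygon`,
#'   optional `note`).
#' @param path output path.
#' @export
write_regions_geojson <- function(regions, path) {
  feats <- lapply(regions, function(r) {
    p <- polygon_matrix(r$polygon)
    ring <- lapply(seq_len(nrow(p)), function(i) c(p[i, 1L], p[i, 2L]))
    ring[[length(ring) + 1L]] <- ring[[1L]]  # close the ring
    list(type = "Feature",
         properties = list(region_id = r$region_id, histology = r$label,
                           note = if (is.null(r$note)) "" else r$note),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Construct and validate a bulk cohort
#'
#' @param expr data frame, first column `sample_id`, remaining columns one per
#'   gene (continuous expression).
#' @param clinical data frame with columns `sample_id, time, event, stage,
#'   age, smoking, sex`; optional `histology` and `mut_*` mutation flags;
#'   unknown columns preserved.
#' @return object of class `bulk_cohort` (list with `expr` and `clinical`,
#'   rows aligned on `sample_id`).
#' @export
bulk_cohort <- function(expr, clinical) {
  if (names(expr)[1L] != "sample_id") stop("expr first column must be sample_id")
  req <- c("sample_id", "time", "event", "stage", "age", "smoking", "sex")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("missing required clinical column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(expr$sample_id) || anyDuplicated(clinical$sample_id))
    stop("duplicate sample_id")
  if (!setequal(expr$sample_id, clinical$sample_id))
    stop("expr and clinical sample_id sets differ")
  clinical <- clinical[match(expr$sample_id, clinical$sample_id), , drop = FALSE]
  rownames(clinical) <- NULL
  .check_rows(!is.finite(clinical$time) | clinical$time <= 0,
              "non-positive survival time", "clinical")
  .check_rows(!clinical$event %in% c(0L, 1L), "event flag not in {0,1}",
              "clinical")
  gm <- as.matrix(expr[-1L])
  .check_rows(apply(gm, 1L, function(r) any(!is.finite(r))),
              "missing or non-finite expression value", "expr")
  structure(list(expr = expr, clinical = clinical), class = "bulk_cohort")
}

#' Read a bulk cohort from expression + clinical CSVs
#' @param expr_path samples x genes CSV (first column `sample_id`).
#' @param clinical_path clinical CSV (see [bulk_cohort()]).
#' @return a `bulk_cohort`.
#' @export
read_bulk <- function(expr_path, clinical_path) {
  expr <- utils::read.csv(expr_path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  clinical <- utils::read.csv(clinical_path, stringsAsFactors = FALSE,
                              check.names = FALSE)
  bulk_cohort(expr, clinical)
}

#' Write a bulk cohort to expression + clinical CSVs
#' @param cohort a `bulk_cohort`.
#' @param expr_path,clinical_path output CSV paths.
#' @export
write_bulk <- function(cohort, expr_path, clinical_path) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  utils::write.csv(cohort$expr, expr_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$clinical, clinical_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(expr_path, clinical_path))
}

#' Write an analysis report as JSON
#' @param results named list of results (coerced with `auto_unbox`).
#' @param path output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}
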