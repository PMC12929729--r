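# End-to-end orchestration: one config drives simulation (or ingestion),
# the spatial stage (normalize -> cluster -> keratin call -> ROI audit ->
# dropout screen -> subtype positivity -> RGB map -> coexpression) and the
# bulk stage (median split -> KM/log-rank -> Cox -> mutation enrichment).
# Every artifact is written to disk and listed in a machine-readable report.

.default_params <- function() {
  list(n_pcs = 50L, k_neighbors = 15L, resolution = 1.0, seed = 1L,
       tau = 0.75, K = 20L, keratin_genes = c("KRT7", "KRT15"),
       audit_gene = "EPCAM", grid = c(8L, 8L), rgb_backend = "umap",
       rgb = TRUE, exclude_normal = TRUE, bicor_threshold = 0.2,
       coexpr_genes = NULL, marker = "SLC2A1")
}

#' Read a pipeline run configuration from YAML
#'
#' The config mirrors the pipeline surface: either `simulate: true` with an
#' optional `sim:` block (passed to [sim_config()] /
#' [simulate_bulk_cohort()]) or explicit input `paths:`; a `params:` block
#' overriding any analysis default (tau, K, clustering parameters, seeds,
#' keratin/audit/marker gene names, grid, backend, bicor threshold).
#'
#' @param path YAML file path.
#' @return named list ready for [run_spatial_stage()] / [run_bulk_stage()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.merge_params <- function(config) {
  p <- .default_params()
  if (!is.null(config$params)) p[names(config$params)] <- config$params
  p$seed <- as.integer(p$seed)
  p
}

.stage_step <- function(stage, step, expr) {
  tryCatch(expr, error = function(e)
    stop("[", stage, "/", step, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the spatial stage of the pipeline
#'
#' Executes the full spatial flow on simulated or on-disk data and writes all
#' intermediate artifacts plus `spatial_report.json` into `outdir`. Steps:
#' area normalization, Leiden clustering, keratin log2FC tumor calling, ROI
#' audit (marker positivity inside vs outside normal foci) and exclusion of
#' histologically normal cells, tumor-content estimation, dropout-quadrant
#' marker screening with top-K ranking, per-cluster z-scores, subtype
#' positivity, optional RGB embedding + treemap, and per-subtype bicor
#' networks.
#'
#' @param config list: `simulate = TRUE` (default) with optional `sim` block,
#'   or `paths` (named: `matrix`, `features`, `barcodes`, `cells`,
#'   `regions`); `params` overriding [`.default_params`] entries.
#' @param outdir output directory (created).
#' @return invisibly, the report list.
#' @export
run_spatial_stage <- function(config = list(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .merge_params(config)
  simulate <- isTRUE(config$simulate) || is.null(config$paths)

  if (simulate) {
    sim_args <- config$sim
    if (is.null(sim_args)) sim_args <- list()
    if (is.null(sim_args$seed)) sim_args$seed <- p$seed
    sim <- .stage_step("spatial", "simulate", {
      cfg <- do.call(sim_config, sim_args)
      simulate_cells(cfg)
    })
    truth <- sim$truth
  } else {
    pths <- config$paths
    for (nm in c("matrix", "features", "barcodes", "cells", "regions"))
      if (is.null(pths[[nm]]) || !file.exists(pths[[nm]]))
        stop("[spatial/preflight] missing input file for '", nm, "'")
    sim <- .stage_step("spatial", "load", {
      cfm <- read_cell_feature_matrix(pths$matrix, pths$features,
                                      pths$barcodes)
      cells <- read_cells_csv(pths$cells)
      if (!setequal(cells$cell_id, cfm$cells))
        stop("cell ids in cells CSV and barcodes differ")
      cells <- cells[match(cfm$cells, cells$cell_id), , drop = FALSE]
      list(cells = cells, counts = cfm$counts, genes = cfm$genes,
           regions = read_regions_geojson(pths$regions))
    })
    truth <- NULL
  }

  cells <- sim$cells; counts <- sim$counts; regions <- sim$regions
  write_cells_csv(cells, file.path(outdir, "cells.csv"))
  write_cell_feature_matrix(counts, file.path(outdir, "cell_feature_matrix"))
  write_regions_geojson(regions, file.path(outdir, "regions.geojson"))

  norm <- .stage_step("spatial", "normalize",
                      normalize_by_area(counts, cells$cell_area))
  clusters <- .stage_step("spatial", "cluster",
                          cluster_cells(norm, n_pcs = p$n_pcs,
                                        k_neighbors = p$k_neighbors,
                                        resolution = p$resolution,
                                        seed = p$seed))
  log2fc <- .stage_step("spatial", "keratin",
                        keratin_log2fc(norm, clusters, p$keratin_genes))
  kp <- classify_keratin_clusters(log2fc)
  tumor_fraction_raw <- tumor_content(kp, clusters)

  utils::write.csv(
    data.frame(cell_id = cells$cell_id, cluster = clusters,
               keratin_positive = unname(kp[as.character(clusters)])),
    file.path(outdir, "clusters.csv"), row.names = FALSE, quote = FALSE)
  write_report(list(sizes = as.list(table(clusters)),
                    keratin_log2fc = as.list(log2fc),
                    keratin_positive = as.list(kp)),
               file.path(outdir, "cluster_summary.json"))

  # ROI audit over regions annotated as normal epithelium (or explicit ROIs)
  roi_regions <- Filter(function(r) r$label %in% c("normal", "ROI"), regions)
  excluded <- data.frame(cell_id = character(0), roi = character(0),
                         reason = character(0))
  roi_report <- NULL
  post <- list(cells = cells, counts = counts)
  if (length(roi_regions) > 0L && p$exclude_normal) {
    roi_assign <- .stage_step("spatial", "roi_assign",
                              assign_rois(cells, roi_regions))
    inside <- !is.na(roi_assign)
    kp_cell <- unname(kp[as.character(clusters)])
    roi_report <- .stage_step("spatial", "roi_audit", {
      sel <- kp_cell  # audit within the keratin-positive compartment
      compare_positivity(counts[, sel, drop = FALSE], p$audit_gene,
                         clusters[sel], inside[sel])
    })
    utils::write.csv(roi_report, file.path(outdir, "roi_report.csv"),
                     row.names = FALSE, quote = FALSE)
    write_report(list(audit_gene = p$audit_gene,
                      rois = vapply(roi_regions, `[[`, "", "region_id"),
                      per_cluster = roi_report),
                 file.path(outdir, "roi_report.json"))
    post <- .stage_step("spatial", "exclude",
                        exclude_cells(sim, roi_assign,
                                      vapply(roi_regions, `[[`, "",
                                             "region_id"),
                                      regions = roi_regions))
    excluded <- post$excluded
  }
  utils::write.csv(excluded, file.path(outdir, "excluded_cells.csv"),
                   row.names = FALSE, quote = FALSE)

  keep_idx <- match(post$cells$cell_id, cells$cell_id)
  clusters_post <- clusters[keep_idx]
  norm_post <- norm[, keep_idx, drop = FALSE]
  kp_cell_post <- unname(kp[as.character(clusters_post)])
  # tumor purity: keratin-positive minus excluded-normal, over ALL cells
  tumor_fraction <- sum(kp_cell_post) / nrow(cells)

  mask <- .stage_step("spatial", "screen",
                      tumor_mask(clusters_post, kp))
  profiles <- .stage_step("spatial", "screen",
                          dropout_profiles(post$counts, mask, tau = p$tau))
  topk <- top_tumor_specific(profiles, K = p$K)
  utils::write.csv(profiles, file.path(outdir, "dropout_profiles.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(topk, file.path(outdir, "markers_topK.csv"),
                   row.names = FALSE, quote = FALSE)

  zmat <- .stage_step("spatial", "zscore",
                      cluster_zscore_matrix(norm_post, clusters_post,
                                            topk$gene))
  utils::write.csv(as.data.frame(zmat), file.path(outdir, "zscore_matrix.csv"),
                   quote = FALSE)

  subtype <- .stage_step("spatial", "subtype",
                         annotate_subtypes(post$cells, regions))
  subtype[!mask] <- NA  # subtype analyses cover tumor cells only
  subpos <- .stage_step("spatial", "subtype",
                        subtype_positivity(post$counts, norm_post, subtype,
                                           profiles$gene[profiles$category ==
                                                           "tumor_specific"]))
  utils::write.csv(subpos, file.path(outdir, "subtype_positivity.csv"),
                   row.names = FALSE, quote = FALSE)

  if (isTRUE(p$rgb)) {
    tum_idx <- which(kp_cell_post)
    emb <- .stage_step("spatial", "rgb_umap",
                       embed3(norm_post[, tum_idx, drop = FALSE],
                              rep(TRUE, length(tum_idx)), seed = p$seed,
                              backend = p$rgb_backend))
    rgb <- scale_to_rgb(emb)
    rgb_tab <- spatial_rgb_table(post$cells[tum_idx, , drop = FALSE], rgb,
                                 emb)
    utils::write.csv(rgb_tab, file.path(outdir, "rgb_cells.csv"),
                     row.names = FALSE, quote = FALSE)
    tm <- treemap_summary(post$cells[tum_idx, , drop = FALSE],
                          clusters_post[tum_idx], rgb, grid = p$grid)
    write_report(list(total_cells = tm$total_cells, blocks = lapply(
      tm$blocks, function(b) list(block_id = b$block_id,
                                  bounds = as.list(b$bounds),
                                  clusters = b$clusters))),
      file.path(outdir, "treemap.json"))
  }

  net_genes <- p$coexpr_genes
  if (is.null(net_genes)) net_genes <- topk$gene
  networks <- list()
  for (s in c("ADC", "TTF1neg_p40neg", "SCC")) {
    sel <- which(!is.na(subtype) & subtype == s)
    if (length(sel) < 4L) next
    bm <- .stage_step("spatial", "coexpression",
                      bicor_matrix(norm_post[, sel, drop = FALSE], net_genes))
    sizes <- Matrix::rowMeans(norm_post[net_genes, sel, drop = FALSE])
    net <- build_network(bm, sizes, threshold = p$bicor_threshold,
                         subtype = s)
    utils::write.csv(
      data.frame(gene1 = rep(net_genes, each = length(net_genes)),
                 gene2 = rep(net_genes, length(net_genes)),
                 bicor = as.vector(t(bm))),
      file.path(outdir, paste0("bicor_", s, ".csv")),
      row.names = FALSE, quote = FALSE)
    write_report(list(subtype = s, threshold = net$threshold,
                      nodes = net$nodes, edges = net$edges),
                 file.path(outdir, paste0("network_", s, ".json")))
    networks[[s]] <- net
  }

  report <- list(
    stage = "spatial",
    package_version = as.character(utils::packageVersion("spatmark")),
    parameters = p[c("n_pcs", "k_neighbors", "resolution", "seed", "tau", "K",
                     "keratin_genes", "audit_gene", "rgb_backend",
                     "bicor_threshold")],
    n_cells = nrow(cells), n_genes = nrow(counts),
    n_clusters = length(unique(clusters)),
    n_keratin_positive_clusters = sum(kp),
    n_excluded = nrow(excluded),
    tumor_fraction_raw = tumor_fraction_raw,
    tumor_fraction = tumor_fraction,
    n_tumor_specific = sum(profiles$category == "tumor_specific"),
    top_genes = topk$gene,
    tumor_specific_genes = profiles$gene[profiles$category ==
                                           "tumor_specific"],
    subtype_cell_counts = as.list(table(subtype[!is.na(subtype)])),
    artifacts = list.files(outdir))
  if (!is.null(truth)) {
    report$truth <- list(tumor_fraction = truth$tumor_fraction,
                         n_true_tumor_specific =
                           sum(truth$quadrant == "tumor_specific"))
  }
  write_report(report, file.path(outdir, "spatial_report.json"))
  invisible(c(report, list(
    profiles = profiles, clusters = clusters, keratin_positive = kp,
    cells = cells, post = post, subtype = subtype, networks = networks,
    truth_full = truth)))
}

#' Run the bulk stage of the pipeline
#'
#' Median split on the marker, Kaplan-Meier + log-rank overall and within the
#' configured subgroups (stage I/II, stage III/IV, EGFR/KRAS wild-type when
#' mutation flags are available), multivariable Cox adjusted for stage, age,
#' smoking and sex, and mutation enrichment between marker groups. Artifacts
#' and `bulk_report.json` are written to `outdir`.
#'
#' @param config list with either `simulate = TRUE` (+ optional `bulk` block:
#'   `n_patients`, `beta`, `censor_rate`) or `paths` (`bulk_expr`,
#'   `clinical`); `params$marker` names the marker gene.
#' @param outdir output directory.
#' @return invisibly, the report list.
#' @export
run_bulk_stage <- function(config = list(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- .merge_params(config)
  simulate <- isTRUE(config$simulate) || is.null(config$paths)

  if (simulate) {
    b <- config$bulk
    if (is.null(b)) b <- list()
    n <- if (is.null(b$n_patients)) 600L else b$n_patients
    beta <- if (is.null(b$beta)) log(2.64) else b$beta
    cr <- if (is.null(b$censor_rate)) 0.3 else b$censor_rate
    simres <- .stage_step("bulk", "simulate",
                          simulate_bulk_cohort(n, beta = beta,
                                               censor_rate = cr,
                                               seed = p$seed,
                                               marker = p$marker))
    cohort <- simres$cohort
    truth <- simres$truth
  } else {
    for (nm in c("bulk_expr", "clinical"))
      if (is.null(config$paths[[nm]]) || !file.exists(config$paths[[nm]]))
        stop("[bulk/preflight] missing input file for '", nm, "'")
    cohort <- .stage_step("bulk", "load",
                          read_bulk(config$paths$bulk_expr,
                                    config$paths$clinical))
    truth <- NULL
  }
  write_bulk(cohort, file.path(outdir, "bulk_expression.csv"),
             file.path(outdir, "clinical.csv"))

  subgroups <- list(
    stage_I_II = function(d) !d$stage %in% c("III", "IV", "III/IV"),
    stage_III_IV = function(d) d$stage %in% c("III", "IV", "III/IV"))
  if (all(c("mut_EGFR", "mut_KRAS") %in% names(cohort$clinical)))
    subgroups$EGFR_KRAS_wt <- function(d) d$mut_EGFR == 0L & d$mut_KRAS == 0L

  res <- .stage_step("bulk", "survival",
                     bulk_survival(cohort, p$marker, subgroups))

  km <- rbind(cbind(group = "high", res$overall$km_high$curve),
              cbind(group = "low", res$overall$km_low$curve))
  utils::write.csv(km, file.path(outdir, "km_curves.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(res$cox, file.path(outdir, "cox_table.csv"),
                   row.names = FALSE, quote = FALSE)

  enrich <- NULL
  mut_cols <- grep("^mut_", names(cohort$clinical), value = TRUE)
  if (length(mut_cols)) {
    hi <- res$split[cohort$clinical$sample_id] == "high"
    mk <- function(sel) {
      m <- as.matrix(cohort$clinical[sel, mut_cols, drop = FALSE])
      out <- cbind(mutated = colSums(m), wildtype = colSums(1 - m))
      rownames(out) <- sub("^mut_", "", mut_cols)
      out
    }
    enrich <- .stage_step("bulk", "enrichment",
                          fisher_enrichment(mk(hi), mk(!hi)))
    utils::write.csv(enrich, file.path(outdir, "enrichment.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  report <- list(
    stage = "bulk",
    package_version = as.character(utils::packageVersion("spatmark")),
    marker = p$marker, seed = p$seed,
    n_patients = nrow(cohort$clinical),
    n_events = sum(cohort$clinical$event),
    logrank_p = res$overall$logrank$p,
    cox = res$cox,
    subgroup_logrank_p = lapply(res$subgroups, function(s) s$logrank$p),
    artifacts = list.files(outdir))
  if (!is.null(truth))
    report$truth <- truth[c("beta", "hr", "censor_rate",
                            "realized_censoring")]
  write_report(report, file.path(outdir, "bulk_report.json"))
  invisible(c(report, list(result = res, cohort = cohort,
                           enrichment = enrich)))
}

#' Run both pipeline stages
#'
#' @param config run configuration (see [run_spatial_stage()] and
#'   [run_bulk_stage()]); `outdir` entries may also live in the config.
#' @param outdir output directory; stages write to `spatial/` and `bulk/`
#'   subdirectories.
#' @return invisibly, list with both stage reports.
#' @export
run_pipeline <- function(config = list(), outdir) {
  spatial <- run_spatial_stage(config, file.path(outdir, "spatial"))
  bulk <- run_bulk_stage(config, file.path(outdir, "bulk"))
  invisible(list(spatial = spatial, bulk = bulk))
}
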