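#' @title Simulation configuration for synthetic spatial tissue
#'
#' @description Builds the configuration object consumed by [simulate_cells()].
#' The defaults describe a desk-scale adenosquamous-carcinoma-like tissue:
#' a 2600 x 1600 um domain with four rectangular histology blocks
#' (adenocarcinoma `ADC`, squamous `SCC`, double-negative `TTF1neg_p40neg`,
#' and stromal `non_tumor`) plus two circular foci of histologically normal
#' epithelium in the central corridor. Tumor cells are hypertrophic (larger
#' log-normal cell areas than stroma) and per-cell transcript totals grow with
#' cell area; planted marker genes occupy known dropout-rate quadrants so the
#' screening stage can be scored against ground truth.
#'
#' @param seed integer; one global seed drives every RNG sub-stream (fixed
#'   offsets per stage).
#' @param domain numeric length-2, tissue width and height in microns.
#' @param regions list of regions, each `list(region_id, label, polygon)` with
#'   the polygon an n x 2 vertex matrix; labels from
#'   `c("ADC","SCC","TTF1neg_p40neg","normal","non_tumor")`.
#' @param densities named numeric, cells per 10^4 um^2 for each label.
#' @param area_model named list per label of `c(meanlog, sdlog)` for the
#'   log-normal cell-area distribution (um^2). Tumor labels must have a larger
#'   `meanlog` than `non_tumor` (tumor-cell hypertrophy).
#' @param panel data frame describing the gene panel: columns `gene`,
#'   `truth` (intended dropout quadrant) and one expected-rate column per label
#'   (`rate_ADC`, ...), in transcripts per 100 um^2 of cell area.
#' @param library_size_slope global multiplier on the expected transcripts per
#'   unit area (default 1).
#' @param dropout_extra per-gene zero-inflation probability applied on top of
#'   Poisson sampling zeros; scalar or named per-gene vector.
#' @param coexpr optional planted coexpression: `list(genes, label, sd)` adds a
#'   shared log-normal latent factor to the listed genes within one label.
#' @param nucleus_frac length-2 range of the nucleus/cell area ratio.
#'
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       domain = c(width = 2600, height = 1600),
                       regions = default_regions(),
                       densities = c(ADC = 25, SCC = 15, TTF1neg_p40neg = 12,
                                     normal = 35, non_tumor = 35),
                       area_model = list(
                         ADC            = c(meanlog = log(150), sdlog = 0.30),
                         SCC            = c(meanlog = log(150), sdlog = 0.30),
                         TTF1neg_p40neg = c(meanlog = log(150), sdlog = 0.30),
                         normal         = c(meanlog = log(120), sdlog = 0.25),
                         non_tumor      = c(meanlog = log(80),  sdlog = 0.30)),
                       panel = default_panel(),
                       library_size_slope = 1,
                       dropout_extra = 0.05,
                       coexpr = list(genes = c("COEXA", "COEXB"),
                                     label = "SCC", sd = 1.0),
                       nucleus_frac = c(0.2, 0.5)) {
  labels <- c("ADC", "SCC", "TTF1neg_p40neg", "normal", "non_tumor")
  stopifnot(length(seed) == 1L, is.finite(seed))
  seed <- as.integer(seed)
  if (length(domain) != 2L || any(!is.finite(domain)) || any(domain <= 0))
    stop("domain must be two positive numbers (width, height) in microns")

  if (!all(names(densities) %in% labels))
    stop("unknown density label(s): ",
         paste(setdiff(names(densities), labels), collapse = ", "))
  if (any(densities <= 0)) stop("densities must be > 0")

  # region validation: label vocabulary, polygons simple and inside the domain
  for (r in regions) {
    if (!all(c("region_id", "label", "polygon") %in% names(r)))
      stop("each region needs region_id, label and polygon")
    if (!r$label %in% labels)
      stop("region '", r$region_id, "' has unknown label '", r$label, "'")
    p <- polygon_matrix(r$polygon)
    if (!polygon_is_simple(p))
      stop("region '", r$region_id, "' polygon is self-intersecting")
    if (any(p[, 1] < 0) || any(p[, 1] > domain[[1]]) ||
        any(p[, 2] < 0) || any(p[, 2] > domain[[2]]))
      stop("region '", r$region_id, "' extends outside the domain")
    if (!r$label %in% names(densities))
      stop("no cell density given for label '", r$label, "'")
    if (!r$label %in% names(area_model))
      stop("no area model given for label '", r$label, "'")
  }
  # overlapping regions with conflicting labels are rejected up front
  if (length(regions) > 1L) {
    for (i in seq_len(length(regions) - 1L)) {
      for (j in (i + 1L):length(regions)) {
        if (regions[[i]]$label != regions[[j]]$label &&
            polygons_overlap(regions[[i]]$polygon, regions[[j]]$polygon))
          stop("regions '", regions[[i]]$region_id, "' (", regions[[i]]$label,
               ") and '", regions[[j]]$region_id, "' (", regions[[j]]$label,
               ") overlap with conflicting labels")
      }
    }
  }

  rate_cols <- paste0("rate_", labels)
  if (!all(c("gene", "truth", rate_cols) %in% names(panel)))
    stop("panel must have columns gene, truth and ", paste(rate_cols, collapse = ", "))
  if (anyDuplicated(panel$gene)) stop("duplicate gene names in panel")
  if (any(!is.finite(as.matrix(panel[rate_cols]))) ||
      any(as.matrix(panel[rate_cols]) < 0))
    stop("panel rates must be finite and >= 0")
  req <- c("KRT7", "KRT15", "EPCAM", "SLC2A1")
  if (!all(req %in% panel$gene))
    stop("panel must contain keratin (KRT7, KRT15), EPCAM and SLC2A1 genes")

  # tumor hypertrophy: tumor labels strictly larger than stroma on meanlog
  mu_nt <- area_model$non_tumor[["meanlog"]]
  for (lab in c("ADC", "SCC", "TTF1neg_p40neg")) {
    if (area_model[[lab]][["meanlog"]] <= mu_nt)
      stop("area_model: tumor label '", lab,
           "' must have meanlog > non_tumor (tumor-cell hypertrophy)")
  }

  de <- dropout_extra
  if (length(de) == 1L) de <- stats::setNames(rep(de, nrow(panel)), panel$gene)
  if (!all(panel$gene %in% names(de)))
    stop("dropout_extra must be scalar or named for every panel gene")
  de <- de[panel$gene]
  if (any(de < 0 | de >= 1)) stop("dropout_extra must be in [0, 1)")

  if (!is.null(coexpr)) {
    stopifnot(all(c("genes", "label", "sd") %in% names(coexpr)))
    if (!all(coexpr$genes %in% panel$gene))
      stop("coexpr genes missing from panel: ",
           paste(setdiff(coexpr$genes, panel$gene), collapse = ", "))
  }

  structure(list(seed = seed, domain = domain, regions = regions,
                 densities = densities, area_model = area_model, panel = panel,
                 library_size_slope = library_size_slope, dropout_extra = de,
                 coexpr = coexpr, nucleus_frac = nucleus_frac),
            class = "sim_config")
}

#' Default region layout for the synthetic tissue
#'
#' Four histology blocks plus two circular normal-epithelium foci in the
#' central corridor; no two regions with different labels overlap.
#'
#' @return list of regions (`region_id`, `label`, `polygon`).
#' @export
default_regions <- function() {
  rect <- function(x0, y0, x1, y1)
    cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  list(
    list(region_id = "block_ADC", label = "ADC",
         polygon = rect(0, 0, 1100, 760)),
    list(region_id = "block_SCC", label = "SCC",
         polygon = rect(1500, 0, 2600, 760)),
    list(region_id = "block_TTF1neg", label = "TTF1neg_p40neg",
         polygon = rect(0, 840, 1100, 1600)),
    list(region_id = "block_stroma", label = "non_tumor",
         polygon = rect(1500, 840, 2600, 1600)),
    list(region_id = "focus_normal_1", label = "normal",
         polygon = circle_polygon(1300, 400, 150)),
    list(region_id = "focus_normal_2", label = "normal",
         polygon = circle_polygon(1300, 1200, 150))
  )
}

#' Default 120-gene synthetic panel
#'
#' A desk-scale stand-in for a targeted lung-cancer expression panel. Named
#' genes: `KRT7`/`KRT15` (epithelial keratins, expressed in tumor *and* normal
#' epithelium but not stroma — the normal-focus failure mode the ROI audit must
#' catch), `EPCAM` (tumor-high, low in normal foci), `SLC2A1` (monotone
#' SCC > TTF1neg > ADC, absent from normal tissue), `COEXA`/`COEXB` (a planted
#' co-regulated pair). Planted groups: `TS*` tumor-specific, `CP*`
#' common-positive, `CN*` common-negative, `NS*` normal/stroma-specific, `FL*`
#' broadly expressed fillers. Rates are expected transcripts per 100 um^2.
#'
#' @return data frame with columns `gene`, `truth`, `rate_<label>`.
#' @export
default_panel <- function() {
  row <- function(gene, truth, adc, scc, ttf, nor, str)
    data.frame(gene = gene, truth = truth, rate_ADC = adc, rate_SCC = scc,
               rate_TTF1neg_p40neg = ttf, rate_normal = nor,
               rate_non_tumor = str, stringsAsFactors = FALSE)
  named <- rbind(
    row("KRT7",   "tumor_specific", 2.5, 2.5, 2.5, 2.40, 0.05),
    row("KRT15",  "tumor_specific", 2.2, 2.4, 2.2, 2.15, 0.05),
    row("EPCAM",  "tumor_specific", 2.5, 2.2, 2.4, 0.15, 0.03),
    row("SLC2A1", "tumor_specific", 0.8, 4.5, 2.2, 0.01, 0.01),
    row("COEXA",  "tumor_specific", 1.0, 2.5, 1.2, 0.90, 0.04),
    row("COEXB",  "tumor_specific", 1.0, 2.5, 1.2, 0.90, 0.04))
  # normal epithelium tracks the ADC expression program closely (low EPCAM,
  # no SLC2A1) so that conventional clustering cannot separate it from tumor
  ts_base <- seq(0.8, 2.0, length.out = 20)
  ts <- row(sprintf("TS%02d", 1:20), "tumor_specific",
            ts_base, ts_base * 1.1, ts_base * 0.95, ts_base * 0.95, 0.03)
  cp_base <- seq(0.6, 1.8, length.out = 20)
  cp <- row(sprintf("CP%02d", 1:20), "common_positive",
            cp_base, cp_base, cp_base, cp_base, cp_base)
  cn <- row(sprintf("CN%02d", 1:20), "common_negative",
            0.04, 0.04, 0.04, 0.04, 0.04)
  ns_base <- seq(1.2, 2.4, length.out = 20)
  ns <- row(sprintf("NS%02d", 1:20), "normal_specific",
            0.04, 0.04, 0.04, 0.06, ns_base)
  fl_base <- seq(0.6, 1.5, length.out = 34)
  fl <- row(sprintf("FL%02d", 1:34), "common_positive",
            fl_base * 1.1, fl_base * 0.9, fl_base, fl_base * 1.05, fl_base)
  out <- rbind(named, ts, cp, cn, ns, fl)
  rownames(out) <- NULL
  out
}

.tumor_labels <- c("ADC", "SCC", "TTF1neg_p40neg")

# uniform points in a polygon by rejection from its bounding box
.runif_in_polygon <- function(n, polygon) {
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  bx <- range(polygon[, 1]); by <- range(polygon[, 2])
  out <- matrix(NA_real_, 0L, 2L)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    x <- stats::runif(m, bx[1], bx[2]); y <- stats::runif(m, by[1], by[2])
    keep <- points_in_polygon(x, y, polygon)
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' @title Simulate a region-structured spatial single-cell dataset
#'
#' @description Places cells by a homogeneous Poisson process within each
#' region at its label's density, draws cell areas from the label's log-normal
#' model, and draws per-cell gene counts as
#' `Poisson(rate(label, gene) * area / 100 * library_size_slope)` followed by
#' per-gene zero-inflation. Transcript totals therefore grow with cell area,
#' reproducing the hypertrophy-linked count inflation the area normalization
#' is designed to remove. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `spatmark_sim` with elements
#'   \describe{
#'     \item{cells}{data frame `cell_id, x, y, cell_area, nucleus_area,
#'       total_counts`}
#'     \item{counts}{sparse integer gene x cell matrix ([Matrix::dgCMatrix])}
#'     \item{genes}{panel gene names, input order preserved}
#'     \item{regions}{the region list used (a valid `RegionSet`)}
#'     \item{truth}{ground truth: per-cell `label` and `region_id`, per-gene
#'       `quadrant`, `tumor_fraction` (exact fraction of cells carrying a
#'       tumor label), and the seed}
#'   }
#' @export
simulate_cells <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config object")
  panel <- config$panel
  genes <- panel$gene
  rate_mat <- as.matrix(panel[paste0("rate_", names(config$densities))])
  # columns ordered by density names; rebuild by label lookup below
  rates_for <- function(lab) panel[[paste0("rate_", lab)]]

  # sub-stream 1: placement + per-cell geometry
  set.seed(config$seed)
  cells_list <- list()
  for (r in config$regions) {
    p <- polygon_matrix(r$polygon)
    area <- polygon_area(p)
    lambda <- config$densities[[r$label]] * area / 1e4
    n <- stats::rpois(1L, lambda)
    if (n == 0L) {
      warning("region '", r$region_id, "' produced zero cells")
      next
    }
    xy <- .runif_in_polygon(n, p)
    am <- config$area_model[[r$label]]
    ca <- stats::rlnorm(n, am[["meanlog"]], am[["sdlog"]])
    nf <- stats::runif(n, config$nucleus_frac[1], config$nucleus_frac[2])
    cells_list[[r$region_id]] <- data.frame(
      x = xy[, 1], y = xy[, 2], cell_area = ca, nucleus_area = nf * ca,
      label = r$label, region_id = r$region_id, stringsAsFactors = FALSE)
  }
  if (length(cells_list) == 0L) stop("no cells generated: all regions empty")
  cells <- do.call(rbind, cells_list)
  rownames(cells) <- NULL
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("cell_%05d", seq_len(n_cells))

  # sub-stream 2: counts
  set.seed(config$seed + 1L)
  counts <- matrix(0L, nrow = length(genes), ncol = n_cells,
                   dimnames = list(genes, cells$cell_id))
  for (lab in unique(cells$label)) {
    idx <- which(cells$label == lab)
    lam <- outer(rates_for(lab),
                 cells$cell_area[idx] / 100 * config$library_size_slope)
    if (!is.null(config$coexpr) && config$coexpr$label == lab) {
      f <- stats::rnorm(length(idx), 0, config$coexpr$sd)
      gi <- match(config$coexpr$genes, genes)
      # mean-preserving shared latent factor -> correlated counts
      lam[gi, ] <- lam[gi, , drop = FALSE] *
        rep(exp(f - config$coexpr$sd^2 / 2), each = length(gi))
    }
    counts[, idx] <- stats::rpois(length(lam), lam)
    de <- config$dropout_extra
    drop <- matrix(stats::runif(length(lam)), nrow = nrow(lam)) < de[genes]
    counts[, idx][drop] <- 0L
  }
  storage.mode(counts) <- "integer"
  cells$total_counts <- as.integer(colSums(counts))
  counts_sp <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "generalMatrix"), "CsparseMatrix")

  truth <- list(
    label = stats::setNames(cells$label, cells$cell_id),
    region_id = stats::setNames(cells$region_id, cells$cell_id),
    quadrant = stats::setNames(panel$truth, panel$gene),
    tumor_fraction = mean(cells$label %in% .tumor_labels),
    seed = config$seed)

  cells_out <- cells[c("cell_id", "x", "y", "cell_area", "nucleus_area",
                       "total_counts")]
  structure(list(cells = cells_out, counts = counts_sp, genes = genes,
                 regions = config$regions, truth = truth),
            class = "spatmark_sim")
}

#' @title Simulate a bulk survival cohort with a planted marker effect
#'
#' @description Generates an adenocarcinoma-like bulk cohort in which the log
#' hazard depends on the median-split indicator of one marker gene plus
#' clinical covariates (stage, age, smoking, sex). Marker expression is
#' log-normal; event times are exponential with
#' `log h = log h0 + beta * I(expr > median) + covariate terms`; censoring is
#' independent uniform, calibrated so the realized censoring proportion
#' approximates `censor_rate`. Optional Bernoulli mutation flags differ in
#' frequency between marker-high and marker-low patients.
#'
#' @param n_patients integer >= 2.
#' @param beta true log hazard ratio of the marker-high indicator.
#' @param covariate_spec named list of covariate log-hazard effects
#'   (`stage`, `age_per_decade`, `smoking`, `sex`) and prevalences
#'   (`p_stage34`, `p_smoking`, `p_male`); defaults are used for omitted
#'   entries.
#' @param censor_rate target censoring proportion in `[0, 1)`.
#' @param seed integer seed.
#' @param marker name of the marker gene column (default `"SLC2A1"`).
#' @param mutation_spec data frame `gene, p_high, p_low` of mutation
#'   probabilities per group, or `NULL` for the default five-gene set
#'   (TP53/KEAP1/RB1/KRAS enriched in marker-high, EGFR in marker-low).
#' @return list with `cohort` (a `bulk_cohort`: `$expr` samples x genes data
#'   frame, `$clinical` data frame) and `truth` (planted `beta`, `hr`,
#'   covariate effects, target and realized censoring rate).
#' @export
simulate_bulk_cohort <- function(n_patients, beta = log(2.64),
                                 covariate_spec = NULL, censor_rate = 0.3,
                                 seed = 1L, marker = "SLC2A1",
                                 mutation_spec = NULL) {
  if (!is.finite(beta)) stop("beta must be finite")
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (censor_rate < 0 || censor_rate >= 1) stop("censor_rate must be in [0, 1)")

  cs <- list(stage = log(2.2), age_per_decade = log(1.25), smoking = log(1.2),
             sex = log(1.1), p_stage34 = 0.4, p_smoking = 0.55, p_male = 0.55)
  if (!is.null(covariate_spec)) cs[names(covariate_spec)] <- covariate_spec

  set.seed(as.integer(seed))
  n <- as.integer(n_patients)
  expr <- stats::rlnorm(n, meanlog = 2, sdlog = 0.8)
  stage34 <- stats::rbinom(n, 1L, cs$p_stage34)
  age <- pmin(pmax(round(stats::rnorm(n, 68, 8)), 30), 92)
  smoking <- stats::rbinom(n, 1L, cs$p_smoking)
  male <- stats::rbinom(n, 1L, cs$p_male)
  high <- expr > stats::median(expr)

  h0 <- log(2) / 60  # baseline median survival 60 months
  loghaz <- log(h0) + beta * high + cs$stage * stage34 +
    cs$age_per_decade * (age - 68) / 10 + cs$smoking * smoking + cs$sex * male
  t_event <- stats::rexp(n, rate = exp(loghaz))

  if (censor_rate > 0) {
    # calibrate the uniform-censoring horizon to the realized event times:
    # P(C < t | horizon) = min(t / horizon, 1) for C ~ U(0, horizon)
    f <- function(cm) mean(pmin(t_event / cm, 1)) - censor_rate
    cmax <- stats::uniroot(f, lower = min(t_event) * 1e-3,
                           upper = max(t_event) * 1e3, tol = 1e-8)$root
    cens <- stats::runif(n, 0, cmax)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  if (is.null(mutation_spec)) {
    mutation_spec <- data.frame(
      gene = c("TP53", "KEAP1", "RB1", "KRAS", "EGFR"),
      p_high = c(0.55, 0.20, 0.12, 0.25, 0.25),
      p_low = c(0.35, 0.08, 0.05, 0.15, 0.50),
      stringsAsFactors = FALSE)
  }
  muts <- sapply(seq_len(nrow(mutation_spec)), function(i) {
    p <- ifelse(high, mutation_spec$p_high[i], mutation_spec$p_low[i])
    stats::rbinom(n, 1L, p)
  })
  colnames(muts) <- paste0("mut_", mutation_spec$gene)

  ids <- sprintf("pt_%04d", seq_len(n))
  # a TTF-1-like gene weakly anti-correlated with the marker
  nkx <- exp(3 - 0.4 * (log(expr) - 2) + stats::rnorm(n, 0, 0.6))
  expr_df <- data.frame(sample_id = ids, expr, nkx, check.names = FALSE,
                        stringsAsFactors = FALSE)
  names(expr_df)[2:3] <- c(marker, "NKX2-1")
  clinical <- data.frame(sample_id = ids, time = time, event = event,
                         stage = ifelse(stage34 == 1L, "III/IV", "I/II"),
                         age = age,
                         smoking = ifelse(smoking == 1L, "ever", "never"),
                         sex = ifelse(male == 1L, "male", "female"),
                         histology = "ADC", stringsAsFactors = FALSE)
  clinical <- cbind(clinical, as.data.frame(muts))

  cohort <- bulk_cohort(expr_df, clinical)
  truth <- list(beta = beta, hr = exp(beta),
                covariate_effects = cs[c("stage", "age_per_decade", "smoking",
                                         "sex")],
                censor_rate = censor_rate,
                realized_censoring = mean(event == 0L), seed = seed)
  list(cohort = cohort, truth = truth)
}

#' @export
print.spatmark_sim <- function(x, ...) {
  cat("Synthetic spatial dataset:", nrow(x$cells), "cells,",
      length(x$genes), "genes\n")
  cat("  true tumor fraction:", round(x$truth$tumor_fraction, 4), "\n")
  tab <- table(x$truth$label)
  cat("  cells per label:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
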