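# Shared fixtures. The default synthetic tissue plus its clustering is the
# most expensive object in the suite, so it is computed once per test run and
# cached.

.fixture_cache <- new.env(parent = emptyenv())

# full spatial flow on the default synthetic tissue (fixed seed), cached
default_spatial_run <- function() {
  if (!is.null(.fixture_cache$run)) return(.fixture_cache$run)
  sim <- simulate_cells(sim_config(seed = 101L))
  norm <- normalize_by_area(sim$counts, sim$cells$cell_area)
  clusters <- cluster_cells(norm, seed = 101L)
  log2fc <- keratin_log2fc(norm, clusters)
  kp <- classify_keratin_clusters(log2fc)
  rois <- Filter(function(r) r$label == "normal", sim$regions)
  roi_assign <- assign_rois(sim$cells, rois)
  post <- exclude_cells(sim, roi_assign,
                        vapply(rois, `[[`, "", "region_id"), regions = rois)
  keep <- match(post$cells$cell_id, sim$cells$cell_id)
  run <- list(sim = sim, norm = norm, clusters = clusters, log2fc = log2fc,
              kp = kp, rois = rois, roi_assign = roi_assign, post = post,
              clusters_post = clusters[keep],
              norm_post = norm[, keep, drop = FALSE])
  .fixture_cache$run <- run
  run
}

# two transcriptionally disjoint populations with fully separated marker sets
two_population_counts <- function(n_per = 500L, n_genes = 40L, seed = 5L,
                                  rate_on = 5, rate_off = 0.05) {
  set.seed(seed)
  half <- n_genes %/% 2L
  a <- rbind(matrix(rpois(half * n_per, rate_on), half),
             matrix(rpois((n_genes - half) * n_per, rate_off),
                    n_genes - half))
  b <- rbind(matrix(rpois(half * n_per, rate_off), half),
             matrix(rpois((n_genes - half) * n_per, rate_on),
                    n_genes - half))
  x <- cbind(a, b)
  dimnames(x) <- list(sprintf("G%02d", seq_len(n_genes)),
                      sprintf("c%04d", seq_len(2L * n_per)))
  list(counts = x, pop = rep(c("A", "B"), each = n_per))
}

# minimal valid panel for custom simulation configs: the required named genes
# plus caller-specified planted genes
mini_panel <- function(extra = NULL) {
  base <- data.frame(
    gene = c("KRT7", "KRT15", "EPCAM", "SLC2A1"),
    truth = "tumor_specific",
    rate_ADC = c(2.5, 2.2, 2.5, 0.8), rate_SCC = c(2.5, 2.4, 2.2, 4.5),
    rate_TTF1neg_p40neg = c(2.5, 2.2, 2.4, 2.2),
    rate_normal = c(2.4, 2.15, 0.15, 0.01),
    rate_non_tumor = c(0.05, 0.05, 0.03, 0.01),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) base <- rbind(base, extra)
  base
}

# simple two-region tissue (one tumor block, one stroma block)
two_region_config <- function(seed = 3L, density_tumor = 25, density_stroma = 30,
                              panel = mini_panel(), coexpr = NULL) {
  rect <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  sim_config(
    seed = seed, domain = c(2000, 1000),
    regions = list(
      list(region_id = "tumor", label = "ADC", polygon = rect(0, 0, 950, 1000)),
      list(region_id = "stroma", label = "non_tumor",
           polygon = rect(1050, 0, 2000, 1000))),
    densities = c(ADC = density_tumor, non_tumor = density_stroma),
    panel = panel, coexpr = coexpr)
}

# small circle polygon without reaching into package internals
circle_polygon_for_test <- function(cx, cy, r, n = 24L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# independent reference implementation of the biweight midcorrelation,
# written as plain scalar loops from the published definition
bicor_reference <- function(x, y) {
  n <- length(x)
  wvec <- function(v) {
    med <- median(v)
    madu <- median(abs(v - med))
    u <- (v - med) / (9 * madu)
    w <- numeric(n)
    for (i in seq_len(n)) if (abs(u[i]) < 1) w[i] <- (1 - u[i]^2)^2
    (v - med) * w
  }
  a <- wvec(x); b <- wvec(y)
  num <- 0; da <- 0; db <- 0
  for (i in seq_len(n)) {
    num <- num + a[i] * b[i]
    da <- da + a[i]^2
    db <- db + b[i]^2
  }
  max(-1, min(1, num / sqrt(da * db)))
}

# two-sided Fisher exact p by hypergeometric enumeration with fixed margins
fisher_enumeration <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two-group log-rank chi-square from the observed-minus-expected formula,
# computed by an explicit loop over distinct event times
logrank_reference <- function(times, events, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(times[events == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ts) {
    at_risk <- times >= t
    n1 <- sum(at_risk & g == 1L); n2 <- sum(at_risk & g == 2L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & g == 1L)
    n <- n1 + n2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}
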