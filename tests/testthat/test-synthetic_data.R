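test_that("simulation is deterministic for a fixed seed", {
  cfg <- two_region_config(seed = 11L, density_tumor = 5, density_stroma = 5)
  a <- simulate_cells(cfg)
  b <- simulate_cells(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(as.matrix(a$counts), as.matrix(b$counts))
  c3 <- simulate_cells(two_region_config(seed = 12L, density_tumor = 5,
                                         density_stroma = 5))
  expect_false(identical(a$cells$x, c3$cells$x))
})

test_that("a zero rate yields all-zero counts for that label", {
  extra <- data.frame(gene = "ZERO", truth = "normal_specific",
                      rate_ADC = 0, rate_SCC = 0, rate_TTF1neg_p40neg = 0,
                      rate_normal = 0, rate_non_tumor = 2,
                      stringsAsFactors = FALSE)
  sim <- simulate_cells(two_region_config(seed = 2L, density_tumor = 8,
                                          density_stroma = 8,
                                          panel = mini_panel(extra)))
  adc <- sim$truth$label == "ADC"
  expect_true(all(sim$counts["ZERO", adc] == 0))
  expect_gt(sum(sim$counts["ZERO", !adc]), 0)
})

test_that("planted high/low rates land in the tumor-specific quadrant and
           match the zero-mass oracle", {
  extra <- data.frame(gene = "PLANT1", truth = "tumor_specific",
                      rate_ADC = 5, rate_SCC = 5, rate_TTF1neg_p40neg = 5,
                      rate_normal = 5, rate_non_tumor = 0.05,
                      stringsAsFactors = FALSE)
  cfg <- two_region_config(seed = 4L, density_tumor = 25, density_stroma = 30,
                           panel = mini_panel(extra))
  sim <- simulate_cells(cfg)
  tum <- sim$truth$label == "ADC"
  expect_gte(sum(tum), 2000)
  expect_gte(sum(!tum), 2000)
  d_T <- mean(sim$counts["PLANT1", tum] == 0)
  d_N <- mean(sim$counts["PLANT1", !tum] == 0)
  expect_lt(d_T, 0.75)
  expect_gte(d_N, 0.75)
  expect_identical(classify_dropout(d_T, d_N), "tumor_specific")

  # oracle: dropout = zero-inflation + (1 - zi) * E_A[exp(-r A / 100)] with
  # A log-normal, evaluated by numerical integration
  zero_mass <- function(rate, meanlog, sdlog, zi) {
    integrand <- function(a) exp(-rate * a / 100) * dlnorm(a, meanlog, sdlog)
    zi + (1 - zi) * integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  }
  am <- cfg$area_model
  expect_lt(abs(d_T - zero_mass(5, am$ADC[["meanlog"]], am$ADC[["sdlog"]],
                                0.05)), 0.02)
  expect_lt(abs(d_N - zero_mass(0.05, am$non_tumor[["meanlog"]],
                                am$non_tumor[["sdlog"]], 0.05)), 0.02)
})

test_that("counts are integer-valued and transcript totals track cell area", {
  run <- default_spatial_run()
  sim <- run$sim
  expect_true(all(sim$counts@x >= 0))
  expect_true(all(sim$counts@x == round(sim$counts@x)))
  expect_gte(nrow(sim$cells), 5000)
  rho <- cor(sim$cells$total_counts, sim$cells$cell_area,
             method = "spearman")
  expect_gt(rho, 0.3)
})

test_that("ground-truth tumor fraction equals the labeled-cell fraction", {
  run <- default_spatial_run()
  lab <- run$sim$truth$label
  expect_identical(run$sim$truth$tumor_fraction,
                   mean(lab %in% c("ADC", "SCC", "TTF1neg_p40neg")))
  expect_gt(run$sim$truth$tumor_fraction, 0)
  expect_lt(run$sim$truth$tumor_fraction, 1)
})

test_that("a gene with identical rates everywhere has matching dropout rates", {
  extra <- data.frame(gene = "FLAT", truth = "common_positive",
                      rate_ADC = 1, rate_SCC = 1, rate_TTF1neg_p40neg = 1,
                      rate_normal = 1, rate_non_tumor = 1,
                      stringsAsFactors = FALSE)
  # equal areas across labels so the rate, not geometry, drives dropout
  cfg <- two_region_config(seed = 9L, density_tumor = 30, density_stroma = 30,
                           panel = mini_panel(extra))
  cfg$area_model$non_tumor <- c(meanlog = log(149), sdlog = 0.30)
  sim <- simulate_cells(cfg)
  tum <- sim$truth$label == "ADC"
  expect_gte(nrow(sim$cells), 5000)
  expect_lt(abs(mean(sim$counts["FLAT", tum] == 0) -
                  mean(sim$counts["FLAT", !tum] == 0)), 0.05)
})

test_that("invalid simulation configs are rejected", {
  rect <- function(x0, y0, x1, y1) cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
  expect_error(sim_config(regions = list(
    list(region_id = "a", label = "ADC", polygon = rect(0, 0, 500, 500)),
    list(region_id = "b", label = "SCC", polygon = rect(250, 250, 700, 700)))),
    "overlap")
  expect_error(sim_config(densities = c(ADC = -1, SCC = 15,
                                        TTF1neg_p40neg = 12, normal = 35,
                                        non_tumor = 35)), "densities")
  bad_area <- list(ADC = c(meanlog = log(70), sdlog = 0.3),
                   SCC = c(meanlog = log(150), sdlog = 0.3),
                   TTF1neg_p40neg = c(meanlog = log(150), sdlog = 0.3),
                   normal = c(meanlog = log(120), sdlog = 0.25),
                   non_tumor = c(meanlog = log(80), sdlog = 0.3))
  expect_error(sim_config(area_model = bad_area), "hypertrophy")
  expect_error(sim_config(panel = default_panel()[-1, ]), "KRT7")
})

test_that("an empty region warns and produces zero cells", {
  cfg <- two_region_config(seed = 21L, density_tumor = 20,
                           density_stroma = 0.0001)
  expect_warning(sim <- simulate_cells(cfg), "zero cells")
  expect_false("non_tumor" %in% sim$truth$label)
})

test_that("bulk cohort simulation honors censoring and the null effect", {
  res0 <- simulate_bulk_cohort(300, beta = 1, censor_rate = 0, seed = 8L)
  expect_true(all(res0$cohort$clinical$event == 1L))

  res <- simulate_bulk_cohort(2000, beta = 1, censor_rate = 0.4, seed = 8L)
  expect_equal(mean(res$cohort$clinical$event == 0L), 0.4, tolerance = 0.05)

  # beta = 0: hazard ratio of the split indicator near 1 at n = 5000
  null <- simulate_bulk_cohort(5000, beta = 0, censor_rate = 0.2, seed = 8L)
  clin <- null$cohort$clinical
  hi <- median_split(null$cohort$expr$SLC2A1) == "high"
  fit <- survival::coxph(survival::Surv(clin$time, clin$event) ~ hi)
  expect_equal(unname(exp(coef(fit))), 1, tolerance = 0.1)

  expect_error(simulate_bulk_cohort(100, beta = Inf), "finite")
  expect_error(simulate_bulk_cohort(1, beta = 0), "n_patients")
  expect_error(simulate_bulk_cohort(10, beta = 0, censor_rate = 1),
               "censor_rate")
})

test_that("planted Cox effect is recoverable from a large simulated cohort", {
  res <- simulate_bulk_cohort(2000, beta = log(2), censor_rate = 0.3,
                              seed = 31L)
  clin <- res$cohort$clinical
  d <- data.frame(time = clin$time, event = clin$event,
                  marker_high = as.integer(
                    median_split(res$cohort$expr$SLC2A1) == "high"),
                  stage = as.integer(clin$stage == "III/IV"),
                  age = clin$age,
                  smoking = as.integer(clin$smoking == "ever"),
                  sex = as.integer(clin$sex == "male"))
  tab <- cox_ph(d)
  hr <- tab$hr[tab$term == "marker_high"]
  expect_gt(hr, 1.7)
  expect_lt(hr, 2.35)
})
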