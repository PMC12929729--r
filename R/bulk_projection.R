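# Projection of a spatially derived marker onto a bulk cohort: median split,
# Kaplan-Meier estimation, log-rank test, multivariable Cox regression and
# mutation enrichment with BH correction. Model fitting is delegated to the
# survival package (Efron tie handling for Cox).

#' Median split of a continuous marker
#'
#' `high` iff the value is strictly greater than the cohort median; values
#' equal to the median go to `low`. The split is invariant to monotone
#' transforms of the values.
#'
#' @param values numeric vector (n >= 2, not all identical).
#' @return factor with levels `c("low", "high")`.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("non-finite marker values")
  if (length(unique(values)) == 1L)
    stop("all marker values identical: degenerate split")
  factor(ifelse(values > stats::median(values), "high", "low"),
         levels = c("low", "high"))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive survival times.
#' @param events event indicators (1 = death, 0 = censored).
#' @param risk_times optional time points at which to report the number at
#'   risk.
#' @return list with `curve` (data frame `time, n_risk, n_event, n_censor,
#'   survival`, one row per observed time) and `risk_table` (if requested).
#' @export
km_estimate <- function(times, events, risk_times = NULL) {
  if (length(times) == 0L) stop("empty input")
  if (any(!is.finite(times)) || any(times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0L, 1L))) stop("events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      survival = fit$surv)
  out <- list(curve = curve)
  if (!is.null(risk_times)) {
    s <- summary(fit, times = risk_times, extend = TRUE)
    out$risk_table <- data.frame(time = s$time, n_risk = s$n.risk)
  }
  out
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square comparing the survival of two groups;
#' the p-value is two-sided and invariant to swapping group labels. When
#' neither group has any event, p = 1 is returned with a warning.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param group two-level factor or vector.
#' @return list with `statistic` (chi-square), `df`, `p`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("group must have exactly 2 non-empty levels")
  if (sum(events) == 0L) {
    warning("no events in either group; log-rank p = 1")
    return(list(statistic = 0, df = 1L, p = 1))
  }
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(statistic = unname(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE))
}

#' Multivariable Cox proportional hazards model
#'
#' Partial-likelihood fit with Efron handling of tied event times. Default
#' terms are the marker-high indicator plus the clinical covariates (stage
#' dichotomized I/II vs III/IV, age, smoking status, sex). Reports per-term
#' hazard ratios with Wald 95% confidence intervals and p-values; refuses to
#' return a silently clipped fit when the likelihood diverges (complete
#' separation) or the fit fails to converge.
#'
#' @param data data frame containing `time`, `event` and the term columns.
#' @param terms character vector of term (column) names.
#' @return data frame `term, coef, hr, lower95, upper95, p`.
#' @export
cox_ph <- function(data, terms = c("marker_high", "stage", "age", "smoking",
                                   "sex")) {
  miss <- setdiff(c("time", "event", terms), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (sum(data$event) < length(terms))
    stop("fewer events (", sum(data$event), ") than model terms (",
         length(terms), ")")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", terms),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite|beta may be infinite|Loglik converged",
                conditionMessage(w)))
        stop("Cox model did not converge (possible complete separation): ",
             conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit)
  data.frame(term = rownames(s$coefficients),
             coef = s$coefficients[, "coef"],
             hr = s$conf.int[, "exp(coef)"],
             lower95 = s$conf.int[, "lower .95"],
             upper95 = s$conf.int[, "upper .95"],
             p = s$coefficients[, "Pr(>|z|)"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control; q-values are monotone in the p-value ranks and never
#' exceed 1.
#'
#' @param pvals numeric p-values.
#' @return q-values, same order as input.
#' @export
bh_adjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Mutation enrichment between marker-high and marker-low groups
#'
#' Per gene, a two-sided Fisher exact test (conditional-MLE odds ratio, the
#' convention of `stats::fisher.test`) of the 2x2 table mutated/wild-type x
#' high/low, with BH adjustment across the tested genes.
#'
#' @param counts_high,counts_low data frames or matrices with columns
#'   `mutated` and `wildtype` and one row per gene (shared rownames/order).
#' @return data frame `gene, odds_ratio, p, q`.
#' @export
fisher_enrichment <- function(counts_high, counts_low) {
  ch <- as.matrix(counts_high); cl <- as.matrix(counts_low)
  if (!all(c("mutated", "wildtype") %in% colnames(ch)) ||
      !all(c("mutated", "wildtype") %in% colnames(cl)))
    stop("counts need columns 'mutated' and 'wildtype'")
  if (nrow(ch) != nrow(cl)) stop("gene sets differ between groups")
  if (any(ch < 0) || any(cl < 0)) stop("negative counts")
  genes <- rownames(ch)
  if (is.null(genes)) genes <- sprintf("gene_%d", seq_len(nrow(ch)))
  res <- t(vapply(seq_len(nrow(ch)), function(i) {
    tab <- rbind(high = ch[i, c("mutated", "wildtype")],
                 low = cl[i, c("mutated", "wildtype")])
    ft <- stats::fisher.test(tab)
    c(or = unname(ft$estimate), p = ft$p.value)
  }, numeric(2)))
  data.frame(gene = genes, odds_ratio = res[, "or"], p = res[, "p"],
             q = bh_adjust(res[, "p"]), stringsAsFactors = FALSE)
}

#' Marker-stratified survival analysis of a bulk cohort
#'
#' The full projection flow: median split on the chosen marker over the whole
#' cohort, Kaplan-Meier curves and log-rank test overall and within optional
#' subgroups (row filters applied after the split), and a multivariable Cox
#' model of the marker-high indicator adjusted for stage (I/II vs III/IV),
#' age, smoking and sex.
#'
#' @param cohort a `bulk_cohort`.
#' @param marker marker gene name (column of `cohort$expr`).
#' @param subgroups named list of predicate functions over the clinical data
#'   frame, e.g. `list(stage34 = function(d) d$stage == "III/IV")`.
#' @param risk_times time points for the number-at-risk table.
#' @return list of class `survival_result`: `marker`, `split` (per-sample
#'   labels), `overall` (`km_high`, `km_low`, `logrank`), `subgroups`,
#'   `cox` (term table).
#' @export
bulk_survival <- function(cohort, marker, subgroups = NULL,
                          risk_times = seq(0, 120, by = 24)) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  if (!marker %in% names(cohort$expr))
    stop("marker gene '", marker, "' absent from the bulk expression matrix")
  clin <- cohort$clinical
  split <- median_split(cohort$expr[[marker]])

  analyze <- function(sel) {
    d <- clin[sel, , drop = FALSE]
    g <- split[sel]
    if (length(unique(g[d$event == 1L])) == 0L || nlevels(droplevels(g)) < 2L)
      return(NULL)
    list(km_high = km_estimate(d$time[g == "high"], d$event[g == "high"],
                               risk_times),
         km_low = km_estimate(d$time[g == "low"], d$event[g == "low"],
                              risk_times),
         logrank = logrank_test(d$time, d$event, g),
         n = c(high = sum(g == "high"), low = sum(g == "low")))
  }

  overall <- analyze(rep(TRUE, nrow(clin)))
  sub_out <- list()
  if (!is.null(subgroups)) {
    for (nm in names(subgroups)) {
      sel <- subgroups[[nm]](clin)
      sel[is.na(sel)] <- FALSE
      res <- if (sum(sel) >= 2L) analyze(sel) else NULL
      if (is.null(res)) {
        warning("subgroup '", nm, "' is empty or degenerate; skipped")
      } else {
        sub_out[[nm]] <- res
      }
    }
  }

  cox_data <- data.frame(time = clin$time, event = clin$event,
                         marker_high = as.integer(split == "high"),
                         stage = as.integer(clin$stage %in%
                                              c("III", "IV", "III/IV")),
                         age = clin$age,
                         smoking = as.integer(clin$smoking %in%
                                                c("ever", "current", "yes",
                                                  "1")),
                         sex = as.integer(clin$sex %in% c("male", "M", "1")))
  cox <- cox_ph(cox_data)

  structure(list(marker = marker,
                 split = stats::setNames(as.character(split),
                                         clin$sample_id),
                 overall = overall, subgroups = sub_out, cox = cox),
            class = "survival_result")
}
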