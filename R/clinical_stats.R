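# Statistics on global (MS-measured) 5mC/5hmC levels: condition and ISS
# comparisons, covariate checks, and biomarker-dichotomized survival.

.analyte_col <- function(analyte) {
  analyte <- match.arg(analyte, c("hmc", "mc"))
  paste0(analyte, "_percent")
}

#' Percent reduction of a test group relative to a reference
#'
#' \code{100 * (mean(reference) - mean(test)) / mean(reference)}; scale
#' invariant, and medians can be used instead of means.
#'
#' @param reference,test numeric vectors (NAs dropped).
#' @param use "mean" (default) or "median".
#' @return percent reduction (positive when the test group is lower).
#' @export
percent_reduction <- function(reference, test, use = c("mean", "median")) {
  use <- match.arg(use)
  f <- if (use == "mean") mean else stats::median
  ref <- f(reference, na.rm = TRUE)
  if (!is.finite(ref) || ref <= 0) stop("reference mean must be > 0")
  100 * (ref - f(test, na.rm = TRUE)) / ref
}

#' Compare global levels between normal and tumor samples
#'
#' Normal plasma cells (condition NPC) versus newly diagnosed tumors
#' (condition NDMM); missing analyte values are dropped with a notice.
#'
#' @param samples sample table (see \code{\link{simulate_cohort}}).
#' @param analyte "hmc" or "mc".
#' @param test "wilcox" (two-sided Mann-Whitney, default) or "t".
#' @param use summary for the reduction, "mean" or "median".
#' @return list: \code{reduction} (percent), \code{p}, \code{n_npc},
#'   \code{n_ndmm}.
#' @export
compare_conditions <- function(samples, analyte = c("hmc", "mc"),
                               test = c("wilcox", "t"),
                               use = c("mean", "median")) {
  col <- .analyte_col(analyte)
  test <- match.arg(test)
  ref <- samples[samples$condition == "NPC", col]
  tum <- samples[samples$condition == "NDMM", col]
  n_miss <- sum(is.na(ref)) + sum(is.na(tum))
  if (n_miss) message("dropping ", n_miss, " missing ", col, " value(s)")
  ref <- ref[!is.na(ref)]; tum <- tum[!is.na(tum)]
  if (length(ref) < 2 || length(tum) < 2)
    stop("need >= 2 samples per condition")
  p <- if (test == "wilcox")
    stats::wilcox.test(ref, tum)$p.value
  else stats::t.test(ref, tum)$p.value
  list(reduction = percent_reduction(ref, tum, use = use), p = p,
       n_npc = length(ref), n_ndmm = length(tum))
}

#' ISS stage trend of a global level
#'
#' Per-stage means among NDMM samples plus stage-I-vs-II and I-vs-III percent
#' reductions with two-sided Mann-Whitney p-values; stage-NA samples are
#' excluded.
#'
#' @inheritParams compare_conditions
#' @return list: \code{stage_means}, \code{reduction_I_vs_II},
#'   \code{p_I_vs_II}, \code{reduction_I_vs_III}, \code{p_I_vs_III}.
#' @export
iss_trend <- function(samples, analyte = c("hmc", "mc")) {
  col <- .analyte_col(analyte)
  d <- samples[samples$condition == "NDMM" & !is.na(samples$iss) &
                 samples$iss != "NA" & !is.na(samples[[col]]), ]
  v <- split(d[[col]], factor(d$iss, levels = c("I", "II", "III")))
  empty <- names(v)[lengths(v) < 2]
  if (length(empty)) stop("stage with < 2 samples: ", empty[1])
  list(stage_means = vapply(v, mean, 0),
       reduction_I_vs_II = percent_reduction(v$I, v$II),
       p_I_vs_II = stats::wilcox.test(v$I, v$II)$p.value,
       reduction_I_vs_III = percent_reduction(v$I, v$III),
       p_I_vs_III = stats::wilcox.test(v$I, v$III)$p.value)
}

#' Association of a global level with age or sex
#'
#' Age: Pearson correlation and its t-test p. Sex: two-sided Mann-Whitney.
#'
#' @inheritParams compare_conditions
#' @param covariate "age" or "sex".
#' @return list: \code{statistic}, \code{p}, \code{n}.
#' @export
covariate_association <- function(samples, analyte = c("hmc", "mc"),
                                  covariate = c("age", "sex")) {
  col <- .analyte_col(analyte)
  covariate <- match.arg(covariate)
  d <- samples[!is.na(samples[[col]]) & !is.na(samples[[covariate]]), ]
  if (length(unique(d[[covariate]])) < 2) stop("constant covariate")
  if (covariate == "age") {
    ct <- stats::cor.test(d$age, d[[col]])
    list(statistic = unname(ct$estimate), p = ct$p.value, n = nrow(d))
  } else {
    grp <- split(d[[col]], d$sex)
    w <- stats::wilcox.test(grp[[1]], grp[[2]])
    list(statistic = unname(w$statistic), p = w$p.value, n = nrow(d))
  }
}

#' Median-dichotomized survival analysis
#'
#' NDMM samples with a measured analyte are split at the median (values less
#' than or equal to the median go to "low", so an odd n of 39 gives 20/19);
#' Kaplan-Meier curves per group, a log-rank p, and a Cox proportional-hazards
#' fit on the binary indicator. The hazard ratio is oriented low-versus-high,
#' so HR > 1 means a worse outcome with less 5hmC. A group with zero events
#' is flagged as unstable.
#'
#' @inheritParams compare_conditions
#' @param split only "median" is implemented.
#' @return list of class \code{survival_split}: \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p_logrank}, \code{n_low}, \code{n_high},
#'   \code{split_value}, \code{unstable}, \code{km} (data.frame: group, time,
#'   survival, at_risk), and the \code{cox} fit.
#' @export
dichotomized_survival <- function(samples, analyte = c("hmc", "mc"),
                                  split = "median") {
  split <- match.arg(split)
  col <- .analyte_col(analyte)
  d <- samples[samples$condition == "NDMM" & !is.na(samples[[col]]) &
                 !is.na(samples$os_months) & !is.na(samples$os_event), ]
  if (sum(d$os_event) < 2) stop("need at least 2 events")
  med <- stats::median(d[[col]])
  d$grp <- factor(ifelse(d[[col]] <= med, "low", "high"),
                  levels = c("high", "low"))
  if (nlevels(droplevels(d$grp)) < 2)
    stop("degenerate split: all samples on one side of the median")
  s <- survival::Surv(d$os_months, d$os_event)
  cox <- suppressWarnings(survival::coxph(s ~ grp, data = d))
  beta <- unname(stats::coef(cox)[1]); se <- sqrt(unname(cox$var[1, 1]))
  lr <- survival::survdiff(s ~ grp, data = d)
  sf <- survival::survfit(s ~ grp, data = d)
  km <- data.frame(
    group = rep(sub("^grp=", "", names(sf$strata)), sf$strata),
    time = sf$time, survival = sf$surv, at_risk = sf$n.risk)
  ev <- tapply(d$os_event, d$grp, sum)
  structure(list(hr = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 p_logrank = 1 - stats::pchisq(lr$chisq, df = 1),
                 n_low = sum(d$grp == "low"), n_high = sum(d$grp == "high"),
                 split_value = med, unstable = any(ev == 0),
                 km = km, cox = cox),
            class = "survival_split")
}

#' @export
print.survival_split <- function(x, ...) {
  cat(sprintf(
    "survival_split: HR = %.2f [%.2f, %.2f] (low vs high), log-rank p = %.3g, n = %d/%d%s\n",
    x$hr, x$ci_low, x$ci_high, x$p_logrank, x$n_low, x$n_high,
    if (x$unstable) " [unstable: a group has zero events]" else ""))
  invisible(x)
}

#' Read a sample sheet TSV
#'
#' Tab-separated with a header; must contain the columns written by
#' \code{\link{write_cohort}}.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "condition", "group", "iss", "sex", "age",
            "mc_percent", "hmc_percent", "os_months", "os_event")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("sample sheet missing columns: ",
                         paste(miss, collapse = ", "))
  d
}
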