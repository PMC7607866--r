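# Observed fraction of a CpG set inside domains versus a resampling null
# drawn from a CpG universe.

#' Fraction of CpG sites inside domains
#'
#' Membership is by half-open containment of the site position.
#'
#' @param points \code{GRanges} of 1-bp CpG sites.
#' @param domains flattened \code{GRanges} of domains.
#' @return fraction in [0, 1].
#' @export
overlap_fraction <- function(points, domains) {
  if (!length(points)) stop("empty point set")
  mean(suppressWarnings(
    GenomicRanges::countOverlaps(points, domains, ignore.strand = TRUE)) > 0)
}

#' Resampling null for CpG-set overlap with domains
#'
#' Each resample draws \code{|target|} CpGs from the universe without
#' replacement and records its overlap fraction with the domains; the
#' observed fraction of the target set is compared with the null mean and SD,
#' and an upper one-sided empirical p-value
#' \code{(1 + #\{null >= observed\}) / (n_resamples + 1)} is reported.
#' Deterministic given \code{seed}.
#'
#' @param target \code{GRanges} of 1-bp CpG sites of interest.
#' @param universe \code{GRanges} of 1-bp background CpGs (at least as many
#'   as the target).
#' @param domains flattened domain \code{GRanges}.
#' @param n_resamples number of resamples (>= 100).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return list of class \code{overlap_null}: \code{observed_fraction},
#'   \code{null_mean}, \code{null_sd}, \code{n_resamples},
#'   \code{empirical_p}, \code{null_fractions}.
#' @export
resampling_null <- function(target, universe, domains, n_resamples = 1000,
                            seed) {
  if (missing(seed)) stop("seed is required")
  if (length(universe) < length(target))
    stop("universe smaller than target (", length(universe), " < ",
         length(target), ")")
  if (n_resamples < 100) stop("n_resamples must be >= 100")
  domains <- flatten(domains)
  observed <- overlap_fraction(target, domains)
  inside <- suppressWarnings(
    GenomicRanges::countOverlaps(universe, domains, ignore.strand = TRUE)) > 0
  set.seed(seed)
  k <- length(target)
  null <- vapply(seq_len(n_resamples), function(i)
    mean(inside[sample.int(length(universe), k)]), 0)
  structure(list(observed_fraction = observed, null_mean = mean(null),
                 null_sd = stats::sd(null), n_resamples = n_resamples,
                 empirical_p = (1 + sum(null >= observed)) / (n_resamples + 1),
                 null_fractions = null),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    "overlap_null: observed %.1f%% vs null %.1f%% (+/- %.2f%%), p = %.4g (%d resamples)\n",
    100 * x$observed_fraction, 100 * x$null_mean, 100 * x$null_sd,
    x$empirical_p, x$n_resamples))
  invisible(x)
}
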