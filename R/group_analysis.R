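# Group-specific domain statistics and diagnosis-vs-relapse differential
# analysis with a replicate-aware moderated test.

# Welch two-sided t on log2(x+1); degenerate inputs get p = 1 by convention
.welch_p <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("Welch test needs >= 2 per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    return(list(p = 1, effect = mean(x) - mean(y)))
  tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  if (is.null(tt)) return(list(p = 1, effect = mean(x) - mean(y)))
  list(p = tt$p.value, effect = unname(tt$estimate[1] - tt$estimate[2]))
}

#' Group-specific consensus domains
#'
#' Per domain and per group, a Welch two-sided t-test of log2(signal + 1)
#' contrasts the group's samples against all other samples (normal donors
#' form their own group); Benjamini-Hochberg FDR is applied per group across
#' domains. A domain is "specifically up" at \code{fdr < 0.05} with a
#' positive effect; down-hydroxymethylation is reported symmetrically via
#' \code{direction}.
#'
#' @param consensus a \code{\link{consensus_domains}} with a signal matrix,
#'   or a plain domains x samples matrix.
#' @param groups named character vector: group label per sample (names must
#'   cover the matrix columns).
#' @param fdr_threshold significance threshold (default 0.05).
#' @return data.frame: \code{domain_id}, \code{group}, \code{effect}
#'   (difference of group means on the log2 scale), \code{p}, \code{fdr},
#'   \code{direction}, \code{significant}.
#' @export
group_specific_domains <- function(consensus, groups, fdr_threshold = 0.05) {
  mat <- if (inherits(consensus, "consensus_domains"))
    consensus$signal_matrix else consensus
  if (is.null(mat)) stop("consensus has no signal matrix")
  groups <- groups[colnames(mat)]
  if (any(is.na(groups))) stop("groups missing for some samples")
  lmat <- log2(mat + 1)
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) stop("group with < 2 samples: ", g)
    if (ncol(lmat) - length(idx) < 2)
      stop("fewer than 2 samples outside group: ", g)
    res <- lapply(seq_len(nrow(lmat)), function(i)
      .welch_p(lmat[i, idx], lmat[i, -idx]))
    p <- vapply(res, `[[`, 0, "p")
    eff <- vapply(res, `[[`, 0, "effect")
    out[[g]] <- data.frame(
      domain_id = rownames(lmat), group = g, effect = eff, p = p,
      fdr = stats::p.adjust(p, method = "BH"),
      direction = ifelse(eff > 0, "up", "down"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$significant <- res$fdr < fdr_threshold
  rownames(res) <- NULL
  res
}

#' Differential domains between diagnosis and relapse replicates
#'
#' Columns are library-size normalized to a common scale (the mean of the
#' replicate totals over the analysed domains), then per-domain
#' \code{log2fc = mean log2(relapse + 1) - mean log2(diagnosis + 1)}. The
#' per-domain pooled within-condition variance is shrunk toward the
#' across-domain median variance with 4 pseudo-degrees of freedom, giving a
#' moderated t with \code{df = 2 * (nrep - 1) + 4}; BH FDR follows. Because
#' of library normalization a uniform global shift is, by design, not
#' detectable.
#'
#' @param mat domains x replicates matrix (rownames are domain ids).
#' @param condition character vector over columns with exactly the values
#'   \code{"diagnosis"} and \code{"relapse"}, at least 2 replicates each.
#' @param fdr_threshold significance threshold (default 0.05).
#' @param prior_df pseudo-degrees of freedom for variance shrinkage.
#' @return data.frame: \code{domain_id}, \code{log2fc}, \code{t}, \code{p},
#'   \code{fdr}, \code{significant}, \code{n_replicates}.
#' @export
differential_domains <- function(mat, condition, fdr_threshold = 0.05,
                                 prior_df = 4) {
  if (length(condition) != ncol(mat))
    stop("condition must label every column")
  if (!setequal(unique(condition), c("diagnosis", "relapse")))
    stop("condition must contain exactly 'diagnosis' and 'relapse'")
  i_d <- which(condition == "diagnosis"); i_r <- which(condition == "relapse")
  if (length(i_d) < 2 || length(i_r) < 2)
    stop("need >= 2 replicates per condition")
  tot <- colSums(mat)
  if (any(tot <= 0)) stop("zero total signal in replicate ",
                          colnames(mat)[which(tot <= 0)[1]])
  norm <- sweep(mat, 2, mean(tot) / tot, `*`)
  l <- log2(norm + 1)
  m_d <- rowMeans(l[, i_d, drop = FALSE])
  m_r <- rowMeans(l[, i_r, drop = FALSE])
  fc <- m_r - m_d
  v_d <- apply(l[, i_d, drop = FALSE], 1, stats::var)
  v_r <- apply(l[, i_r, drop = FALSE], 1, stats::var)
  d1 <- length(i_d) - 1; d2 <- length(i_r) - 1
  v_pool <- (d1 * v_d + d2 * v_r) / (d1 + d2)
  df <- d1 + d2
  v0 <- stats::median(v_pool)
  v_mod <- (prior_df * v0 + df * v_pool) / (prior_df + df)
  se <- sqrt(v_mod * (1 / length(i_d) + 1 / length(i_r)))
  tstat <- ifelse(se > 0, fc / se, 0)
  df_mod <- df + prior_df
  p <- 2 * stats::pt(abs(tstat), df = df_mod, lower.tail = FALSE)
  fdr <- stats::p.adjust(p, method = "BH")
  data.frame(domain_id = rownames(mat), log2fc = fc, t = tstat, p = p,
             fdr = fdr, significant = fdr < fdr_threshold,
             n_replicates = paste0(length(i_d), "+", length(i_r)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-patient relapse analysis on a synthetic cohort
#'
#' For one diagnosis/relapse pair of a \code{\link{simulate_cohort}} result:
#' builds the patient's own consensus from the four replicate tracks (peaks
#' called per replicate, stitched, consensus at \code{min_support = 2}),
#' scores each replicate on it, and runs \code{\link{differential_domains}}.
#'
#' @param sim a \code{synthetic_cohort}.
#' @param patient patient id (a name of \code{sim$relapse}).
#' @param stitch_distance stitch distance in bp.
#' @return list with \code{consensus} and \code{results}.
#' @export
relapse_differential <- function(sim, patient, stitch_distance = 12500) {
  if (!patient %in% names(sim$relapse)) stop("unknown patient: ", patient)
  reps <- sim$relapse[[patient]]$replicates
  tracks <- c(reps$diagnosis, reps$relapse)
  names(tracks) <- c("diagnosis_1", "diagnosis_2", "relapse_1", "relapse_2")
  dsets <- lapply(tracks, function(tr)
    stitch_peaks(call_peaks(tr), stitch_distance))
  cons <- consensus_domains(dsets, min_support = 2, tracks = tracks)
  res <- differential_domains(
    cons$signal_matrix,
    condition = sub("_[12]$", "", colnames(cons$signal_matrix)))
  list(consensus = cons, results = res)
}
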