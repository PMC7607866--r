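# Descriptive chromatin-context computations: ChromHMM state signal
# distributions, binned-track correlation matrices, peak-centered
# meta-profiles and expression-stratified metagene profiles.

#' Signal distribution over chromatin states
#'
#' One length-weighted mean signal per segmentation interval, grouped by its
#' state label (labels are free text and passed through), with per-state
#' quartile summaries.
#'
#' @param track a \code{binned_track}.
#' @param seg \code{GRanges} with a \code{state} metadata column.
#' @return list: \code{per_interval} (data.frame state, mean) and
#'   \code{summary} (state, n, q25, median, q75).
#' @export
state_signal_distribution <- function(track, seg) {
  if (!"state" %in% colnames(S4Vectors::mcols(seg)))
    stop("segmentation needs a 'state' column")
  m <- mean_signal(track, seg)
  per <- data.frame(state = seg$state, mean = m, stringsAsFactors = FALSE)
  s <- do.call(rbind, lapply(split(per$mean, per$state), function(v)
    data.frame(n = length(v), q25 = stats::quantile(v, 0.25),
               median = stats::median(v), q75 = stats::quantile(v, 0.75))))
  s <- data.frame(state = rownames(s), s, row.names = NULL)
  list(per_interval = per, summary = s)
}

#' Pearson correlation matrix of binned tracks
#'
#' Tracks are rebinned to \code{bin_width} (default 10 kb), bins where all
#' tracks are zero are dropped (uncovered genome would inflate correlations),
#' and Pearson r is computed on log2(x + 1). A zero-variance track yields NA
#' against the others; the diagonal is 1.
#'
#' @param tracks named list of \code{binned_track}s on the same genome.
#' @param bin_width correlation bin width in bp.
#' @return symmetric correlation matrix.
#' @export
binned_correlation_matrix <- function(tracks, bin_width = 10000) {
  if (length(tracks) < 2) stop("need at least 2 tracks")
  n_bins <- sum(ceiling(tracks[[1]]$chrom_sizes / bin_width))
  vals <- vapply(tracks, function(tr) {
    rb <- rebin(tr, bin_width)
    unlist(rb$values, use.names = FALSE)
  }, numeric(n_bins))
  if (is.null(dim(vals)))
    vals <- matrix(vals, nrow = n_bins,
                   dimnames = list(NULL, names(tracks)))
  keep <- rowSums(vals != 0) > 0
  lv <- log2(vals[keep, , drop = FALSE] + 1)
  r <- suppressWarnings(stats::cor(lv))
  diag(r) <- 1
  r
}

#' Peak-centered meta-profile
#'
#' Signal is sampled at peak centers plus offsets on a step grid and averaged
#' across peaks; peaks whose window would be truncated at a chromosome edge
#' are dropped.
#'
#' @param track a \code{binned_track}.
#' @param peaks non-empty \code{GRanges}.
#' @param half_window window half width in bp (> 0).
#' @param step sampling step in bp.
#' @return object of class \code{meta_profile}: list with \code{position}
#'   (relative bp), \code{mean}, \code{n}.
#' @export
peak_metaprofile <- function(track, peaks, half_window = 5000, step = 100) {
  if (half_window <= 0) stop("half_window must be > 0")
  if (!length(peaks)) stop("no peaks")
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  center <- floor((start0(peaks) + end0(peaks)) / 2)
  keep <- center - half_window >= 0 &
    center + half_window < track$chrom_sizes[chrom]
  chrom <- chrom[keep]; center <- center[keep]
  if (!length(center)) stop("all peaks truncated at chromosome edges")
  offs <- seq(-half_window, half_window, by = step)
  prof <- vapply(offs, function(o)
    mean(signal_at(track, chrom, center + o)), 0)
  structure(list(position = offs, mean = prof, n = length(center)),
            class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat("meta_profile:", length(x$position), "positions over n =", x$n,
      "regions; mean range", format(range(x$mean), digits = 4), "\n")
  invisible(x)
}

# per-gene scaled body + absolute flank profile, strand-oriented
.gene_profile <- function(track, chrom, s, e, strand, n_body_bins, n_flank,
                          flank) {
  fl_w <- flank / n_flank
  up <- s - flank + (seq_len(n_flank) - 1) * fl_w
  body <- s + (seq_len(n_body_bins) - 1) * (e - s) / n_body_bins
  body_e <- s + seq_len(n_body_bins) * (e - s) / n_body_bins
  dn <- e + (seq_len(n_flank) - 1) * fl_w
  starts <- c(up, body, dn)
  ends <- c(up + fl_w, body_e, dn + fl_w)
  v <- .region_mass(track, rep(chrom, length(starts)), starts, ends) /
    (ends - starts)
  if (strand == "-") v <- rev(v)
  v
}

#' Expression-stratified metagene profiles
#'
#' Each gene body is rescaled to \code{n_body_bins} length-weighted positions
#' with absolute-bp flanks, oriented by strand (profiles of "-" genes are
#' flipped), and averaged within expression classes defined on the mean RPKM
#' across \code{samples}: [0, 1), [1, 10), [10, 100) and [100, Inf),
#' boundaries closed on the left. Genes shorter than \code{n_body_bins} bp or
#' with flanks outside the chromosome are dropped; empty classes are omitted
#' with a notice.
#'
#' @param track a \code{binned_track}.
#' @param genes gene-model \code{GRanges}.
#' @param expr genes x samples RPKM matrix.
#' @param samples columns of \code{expr} to average (default all).
#' @param n_body_bins scaled body positions (default 100).
#' @param flank flank size in bp (default 2000).
#' @return named list of \code{meta_profile} objects, one per non-empty
#'   class; positions are indices (flank / body / flank), with the body span
#'   marked in the \code{body} attribute.
#' @export
metagene_by_expression <- function(track, genes, expr, samples = NULL,
                                   n_body_bins = 100, flank = 2000) {
  if (is.null(samples)) samples <- colnames(expr)
  mean_rpkm <- rowMeans(expr[genes$gene_id, samples, drop = FALSE])
  cls <- cut(mean_rpkm, c(0, 1, 10, 100, Inf), right = FALSE,
             labels = c("<1", "1-10", "10-100", ">100"),
             include.lowest = TRUE)
  n_flank <- max(1L, round(flank / track$bin_width))
  chrom <- as.character(GenomicRanges::seqnames(genes))
  s <- start0(genes); e <- end0(genes)
  ok <- (e - s) >= n_body_bins & s - flank >= 0 &
    e + flank <= track$chrom_sizes[chrom]
  out <- list()
  for (cl in levels(cls)) {
    idx <- which(ok & cls == cl)
    if (!length(idx)) {
      message("metagene class omitted (no genes): ", cl)
      next
    }
    profs <- vapply(idx, function(i)
      .gene_profile(track, chrom[i], s[i], e[i],
                    as.character(GenomicRanges::strand(genes))[i],
                    n_body_bins, n_flank, flank),
      numeric(2 * n_flank + n_body_bins))
    mp <- structure(list(position = seq_len(2 * n_flank + n_body_bins),
                         mean = rowMeans(profs), n = length(idx)),
                    class = "meta_profile")
    attr(mp, "body") <- c(n_flank + 1, n_flank + n_body_bins)
    out[[cl]] <- mp
  }
  out
}
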