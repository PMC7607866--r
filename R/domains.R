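# ROSE-style 5hmC-enriched domain calling: stitch peaks across small gaps,
# rank stitched domains by aggregate signal, cut the ranked curve at the
# slope-1 tangent point, and build a cross-sample consensus.

#' Stitch peaks into enriched domains
#'
#' Peaks separated by a gap (next start minus previous end) of at most
#' \code{distance} bp are merged transitively, on the same chromosome only.
#' The gap is measured between peak edges, exclusive of the peak lengths.
#' The cohort default of 12,500 bp merges 5hmC peaks into the large enriched
#' domains analysed throughout the package.
#'
#' @param peaks a \code{GRanges} of peaks.
#' @param distance maximum gap in bp (>= 0).
#' @return disjoint sorted \code{GRanges} of stitched domains.
#' @export
stitch_peaks <- function(peaks, distance = 12500) {
  if (length(distance) != 1 || is.na(distance) || distance < 0)
    stop("stitch distance must be a single non-negative number")
  GenomicRanges::reduce(GenomicRanges::sort(peaks, ignore.strand = TRUE),
                        min.gapwidth = distance + 1, ignore.strand = TRUE)
}

#' Domain count as a function of stitching distance
#'
#' Recomputes \code{\link{stitch_peaks}} over a grid of distances and reports
#' how many domains remain at each, together with a knee estimate: the grid
#' point maximizing the perpendicular distance to the chord joining the first
#' and last curve points after min-max scaling both axes (so the estimate does
#' not depend on the units of either axis).
#'
#' @param peaks a \code{GRanges} of peaks.
#' @param distances non-empty numeric grid of non-negative distances.
#' @return list with \code{curve} (data.frame: distance, n_domains) and
#'   \code{knee} (the estimated elbow distance).
#' @export
stitching_curve <- function(peaks, distances = seq(0, 25000, by = 2500)) {
  if (!length(distances) || any(distances < 0))
    stop("distances must be a non-empty grid of non-negative values")
  distances <- sort(distances)
  n <- vapply(distances, function(d) length(stitch_peaks(peaks, d)), 0L)
  knee <- if (length(distances) < 3 || diff(range(n)) == 0 ||
              diff(range(distances)) == 0) {
    distances[1]
  } else {
    x <- (distances - min(distances)) / diff(range(distances))
    y <- (n - min(n)) / diff(range(n))
    # distance from (x,y) to the chord from (x1,y1) to (xn,yn)
    dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
    d <- abs(dy * x - dx * y + x[length(x)] * y[1] - y[length(y)] * x[1]) /
      sqrt(dx^2 + dy^2)
    distances[which.max(d)]
  }
  list(curve = data.frame(distance = distances, n_domains = n), knee = knee)
}

#' Score and rank stitched domains
#'
#' Per-domain signal is the aggregate track signal over the domain (sum of
#' overlapped bin values, partial bins weighted) divided by
#' \code{library_scale}. Domains are ranked descending by signal (rank 1 is
#' strongest); ties are broken leftmost-first in (chromosome, start) order.
#'
#' @param stitched disjoint \code{GRanges} of stitched domains.
#' @param track the sample's \code{binned_track}.
#' @param library_scale positive scale factor; default is the track's total
#'   signal divided by 1e6 (CPM-like). A spike-in-derived factor may be
#'   passed instead.
#' @param sample_id optional sample label stored as an attribute.
#' @return \code{GRanges} in coordinate order with \code{signal} and
#'   \code{rank} metadata columns.
#' @export
score_domains <- function(stitched, track, library_scale = NULL,
                          sample_id = NULL) {
  stitched <- GenomicRanges::sort(stitched, ignore.strand = TRUE)
  if (is.null(library_scale)) library_scale <- track_total(track) / 1e6
  if (length(library_scale) != 1 || library_scale <= 0)
    stop("library_scale must be a single positive number")
  sig <- region_signal(track, stitched) / library_scale
  ord <- order(-sig, as.character(GenomicRanges::seqnames(stitched)),
               start0(stitched))
  rk <- integer(length(sig)); rk[ord] <- seq_along(sig)
  S4Vectors::mcols(stitched)$signal <- sig
  S4Vectors::mcols(stitched)$rank <- rk
  if (!is.null(sample_id)) attr(stitched, "sample_id") <- sample_id
  stitched
}

#' ROSE-style cutoff on a ranked signal vector
#'
#' With scores sorted ascending and both axes min-max scaled to [0, 1], the
#' cutoff sits where a line of slope 1 is tangent to the curve: walking from
#' the right (strongest scores), the cutoff is the score at the last point
#' whose right-adjacent discrete slope still exceeds 1. Domains with signal
#' strictly above the cutoff are "super" domains. With all-equal scores the
#' scaling degenerates and no domain is called (n_super = 0).
#'
#' @param scores numeric vector of domain signals (any order; n >= 2).
#' @return list with \code{cutoff_value} and \code{n_super}.
#' @export
rose_cutoff <- function(scores) {
  if (length(scores) < 2) stop("rose_cutoff needs at least 2 scores")
  s <- sort(scores)
  if (diff(range(s)) == 0)
    return(list(cutoff_value = s[1], n_super = 0L))
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  slopes <- diff(y) / diff(x)           # slope of segment i -> i+1
  i <- n
  while (i > 1 && slopes[i - 1] > 1) i <- i - 1
  cutoff <- s[i]
  list(cutoff_value = cutoff, n_super = sum(scores > cutoff))
}

#' Keep the strongest domains of a sample
#'
#' @param domains output of \code{\link{score_domains}}.
#' @param top_n integer, or \code{"auto"} to use \code{\link{rose_cutoff}} on
#'   the signal vector (the super-domain rule). The fixed default of 500
#'   matches a per-patient "top 500" selection.
#' @return \code{GRanges} subset, coordinate-sorted.
#' @export
top_domains <- function(domains, top_n = 500) {
  if (identical(top_n, "auto")) {
    rc <- rose_cutoff(S4Vectors::mcols(domains)$signal)
    keep <- S4Vectors::mcols(domains)$signal > rc$cutoff_value
  } else {
    if (top_n < 1) stop("top_n must be >= 1 or 'auto'")
    keep <- S4Vectors::mcols(domains)$rank <= top_n
  }
  GenomicRanges::sort(domains[keep], ignore.strand = TRUE)
}

#' Stable domain identifier
#' @param gr a \code{GRanges}.
#' @return character "chrom:start-end" (0-based half-open).
#' @export
domain_id <- function(gr) {
  if (!length(gr)) return(character(0))
  paste0(as.character(GenomicRanges::seqnames(gr)), ":",
         format(start0(gr), scientific = FALSE, trim = TRUE), "-",
         format(end0(gr), scientific = FALSE, trim = TRUE))
}

#' Cross-sample consensus domains
#'
#' The union of all samples' domains is flattened to a disjoint cover; each
#' flattened interval is supported by the number of distinct samples
#' contributing at least 1 bp of overlap, and intervals with support below
#' \code{min_support} (default 2: kept when overlapping in at least two
#' samples) are dropped. When per-sample tracks are supplied, a domains x
#' samples signal matrix is filled by scoring every sample on the kept
#' intervals (each sample at its own CPM-like library scale).
#'
#' @param domain_sets named list of per-sample domain \code{GRanges}.
#' @param min_support minimum number of supporting samples (>= 1).
#' @param tracks optional named list of \code{binned_track}s (same names).
#' @param library_scales optional named numeric overrides.
#' @return list of class \code{consensus_domains}: \code{domains} (a
#'   \code{GRanges} with \code{domain_id} and \code{support}) and
#'   \code{signal_matrix} (or NULL when no tracks given).
#' @export
consensus_domains <- function(domain_sets, min_support = 2, tracks = NULL,
                              library_scales = NULL) {
  if (!length(domain_sets)) stop("need at least one domain set")
  if (min_support < 1) stop("min_support must be >= 1")
  if (is.null(names(domain_sets)))
    names(domain_sets) <- paste0("S", seq_along(domain_sets))
  union <- flatten(do.call(c, lapply(unname(domain_sets), function(g) {
    S4Vectors::mcols(g) <- NULL
    g
  })))
  support <- Reduce(`+`, lapply(domain_sets, function(g) {
    as.integer(GenomicRanges::countOverlaps(union, g, ignore.strand = TRUE) > 0)
  }))
  keep <- support >= min_support
  dom <- union[keep]
  S4Vectors::mcols(dom)$domain_id <- domain_id(dom)
  S4Vectors::mcols(dom)$support <- support[keep]
  mat <- NULL
  if (!is.null(tracks) && length(dom)) {
    mat <- sapply(names(domain_sets), function(sm) {
      ls <- if (!is.null(library_scales)) library_scales[[sm]] else NULL
      S4Vectors::mcols(score_domains(dom, tracks[[sm]], ls))$signal
    })
    mat <- matrix(mat, nrow = length(dom),
                  dimnames = list(S4Vectors::mcols(dom)$domain_id,
                                  names(domain_sets)))
  }
  structure(list(domains = dom, signal_matrix = mat),
            class = "consensus_domains")
}

#' @export
print.consensus_domains <- function(x, ...) {
  cat("consensus_domains:", length(x$domains), "domains")
  if (length(x$domains))
    cat(", support range ", min(x$domains$support), "-",
        max(x$domains$support), sep = "")
  if (!is.null(x$signal_matrix))
    cat("; signal matrix over", ncol(x$signal_matrix), "samples")
  cat("\n")
  invisible(x)
}

#' Minimal Poisson bin peak caller
#'
#' Provided for the synthetic pipeline only: bins whose signal is at least
#' \code{fold} times the genome-wide mean and whose upper Poisson tail
#' probability (at the genome-wide mean) is below \code{p_threshold} are
#' significant; runs of at least \code{min_bins} consecutive significant bins
#' become peaks. It makes no claim to reproduce any production peak caller.
#'
#' @param track a \code{binned_track} of count-scale signal.
#' @param fold minimum fold over the track mean (default 2).
#' @param p_threshold Poisson upper-tail threshold (default 1e-5).
#' @param min_bins minimum number of significant bins per peak (default 3;
#'   isolated or paired noise bins are not peaks).
#' @param max_hole_bins holes of at most this many consecutive
#'   non-significant bins inside a significant run are closed before the run
#'   test, so bin-level noise does not shatter one peak into fragments; the
#'   \code{min_bins} count is taken over the originally significant bins only.
#' @return \code{GRanges} of peaks.
#' @export
call_peaks <- function(track, fold = 2, p_threshold = 1e-5, min_bins = 3,
                       max_hole_bins = 2) {
  lambda <- track_total(track) /
    sum(vapply(names(track$values), function(ch)
      length(track$values[[ch]]), 0L))
  chroms <- character(); starts <- numeric(); ends <- numeric()
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    sig <- v >= fold * lambda &
      stats::ppois(ceiling(v) - 1, lambda, lower.tail = FALSE) < p_threshold
    r <- rle(sig)
    if (max_hole_bins > 0 && length(r$lengths) > 2) {
      hole <- !r$values & r$lengths <= max_hole_bins &
        seq_along(r$values) > 1 & seq_along(r$values) < length(r$values)
      r$values[hole] <- TRUE
      r <- rle(inverse.rle(r))
    }
    if (!any(r$values)) next
    cend <- cumsum(r$lengths)
    cstart <- cend - r$lengths + 1
    nsig <- vapply(seq_along(r$values), function(i)
      if (r$values[i]) sum(sig[cstart[i]:cend[i]]) else 0L, 0L)
    ok <- which(r$values & nsig >= min_bins)
    if (!length(ok)) next
    chroms <- c(chroms, rep(ch, length(ok)))
    starts <- c(starts, (cstart[ok] - 1) * track$bin_width)
    ends <- c(ends, pmin(cend[ok] * track$bin_width,
                         track$chrom_sizes[[ch]]))
  }
  interval_set(chroms, starts, ends)
}
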