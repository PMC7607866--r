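# TAD-constrained assignment of consensus domains to their most-correlated
# expressed gene, intra-TAD domain-domain correlation, and putative-enhancer
# flagging (the genic + extragenic correlated-pair logic).

# TAD index containing each domain midpoint (NA when none)
.tad_of_midpoint <- function(domains, tads) {
  mid <- floor((start0(domains) + end0(domains)) / 2)
  mp <- GenomicRanges::GRanges(GenomicRanges::seqnames(domains),
                               IRanges::IRanges(mid + 1, mid + 1))
  hits <- GenomicRanges::findOverlaps(mp, tads, ignore.strand = TRUE)
  out <- rep(NA_integer_, length(domains))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  out
}

.log2p1 <- function(x) log2(x + 1)

#' Assign consensus domains to genes by TAD-constrained correlation
#'
#' For each consensus domain, the TAD containing its midpoint is located;
#' candidate genes are those with a TSS inside that TAD and mean RPKM at
#' least \code{min_mean_rpkm} over the correlation samples. Pearson r is
#' computed between log2(domain signal + 1) and log2(RPKM + 1) across the
#' shared tumor samples, and the gene with the largest r-squared wins, ties
#' broken by nearest TSS. Domains in no TAD or with no candidate are returned
#' unassigned; a gene assigned to exactly one domain marks that domain
#' gene-specific.
#'
#' @param consensus a \code{\link{consensus_domains}} object with a signal
#'   matrix.
#' @param expr genes x samples RPKM matrix (rownames are gene ids).
#' @param genes gene-model \code{GRanges} (see \code{\link{gene_models}}).
#' @param tads flattened TAD \code{GRanges}.
#' @param samples sample ids to correlate over (the tumor diagnosis samples);
#'   default: all columns shared by \code{expr} and the signal matrix. At
#'   least 3 shared samples are required.
#' @param min_mean_rpkm expression floor for candidate genes (default 1).
#' @return data.frame with one row per consensus domain: \code{domain_id},
#'   coordinates, \code{gene_id} (NA if unassigned), \code{r}, \code{r2},
#'   \code{n_samples}, \code{tad_id}, \code{gene_specific}.
#' @export
assign_domain_gene <- function(consensus, expr, genes, tads,
                               samples = NULL, min_mean_rpkm = 1) {
  mat <- consensus$signal_matrix
  if (is.null(mat)) stop("consensus has no signal matrix")
  if (is.null(samples))
    samples <- intersect(colnames(mat), colnames(expr))
  samples <- intersect(intersect(samples, colnames(mat)), colnames(expr))
  if (length(samples) < 3)
    stop("need at least 3 shared samples for correlation, got ",
         length(samples))
  dom <- consensus$domains
  if (!length(genes)) {
    return(data.frame(domain_id = dom$domain_id,
                      chrom = as.character(GenomicRanges::seqnames(dom)),
                      start = start0(dom), end = end0(dom),
                      gene_id = NA_character_, r = NA_real_, r2 = NA_real_,
                      n_samples = length(samples), tad_id = NA_integer_,
                      gene_specific = FALSE))
  }
  tad_idx <- .tad_of_midpoint(dom, tads)
  tss <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  tss_tad <- .tad_of_midpoint(tss, tads)
  expressed <- rowMeans(expr[, samples, drop = FALSE]) >= min_mean_rpkm
  x_all <- .log2p1(mat[, samples, drop = FALSE])
  e_all <- .log2p1(as.matrix(expr[, samples, drop = FALSE]))

  n <- length(dom)
  gene_id <- rep(NA_character_, n); rr <- rep(NA_real_, n)
  mid <- floor((start0(dom) + end0(dom)) / 2)
  for (i in seq_len(n)) {
    if (is.na(tad_idx[i])) next
    cand <- which(!is.na(tss_tad) & tss_tad == tad_idx[i] &
                    expressed[genes$gene_id])
    if (!length(cand)) next
    x <- x_all[i, ]
    if (stats::sd(x) == 0) {
      r <- rep(0, length(cand))
    } else {
      r <- vapply(cand, function(g) {
        y <- e_all[genes$gene_id[g], ]
        if (stats::sd(y) == 0) 0 else stats::cor(x, y)
      }, 0)
    }
    r2 <- r^2
    best <- which(r2 == max(r2))
    if (length(best) > 1)
      best <- best[which.min(abs(genes$tss[cand[best]] - mid[i]))]
    gene_id[i] <- genes$gene_id[cand[best]]
    rr[i] <- r[best]
  }
  assigned_tab <- table(gene_id[!is.na(gene_id)])
  data.frame(domain_id = dom$domain_id,
             chrom = as.character(GenomicRanges::seqnames(dom)),
             start = start0(dom), end = end0(dom),
             gene_id = gene_id, r = rr, r2 = rr^2,
             n_samples = length(samples), tad_id = tad_idx,
             gene_specific = !is.na(gene_id) &
               assigned_tab[gene_id] == 1 & !is.na(rr),
             row.names = NULL)
}

#' Correlated intra-TAD domain pairs
#'
#' All pairs of consensus domains whose midpoints fall in the same TAD, with
#' the squared Pearson correlation of their log2 signals across the
#' correlation samples; filtered at \code{pair_r2 >= min_r2} and sorted
#' descending. Self-pairs are excluded.
#'
#' @inheritParams assign_domain_gene
#' @param min_r2 retention threshold (default 0.5).
#' @return data.frame: \code{domain_a}, \code{domain_b}, \code{tad_id},
#'   \code{pair_r2}.
#' @export
domain_pair_correlation <- function(consensus, tads, samples = NULL,
                                    min_r2 = 0.5) {
  mat <- consensus$signal_matrix
  if (is.null(mat)) stop("consensus has no signal matrix")
  if (is.null(samples)) samples <- colnames(mat)
  samples <- intersect(samples, colnames(mat))
  dom <- consensus$domains
  empty <- data.frame(domain_a = character(), domain_b = character(),
                      tad_id = integer(), pair_r2 = numeric())
  if (length(dom) < 2) return(empty)
  tad_idx <- .tad_of_midpoint(dom, tads)
  x <- .log2p1(mat[, samples, drop = FALSE])
  out <- list()
  for (td in unique(tad_idx[!is.na(tad_idx)])) {
    idx <- which(!is.na(tad_idx) & tad_idx == td)
    if (length(idx) < 2) next
    cm <- suppressWarnings(stats::cor(t(x[idx, , drop = FALSE])))
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      r2 <- cm[a, b]^2
      if (!is.na(r2) && r2 >= min_r2)
        out[[length(out) + 1]] <- data.frame(
          domain_a = dom$domain_id[idx[a]], domain_b = dom$domain_id[idx[b]],
          tad_id = td, pair_r2 = r2, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res[order(-res$pair_r2), , drop = FALSE]
}

#' Flag putative enhancer candidates from correlated domain pairs
#'
#' For each retained intra-TAD pair in which exactly one member overlaps the
#' body of its assigned gene while the other overlaps no part of that gene
#' body, emit a candidate with the distance between the facing edges of the
#' two domains. This is the logic that nominates an extragenic domain,
#' strongly correlated with a genic one, as the gene's putative enhancer.
#'
#' @param assignments output of \code{\link{assign_domain_gene}}.
#' @param pairs output of \code{\link{domain_pair_correlation}} on the same
#'   consensus.
#' @param genes gene-model \code{GRanges}.
#' @return data.frame: \code{gene_id}, \code{genic_domain_id},
#'   \code{extragenic_domain_id}, \code{pair_r2}, \code{distance_bp}.
#' @export
flag_enhancer_candidates <- function(assignments, pairs, genes) {
  empty <- data.frame(gene_id = character(), genic_domain_id = character(),
                      extragenic_domain_id = character(),
                      pair_r2 = numeric(), distance_bp = numeric())
  if (!nrow(pairs)) return(empty)
  rows <- assignments[match(c(pairs$domain_a, pairs$domain_b),
                            assignments$domain_id), ]
  a <- rows[seq_len(nrow(pairs)), ]; b <- rows[-seq_len(nrow(pairs)), ]
  gene_of <- function(id) {
    i <- match(id, genes$gene_id)
    list(chrom = as.character(GenomicRanges::seqnames(genes))[i],
         start = start0(genes)[i], end = end0(genes)[i])
  }
  overlaps_gene <- function(row) {
    if (is.na(row$gene_id)) return(NA)
    g <- gene_of(row$gene_id)
    row$chrom == g$chrom && row$start < g$end && row$end > g$start
  }
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    ra <- a[i, ]; rb <- b[i, ]
    ga <- overlaps_gene(ra); gb <- overlaps_gene(rb)
    genic <- NULL; other <- NULL
    if (isTRUE(ga) && !isTRUE(gb)) { genic <- ra; other <- rb }
    if (isTRUE(gb) && !isTRUE(ga)) { genic <- rb; other <- ra }
    if (is.null(genic)) next
    g <- gene_of(genic$gene_id)
    # the extragenic member must not touch the assigned gene's body at all
    if (other$chrom == g$chrom && other$start < g$end && other$end > g$start)
      next
    dist <- max(0, max(genic$start, other$start) -
                  min(genic$end, other$end))
    out[[length(out) + 1]] <- data.frame(
      gene_id = genic$gene_id, genic_domain_id = genic$domain_id,
      extragenic_domain_id = other$domain_id, pair_r2 = pairs$pair_r2[i],
      distance_bp = dist, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
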