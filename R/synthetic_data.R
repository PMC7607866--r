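# Fully synthetic plasma-cell cohort with planted effects: enriched domains
# built from peak clusters, domain-coupled gene expression, group-specific
# domains, ISS-graded global 5hmC, survival tied to the 5hmC level, and
# diagnosis/relapse replicate tracks. Every downstream stage of the package
# can be exercised against the planted truth.

#' Synthetic cohort configuration
#'
#' Defaults mirror a myeloma-style study: 5 normal plasma-cell donors, 40
#' newly diagnosed tumors split into molecular groups (MMSET 9, CCND1 11,
#' hyperdiploid 16, other 4), ISS stages I/II/III/NA = 9/17/13/1 with one
#' 5hmC measurement failure (39 measured values), a 69\% global 5hmC and 34\%
#' 5mC reduction in tumors, ISS II/III 5hmC reduced 25\%/31\% versus stage I,
#' a survival hazard ratio of 2.6 for the below-median-5hmC half, a strongest
#' planted domain-gene link at R-squared 0.78 and enhancer pairs at 0.88, and
#' four diagnosis/relapse pairs with two technical replicates per condition.
#'
#' @param seed integer seed; every stochastic output category (layout, tracks,
#'   expression, clinical, survival, relapse, CpG) draws from its own stream
#'   derived from it.
#' @param n_normal,n_tumor,n_relapse_pairs cohort sizes.
#' @param genome named vector of chromosome lengths (default 3 x 10 Mb).
#' @param bin_width track bin width in bp.
#' @param tad_width TAD tile width in bp.
#' @param group_sizes named counts for MMSET/CCND1/HD/other; must sum to
#'   \code{n_tumor}. \code{NULL} scales the 9/11/16/4 proportions.
#' @param iss_sizes named counts for stages I/II/III/NA; \code{NULL} scales
#'   9/17/13/1.
#' @param n_shared_domains domains active in every sample (these carry the
#'   planted domain-gene links).
#' @param n_enhancer_pairs genic/extragenic domain pairs sharing activity.
#' @param n_group_specific planted up-domains per group (MMSET, CCND1, HD and
#'   normal).
#' @param n_down_specific domains silenced specifically in the CCND1 group.
#' @param enrichment_fold multiplicative peak enrichment over background.
#' @param activity_sd sd of per-sample log domain activity.
#' @param domain_gene_r2 target squared correlation of the strongest planted
#'   link; remaining links draw targets from \code{link_r2_range}.
#' @param link_r2_range range of target r-squared for the other links.
#' @param pair_r2 target squared correlation within enhancer pairs.
#' @param noise_sd sd of per-sample log2 expression noise for unlinked genes.
#' @param hmc_npc_mean,mc_npc_mean normal-donor global 5hmC / 5mC (\% per C).
#' @param hmc_reduction,mc_reduction tumor-vs-normal mean reduction fractions.
#' @param iss_ratios stage means relative to stage I for 5hmC.
#' @param noise_cv lognormal CV of the global measurements.
#' @param survival_hr hazard multiplier for the below-median-5hmC half.
#' @param baseline_hazard exponential hazard (per month) of the high half.
#' @param censor_horizon administrative censoring time in months (tuned for
#'   roughly 40\% events, ~16 of 39).
#' @param relapse_plan list, one element per pair, each with
#'   \code{frac_down}, \code{down_fold}, \code{frac_up}, \code{up_fold}.
#' @param replicate_depth Poisson depth multiplier for technical replicates.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(seed = 1,
                          n_normal = 5, n_tumor = 40, n_relapse_pairs = 4,
                          genome = c(chr1 = 1e7, chr2 = 1e7, chr3 = 1e7),
                          bin_width = 100, tad_width = 1e6,
                          group_sizes = NULL, iss_sizes = NULL,
                          n_shared_domains = 24, n_enhancer_pairs = 3,
                          n_group_specific = 2, n_down_specific = 1,
                          enrichment_fold = 12, activity_sd = 0.6,
                          domain_gene_r2 = 0.78,
                          link_r2_range = c(0.25, 0.6), pair_r2 = 0.88,
                          noise_sd = 0.5,
                          hmc_npc_mean = 0.10, mc_npc_mean = 4.0,
                          hmc_reduction = 0.69, mc_reduction = 0.34,
                          iss_ratios = c(I = 1, II = 0.75, III = 0.69),
                          noise_cv = 0.15,
                          survival_hr = 2.6, baseline_hazard = 0.0055,
                          censor_horizon = 60,
                          relapse_plan = NULL, replicate_depth = 1) {
  if (is.null(group_sizes))
    group_sizes <- .scale_counts(c(MMSET = 9, CCND1 = 11, HD = 16, other = 4),
                                 n_tumor)
  if (is.null(iss_sizes))
    iss_sizes <- .scale_counts(c(I = 9, II = 17, III = 13, "NA" = 1), n_tumor)
  if (is.null(relapse_plan))
    relapse_plan <- list(
      list(frac_down = 0.48, down_fold = 0.5, frac_up = 0.035, up_fold = 2.5),
      list(frac_down = 0.032, down_fold = 0.5, frac_up = 0.01, up_fold = 2),
      list(frac_down = 0.05, down_fold = 0.7, frac_up = 0.05, up_fold = 1.3),
      list(frac_down = 0.22, down_fold = 0.6, frac_up = 0.30, up_fold = 1.8))
  cfg <- list(seed = as.integer(seed), n_normal = n_normal, n_tumor = n_tumor,
              n_relapse_pairs = n_relapse_pairs, genome = genome,
              bin_width = bin_width, tad_width = tad_width,
              group_sizes = group_sizes, iss_sizes = iss_sizes,
              n_shared_domains = n_shared_domains,
              n_enhancer_pairs = n_enhancer_pairs,
              n_group_specific = n_group_specific,
              n_down_specific = n_down_specific,
              enrichment_fold = enrichment_fold, activity_sd = activity_sd,
              domain_gene_r2 = domain_gene_r2,
              link_r2_range = link_r2_range, pair_r2 = pair_r2,
              noise_sd = noise_sd,
              hmc_npc_mean = hmc_npc_mean, mc_npc_mean = mc_npc_mean,
              hmc_reduction = hmc_reduction, mc_reduction = mc_reduction,
              iss_ratios = iss_ratios, noise_cv = noise_cv,
              survival_hr = survival_hr, baseline_hazard = baseline_hazard,
              censor_horizon = censor_horizon, relapse_plan = relapse_plan,
              replicate_depth = replicate_depth)
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

.scale_counts <- function(base, total) {
  k <- floor(base / sum(base) * total)
  rem <- total - sum(k)
  if (rem > 0) {
    ord <- order(base / sum(base) * total - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  k
}

#' Validate a cohort configuration
#'
#' Checks counts, positivity, and that the planted layout fits the genome.
#' Called by \code{\link{simulate_cohort}} and \code{\link{run_pipeline}}
#' before any stage runs.
#'
#' @param config a \code{cohort_config}.
#' @return the config, invisibly; errors on an infeasible config.
#' @export
validate_config <- function(config) {
  with(config, {
    if (n_tumor < 1) stop("n_tumor must be >= 1")
    if (n_normal < 0 || n_relapse_pairs < 0) stop("negative cohort counts")
    if (sum(group_sizes) != n_tumor)
      stop("group_sizes must sum to n_tumor (",
           sum(group_sizes), " != ", n_tumor, ")")
    if (any(group_sizes < 0) || any(iss_sizes < 0)) stop("negative counts")
    if (sum(iss_sizes) != n_tumor) stop("iss_sizes must sum to n_tumor")
    if (survival_hr <= 0) stop("survival_hr must be > 0")
    if (domain_gene_r2 < 0 || domain_gene_r2 > 1 || pair_r2 < 0 || pair_r2 > 1)
      stop("target r-squared values must lie in [0, 1]")
    if (n_relapse_pairs > n_tumor) stop("more relapse pairs than tumors")
    if (n_relapse_pairs > length(relapse_plan))
      stop("relapse_plan shorter than n_relapse_pairs")
    n_tads <- sum(floor(genome / tad_width))
    n_slots <- 2 * (n_tads - n_enhancer_pairs)
    n_single <- n_shared_domains + 4 * n_group_specific + n_down_specific
    if (n_enhancer_pairs > n_tads || n_single > n_slots)
      stop("infeasible config: ", n_single, " planted domains need more TAD ",
           "slots than the genome provides (", max(0, n_slots), ")")
  })
  invisible(config)
}

# independent RNG stream seeds, one per output category
.stream_seeds <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1, 8),
                  c("layout", "tracks", "expression", "clinical",
                    "survival", "relapse", "cpg", "misc"))
}

# snap to bin grid
.snap <- function(x, w) round(x / w) * w

# ---- layout ----------------------------------------------------------------

# Deterministic-given-seed placement of TADs, planted domains (as peak
# clusters with gaps drawn below the stitch distance), genes and ChromHMM
# states.
.simulate_layout <- function(config) {
  set.seed(.stream_seeds(config$seed)[["layout"]])
  w <- config$bin_width
  tw <- config$tad_width
  chroms <- names(config$genome)
  tad_chrom <- rep(chroms, floor(config$genome / tw))
  tad_start <- unlist(lapply(floor(config$genome / tw),
                             function(k) (seq_len(k) - 1) * tw),
                      use.names = FALSE)
  tads <- interval_set(tad_chrom, tad_start, tad_start + tw,
                       name = sprintf("TAD%02d", seq_along(tad_chrom)))
  n_tads <- length(tads)

  # one planted domain: a cluster of peaks with gaps < 12.5 kb
  make_domain <- function(chrom, start, n_peaks = NULL, max_gap = 12400) {
    if (is.null(n_peaks)) n_peaks <- sample(3:5, 1)
    pw <- .snap(stats::runif(n_peaks, 1500, 2500), w)
    gaps <- .snap(stats::runif(max(0, n_peaks - 1), 4000, max_gap), w)
    ps <- start + cumsum(c(0, pw[-n_peaks] + gaps))
    list(peaks = interval_set(rep(chrom, n_peaks), ps, ps + pw),
         extent = c(start, ps[n_peaks] + pw[n_peaks]))
  }

  kinds <- c(rep("shared", config$n_shared_domains),
             rep(c("MMSET", "CCND1", "HD", "normal"),
                 each = config$n_group_specific),
             rep("CCND1_down", config$n_down_specific))
  pair_tads <- seq_len(config$n_enhancer_pairs)
  free_tads <- setdiff(seq_len(n_tads), pair_tads)
  slots <- data.frame(tad = rep(free_tads, each = 2), slot = c(0, 1))
  if (length(kinds) > nrow(slots)) stop("infeasible layout")
  slots <- slots[seq_along(kinds), , drop = FALSE]

  dom_chrom <- character(); dom_start <- numeric(); dom_end <- numeric()
  dom_kind <- character(); dom_tad <- integer()
  peaks_by_domain <- list()
  genes <- list(); links <- list(); pairs <- list()
  gidx <- 0

  add_gene <- function(chrom, start, end, strand = NULL) {
    gidx <<- gidx + 1
    id <- sprintf("G%03d", gidx)
    if (is.null(strand)) strand <- sample(c("+", "-"), 1)
    genes[[gidx]] <<- data.frame(chrom = chrom, start = start, end = end,
                                 gene_id = id, strand = strand,
                                 stringsAsFactors = FALSE)
    id
  }

  # single-slot domains (shared / group / down) with a linked gene for shared
  for (i in seq_along(kinds)) {
    td <- slots$tad[i]
    chrom <- as.character(GenomicRanges::seqnames(tads))[td]
    base <- start0(tads)[td] + ifelse(slots$slot[i] == 0, 0.05e6, 0.45e6)
    start <- .snap(base + stats::runif(1, 0, 60000), w)
    d <- make_domain(chrom, start)
    peaks_by_domain[[length(peaks_by_domain) + 1]] <- d$peaks
    dom_chrom <- c(dom_chrom, chrom); dom_start <- c(dom_start, d$extent[1])
    dom_end <- c(dom_end, d$extent[2]); dom_kind <- c(dom_kind, kinds[i])
    dom_tad <- c(dom_tad, td)
    if (kinds[i] == "shared") {
      gs <- .snap(d$extent[2] + stats::runif(1, 20000, 50000), w)
      ge <- gs + .snap(stats::runif(1, 5000, 30000), w)
      id <- add_gene(chrom, gs, ge)
      r2 <- if (length(links) == 0) config$domain_gene_r2 else
        stats::runif(1, config$link_r2_range[1], config$link_r2_range[2])
      links[[length(links) + 1]] <-
        data.frame(domain = length(dom_chrom), gene_id = id, target_r2 = r2,
                   stringsAsFactors = FALSE)
    }
  }

  # enhancer pairs: a genic domain inside the gene body plus an extragenic
  # domain far upstream in the same TAD, sharing activity
  for (p in pair_tads) {
    chrom <- as.character(GenomicRanges::seqnames(tads))[p]
    t0 <- start0(tads)[p]
    gs <- .snap(t0 + 0.30e6, w); ge <- gs + .snap(stats::runif(1, 35000, 60000), w)
    id <- add_gene(chrom, gs, ge, strand = "+")
    dg <- make_domain(chrom, .snap(gs + 2000, w), n_peaks = 3, max_gap = 8000)
    de <- make_domain(chrom, .snap(t0 + 0.10e6, w))
    for (d in list(dg, de)) {
      peaks_by_domain[[length(peaks_by_domain) + 1]] <- d$peaks
      dom_chrom <- c(dom_chrom, chrom); dom_start <- c(dom_start, d$extent[1])
      dom_end <- c(dom_end, d$extent[2]); dom_tad <- c(dom_tad, p)
    }
    dom_kind <- c(dom_kind, "pair_genic", "pair_extragenic")
    n <- length(dom_chrom)
    pairs[[length(pairs) + 1]] <-
      data.frame(pair = length(pairs) + 1, genic = n - 1, extragenic = n,
                 gene_id = id, stringsAsFactors = FALSE)
    links[[length(links) + 1]] <-
      data.frame(domain = n - 1, gene_id = id,
                 target_r2 = stats::runif(1, 0.45, 0.65),
                 stringsAsFactors = FALSE)
  }

  # filler genes in a reserved zone of every TAD
  for (td in seq_len(n_tads)) {
    chrom <- as.character(GenomicRanges::seqnames(tads))[td]
    t0 <- start0(tads)[td]
    for (off in c(0.80e6, 0.86e6, 0.92e6)) {
      gs <- .snap(t0 + off + stats::runif(1, 0, 10000), w)
      add_gene(chrom, gs, gs + .snap(stats::runif(1, 5000, 30000), w))
    }
  }

  genes <- do.call(rbind, genes)
  genes_gr <- gene_models(genes$chrom, genes$start, genes$end,
                          genes$gene_id, genes$strand)
  domains <- interval_set(dom_chrom, dom_start, dom_end,
                          kind = dom_kind, tad = dom_tad)
  # interval_set sorts; keep original (already sorted by construction order
  # per chrom) indices aligned with peaks/links via an explicit id
  ord <- order(factor(dom_chrom, levels = chroms), dom_start)
  domains <- interval_set(dom_chrom[ord], dom_start[ord], dom_end[ord],
                          kind = dom_kind[ord], tad = dom_tad[ord],
                          planted_id = ord)
  remap <- match(seq_along(ord), ord)      # old index -> sorted position

  links <- do.call(rbind, links)
  links$domain <- remap[links$domain]
  pairs <- if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    pr$genic <- remap[pr$genic]; pr$extragenic <- remap[pr$extragenic]
    pr
  } else data.frame()
  peaks_by_domain <- peaks_by_domain[ord]

  # ChromHMM-style segmentation: enhancer states on planted domains,
  # promoters around TSS, transcribed gene bodies, mixed background tiles
  strip <- function(g) { S4Vectors::mcols(g) <- NULL; GenomicRanges::strand(g) <- "*"; g }
  proms <- interval_set(genes$chrom, pmax(0, genes_gr$tss - 1000),
                        genes_gr$tss + 1000)
  used <- flatten(c(strip(domains), strip(genes_gr), strip(proms)))
  bg <- GenomicRanges::setdiff(
    interval_set(chroms, rep(0, length(chroms)), config$genome), used,
    ignore.strand = TRUE)
  # split background into ~50 kb tiles with rotating quiet states
  tile_w <- 5e4
  bgs <- start0(bg); bge <- end0(bg); bgc <- as.character(GenomicRanges::seqnames(bg))
  tc <- character(); ts <- numeric(); te <- numeric()
  for (i in seq_along(bgs)) {
    cuts <- unique(c(seq(bgs[i], bge[i], by = tile_w), bge[i]))
    if (length(cuts) < 2) next
    tc <- c(tc, rep(bgc[i], length(cuts) - 1))
    ts <- c(ts, cuts[-length(cuts)]); te <- c(te, cuts[-1])
  }
  quiet <- c("heterochromatin", "insulator", "polycomb_repressed",
             "repetitive", "heterochromatin")
  seg <- c(
    interval_set(tc, ts, te,
                 state = quiet[(seq_along(tc) - 1) %% length(quiet) + 1]),
    {
      d2 <- strip(domains)
      S4Vectors::mcols(d2)$state <- "strong_enhancer"; d2
    },
    {
      gb <- GenomicRanges::setdiff(strip(genes_gr),
                                   c(strip(domains), strip(proms)),
                                   ignore.strand = TRUE)
      S4Vectors::mcols(gb)$state <- "transcribed"; gb
    },
    {
      p2 <- flatten(strip(proms)); S4Vectors::mcols(p2)$state <- "promoter"; p2
    })
  seg <- GenomicRanges::sort(seg, ignore.strand = TRUE)

  list(tads = tads, domains = domains, peaks_by_domain = peaks_by_domain,
       genes = genes_gr, links = links, pairs = pairs, chromhmm = seg)
}

# ---- full cohort ------------------------------------------------------------

#' Simulate a synthetic cohort
#'
#' Generates per-sample binned 5hmC tracks (Gamma background with
#' multiplicative enrichment at planted peak clusters), per-sample peak calls
#' (via \code{\link{call_peaks}}), a genes x samples RPKM matrix with planted
#' domain-coupled genes, TADs, a ChromHMM-style segmentation, a clinical
#' sample table with ISS-graded global 5hmC and exponential survival whose
#' hazard is multiplied by \code{survival_hr} for the below-median-5hmC half,
#' and diagnosis/relapse Poisson technical replicates with planted
#' fold-changes. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return a list of class \code{synthetic_cohort} with elements
#'   \code{config}, \code{chrom_sizes}, \code{bin_width}, \code{tads},
#'   \code{genes}, \code{chromhmm}, \code{tracks}, \code{peaks}, \code{expr},
#'   \code{sample_table}, \code{relapse} and \code{truth}.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  seeds <- .stream_seeds(config$seed)
  lay <- .simulate_layout(config)
  w <- config$bin_width
  chroms <- names(config$genome)
  n_bins <- ceiling(config$genome / w)

  normals <- sprintf("N%02d", seq_len(config$n_normal))
  tumors <- sprintf("MM%02d", seq_len(config$n_tumor))
  groups <- c(stats::setNames(rep(names(config$group_sizes),
                                  config$group_sizes), NULL))
  names(groups) <- tumors
  all_samples <- c(normals, tumors)
  sample_group <- c(stats::setNames(rep("normal", length(normals)), normals),
                    groups)

  # gene-body multiplier coupling 5hmC to (base) expression class
  set.seed(seeds[["expression"]])
  base_expr <- stats::runif(length(lay$genes), -3, 8.5)   # log2 RPKM scale
  names(base_expr) <- lay$genes$gene_id
  linked <- lay$links$gene_id
  base_expr[linked] <- stats::runif(length(linked), 3.5, 8)
  expr_noise <- matrix(stats::rnorm(length(lay$genes) * length(all_samples),
                                    0, config$noise_sd),
                       nrow = length(lay$genes),
                       dimnames = list(lay$genes$gene_id, all_samples))
  link_noise <- matrix(stats::rnorm(nrow(lay$links) * length(tumors)),
                       nrow = nrow(lay$links),
                       dimnames = list(NULL, tumors))

  gene_factor <- pmin(1.9, 1 + 0.1 * pmax(0, base_expr))
  base_factor <- lapply(chroms, function(ch) rep(1, n_bins[[ch]]))
  names(base_factor) <- chroms
  gchrom <- as.character(GenomicRanges::seqnames(lay$genes))
  for (i in seq_along(lay$genes)) {
    b <- (floor(start0(lay$genes)[i] / w) + 1):
      min(ceiling(end0(lay$genes)[i] / w), n_bins[[gchrom[i]]])
    base_factor[[gchrom[i]]][b] <-
      pmax(base_factor[[gchrom[i]]][b], gene_factor[i])
  }

  # per-domain peak bin indices
  dchrom <- as.character(GenomicRanges::seqnames(lay$domains))
  peak_bins <- lapply(lay$peaks_by_domain, function(p) {
    ch <- as.character(GenomicRanges::seqnames(p))[1]
    idx <- unlist(mapply(function(s, e) (floor(s / w) + 1):ceiling(e / w),
                         start0(p), end0(p), SIMPLIFY = FALSE))
    list(chrom = ch, bins = idx)
  })

  kinds <- lay$domains$kind
  active_in <- function(kind, sample) {
    g <- sample_group[[sample]]
    switch(kind,
           shared = , pair_genic = , pair_extragenic = TRUE,
           MMSET = g == "MMSET", CCND1 = g == "CCND1", HD = g == "HD",
           normal = g == "normal", CCND1_down = g != "CCND1")
  }

  # domain activity (log-normal), enhancer pairs sharing a latent factor
  set.seed(seeds[["tracks"]])
  nd <- length(lay$domains)
  z <- matrix(stats::rnorm(nd * length(all_samples)), nrow = nd,
              dimnames = list(NULL, all_samples))
  if (nrow(lay$pairs)) {
    rho <- sqrt(config$pair_r2)
    for (p in seq_len(nrow(lay$pairs))) {
      gi <- lay$pairs$genic[p]; ei <- lay$pairs$extragenic[p]
      z[ei, ] <- rho * z[gi, ] + sqrt(1 - rho^2) * z[ei, ]
    }
  }
  activity <- exp(config$activity_sd * z)
  track_seeds <- sample.int(.Machine$integer.max - 1, length(all_samples))
  names(track_seeds) <- all_samples

  make_track <- function(sample, expected = FALSE) {
    vals <- list()
    if (!expected) set.seed(track_seeds[[sample]])
    for (ch in chroms) {
      v <- if (expected) 2 * base_factor[[ch]] else
        stats::rgamma(n_bins[[ch]], shape = 2, scale = 1) * base_factor[[ch]]
      vals[[ch]] <- v
    }
    for (d in seq_len(nd)) {
      if (!active_in(kinds[d], sample)) next
      pb <- peak_bins[[d]]
      vals[[pb$chrom]][pb$bins] <- vals[[pb$chrom]][pb$bins] *
        config$enrichment_fold * activity[d, sample]
    }
    binned_track(config$genome, w, vals)
  }
  tracks <- lapply(stats::setNames(all_samples, all_samples), make_track)
  peaks <- lapply(tracks, call_peaks)

  # expression: unlinked genes from their base class; linked genes coupled to
  # the measured domain signal on the log2 scale at the target r-squared
  expr <- matrix(pmax(0, 2^(base_expr + expr_noise) - 1),
                 nrow = length(lay$genes),
                 dimnames = list(lay$genes$gene_id, all_samples))
  link_dom <- lay$domains[lay$links$domain]
  logsig <- sapply(tumors, function(sm) {
    ls <- track_total(tracks[[sm]]) / 1e6
    log2(region_signal(tracks[[sm]], link_dom) / ls + 1)
  })
  logsig <- matrix(logsig, nrow = nrow(lay$links))
  for (i in seq_len(nrow(lay$links))) {
    x <- logsig[i, ]
    r2 <- lay$links$target_r2[i]
    sde <- if (r2 >= 1) 0 else stats::sd(x) * sqrt((1 - r2) / r2)
    y <- base_expr[[lay$links$gene_id[i]]] + (x - mean(x)) +
      sde * link_noise[i, ]
    expr[lay$links$gene_id[i], tumors] <- pmax(0, 2^y - 1)
  }

  sample_table <- .simulate_clinical(config, normals, tumors, groups, seeds)

  relapse <- .simulate_relapse(config, lay, tumors, groups, activity,
                               peak_bins, kinds, base_factor, n_bins, seeds,
                               sample_group)
  if (length(relapse)) {
    st_r <- do.call(rbind, lapply(relapse, function(rp) rp$row))
    sample_table$pair_id[match(names(relapse), sample_table$sample_id)] <-
      names(relapse)
    sample_table <- rbind(sample_table, st_r)
  }
  rownames(sample_table) <- NULL

  truth <- list(domains = lay$domains, peaks_by_domain = lay$peaks_by_domain,
                links = lay$links, pairs = lay$pairs, activity = activity,
                base_expr = base_expr,
                relapse = lapply(relapse, function(rp) rp$truth))
  structure(list(config = config, chrom_sizes = config$genome, bin_width = w,
                 tads = lay$tads, genes = lay$genes, chromhmm = lay$chromhmm,
                 tracks = tracks, peaks = peaks, expr = expr,
                 sample_table = sample_table, relapse =
                   lapply(relapse, function(rp) rp[c("replicates", "truth")]),
                 truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", x$config$n_normal, "normal +", x$config$n_tumor,
      "tumor samples,", length(x$truth$domains), "planted domains,",
      length(x$genes), "genes,", length(x$relapse), "relapse pairs\n")
  invisible(x)
}

# clinical + survival streams; also usable standalone via
# simulate_sample_table()
.simulate_clinical <- function(config, normals, tumors, groups, seeds) {
  set.seed(seeds[["clinical"]])
  n_t <- length(tumors)
  iss <- sample(rep(names(config$iss_sizes), config$iss_sizes))
  fail <- if (any(iss == "III")) which(iss == "III")[1] else 1L
  measured <- setdiff(seq_len(n_t), fail)

  # stage means: ratios r_I:r_II:r_III with the measured-tumor mean hitting
  # the target overall reduction; NA-stage samples sit at the staged mean
  r <- config$iss_ratios
  m <- vapply(c("I", "II", "III"), function(s)
    sum(iss[measured] == s), 0L)
  n_na <- sum(iss[measured] == "NA")
  target <- config$hmc_npc_mean * (1 - config$hmc_reduction)
  denom <- sum(m * r) * (1 + n_na / max(1, sum(m)))
  x_I <- target * length(measured) / denom
  stage_mean <- c(I = x_I, II = x_I * r[["II"]], III = x_I * r[["III"]])
  na_mean <- sum(m * stage_mean[c("I", "II", "III")]) / max(1, sum(m))
  mu <- ifelse(iss == "NA", na_mean, stage_mean[iss])

  sdlog <- sqrt(log(1 + config$noise_cv^2))
  ln <- function(n, mean) mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  hmc_t <- mu * exp(stats::rnorm(n_t, -sdlog^2 / 2, sdlog))
  hmc_t[fail] <- NA
  hmc_n <- ln(length(normals), config$hmc_npc_mean)
  mc_n <- ln(length(normals), config$mc_npc_mean)
  mc_t <- ln(n_t, config$mc_npc_mean * (1 - config$mc_reduction))
  sex <- sample(c("F", "M"), length(normals) + n_t, replace = TRUE)
  age <- round(stats::rnorm(length(normals) + n_t, 65, 8))

  set.seed(seeds[["survival"]])
  med <- stats::median(hmc_t, na.rm = TRUE)
  low <- !is.na(hmc_t) & hmc_t <= med
  hz <- config$baseline_hazard * ifelse(low, config$survival_hr, 1)
  t_ev <- stats::rexp(n_t, hz)
  os <- pmin(t_ev, config$censor_horizon)
  ev <- as.integer(t_ev <= config$censor_horizon)

  data.frame(
    sample_id = c(normals, tumors),
    condition = c(rep("NPC", length(normals)), rep("NDMM", n_t)),
    group = c(rep("normal", length(normals)), unname(groups)),
    iss = c(rep(NA_character_, length(normals)), iss),
    sex = sex, age = age,
    mc_percent = c(mc_n, mc_t), hmc_percent = c(hmc_n, hmc_t),
    os_months = c(rep(NA_real_, length(normals)), os),
    os_event = c(rep(NA_integer_, length(normals)), ev),
    pair_id = NA_character_, replicate = 1L,
    stringsAsFactors = FALSE)
}

#' Simulate only the clinical sample table
#'
#' The clinical and survival output categories of \code{\link{simulate_cohort}}
#' without tracks or expression; useful for survival-calibration studies at
#' large n.
#'
#' @param config a \code{\link{cohort_config}}.
#' @return the sample table data.frame (no relapse rows).
#' @export
simulate_sample_table <- function(config = cohort_config()) {
  validate_config(config)
  normals <- sprintf("N%02d", seq_len(config$n_normal))
  tumors <- sprintf("MM%02d", seq_len(config$n_tumor))
  groups <- stats::setNames(rep(names(config$group_sizes),
                                config$group_sizes), tumors)
  .simulate_clinical(config, normals, tumors, groups,
                     .stream_seeds(config$seed))
}

# Poisson technical replicates for diagnosis/relapse pairs with planted
# per-domain fold changes
.simulate_relapse <- function(config, lay, tumors, groups, activity,
                              peak_bins, kinds, base_factor, n_bins, seeds,
                              sample_group) {
  if (config$n_relapse_pairs < 1) return(list())
  set.seed(seeds[["relapse"]])
  # one patient per molecular group where possible
  pick <- unlist(lapply(unique(unname(groups)), function(g)
    names(groups)[groups == g][1]))
  pick <- pick[!is.na(pick)]
  if (length(pick) < config$n_relapse_pairs)
    pick <- unique(c(pick, tumors))
  patients <- pick[seq_len(config$n_relapse_pairs)]

  out <- list()
  for (k in seq_along(patients)) {
    pat <- patients[k]
    plan <- config$relapse_plan[[k]]
    act <- which(vapply(kinds, function(kk) switch(
      kk, shared = , pair_genic = , pair_extragenic = TRUE,
      MMSET = groups[[pat]] == "MMSET", CCND1 = groups[[pat]] == "CCND1",
      HD = groups[[pat]] == "HD", normal = FALSE,
      CCND1_down = groups[[pat]] != "CCND1"), TRUE))
    nd <- length(act)
    n_dn <- round(plan$frac_down * nd); n_up <- round(plan$frac_up * nd)
    chg <- sample(act, min(nd, n_dn + n_up))
    fold <- stats::setNames(rep(1, length(lay$domains)),
                            seq_along(lay$domains))
    if (n_dn) fold[chg[seq_len(n_dn)]] <- plan$down_fold
    if (n_up && length(chg) > n_dn)
      fold[chg[(n_dn + 1):length(chg)]] <- plan$up_fold

    # expected per-bin intensity at diagnosis for this patient
    mu <- lapply(names(n_bins), function(ch) 2 * base_factor[[ch]])
    names(mu) <- names(n_bins)
    mu_rel <- mu
    for (d in seq_along(lay$domains)) {
      if (!(d %in% act)) next
      pb <- peak_bins[[d]]
      amp <- config$enrichment_fold * activity[d, pat]
      mu[[pb$chrom]][pb$bins] <- mu[[pb$chrom]][pb$bins] * amp
      mu_rel[[pb$chrom]][pb$bins] <- mu_rel[[pb$chrom]][pb$bins] * amp * fold[d]
    }
    pois_track <- function(m) {
      binned_track(config$genome, config$bin_width,
                   lapply(m, function(v)
                     stats::rpois(length(v), v * config$replicate_depth) /
                       config$replicate_depth))
    }
    reps <- list(diagnosis = list(pois_track(mu), pois_track(mu)),
                 relapse = list(pois_track(mu_rel), pois_track(mu_rel)))
    hmc_rel <- stats::runif(1, 0.75, 1.02)
    row <- data.frame(sample_id = paste0(pat, "R"), condition = "relapse",
                      group = groups[[pat]], iss = NA_character_,
                      sex = NA_character_, age = NA_real_,
                      mc_percent = NA_real_, hmc_percent = NA_real_,
                      os_months = NA_real_, os_event = NA_integer_,
                      pair_id = pat, replicate = 1L, stringsAsFactors = FALSE)
    out[[pat]] <- list(replicates = reps,
                       truth = list(patient = pat, fold = fold,
                                    active = act,
                                    changed = chg),
                       row = row)
  }
  out
}

# ---- CpG sets ---------------------------------------------------------------

#' Simulate CpG target and universe sets against planted domains
#'
#' Builds a 1-bp CpG "target" set with a controlled fraction inside the
#' planted domains and a background universe, either uniform over the genome
#' or itself built at a controlled inside fraction (the latter is needed to
#' emulate a chip universe whose domain coverage differs from the genome's).
#'
#' @param domains \code{GRanges} of (flattened) domains.
#' @param chrom_sizes named chromosome lengths.
#' @param n_target,n_background set sizes.
#' @param inside_fraction target fraction of target CpGs inside domains.
#' @param background_inside_fraction \code{NULL} for uniform background, or a
#'   fraction in [0, 1].
#' @param seed RNG seed.
#' @return list with \code{target} and \code{universe} (1-bp \code{GRanges}).
#' @export
simulate_cpg_sets <- function(domains, chrom_sizes, n_target = 2000,
                              n_background = 20000, inside_fraction = 0.41,
                              background_inside_fraction = NULL, seed = 1) {
  if (inside_fraction < 0 || inside_fraction > 1)
    stop("inside_fraction must lie in [0, 1]")
  if (n_target > sum(chrom_sizes) || n_background > sum(chrom_sizes))
    stop("requested more CpGs than the genome holds")
  set.seed(seed)
  domains <- flatten(domains)
  dom_w <- as.numeric(GenomicRanges::width(domains))
  draw_inside <- function(n) {
    if (!length(domains) && n > 0) stop("no domains to place CpGs inside")
    i <- sample.int(length(domains), n, replace = TRUE, prob = dom_w)
    pos <- start0(domains)[i] + floor(stats::runif(n) * dom_w[i])
    data.frame(chrom = as.character(GenomicRanges::seqnames(domains))[i],
               pos = pos)
  }
  draw_uniform <- function(n, outside_only = FALSE) {
    got <- NULL
    while (is.null(got) || nrow(got) < n) {
      m <- max(100, 2 * (n - if (is.null(got)) 0 else nrow(got)))
      ch <- sample(names(chrom_sizes), m, replace = TRUE,
                   prob = chrom_sizes / sum(chrom_sizes))
      pos <- floor(stats::runif(m) * chrom_sizes[ch])
      cand <- data.frame(chrom = ch, pos = pos)
      if (outside_only && length(domains)) {
        # test containment on the unsorted candidates
        inside <- GenomicRanges::countOverlaps(
          GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$pos + 1, cand$pos + 1)),
          domains, ignore.strand = TRUE) > 0
        cand <- cand[!inside, , drop = FALSE]
      }
      got <- rbind(got, cand)
    }
    got[seq_len(n), , drop = FALSE]
  }
  build <- function(n, f) {
    k <- round(f * n)
    df <- rbind(draw_inside(k), draw_uniform(n - k, outside_only = TRUE))
    interval_set(df$chrom, df$pos, df$pos + 1)
  }
  target <- build(n_target, inside_fraction)
  universe <- if (is.null(background_inside_fraction))
    with(draw_uniform(n_background), interval_set(chrom, pos, pos + 1))
  else build(n_background, background_inside_fraction)
  list(target = target, universe = universe)
}

# ---- writers ----------------------------------------------------------------

#' Write a synthetic cohort to disk
#'
#' Emits the formats the package's own readers consume: per-sample peak BED
#' files, the sample sheet and expression matrix as TSV, TADs and the
#' ChromHMM segmentation as BED, a chrom-sizes TSV, a JSON truth file, and
#' (optionally, they are large) per-sample bedGraph tracks.
#'
#' @param sim a \code{synthetic_cohort}.
#' @param dir output directory (created if needed).
#' @param tracks also write bedGraph signal tracks.
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(sim, dir, tracks = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(chrom = names(sim$chrom_sizes), length = sim$chrom_sizes),
    file.path(dir, "chrom.sizes"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(sim$sample_table, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene_id = rownames(sim$expr), sim$expr,
                     check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression_rpkm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(sim$tads, file.path(dir, "tads.bed"))
  seg <- sim$chromhmm
  S4Vectors::mcols(seg)$name <- S4Vectors::mcols(seg)$state
  write_bed(seg, file.path(dir, "chromhmm.bed"))
  g <- sim$genes
  utils::write.table(
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = start0(g), end = end0(g), gene_id = g$gene_id,
               strand = as.character(GenomicRanges::strand(g))),
    file.path(dir, "genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  pk <- file.path(dir, "peaks"); dir.create(pk, showWarnings = FALSE)
  for (sm in names(sim$peaks))
    write_bed(sim$peaks[[sm]], file.path(pk, paste0(sm, ".bed")))
  if (tracks) {
    tr <- file.path(dir, "tracks"); dir.create(tr, showWarnings = FALSE)
    for (sm in names(sim$tracks))
      write_bedgraph(sim$tracks[[sm]], file.path(tr, paste0(sm, ".bedgraph")))
  }
  truth <- list(
    domains = data.frame(
      chrom = as.character(GenomicRanges::seqnames(sim$truth$domains)),
      start = start0(sim$truth$domains), end = end0(sim$truth$domains),
      kind = sim$truth$domains$kind),
    links = sim$truth$links, pairs = sim$truth$pairs)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
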