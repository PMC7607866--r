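# Independent brute-force / textbook oracles and shared fixtures.
suppressPackageStartupMessages(library(GenomicRanges))

# ---- shared fixtures (built once per test run) ------------------------------

.fixtures <- new.env(parent = emptyenv())

# default-condition cohort shared across test files
get_cohort <- function(seed = 101) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixtures[[key]]))
    assign(key, simulate_cohort(cohort_config(seed = seed)), .fixtures)
  get(key, .fixtures)
}

# all-sample consensus + signal matrix for the shared cohort
get_consensus <- function(seed = 101) {
  key <- paste0("consensus_", seed)
  if (is.null(.fixtures[[key]])) {
    sim <- get_cohort(seed)
    dsets <- lapply(sim$peaks, stitch_peaks)
    assign(key, consensus_domains(dsets, 2, tracks = sim$tracks), .fixtures)
  }
  get(key, .fixtures)
}

# small fast config for functional (non-recovery) tests
small_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, genome = c(chrA = 3e6, chrB = 3e6),
                n_shared_domains = 5, n_enhancer_pairs = 1,
                n_group_specific = 1, n_down_specific = 1, ...)
}

# ---- random instance generators ---------------------------------------------

rand_intervals <- function(n, max_pos = 1000, chroms = c("c1", "c2")) {
  chrom <- sample(chroms, n, replace = TRUE)
  s <- sample.int(max_pos, n, replace = TRUE) - 1
  w <- sample.int(50, n, replace = TRUE)
  data.frame(chrom = chrom, start = s, end = s + w,
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) interval_set(df$chrom, df$start, df$end)

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(seqnames(gr)), start = start0(gr),
             end = end0(gr), stringsAsFactors = FALSE)
}

# ---- interval oracles -------------------------------------------------------

# O(n^2) transitive-closure merge at gap <= d (same chromosome)
oracle_stitch <- function(df, d) {
  out <- split(df, df$chrom)
  res <- lapply(out, function(x) {
    iv <- Map(c, x$start, x$end)
    repeat {
      merged <- FALSE
      for (i in seq_along(iv)) {
        if (is.null(iv[[i]])) next
        for (j in seq_along(iv)) {
          if (i == j || is.null(iv[[j]])) next
          gap <- max(iv[[i]][1], iv[[j]][1]) - min(iv[[i]][2], iv[[j]][2])
          if (gap <= d) {
            iv[[i]] <- c(min(iv[[i]][1], iv[[j]][1]),
                         max(iv[[i]][2], iv[[j]][2]))
            iv[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
    iv <- Filter(Negate(is.null), iv)
    m <- do.call(rbind, iv)
    data.frame(chrom = x$chrom[1], start = m[, 1], end = m[, 2])
  })
  res <- do.call(rbind, res)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-base boolean-mask flatten
oracle_flatten <- function(df, max_pos = 2000) {
  res <- lapply(split(df, df$chrom), function(x) {
    mask <- logical(max_pos)
    for (i in seq_len(nrow(x))) mask[(x$start[i] + 1):x$end[i]] <- TRUE
    r <- rle(mask)
    e <- cumsum(r$lengths); s <- e - r$lengths
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(chrom = x$chrom[1], start = s[keep], end = e[keep])
  })
  res <- do.call(rbind, Filter(Negate(is.null), res))
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# per-base mean signal over a region of a binned track
oracle_mean_signal <- function(track, chrom, start, end) {
  pos <- start:(end - 1)
  v <- track$values[[chrom]][floor(pos / track$bin_width) + 1]
  mean(v)
}

# per-point linear-scan overlap fraction
oracle_overlap_fraction <- function(points_df, dom_df) {
  inside <- vapply(seq_len(nrow(points_df)), function(i) {
    p <- points_df$pos[i]
    any(dom_df$chrom == points_df$chrom[i] & dom_df$start <= p &
          p < dom_df$end)
  }, TRUE)
  mean(inside)
}

# per-base brute-force support counts over flattened union intervals
oracle_support <- function(union_df, sets) {
  vapply(seq_len(nrow(union_df)), function(i) {
    sum(vapply(sets, function(df) {
      any(df$chrom == union_df$chrom[i] & df$start < union_df$end[i] &
            df$end > union_df$start[i])
    }, TRUE))
  }, 0L)
}

# ---- statistical oracles ----------------------------------------------------

# textbook Welch t-test, two-sided
oracle_welch_p <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  2 * pt(abs(t), df, lower.tail = FALSE)
}

# exact two-sided Mann-Whitney p by exhaustive enumeration (no ties)
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  u_obs <- sum(rank(pool)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(idx)
    sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Benjamini-Hochberg step-up by definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    adj[o[i]] <- prev
  }
  adj
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sx <- x - mean(x); sy <- y - mean(y)
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# brute-force slope-1 tangent point on the min-max-scaled ascending curve:
# the point all other points sit on or above the unit-slope line through it
oracle_rose_cutoff <- function(scores) {
  s <- sort(scores)
  n <- length(s)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - s[1]) / (s[n] - s[1])
  best <- which.min(y - x)
  s[best]
}
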