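test_that("stitch_peaks merges gaps up to the distance, per chromosome", {
  # disjoint non-adjacent peaks survive distance 0 unchanged
  p <- interval_set(c("c1", "c1", "c2"), c(0, 200, 0), c(100, 300, 50))
  expect_equal(gr_to_df(stitch_peaks(p, 0)), gr_to_df(p))

  # a 10 kb gap merges at the 12.5 kb default
  p2 <- interval_set(c("c1", "c1"), c(0, 10100), c(100, 10200))
  expect_equal(gr_to_df(stitch_peaks(p2, 12500)),
               data.frame(chrom = "c1", start = 0, end = 10200))
  # ... but not at a distance just below the gap
  expect_equal(length(stitch_peaks(p2, 9999)), 2)
  expect_error(stitch_peaks(p2, -1), "non-negative")

  set.seed(10)
  for (i in 1:20) {
    df <- rand_intervals(200, max_pos = 5000)
    d <- sample(c(0, 5, 20, 100, 500), 1)
    expect_equal(gr_to_df(stitch_peaks(df_to_gr(df), d)),
                 oracle_stitch(df, d))
  }
})

test_that("stitch_peaks is monotone in distance and idempotent", {
  set.seed(11)
  df <- rand_intervals(100, max_pos = 4000)
  gr <- df_to_gr(df)
  n <- vapply(c(0, 10, 50, 200, 1000), function(d)
    length(stitch_peaks(gr, d)), 0L)
  expect_true(all(diff(n) <= 0))
  s <- stitch_peaks(gr, 50)
  expect_equal(gr_to_df(stitch_peaks(s, 50)), gr_to_df(s))
})

test_that("stitching_curve is non-increasing with a scale-free knee", {
  p <- interval_set("c1", 0, 100)
  sc <- stitching_curve(p, c(0, 100, 200))
  expect_true(all(sc$curve$n_domains == 1))

  set.seed(12)
  df <- rand_intervals(150, max_pos = 20000)
  sc2 <- stitching_curve(df_to_gr(df), seq(0, 2000, by = 100))
  expect_true(all(diff(sc2$curve$n_domains) <= 0))

  # planted gap structure below 12.5 kb puts the knee at 12.5 kb
  sim <- get_cohort()
  tum1 <- sim$sample_table$sample_id[sim$sample_table$condition == "NDMM"][1]
  sc3 <- stitching_curve(sim$peaks[[tum1]])
  expect_equal(sc3$knee, 12500)
})

test_that("score_domains ranks by normalized aggregate signal", {
  cs <- c(c1 = 2000)
  tr <- binned_track(cs, 100, list(c1 = rep(2, 20)))
  d <- interval_set(c("c1", "c1"), c(0, 500), c(300, 1500))
  sd1 <- score_domains(d, tr, library_scale = 1)
  # constant track: signal proportional to length, longest domain ranks first
  expect_equal(sd1$signal, c(6, 20))
  expect_equal(sd1$rank, c(2L, 1L))
  # equal-signal tie broken leftmost-first
  d2 <- interval_set(c("c1", "c1"), c(0, 1000), c(300, 1300))
  sd2 <- score_domains(d2, tr, library_scale = 1)
  expect_equal(sd2$rank, c(1L, 2L))
  expect_error(score_domains(d, tr, library_scale = 0), "positive")
  expect_error(score_domains(interval_set("c1", 1900, 2100), tr),
               "outside")

  set.seed(13)
  tr3 <- binned_track(cs, 100, list(c1 = rgamma(20, 2)))
  df <- oracle_flatten(rand_intervals(12, max_pos = 1900, chroms = "c1"))
  sd3 <- score_domains(df_to_gr(df), tr3, library_scale = 1)
  # naive sort oracle on the signals
  expect_equal(sd3$rank[order(-sd3$signal)], seq_len(nrow(df)))
})

test_that("signal is conserved by stitching", {
  set.seed(14)
  tr <- binned_track(c(c1 = 10000), 100, list(c1 = rgamma(100, 2)))
  df <- oracle_flatten(rand_intervals(30, max_pos = 9000, chroms = "c1"),
                       max_pos = 10000)
  gr <- df_to_gr(df)
  st <- stitch_peaks(gr, 0)  # flatten only: same covered bins
  expect_equal(sum(region_signal(tr, gr)), sum(region_signal(tr, st)),
               tolerance = 1e-9)
})

test_that("rose_cutoff finds the slope-1 tangent point", {
  # single spike: one super domain
  expect_equal(rose_cutoff(c(0, 0, 0, 0, 100))$n_super, 1L)
  # all-equal scores: degenerate, none called
  expect_equal(rose_cutoff(rep(5, 10))$n_super, 0L)
  expect_error(rose_cutoff(3), "at least 2")

  # convex toy curves match the brute-force tangent oracle
  set.seed(15)
  for (i in 1:30) {
    s <- sort(exp(seq(0, runif(1, 2, 6), length.out = 20)) +
                runif(20, 0, 0.1))
    rc <- rose_cutoff(s)
    expect_equal(rc$cutoff_value, oracle_rose_cutoff(s), tolerance = 1e-9)
    expect_equal(rc$n_super, sum(s > oracle_rose_cutoff(s)))
  }
})

test_that("top_domains supports fixed and auto cutoffs", {
  set.seed(16)
  tr <- binned_track(c(c1 = 100000), 100, list(c1 = rgamma(1000, 2)))
  df <- oracle_flatten(rand_intervals(40, max_pos = 90000, chroms = "c1"),
                       max_pos = 100000)
  sd <- score_domains(df_to_gr(df), tr)
  expect_equal(length(top_domains(sd, 5)), 5)
  auto <- top_domains(sd, "auto")
  rc <- rose_cutoff(sd$signal)
  expect_equal(length(auto), rc$n_super)
})

test_that("consensus support matches a brute-force oracle and min_support", {
  # one sample cannot reach support 2
  one <- list(A = interval_set("c1", 0, 100))
  expect_equal(length(consensus_domains(one, 2)$domains), 0)
  expect_error(consensus_domains(one, 0), "min_support")

  # three samples sharing one identical domain
  three <- list(A = interval_set("c1", 0, 100),
                B = interval_set("c1", 0, 100),
                C = interval_set("c1", 0, 100))
  cd <- consensus_domains(three, 2)
  expect_equal(length(cd$domains), 1)
  expect_equal(cd$domains$support, 3L)

  set.seed(17)
  for (i in 1:10) {
    sets <- lapply(1:5, function(k)
      oracle_flatten(rand_intervals(8, max_pos = 800)))
    cd <- consensus_domains(lapply(sets, df_to_gr), min_support = 1)
    un <- gr_to_df(cd$domains)
    expect_equal(cd$domains$support, oracle_support(un, sets))
    # consensus size non-increasing in min_support
    sizes <- vapply(1:4, function(ms)
      length(consensus_domains(lapply(sets, df_to_gr), ms)$domains), 0L)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("call_peaks finds planted enrichment and little else", {
  set.seed(18)
  v <- rgamma(2000, 2, scale = 1)
  v[501:520] <- v[501:520] * 12      # one planted 2 kb peak
  tr <- binned_track(c(c1 = 2e5), 100, list(c1 = v))
  pk <- call_peaks(tr)
  expect_true(length(pk) >= 1)
  expect_true(any(start0(pk) <= 50100 & end0(pk) >= 51900))
  expect_lte(length(pk), 3)
  # all-background track: no peaks
  tr0 <- binned_track(c(c1 = 2e5), 100, list(c1 = rgamma(2000, 2)))
  expect_lte(length(call_peaks(tr0)), 1)
})
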