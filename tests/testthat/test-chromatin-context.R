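test_that("state signal distributions aggregate per interval and state", {
  cs <- c(c1 = 1000)
  tr <- binned_track(cs, 100, list(c1 = rep(2.5, 10)))
  seg <- interval_set(c("c1", "c1"), c(0, 500), c(500, 1000),
                      state = c("enh", "het"))
  d <- state_signal_distribution(tr, seg)
  expect_equal(d$per_interval$mean, c(2.5, 2.5))

  # hand-built 4-interval toy against the per-base oracle
  tr2 <- binned_track(cs, 100, list(c1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)))
  seg2 <- interval_set(rep("c1", 4), c(0, 250, 500, 750),
                       c(250, 500, 750, 1000),
                       state = c("a", "a", "b", "b"))
  d2 <- state_signal_distribution(tr2, seg2)
  ora <- vapply(seq_len(4), function(i)
    oracle_mean_signal(tr2, "c1", start0(seg2)[i], end0(seg2)[i]), 0)
  expect_equal(d2$per_interval$mean, ora, tolerance = 1e-9)
  expect_error(state_signal_distribution(tr, interval_set("c1", 0, 10)),
               "state")
})

test_that("planted enhancer states outrank heterochromatin on the cohort", {
  sim <- get_cohort()
  sm <- sim$sample_table$sample_id[sim$sample_table$condition == "NDMM"][1]
  d <- state_signal_distribution(sim$tracks[[sm]], sim$chromhmm)
  med <- setNames(d$summary$median, d$summary$state)
  expect_gt(med[["strong_enhancer"]], med[["heterochromatin"]])
})

test_that("correlation matrix is symmetric, unit-diagonal and PSD", {
  set.seed(50)
  cs <- c(c1 = 2e5)
  v <- rgamma(2000, 2)
  t1 <- binned_track(cs, 100, list(c1 = v))
  t2 <- binned_track(cs, 100, list(c1 = max(v) - v))   # anti-correlated
  t3 <- binned_track(cs, 100, list(c1 = rgamma(2000, 2)))
  cm <- binned_correlation_matrix(list(a = t1, b = t2, c = t3),
                                  bin_width = 1000)
  expect_equal(cm["a", "a"], 1)
  expect_lt(cm["a", "b"], -0.8)
  expect_equal(cm, t(cm))
  expect_gte(min(eigen(cm, symmetric = TRUE)$values), -1e-8)

  # textbook Pearson oracle on small toy tracks, rebinned by hand
  t4 <- binned_track(c(c1 = 400), 100, list(c1 = c(1, 5, 2, 8)))
  t5 <- binned_track(c(c1 = 400), 100, list(c1 = c(2, 4, 1, 9)))
  cm2 <- binned_correlation_matrix(list(x = t4, y = t5), bin_width = 100)
  expect_equal(cm2["x", "y"],
               oracle_pearson(log2(c(1, 5, 2, 8) + 1),
                              log2(c(2, 4, 1, 9) + 1)), tolerance = 1e-12)
  # zero-variance track reported as missing
  t6 <- binned_track(c(c1 = 400), 100, list(c1 = rep(3, 4)))
  cm3 <- binned_correlation_matrix(list(x = t4, z = t6))
  expect_true(is.na(cm3["x", "z"]))
})

test_that("peak metaprofile reproduces single-region shapes", {
  cs <- c(c1 = 10000)
  # constant track gives a flat profile
  tr <- binned_track(cs, 100, list(c1 = rep(2, 100)))
  pk <- interval_set("c1", 4900, 5100)
  mp <- peak_metaprofile(tr, pk, half_window = 1000, step = 100)
  expect_true(all(mp$mean == 2))
  expect_equal(mp$n, 1)

  # single triangular peak is reproduced exactly
  tri <- c(rep(0, 40), 1:10, 10:1, rep(0, 40))
  tr2 <- binned_track(cs, 100, list(c1 = tri))
  mp2 <- peak_metaprofile(tr2, interval_set("c1", 4900, 5100),
                          half_window = 900, step = 100)
  expect_equal(mp2$mean, tri[42:60])

  # peaks truncated at chromosome edges are dropped
  pk3 <- c(interval_set("c1", 0, 200), interval_set("c1", 4900, 5100))
  mp3 <- peak_metaprofile(tr, pk3, half_window = 1000, step = 500)
  expect_equal(mp3$n, 1)
  expect_error(peak_metaprofile(tr, pk, half_window = 0), "half_window")

  # planted domains show center enrichment over flanks on the cohort
  sim <- get_cohort()
  sm <- sim$sample_table$sample_id[sim$sample_table$condition == "NDMM"][1]
  mp4 <- peak_metaprofile(sim$tracks[[sm]], sim$peaks[[sm]])
  center <- mp4$mean[abs(mp4$position) <= 500]
  flank <- mp4$mean[abs(mp4$position) >= 4500]
  expect_gt(mean(center), 2 * mean(flank))
})

test_that("metagene profiles are strand-oriented and class-ordered", {
  cs <- c(c1 = 100000)
  # constant track: all class profiles flat at the constant
  tr <- binned_track(cs, 100, list(c1 = rep(4, 1000)))
  genes <- gene_models(c("c1", "c1"), c(20000, 60000), c(30000, 70000),
                      c("g1", "g2"), c("+", "+"))
  expr <- matrix(c(0.5, 0.5, 200, 200), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  suppressMessages(mg <- metagene_by_expression(tr, genes, expr))
  expect_equal(names(mg), c("<1", ">100"))
  expect_true(all(vapply(mg, function(m) all(m$mean == 4), TRUE)))

  # mirrored signal on opposite strands gives identical oriented profiles
  asc <- c(rep(1, 50), seq(2, 6, length.out = 50))
  vplus <- rep(1, 1000); vplus[201:300] <- asc
  vminus <- rep(1, 1000); vminus[601:700] <- rev(asc)
  trp <- binned_track(cs, 100, list(c1 = vplus))
  trm <- binned_track(cs, 100, list(c1 = vminus))
  gp <- gene_models("c1", 20000, 30000, "g1", "+")
  gm <- gene_models("c1", 60000, 70000, "g1", "-")
  ex1 <- matrix(50, 1, 2, dimnames = list("g1", c("s1", "s2")))
  suppressMessages({
    mp <- metagene_by_expression(trp, gp, ex1)
    mm <- metagene_by_expression(trm, gm, ex1)
  })
  expect_equal(mp[["10-100"]]$mean, mm[["10-100"]]$mean, tolerance = 1e-9)

  # planted coupling on the cohort: higher classes carry more body signal
  sim <- get_cohort()
  sm <- sim$sample_table$sample_id[sim$sample_table$condition == "NDMM"][1]
  tumors <- sim$sample_table$sample_id[sim$sample_table$condition == "NDMM"]
  suppressMessages(
    mg2 <- metagene_by_expression(sim$tracks[[sm]], sim$genes, sim$expr,
                                  samples = tumors))
  body_mean <- vapply(mg2, function(m) {
    b <- attr(m, "body"); mean(m$mean[b[1]:b[2]])
  }, 0)
  cls <- intersect(c("<1", "1-10", "10-100", ">100"), names(body_mean))
  expect_true(all(diff(body_mean[cls]) >= 0))
})

test_that("metagene of a concatenation is the n-weighted average", {
  set.seed(51)
  cs <- c(c1 = 200000)
  tr <- binned_track(cs, 100, list(c1 = rgamma(2000, 2)))
  g1 <- gene_models(rep("c1", 2), c(20000, 50000), c(30000, 64000),
                    c("a", "b"), c("+", "+"))
  g2 <- gene_models(rep("c1", 3), c(90000, 120000, 150000),
                    c(101000, 132000, 161000), c("c", "d", "e"),
                    c("+", "+", "+"))
  ex <- matrix(50, 5, 2, dimnames = list(c("a", "b", "c", "d", "e"),
                                         c("s1", "s2")))
  suppressMessages({
    m1 <- metagene_by_expression(tr, g1, ex)[["10-100"]]
    m2 <- metagene_by_expression(tr, g2, ex)[["10-100"]]
    m12 <- metagene_by_expression(tr, c(g1, g2), ex)[["10-100"]]
  })
  expect_equal(m12$mean, (m1$n * m1$mean + m2$n * m2$mean) / (m1$n + m2$n),
               tolerance = 1e-9)
})
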