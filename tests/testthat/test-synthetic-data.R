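test_that("configuration is validated before anything runs", {
  expect_error(cohort_config(n_tumor = 0), "n_tumor")
  expect_error(cohort_config(n_tumor = 10,
                             group_sizes = c(MMSET = 5, CCND1 = 3,
                                             HD = 1, other = 0)),
               "sum to n_tumor")
  expect_error(cohort_config(survival_hr = -1), "survival_hr")
  # domains exceeding the genome's TAD capacity
  expect_error(cohort_config(genome = c(c1 = 2e6), n_shared_domains = 50),
               "infeasible")
})

test_that("the same seed reproduces the cohort exactly", {
  cfg <- small_config(seed = 5)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$sample_table, s2$sample_table)
  expect_identical(s1$tracks, s2$tracks)
  expect_identical(s1$expr, s2$expr)
  expect_identical(gr_to_df(s1$truth$domains), gr_to_df(s2$truth$domains))
  s3 <- simulate_cohort(small_config(seed = 6))
  expect_false(identical(s1$tracks[[1]]$values, s3$tracks[[1]]$values))
})

test_that("cohort structure mirrors the configured study design", {
  sim <- get_cohort()
  st <- sim$sample_table
  expect_equal(sum(st$condition == "NPC"), 5)
  expect_equal(sum(st$condition == "NDMM"), 40)
  expect_equal(sum(st$condition == "relapse"), 4)
  expect_equal(as.integer(table(st$group[st$condition == "NDMM"])[
    c("MMSET", "CCND1", "HD", "other")]), c(9L, 11L, 16L, 4L))
  expect_equal(as.integer(table(st$iss[st$condition == "NDMM"])[
    c("I", "II", "III", "NA")]), c(9L, 17L, 13L, 1L))
  # one MS failure: 39 measured tumor 5hmC values
  expect_equal(sum(!is.na(st$hmc_percent[st$condition == "NDMM"])), 39)
  expect_true(all(st$hmc_percent >= 0, na.rm = TRUE))
  expect_true(all(st$mc_percent >= 0, na.rm = TRUE))
  expect_true(all(st$os_event %in% c(0, 1, NA)))
  # every planted domain lies within the genome, intra-TAD with its gene
  pd <- sim$truth$domains
  expect_true(all(end0(pd) <= sim$chrom_sizes[
    as.character(seqnames(pd))]))
  links <- sim$truth$links
  tad_dom <- findOverlaps(pd[links$domain], sim$tads, select = "first")
  tss <- sim$genes$tss[match(links$gene_id, sim$genes$gene_id)]
  gchr <- as.character(seqnames(sim$genes))[
    match(links$gene_id, sim$genes$gene_id)]
  tad_gene <- findOverlaps(
    GRanges(gchr, IRanges(tss + 1, tss + 1)), sim$tads, select = "first")
  expect_equal(tad_dom, tad_gene)
})

test_that("emitted files round-trip through the package readers", {
  sim <- simulate_cohort(small_config(seed = 7))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir, tracks = TRUE)
  cs <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  expect_equal(cs, sim$chrom_sizes)
  st <- read_sample_table(file.path(dir, "sample_sheet.tsv"))
  expect_equal(st$sample_id, sim$sample_table$sample_id)
  tads <- read_bed(file.path(dir, "tads.bed"))
  expect_equal(gr_to_df(tads)[1:3], gr_to_df(sim$tads)[1:3])
  genes <- read_genes(file.path(dir, "genes.tsv"))
  expect_equal(sort(genes$gene_id), sort(sim$genes$gene_id))
  sm <- sim$sample_table$sample_id[1]
  pk <- read_bed(file.path(dir, "peaks", paste0(sm, ".bed")))
  expect_equal(gr_to_df(pk), gr_to_df(sim$peaks[[sm]]))
  tr <- read_bedgraph(file.path(dir, "tracks", paste0(sm, ".bedgraph")),
                      cs, sim$bin_width)
  expect_equal(tr$values[[1]], sim$tracks[[sm]]$values[[1]],
               tolerance = 1e-5)
})

test_that("a perfect planted link yields r-squared of exactly 1", {
  cfg <- small_config(seed = 8, domain_gene_r2 = 1)
  sim <- simulate_cohort(cfg)
  st <- sim$sample_table
  tumors <- st$sample_id[st$condition == "NDMM"]
  links <- sim$truth$links
  dom <- sim$truth$domains[links$domain[1]]
  x <- vapply(tumors, function(sm)
    log2(region_signal(sim$tracks[[sm]], dom) /
           (track_total(sim$tracks[[sm]]) / 1e6) + 1), 0)
  y <- log2(sim$expr[links$gene_id[1], tumors] + 1)
  expect_equal(cor(x, y)^2, 1, tolerance = 1e-6)
})

test_that("planted survival effect is recovered at large n", {
  hrs <- vapply(1:20, function(s) {
    st <- simulate_sample_table(cohort_config(seed = s, n_tumor = 400))
    dichotomized_survival(st, "hmc")$hr
  }, 0)
  expect_gte(median(hrs), 2.0)
  expect_lte(median(hrs), 3.4)
})

test_that("CpG sets honor the requested inside fractions", {
  sim <- get_cohort()
  dom <- flatten(sim$truth$domains)
  for (f in c(0, 0.41, 1)) {
    sets <- simulate_cpg_sets(dom, sim$chrom_sizes, n_target = 1000,
                              n_background = 5000, inside_fraction = f,
                              seed = 3)
    expect_equal(overlap_fraction(sets$target, dom), f,
                 tolerance = 1 / 1000 + 1e-9)
  }
  sets <- simulate_cpg_sets(dom, sim$chrom_sizes, n_target = 500,
                            n_background = 8000, inside_fraction = 0.41,
                            background_inside_fraction = 0.11, seed = 4)
  expect_equal(overlap_fraction(sets$universe, dom), 0.11,
               tolerance = 1 / 8000 + 1e-9)
  expect_error(simulate_cpg_sets(dom, sim$chrom_sizes, n_target = 1e9),
               "more CpGs")
  expect_error(simulate_cpg_sets(dom, sim$chrom_sizes,
                                 inside_fraction = 1.5), "inside_fraction")
})

test_that("relapse replicates carry the planted fold-changes", {
  sim <- get_cohort()
  pat <- names(sim$relapse)[1]
  rl <- sim$relapse[[pat]]
  truth <- rl$truth
  pd <- sim$truth$domains
  changed_down <- as.integer(names(truth$fold))[truth$fold < 1]
  expect_gt(length(changed_down), 0)
  d1 <- rl$replicates$diagnosis[[1]]
  r1 <- rl$replicates$relapse[[1]]
  sig_d <- region_signal(d1, pd[changed_down])
  sig_r <- region_signal(r1, pd[changed_down])
  # raw (un-normalized) fold at down-planted domains is clearly below 1
  expect_true(median(sig_r / sig_d) < 0.8)
})
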