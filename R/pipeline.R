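# End-to-end orchestration of the synthetic study: simulate -> per-sample
# domains -> consensus -> gene assignment -> group-specific -> differential ->
# overlap null -> profiles -> clinical, with a machine-readable summary.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full synthetic-cohort analysis
#'
#' Executes every stage of the package on a simulated cohort and returns (and
#' optionally writes) a machine-readable summary. Stage outputs are plain
#' files; any stage failure aborts with the stage name, retaining files
#' already written. Two runs with the same config produce identical
#' summaries.
#'
#' @param config a \code{\link{cohort_config}}.
#' @param out_dir optional output directory; when given, consensus BED5
#'   (name = domain id, score = support), signal matrix TSV, assignment and
#'   group-specific TSVs, differential TSVs, the overlap-null JSON, the
#'   clinical JSON, a summary JSON and a parameter log are written.
#' @param stitch_distance peak stitch distance in bp (default 12,500).
#' @param min_support consensus support threshold (default 2).
#' @param min_mean_rpkm expression floor for candidate genes.
#' @param fdr_threshold FDR threshold for group and differential calls.
#' @param n_resamples resamples for the CpG overlap null.
#' @param cpg_inside_fraction,cpg_background_fraction CpG-set construction
#'   fractions for the overlap-null stage.
#' @return list of class \code{pipeline_result} with the cohort, consensus
#'   objects, all stage results and \code{summary}.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         stitch_distance = 12500, min_support = 2,
                         min_mean_rpkm = 1, fdr_threshold = 0.05,
                         n_resamples = 1000, cpg_inside_fraction = 0.41,
                         cpg_background_fraction = 0.11) {
  .stage("validate", validate_config(config))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  sim <- .stage("simulate", simulate_cohort(config))
  st <- sim$sample_table
  tumors <- st$sample_id[st$condition == "NDMM"]
  groups <- stats::setNames(st$group, st$sample_id)

  domains <- .stage("domains", lapply(sim$peaks, function(p)
    stitch_peaks(p, stitch_distance)))
  curve <- .stage("stitching_curve",
                  stitching_curve(sim$peaks[[tumors[1]]]))

  cons_all <- .stage("consensus", consensus_domains(
    domains, min_support = min_support, tracks = sim$tracks))
  cons_tum <- .stage("consensus_tumor", consensus_domains(
    domains[tumors], min_support = min_support,
    tracks = sim$tracks[tumors]))

  assign <- .stage("assign_genes", assign_domain_gene(
    cons_tum, sim$expr, sim$genes, sim$tads, samples = tumors,
    min_mean_rpkm = min_mean_rpkm))
  pairs <- .stage("domain_pairs", domain_pair_correlation(
    cons_tum, sim$tads, samples = tumors))
  enhancers <- .stage("enhancers",
                      flag_enhancer_candidates(assign, pairs, sim$genes))

  group_res <- .stage("group_specific", group_specific_domains(
    cons_all, groups[colnames(cons_all$signal_matrix)],
    fdr_threshold = fdr_threshold))

  differential <- .stage("differential", lapply(
    stats::setNames(names(sim$relapse), names(sim$relapse)),
    function(pat) relapse_differential(sim, pat, stitch_distance)))

  cpg <- .stage("cpg_sets", simulate_cpg_sets(
    sim$truth$domains, sim$chrom_sizes,
    inside_fraction = cpg_inside_fraction,
    background_inside_fraction = cpg_background_fraction,
    seed = config$seed))
  onull <- .stage("overlap_null", resampling_null(
    cpg$target, cpg$universe, cons_all$domains,
    n_resamples = n_resamples, seed = config$seed))

  t1 <- sim$tracks[[tumors[1]]]
  profiles <- .stage("profiles", list(
    states = state_signal_distribution(t1, sim$chromhmm),
    peak_profile = peak_metaprofile(t1, sim$peaks[[tumors[1]]]),
    metagene = metagene_by_expression(t1, sim$genes, sim$expr,
                                      samples = tumors),
    correlation = binned_correlation_matrix(
      sim$tracks[c(tumors[1], tumors[2], st$sample_id[1])])))

  clinical <- .stage("clinical", list(
    hmc = compare_conditions(st, "hmc"),
    mc = compare_conditions(st, "mc"),
    iss = iss_trend(st, "hmc"),
    age = covariate_association(st, "hmc", "age"),
    sex = covariate_association(st, "hmc", "sex"),
    survival = dichotomized_survival(st, "hmc")))

  top_group <- group_res[group_res$significant & group_res$direction == "up", ]
  top_group <- top_group[order(top_group$fdr), ]
  summary <- list(
    seed = config$seed,
    n_samples = nrow(st), n_tumor = length(tumors),
    stitch_knee_bp = curve$knee,
    n_consensus_all = length(cons_all$domains),
    n_consensus_tumor = length(cons_tum$domains),
    n_assigned = sum(!is.na(assign$gene_id)),
    n_gene_specific = sum(assign$gene_specific),
    max_link_r2 = if (any(!is.na(assign$r2))) max(assign$r2, na.rm = TRUE)
      else NA_real_,
    max_pair_r2 = if (nrow(pairs)) max(pairs$pair_r2) else NA_real_,
    n_enhancer_candidates = nrow(enhancers),
    n_group_specific_up = sum(group_res$significant &
                                group_res$direction == "up"),
    top_group_hit = if (nrow(top_group))
      paste(top_group$group[1], top_group$domain_id[1]) else NA_character_,
    pct_reduced_relapse = vapply(differential, function(d)
      100 * mean(d$results$significant & d$results$log2fc < 0), 0),
    overlap_observed = onull$observed_fraction,
    overlap_null_mean = onull$null_mean,
    hmc_reduction_pct = clinical$hmc$reduction,
    mc_reduction_pct = clinical$mc$reduction,
    iss_reduction_II_pct = clinical$iss$reduction_I_vs_II,
    iss_reduction_III_pct = clinical$iss$reduction_I_vs_III,
    cox_hr_low_vs_high = clinical$survival$hr)

  if (!is.null(out_dir)) {
    .stage("write", {
      cd <- cons_all$domains
      S4Vectors::mcols(cd) <- S4Vectors::DataFrame(
        name = cd$domain_id, score = cd$support)
      write_bed(cd, file.path(out_dir, "consensus_all.bed"))
      utils::write.table(
        data.frame(domain_id = rownames(cons_all$signal_matrix),
                   cons_all$signal_matrix, check.names = FALSE),
        file.path(out_dir, "signal_matrix.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      utils::write.table(assign, file.path(out_dir, "assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(enhancers,
                         file.path(out_dir, "enhancer_candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(group_res, file.path(out_dir, "group_specific.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      for (pat in names(differential))
        utils::write.table(
          differential[[pat]]$results,
          file.path(out_dir, paste0("differential_", pat, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        onull[c("observed_fraction", "null_mean", "null_sd",
                "n_resamples", "empirical_p")],
        file.path(out_dir, "overlap_null.json"), auto_unbox = TRUE,
        digits = NA)
      cl <- clinical
      cl$survival <- clinical$survival[c("hr", "ci_low", "ci_high",
                                         "p_logrank", "n_low", "n_high",
                                         "split_value")]
      jsonlite::write_json(cl, file.path(out_dir, "clinical.json"),
                           auto_unbox = TRUE, digits = NA)
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
      log <- c(paste("R", paste(R.version$major, R.version$minor, sep = ".")),
               paste("hydroxydomains",
                     as.character(utils::packageVersion("hydroxydomains"))),
               paste("stitch_distance", stitch_distance),
               paste("min_support", min_support),
               paste("min_mean_rpkm", min_mean_rpkm),
               paste("fdr_threshold", fdr_threshold),
               paste("n_resamples", n_resamples),
               paste("cpg_inside_fraction", cpg_inside_fraction),
               paste("cpg_background_fraction", cpg_background_fraction),
               vapply(names(config), function(k)
                 paste(k, paste(format(unlist(config[[k]])), collapse = " ")),
                 ""))
      writeLines(log, file.path(out_dir, "run_log.txt"))
    })
  }

  structure(list(sim = sim, domains = domains, curve = curve,
                 consensus_all = cons_all, consensus_tumor = cons_tum,
                 assignments = assign, pairs = pairs, enhancers = enhancers,
                 group_specific = group_res, differential = differential,
                 overlap_null = onull, profiles = profiles,
                 clinical = clinical, summary = summary),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat("pipeline_result (seed ", s$seed, "):\n",
      "  consensus domains: ", s$n_consensus_all, " (", s$n_consensus_tumor,
      " tumor-only), assigned ", s$n_assigned, ", gene-specific ",
      s$n_gene_specific, "\n",
      "  max link R2 ", round(s$max_link_r2, 3), ", max pair R2 ",
      round(s$max_pair_r2, 3), ", enhancer candidates ",
      s$n_enhancer_candidates, "\n",
      "  5hmC reduction ", round(s$hmc_reduction_pct, 1), "%, 5mC ",
      round(s$mc_reduction_pct, 1), "%, HR(low vs high) ",
      round(s$cox_hr_low_vs_high, 2), "\n",
      "  CpG overlap ", round(100 * s$overlap_observed, 1), "% vs null ",
      round(100 * s$overlap_null_mean, 1), "%\n", sep = "")
  invisible(x)
}
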