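# Pipeline orchestration: one call running every QC stage in order and,
# optionally, writing the full audit bundle (CSV + JSON + newick) to disk.

#' Summarise a cross design by source group
#'
#' @param design A `cross_design`.
#' @return Data.frame with one row per source group plus a `Total` row:
#'   `source_group`, `n_lines` (distinct females), `n_crosses`, `n_f1`.
#' @export
summarize_design <- function(design) {
  stopifnot(inherits(design, "cross_design"))
  cr <- design$crosses
  if (nrow(cr) == 0) {
    return(data.frame(source_group = "Total", n_lines = 0L, n_crosses = 0L,
                      n_f1 = 0L, stringsAsFactors = FALSE))
  }
  grp <- ifelse(is.na(cr$source_group), "unspecified", cr$source_group)
  f1_per_cross <- table(factor(design$f1_map$cross_id, levels = cr$cross_id))
  levels_g <- unique(grp)
  rows <- lapply(levels_g, function(g) {
    sel <- grp == g
    data.frame(source_group = g,
               n_lines = length(unique(cr$female_id[sel])),
               n_crosses = sum(sel),
               n_f1 = as.integer(sum(f1_per_cross[sel])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rbind(out, data.frame(source_group = "Total",
                        n_lines = length(unique(cr$female_id)),
                        n_crosses = nrow(cr),
                        n_f1 = nrow(design$f1_map),
                        stringsAsFactors = FALSE))
}

#' Run the full marker-QC pipeline
#'
#' Executes the analysis stages in order: per-marker summaries and panel
#' screening, parental fingerprints, per-cross polymorphism and marker
#' efficiency, F1 hybridity classification with per-cross success rates and
#' the cohort summary, the parent/F1 heterozygosity contrast, and parental
#' relatedness (distances, Neighbor-Joining tree, related-pair flags, PCA
#' with marker contributions). When `output_dir` is given, every artifact is
#' written as CSV/JSON/newick together with a machine-readable run manifest
#' and a plain-text log.
#'
#' @param genotypes A `geno_matrix` holding parents and putative F1s.
#' @param design A `cross_design`.
#' @param hybridity_threshold Hybridity percentage below which an F1 is a
#'   self (default 20).
#' @param min_informative Minimum evaluable informative loci per F1
#'   (default 1).
#' @param max_missing_parent Parent missingness ceiling for the relatedness
#'   stage (default 0.10).
#' @param fingerprint_threshold Missingness bound for fingerprint
#'   reliability (default 0.55).
#' @param related_threshold Distance below which a parental pair is flagged
#'   as related (default 2.0).
#' @param bias_threshold,het_threshold Panel-screening bounds
#'   (defaults 0.75 and 0.04; see [screen_marker()]).
#' @param output_dir Optional directory for the artifact bundle.
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List of class `hybriqc_run` with elements `design_summary`,
#'   `marker_summary`, `marker_screen`, `fingerprints`, `pair_polymorphism`,
#'   `marker_efficiency`, `informative_distribution`, `hybridity`,
#'   `cross_success`, `success_distribution`, `cohort_summary`,
#'   `het_contrast`, `distance`, `tree`, `related_pairs`, `pca`,
#'   `contributions`, `manifest`, `log`.
#' @export
run_pipeline <- function(genotypes, design,
                         hybridity_threshold = 20, min_informative = 1,
                         max_missing_parent = 0.10,
                         fingerprint_threshold = 0.55,
                         related_threshold = 2.0,
                         bias_threshold = 0.75, het_threshold = 0.04,
                         output_dir = NULL, seed = NULL) {
  stopifnot(inherits(genotypes, "geno_matrix"), inherits(design, "cross_design"))
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ds <- design_samples(design)
  note("input: ", nrow(genotypes$calls), " samples x ", ncol(genotypes$calls),
       " markers; ", nrow(design$crosses), " crosses, ",
       nrow(design$f1_map), " putative F1s")

  design_summary <- stage("design_summary", summarize_design(design))
  msum <- stage("marker_summary", marker_summary_table(genotypes))
  screen <- stage("marker_screen",
                  screen_marker(msum$per_marker, bias_threshold, het_threshold))
  note("marker summary: mean MAF ",
       sprintf("%.3f", msum$panel$mean[msum$panel$statistic == "maf"]),
       "; ", sum(!screen$pass), " marker(s) fail the panel screen")

  parents_present <- intersect(ds$parents, genotypes$sample_ids)
  fingerprints <- stage("fingerprints",
                        fingerprint_report(genotypes, parents_present,
                                           fingerprint_threshold))
  note("fingerprints: ", sum(!fingerprints$reliable), " of ",
       nrow(fingerprints), " parents unreliable (> ",
       100 * fingerprint_threshold, "% missing)")

  pairs <- stage("pair_polymorphism", pair_polymorphism_table(genotypes, design))
  eff <- stage("marker_efficiency", marker_efficiency_table(pairs))
  dist_info <- stage("informative_distribution",
                     informative_marker_distribution(pairs))
  note("polymorphism: mean marker efficiency ",
       sprintf("%.2f%%", eff$panel$mean), "; ",
       length(dist_info$left_tail), " cross(es) with <= 2 informative markers")

  hyb <- stage("hybridity",
               hybridity_table(genotypes, design, pairs,
                               threshold = hybridity_threshold,
                               min_informative = min_informative))
  success <- stage("cross_success", cross_success_table(hyb, design))
  success_dist <- stage("success_distribution", success_rate_distribution(success))
  cohort <- stage("cohort_summary", cohort_summary(hyb))
  note("hybridity: ",
       paste(sprintf("%s %d (%d%%)", cohort$categories$category,
                     cohort$categories$n, cohort$categories$percent_rounded),
             collapse = ", "))

  het <- stage("het_contrast", heterozygosity_contrast(genotypes, design))

  # relatedness is computed on parents surviving the missingness filter
  parent_gm <- subset_samples(genotypes, parents_present)
  pr_miss <- rowMeans(is.na(parent_gm$calls))
  keep <- parent_gm$sample_ids[pr_miss <= max_missing_parent]
  note("relatedness: ", length(keep), " of ", length(parents_present),
       " parents pass the ", 100 * max_missing_parent, "% missingness filter")
  relate_gm <- subset_samples(parent_gm, keep)
  d <- stage("distance", pairwise_distance(relate_gm))
  tree <- if (length(keep) >= 2 && !anyNA(unclass(d))) {
    stage("neighbor_joining", neighbor_joining(unclass(d)))
  } else {
    note("neighbor-joining skipped: undefined distances or too few parents")
    NULL
  }
  related <- stage("related_pairs", flag_related_pairs(d, related_threshold))
  pca <- stage("pca", pca_genotypes(genotypes))
  contrib <- stage("marker_contributions", marker_contributions(pca, dims = 2))

  manifest <- list(
    package = "hybriqc",
    version = as.character(packageVersion("hybriqc")),
    n_samples = nrow(genotypes$calls),
    n_markers = ncol(genotypes$calls),
    n_crosses = nrow(design$crosses),
    n_f1 = nrow(design$f1_map),
    thresholds = list(hybridity = hybridity_threshold,
                      min_informative = min_informative,
                      max_missing_parent = max_missing_parent,
                      fingerprint = fingerprint_threshold,
                      related_pair = related_threshold,
                      bias = bias_threshold, het_screen = het_threshold),
    seed = seed
  )
  out <- structure(list(
    design_summary = design_summary, marker_summary = msum,
    marker_screen = screen, fingerprints = fingerprints,
    pair_polymorphism = pairs, marker_efficiency = eff,
    informative_distribution = dist_info, hybridity = hyb,
    cross_success = success, success_distribution = success_dist,
    cohort_summary = cohort, het_contrast = het,
    distance = d, tree = tree, related_pairs = related,
    pca = pca, contributions = contrib,
    manifest = manifest, log = log
  ), class = "hybriqc_run")
  if (!is.null(output_dir)) write_run_bundle(out, output_dir)
  out
}

#' @export
print.hybriqc_run <- function(x, ...) {
  cat("hybriqc run:\n")
  for (line in x$log) cat("  -", line, "\n")
  invisible(x)
}

#' Write a pipeline run's artifact bundle
#'
#' @param run A `hybriqc_run` from [run_pipeline()].
#' @param output_dir Directory (created if needed).
#' @return `output_dir`, invisibly.
#' @export
write_run_bundle <- function(run, output_dir) {
  stopifnot(inherits(run, "hybriqc_run"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(output_dir, f)
  write.csv(run$design_summary, path("design_summary.csv"), row.names = FALSE)
  write.csv(run$marker_summary$per_marker, path("marker_summary.csv"), row.names = FALSE)
  write.csv(run$marker_summary$panel, path("marker_summary_panel.csv"), row.names = FALSE)
  write.csv(run$marker_screen, path("marker_screen.csv"), row.names = FALSE)
  write.csv(run$fingerprints, path("fingerprints.csv"), row.names = FALSE)
  write.csv(run$pair_polymorphism$pairs, path("pair_polymorphism.csv"), row.names = FALSE)
  write.csv(cbind(cross_id = rownames(run$pair_polymorphism$scores),
                  as.data.frame(run$pair_polymorphism$scores)),
            path("pair_scores.csv"), row.names = FALSE)
  write.csv(run$marker_efficiency$per_marker, path("marker_efficiency.csv"), row.names = FALSE)
  write.csv(run$hybridity, path("hybridity.csv"), row.names = FALSE)
  write.csv(run$cross_success, path("cross_success.csv"), row.names = FALSE)
  jsonlite::write_json(run$cohort_summary, path("cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write.csv(run$het_contrast$samples, path("heterozygosity_samples.csv"), row.names = FALSE)
  write.csv(run$het_contrast$bins, path("heterozygosity_bins.csv"), row.names = FALSE)
  write.csv(as.data.frame(unclass(run$distance)), path("distance_matrix.csv"))
  if (!is.null(run$tree)) write_newick(run$tree, path("nj_tree.nwk"))
  write.csv(run$related_pairs, path("related_pairs.csv"), row.names = FALSE)
  write.csv(as.data.frame(run$pca$scores), path("pca_scores.csv"))
  write.csv(as.data.frame(run$pca$loadings), path("pca_loadings.csv"))
  write.csv(data.frame(marker_id = names(run$contributions$combined),
                       contribution = run$contributions$combined),
            path("pca_contributions.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(run$log, path("run_log.txt"))
  invisible(output_dir)
}
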