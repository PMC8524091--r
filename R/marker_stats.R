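# Per-marker genetic summaries, panel screening, dataset filtering and
# parental fingerprint reports.

#' Gene-count allele frequencies at one marker
#'
#' Each homozygote contributes two copies of its allele and each heterozygote
#' one copy of each; missing calls are excluded from the denominator.
#'
#' @param gm A `geno_matrix`.
#' @param marker_id A marker in `gm`'s panel.
#' @return Named numeric `c(freq_allele1, freq_allele2)`, summing to 1.
#' @export
#' @examples
#' # HOM1, HET, HOM2, missing -> allele 1 carries (2 + 1) of 6 copies = 0.5
allele_frequencies <- function(gm, marker_id) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (!marker_id %in% gm$panel$marker_id) stop("unknown marker: ", marker_id)
  f <- .allele_freq_one(gm$calls[, marker_id])
  if (anyNA(f)) {
    stop("all calls missing at marker ", marker_id, "; frequencies undefined")
  }
  names(f) <- c("freq_allele1", "freq_allele2")
  f
}

.allele_freq_one <- function(states) {
  n_hom1 <- sum(states == "HOM1", na.rm = TRUE)
  n_hom2 <- sum(states == "HOM2", na.rm = TRUE)
  n_het <- sum(states == "HET", na.rm = TRUE)
  total <- 2 * (n_hom1 + n_hom2 + n_het)
  if (total == 0) return(c(NA_real_, NA_real_))
  c((2 * n_hom1 + n_het) / total, (2 * n_hom2 + n_het) / total)
}

#' Polymorphism information content
#'
#' For a biallelic locus PIC = 1 - (p1^2 + p2^2), bounded by 0.5, reached at
#' allele frequencies 0.5/0.5.
#'
#' @param freqs Non-negative allele frequencies summing to 1 (within 1e-9).
#' @return The PIC value.
#' @export
compute_pic <- function(freqs) {
  if (any(freqs < 0)) stop("negative allele frequency")
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop("allele frequencies must sum to 1 (got ", sum(freqs), ")")
  }
  1 - sum(freqs^2)
}

#' Per-marker summary statistics
#'
#' For every marker: major and minor allele frequency (gene counting),
#' proportion of non-missing calls that are heterozygous, proportion of
#' missing calls, and PIC. Markers with no non-missing calls get `NA`
#' frequencies/PIC and are flagged.
#'
#' @param gm A `geno_matrix`.
#' @return List with `$per_marker` (data.frame, one row per marker) and
#'   `$panel` (min/mean/max of each statistic over markers with defined
#'   values).
#' @export
marker_summary_table <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  n <- nrow(gm$calls)
  rows <- lapply(seq_len(ncol(gm$calls)), function(j) {
    st <- gm$calls[, j]
    f <- .allele_freq_one(st)
    n_called <- sum(!is.na(st))
    maf <- if (anyNA(f)) NA_real_ else max(f)
    mnaf <- if (anyNA(f)) NA_real_ else min(f)
    data.frame(
      marker_id = gm$panel$marker_id[j],
      n_called = n_called,
      maf = maf, mnaf = mnaf,
      pr_het = if (n_called > 0) sum(st == "HET", na.rm = TRUE) / n_called else NA_real_,
      pr_missing = (n - n_called) / n,
      pic = if (anyNA(f)) NA_real_ else compute_pic(f),
      all_missing = n_called == 0,
      stringsAsFactors = FALSE
    )
  })
  per_marker <- do.call(rbind, rows)
  stats <- c("maf", "mnaf", "pr_het", "pr_missing", "pic")
  panel <- data.frame(
    statistic = stats,
    min = vapply(stats, function(s) min(per_marker[[s]], na.rm = TRUE), numeric(1)),
    mean = vapply(stats, function(s) mean(per_marker[[s]], na.rm = TRUE), numeric(1)),
    max = vapply(stats, function(s) max(per_marker[[s]], na.rm = TRUE), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_marker = per_marker, panel = panel)
}

#' Screen markers against the QC panel admission criteria
#'
#' A marker is `biased` when either allele is called more than
#' `bias_threshold` of the time (i.e. MAF > 0.75 by default, the neutrality
#' screen), and fails the heterozygosity screen when its proportion of
#' heterozygous calls is `het_threshold` or more (the "< 4% heterozygous
#' calls" admission rule). A marker passes when neither flag is raised.
#'
#' @param summary The `$per_marker` data.frame from [marker_summary_table()]
#'   (or any data.frame with `marker_id`, `maf`, `pr_het`).
#' @param bias_threshold Major-allele-frequency bound (strict `>` flags bias).
#' @param het_threshold Heterozygosity bound (calls with `pr_het >=` this fail).
#' @return Data.frame: `marker_id`, `biased`, `het_fail`, `pass`.
#' @export
screen_marker <- function(summary, bias_threshold = 0.75, het_threshold = 0.04) {
  stopifnot(all(c("marker_id", "maf", "pr_het") %in% names(summary)))
  biased <- summary$maf > bias_threshold
  het_fail <- summary$pr_het >= het_threshold
  data.frame(marker_id = summary$marker_id,
             biased = biased, het_fail = het_fail,
             pass = !biased & !het_fail,
             stringsAsFactors = FALSE)
}

#' Filter a genotype dataset on missingness and minor allele frequency
#'
#' Samples whose proportion of missing calls exceeds
#' `max_missing_per_sample` (strictly) are removed first; then markers whose
#' minor allele frequency, recomputed on the surviving samples, falls below
#' `min_mnaf` (strictly) are removed. Row and column order is preserved.
#'
#' @param gm A `geno_matrix`.
#' @param max_missing_per_sample Per-sample missingness ceiling in \[0,1\]
#'   (default 0.10, the "more than 10% missing" removal rule).
#' @param min_mnaf Minor-allele-frequency floor in \[0,1\] (default 0.05).
#'   Markers with undefined frequencies (all calls missing) are removed
#'   whenever `min_mnaf > 0`.
#' @return The filtered `geno_matrix`, with attribute `removal`: a list of
#'   `samples_removed` and `markers_removed`.
#' @export
filter_dataset <- function(gm, max_missing_per_sample = 0.10, min_mnaf = 0.05) {
  stopifnot(inherits(gm, "geno_matrix"),
            max_missing_per_sample >= 0, max_missing_per_sample <= 1,
            min_mnaf >= 0, min_mnaf <= 1)
  pr_missing <- rowMeans(is.na(gm$calls))
  keep_samples <- pr_missing <= max_missing_per_sample
  if (!any(keep_samples)) {
    stop("all samples exceed the missingness threshold; nothing retained")
  }
  calls <- gm$calls[keep_samples, , drop = FALSE]
  mnaf <- apply(calls, 2, function(st) {
    f <- .allele_freq_one(st)
    if (anyNA(f)) 0 else min(f)
  })
  keep_markers <- mnaf >= min_mnaf
  out <- geno_matrix(calls[, keep_markers, drop = FALSE],
                     validate_marker_panel(gm$panel[keep_markers, , drop = FALSE]))
  attr(out, "removal") <- list(
    samples_removed = gm$sample_ids[!keep_samples],
    markers_removed = gm$panel$marker_id[!keep_markers]
  )
  out
}

#' Parental fingerprint report
#'
#' A fingerprint is a sample's ordered per-marker call string rendered with
#' the panel alleles (e.g. `"T:T|T:C|?"`, `?` for missing). A fingerprint is
#' `reliable` when the sample's missingness does not exceed
#' `reliability_threshold` (default 0.55: profiles with more than 55% missing
#' SNP information are unreliable).
#'
#' @param gm A `geno_matrix`.
#' @param sample_ids Samples to report (default all).
#' @param reliability_threshold Missingness bound in \[0,1\].
#' @return Data.frame: `sample_id`, `call_string`, `pr_missing`, `pr_het`,
#'   `reliable`.
#' @export
fingerprint_report <- function(gm, sample_ids = gm$sample_ids,
                               reliability_threshold = 0.55) {
  stopifnot(inherits(gm, "geno_matrix"))
  unknown <- setdiff(sample_ids, gm$sample_ids)
  if (length(unknown) > 0) {
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "))
  }
  panel <- gm$panel
  token <- function(st, j) {
    if (is.na(st)) return("?")
    switch(st,
           HOM1 = paste0(panel$allele1[j], ":", panel$allele1[j]),
           HOM2 = paste0(panel$allele2[j], ":", panel$allele2[j]),
           HET = paste0(panel$allele1[j], ":", panel$allele2[j]))
  }
  rows <- lapply(sample_ids, function(id) {
    st <- gm$calls[id, ]
    n_called <- sum(!is.na(st))
    pr_missing <- mean(is.na(st))
    data.frame(
      sample_id = id,
      call_string = paste(vapply(seq_along(st), function(j) token(st[[j]], j),
                                 character(1)), collapse = "|"),
      pr_missing = pr_missing,
      pr_het = if (n_called > 0) sum(st == "HET", na.rm = TRUE) / n_called else NA_real_,
      reliable = pr_missing <= reliability_threshold,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Per-sample heterozygosity and missingness
#'
#' @param gm A `geno_matrix`.
#' @return Data.frame: `sample_id`, `pr_het` (share of non-missing calls that
#'   are heterozygous), `pr_missing`.
#' @export
sample_heterozygosity <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  n_called <- rowSums(!is.na(gm$calls))
  n_het <- rowSums(gm$calls == "HET", na.rm = TRUE)
  data.frame(sample_id = gm$sample_ids,
             pr_het = ifelse(n_called > 0, n_het / n_called, NA_real_),
             pr_missing = rowMeans(is.na(gm$calls)),
             stringsAsFactors = FALSE)
}
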