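# F1 hybridity authentication.
#
# A putative F1 is diagnosed at informative loci only (markers where its two
# parents are opposite homozygotes). Hybridity = 100 * L_het / (evaluable
# informative loci), where L_het counts loci at which the F1 is heterozygous.
# F1 calls missing at informative loci are dropped from both numerator and
# denominator. Classification: below 20% hybridity the sample is regarded as
# a self; at or above, a true hybrid.

.HYBRIDITY_CATEGORIES <- c("TRUE_HYBRID", "SELF",
                           "UNDETERMINED_MISSING", "UNDETERMINED_NO_POLYMORPHISM")

#' Classify one putative F1
#'
#' @param f1_calls Call-state vector for the F1, aligned to the panel.
#' @param pair_scores Integer 1/0/NA polymorphism scores for the F1's
#'   parental pair (see [score_parental_pair()]).
#' @param threshold Hybridity percentage below which the sample is a self
#'   (default 20; the boundary itself classifies as TRUE_HYBRID).
#' @param min_informative Minimum evaluable informative loci required to call
#'   a sample (default 1). Fewer than 3 informative markers weakens the
#'   diagnosis; see the `low_power` flag.
#' @param female_calls,male_calls Optional parental call vectors; when given,
#'   F1 homozygous calls matching the male at informative loci are counted in
#'   `n_male_hom`, a pollen-contamination/outcross signal inconsistent with
#'   selfing.
#' @return One-row data.frame: `L_het`, `Pm` (informative loci of the pair),
#'   `n_missing_informative`, `n_evaluable`, `hybridity_percent`, `category`,
#'   `n_male_hom`, `low_power`.
#' @export
classify_f1 <- function(f1_calls, pair_scores, threshold = 20,
                        min_informative = 1,
                        female_calls = NULL, male_calls = NULL) {
  if (length(f1_calls) != length(pair_scores)) {
    stop("f1_calls and pair_scores differ in length")
  }
  informative <- which(!is.na(pair_scores) & pair_scores == 1L)
  Pm <- length(informative)
  st <- f1_calls[informative]
  evaluable <- informative[!is.na(st)]
  n_eval <- length(evaluable)
  n_missing_informative <- Pm - n_eval
  L_het <- sum(f1_calls[evaluable] == "HET")
  n_male_hom <- NA_integer_
  if (!is.null(male_calls)) {
    n_male_hom <- sum(f1_calls[evaluable] != "HET" &
                        f1_calls[evaluable] == male_calls[evaluable])
  }
  if (Pm == 0) {
    category <- "UNDETERMINED_NO_POLYMORPHISM"
    pct <- NA_real_
  } else if (n_eval < min_informative) {
    category <- "UNDETERMINED_MISSING"
    pct <- NA_real_
  } else {
    pct <- 100 * L_het / n_eval
    category <- if (pct >= threshold) "TRUE_HYBRID" else "SELF"
  }
  data.frame(L_het = L_het, Pm = Pm,
             n_missing_informative = n_missing_informative,
             n_evaluable = n_eval,
             hybridity_percent = pct,
             category = factor(category, levels = .HYBRIDITY_CATEGORIES),
             n_male_hom = n_male_hom,
             low_power = Pm < 3,
             stringsAsFactors = FALSE)
}

#' Classify every putative F1 of a design
#'
#' @param gm A `geno_matrix` containing the F1 samples (and, for the outcross
#'   flag, the parents).
#' @param design A `cross_design`.
#' @param pairs Optional precomputed [pair_polymorphism_table()]; computed
#'   from `gm` and `design` when omitted.
#' @param threshold,min_informative See [classify_f1()].
#' @return Data.frame, one row per F1 present in `gm`: `f1_id`, `cross_id`
#'   plus the [classify_f1()] columns. F1s absent from the genotype table are
#'   dropped with a warning.
#' @export
hybridity_table <- function(gm, design, pairs = NULL, threshold = 20,
                            min_informative = 1) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(design, "cross_design"))
  if (is.null(pairs)) pairs <- pair_polymorphism_table(gm, design)
  f1_map <- design$f1_map
  present <- f1_map$f1_id %in% gm$sample_ids
  if (!all(present)) {
    warning(sum(!present), " F1 sample(s) absent from the genotype table; dropped")
    f1_map <- f1_map[present, , drop = FALSE]
  }
  crosses <- design$crosses
  rows <- lapply(seq_len(nrow(f1_map)), function(i) {
    cid <- f1_map$cross_id[i]
    k <- match(cid, crosses$cross_id)
    if (is.na(k)) stop("F1 ", f1_map$f1_id[i], " not assigned to a known cross")
    fem <- crosses$female_id[k]; mal <- crosses$male_id[k]
    res <- classify_f1(
      gm$calls[f1_map$f1_id[i], ], pairs$scores[cid, ],
      threshold = threshold, min_informative = min_informative,
      female_calls = if (fem %in% gm$sample_ids) gm$calls[fem, ],
      male_calls = if (mal %in% gm$sample_ids) gm$calls[mal, ]
    )
    cbind(data.frame(f1_id = f1_map$f1_id[i], cross_id = cid,
                     stringsAsFactors = FALSE), res)
  })
  do.call(rbind, rows)
}

#' Per-cross hybridity success rates
#'
#' Success rate = `100 * n_true / n_total` where `n_true` counts TRUE_HYBRID
#' F1s. By default undetermined F1s are excluded from `n_total`; a cross with
#' no determined F1 gets an `NA` rate and is reported as undetermined.
#'
#' @param results Output of [hybridity_table()].
#' @param design A `cross_design`; crosses with no classified F1s are
#'   included with zero counts.
#' @param include_undetermined Count undetermined F1s in `n_total`?
#' @return Data.frame per cross: `cross_id`, `n_true`, `n_self`, `n_undet`,
#'   `n_total`, `success_rate`, `undetermined_cross`.
#' @export
cross_success_table <- function(results, design, include_undetermined = FALSE) {
  stopifnot(inherits(design, "cross_design"))
  ids <- design$crosses$cross_id
  cid <- factor(results$cross_id, levels = ids)
  n_true <- tapply(results$category == "TRUE_HYBRID", cid, sum, default = 0L)
  n_self <- tapply(results$category == "SELF", cid, sum, default = 0L)
  n_undet <- tapply(grepl("^UNDETERMINED", results$category), cid, sum, default = 0L)
  n_total <- if (include_undetermined) n_true + n_self + n_undet else n_true + n_self
  data.frame(
    cross_id = ids,
    n_true = as.integer(n_true), n_self = as.integer(n_self),
    n_undet = as.integer(n_undet), n_total = as.integer(n_total),
    success_rate = ifelse(n_total > 0, 100 * n_true / n_total, NA_real_),
    undetermined_cross = n_total == 0 & (n_undet > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Distribution of per-cross success rates
#'
#' Bins crosses into full success (100%), intermediate, zero success, and
#' undetermined — the shape of the cohort's success histogram.
#'
#' @param success Output of [cross_success_table()].
#' @return Data.frame: `bin`, `n`, `percent` (over all crosses).
#' @export
success_rate_distribution <- function(success) {
  r <- success$success_rate
  bin <- ifelse(is.na(r), "undetermined",
                ifelse(r == 100, "100%", ifelse(r == 0, "0%", "intermediate")))
  bin <- factor(bin, levels = c("100%", "intermediate", "0%", "undetermined"))
  tab <- table(bin)
  data.frame(bin = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / length(r),
             stringsAsFactors = FALSE)
}

# Half-up rounding to integer percent; R's round() is round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Cohort-level hybridity summary
#'
#' Counts and percentages of the four hybridity categories over all
#' classified F1s, plus the combined undetermined total. Percentages are
#' reported unrounded and rounded half-up to integer percent.
#'
#' @param results Output of [hybridity_table()], or a character/factor vector
#'   of categories.
#' @return List: `$categories` (data.frame: `category`, `n`, `percent`,
#'   `percent_rounded`), `$n_total`, `$undetermined` (combined count and
#'   percentages).
#' @export
cohort_summary <- function(results) {
  cats <- if (is.data.frame(results)) results$category else results
  cats <- factor(as.character(cats), levels = .HYBRIDITY_CATEGORIES)
  if (anyNA(cats)) stop("unknown hybridity category")
  n_total <- length(cats)
  if (n_total == 0) stop("no hybridity results to summarise")
  tab <- table(cats)
  pct <- 100 * as.integer(tab) / n_total
  categories <- data.frame(category = names(tab), n = as.integer(tab),
                           percent = pct,
                           percent_rounded = round_half_up(pct),
                           stringsAsFactors = FALSE)
  n_undet <- sum(tab[c("UNDETERMINED_MISSING", "UNDETERMINED_NO_POLYMORPHISM")])
  list(categories = categories, n_total = n_total,
       undetermined = list(n = as.integer(n_undet),
                           percent = 100 * n_undet / n_total,
                           percent_rounded = round_half_up(100 * n_undet / n_total)))
}

#' Heterozygosity contrast between parents and F1s
#'
#' Raw per-sample heterozygosity (share of non-missing calls that are HET)
#' split into the parent and F1 groups of a design, with group min/mean/max
#' and a binned tabulation: samples exceeding `max_missing` missingness form
#' a "filtered" class; the rest are binned at 0%, (0-6)%, 6-10% and >10%
#' heterozygosity.
#'
#' @param gm A `geno_matrix` holding parents and F1s.
#' @param design A `cross_design`.
#' @param max_missing Missingness ceiling for the binned tabulation
#'   (default 0.10).
#' @return List: `$samples` (per-sample `pr_het`, `pr_missing`, `group`),
#'   `$group_stats` (min/mean/max `pr_het` per group, over unfiltered
#'   samples), `$bins` (counts per group and heterozygosity class).
#' @export
heterozygosity_contrast <- function(gm, design, max_missing = 0.10) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(design, "cross_design"))
  ds <- design_samples(design)
  het <- sample_heterozygosity(gm)
  het$group <- ifelse(het$sample_id %in% ds$parents, "parent",
                      ifelse(het$sample_id %in% ds$f1s, "F1", "unassigned"))
  het <- het[het$group != "unassigned", , drop = FALSE]
  kept <- het[het$pr_missing <= max_missing & !is.na(het$pr_het), , drop = FALSE]
  group_stats <- do.call(rbind, lapply(split(kept$pr_het, kept$group), function(v) {
    data.frame(min = min(v), mean = mean(v), max = max(v))
  }))
  group_stats <- cbind(group = rownames(group_stats), group_stats)
  rownames(group_stats) <- NULL
  bin_of <- function(pr_het, pr_missing) {
    ifelse(pr_missing > max_missing | is.na(pr_het), "filtered",
           ifelse(pr_het == 0, "0%",
                  ifelse(pr_het < 0.06, "(0-6)%",
                         ifelse(pr_het <= 0.10, "6-10%", ">10%"))))
  }
  het$het_bin <- factor(bin_of(het$pr_het, het$pr_missing),
                        levels = c("0%", "(0-6)%", "6-10%", ">10%", "filtered"))
  bins <- as.data.frame(table(group = het$group, het_bin = het$het_bin),
                        stringsAsFactors = FALSE)
  names(bins)[3] <- "n"
  list(samples = het, group_stats = group_stats, bins = bins)
}
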