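# Synthetic crossing-programme cohorts with ground truth.
#
# The default configuration mirrors a large cowpea crossing block: 220
# inbred female parents in four source groups, two near-identical "sister
# line" males, 225 cross combinations and 1,436 putative F1s, of which a
# fraction s are accidental selfs. Parents are near-homozygous with a small
# residual heterozygosity; observation noise (per-call missingness and
# optional genotyping error) is applied after the true genotypes, and the
# truth labels are recorded pre-corruption.

#' Simulation configuration
#'
#' Defaults describe the reference crossing-programme scenario: the four
#' female source groups (89 + 31 + 85 + 15 = 220 lines, of which 3 + 2 are
#' crossed to both males), 225 crosses, 1,436 F1s split 428/214/637/157 over
#' the groups, selfing rate 0.15, residual parental heterozygosity 0.02 per
#' locus, per-call missingness 0.05, no genotyping error, and sister males
#' that are genetically identical. Per-marker allele-1 frequencies default to
#' an evenly spaced 0.53-0.99 gradient (mean 0.76), matching a panel whose
#' major-allele frequencies average 0.76 in the breeding pool; use
#' `rep(0.5, 17)` for the neutral regime the panel was screened for.
#'
#' @param n_females Number of female parents.
#' @param groups Named integer vector of females per source group.
#' @param f1_group_totals Named integer vector of F1 counts per source group
#'   (allocated as evenly as possible over the group's crosses).
#' @param selfing_rate Probability that a putative F1 is a self.
#' @param allele1_freq Per-marker probability that a parent is homozygous for
#'   allele 1 (length = panel size, recycled if scalar).
#' @param residual_het_rate Per parent per locus heterozygosity rate.
#' @param missing_rate Per-call missingness rate applied at observation.
#' @param genotyping_error_rate Per-call probability that an observed call is
#'   replaced by a uniformly chosen different state.
#' @param sister_male_divergence Number of loci at which male 2 differs from
#'   male 1 (0 = identical sister lines).
#' @param seed Optional RNG seed for reproducibility.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_females = 220,
                       groups = c(IET = 89, PYT = 31, AYT = 85, landrace = 15),
                       f1_group_totals = c(IET = 428, PYT = 214, AYT = 637,
                                           landrace = 157),
                       selfing_rate = 0.15,
                       allele1_freq = seq(0.53, 0.99, length.out = 17),
                       residual_het_rate = 0.02,
                       missing_rate = 0.05,
                       genotyping_error_rate = 0,
                       sister_male_divergence = 0,
                       seed = NULL) {
  rates <- c(selfing_rate, residual_het_rate, missing_rate,
             genotyping_error_rate, allele1_freq)
  if (any(rates < 0 | rates > 1)) stop("all rates/frequencies must be in [0,1]")
  if (sum(groups) != n_females) {
    stop("group sizes (", sum(groups), ") must sum to n_females (", n_females, ")")
  }
  if (!identical(names(groups), names(f1_group_totals))) {
    stop("groups and f1_group_totals must share names")
  }
  structure(list(n_females = n_females, groups = groups,
                 f1_group_totals = f1_group_totals,
                 selfing_rate = selfing_rate, allele1_freq = allele1_freq,
                 residual_het_rate = residual_het_rate,
                 missing_rate = missing_rate,
                 genotyping_error_rate = genotyping_error_rate,
                 sister_male_divergence = sister_male_divergence,
                 seed = seed),
            class = "sim_config")
}

# Study-like crossing structure: most crosses use male 1; a fixed number per
# group (reusing some females) also cross to male 2.
.MALE_IDS <- c("MALE-573-1", "MALE-573-2")

#' Simulated cross design
#'
#' Builds the crossing structure of the reference scenario. Per group with
#' `n` females, `k` male-2 crosses and `r` females used with both males: the
#' first `n - k + r` females cross male 1 and the last `k` cross male 2
#' (overlap `r`), so the group contributes `n + r` crosses. The default
#' groups give 92 + 33 + 85 + 15 = 225 crosses from 220 females, 5 of them
#' used twice. F1 counts per group are spread as evenly as possible over the
#' group's crosses.
#'
#' @param config A [sim_config()].
#' @return A `cross_design` with `source_group` set.
#' @export
simulate_design <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  groups <- config$groups
  female_ids <- sprintf("F%03d", seq_len(config$n_females))
  group_of <- rep(names(groups), groups)
  crosses <- data.frame(cross_id = character(0), female_id = character(0),
                        male_id = character(0), source_group = character(0),
                        stringsAsFactors = FALSE)
  # (male-2 crosses, reused females) per group: the reference structure for
  # the default group sizes, none otherwise
  default_groups <- length(groups) == 4 && all(unname(groups) == c(89, 31, 85, 15))
  male2_n <- if (default_groups) c(15L, 2L, 0L, 0L) else rep(0L, length(groups))
  reuse_n <- if (default_groups) c(3L, 2L, 0L, 0L) else rep(0L, length(groups))
  for (g in seq_along(groups)) {
    gf <- female_ids[group_of == names(groups)[g]]
    k <- male2_n[g]; r <- reuse_n[g]
    n1 <- length(gf) - k + r
    df1 <- data.frame(female_id = gf[seq_len(n1)], male_id = .MALE_IDS[1],
                      source_group = names(groups)[g], stringsAsFactors = FALSE)
    df2 <- if (k > 0) {
      data.frame(female_id = utils::tail(gf, k), male_id = .MALE_IDS[2],
                 source_group = names(groups)[g], stringsAsFactors = FALSE)
    } else NULL
    crosses <- rbind(crosses, df1, df2)
  }
  crosses$cross_id <- sprintf("C%03d", seq_len(nrow(crosses)))
  crosses <- crosses[, c("cross_id", "female_id", "male_id", "source_group")]
  # allocate per-group F1 totals over that group's crosses
  f1_lists <- vector("list", nrow(crosses))
  for (g in names(groups)) {
    idx <- which(crosses$source_group == g)
    total <- config$f1_group_totals[[g]]
    base <- total %/% length(idx)
    extra <- total %% length(idx)
    counts <- rep(base, length(idx)) + c(rep(1L, extra), rep(0L, length(idx) - extra))
    for (k in seq_along(idx)) {
      i <- idx[k]
      f1_lists[[i]] <- if (counts[k] > 0)
        sprintf("%s-P%02d", crosses$cross_id[i], seq_len(counts[k])) else character(0)
    }
  }
  cross_design(crosses, f1_lists)
}

#' Simulate parental genotypes
#'
#' Each parent draws HOM1 at locus j with probability `allele1_freq[j]`, HOM2
#' otherwise, then flips to HET with `residual_het_rate`. Male 2 is a copy of
#' male 1 diverging at `sister_male_divergence` homozygous loci (opposite
#' homozygote). These are true genotypes: observation noise is applied
#' separately (see [simulate_cohort()]).
#'
#' @param config A [sim_config()].
#' @param panel A `marker_panel` (defaults to the bundled 17-SNP panel).
#' @return A `geno_matrix` of the females then the two males, with attribute
#'   `true_het_loci`: a list per parent of its residual-heterozygous loci.
#' @export
simulate_parents <- function(config = sim_config(),
                             panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- rep_len(config$allele1_freq, nrow(panel))
  draw_parent <- function() {
    st <- ifelse(stats::runif(nrow(panel)) < p, "HOM1", "HOM2")
    het <- stats::runif(nrow(panel)) < config$residual_het_rate
    st[het] <- "HET"
    st
  }
  female_ids <- sprintf("F%03d", seq_len(config$n_females))
  calls <- t(vapply(seq_len(config$n_females), function(i) draw_parent(),
                    character(nrow(panel))))
  male1 <- draw_parent()
  male2 <- male1
  if (config$sister_male_divergence > 0) {
    hom <- which(male2 != "HET")
    flip <- utils::head(sample(hom), config$sister_male_divergence)
    male2[flip] <- ifelse(male2[flip] == "HOM1", "HOM2", "HOM1")
  }
  calls <- rbind(calls, male1, male2)
  rownames(calls) <- c(female_ids, .MALE_IDS)
  colnames(calls) <- panel$marker_id
  gm <- geno_matrix(calls, panel)
  attr(gm, "true_het_loci") <- apply(calls, 1, function(s) which(s == "HET"),
                                     simplify = FALSE)
  gm
}

# One gamete per locus from a parent's call-state vector: HOM1 -> allele 1,
# HOM2 -> allele 2, HET -> either with probability 1/2. Encoded 1/2.
.gametes <- function(states) {
  g <- ifelse(states == "HOM1", 1L, ifelse(states == "HOM2", 2L, NA_integer_))
  het <- states == "HET"
  g[het] <- sample(1:2, sum(het), replace = TRUE)
  g
}

.zygote <- function(g1, g2) {
  ifelse(g1 == 1L & g2 == 1L, "HOM1",
         ifelse(g1 == 2L & g2 == 2L, "HOM2", "HET"))
}

#' Simulate putative F1 genotypes with truth labels
#'
#' Each putative F1 is a true hybrid with probability `1 - selfing_rate`
#' (one gamete from each parent; heterozygous parental loci transmit either
#' allele with probability 1/2) and otherwise a self of the female (two
#' female gametes, so a heterozygous female locus segregates 1:2:1). Truth is
#' recorded before any observation noise; this function returns clean
#' genotypes (see [corrupt_calls()] / [simulate_cohort()] for noise).
#'
#' @param parents True parental `geno_matrix` from [simulate_parents()].
#' @param design A `cross_design` referencing those parents.
#' @param config A [sim_config()].
#' @return List: `$genotypes` (a `geno_matrix` of the F1s), `$truth`
#'   (data.frame: `f1_id`, `cross_id`, `true_status` in HYBRID/SELF).
#' @export
simulate_f1_cohort <- function(parents, design, config = sim_config()) {
  stopifnot(inherits(parents, "geno_matrix"), inherits(design, "cross_design"))
  unknown <- setdiff(unique(c(design$crosses$female_id, design$crosses$male_id)),
                     parents$sample_ids)
  if (length(unknown) > 0) {
    stop("design references unknown parent(s): ", paste(unknown, collapse = ", "))
  }
  f1_map <- design$f1_map
  crosses <- design$crosses
  n <- nrow(f1_map)
  m <- ncol(parents$calls)
  calls <- matrix(NA_character_, nrow = n, ncol = m,
                  dimnames = list(f1_map$f1_id, colnames(parents$calls)))
  status <- character(n)
  for (i in seq_len(n)) {
    k <- match(f1_map$cross_id[i], crosses$cross_id)
    fem <- parents$calls[crosses$female_id[k], ]
    mal <- parents$calls[crosses$male_id[k], ]
    if (stats::runif(1) < config$selfing_rate) {
      status[i] <- "SELF"
      calls[i, ] <- .zygote(.gametes(fem), .gametes(fem))
    } else {
      status[i] <- "HYBRID"
      calls[i, ] <- .zygote(.gametes(fem), .gametes(mal))
    }
  }
  list(genotypes = geno_matrix(calls, parents$panel),
       truth = data.frame(f1_id = f1_map$f1_id, cross_id = f1_map$cross_id,
                          true_status = status, stringsAsFactors = FALSE))
}

#' Apply observation noise to a genotype matrix
#'
#' With probability `error_rate` a call is replaced by a uniformly chosen
#' different state (among HOM1/HOM2/HET); independently, with probability
#' `missing_rate` a call is set missing.
#'
#' @param gm A `geno_matrix` of true genotypes.
#' @param missing_rate,error_rate Per-call probabilities.
#' @return The corrupted `geno_matrix`.
#' @export
corrupt_calls <- function(gm, missing_rate = 0, error_rate = 0) {
  stopifnot(inherits(gm, "geno_matrix"))
  calls <- gm$calls
  if (error_rate > 0) {
    err <- which(!is.na(calls) & stats::runif(length(calls)) < error_rate)
    for (i in err) {
      calls[i] <- sample(setdiff(.CALL_STATES, calls[i]), 1)
    }
  }
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_character_
  }
  geno_matrix(calls, gm$panel)
}

#' Simulate a complete observed cohort
#'
#' Convenience wrapper: builds the design, draws true parents and F1s, then
#' applies per-call missingness and genotyping error to the merged observed
#' matrix (parents and F1s alike; gametes always come from the uncorrupted
#' parental genotypes).
#'
#' @param config A [sim_config()].
#' @param panel A `marker_panel` (defaults to the bundled panel).
#' @return List: `$genotypes` (observed merged `geno_matrix`), `$design`,
#'   `$truth`, `$parents_true`, `$f1_true`.
#' @export
simulate_cohort <- function(config = sim_config(),
                            panel = default_panel()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  design <- simulate_design(config)
  cfg_noseed <- config
  cfg_noseed$seed <- NULL  # seed already consumed; keep one RNG stream
  parents <- simulate_parents(cfg_noseed, panel)
  f1 <- simulate_f1_cohort(parents, design, cfg_noseed)
  observed <- corrupt_calls(bind_samples(parents, f1$genotypes),
                            missing_rate = config$missing_rate,
                            error_rate = config$genotyping_error_rate)
  list(genotypes = observed, design = design, truth = f1$truth,
       parents_true = parents, f1_true = f1$genotypes)
}

#' Classifier recovery report against simulation truth
#'
#' Restricted to determined F1s (TRUE_HYBRID or SELF): the confusion matrix
#' of truth vs. call, the estimated selfing rate (classified-SELF fraction
#' among determined samples), and sensitivity/specificity for detecting
#' selfs.
#'
#' @param results Output of [hybridity_table()].
#' @param truth Truth data.frame from the simulator.
#' @return List: `$confusion`, `$s_hat`, `$sensitivity_self`,
#'   `$specificity_self`, `$n_determined`, `$n_discordant`.
#' @export
recovery_report <- function(results, truth) {
  merged <- merge(results[, c("f1_id", "category")],
                  truth[, c("f1_id", "true_status")], by = "f1_id")
  if (nrow(merged) != nrow(results)) {
    stop("truth labels do not cover every classified F1")
  }
  det <- merged[merged$category %in% c("TRUE_HYBRID", "SELF"), , drop = FALSE]
  called_self <- det$category == "SELF"
  true_self <- det$true_status == "SELF"
  confusion <- table(truth = det$true_status,
                     called = droplevels(det$category))
  list(confusion = confusion,
       s_hat = mean(called_self),
       sensitivity_self = if (any(true_self)) mean(called_self[true_self]) else NA_real_,
       specificity_self = if (any(!true_self)) mean(!called_self[!true_self]) else NA_real_,
       n_determined = nrow(det),
       n_discordant = sum(called_self != true_self))
}
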