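# Per-cross marker polymorphism and per-marker efficiency.
#
# A marker is informative (polymorphic) for a cross when the two parents are
# opposite homozygotes there; only such loci can expose hybridity as
# heterozygosity in the F1. Scores follow the 1 / 0 / NA convention:
# 1 = polymorphic, 0 = not polymorphic, NA = not evaluable.

#' Score marker polymorphism between the two parents of a cross
#'
#' @param female_calls,male_calls Call-state vectors aligned to the same
#'   panel (`"HOM1"`/`"HOM2"`/`"HET"`/`NA`).
#' @param het_policy What a heterozygous parent call scores: `"na"` (default;
#'   hybridity at such a locus is undiagnosable, so it is uninformative) or
#'   `"zero"` (counted as not polymorphic).
#' @return Integer vector per marker: 1 when the parents are opposite
#'   homozygotes, 0 when identical homozygotes, NA when either call is
#'   missing (or heterozygous, under the default policy).
#' @export
score_parental_pair <- function(female_calls, male_calls,
                                het_policy = c("na", "zero")) {
  het_policy <- match.arg(het_policy)
  if (length(female_calls) != length(male_calls)) {
    stop("parental call vectors differ in length")
  }
  score <- rep(NA_integer_, length(female_calls))
  has_het <- !is.na(female_calls) & female_calls == "HET" |
    !is.na(male_calls) & male_calls == "HET"
  both_hom <- !is.na(female_calls) & !is.na(male_calls) &
    female_calls %in% c("HOM1", "HOM2") & male_calls %in% c("HOM1", "HOM2")
  score[both_hom] <- as.integer(female_calls[both_hom] != male_calls[both_hom])
  if (het_policy == "zero") score[has_het & !is.na(female_calls) & !is.na(male_calls)] <- 0L
  else score[has_het] <- NA_integer_
  score
}

#' Percent parental marker polymorphism of one cross
#'
#' `100 * Pm / Tm`, where `Pm` is the number of markers scoring 1 and `Tm`
#' the number of evaluable (non-NA) markers for that parent pair.
#'
#' @param scores Integer score vector from [score_parental_pair()].
#' @return Percentage in \[0, 100\], or `NA` when no marker is evaluable
#'   (`Tm = 0`), in which case the cross carries no informative data.
#' @export
percent_parental_polymorphism <- function(scores) {
  Tm <- sum(!is.na(scores))
  if (Tm == 0) return(NA_real_)
  100 * sum(scores == 1L, na.rm = TRUE) / Tm
}

#' Polymorphism scores for every cross in a design
#'
#' @param gm A `geno_matrix` containing the parents.
#' @param design A `cross_design`.
#' @param het_policy Passed to [score_parental_pair()].
#' @return List of class `pair_polymorphism`:
#'   `$scores` — crosses x markers integer matrix of 1/0/NA scores;
#'   `$pairs` — data.frame per cross with `Pm` (markers scoring 1), `Tm`
#'   (evaluable markers), `percent` (`100*Pm/Tm`, NA when `Tm = 0`) and a
#'   `no_data` flag. Crosses whose parents are absent from `gm` get all-NA
#'   scores and a warning.
#' @export
pair_polymorphism_table <- function(gm, design, het_policy = c("na", "zero")) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(design, "cross_design"))
  het_policy <- match.arg(het_policy)
  crosses <- design$crosses
  m <- ncol(gm$calls)
  scores <- matrix(NA_integer_, nrow = nrow(crosses), ncol = m,
                   dimnames = list(crosses$cross_id, gm$panel$marker_id))
  absent <- character(0)
  for (i in seq_len(nrow(crosses))) {
    f <- crosses$female_id[i]; ml <- crosses$male_id[i]
    if (!(f %in% gm$sample_ids) || !(ml %in% gm$sample_ids)) {
      absent <- c(absent, crosses$cross_id[i])
      next
    }
    scores[i, ] <- score_parental_pair(gm$calls[f, ], gm$calls[ml, ], het_policy)
  }
  if (length(absent) > 0) {
    warning("parent genotypes missing for cross(es): ",
            paste(utils::head(absent, 10L), collapse = ", "),
            if (length(absent) > 10L) ", ..." else "",
            "; scored as all-NA")
  }
  Pm <- rowSums(scores == 1L, na.rm = TRUE)
  Tm <- rowSums(!is.na(scores))
  pairs <- data.frame(
    cross_id = crosses$cross_id,
    female_id = crosses$female_id,
    male_id = crosses$male_id,
    Pm = Pm, Tm = Tm,
    percent = ifelse(Tm > 0, 100 * Pm / Tm, NA_real_),
    no_data = Tm == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(scores = scores, pairs = pairs, het_policy = het_policy),
            class = "pair_polymorphism")
}

#' @export
print.pair_polymorphism <- function(x, ...) {
  cat("pair_polymorphism:", nrow(x$pairs), "crosses x", ncol(x$scores),
      "markers; mean % polymorphism",
      sprintf("%.1f", mean(x$pairs$percent, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Marker efficiency across all parental pairs
#'
#' For each marker: `fm`, the number of crosses in which it is polymorphic,
#' over `Tc`, the number of crosses in which it is evaluable (pairs with a
#' missing call at that marker are excluded from the denominator); efficiency
#' is `100 * fm / Tc`.
#'
#' @param pairs A `pair_polymorphism` object (or its `$scores` matrix).
#' @return List with `$per_marker` (data.frame: `marker_id`, `fm`, `Tc`,
#'   `percent`, `undefined` flag when `Tc = 0`) and `$panel`
#'   (min/mean/max efficiency over markers with defined values).
#' @export
marker_efficiency_table <- function(pairs) {
  scores <- if (inherits(pairs, "pair_polymorphism")) pairs$scores else pairs
  stopifnot(is.matrix(scores))
  fm <- as.integer(colSums(scores == 1L, na.rm = TRUE))
  Tc <- as.integer(colSums(!is.na(scores)))
  percent <- ifelse(Tc > 0, 100 * fm / Tc, NA_real_)
  per_marker <- data.frame(marker_id = colnames(scores),
                           fm = fm, Tc = Tc, percent = percent,
                           undefined = Tc == 0,
                           stringsAsFactors = FALSE, row.names = NULL)
  defined <- per_marker$percent[!is.na(per_marker$percent)]
  panel <- data.frame(min = min(defined), mean = mean(defined), max = max(defined))
  list(per_marker = per_marker, panel = panel)
}

#' Distribution of informative markers over crosses
#'
#' @param pairs A `pair_polymorphism` object.
#' @param breaks Percent-polymorphism histogram breaks (default steps of 10).
#' @return List: `$pm_counts` — number of crosses per informative-marker
#'   count `Pm`; `$percent_hist` — crosses per percent bin; `$left_tail` —
#'   cross IDs with at most 2 informative markers, whose F1s are at risk of
#'   being undeterminable.
#' @export
informative_marker_distribution <- function(pairs, breaks = seq(0, 100, by = 10)) {
  stopifnot(inherits(pairs, "pair_polymorphism"))
  p <- pairs$pairs
  pm_counts <- table(factor(p$Pm, levels = 0:ncol(pairs$scores)))
  pct <- p$percent[!is.na(p$percent)]
  percent_hist <- table(cut(pct, breaks = breaks, include.lowest = TRUE, right = TRUE))
  list(pm_counts = pm_counts,
       percent_hist = percent_hist,
       left_tail = p$cross_id[p$Pm <= 2])
}
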