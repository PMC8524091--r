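# Shared scaffold: two fully homozygous opposite parents over 6 informative
# loci (panel of 8; loci 7-8 monomorphic between the parents).
hyb_scaffold <- function() {
  panel <- wide_panel(8)
  gm <- gm_from_codes(list(fem = "11111111", mal = "22222211"), panel)
  scores <- score_parental_pair(gm$calls["fem", ], gm$calls["mal", ])
  list(panel = panel, gm = gm, scores = scores)
}

test_that("classification covers hybrid, self, threshold and degenerate cases", {
  sc <- hyb_scaffold()
  expect_equal(sum(sc$scores == 1L, na.rm = TRUE), 6L)
  het6 <- c(rep("HET", 6), "HOM1", "HOM1")
  r <- classify_f1(het6, sc$scores)
  expect_equal(r$hybridity_percent, 100)
  expect_equal(as.character(r$category), "TRUE_HYBRID")
  # identical to the female at informative loci -> 0% -> self
  r <- classify_f1(rep("HOM1", 8), sc$scores)
  expect_equal(r$hybridity_percent, 0)
  expect_equal(as.character(r$category), "SELF")
  # 1 het of 6 informative = 16.67% < 20 -> self
  r <- classify_f1(c("HET", rep("HOM1", 7)), sc$scores)
  expect_equal(r$hybridity_percent, 100 / 6, tolerance = 1e-12)
  expect_equal(round(r$hybridity_percent, 2), 16.67)
  expect_equal(as.character(r$category), "SELF")
  # boundary: exactly 20% goes to TRUE_HYBRID (1 het of 5 evaluable)
  r <- classify_f1(c("HET", rep("HOM1", 4), NA, "HOM1", "HOM1"), sc$scores)
  expect_equal(r$n_evaluable, 5L)
  expect_equal(r$hybridity_percent, 20)
  expect_equal(as.character(r$category), "TRUE_HYBRID")
  # no polymorphism at all
  r <- classify_f1(rep("HOM1", 8), rep(0L, 8))
  expect_equal(as.character(r$category), "UNDETERMINED_NO_POLYMORPHISM")
  expect_equal(r$Pm, 0L)
  # all informative loci missing in the F1
  r <- classify_f1(c(rep(NA, 6), "HOM1", "HOM1"), sc$scores)
  expect_equal(as.character(r$category), "UNDETERMINED_MISSING")
  expect_equal(r$n_missing_informative, 6L)
})

test_that("missing informative loci leave numerator and denominator together", {
  sc <- hyb_scaffold()
  # 2 het, 2 hom, 2 missing among the 6 informative loci -> 2/4 = 50%
  f1 <- c("HET", "HET", "HOM1", "HOM1", NA, NA, "HOM1", "HOM1")
  r <- classify_f1(f1, sc$scores)
  expect_equal(r$L_het, 2L)
  expect_equal(r$n_evaluable, 4L)
  expect_equal(r$hybridity_percent, 50)
  # min_informative gates the call
  r <- classify_f1(c("HET", rep(NA, 5), "HOM1", "HOM1"), sc$scores,
                   min_informative = 3)
  expect_equal(as.character(r$category), "UNDETERMINED_MISSING")
})

test_that("raising the threshold never converts a self into a true hybrid", {
  sc <- hyb_scaffold()
  set.seed(5)
  for (i in 1:25) {
    f1 <- sample(c("HOM1", "HOM2", "HET", NA), 8, replace = TRUE)
    lo <- classify_f1(f1, sc$scores, threshold = 20)
    hi <- classify_f1(f1, sc$scores, threshold = 60)
    if (as.character(lo$category) == "SELF") {
      expect_equal(as.character(hi$category), "SELF")
    }
    # categories that are undetermined are threshold-invariant
    if (grepl("UNDETERMINED", lo$category)) {
      expect_equal(as.character(hi$category), as.character(lo$category))
    }
  }
})

test_that("male-homozygote calls at informative loci raise the outcross flag", {
  sc <- hyb_scaffold()
  f1 <- c("HOM2", "HOM2", "HET", "HOM1", "HOM1", "HOM1", "HOM1", "HOM1")
  r <- classify_f1(f1, sc$scores,
                   female_calls = sc$gm$calls["fem", ],
                   male_calls = sc$gm$calls["mal", ])
  expect_equal(r$n_male_hom, 2L)
})

test_that("cross success rates and their distribution bin correctly", {
  design <- cross_design(
    data.frame(cross_id = c("a", "b", "c", "d"),
               female_id = paste0("f", 1:4), male_id = "m",
               stringsAsFactors = FALSE),
    list(paste0("a", 1:4), paste0("b", 1:2), "c1", "d1"))
  results <- data.frame(
    f1_id = c(paste0("a", 1:4), "b1", "b2", "c1", "d1"),
    cross_id = c(rep("a", 4), "b", "b", "c", "d"),
    category = factor(c("TRUE_HYBRID", "TRUE_HYBRID", "SELF", "TRUE_HYBRID",
                        "TRUE_HYBRID", "TRUE_HYBRID", "SELF",
                        "UNDETERMINED_NO_POLYMORPHISM"),
                      levels = hybriqc:::.HYBRIDITY_CATEGORIES))
  cs <- cross_success_table(results, design)
  expect_equal(cs$success_rate, c(75, 100, 0, NA))
  expect_true(cs$undetermined_cross[4])
  dist <- success_rate_distribution(cs)
  expect_equal(dist$n, c(1L, 1L, 1L, 1L))
  # undetermined F1s counted in the denominator when requested
  cs2 <- cross_success_table(results, design, include_undetermined = TRUE)
  expect_equal(cs2$n_total[4], 1L)
  expect_equal(cs2$success_rate[4], 0)
})

test_that("cohort summary reports counts and half-up integer percentages", {
  cats <- c(rep("TRUE_HYBRID", 1131), rep("SELF", 205),
            rep("UNDETERMINED_MISSING", 86), rep("UNDETERMINED_NO_POLYMORPHISM", 14))
  s <- cohort_summary(cats)
  expect_equal(s$n_total, 1436L)
  expect_equal(s$categories$n, c(1131L, 205L, 86L, 14L))
  expect_equal(s$categories$percent_rounded[1:2], c(79, 14))
  expect_equal(s$undetermined$n, 100L)
  expect_equal(s$undetermined$percent_rounded, 7)
  # unrounded percentages sum to exactly 100
  expect_equal(sum(s$categories$percent), 100)
  # degenerate cohorts
  one <- cohort_summary("SELF")
  expect_equal(one$categories$percent[one$categories$category == "SELF"], 100)
  all_true <- cohort_summary(rep("TRUE_HYBRID", 10))
  expect_equal(all_true$categories$percent, c(100, 0, 0, 0))
})

test_that("classification is invariant to sample order", {
  cfg <- sim_config(n_females = 12, groups = c(G = 12),
                    f1_group_totals = c(G = 36), selfing_rate = 0.3,
                    allele1_freq = rep(0.5, 17), missing_rate = 0.05,
                    seed = 99)
  sim <- simulate_cohort(cfg)
  h1 <- hybridity_table(sim$genotypes, sim$design)
  perm <- sample(sim$genotypes$sample_ids)
  h2 <- hybridity_table(subset_samples(sim$genotypes, perm), sim$design)
  h2 <- h2[match(h1$f1_id, h2$f1_id), ]
  expect_equal(as.character(h1$category), as.character(h2$category))
  expect_equal(h1$hybridity_percent, h2$hybridity_percent)
})

test_that("heterozygosity contrast splits groups and bins samples", {
  panel <- wide_panel(17)
  hom <- paste(rep("1", 17), collapse = "")
  het8 <- paste(c(rep("H", 8), rep("1", 9)), collapse = "")
  het1 <- paste(c("H", rep("1", 16)), collapse = "")  # 1/17 = 5.9% -> (0-6)%
  miss <- paste(c(rep(".", 5), rep("1", 12)), collapse = "")
  gm <- gm_from_codes(list(fem = hom, mal = hom, p1 = het1,
                           x1 = het8, x2 = hom, x3 = miss), panel)
  design <- cross_design(
    data.frame(cross_id = c("c1", "c2"), female_id = c("fem", "p1"),
               male_id = "mal", stringsAsFactors = FALSE),
    list(c("x1", "x2"), "x3"))
  hc <- heterozygosity_contrast(gm, design)
  expect_equal(hc$samples$group[hc$samples$sample_id == "p1"], "parent")
  # F1 het at 8 of 17 loci with none missing -> 0.471
  expect_equal(round(hc$samples$pr_het[hc$samples$sample_id == "x1"], 3), 0.471)
  pstats <- hc$group_stats[hc$group_stats$group == "parent", ]
  expect_equal(pstats$min, 0)
  bins <- hc$bins
  n_of <- function(g, b) bins$n[bins$group == g & bins$het_bin == b]
  expect_equal(n_of("parent", "0%"), 2L)
  expect_equal(n_of("parent", "(0-6)%"), 1L)
  expect_equal(n_of("F1", ">10%"), 1L)
  expect_equal(n_of("F1", "0%"), 1L)
  expect_equal(n_of("F1", "filtered"), 1L)
})

test_that("bin edges follow the 0 / 6-10 / >10 percent convention", {
  panel <- wide_panel(100)
  mk <- function(k_het) paste(c(rep("H", k_het), rep("1", 100 - k_het)), collapse = "")
  gm <- gm_from_codes(list(fem = mk(0), mal = mk(7), x1 = mk(30)), panel)
  design <- cross_design(
    data.frame(cross_id = "c", female_id = "fem", male_id = "mal",
               stringsAsFactors = FALSE), list("x1"))
  hc <- heterozygosity_contrast(gm, design)
  b <- hc$samples$het_bin
  names(b) <- hc$samples$sample_id
  expect_equal(as.character(b[c("fem", "mal", "x1")]),
               c("0%", "6-10%", ">10%"))
})
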