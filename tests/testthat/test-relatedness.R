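test_that("dosage encoding maps states to 0 / 0.5 / 1 and keeps NA", {
  gm <- gm_from_codes(list(a = "12H.", b = "2H1."))
  num <- encode_numeric(gm)
  expect_equal(unname(num["a", ]), c(0, 1, 0.5, NA))
  expect_equal(unname(num["b", ]), c(1, 0.5, 0, NA))
})

test_that("distances use pairwise-complete loci with no rescaling", {
  panel <- wide_panel(17)
  hom1 <- paste(rep("1", 17), collapse = "")
  # differ at 14 of 17 loci, fully homozygous -> exactly sqrt(14)
  diff14 <- paste(c(rep("2", 14), rep("1", 3)), collapse = "")
  het1 <- paste(c("H", rep("1", 16)), collapse = "")
  gm <- gm_from_codes(list(a = hom1, b = diff14, c = het1, d = hom1), panel)
  d <- pairwise_distance(gm)
  expect_equal(d["a", "b"], sqrt(14))
  expect_equal(round(d["a", "b"], 3), 3.742)
  expect_equal(d["a", "c"], 0.5)     # single HOM1-vs-HET term
  expect_equal(d["a", "d"], 0)       # identical samples
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  expect_true(all(d[!is.na(d)] <= sqrt(17) + 1e-12))
  # masked loci drop out of the sum without rescaling
  gm2 <- gm_from_codes(list(a = "1222", b = ".122"))
  d2 <- pairwise_distance(gm2)
  expect_equal(d2["a", "b"], 1)  # only locus 2 differs among shared loci
  # a pair sharing no non-missing locus is undefined and flagged
  gm3 <- gm_from_codes(list(a = "11..", b = "..11", c = "1111"))
  d3 <- pairwise_distance(gm3)
  expect_true(is.na(d3["a", "b"]))
  expect_equal(attr(d3, "undefined_pairs")$id1, "a")
})

test_that("distance axioms hold on random complete matrices", {
  set.seed(21)
  panel <- wide_panel(12)
  codes <- replicate(8, paste(sample(c("1", "2", "H"), 12, TRUE), collapse = ""))
  gm <- gm_from_codes(setNames(as.list(codes), paste0("s", 1:8)), panel)
  d <- unclass(pairwise_distance(gm))
  expect_true(all(d >= 0))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("neighbor joining resolves the additive quartet exactly", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(c(0, 2, 4, 4,
                2, 0, 4, 4,
                4, 4, 0, 2,
                4, 4, 2, 0), 4, dimnames = list(ids, ids))
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, ids)
  # topology AB|CD: path lengths reproduce the input distances exactly
  path <- ape::cophenetic.phylo(tree)[ids, ids]
  expect_equal(path, d, tolerance = 1e-9)
  # leaf branches 1, internal branch 2
  ext <- tree$edge.length[tree$edge[, 2] <= 4]
  expect_equal(sort(ext), rep(1, 4))
  expect_equal(sum(tree$edge.length) - 4, 2)
})

test_that("NJ recovers additive 4- and 5-taxon trees and matches ape", {
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (rep in 1:6) {
    n <- sample(4:5, 1)
    ref <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.3, 2))
    ref$tip.label <- paste0("t", seq_len(n))
    d <- ape::cophenetic.phylo(ref)
    tree <- neighbor_joining(d)
    # additive recovery: path lengths equal the generating distances
    expect_equal(ape::cophenetic.phylo(tree)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # independent oracle: same topology as ape's NJ
    expect_equal(phangorn::RF.dist(tree, ape::nj(d)), 0)
  }
})

test_that("NJ handles n = 2, n = 3 and rejects bad input", {
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbor_joining(d2)
  expect_equal(ape::cophenetic.phylo(t2)["A", "B"], 3)
  ids <- c("A", "B", "C")
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(ids, ids))
  t3 <- neighbor_joining(d3)
  # three-point formulas: a = (AB+AC-BC)/2 = 1, b = 2, c = 3
  path <- ape::cophenetic.phylo(t3)[ids, ids]
  expect_equal(path, d3, tolerance = 1e-9)
  dna <- d3; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(neighbor_joining(dna), "incomplete")
  expect_error(neighbor_joining(matrix(0, 1, 1, dimnames = list("A", "A"))),
               "at least 2")
})

test_that("NJ clamps negative branch lengths and logs raw values", {
  # a non-additive matrix known to produce a negative pendant branch
  ids <- paste0("x", 1:4)
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 2,
                6, 6, 0, 6,
                6, 2, 6, 0), 4, dimnames = list(ids, ids))
  tree <- neighbor_joining(d)
  expect_true(all(tree$edge.length >= 0))
  log <- attr(tree, "join_log")
  expect_true(any(c(log$raw_left, log$raw_right) < 0, na.rm = TRUE))
})

test_that("newick serialisation round-trips topology and branch lengths", {
  set.seed(55)
  panel <- wide_panel(15)
  codes <- replicate(7, paste(sample(c("1", "2"), 15, TRUE), collapse = ""))
  gm <- gm_from_codes(setNames(as.list(codes), paste0("s", 1:7)), panel)
  tree <- neighbor_joining(unclass(pairwise_distance(gm)))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(as.numeric(ape::dist.topo(tree, back)), 0)
  o <- order(tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[tree$tip.label[o], tree$tip.label[o]],
               ape::cophenetic.phylo(tree)[tree$tip.label[o], tree$tip.label[o]],
               tolerance = 1e-9)
})

test_that("related pairs are flagged below the threshold, strictly", {
  panel <- wide_panel(17)
  a <- paste(rep("1", 17), collapse = "")
  sister <- a                                  # identical sister line
  far <- paste(rep("2", 17), collapse = "")
  near <- paste(c(rep("2", 3), rep("1", 14)), collapse = "")  # sqrt(3) = 1.73
  gm <- gm_from_codes(list(p1 = a, p2 = sister, p3 = far, p4 = near), panel)
  d <- pairwise_distance(gm)
  fl <- flag_related_pairs(d, threshold = 2.0)
  expect_equal(fl$distance[1], 0)
  expect_equal(sort(c(fl$id1[1], fl$id2[1])), c("p1", "p2"))
  expect_true(all(fl$distance < 2))
  expect_equal(nrow(flag_related_pairs(d, threshold = 0)), 0L)  # strict <
  # restriction to designed pairs
  pairs <- data.frame(female_id = c("p1", "p3"), male_id = c("p4", "p4"))
  fl2 <- flag_related_pairs(d, 2.0, pairs = pairs)
  expect_equal(nrow(fl2), 1L)
  expect_setequal(c(fl2$id1, fl2$id2), c("p1", "p4"))
})

test_that("PCA centers, imputes, fixes signs and reconstructs exactly", {
  set.seed(77)
  panel <- wide_panel(10)
  codes <- replicate(12, paste(sample(c("1", "2", "H", "."), 10, TRUE,
                                      prob = c(.4, .4, .15, .05)), collapse = ""))
  gm <- gm_from_codes(setNames(as.list(codes), paste0("s", 1:12)), panel)
  p <- pca_genotypes(gm)
  expect_equal(sum(p$variance_explained), 100, tolerance = 1e-9)
  # reconstruction from all components equals the centered imputed matrix
  centered <- sweep(p$imputed, 2, p$center)
  expect_equal(p$scores %*% t(p$loadings), centered, tolerance = 1e-9)
  # deterministic sign: each loading vector's largest entry is positive
  for (k in seq_len(ncol(p$loadings))) {
    expect_gte(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  }
  # duplicated samples land on identical scores
  gm2 <- gm_from_codes(setNames(as.list(c(codes, codes[1])),
                                c(paste0("s", 1:12), "dup")), panel)
  p2 <- pca_genotypes(gm2)
  expect_equal(p2$scores["s1", ], p2$scores["dup", ], tolerance = 1e-9)
  # degenerate inputs
  expect_error(pca_genotypes(gm_from_codes(list(a = "1111", b = "1111"))),
               "zero-variance")
  rank1 <- gm_from_codes(list(a = "1111", b = "2222", c = "1111"))
  expect_equal(pca_genotypes(rank1)$variance_explained[1], 100)
})

test_that("marker contributions sum to 100 per component and combined", {
  set.seed(78)
  panel <- wide_panel(9)
  codes <- replicate(10, paste(sample(c("1", "2", "H"), 9, TRUE), collapse = ""))
  gm <- gm_from_codes(setNames(as.list(codes), paste0("s", 1:10)), panel)
  p <- pca_genotypes(gm)
  for (dims in c(1, 2, 4)) {
    mc <- marker_contributions(p, dims = dims)
    expect_equal(colSums(mc$per_component), rep(100, dims),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(sum(mc$combined), 100, tolerance = 1e-9)
  }
  # a single dominating loading takes all the contribution
  fake <- structure(list(loadings = cbind(c(1, 0, 0)), eigenvalues = 2,
                         scores = NULL), class = "geno_pca")
  expect_equal(unname(marker_contributions(fake, 1)$combined), c(100, 0, 0))
})
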