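# Genetic relatedness: dosage encoding, pairwise Euclidean distances,
# related-pair flagging, and PCA with per-marker contributions.

#' Encode a genotype matrix as allele dosages
#'
#' HOM1 -> 0, HET -> 0.5, HOM2 -> 1; missing stays `NA` (no imputation at
#' this stage).
#'
#' @param gm A `geno_matrix`.
#' @return Numeric samples x markers matrix.
#' @export
encode_numeric <- function(gm) {
  stopifnot(inherits(gm, "geno_matrix"))
  num <- matrix(NA_real_, nrow = nrow(gm$calls), ncol = ncol(gm$calls),
                dimnames = dimnames(gm$calls))
  num[gm$calls == "HOM1"] <- 0
  num[gm$calls == "HET"] <- 0.5
  num[gm$calls == "HOM2"] <- 1
  num
}

#' Pairwise Euclidean genetic distances
#'
#' `d(i,j) = sqrt(sum over loci non-missing in both samples of (v_i - v_j)^2)`
#' on the 0/0.5/1 dosage encoding. Loci missing in either sample are skipped
#' with no rescaling, so distances are bounded by `sqrt(n_markers)` and two
#' fully homozygous samples differing at k loci sit at exactly `sqrt(k)`.
#'
#' @param num Numeric dosage matrix from [encode_numeric()] (or a
#'   `geno_matrix`, encoded on the fly).
#' @return Symmetric matrix of class `geno_dist` with zero diagonal. Pairs
#'   sharing no non-missing locus get `NA` and are listed in the
#'   `undefined_pairs` attribute.
#' @export
pairwise_distance <- function(num) {
  if (inherits(num, "geno_matrix")) num <- encode_numeric(num)
  stopifnot(is.matrix(num), nrow(num) >= 2)
  obs <- !is.na(num)
  x <- num
  x[!obs] <- 0
  # sum over shared loci of (vi - vj)^2, expanded so that masked loci drop out
  sq <- x^2
  shared_sq <- sq %*% t(obs) + obs %*% t(sq)  # sum vi^2 + vj^2 over shared loci
  cross <- x %*% t(x)
  d2 <- shared_sq - 2 * cross
  d2[d2 < 0] <- 0  # numeric guard
  d <- sqrt(d2)
  n_shared <- obs %*% t(obs)
  d[n_shared == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(rownames(num), rownames(num))
  undef <- which(n_shared == 0 & upper.tri(n_shared), arr.ind = TRUE)
  attr(d, "undefined_pairs") <- data.frame(
    id1 = rownames(num)[undef[, 1]], id2 = rownames(num)[undef[, 2]],
    stringsAsFactors = FALSE)
  class(d) <- c("geno_dist", class(d))
  d
}

#' Flag closely related sample pairs
#'
#' All unordered pairs with distance strictly below `threshold`, sorted by
#' ascending distance. Sister lines and duplicated samples surface at
#' distance 0.
#'
#' @param d A distance matrix from [pairwise_distance()].
#' @param threshold Flagging bound (default 2.0).
#' @param pairs Optional two-column data.frame (e.g. `female_id`, `male_id`
#'   of designed crosses) restricting the comparison to those pairs.
#' @return Data.frame: `id1`, `id2`, `distance`.
#' @export
flag_related_pairs <- function(d, threshold = 2.0, pairs = NULL) {
  stopifnot(is.matrix(d))
  ids <- rownames(d)
  if (is.null(pairs)) {
    idx <- which(upper.tri(d) & !is.na(d) & d < threshold, arr.ind = TRUE)
    out <- data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                      distance = d[idx], stringsAsFactors = FALSE)
  } else {
    stopifnot(ncol(pairs) >= 2)
    a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
    keep <- a %in% ids & b %in% ids
    a <- a[keep]; b <- b[keep]
    dv <- d[cbind(match(a, ids), match(b, ids))]
    sel <- !is.na(dv) & dv < threshold
    out <- unique(data.frame(id1 = pmin(a[sel], b[sel]),
                             id2 = pmax(a[sel], b[sel]),
                             distance = dv[sel], stringsAsFactors = FALSE))
  }
  out[order(out$distance, out$id1, out$id2), , drop = FALSE]
}

#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per marker, the matrix is centered (not
#' scaled) and eigendecomposed via [stats::prcomp()]. Component signs are
#' fixed deterministically: each loading vector's largest-magnitude entry is
#' made positive.
#'
#' @param num Dosage matrix from [encode_numeric()] (or a `geno_matrix`).
#' @param n_components Number of components to retain (default: all).
#' @return List of class `geno_pca`: `$scores` (samples x components),
#'   `$loadings` (markers x components), `$eigenvalues` (component
#'   variances), `$variance_explained` (percent, summing to 100 over all
#'   components), `$center`, `$imputed` (the imputed dosage matrix).
#' @export
pca_genotypes <- function(num, n_components = NULL) {
  if (inherits(num, "geno_matrix")) num <- encode_numeric(num)
  stopifnot(is.matrix(num), nrow(num) >= 2)
  col_mean <- colMeans(num, na.rm = TRUE)
  if (anyNA(col_mean)) {
    stop("marker(s) with no non-missing calls cannot be imputed: ",
         paste(colnames(num)[is.na(col_mean)], collapse = ", "))
  }
  imputed <- num
  for (j in seq_len(ncol(num))) {
    miss <- is.na(imputed[, j])
    imputed[miss, j] <- col_mean[j]
  }
  if (all(apply(imputed, 2, sd) < 1e-12)) {
    stop("zero-variance genotype matrix; PCA undefined")
  }
  p <- prcomp(imputed, center = TRUE, scale. = FALSE)
  k_all <- length(p$sdev)
  eigenvalues <- p$sdev^2
  var_explained <- 100 * eigenvalues / sum(eigenvalues)
  k <- if (is.null(n_components)) k_all else min(n_components, k_all)
  scores <- p$x[, seq_len(k), drop = FALSE]
  loadings <- p$rotation[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    j_star <- which.max(abs(loadings[, c]))
    if (loadings[j_star, c] < 0) {
      loadings[, c] <- -loadings[, c]
      scores[, c] <- -scores[, c]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 eigenvalues = eigenvalues[seq_len(k)],
                 variance_explained = var_explained[seq_len(k)],
                 all_eigenvalues = eigenvalues,
                 center = p$center, imputed = imputed),
            class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat("geno_pca:", nrow(x$scores), "samples,", ncol(x$scores), "components;",
      sprintf("PC1+PC2 explain %.1f%%\n",
              sum(x$variance_explained[seq_len(min(2, length(x$variance_explained)))])))
  invisible(x)
}

#' Per-marker contributions to principal components
#'
#' Per component k, marker j contributes
#' `100 * loading(j,k)^2 / sum_j loading(j,k)^2` percent. The combined
#' contribution over the first `dims` components weights each component by
#' its eigenvalue, so combined contributions also sum to 100 over markers.
#'
#' @param pca A `geno_pca`.
#' @param dims Number of leading components to combine (default 2).
#' @return List: `$per_component` (markers x dims percent matrix),
#'   `$combined` (named percent vector over markers).
#' @export
marker_contributions <- function(pca, dims = 2) {
  stopifnot(inherits(pca, "geno_pca"), dims >= 1, dims <= ncol(pca$loadings))
  L <- pca$loadings[, seq_len(dims), drop = FALSE]
  per_component <- 100 * sweep(L^2, 2, colSums(L^2), "/")
  lambda <- pca$eigenvalues[seq_len(dims)]
  combined <- as.vector(per_component %*% lambda / sum(lambda))
  names(combined) <- rownames(L)
  list(per_component = per_component, combined = combined)
}
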