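# Neighbor-Joining tree construction (Saitou & Nei agglomeration).
#
# Implemented in-package so that the contract details are deterministic and
# auditable: lexicographic tie-breaking among equal-minimum Q entries, and
# clamp-and-transfer handling of negative branch lengths (a negative pendant
# length is set to 0 and its deficit moved to the sister branch; raw lengths
# are retained in a diagnostic join log). Exact on additive distance
# matrices. Trees are returned as ape "phylo" objects via newick.

#' Neighbor-Joining tree from a distance matrix
#'
#' Classic agglomeration: with `r` the row sums of the current distance
#' matrix `d` over `n` active nodes, `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)`;
#' the minimal-Q pair is joined (ties broken by the lexicographically
#' smallest index pair), pendant branches get
#' `b_i = d(i,j)/2 + (r_i - r_j) / (2(n-2))`, `b_j = d(i,j) - b_i`, and
#' distances to the new node are `(d(i,k) + d(j,k) - d(i,j)) / 2`. Negative
#' pendant lengths are clamped to zero with the deficit transferred to the
#' sister branch.
#'
#' @param d Complete symmetric distance matrix with row/col names
#'   (`NA` entries are an error) over at least 2 samples.
#' @return An unrooted `ape::phylo` tree whose leaf set equals the input
#'   samples. Attribute `join_log` records, per join, the raw (pre-clamp)
#'   and final branch lengths. For `n = 2` the two tips are joined by a
#'   single path of length `d(1,2)`.
#' @export
neighbor_joining <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  ids <- rownames(d)
  if (is.null(ids)) stop("distance matrix must have row names")
  if (anyNA(d)) stop("incomplete distance matrix: NA entries present")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2) stop("need at least 2 samples")
  bad <- grepl("[(),:;]", ids)
  if (any(bad)) stop("sample ID(s) contain newick metacharacters: ",
                     paste(ids[bad], collapse = ", "))
  fmt <- function(x) sprintf("%.12g", x)
  if (n == 2) {
    nwk <- paste0("(", ids[1], ":", fmt(d[1, 2] / 2),
                  ",", ids[2], ":", fmt(d[1, 2] / 2), ");")
    tree <- ape::read.tree(text = nwk)
    attr(tree, "join_log") <- data.frame()
    return(tree)
  }
  frag <- ids
  D <- unname(d)
  log_rows <- list()
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    # lexicographically smallest (i, j), i < j, among minima
    cand <- which(Q <= qmin + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[Q[cand] == qmin, , drop = FALSE]
    ord <- order(cand[, 1], cand[, 2])
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    bi_raw <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj_raw <- D[i, j] - bi_raw
    b <- .clamp_transfer(bi_raw, bj_raw)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      left = frag[i], right = frag[j],
      raw_left = bi_raw, raw_right = bj_raw,
      length_left = b[1], length_right = b[2])
    new_frag <- paste0("(", frag[i], ":", fmt(b[1]),
                       ",", frag[j], ":", fmt(b[2]), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    D <- D2
  }
  # final three nodes: star resolution from the three-point formulas
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  raw <- c(b1, b2, b3)
  fin <- pmax(raw, 0)
  log_rows[[length(log_rows) + 1L]] <- data.frame(
    left = frag[1], right = paste(frag[2], frag[3], sep = "|"),
    raw_left = raw[1], raw_right = NA_real_,
    length_left = fin[1], length_right = NA_real_)
  nwk <- paste0("(", frag[1], ":", fmt(fin[1]),
                ",", frag[2], ":", fmt(fin[2]),
                ",", frag[3], ":", fmt(fin[3]), ");")
  tree <- ape::read.tree(text = nwk)
  attr(tree, "join_log") <- do.call(rbind, log_rows)
  tree
}

# Clamp negative pendant branch lengths to zero, transferring the deficit to
# the sister branch so the path length between the joined nodes is preserved.
.clamp_transfer <- function(bi, bj) {
  if (bi < 0) { bj <- bj + bi; bi <- 0 }
  if (bj < 0) { bi <- max(bi + bj, 0); bj <- 0 }
  c(bi, bj)
}

#' Write a tree in newick format
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
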