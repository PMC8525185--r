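#' Classical MDS (principal coordinates) of an F_ST distance matrix
#'
#' Treats the pairwise F_ST values directly as distances (no transform) and
#' runs classical multidimensional scaling: double-centre the squared
#' distances, eigendecompose, and scale each retained eigenvector by the
#' square root of its eigenvalue. Axes with non-positive eigenvalues get
#' all-zero coordinates. Eigenvector sign is arbitrary, so each axis is
#' oriented with its largest-magnitude coordinate positive, making the axes
#' reproducible for downstream regression.
#'
#' Negative input distances (possible from the bias correction) are clamped
#' to 0 with a warning giving the count.
#'
#' @param fst an `fst_matrix` from [pairwise_fst()], or a symmetric numeric
#'   distance matrix
#' @param k number of axes to retain (>= 2)
#' @return an object of class `mds_result`: `points` (J x k, population
#'   rownames), `eig` (all eigenvalues, descending), `C` (cumulative
#'   contribution ratios over all axes, negative eigenvalues zeroed), `k`
#' @export
classical_mds <- function(fst, k = 2) {
  d <- .as_distance_matrix(fst, caller = "classical_mds")
  if (k < 2) .stopf("k must be >= 2")
  J <- nrow(d)
  k <- min(k, J - 1L)
  # cmdscale warns when fewer than k eigenvalues are positive; the missing
  # axes are filled with zero coordinates below, per the C_k convention
  mds <- suppressWarnings(stats::cmdscale(d, k = k, eig = TRUE))
  eig <- mds$eig
  pts <- matrix(0, J, k, dimnames = list(rownames(d), paste0("mds", seq_len(k))))
  got <- mds$points
  if (!is.null(got) && ncol(got)) {
    m <- min(ncol(got), k)
    # axes whose eigenvalue is zero to numerical precision stay all-zero
    keep <- which(eig[seq_len(m)] > max(eig) * 1e-12)
    pts[, keep] <- got[, keep, drop = FALSE]
  }
  # orient: largest-|coordinate| population positive on each axis
  for (a in seq_len(k)) {
    i <- which.max(abs(pts[, a]))
    if (length(i) && pts[i, a] < 0) pts[, a] <- -pts[, a]
  }
  pos <- pmax(eig, 0)
  if (sum(pos) <= 0) .stopf("all eigenvalues non-positive; no embedding")
  structure(list(points = pts, eig = eig, C = cumsum(pos) / sum(pos), k = k),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("Classical MDS: %d populations, %d retained axes\n",
              nrow(x$points), x$k))
  cat(sprintf("  cumulative contribution C_k: %s\n",
              paste(sprintf("%.3f", x$C[seq_len(min(x$k, length(x$C)))]),
                    collapse = ", ")))
  invisible(x)
}

.as_distance_matrix <- function(fst, caller) {
  if (inherits(fst, "fst_matrix")) {
    if (!all(fst$defined))
      .stopf("%s: matrix has undefined pairs; subset or impute first", caller)
    d <- fst$fst
  } else {
    d <- as.matrix(fst)
  }
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-9)
    .stopf("%s: input matrix must be symmetric", caller)
  if (anyNA(d)) .stopf("%s: matrix has undefined pairs; subset or impute first", caller)
  nneg <- sum(d < 0)
  if (nneg) {
    warning(sprintf("%s: clamped %d negative distance(s) to 0", caller, nneg),
            call. = FALSE)
    d[d < 0] <- 0
  }
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("pop", seq_len(nrow(d)))
  d
}

#' Cumulative contribution ratio of MDS axes
#'
#' `C_k = sum_{j<=k} max(lambda_j, 0) / sum_j max(lambda_j, 0)`: the share
#' of the positive eigenvalue mass captured by the first k axes, with
#' negative eigenvalues treated as zero.
#'
#' @param eigenvalues eigenvalues in descending order
#' @param k number of leading axes
#' @return `C_k`, a number in `[0, 1]`
#' @export
explained_variation <- function(eigenvalues, k) {
  if (k < 1) .stopf("k must be >= 1")
  pos <- pmax(eigenvalues, 0)
  if (sum(pos) <= 0) .stopf("all eigenvalues non-positive; C_k undefined")
  sum(pos[seq_len(min(k, length(pos)))]) / sum(pos)
}

#' Neighbor-joining tree from a pairwise F_ST matrix
#'
#' Saitou-Nei neighbor joining on the F_ST distance matrix, returning an
#' unrooted [ape::phylo] tree. Negative distances are clamped to 0 with a
#' warning. NJ is exact on additive matrices.
#'
#' @param fst an `fst_matrix` or symmetric distance matrix (>= 3 populations)
#' @return an unrooted `phylo` tree with populations as tips
#' @export
nj_tree <- function(fst) {
  d <- .as_distance_matrix(fst, caller = "nj_tree")
  if (nrow(d) < 3) .stopf("nj_tree needs at least 3 populations")
  tr <- ape::nj(d)
  neg <- sum(tr$edge.length < 0)
  if (neg) {
    warning(sprintf("nj_tree: clamped %d negative branch length(s) to 0", neg),
            call. = FALSE)
    tr$edge.length <- pmax(tr$edge.length, 0)
  }
  tr
}

#' AIC for TreeMix admixture-graph models
#'
#' Parameter accounting for comparing TreeMix models by the Akaike
#' information criterion: each migration event contributes three parameters
#' (migration edge, branch length, migration weight), so
#' `AIC = -2 * loglik + 2 * (3 * n_migration_events)`. The composite
#' log-likelihood itself comes from an external TreeMix run.
#'
#' @param loglik maximum composite log-likelihood of the fitted model
#' @param n_migration_events number of migration (admixture) events, >= 0
#' @return the AIC value
#' @export
treemix_aic <- function(loglik, n_migration_events) {
  if (!.is_count(n_migration_events))
    .stopf("n_migration_events must be a non-negative integer")
  -2 * loglik + 2 * (3 * n_migration_events)
}
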