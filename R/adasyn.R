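# ADASYN adaptive synthetic minority oversampling.

# indices of the k nearest rows of `ref` for each row of `query`
# (excluding self-matches when `exclude_self`); plain Euclidean distance
knn_indices <- function(query, ref, k, exclude_self = FALSE) {
  q2 <- rowSums(query^2)
  r2 <- rowSums(ref^2)
  nq <- nrow(query)
  out <- matrix(0L, nq, k)
  block <- max(1L, floor(5e7 / max(nrow(ref), 1)))
  for (start in seq(1L, nq, by = block)) {
    idx <- start:min(start + block - 1L, nq)
    d2 <- outer(q2[idx], r2, "+") - 2 * tcrossprod(query[idx, , drop = FALSE], ref)
    if (exclude_self) d2[cbind(seq_along(idx), idx)] <- Inf
    for (i in seq_along(idx)) {
      out[idx[i], ] <- order(d2[i, ])[seq_len(k)]
    }
  }
  out
}

#' ADASYN minority oversampling
#'
#' Adaptive synthetic sampling for imbalanced binary outcomes. For each
#' minority observation, the fraction of majority points among its k
#' nearest neighbours (in the full sample) defines a density weight;
#' weights are normalized and allocate the synthesis budget
#' \code{G = (n_majority - n_minority) * ratio}, so more synthetic points
#' are generated in regions dominated by the majority class. Each synthetic
#' point is a convex combination of a minority point and one of its k
#' nearest minority neighbours. A minority point with no minority
#' neighbour is duplicated instead.
#'
#' @param x Numeric matrix of features (standardized recommended).
#' @param y Binary 0/1 outcome with both classes present.
#' @param ratio Target minority/majority ratio after augmentation.
#'   Default 1 (full balance). No synthesis occurs if the data already
#'   meet the target.
#' @param k Number of nearest neighbours, at least 1. Default 5.
#' @param seed Integer seed.
#' @return A list with \code{x} (original rows then synthetic rows),
#'   \code{y}, \code{n_synthetic}, and \code{weights} (the normalized
#'   per-minority-point density weights; zero vector when no deficit).
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40), ncol = 2)
#' y <- c(rep(1, 3), rep(0, 17))
#' out <- adasyn_oversample(x, y, ratio = 1, k = 3, seed = 1)
#' table(out$y)
adasyn_oversample <- function(x, y, ratio = 1, k = 5, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("x and y must have matching lengths")
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  n_min <- min(n1, n0); n_maj <- max(n1, n0)
  if (k >= nrow(x) - 1) stop("k must be smaller than n - 1")

  G <- round((n_maj - n_min) * ratio)
  min_idx <- which(y == minority)
  weights <- rep(0, n_min)
  if (G <= 0 || n_min / n_maj >= ratio) {
    return(list(x = x, y = y, n_synthetic = 0L, weights = weights))
  }

  xm <- x[min_idx, , drop = FALSE]
  # k nearest neighbours in the full sample, excluding the point itself
  nn_all <- knn_indices(xm, x, k + 1, exclude_self = FALSE)
  maj_frac <- vapply(seq_len(n_min), function(i) {
    nb <- nn_all[i, ]
    nb <- nb[nb != min_idx[i]]
    mean(y[nb[seq_len(k)]] != minority)
  }, numeric(1))
  if (sum(maj_frac) == 0) {
    # uniformly surrounded by minority: spread synthesis evenly
    weights <- rep(1 / n_min, n_min)
  } else {
    weights <- maj_frac / sum(maj_frac)
  }
  g <- round(weights * G)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  synth <- NULL
  if (sum(g) > 0) {
    kk <- min(k, n_min - 1)
    nn_min <- if (n_min > 1) knn_indices(xm, xm, kk, exclude_self = TRUE) else NULL
    parents <- rep(seq_len(n_min), g)
    lambda <- runif(length(parents))
    if (is.null(nn_min)) {
      mates <- parents  # single minority point: duplicate
    } else {
      mates <- nn_min[cbind(parents, sample.int(kk, length(parents),
                                                replace = TRUE))]
    }
    synth <- xm[parents, , drop = FALSE] +
      lambda * (xm[mates, , drop = FALSE] - xm[parents, , drop = FALSE])
  }
  n_syn <- if (is.null(synth)) 0L else nrow(synth)
  list(x = rbind(x, synth),
       y = c(y, rep(minority, n_syn)),
       n_synthetic = n_syn,
       weights = weights)
}
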