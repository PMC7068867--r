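## clustering: SVD reduction of the feature matrix and segmentation of the
## graphs with k-medoids (cluster::pam), Ward agglomerative or spectral
## clustering, scored by average silhouette width or Calinski-Harabasz.

#' SVD reduction of a feature matrix
#'
#' Coordinates are the left singular vectors scaled by the singular values,
#' truncated to the requested rank or to the smallest rank reaching the
#' requested energy (squared-singular-value) fraction. Component signs are
#' fixed so the largest-magnitude loading of each right singular vector is
#' positive, making the embedding reproducible.
#'
#' @param features a \code{\linkS4class{FeatureMatrix}}.
#' @param rank integer rank, or NULL to use \code{energy}.
#' @param energy energy fraction in (0, 1] used when \code{rank} is NULL
#'   (default 0.9, capped at min(n - 1, 100) components).
#' @return a \code{\linkS4class{GraphEmbedding}}.
#' @export
svdReduce <- function(features, rank = NULL, energy = 0.9) {
  m <- features@matrix
  stopifnot(nrow(m) >= 2, ncol(m) >= 1)
  s <- svd(m)
  ## sign convention: largest-|loading| entry of each right vector positive
  for (k in seq_along(s$d)) {
    i <- which.max(abs(s$v[, k]))
    if (s$v[i, k] < 0) { s$v[, k] <- -s$v[, k]; s$u[, k] <- -s$u[, k] }
  }
  maxRank <- min(dim(m))
  if (is.null(rank)) {
    cap <- min(nrow(m) - 1L, 100L)
    en <- cumsum(s$d^2) / sum(s$d^2)
    rank <- min(which(en >= energy), cap)
  } else if (rank > maxRank) {
    warning("rank ", rank, " clamped to ", maxRank)
    rank <- maxRank
  }
  rank <- max(1L, as.integer(rank))
  coords <- s$u[, seq_len(rank), drop = FALSE] %*%
    diag(s$d[seq_len(rank)], nrow = rank)
  rownames(coords) <- rownames(m)
  new("GraphEmbedding", coordinates = coords, singularValues = s$d,
      retainedRank = rank)
}

## Degenerate guard: fewer distinct rows than k.
.degenerateLabels <- function(n, k) rep(seq_len(k), length.out = n)

.spectralLabels <- function(x, k, seed) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  sigma <- median(d[upper.tri(d)])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  a <- exp(-d^2 / (2 * sigma^2)); diag(a) <- 0
  deg <- rowSums(a); deg[deg <= 0] <- 1e-12
  lsym <- diag(n) - diag(1 / sqrt(deg)) %*% a %*% diag(1 / sqrt(deg))
  ev <- eigen(lsym, symmetric = TRUE)
  u <- ev$vectors[, n - seq_len(k) + 1L, drop = FALSE]  # k smallest
  norms <- sqrt(rowSums(u^2)); norms[norms == 0] <- 1
  u <- u / norms
  set.seed(seed)
  if (nrow(unique(u)) < k) return(.degenerateLabels(n, k))
  kmeans(u, centers = k, nstart = 10, iter.max = 100)$cluster
}

#' Cluster the embedded graphs
#'
#' @param embedding a \code{GraphEmbedding}.
#' @param algorithm "kmedoids" (PAM build+swap on Euclidean distances),
#'   "agglomerative" (Ward on Euclidean, deterministic) or "spectral" (RBF
#'   affinity with median-distance bandwidth, normalized Laplacian,
#'   seed-controlled k-means on the spectral embedding).
#' @param k number of groups, 2..n-1.
#' @param seed RNG seed honored by the seed-sensitive algorithms.
#' @return named integer vector of 1-based group labels (contiguous 1..k).
#' @export
runClustering <- function(embedding, algorithm = c("kmedoids", "agglomerative",
                                                   "spectral"),
                          k, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- embedding@coordinates
  n <- nrow(x)
  if (k < 2L || k > n - 1L)
    stop("k must satisfy 2 <= k <= n_graphs - 1 (got k=", k, ", n=", n, ")")
  labels <- if (nrow(unique(x)) < k) {
    .degenerateLabels(n, k)
  } else if (algorithm == "kmedoids") {
    set.seed(seed)
    cluster::pam(x, k = k, metric = "euclidean", cluster.only = TRUE)
  } else if (algorithm == "agglomerative") {
    cutree(hclust(dist(x), method = "ward.D2"), k = k)
  } else {
    .spectralLabels(x, k, seed)
  }
  ## make group indices contiguous in order of first appearance
  labels <- match(labels, unique(labels))
  structure(as.integer(labels), names = rownames(x))
}

#' Average silhouette width
#'
#' Mean over points of (b - a) / max(a, b) with Euclidean distances, with
#' the conventions: a point whose max(a, b) is 0 contributes 0, and
#' singleton-cluster points contribute 0.
#'
#' @param x coordinate matrix.
#' @param labels integer group labels.
#' @return asw in [-1, 1].
#' @export
silhouetteWidth <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }   # singleton convention
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    m <- max(a, b)
    s[i] <- if (m == 0) 0 else (b - a) / m     # 0/0 := 0 convention
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' Between-group over within-group dispersion ratio,
#' (B / (k - 1)) / (W / (n - k)); defined as 0 when the within-group
#' dispersion is 0 together with zero between-group dispersion, and Inf for
#' perfectly tight separated groups.
#'
#' @param x coordinate matrix.
#' @param labels integer group labels.
#' @return non-negative real (possibly Inf).
#' @export
calinskiHarabasz <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  gm <- colMeans(x)
  b <- 0; w <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    cg <- colMeans(xi)
    b <- b + nrow(xi) * sum((cg - gm)^2)
    w <- w + sum(sweep(xi, 2, cg)^2)
  }
  if (w == 0) return(if (b == 0) 0 else Inf)
  (b / (k - 1)) / (w / (n - k))
}

#' Score a clustering with the selected metric
#'
#' @param embedding a \code{GraphEmbedding}.
#' @param labels labels as returned by \code{\link{runClustering}}.
#' @param metric "asw" or "calinski_harabasz".
#' @return the score.
#' @export
scoreClustering <- function(embedding, labels,
                            metric = c("asw", "calinski_harabasz")) {
  metric <- match.arg(metric)
  x <- embedding@coordinates
  stopifnot(length(labels) == nrow(x), length(unique(labels)) >= 2)
  if (metric == "asw") silhouetteWidth(x, labels)
  else calinskiHarabasz(x, labels)
}

#' Fit clusterings over a k range and keep the best
#'
#' Fits every k in \code{kRange}, scores each with the metric and returns
#' the maximizing model; ties are broken toward smaller k. The default
#' range is 2..min(15, n - 1).
#'
#' @param embedding a \code{GraphEmbedding}.
#' @param algorithm,metric see \code{\link{runClustering}} and
#'   \code{\link{scoreClustering}}; defaults k-medoids scored by asw.
#' @param kRange integer vector of candidate k (default 2..min(15, n-1)).
#' @param seed RNG seed.
#' @return a \code{\linkS4class{ClusterModel}}.
#' @export
selectClusterModel <- function(embedding, algorithm = "kmedoids",
                               metric = "asw", kRange = NULL, seed = 1L) {
  n <- nrow(embedding@coordinates)
  if (is.null(kRange)) kRange <- seq(2L, max(2L, min(15L, n - 1L)))
  stopifnot(length(kRange) >= 1)
  best <- NULL
  for (k in sort(as.integer(kRange))) {
    labels <- runClustering(embedding, algorithm, k, seed)
    score <- scoreClustering(embedding, labels, metric)
    if (is.null(best) || score > best$score)
      best <- list(k = k, labels = labels, score = score)
  }
  new("ClusterModel", algorithm = algorithm, k = best$k,
      labels = best$labels, metric = metric, score = best$score,
      seed = as.integer(seed))
}
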