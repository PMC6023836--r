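#' Standardize stage profiles to mean 0, SD 1
#'
#' Each feature's profile is centered and scaled by its population SD
#' (divide by n; `sd_type = "sample"` divides by n-1). Zero-variance
#' profiles cannot be standardized and are excluded, their ids reported.
#'
#' @param profiles numeric matrix, features x stages (e.g. [stage_means()]).
#' @param sd_type "population" (default) or "sample".
#' @return List with `profiles` (standardized matrix) and `excluded`
#'   (character vector of zero-SD feature ids).
#' @export
standardize_profiles <- function(profiles, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  profiles <- unclass(profiles)
  if (ncol(profiles) < 2) stop("profiles need at least 2 stages")
  mu <- rowMeans(profiles)
  centered <- profiles - mu
  n <- ncol(profiles)
  denom <- if (sd_type == "population") n else n - 1
  s <- sqrt(rowSums(centered^2) / denom)
  excluded <- rownames(profiles)[s == 0]
  keep <- s > 0
  if (!any(keep)) stop("all profiles have zero SD; nothing to standardize")
  out <- centered[keep, , drop = FALSE] / s[keep]
  list(profiles = out, excluded = excluded)
}

# squared Euclidean distances rows of X to rows of C
sqdist_to_centroids <- function(X, C) {
  d2 <- outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
  pmax(d2, 0)
}

# membership update for fuzzy c-means; points coincident with a centroid get
# crisp membership there
fcm_membership <- function(d2, m) {
  pow <- 1 / (m - 1)
  U <- 1 / (d2^pow * rowSums((1 / d2)^pow))
  zero <- d2 < 1e-300
  hit <- rowSums(zero) > 0
  if (any(hit)) {
    U[hit, ] <- 0
    U[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
  }
  U
}

fcm_objective <- function(U, d2, m) sum(U^m * d2)

# k-means++-style centroid seeding on rows of X
seed_centroids <- function(X, c) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  for (j in seq_len(c - 1)) {
    d2 <- sqdist_to_centroids(X, X[idx, , drop = FALSE])
    mind <- apply(d2, 1, min)
    mind[idx] <- 0
    probs <- if (sum(mind) > 0) mind / sum(mind) else rep(1 / n, n)
    idx <- c(idx, sample.int(n, 1, prob = probs))
  }
  X[idx, , drop = FALSE]
}

#' Fuzzy c-means clustering of standardized profiles
#'
#' Standard fuzzy c-means with Euclidean distance: memberships
#' U_ij = 1 / sum_k (d_ij/d_ik)^(2/(m-1)) and centroids as U^m-weighted
#' means. Multiple random restarts (k-means++-style seeding) are run and the
#' fit with the lowest objective J = sum_ij U_ij^m d_ij^2 is kept.
#' Convergence is declared when the largest membership change falls below
#' `tol`.
#'
#' @param X numeric matrix of standardized profiles (features x stages).
#' @param c number of clusters (>= 1, <= number of features).
#' @param m fuzzifier, > 1 (default 2).
#' @param tol convergence tolerance on max |delta U|.
#' @param max_iter iteration cap per restart.
#' @param restarts number of random restarts.
#' @param seed RNG seed for reproducible restarts.
#' @return A `ClusterModel` list: `centroids` (c x stages), `membership`
#'   (features x c), `cluster` (hard labels, argmax membership with lowest
#'   index winning ties), `m`, `c`, `objective`, `J_trace` (per-iteration
#'   objective of the winning restart), `seed`, `restarts`.
#' @export
fuzzy_cmeans <- function(X, c, m = 2, tol = 1e-8, max_iter = 500,
                         restarts = 5, seed = NULL) {
  X <- unclass(X)
  if (!is.matrix(X) || any(!is.finite(X))) stop("X must be a finite matrix")
  if (m <= 1) stop("fuzzifier m must be > 1")
  if (c > nrow(X)) stop("more clusters than features")
  if (!is.null(seed)) set.seed(seed)
  if (c == 1) {
    centroid <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
    U <- matrix(1, nrow(X), 1, dimnames = list(rownames(X), NULL))
    d2 <- sqdist_to_centroids(X, centroid)
    model <- list(centroids = centroid, membership = U,
                  cluster = stats::setNames(rep(1L, nrow(X)), rownames(X)),
                  m = m, c = 1L, objective = sum(d2), J_trace = sum(d2),
                  seed = seed, restarts = 0L)
    class(model) <- "ClusterModel"
    return(model)
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    C <- seed_centroids(X, c)
    U <- fcm_membership(sqdist_to_centroids(X, C), m)
    J_trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      W <- U^m
      C <- (t(W) %*% X) / colSums(W)
      d2 <- sqdist_to_centroids(X, C)
      U_new <- fcm_membership(d2, m)
      J_trace <- c(J_trace, fcm_objective(U_new, d2, m))
      delta <- max(abs(U_new - U))
      U <- U_new
      if (delta < tol) break
    }
    J <- J_trace[length(J_trace)]
    if (is.null(best) || J < best$objective) {
      best <- list(centroids = C, membership = U, J_trace = J_trace,
                   objective = J)
    }
  }
  rownames(best$membership) <- rownames(X)
  colnames(best$centroids) <- colnames(X)
  hard <- apply(best$membership, 1, which.max)  # ties: lowest index
  model <- list(centroids = best$centroids, membership = best$membership,
                cluster = stats::setNames(as.integer(hard), rownames(X)),
                m = m, c = as.integer(c), objective = best$objective,
                J_trace = best$J_trace, seed = seed, restarts = restarts)
  class(model) <- "ClusterModel"
  model
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat(sprintf("ClusterModel: c=%d, m=%g, %d features, J=%.4g\n",
              x$c, x$m, nrow(x$membership), x$objective))
  invisible(x)
}

#' Minimum-centroid-distance curve for cluster number selection
#'
#' For each candidate cluster count, fits fuzzy c-means and records the
#' minimum pairwise Euclidean distance between centroids. A sharp drop in
#' this curve suggests the cluster count has exceeded the number of distinct
#' temporal patterns; the choice remains advisory and is inspected by the
#' user.
#'
#' @param X standardized profile matrix.
#' @param c_range candidate cluster counts (>= 2).
#' @param m fuzzifier.
#' @param seed RNG seed (each c gets a derived seed for reproducibility).
#' @param ... passed to [fuzzy_cmeans()].
#' @return data.frame with columns `c` and `dmin`.
#' @export
dmin_curve <- function(X, c_range = 2:10, m = 2, seed = NULL, ...) {
  c_range <- sort(unique(as.integer(c_range)))
  if (any(c_range < 2)) stop("c_range values must be >= 2")
  rows <- lapply(c_range, function(cc) {
    s <- if (is.null(seed)) NULL else seed + cc
    fit <- fuzzy_cmeans(X, cc, m = m, seed = s, ...)
    d <- stats::dist(fit$centroids)
    data.frame(c = cc, dmin = min(d))
  })
  do.call(rbind, rows)
}

#' Order clusters by temporal trend
#'
#' Relabels clusters so that index 1 is the most downregulated: clusters are
#' sorted by increasing (centroid value at the last stage minus value at the
#' first stage), ties broken by increasing centroid mean.
#'
#' @param model a `ClusterModel`.
#' @return The model with clusters relabeled accordingly.
#' @export
order_clusters <- function(model) {
  stopifnot(inherits(model, "ClusterModel"))
  C <- model$centroids
  trend <- C[, ncol(C)] - C[, 1]
  ord <- order(trend, rowMeans(C))
  relabel <- match(seq_len(model$c), ord)  # old index -> new index
  model$centroids <- C[ord, , drop = FALSE]
  model$membership <- model$membership[, ord, drop = FALSE]
  model$cluster <- stats::setNames(relabel[model$cluster], names(model$cluster))
  model
}

#' Contingency table of two clusterings
#'
#' Cross-tabulates hard labels of the features shared by both models;
#' features present in only one model are reported separately.
#'
#' @param model_a,model_b `ClusterModel` objects.
#' @return List with `table` (c_a x c_b counts), `only_a`, `only_b`
#'   (feature ids present in a single model).
#' @export
cluster_overlap_table <- function(model_a, model_b) {
  fa <- names(model_a$cluster); fb <- names(model_b$cluster)
  common <- intersect(fa, fb)
  tab <- table(factor(model_a$cluster[common], levels = seq_len(model_a$c)),
               factor(model_b$cluster[common], levels = seq_len(model_b$c)))
  dimnames(tab) <- list(cluster_a = seq_len(model_a$c),
                        cluster_b = seq_len(model_b$c))
  list(table = unclass(tab), only_a = setdiff(fa, fb), only_b = setdiff(fb, fa))
}

#' Adjusted Rand index between two hard labelings
#'
#' @param a,b label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
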