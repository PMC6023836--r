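test_that("standardization gives mean 0, population SD 1", {
  prof <- matrix(c(2, 4, 6), 1, dimnames = list("f1", NULL))
  out <- standardize_profiles(prof)
  expect_equal(unname(out$profiles[1, ]), c(-1.224745, 0, 1.224745),
               tolerance = 1e-6)

  both <- rbind(f1 = c(2, 4, 6), f2 = c(5, 5, 5))
  res <- standardize_profiles(both)
  expect_equal(res$excluded, "f2")
  expect_equal(rownames(res$profiles), "f1")

  # idempotence
  again <- standardize_profiles(res$profiles)
  expect_equal(again$profiles, res$profiles, tolerance = 1e-12)

  expect_error(standardize_profiles(matrix(3, 2, 4)), "zero SD")
})

test_that("fuzzy c-means closed forms hold", {
  set.seed(1)
  X <- matrix(rnorm(60), 10, 6)
  one <- fuzzy_cmeans(X, 1)
  expect_equal(unname(one$centroids[1, ]), colMeans(X))
  expect_true(all(one$membership == 1))

  # duplicated points at two locations: centroids coincide with the points,
  # memberships are crisp
  Y <- rbind(matrix(rep(c(1, 0, 0), 5), 5, byrow = TRUE),
             matrix(rep(c(0, 0, 1), 5), 5, byrow = TRUE))
  fit <- fuzzy_cmeans(Y, 2, seed = 3)
  expect_true(all(fit$membership %in% c(0, 1)))
  expect_equal(sort(fit$centroids[, 1]), c(0, 1))

  expect_error(fuzzy_cmeans(X, 11), "more clusters")
  expect_error(fuzzy_cmeans(X, 2, m = 1), "m must be > 1")
})

test_that("memberships are a partition and J never increases", {
  set.seed(2)
  for (s in 1:5) {
    X <- archetype_panel(c("monotone_down", "monotone_up", "transient_peak"),
                         20, noise_sd = 0.5)$X
    fit <- fuzzy_cmeans(X, 4, seed = s)
    expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
    expect_true(all(diff(fit$J_trace) <= 1e-8))
  }
})

test_that("well-separated planted archetypes are recovered exactly", {
  set.seed(3)
  panel <- archetype_panel(c("monotone_down", "monotone_up"), 25,
                           noise_sd = 0.1)
  fit <- fuzzy_cmeans(panel$X, 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$cluster, panel$truth), 1)
})

test_that("three-archetype recovery is stable across seeds", {
  aris <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    panel <- archetype_panel(c("monotone_down", "monotone_up",
                               "transient_peak"), 50, noise_sd = 0.2)
    fit <- fuzzy_cmeans(panel$X, 3, seed = s)
    adjusted_rand_index(fit$cluster, panel$truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("dmin curve drops once clusters exceed true patterns", {
  set.seed(4)
  panel <- archetype_panel(c("monotone_down", "monotone_up",
                             "postnatal_switch"), 30, noise_sd = 0.2)
  curve <- dmin_curve(panel$X, c_range = 2:5, seed = 9)
  expect_equal(curve$c, 2:5)
  expect_gt(min(curve$dmin[curve$c <= 3]), 2 * max(curve$dmin[curve$c >= 4]))

  single <- dmin_curve(panel$X, c_range = 2, seed = 9)
  expect_equal(nrow(single), 1)

  # one repeated profile only: centroids collapse
  dup <- matrix(rep(c(-1, 0, 1), 12), 12, byrow = TRUE)
  rownames(dup) <- sprintf("d%02d", 1:12)
  flatc <- dmin_curve(dup, c_range = 2:3, seed = 2)
  expect_true(all(flatc$dmin < 1e-6))
})

test_that("cluster ordering starts with downregulated clusters", {
  model <- structure(list(
    centroids = rbind(c(-1, 0, 1), c(1, 0, -1)),
    membership = matrix(c(1, 0, 0, 1), 2, dimnames = list(c("f1", "f2"), NULL)),
    cluster = c(f1 = 1L, f2 = 2L), m = 2, c = 2L, objective = 0,
    J_trace = 0, seed = NULL, restarts = 1L), class = "ClusterModel")
  ord <- order_clusters(model)
  expect_equal(unname(ord$centroids[1, ]), c(1, 0, -1))  # downward first
  expect_equal(ord$cluster, c(f1 = 2L, f2 = 1L))

  # tie on trend: lower mean first
  tie <- model
  tie$centroids <- rbind(c(2, 2, 2), c(0, 0, 0))
  ord2 <- order_clusters(tie)
  expect_equal(unname(ord2$centroids[1, ]), c(0, 0, 0))

  one <- fuzzy_cmeans(matrix(rnorm(30), 10, 3), 1)
  expect_equal(order_clusters(one)$cluster, one$cluster)
})

test_that("cluster overlap tables count shared features", {
  mk <- function(labels) structure(list(
    cluster = labels, c = max(labels),
    membership = matrix(1, length(labels), max(labels),
                        dimnames = list(names(labels), NULL))),
    class = "ClusterModel")
  a <- mk(c(f1 = 1L, f2 = 1L, f3 = 2L, f4 = 2L, f5 = 1L))
  same <- cluster_overlap_table(a, a)
  expect_equal(unname(diag(same$table)), c(3, 2))
  expect_equal(sum(same$table) - sum(diag(same$table)), 0)

  b <- mk(c(f1 = 1L, f2 = 2L, f3 = 2L, f4 = 1L, f6 = 1L))
  tab <- cluster_overlap_table(a, b)
  expect_equal(unname(tab$table), rbind(c(1, 1), c(1, 1)))
  expect_equal(tab$only_a, "f5")
  expect_equal(tab$only_b, "f6")

  disj <- cluster_overlap_table(a, mk(c(x1 = 1L, x2 = 2L)))
  expect_true(all(disj$table == 0))
  expect_setequal(disj$only_a, names(a$cluster))
})

test_that("row permutation permutes memberships identically", {
  set.seed(6)
  panel <- archetype_panel(c("monotone_down", "monotone_up"), 20,
                           noise_sd = 0.1)
  X <- panel$X
  perm <- sample(nrow(X))
  f1 <- fuzzy_cmeans(X, 2, seed = 5, restarts = 8)
  f2 <- fuzzy_cmeans(X[perm, ], 2, seed = 5, restarts = 8)
  # align clusters by centroid proximity, then compare memberships
  cdist <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j)
    sum((f2$centroids[i, ] - f1$centroids[j, ])^2)))
  map <- apply(cdist, 1, which.min)
  expect_equal(unname(f2$membership[rownames(X), map]),
               unname(f1$membership), tolerance = 1e-6)
})
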