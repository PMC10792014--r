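test_that("build_graph collapses pairs per policy and drops self-hits", {
  df <- data.frame(q = c("a", "b", "a"), s = c("b", "a", "a"),
                   x3 = 0, x4 = 0, x5 = 0, x6 = 0, x7 = 0, x8 = 0,
                   x9 = 0, x10 = 0, e = c(1e-20, 1e-18, 1e-50), x12 = 0)
  g <- build_graph(df, "min")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$p, 1e-20)
  expect_equal(build_graph(df, "max")$edges$p, 1e-18)
  expect_equal(build_graph(df, "mean")$edges$p, (1e-20 + 1e-18) / 2)

  df$e <- c("1e-20", "oops", "1e-50")
  expect_error(build_graph(df), "line")
})

test_that("components_at thresholds edges exactly as specified", {
  g <- similarity_graph(
    data.frame(id = c("a", "b", "c")),
    data.frame(v1 = c("a", "b"), v2 = c("b", "c"), p = c(1e-20, 1e-8)))
  p1 <- components_at(g, 1e-15)
  expect_equal(unname(p1$membership[c("a", "b")]),
               rep(unname(p1$membership["a"]), 2))
  expect_false(p1$membership["c"] == p1$membership["a"])
  p2 <- components_at(g, 1e-6)
  expect_equal(length(unique(p2$membership)), 1)
  # threshold equality is inclusive
  p3 <- components_at(g, 1e-8)
  expect_equal(length(unique(p3$membership)), 1)
})

test_that("components match a union-find oracle on random graphs", {
  for (s in 1:10) {
    g <- random_similarity_graph(200, 400, seed = s)
    for (t in c(1e-25, 1e-15, 1e-5)) {
      expect_true(same_partition(components_at(g, t)$membership,
                                 oracle_components(g, t)))
    }
  }
})

test_that("merge_threshold returns the bottleneck P-value", {
  g <- similarity_graph(
    data.frame(id = c("a", "b", "c", "d")),
    data.frame(v1 = c("a", "b"), v2 = c("b", "c"), p = c(1e-30, 1e-12)))
  expect_equal(merge_threshold(g, "a", "c"), 1e-12)
  expect_true(is.na(merge_threshold(g, "a", "d")))
  expect_error(merge_threshold(g, c("a", "b"), c("b", "c")), "disjoint")
})

test_that("merge_threshold equals the threshold-sweep oracle", {
  for (s in 1:15) {
    g <- random_similarity_graph(30, 60, seed = 100 + s)
    ids <- g$vertices$id
    set.seed(s)
    A <- sample(ids, 3); B <- sample(setdiff(ids, A), 3)
    got <- merge_threshold(g, A, B)
    want <- oracle_merge_threshold(g, A, B)
    expect_identical(is.na(got), is.na(want))
    if (!is.na(got)) expect_equal(got, want)
  }
})

test_that("merge_threshold is consistent with components_at", {
  g <- random_similarity_graph(40, 100, seed = 77)
  ids <- g$vertices$id
  A <- ids[1:4]; B <- ids[10:13]
  t0 <- merge_threshold(g, A, B)
  for (t in c(1e-25, 1e-12, 1e-3)) {
    memb <- components_at(g, t)$membership
    joined <- length(intersect(memb[A], memb[B])) > 0
    expect_identical(joined, !is.na(t0) && t0 <= t)
  }
})

test_that("threshold_profile partitions are nested along the ladder", {
  expect_error(threshold_profile(random_similarity_graph(10, 15, 1),
                                 c(1e-6, 1e-35)), "increasing")
  for (s in 1:20) {
    g <- random_similarity_graph(50, 120, seed = 200 + s)
    parts <- threshold_profile(g, c(1e-25, 1e-15, 1e-8, 1e-2))
    sizes <- vapply(parts, function(p) length(unique(p$membership)), 0L)
    expect_true(all(diff(sizes) <= 0))
    for (k in seq_len(length(parts) - 1)) {
      strict <- parts[[k]]$membership; loose <- parts[[k + 1]]$membership
      # every strict component lies inside one loose component
      expect_true(all(tapply(loose, strict,
                             function(x) length(unique(x))) == 1))
    }
  }
  g <- random_similarity_graph(20, 40, seed = 5)
  expect_identical(threshold_profile(g, 1e-10)[[1]]$membership,
                   components_at(g, 1e-10)$membership)
})

test_that("family recovery from simulated similarity is near-perfect", {
  sp <- fixture_species_tree()
  aris <- vapply(1:10, function(s) {
    set.seed(s)
    fams <- lapply(1:3, function(k) ape::rtree(
      20, tip.label = paste0("S", 1:20, "_g", k)))
    names(fams) <- paste0("fam", 1:3)
    g <- simulate_similarity(fams, seed = s)
    part <- components_at(g, 1e-10)
    truth <- stats::setNames(g$vertices$family, g$vertices$id)
    adjusted_rand_index(part$membership, truth)
  }, 0)
  expect_true(all(aris >= 0.95))
})

test_that("annotate_components does majority vote with ties broken lexically", {
  g <- similarity_graph(
    data.frame(id = c("a", "b", "c", "d")),
    data.frame(v1 = c("a", "c"), v2 = c("b", "d"), p = c(1e-9, 1e-9)))
  part <- components_at(g, 1e-6)
  ann <- annotate_components(part, c(a = "CCL", b = "CXCL"))
  expect_equal(unname(ann[as.character(part$membership["a"])]), "CCL")
  expect_match(unname(ann[as.character(part$membership["c"])]), "unnamed")
})

test_that("layout2d is seed-deterministic and separates cliques", {
  ids <- c(paste0("a", 1:6), paste0("b", 1:6))
  cl <- function(v) {
    pr <- t(utils::combn(v, 2))
    data.frame(v1 = pr[, 1], v2 = pr[, 2], p = 1e-20)
  }
  g <- similarity_graph(data.frame(id = ids),
                        rbind(cl(ids[1:6]), cl(ids[7:12])))
  xy0 <- layout2d(g, iterations = 0, seed = 3)
  set.seed(3)
  expect_equal(unname(as.matrix(xy0[, c("x", "y")])),
               matrix(stats::runif(24), ncol = 2))
  xy1 <- layout2d(g, iterations = 400, seed = 3)
  expect_identical(xy1, layout2d(g, iterations = 400, seed = 3))
  pd <- as.matrix(dist(xy1[, c("x", "y")]))
  within <- c(pd[1:6, 1:6][upper.tri(diag(6))],
              pd[7:12, 7:12][upper.tri(diag(6))])
  between <- pd[1:6, 7:12]
  expect_lt(mean(within), mean(between))
})
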