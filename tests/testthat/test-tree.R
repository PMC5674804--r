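test_that("node sampling keeps everything when under-full, else the top-S", {
  set.seed(5)
  small <- ms_points(mz = runif(10, 400, 500), rt = runif(10, 0, 60),
                     intensity = runif(10, 1, 100))
  got <- sample_node(small, 256)
  expect_setequal(got$id, small$id)

  big <- ms_points(mz = runif(1000, 400, 500), rt = runif(1000, 0, 60),
                   intensity = runif(1000, 1, 1e4))
  got <- sample_node(big, 256)
  expect_identical(nrow(got), 256L)
  expect_setequal(got$id, oracle_top_n(big, 256)$id)

  # list-of-child-sets input pools before sampling
  split_got <- sample_node(split(big, rep(1:4, each = 250)), 256)
  expect_setequal(split_got$id, got$id)
})

test_that("sampling ties break on the smaller (mz, rt, id) triple", {
  pts <- ms_points(mz = c(500, 400, 400, 400), rt = c(1, 2, 1, 1),
                   intensity = c(10, 10, 10, 10), id = c(0, 1, 2, 3))
  # S = 2: all tie on intensity; winners are smallest (mz, rt, id)
  got <- sample_node(pts, 2)
  expect_identical(got$id, c(2L, 3L)) # mz 400, rt 1, ids 2 then 3
  expect_identical(whittle(pts, 3)$id, c(2L, 3L, 1L))
})

test_that("whittling returns exactly n by the documented sort rule", {
  set.seed(8)
  cand <- ms_points(mz = runif(500, 300, 1500), rt = runif(500, 0, 600),
                    intensity = runif(500, 1, 1e5))
  expect_setequal(whittle(cand, 500)$id, cand$id) # identity as a set
  got <- whittle(cand, 50)
  expect_identical(nrow(got), 50L)
  expect_setequal(got$id, oracle_top_n(cand, 50)$id)
  expect_error(whittle(cand, 501))

  flat <- ms_points(mz = runif(20, 300, 400), rt = runif(20, 0, 10),
                    intensity = rep(7, 20))
  ord <- order(flat$mz, flat$rt, flat$id)
  expect_setequal(whittle(flat, 5)$id, flat$id[ord[1:5]])
})

test_that("the built tree partitions the culled points and nests bounds", {
  set.seed(3)
  pts <- ms_points(mz = runif(500, 300, 1500), rt = runif(500, 0, 600),
                   intensity = runif(500, 0.2, 50))
  cfg <- lod_config(leaf_capacity = 64, sample_size = 32)
  tree <- build_lod_tree(pts, cfg)
  culled <- cull_points(pts, cfg$intensity_floor)

  # leaves hold exactly the culled multiset, each point exactly once
  gather <- function(node) {
    if (node$leaf) return(tree$points$id[node$leaf_rows])
    unlist(lapply(node$children, gather))
  }
  leaf_ids <- gather(tree$root)
  expect_identical(sort(leaf_ids), sort(culled$id))
  expect_identical(anyDuplicated(leaf_ids), 0L)

  # root bounds are the tight bounding box of the retained points
  b <- tree_bounds(tree)
  expect_identical(c(b$mz_min, b$mz_max), range(culled$mz))
  expect_identical(c(b$rt_min, b$rt_max), range(culled$rt))
  expect_identical(b$point_count, nrow(culled))

  # every child's box lies inside its parent's
  check <- function(node) {
    for (ch in node$children) {
      expect_gte(ch$bounds[["mz_min"]], node$bounds[["mz_min"]])
      expect_lte(ch$bounds[["mz_max"]], node$bounds[["mz_max"]])
      expect_gte(ch$bounds[["rt_min"]], node$bounds[["rt_min"]])
      expect_lte(ch$bounds[["rt_max"]], node$bounds[["rt_max"]])
      check(ch)
    }
  }
  check(tree$root)

  # every sampled reference resolves to a point in some descendant leaf,
  # and internal samples are the top-S of their subtree
  check_sample <- function(node) {
    sub_ids <- gather(node)
    samp_ids <- tree$points$id[node$sample]
    expect_true(all(samp_ids %in% sub_ids))
    sub_pts <- tree$points[match(sub_ids, tree$points$id), ]
    expect_setequal(samp_ids,
                    oracle_top_n(sub_pts, tree$config$sample_size)$id)
    for (ch in node$children) check_sample(ch)
  }
  check_sample(tree$root)
})

test_that("zero retained points give an empty tree whose queries are empty", {
  none <- ms_points(numeric(), numeric(), numeric())
  tree <- build_lod_tree(none)
  expect_identical(nrow(query_points(tree, view_window(0, 1e4, 0, 1e4), 100)),
                   0L)
  expect_identical(tree_bounds(tree)$point_count, 0L)
  # all-noise input culls to the same empty tree
  noisy <- ms_points(mz = runif(50, 300, 400), rt = runif(50, 0, 10),
                     intensity = runif(50, 0.01, 0.9))
  expect_identical(nrow(build_lod_tree(noisy)$points), 0L)
})

test_that("queries equal the brute-force oracle at and below supply", {
  cloud <- make_cloud(10000, seed = 99)
  cfg <- lod_config(leaf_capacity = 128, sample_size = 64)
  tree <- build_lod_tree(cloud, cfg)
  retained <- cull_points(cloud, 1)

  set.seed(1234)
  for (i in 1:50) {
    w <- random_window()
    oracle <- brute_force_query(retained, w)
    supply <- nrow(oracle)

    # n >= supply: exact set equality with the linear scan
    full <- query_points(tree, w, supply + 10)
    expect_setequal(full$id, oracle$id)
    expect_identical(nrow(full), supply)

    # n < supply: exactly n, all in-window, all real, matching the sort rule
    if (supply > 10) {
      n <- supply %/% 2L
      got <- query_points(tree, w, n)
      expect_identical(nrow(got), n)
      expect_true(all(got$mz >= w$mz_min & got$mz <= w$mz_max &
                        got$rt >= w$rt_min & got$rt <= w$rt_max))
      expect_true(all(got$id %in% retained$id))
      expect_setequal(got$id, oracle_top_n(oracle, n)$id)
    }
  }
})

test_that("results at a smaller budget nest inside results at a larger one", {
  cloud <- make_cloud(5000, seed = 55)
  tree <- build_lod_tree(cloud, lod_config(leaf_capacity = 128))
  set.seed(56)
  for (i in 1:10) {
    w <- random_window()
    small <- query_points(tree, w, 25)
    large <- query_points(tree, w, 100)
    expect_true(all(small$id %in% large$id))
  }
})

test_that("level-mode queries honor the budget and shortfall contracts", {
  cloud <- make_cloud(5000, seed = 70)
  tree <- build_lod_tree(cloud, lod_config(leaf_capacity = 128,
                                           sample_size = 64))
  retained <- cull_points(cloud, 1)
  set.seed(71)
  for (i in 1:20) {
    w <- random_window()
    supply <- nrow(brute_force_query(retained, w))
    n <- sample(0:200, 1)
    got <- query_points(tree, w, n, mode = "level")
    expect_identical(nrow(got), min(n, supply))
    if (nrow(got) > 0) {
      expect_true(all(got$mz >= w$mz_min & got$mz <= w$mz_max &
                        got$rt >= w$rt_min & got$rt <= w$rt_max))
      expect_true(all(got$id %in% retained$id))
    }
  }
})

test_that("identical inputs build identical trees with identical answers", {
  cloud <- make_cloud(3000, seed = 42)
  cfg <- lod_config(leaf_capacity = 100, sample_size = 50, seed = 9)
  t1 <- build_lod_tree(cloud, cfg)
  t2 <- build_lod_tree(cloud, cfg)
  expect_identical(t1, t2)
  w <- view_window(500, 900, 100, 400)
  expect_identical(query_points(t1, w, 200), query_points(t2, w, 200))

  f1 <- withr::local_tempfile(fileext = ".idx")
  f2 <- withr::local_tempfile(fileext = ".idx")
  save_lod_index(t1, f1)
  save_lod_index(t2, f2)
  expect_identical(readBin(f1, raw(), file.size(f1)),
                   readBin(f2, raw(), file.size(f2)))
  # reload answers queries identically
  expect_identical(query_points(load_lod_index(f1), w, 200),
                   query_points(t1, w, 200))
})

test_that("tidy and glance summarize the index structure coherently", {
  cloud <- make_cloud(2000, seed = 31)
  tree <- build_lod_tree(cloud, lod_config(leaf_capacity = 100))
  nodes <- tidy(tree)
  g <- glance(tree)
  expect_identical(g$n_nodes, nrow(nodes))
  expect_identical(g$n_leaves, sum(nodes$is_leaf))
  expect_identical(g$n_retained, nrow(tree$points))
  expect_identical(nodes$n_points[1], g$n_retained)
  expect_identical(sum(nodes$n_points[nodes$is_leaf]), g$n_retained)
  expect_true(all(nodes$n_sample <= tree$config$sample_size))
})
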