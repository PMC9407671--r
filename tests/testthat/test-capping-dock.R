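# Docking: site enumeration combinatorics, clash counting vs brute force,
# strand grafting, and rigid-motion invariance.

test_that("sliding-window site counts match the closed form", {
  ss <- c(rep("E", 8), rep("L", 3), rep("E", 6), rep("L", 2), rep("E", 5))
  sites <- enumerate_binding_sites(ss, window = 5)
  expect_equal(nrow(sites), (8 - 5 + 1) + (6 - 5 + 1) + (5 - 5 + 1))
  expect_true(all(sites$length == 5))
  # every window inside one E run
  runs <- ss_runs(ss, "E")
  inside <- vapply(seq_len(nrow(sites)), function(i) {
    any(sites$start[i] >= runs$start & sites$end[i] <= runs$end)
  }, TRUE)
  expect_true(all(inside))
  expect_warning(none <- enumerate_binding_sites(ss, window = 9), "no binding sites")
  expect_equal(nrow(none), 0)
  per_strand <- enumerate_binding_sites(ss, window = 5, mode = "per_strand")
  expect_equal(nrow(per_strand), 3)
  expect_equal(per_strand$length, c(8, 6, 5))
  expect_error(enumerate_binding_sites(ss, window = 2), "minimum")
})

test_that("clash thresholds behave at the boundaries", {
  mk <- function(xyz, ele) data.frame(elesy = ele, x = xyz[, 1], y = xyz[, 2],
                                      z = xyz[, 3])
  a <- mk(matrix(c(0, 0, 0), 1), "C")
  expect_equal(clash_counts(a, mk(matrix(c(10, 0, 0), 1), "C")),
               c(hard = 0L, soft = 0L))
  expect_equal(clash_counts(a, mk(matrix(c(2.0, 0, 0), 1), "C")),
               c(hard = 1L, soft = 0L))
  # 2.6 A C-C: not hard, but < 0.8 * (1.7 + 1.7) = 2.72 -> soft
  expect_equal(clash_counts(a, mk(matrix(c(2.6, 0, 0), 1), "C")),
               c(hard = 0L, soft = 1L))
  expect_equal(clash_counts(a, mk(matrix(c(2.8, 0, 0), 1), "C")),
               c(hard = 0L, soft = 0L))
})

test_that("grid clash counts equal the all-pairs oracle on random sets", {
  for (s in 1:8) {
    set.seed(s)
    na <- 60; nb <- 60
    at_a <- data.frame(elesy = sample(c("C", "N", "O", "S"), na, replace = TRUE),
                       x = runif(na, 0, 15), y = runif(na, 0, 15),
                       z = runif(na, 0, 15))
    at_b <- data.frame(elesy = sample(c("C", "N", "O", "S"), nb, replace = TRUE),
                       x = runif(nb, 0, 15), y = runif(nb, 0, 15),
                       z = runif(nb, 0, 15))
    expect_identical(clash_counts(at_a, at_b), bf_clash_counts(at_a, at_b))
  }
})

test_that("the perfect capper grafts at ~zero rmsd on every site", {
  fixture <- fib_fixture()
  asm <- fixture$asm
  for (endlab in c("plus", "minus")) {
    sites <- enumerate_sites(asm, 1, endlab, window = 6)
    for (i in seq_len(nrow(sites))) {
      cp <- make_complementary_capper(sites[i, ], asm, body_class = "EEH",
                                      seed = 11)
      pose <- graft_scaffold(cp, 1, sites[i, ], asm)
      expect_lt(pose$graft_rmsd, 1e-6)
      expect_equal(pose$hard_clashes, 0L)
      expect_true(pose$accepted)
      expect_equal(pose$orientation, "parallel")
    }
  }
})

test_that("the stored transform is the single source of pose placement", {
  pose <- fib_fixture()$pose
  original <- scaffold_to_model(pose$scaffold, chain = "Z")
  moved <- transform_model(original, pose$transform)
  expect_equal(as.matrix(moved$atoms[, c("x", "y", "z")]),
               as.matrix(pose$posed$atoms[, c("x", "y", "z")]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("docking is invariant under global rigid motion of the fibril", {
  fixture <- fib_fixture()
  pose0 <- fixture$pose
  tf <- rigid_transform(random_rotation(5), c(10, -3, 7))
  moved_model <- transform_model(fixture$fx$model, tf)
  asm2 <- group_layers(moved_model)
  sites2 <- enumerate_sites(asm2, 1, pose0$site$fib_end, window = 6)
  # same site windows enumerated
  expect_equal(sites2$start, fixture$sites$start)
  site2 <- sites2[pose0$site$site_index, ]
  cp2 <- make_complementary_capper(site2, asm2, body_class = "EEH", seed = 11)
  pose2 <- graft_scaffold(cp2, 1, site2, asm2)
  expect_equal(pose2$graft_rmsd, pose0$graft_rmsd, tolerance = 1e-6)
  expect_equal(pose2$hard_clashes, pose0$hard_clashes)
  # an ordinary (non-capper) scaffold docks with identical metrics too
  sc <- build_scaffold(default_blueprint("HEE"), seed = 3)
  pa <- graft_scaffold(sc, 1, fixture$sites[1, ], fixture$asm)
  pb <- graft_scaffold(sc, 1, sites2[1, ], asm2)
  expect_equal(pb$graft_rmsd, pa$graft_rmsd, tolerance = 1e-6)
  expect_equal(pb$hard_clashes, pa$hard_clashes)
  expect_equal(pb$soft_clashes, pa$soft_clashes)
})

test_that("a body built into the fibril hard-clashes and is rejected", {
  fixture <- fib_fixture()
  bad <- clash_capper_body(fixture$capper, fixture$asm, fixture$sites[1, ])
  pose <- graft_scaffold(bad, 1, fixture$sites[1, ], fixture$asm)
  expect_gt(pose$hard_clashes, 0)
  expect_false(pose$accepted)
})

test_that("a strand shorter than the site window is rejected up front", {
  fixture <- fib_fixture()
  sc <- build_scaffold(default_blueprint("HEE", helix_len = 16, strand_len = 5),
                       seed = 2)
  expect_error(graft_scaffold(sc, 1, fixture$sites[1, ], fixture$asm),
               "shorter than the site window")
  expect_error(graft_scaffold(sc, 9, fixture$sites[1, ], fixture$asm),
               "no strand element")
})

test_that("pose complexes write with the scaffold as chain Z", {
  fixture <- fib_fixture()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pose_complex(fixture$pose, fixture$asm, f)
  m <- read_structure(f)
  expect_true("Z" %in% chain_ids(m))
  expect_equal(length(chain_ids(m)),
               length(chain_ids(fixture$fx$model)) + 1)
})
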