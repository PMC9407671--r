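# Fibril assembly: screw-symmetry fitting, protofilament grouping, the
# virtual next layer, and dihedral secondary structure.

test_that("screw fit recovers the generator's rise and twist exactly", {
  fx <- fib_fixture()$fx
  m <- fx$model
  ids <- fx$truth$chains[[1]]
  for (k in seq_len(length(ids) - 1)) {
    sym <- fit_screw_symmetry(chain_backbone(m, ids[k])$bb,
                              chain_backbone(m, ids[k + 1])$bb)
    expect_equal(sym$rise, fx$truth$symmetry$rise, tolerance = 1e-6)
    expect_equal(abs(sym$twist), abs(fx$truth$symmetry$twist), tolerance = 1e-6)
    expect_lt(sym$rmsd, 1e-9)
    # consecutive-pair operators agree with each other
    if (k == 1) first <- sym
    expect_equal(sym$rise, first$rise, tolerance = 1e-6)
    expect_equal(sym$twist, first$twist, tolerance = 1e-6)
  }
})

test_that("a pure translation fits as twist zero with the right rise", {
  bb <- build_backbone(rep(-139, 8), rep(135, 8))
  shifted <- apply_transform(bb, rigid_transform(diag(3), c(0, 0, 4.8)))
  sym <- fit_screw_symmetry(bb, shifted)
  expect_equal(sym$twist, 0, tolerance = 1e-9)
  expect_equal(sym$rise, 4.8, tolerance = 1e-9)
  expect_equal(abs(sym$axis_dir[3]), 1, tolerance = 1e-9)
  expect_error(fit_screw_symmetry(bb, build_backbone(rep(-139, 5), rep(135, 5))),
               "mismatched")
})

test_that("screw fit degrades gracefully under coordinate noise", {
  spec0 <- fibril_spec()
  pair_rise <- pair_twist <- cons_rise <- cons_twist <- numeric(20)
  for (s in 1:20) {
    fx <- make_ideal_fibril(fibril_spec(noise_sd = 0.1, seed = s))
    sym <- fit_screw_symmetry(chain_backbone(fx$model, "A")$bb,
                              chain_backbone(fx$model, "B")$bb)
    pair_rise[s] <- abs(sym$rise - spec0$rise)
    pair_twist[s] <- abs(abs(sym$twist) - abs(spec0$twist))
    cs <- consensus_symmetry(group_layers(fx$model))
    cons_rise[s] <- abs(cs$rise - spec0$rise)
    cons_twist[s] <- abs(abs(cs$twist) - abs(spec0$twist))
  }
  # a single layer pair is noise-limited (the information floor of ~100
  # atoms at sigma = 0.1 A); the whole-fibril consensus meets the tight
  # bounds
  expect_lt(max(pair_rise), 0.15)
  expect_lt(max(pair_twist), 0.5)
  expect_lt(max(cons_rise), 0.05)
  expect_lt(max(cons_twist), 0.5)
})

test_that("the consensus operator pools layer pairs and tightens noisy fits", {
  fixture <- fib_fixture()
  cs <- consensus_symmetry(fixture$asm)
  expect_equal(cs$rise, fixture$fx$truth$symmetry$rise, tolerance = 1e-9)
  expect_equal(abs(cs$twist), abs(fixture$fx$truth$symmetry$twist),
               tolerance = 1e-9)
  expect_equal(cs$n_pairs, 5)
  expect_lt(cs$rise_sd, 1e-9)
  noisy <- make_ideal_fibril(fibril_spec(noise_sd = 0.1, seed = 77))
  csn <- consensus_symmetry(group_layers(noisy$model))
  expect_lt(abs(csn$rise - 4.75), 0.05)
  expect_gt(csn$rise_sd, 0)
})

test_that("layer grouping finds one ordered protofilament", {
  fixture <- fib_fixture()
  asm <- fixture$asm
  expect_length(asm$protofilaments, 1)
  expect_setequal(asm$protofilaments[[1]], fixture$fx$truth$chains[[1]])
  # ordered monotonically along the axis
  cents <- vapply(asm$protofilaments[[1]], function(ch) {
    mean(chain_atoms(asm$model, ch)$z)
  }, 0)
  expect_true(all(diff(cents) > 0) || all(diff(cents) < 0))
})

test_that("two C2-related protofilaments are separated and sized correctly", {
  fx2 <- make_ideal_fibril(fibril_spec(n_protofilaments = 2))
  asm2 <- group_layers(fx2$model)
  expect_length(asm2$protofilaments, 2)
  expect_equal(sort(vapply(asm2$protofilaments, length, 0L)), c(6L, 6L))
  got <- lapply(asm2$protofilaments, sort)
  want <- lapply(fx2$truth$chains, sort)
  expect_setequal(vapply(got, paste, "", collapse = ","),
                  vapply(want, paste, "", collapse = ","))
})

test_that("grouping is invariant to chain order permutation", {
  fx <- fib_fixture()$fx
  at <- fx$model$atoms
  set.seed(3)
  perm <- sample(unique(at$chain))
  at2 <- do.call(rbind, lapply(perm, function(ch) at[at$chain == ch, ]))
  m2 <- structure_model(at2, "permuted")
  asm2 <- group_layers(m2)
  asm1 <- fib_fixture()$asm
  same_or_reversed <- identical(asm2$protofilaments[[1]], asm1$protofilaments[[1]]) ||
    identical(asm2$protofilaments[[1]], rev(asm1$protofilaments[[1]]))
  expect_true(same_or_reversed)
})

test_that("grouping a single chain is a cannot-infer error", {
  fx <- fib_fixture()$fx
  single <- structure_model(chain_atoms(fx$model, "A"), "one chain")
  expect_error(group_layers(single), "fewer than 2")
})

test_that("the virtual next layer reproduces the held-out layer", {
  fixture <- fib_fixture()
  asm <- fixture$asm
  truth <- fixture$fx$truth
  top_end <- generator_top_end(asm, truth)
  vl <- virtual_next_layer(asm, 1, top_end)
  got <- backbone_coords(chain_backbone(vl, "v")$bb)
  want <- backbone_coords(truth$next_layer_above[[1]])
  expect_lt(sqrt(mean(rowSums((got - want)^2))), 1e-6)
  # the opposite end reproduces the layer below the bottom
  other <- if (top_end == "plus") "minus" else "plus"
  vl2 <- virtual_next_layer(asm, 1, other)
  got2 <- backbone_coords(chain_backbone(vl2, "v")$bb)
  want2 <- backbone_coords(truth$next_layer_below[[1]])
  expect_lt(sqrt(mean(rowSums((got2 - want2)^2))), 1e-6)
  expect_error(virtual_next_layer(asm, 99, "plus"), "unknown protofilament")
})

test_that("applying the screw operator twice equals the doubled operator", {
  sym <- screw_symmetry(4.75, -1.2)
  X <- matrix(rnorm(30, sd = 8), 10, 3)
  twice <- apply_transform(apply_transform(X, screw_transform(sym, 1)),
                           screw_transform(sym, 1))
  doubled <- apply_transform(X, screw_transform(sym, 2))
  expect_equal(twice, doubled, tolerance = 1e-10)
  # inverse composes to identity
  back <- apply_transform(apply_transform(X, screw_transform(sym, 1)),
                          screw_transform(sym, -1))
  expect_equal(back, X, tolerance = 1e-10)
})

test_that("minus-end virtual layer of a pure-translation fibril is a -rise shift", {
  fx <- make_ideal_fibril(fibril_spec(twist = 0, n_layers = 4))
  asm <- group_layers(fx$model)
  top_end <- generator_top_end(asm, fx$truth)
  bottom_end <- if (top_end == "plus") "minus" else "plus"
  vl <- virtual_next_layer(asm, 1, bottom_end)
  bottom <- chain_backbone(asm$model, fx$truth$chains[[1]][1])$bb
  got <- chain_backbone(vl, "v")$bb
  shift <- backbone_coords(bottom) - backbone_coords(got)
  expect_equal(colMeans(shift), c(0, 0, fx$truth$symmetry$rise),
               tolerance = 1e-6)
  expect_lt(max(abs(sweep(shift, 2, colMeans(shift)))), 1e-6)
})

test_that("secondary structure basins label ideal geometries", {
  helix <- build_backbone(rep(-57, 10), rep(-47, 10))
  ss_h <- assign_secondary_structure(helix)
  expect_true(all(ss_h[2:9] == "H"))
  expect_equal(ss_h[c(1, 10)], c("L", "L"))
  strand <- build_backbone(rep(-139, 10), rep(135, 10))
  ss_e <- assign_secondary_structure(strand)
  expect_true(all(ss_e[2:9] == "E"))
  tiny <- build_backbone(rep(-57, 2), rep(-47, 2))
  expect_equal(assign_secondary_structure(tiny), c("L", "L"))
})

test_that("fixture layer strands are recovered as E runs inside the truth", {
  fixture <- fib_fixture()
  cb <- chain_backbone(fixture$fx$model, "A")
  ss <- assign_secondary_structure(cb$bb)
  got_runs <- ss_runs(ss, "E")
  true_runs <- fixture$fx$truth$site_runs
  expect_equal(nrow(got_runs), nrow(true_runs))
  for (r in seq_len(nrow(got_runs))) {
    # assigned runs sit inside the true strands, eroded at most by the
    # boundary residues whose dihedrals touch the loops/termini
    expect_gte(got_runs$start[r], true_runs$start[r])
    expect_lte(got_runs$end[r], true_runs$end[r])
    expect_gte(got_runs$length[r], true_runs$length[r] - 2)
  }
})

test_that("short H and E runs are smoothed to loop", {
  lab <- c("L", "H", "H", "H", "L", "E", "E", "L", "E", "E", "E", "L")
  sm <- fibrilcap:::smooth_ss_runs(lab)
  expect_equal(sm, c("L", "L", "L", "L", "L", "L", "L", "L", "E", "E", "E", "L"))
})
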