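test_that("kabsch_fit recovers exact rigid motions", {
  set.seed(11)
  x <- matrix(rnorm(30), 10, 3)
  s0 <- kabsch_fit(x, x)
  expect_lt(s0$rmsd, 1e-9)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # rotate 37 degrees about z, translate (1,2,3): fit inverts it exactly
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  y <- sweep(x %*% t(R), 2, c(1, 2, 3), "+")
  s <- kabsch_fit(y, x)
  expect_lt(s$rmsd, 1e-9)
  expect_equal(s$rotation %*% R, diag(3), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-8)
})

test_that("kabsch_fit rejects degenerate input", {
  expect_error(kabsch_fit(matrix(0, 2, 3), matrix(0, 2, 3)), "3")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(kabsch_fit(line, line), "collinear|degenerate")
})

test_that("kabsch_fit attains the brute-force rotation-grid optimum", {
  set.seed(7)
  for (rep in 1:3) {
    x <- matrix(rnorm(18), 6, 3)
    y <- sweep(x %*% t(random_rotation()), 2, rnorm(3), "+") +
      matrix(rnorm(18, 0, 0.1), 6, 3)
    s <- kabsch_fit(y, x)
    oracle <- rotation_grid_oracle(y, x)
    expect_lte(s$rmsd, oracle$grid_min + 1e-9)
    expect_equal(s$rmsd, oracle$refined_min, tolerance = 1e-6)
  }
})

test_that("rmsd is invariant under proper rigid motion of either input", {
  set.seed(21)
  a <- fixture_bundle()$bundle
  b <- fixture_bundle2()$bundle
  r0 <- rmsd_between(a, b, "kabsch")
  for (rep in 1:3) {
    bm <- rigidly_move_bundle(b, random_rotation(), rnorm(3, 0, 20))
    expect_equal(rmsd_between(a, bm, "kabsch"), r0, tolerance = 1e-9)
  }
  s0 <- rmsd_between(a, b, "ssm")
  bm <- rigidly_move_bundle(b, random_rotation(), rnorm(3, 0, 20))
  expect_equal(rmsd_between(a, bm, "ssm"), s0, tolerance = 1e-9)
})

test_that("rmsd_between is symmetric and zero on self", {
  a <- fixture_bundle()$bundle
  b <- fixture_bundle2()$bundle
  expect_equal(rmsd_between(a, a, "kabsch"), 0, tolerance = 1e-9)
  expect_equal(rmsd_between(a, a, "ssm"), 0, tolerance = 1e-9)
  expect_equal(rmsd_between(a, b, "kabsch"), rmsd_between(b, a, "kabsch"),
               tolerance = 1e-6)
  expect_equal(rmsd_between(a, b, "ssm"), rmsd_between(b, a, "ssm"),
               tolerance = 1e-6)
})

test_that("ssm fit isolates a rigidly shifted helix", {
  fx <- fixture_bundle()
  ref <- fx$bundle
  ch <- perturb(fx$chain, fx$map, helix = 3, translation = c(2, 0, 0),
                sigma = 0)
  moved <- extract_bundle(ch, fx$map)
  sup <- ssm_fit(moved, ref)
  d <- per_position_deviation(transform_bundle(moved, sup), ref)
  h3 <- ref$positions$helix == 3L
  expect_equal(mean(d[h3]), 2, tolerance = 0.05)
  expect_lt(max(d[!h3]), 0.05)
  # matched set excludes the displaced helix
  expect_lte(sup$n_matched, 200L - sum(h3))
})

test_that("per-position deviation vanishes for self and for pure offsets", {
  a <- fixture_bundle()$bundle
  expect_equal(unname(per_position_deviation(a, a)), rep(0, 200))
  # a uniform 1.5 A z-offset is pure rigid motion: removed by fitting
  b <- rigidly_move_bundle(a, diag(3), c(0, 0, 1.5))
  sup <- kabsch_fit(b$xyz, a$xyz)
  expect_lt(max(per_position_deviation(transform_bundle(b, sup), a)), 1e-9)
})

test_that("a tilted helix deviates progressively toward its moving end", {
  fx <- fixture_bundle()
  ref <- fx$bundle
  def <- bundle_definition()
  # rotate helix VI 10 degrees about an axis through its base
  lo <- bw_to_author(fx$map, "6.29")
  base_ca <- ca_trace(fx$chain)
  base <- as.numeric(base_ca[base_ca$resno == lo, c("x", "y", "z")])
  ch <- fx$chain
  sel <- !ch$atoms$het & ch$atoms$resno >= lo &
    ch$atoms$resno <= bw_to_author(fx$map, "6.60")
  R <- tmbundle:::rotation_about_axis(c(1, 0, 0), 10)
  xyz <- as.matrix(ch$atoms[sel, c("x", "y", "z")])
  ch$atoms[sel, c("x", "y", "z")] <- sweep(
    sweep(xyz, 2, base) %*% t(R), 2, base, "+")
  moved <- extract_bundle(ch, fx$map)
  sup <- ssm_fit(moved, ref)
  d <- per_position_deviation(transform_bundle(moved, sup), ref)
  h6 <- ref$positions$helix == 6L
  expect_lt(max(d[!h6]), 0.1)
  d6 <- d[h6]
  # grows from the fixed base toward the free end
  expect_lt(d6[1L], 0.15)
  expect_gt(d6[length(d6)], 1)
  expect_gt(stats::cor(seq_along(d6), d6), 0.95)
})

test_that("deviation profile is robust to the choice of reference", {
  dir <- withr::local_tempdir()
  ens <- make_ensemble(9, dir, receptor_ids = c("ra", "rb", "rc"),
                       sigma = 0.1, seed = 5)
  bundles <- lapply(seq_len(9), function(i) {
    ch <- select_chain(read_structure(ens$files[i]),
                       ens$ledger$entry_id[i], "A")
    extract_bundle(ch, ens$maps[[ens$ledger$receptor_id[i]]])
  })
  p1 <- deviation_profile(bundles, bundles[[1L]], "common_reference", "ssm")
  p2 <- deviation_profile(bundles, bundles[[5L]], "common_reference", "ssm")
  expect_lt(max(abs(p1$mean_dev - p2$mean_dev)), 0.3)
})

test_that("kabsch_fit agrees with an independent library superposition", {
  set.seed(33)
  x <- matrix(rnorm(60), 20, 3)
  y <- sweep(x %*% t(random_rotation()), 2, rnorm(3), "+") +
    matrix(rnorm(60, 0, 0.3), 20, 3)
  ours <- kabsch_fit(y, x)
  fitted <- bio3d::fit.xyz(fixed = as.vector(t(x)), mobile = as.vector(t(y)),
                           fixed.inds = bio3d::atom2xyz(1:20),
                           mobile.inds = bio3d::atom2xyz(1:20))
  ref_rmsd <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) -
                                 x)^2)))
  expect_equal(ours$rmsd, ref_rmsd, tolerance = 1e-6)
})
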