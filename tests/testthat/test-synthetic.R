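test_that("ideal helices have canonical alpha-helix geometry", {
  ca <- ideal_helix(25)
  d1 <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d1 - 3.8) < 0.1))
  d4 <- sqrt(rowSums((ca[5:25, ] - ca[1:21, ])^2))
  expect_true(all(abs(d4 - 6.2) < 0.4))
  # along (0,0,1) from origin 0, z climbs by the rise per residue
  expect_equal(ca[, 3], 1.5 * (0:24))
  expect_error(ideal_helix(3), "4")
})

test_that("backbone-mode helices are assigned alpha-helical", {
  bb_long <- ideal_helix(30, with_backbone = TRUE)
  bb <- tmbundle:::finish_backbone(bb_long)
  ss <- assign_helix(bb)
  expect_gte(mean(ss$labels == "H"), 0.8)
  # CA geometry still canonical after the internal-coordinate build
  ca <- as.matrix(bb[, c("ca_x", "ca_y", "ca_z")])
  d1 <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(d1 - 3.8) < 0.15))
})

test_that("build_bundle produces a complete, extractable 200-residue bundle", {
  fx <- fixture_bundle()
  expect_equal(nrow(fx$bundle$positions), 200L)
  expect_equal(sequence_identity(fx$bundle, fx$bundle), 100)
  expect_error(build_bundle(sequence = "ACDE"), "200")
  # sequences differing at 75 positions give identity 62.5
  s1 <- strrep("A", 200)
  s2 <- paste0(strrep("G", 75), strrep("A", 125))
  b1 <- extract_bundle(build_bundle(sequence = s1)$chain,
                       build_bundle(sequence = s1)$map)
  b2 <- extract_bundle(build_bundle(sequence = s2)$chain,
                       build_bundle(sequence = s2)$map)
  expect_equal(sequence_identity(b1, b2), 62.5)
})

test_that("perturb applies exact rigid translations and is seeded", {
  fx <- fixture_bundle()
  p <- perturb(fx$chain, fx$map, helix = 3, translation = c(2, 0, 0),
               sigma = 0)
  moved <- as.matrix(p$atoms[, c("x", "y", "z")]) -
    as.matrix(fx$chain$atoms[, c("x", "y", "z")])
  def <- bundle_definition()
  lo <- bw_to_author(fx$map, "3.22"); hi <- bw_to_author(fx$map, "3.55")
  in3 <- fx$chain$atoms$resno >= lo & fx$chain$atoms$resno <= hi
  expect_true(all(abs(moved[in3, 1] - 2) < 1e-12))
  expect_true(all(abs(moved[!in3, ]) < 1e-12))
  # determinism under a fixed seed
  a <- perturb(fx$chain, fx$map, sigma = 0.2, seed = 99)
  b <- perturb(fx$chain, fx$map, sigma = 0.2, seed = 99)
  expect_identical(a$atoms, b$atoms)
  c2 <- perturb(fx$chain, fx$map, sigma = 0.2, seed = 100)
  expect_false(identical(a$atoms, c2$atoms))
})

test_that("rotation about the helix axis displaces with radius", {
  fx <- fixture_bundle()
  p <- perturb(fx$chain, fx$map, helix = 3, rot_angle = 10, sigma = 0)
  d <- sqrt(rowSums((as.matrix(p$atoms[, c("x", "y", "z")]) -
                     as.matrix(fx$chain$atoms[, c("x", "y", "z")]))^2))
  lo <- bw_to_author(fx$map, "3.22"); hi <- bw_to_author(fx$map, "3.55")
  in3 <- fx$chain$atoms$resno >= lo & fx$chain$atoms$resno <= hi
  expect_true(all(d[!in3] < 1e-12))
  # all helix III CAs sit at the same radius (2.3 A): equal displacement,
  # matching 2 * r * sin(theta / 2)
  expect_true(all(abs(d[in3] - 2 * 2.3 * sin(5 * pi / 180)) < 0.05))
})

test_that("make_ensemble writes files, ledger, maps and truth table", {
  dir <- withr::local_tempdir()
  ens <- make_ensemble(4, dir, receptor_ids = c("ra", "rb"),
                       sigma = 0.05, seed = 2)
  expect_length(ens$files, 4L)
  expect_true(all(file.exists(ens$files)))
  expect_equal(nrow(ens$truth), 4L)
  expect_true(file.exists(file.path(dir, "ledger.tsv")))
  expect_true(file.exists(file.path(dir, "maps", "ra.map")))
  led <- read_chain_ledger(file.path(dir, "ledger.tsv"))
  expect_equal(led$state, rep("inactivated", 4L))
  # same receptor shares a sequence; different receptors differ
  bs <- lapply(1:4, function(i) {
    ch <- select_chain(read_structure(ens$files[i]), ens$truth$entry[i], "A")
    extract_bundle(ch, ens$maps[[led$receptor_id[i]]])
  })
  expect_equal(sequence_identity(bs[[1]], bs[[3]]), 100)
  expect_lt(sequence_identity(bs[[1]], bs[[2]]), 50)
})

test_that("quiet ensembles yield flat deviation profiles, perturbed ones peak", {
  dir <- withr::local_tempdir()
  ens <- make_ensemble(9, dir, sigma = 0.1, seed = 31)
  bundles <- lapply(1:9, function(i) {
    ch <- select_chain(read_structure(ens$files[i]), ens$truth$entry[i], "A")
    extract_bundle(ch, ens$maps[["syn"]])
  })
  prof <- deviation_profile(bundles, bundles[[1L]], "common_reference", "ssm")
  expect_equal(prof$n_pairs[1L], 36L)
  expect_true(all(prof$mean_dev < 0.4))
  # shift chain 9's helix III by 2 A: elevation localises to helix III
  pert <- data.frame(chain = 9, helix = 3, dx = 2, dy = 0, dz = 0)
  ens2 <- make_ensemble(9, dir = withr::local_tempdir(),
                        perturbations = pert, sigma = 0.1, seed = 31)
  bundles2 <- lapply(1:9, function(i) {
    ch <- select_chain(read_structure(ens2$files[i]), ens2$truth$entry[i], "A")
    extract_bundle(ch, ens2$maps[["syn"]])
  })
  prof2 <- deviation_profile(bundles2, bundles2[[1L]],
                             "common_reference", "ssm")
  h3 <- prof2$helix == 3L
  expect_gt(mean(prof2$mean_dev[h3]), mean(prof2$mean_dev[!h3]) + 0.2)
  expect_true(all(abs(prof2$mean_dev[!h3] - prof$mean_dev[!h3]) < 0.2))
})
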