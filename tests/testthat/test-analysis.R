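test_that("ligand class determines activation state, unknowns error", {
  expect_equal(classify_chain("inverse_agonist"), "inactivated")
  expect_equal(classify_chain("antagonist"), "inactivated")
  expect_equal(classify_chain("agonist"), "activated")
  expect_equal(classify_chain("ligand_free"), "activated")
  expect_error(classify_chain("allosteric"), "unknown ligand class")
})

test_that("receptor-pair grouping obeys the closed-form counts", {
  # the study's inactivated chain census: 10 receptors
  counts <- c(11, 5, 5, 12, 6, 5, 2, 1, 1, 2)
  expect_equal(receptor_pair_group_count(counts), 53L)
  # after excluding 7 chains of one receptor the chain total drops 50 -> 43
  expect_equal(sum(counts) - 7, 43)
  expect_equal(choose(50, 2), 1225)
  expect_equal(choose(43, 2), 903)
  expect_equal(choose(11, 2), 55)
})

test_that("average_by_receptor_pair groups and counts chain pairs", {
  # 5 chains of 3 receptors: a x2, b x2, c x1
  fx <- fixture_bundle()
  mk <- function(id, rid) {
    b <- fx$bundle; b$entry_id <- id; b$receptor_id <- rid; b
  }
  bundles <- list(mk("E1", "a"), mk("E2", "a"), mk("E3", "b"),
                  mk("E4", "b"), mk("E5", "c"))
  m <- pairwise_rmsd_matrix(bundles, "kabsch")
  expect_equal(sum(upper.tri(m)), 10L)
  receptors <- vapply(bundles, function(b) b$receptor_id, "")
  grid <- average_by_receptor_pair(m, receptors,
                                   pairwise_identity_matrix(bundles))
  # groups: 3 cross + self for a and b (c has one chain) = 5
  expect_equal(nrow(grid), 5L)
  key <- paste(grid$receptor_a, grid$receptor_b)
  expect_equal(grid$n[key == "a a"], 1L)
  expect_equal(grid$n[key == "a b"], 4L)
  expect_equal(grid$n[key == "a c"], 2L)
  expect_false("c c" %in% key)
  expect_equal(sum(grid$n), 10L)
  # identical chains: self means are exactly zero, identity 100
  expect_equal(grid$mean[key == "a a"], 0)
  expect_equal(grid$mean_identity[key == "a a"], 100)
})

test_that("deviation_profile needs two bundles and zeroes on duplicates", {
  a <- fixture_bundle()$bundle
  expect_error(deviation_profile(list(a)), "2")
  p <- deviation_profile(list(a, a, a), a, "common_reference", "kabsch")
  expect_equal(nrow(p), 200L)
  expect_true(all(p$mean_dev < 1e-9))
  expect_equal(p$n_pairs[1L], 3L)
})

test_that("sectional rmsds obey the weighted-square decomposition exactly", {
  fx <- fixture_bundle()
  sec <- section_definition(fx$bundle)
  a <- fx$bundle
  b <- fixture_bundle2()$bundle
  bb <- b
  set.seed(4)
  bb$xyz <- b$xyz + matrix(rnorm(600, 0, 0.5), 200, 3)
  v <- sectional_rmsd(a, bb, sec, "kabsch")
  n_s <- table(assign_section(a$positions$bw, sec))
  expect_equal(attr(v, "total")^2,
               sum(as.numeric(n_s) * v^2) / 200, tolerance = 1e-12)
  # identical bundles: five zeros
  v0 <- sectional_rmsd(a, a, sec, "kabsch")
  expect_lt(max(v0), 1e-9)
})

test_that("a difference confined to one section appears only there", {
  fx <- fixture_bundle()
  sec <- section_definition(fx$bundle)
  a <- fx$bundle
  b <- a
  s1 <- assign_section(a$positions$bw, sec) == 1L
  set.seed(8)
  b$xyz[s1, ] <- b$xyz[s1, ] + matrix(rnorm(3 * sum(s1), 0, 0.8),
                                      sum(s1), 3)
  v <- sectional_rmsd(a, b, sec, "ssm")
  expect_gt(v[["section1"]], 0.4)
  expect_true(all(v[paste0("section", 2:5)] < 0.15))
})

test_that("sequence identity is symmetric, 100 on self, arithmetic on diffs", {
  a <- fixture_bundle()$bundle
  b <- fixture_bundle2()$bundle
  expect_equal(sequence_identity(a, a), 100)
  expect_equal(sequence_identity(a, b), sequence_identity(b, a))
  d <- a
  d$positions$aa[1:50] <- "W"
  expect_equal(sequence_identity(a, d), 75.0)
})

test_that("isolated-helix comparison recovers injected rigid displacements", {
  fx <- fixture_bundle()
  ref <- fx$bundle
  for (d in c(0.5, 1, 2, 4)) {
    ch <- perturb(fx$chain, fx$map, helix = 3, translation = c(d, 0, 0),
                  sigma = 0.2, seed = 17)
    bun <- extract_bundle(ch, fx$map)
    r <- isolated_helix_comparison(list(bun), 3L, ref, "ssm")
    expect_lt(abs(r$bundle_frame_dev - d), 0.15)
    # helix shape itself is unchanged: isolated fit absorbs the motion
    expect_lt(r$isolated_rmsd, 2.5 * 0.2)
  }
  # unperturbed chain: both measures near zero
  r0 <- isolated_helix_comparison(list(ref), 3L, ref, "ssm")
  expect_lt(r0$bundle_frame_dev, 1e-9)
  expect_lt(r0$isolated_rmsd, 1e-9)
})

test_that("ionic lock detection follows the distance and partner rules", {
  fx <- fixture_bundle()
  r350 <- bw_to_author(fx$map, "3.50")
  r630 <- bw_to_author(fx$map, "6.30")
  locked <- add_ionic_lock_sidechains(fx$chain, r350, r630, "GLU", 2.8)
  st <- ionic_lock_state(locked, fx$map)
  expect_equal(st$state, "locked")
  expect_equal(st$min_distance, 2.8, tolerance = 0.01)
  # beyond the 4.0 A default: unlocked
  open <- add_ionic_lock_sidechains(fx$chain, r350, r630, "GLU", 4.5)
  expect_equal(ionic_lock_state(open, fx$map)$state, "unlocked")
  # asp partner works identically
  asp <- add_ionic_lock_sidechains(fx$chain, r350, r630, "ASP", 3.0)
  expect_equal(ionic_lock_state(asp, fx$map)$state, "locked")
  # alanine at 6.30: no acidic partner regardless of geometry
  ala <- locked
  ala$atoms <- ala$atoms[!(ala$atoms$resno == r630 &
                           ala$atoms$atom_name %in% c("OE1", "OE2")), ]
  ala$atoms$resname[ala$atoms$resno == r630] <- "ALA"
  expect_equal(ionic_lock_state(ala, fx$map)$state, "no_acidic_partner")
  # acidic partner but side chains unresolved: indeterminate
  ind <- locked
  ind$atoms <- ind$atoms[!(ind$atoms$atom_name %in%
                           c("NE", "NH1", "NH2")), ]
  expect_equal(ionic_lock_state(ind, fx$map)$state, "indeterminate")
  # non-arginine at 3.50: unlocked with a warning
  nonarg <- locked
  nonarg$atoms$resname[nonarg$atoms$resno == r350] <- "LYS"
  expect_warning(st2 <- ionic_lock_state(nonarg, fx$map), "not Arg")
  expect_equal(st2$state, "unlocked")
})

test_that("outlier screening flags regionally displaced chains", {
  fx <- fixture_bundle()
  mk <- function(i, chain) {
    ch <- chain; ch$entry_id <- sprintf("E%d", i)
    extract_bundle(ch, fx$map)
  }
  displaced <- fx$chain
  # displace the helix I N-terminal third by 3 A
  lo <- bw_to_author(fx$map, "1.35"); hi <- bw_to_author(fx$map, "1.44")
  sel <- displaced$atoms$resno >= lo & displaced$atoms$resno <= hi
  displaced$atoms[sel, "x"] <- displaced$atoms[sel, "x"] + 3
  bundles <- list(mk(1, fx$chain), mk(2, fx$chain), mk(3, displaced))
  scr <- outlier_screen(bundles, c("1.35", "1.44"), threshold = 2,
                        method = "ssm")
  expect_equal(scr$flagged, c(FALSE, FALSE, TRUE))
  # homogeneous set: nothing flagged
  hom <- outlier_screen(list(mk(1, fx$chain), mk(2, fx$chain)),
                        c("1.35", "1.44"), threshold = 2)
  expect_false(any(hom$flagged))
  # threshold zero: every non-medoid chain flagged (degenerate but defined)
  noisy <- lapply(1:3, function(i) {
    ch <- perturb(fx$chain, fx$map, sigma = 0.1, seed = i)
    ch$entry_id <- sprintf("N%d", i)
    extract_bundle(ch, fx$map)
  })
  scr0 <- outlier_screen(noisy, c("1.35", "1.44"), threshold = 0)
  expect_equal(sum(scr0$flagged), 2L)
})
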