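test_that("amide hydrogen is placed opposing the carbonyl at 1.0 A", {
  # hand-computed collinear toy geometry
  H <- reconstruct_amide_h(prev_C = c(0, 0, 0), prev_O = c(0, 1, 0),
                           N = c(1.33, 0, 0))
  expect_equal(H, c(1.33 + sqrt(2) / 2, -sqrt(2) / 2, 0), tolerance = 1e-9)
  # N-H distance is 1.0 by construction for arbitrary geometry
  set.seed(3)
  for (i in 1:5) {
    C <- rnorm(3); O <- C + rnorm(3); N <- C + rnorm(3)
    h <- reconstruct_amide_h(C, O, N)
    expect_equal(sqrt(sum((h - N)^2)), 1.0, tolerance = 1e-9)
  }
})

test_that("backbone extraction skips H for chain start and prolines", {
  b <- build_bundle(sequence = paste0("PA", strrep("A", 198)),
                    with_backbone = TRUE)
  bb <- backbone_residues(b$chain)
  expect_true(is.na(bb$h_x[1L]))              # chain start
  expect_true(all(is.na(bb$h_x[toupper(bb$resname) == "PRO"])))
  # H exists everywhere except prolines and the first residue of each
  # helix, which has no covalently bonded predecessor
  def <- bundle_definition()
  helix_starts <- 100L * (1:7) + def$start
  regular <- !(bb$resno %in% helix_starts) & toupper(bb$resname) != "PRO"
  expect_false(anyNA(bb$h_x[regular]))
})

test_that("ideal helix i->i+4 pairs are hydrogen bonded, distant pairs not", {
  b <- build_bundle(with_backbone = TRUE)
  bb <- backbone_residues(b$chain)
  h1 <- bb[1:25, ]                             # helix I residues
  e <- hbond_energy(h1[9, ], h1[5, ])          # donor i+4, acceptor i
  expect_lt(e, -0.5)
  # residues ~30 A apart: the four 1/r terms cancel toward zero
  far <- which.max(sqrt((bb$ca_x - bb$ca_x[5])^2 +
                        (bb$ca_y - bb$ca_y[5])^2 +
                        (bb$ca_z - bb$ca_z[5])^2))
  expect_lt(abs(hbond_energy(bb[far, ], bb[5, ])), 0.05)
})

test_that("hbond energy is role-asymmetric and rigid-motion invariant", {
  b <- build_bundle(with_backbone = TRUE)
  bb <- backbone_residues(b$chain)
  e1 <- hbond_energy(bb[9, ], bb[5, ])
  e2 <- hbond_energy(bb[5, ], bb[9, ])
  expect_gt(abs(e1 - e2), 0.1)                 # donor/acceptor roles differ
  set.seed(9)
  R <- random_rotation(); t <- rnorm(3, 0, 10)
  move <- function(row) {
    for (p in c("n", "ca", "c", "o", "h")) {
      v <- c(row[[paste0(p, "_x")]], row[[paste0(p, "_y")]],
             row[[paste0(p, "_z")]])
      v2 <- drop(R %*% v) + t
      row[[paste0(p, "_x")]] <- v2[1]; row[[paste0(p, "_y")]] <- v2[2]
      row[[paste0(p, "_z")]] <- v2[3]
    }
    row
  }
  expect_equal(hbond_energy(move(bb[9, ]), move(bb[5, ])), e1,
               tolerance = 1e-9)
})

test_that("helix assignment labels ideal helices H and strands not", {
  bb30 <- tmbundle:::ideal_backbone(30)
  bb30$resname <- "ALA"
  bb30 <- tmbundle:::finish_backbone(bb30)
  ss <- assign_helix(bb30)
  expect_gte(mean(ss$labels == "H"), 0.8)
  # extended strand dihedrals: no alpha-helical hydrogen bonds
  strand <- tmbundle:::ideal_backbone(30, phi = -139, psi = 135)
  strand$resname <- "ALA"
  strand <- tmbundle:::finish_backbone(strand)
  ss2 <- assign_helix(strand)
  expect_false(any(ss2$labels == "H"))
  expect_error(assign_helix(bb30[1:4, ]), "5")
})

test_that("synthetic bundles with backbones assign helix at every TM segment", {
  b <- build_bundle(with_backbone = TRUE)
  bb <- backbone_residues(b$chain)
  def <- bundle_definition()
  ss <- assign_helix(bb)
  starts <- cumsum(c(1, head(def$length, -1)))
  for (h in 1:7) {
    sel <- starts[h]:(starts[h] + def$length[h] - 1L)
    expect_gte(mean(ss$labels[sel] == "H"), 0.8)
  }
})

test_that("kink angles separate straight from bent helices", {
  ca <- ideal_helix(30)
  expect_lt(max(kink_angle(ca)), 5)
  expect_true(is_regular_helix(ca))
  # bend 30 degrees at the midpoint
  bent <- ca
  R <- tmbundle:::rotation_about_axis(c(1, 0, 0), 30)
  pivot <- ca[15, ]
  bent[16:30, ] <- sweep(sweep(ca[16:30, ], 2, pivot) %*% t(R), 2,
                         pivot, "+")
  ka <- kink_angle(bent)
  expect_equal(max(ka), 30, tolerance = 5)
  expect_false(is_regular_helix(bent))
  expect_error(kink_angle(ca[1:10, ], window = 7), "short")
})
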