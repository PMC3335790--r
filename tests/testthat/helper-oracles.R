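# Independent brute-force oracle for rigid-body superposition: searches
# proper rotations on an Euler-angle grid (optimal translation in closed
# form at each grid point), then refines the best grid point by
# Nelder-Mead.  Shares no code with the SVD path under test.

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

grid_fit_rmsd <- function(angles, moving, fixed) {
  R <- euler_rotation(angles[1], angles[2], angles[3])
  mv <- sweep(moving, 2, colMeans(moving)) %*% t(R)
  fx <- sweep(fixed, 2, colMeans(fixed))
  sqrt(mean(rowSums((mv - fx)^2)))
}

# returns list(grid_min = best rmsd on the raw grid,
#              refined_min = rmsd after Nelder-Mead from the best point)
rotation_grid_oracle <- function(moving, fixed, step_deg = 15) {
  s <- step_deg * pi / 180
  alphas <- seq(0, 2 * pi - s / 2, by = s)
  betas <- seq(0, pi, by = s)
  gammas <- alphas
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in alphas) for (b in betas) for (g in gammas) {
    r <- grid_fit_rmsd(c(a, b, g), moving, fixed)
    if (r < best) { best <- r; best_ang <- c(a, b, g) }
  }
  ref <- stats::optim(best_ang, grid_fit_rmsd, moving = moving,
                      fixed = fixed,
                      control = list(reltol = 1e-14, maxit = 5000))
  list(grid_min = best, refined_min = ref$value)
}
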