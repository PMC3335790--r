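#' Backbone residues of a chain
#'
#' Collects N, CA, C, O coordinates per residue (altlocs resolved as for
#' [ca_trace()]: highest occupancy, ties prefer "A" then blank) and
#' reconstructs the amide hydrogen, which crystal structures lack.
#' Residues missing any backbone heavy atom are dropped.
#'
#' @param chain A `ChainModel`.
#' @return Data frame with one row per residue: `resno`, `resname`, and
#'   coordinates `n_*`, `ca_*`, `c_*`, `o_*`, `h_*` (x/y/z; `h_*` is NA
#'   for the first residue and for prolines).
#' @export
backbone_residues <- function(chain) {
  stopifnot(inherits(chain, "ChainModel"))
  a <- chain$atoms
  a <- a[!a$het & a$atom_name %in% c("N", "CA", "C", "O"), , drop = FALSE]
  key <- paste(a$resno, a$icode, sep = "|")
  res_keys <- unique(key)
  rows <- lapply(res_keys, function(k) {
    r <- a[key == k, , drop = FALSE]
    get1 <- function(name) {
      s <- r[r$atom_name == name, , drop = FALSE]
      if (nrow(s) == 0L) return(NULL)
      if (nrow(s) > 1L) {
        s <- s[order(-s$occupancy, s$altloc != "A", s$altloc != ""), ,
               drop = FALSE]
      }
      c(s$x[1L], s$y[1L], s$z[1L])
    }
    n <- get1("N"); ca <- get1("CA"); cc <- get1("C"); o <- get1("O")
    if (is.null(n) || is.null(ca) || is.null(cc) || is.null(o)) return(NULL)
    data.frame(resno = r$resno[1L], resname = r$resname[1L],
               n_x = n[1], n_y = n[2], n_z = n[3],
               ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
               c_x = cc[1], c_y = cc[2], c_z = cc[3],
               o_x = o[1], o_y = o[2], o_z = o[3],
               stringsAsFactors = FALSE)
  })
  bb <- do.call(rbind, rows)
  if (is.null(bb) || nrow(bb) == 0L)
    stop("no complete backbone residues in ", chain$entry_id, "-",
         chain$chain_id)
  bb$h_x <- NA_real_; bb$h_y <- NA_real_; bb$h_z <- NA_real_
  for (i in seq_len(nrow(bb))[-1L]) {
    if (toupper(bb$resname[i]) == "PRO") next
    gap <- sqrt((bb$n_x[i] - bb$c_x[i - 1L])^2 +
                (bb$n_y[i] - bb$c_y[i - 1L])^2 +
                (bb$n_z[i] - bb$c_z[i - 1L])^2)
    if (gap > 2.5) next                     # chain break: no bonded predecessor
    h <- reconstruct_amide_h(
      prev_C = c(bb$c_x[i - 1L], bb$c_y[i - 1L], bb$c_z[i - 1L]),
      prev_O = c(bb$o_x[i - 1L], bb$o_y[i - 1L], bb$o_z[i - 1L]),
      N = c(bb$n_x[i], bb$n_y[i], bb$n_z[i])
    )
    bb$h_x[i] <- h[1]; bb$h_y[i] <- h[2]; bb$h_z[i] <- h[3]
  }
  rownames(bb) <- NULL
  bb
}

# wide per-residue backbone frame from a long (resno, atom_name, x, y, z)
# table, with amide hydrogens reconstructed; used for generated backbones
finish_backbone <- function(bb_long) {
  resnos <- unique(bb_long$resno)
  rows <- lapply(resnos, function(rn) {
    r <- bb_long[bb_long$resno == rn, , drop = FALSE]
    g <- function(name) {
      s <- r[r$atom_name == name, , drop = FALSE]
      c(s$x[1L], s$y[1L], s$z[1L])
    }
    n <- g("N"); ca <- g("CA"); cc <- g("C"); o <- g("O")
    data.frame(resno = rn,
               resname = if ("resname" %in% names(r)) r$resname[1L] else "ALA",
               n_x = n[1], n_y = n[2], n_z = n[3],
               ca_x = ca[1], ca_y = ca[2], ca_z = ca[3],
               c_x = cc[1], c_y = cc[2], c_z = cc[3],
               o_x = o[1], o_y = o[2], o_z = o[3],
               stringsAsFactors = FALSE)
  })
  bb <- do.call(rbind, rows)
  bb$h_x <- NA_real_; bb$h_y <- NA_real_; bb$h_z <- NA_real_
  for (i in seq_len(nrow(bb))[-1L]) {
    if (toupper(bb$resname[i]) == "PRO") next
    gap <- sqrt((bb$n_x[i] - bb$c_x[i - 1L])^2 +
                (bb$n_y[i] - bb$c_y[i - 1L])^2 +
                (bb$n_z[i] - bb$c_z[i - 1L])^2)
    if (gap > 2.5) next                     # chain break: no bonded predecessor
    h <- reconstruct_amide_h(
      prev_C = c(bb$c_x[i - 1L], bb$c_y[i - 1L], bb$c_z[i - 1L]),
      prev_O = c(bb$o_x[i - 1L], bb$o_y[i - 1L], bb$o_z[i - 1L]),
      N = c(bb$n_x[i], bb$n_y[i], bb$n_z[i])
    )
    bb$h_x[i] <- h[1]; bb$h_y[i] <- h[2]; bb$h_z[i] <- h[3]
  }
  rownames(bb) <- NULL
  bb
}

#' Reconstruct the backbone amide hydrogen
#'
#' Places H 1.0 angstrom from N along the direction bisecting the unit
#' vectors N - C(prev) and C(prev) - O(prev): the N-H bond opposes the
#' preceding carbonyl, the standard placement used for hydrogen-bond
#' energy evaluation on hydrogen-free crystal structures.
#'
#' @param prev_C,prev_O,N 3-vectors: previous residue's C and O, this
#'   residue's N.
#' @return 3-vector H position.
#' @export
reconstruct_amide_h <- function(prev_C, prev_O, N) {
  u1 <- N - prev_C; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- prev_C - prev_O; u2 <- u2 / sqrt(sum(u2^2))
  d <- u1 + u2
  nd <- sqrt(sum(d^2))
  if (nd < 1e-9) stop("degenerate carbonyl geometry for H reconstruction")
  N + d / nd
}

#' Backbone hydrogen-bond energy (Kabsch-Sander electrostatic form)
#'
#' E = 0.084 * 332 * (1/d(O,N) + 1/d(C,H) - 1/d(O,H) - 1/d(C,N)) kcal/mol,
#' where C, O belong to the acceptor's carbonyl and N, H to the donor's
#' amide.  A bond is called at E < -0.5 kcal/mol.  Clashes (any distance
#' under 0.5 angstrom) are capped at -9.9 by convention.
#'
#' @param donor,acceptor Single rows of a [backbone_residues()] frame
#'   (donor supplies N-H, acceptor supplies C=O).
#' @return Energy in kcal/mol (Inf if the donor has no hydrogen, e.g.
#'   proline or a chain start).
#' @export
hbond_energy <- function(donor, acceptor) {
  N <- c(donor$n_x, donor$n_y, donor$n_z)
  H <- c(donor$h_x, donor$h_y, donor$h_z)
  C <- c(acceptor$c_x, acceptor$c_y, acceptor$c_z)
  O <- c(acceptor$o_x, acceptor$o_y, acceptor$o_z)
  if (anyNA(H)) return(Inf)
  d <- c(ON = sqrt(sum((O - N)^2)), CH = sqrt(sum((C - H)^2)),
         OH = sqrt(sum((O - H)^2)), CN = sqrt(sum((C - N)^2)))
  if (any(d < 0.5)) return(-9.9)
  e <- 0.084 * 332 * (1 / d["ON"] + 1 / d["CH"] - 1 / d["OH"] - 1 / d["CN"])
  max(unname(e), -9.9)
}

hbond_cutoff <- -0.5

#' Assign alpha-helical secondary structure
#'
#' Kabsch-Sander-style assignment from backbone hydrogen bonds.  An
#' i -> i+4 turn exists when the amide of residue i+4 donates a bond
#' (E < -0.5 kcal/mol) to the carbonyl of residue i; two consecutive
#' turns (at i-1 and i) start a minimal alpha helix covering i..i+3.
#' Analogous i+3 / i+5 patterns yield 3-10 (G) and pi (I) labels where
#' not already part of an alpha helix; single turns are marked T.
#'
#' @param bb A [backbone_residues()] frame with >= 5 rows.
#' @return An object of class `SSAssignment`: list with `labels`
#'   (character vector over residues, alphabet H/G/I/T/-), `energy4`
#'   (the i -> i+4 bond energies, kcal/mol, NA-padded), and `resno`.
#' @export
assign_helix <- function(bb) {
  n <- nrow(bb)
  if (n < 5L) stop("at least 5 residues are required for helix assignment")
  bond_at <- function(sep) {
    b <- rep(FALSE, n); e <- rep(NA_real_, n)
    for (i in seq_len(n - sep)) {
      en <- hbond_energy(bb[i + sep, , drop = FALSE], bb[i, , drop = FALSE])
      e[i] <- if (is.finite(en)) en else NA_real_
      b[i] <- is.finite(en) && en < hbond_cutoff
    }
    list(bond = b, energy = e)
  }
  t3 <- bond_at(3L); t4 <- bond_at(4L); t5 <- bond_at(5L)
  labels <- rep("-", n)
  mark_runs <- function(bond, sep, code) {
    for (i in which(bond)) {
      if (i > 1L && bond[i - 1L]) {
        span <- i:(i + sep - 1L)
        span <- span[labels[span] == "-" | code == "H"]
        labels[span] <<- code
      }
    }
  }
  mark_runs(t4$bond, 4L, "H")
  mark_runs(t3$bond, 3L, "G")
  mark_runs(t5$bond, 5L, "I")
  # isolated turns
  turn <- (t3$bond | t4$bond | t5$bond)
  for (i in which(turn)) {
    sep <- if (t4$bond[i]) 4L else if (t3$bond[i]) 3L else 5L
    span <- (i + 1L):(i + sep - 1L)
    span <- span[span <= n]
    labels[span][labels[span] == "-"] <- "T"
  }
  structure(
    list(labels = labels, energy4 = t4$energy, resno = bb$resno),
    class = "SSAssignment"
  )
}

#' @export
print.SSAssignment <- function(x, ...) {
  cat(paste(x$labels, collapse = ""), "\n")
  invisible(x)
}

#' Local kink angles along a helix
#'
#' At each interior position, the angle between the principal axes of the
#' preceding and following windows of C-alpha atoms (axes oriented N to C).
#' A regular helix shows only a few degrees everywhere; a genuine kink
#' shows a pronounced local maximum.
#'
#' @param ca N x 3 matrix of helix C-alpha coordinates, N >= 2 * window + 1.
#' @param window Residues per side window (default 7).
#' @return Named numeric vector of angles in degrees, one per interior
#'   position `window + 1 .. N - window`.
#' @export
kink_angle <- function(ca, window = 7L) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (n < 2L * window + 1L)
    stop("helix too short for window ", window, ": need at least ",
         2L * window + 1L, " residues, got ", n)
  idx <- (window + 1L):(n - window)
  ang <- vapply(idx, function(i) {
    a1 <- principal_axis(ca[(i - window):i, , drop = FALSE])
    a2 <- principal_axis(ca[i:(i + window), , drop = FALSE])
    acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
  }, 0)
  names(ang) <- idx
  ang
}

#' Is a helix free of obvious kinks?
#'
#' @param ca Helix C-alpha coordinates.
#' @param window Window for [kink_angle()].
#' @param max_kink Threshold in degrees (default 15): the maximum local
#'   axis bend tolerated before the helix is called kinked.
#' @return Logical.
#' @export
is_regular_helix <- function(ca, window = 7L, max_kink = 15) {
  max(kink_angle(ca, window)) < max_kink
}
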