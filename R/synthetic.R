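#' Ideal alpha-helix coordinates
#'
#' C-alpha positions are generated on a helical curve with canonical
#' alpha-helix parameters: rise 1.5 angstrom/residue, twist 100
#' degrees/residue, C-alpha radius 2.3 angstrom.  With `with_backbone`,
#' full N/CA/C/O backbones are built instead by internal-coordinate chain
#' extension at phi = -57, psi = -47 (ideal alpha-helical dihedrals,
#' standard bond lengths and angles), then rigidly aligned to the
#' requested axis, origin and phase — so the hydrogen-bonding geometry is
#' physically correct and secondary-structure assignment recovers H.
#'
#' @param length Number of residues (>= 4).
#' @param origin Axis point at the level of the first residue's C-alpha.
#' @param axis Helix direction (need not be unit length).
#' @param phase Azimuthal phase of the first C-alpha, degrees.
#' @param rise,twist,radius Helical parameters (C-alpha curve mode only).
#' @param with_backbone Build full backbone geometry?
#' @return A matrix of C-alpha coordinates (curve mode), or a data frame
#'   of backbone atoms (`resno`, `atom_name`, `x`, `y`, `z`).
#' @export
ideal_helix <- function(length, origin = c(0, 0, 0), axis = c(0, 0, 1),
                        phase = 0, rise = 1.5, twist = 100, radius = 2.3,
                        with_backbone = FALSE) {
  if (length < 4L) stop("a helix needs at least 4 residues")
  axis <- axis / sqrt(sum(axis^2))
  if (!with_backbone) {
    i <- seq_len(length) - 1L
    theta <- (phase + i * twist) * pi / 180
    local <- cbind(radius * cos(theta), radius * sin(theta), i * rise)
    R <- rotation_from_to(c(0, 0, 1), axis)
    return(sweep(local %*% t(R), 2, origin, "+"))
  }
  bb <- ideal_backbone(length)
  align_helix_frame(bb, origin, axis, phase)
}

# rotation carrying unit vector a onto unit vector b (Rodrigues)
rotation_from_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c2 <- sum(a * b)
  if (c2 < -1 + 1e-12) {
    # antiparallel: rotate 180 degrees about any perpendicular
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c2)
}

# place atom D given A, B, C with bond |C-D|, angle B-C-D (deg),
# torsion A-B-C-D (deg): standard internal-to-Cartesian step
place_atom <- function(A, B, C, bond, angle, torsion) {
  angle <- angle * pi / 180; torsion <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(angle),
         bond * sin(angle) * cos(torsion),
         bond * sin(angle) * sin(torsion))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# full backbone at phi=-57 psi=-47 omega=180; standard geometry
ideal_backbone <- function(length, phi = -57, psi = -47) {
  N <- matrix(NA_real_, length, 3)
  CA <- matrix(NA_real_, length, 3)
  C <- matrix(NA_real_, length, 3)
  O <- matrix(NA_real_, length, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  th <- 111.2 * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(-cos(th), sin(th), 0)
  for (i in seq_len(length - 1L)) {
    N[i + 1L, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.329, 116.2, psi)
    CA[i + 1L, ] <- place_atom(CA[i, ], C[i, ], N[i + 1L, ], 1.458, 121.7, 180)
    C[i + 1L, ] <- place_atom(C[i, ], N[i + 1L, ], CA[i + 1L, ],
                              1.525, 111.2, phi)
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], 1.231, 120.5, psi + 180)
  }
  O[length, ] <- place_atom(N[length, ], CA[length, ], C[length, ],
                            1.231, 120.5, psi + 180)
  do.call(rbind, lapply(seq_len(length), function(i) {
    data.frame(resno = i,
               atom_name = c("N", "CA", "C", "O"),
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1]),
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2]),
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3]),
               stringsAsFactors = FALSE)
  }))
}

# rigidly move a backbone so its CA principal axis runs along `axis`,
# the axis point at CA1's level sits at `origin`, and CA1 sits at
# azimuth `phase` degrees around the axis
align_helix_frame <- function(bb, origin, axis, phase) {
  ca <- as.matrix(bb[bb$atom_name == "CA", c("x", "y", "z")])
  ax0 <- principal_axis(ca)
  R1 <- rotation_from_to(ax0, c(0, 0, 1))
  xyz <- as.matrix(bb[, c("x", "y", "z")]) %*% t(R1)
  ca_z <- ca %*% t(R1)
  cz <- colMeans(ca_z)
  xyz <- sweep(xyz, 2, c(cz[1], cz[2], 0))      # axis through z-axis
  ca_z <- sweep(ca_z, 2, c(cz[1], cz[2], 0))
  cur_phase <- atan2(ca_z[1, 2], ca_z[1, 1]) * 180 / pi
  R2 <- rotation_from_to(c(1, 0, 0), c(cos((phase - cur_phase) * pi / 180),
                                       sin((phase - cur_phase) * pi / 180), 0))
  xyz <- xyz %*% t(R2)
  ca_z <- ca_z %*% t(R2)
  xyz[, 3] <- xyz[, 3] - ca_z[1, 3]             # CA1 level = axial zero
  R3 <- rotation_from_to(c(0, 0, 1), axis / sqrt(sum(axis^2)))
  xyz <- sweep(xyz %*% t(R3), 2, origin, "+")
  bb[, c("x", "y", "z")] <- xyz
  bb
}

#' Build a synthetic 7TM bundle
#'
#' Seven ideal helices with the bundle lengths (25, 30, 34, 25, 30, 32,
#' 24 residues), their centroids on a circle, axes alternating up/down
#' (odd helices N to C "up", even "down") to mimic an antiparallel TM
#' bundle.  Author numbering is `100 * helix + BW index`, so every h.50
#' anchor is `100 h + 50`; the matching receptor map is returned
#' alongside the chain.  This emulates the geometry of a receptor bundle,
#' not any particular receptor's packing.
#'
#' @param receptor_id Label recorded on the map and chain.
#' @param sequence 200 one-letter codes (single string or vector);
#'   default poly-alanine.
#' @param entry_id,chain_id Identifiers stamped on the chain.
#' @param circle_radius Radius of the helix-centroid circle, angstrom.
#' @param with_backbone Build full N/CA/C/O backbones (needed for
#'   secondary-structure work); otherwise C-alpha only.
#' @param rise,twist,radius Helical parameters for C-alpha curve mode.
#' @return List with `chain` (a `ChainModel`) and `map` (a `ReceptorMap`).
#' @export
build_bundle <- function(receptor_id = "syn", sequence = NULL,
                         entry_id = "SYN1", chain_id = "A",
                         circle_radius = 12, with_backbone = FALSE,
                         rise = 1.5, twist = 100, radius = 2.3) {
  def <- bundle_definition()
  if (is.null(sequence)) sequence <- strrep("A", 200)
  if (length(sequence) == 1L && nchar(sequence) == 200L)
    sequence <- strsplit(sequence, "")[[1L]]
  if (length(sequence) != 200L)
    stop("sequence must contain exactly 200 one-letter codes")
  pos <- bundle_positions(def)
  resname <- bio3d::aa123(sequence)
  if (anyNA(resname)) stop("unknown one-letter code(s) in sequence")
  atom_rows <- vector("list", 7L)
  for (h in 1:7) {
    len <- def$length[h]
    up <- h %% 2L == 1L
    ang <- -(h - 1) * 2 * pi / 7
    cxy <- circle_radius * c(cos(ang), sin(ang))
    ax <- c(0, 0, if (up) 1 else -1)
    span <- (len - 1) * 1.5
    orig <- c(cxy, if (up) -span / 2 else span / 2)
    resno_h <- 100L * h + def$start[h]:def$end[h]
    sel <- pos$helix == h
    if (with_backbone) {
      bb <- ideal_helix(len, origin = orig, axis = ax, phase = h * 40,
                        with_backbone = TRUE)
      bb$resno <- resno_h[bb$resno]
      bb$resname <- resname[sel][match(bb$resno, resno_h)]
      atom_rows[[h]] <- bb
    } else {
      ca <- ideal_helix(len, origin = orig, axis = ax, phase = h * 40,
                        rise = rise, twist = twist, radius = radius)
      atom_rows[[h]] <- data.frame(
        resno = resno_h, atom_name = "CA",
        x = ca[, 1], y = ca[, 2], z = ca[, 3],
        resname = resname[sel], stringsAsFactors = FALSE
      )
    }
  }
  at <- do.call(rbind, atom_rows)
  atoms <- data.frame(
    atom_name = at$atom_name,
    element = substr(at$atom_name, 1L, 1L),
    x = at$x, y = at$y, z = at$z,
    occupancy = 1, altloc = "",
    resno = at$resno, icode = "",
    resname = at$resname, chain_id = chain_id, het = FALSE,
    stringsAsFactors = FALSE
  )
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  rownames(atoms) <- NULL
  chain <- structure(
    list(entry_id = entry_id, chain_id = chain_id, model_index = 1L,
         atoms = atoms),
    class = "ChainModel"
  )
  map <- receptor_map(receptor_id, 100L * (1:7) + 50L,
                      source_note = "synthetic bundle, anchors by construction")
  list(chain = chain, map = map)
}

#' Rigid-body perturbation of one helix plus coordinate noise
#'
#' Applies a rigid translation and/or rotation (about the helix centroid)
#' to every atom of the target helix, then adds i.i.d. Gaussian noise of
#' standard deviation `sigma` to every atom of the chain.  Deterministic
#' for a fixed seed.  Whole-helix rigid semantics emulate rigid-body
#' helix rearrangements within the bundle.
#'
#' @param chain A `ChainModel` (typically from [build_bundle()]).
#' @param map The chain's `ReceptorMap`.
#' @param helix Target helix 1-7 (ignored if neither translation nor
#'   rotation is requested).
#' @param translation Length-3 rigid shift, angstrom.
#' @param rot_axis,rot_angle Rotation axis (default: the helix's own
#'   principal axis) and angle in degrees.
#' @param sigma Noise standard deviation, angstrom.
#' @param seed Integer seed for the noise.
#' @param def Bundle definition.
#' @return The perturbed `ChainModel`.
#' @export
perturb <- function(chain, map, helix = 3L, translation = c(0, 0, 0),
                    rot_axis = NULL, rot_angle = 0, sigma = 0,
                    seed = 1L, def = bundle_definition()) {
  stopifnot(inherits(chain, "ChainModel"), inherits(map, "ReceptorMap"))
  if (!helix %in% 1:7) stop("helix must be in 1..7")
  atoms <- chain$atoms
  lo <- bw_to_author(map, bw_format(helix, def$start[helix]), def)
  hi <- bw_to_author(map, bw_format(helix, def$end[helix]), def)
  in_helix <- !atoms$het & atoms$resno >= lo & atoms$resno <= hi
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (rot_angle != 0) {
    ca_sel <- in_helix & atoms$atom_name == "CA"
    centroid <- colMeans(xyz[ca_sel, , drop = FALSE])
    ax <- if (is.null(rot_axis)) principal_axis(xyz[ca_sel, , drop = FALSE])
          else rot_axis / sqrt(sum(rot_axis^2))
    R <- rotation_about_axis(ax, rot_angle)
    xyz[in_helix, ] <- sweep(
      sweep(xyz[in_helix, , drop = FALSE], 2, centroid) %*% t(R),
      2, centroid, "+")
  }
  xyz[in_helix, ] <- sweep(xyz[in_helix, , drop = FALSE], 2,
                           as.numeric(translation), "+")
  if (sigma > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, sigma), ncol = 3)
  }
  atoms[, c("x", "y", "z")] <- xyz
  out <- chain
  out$atoms <- atoms
  out
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Place pseudo side-chain atoms for an ionic-lock test pair
#'
#' Synthetic bundles carry no side chains; this injects guanidinium
#' nitrogens (NE, NH1, NH2) on an arginine and carboxylate oxygens
#' (OE1/OE2 or OD1/OD2) on a glutamate/aspartate, positioned so the
#' minimum N-O distance equals `distance`.
#'
#' @param chain A `ChainModel`.
#' @param arg_resno Author residue number of the arginine.
#' @param partner_resno Author residue number of the acidic partner.
#' @param partner_resname `"GLU"` or `"ASP"` (the partner's residue name
#'   is rewritten accordingly).
#' @param distance Target minimum N-O distance, angstrom.
#' @return The augmented `ChainModel`.
#' @export
add_ionic_lock_sidechains <- function(chain, arg_resno, partner_resno,
                                      partner_resname = "GLU",
                                      distance = 2.8) {
  stopifnot(inherits(chain, "ChainModel"))
  atoms <- chain$atoms
  ca_of <- function(resno) {
    i <- which(!atoms$het & atoms$resno == resno & atoms$atom_name == "CA")
    if (length(i) == 0L) stop("no CA at residue ", resno)
    as.numeric(atoms[i[1L], c("x", "y", "z")])
  }
  ca_a <- ca_of(arg_resno); ca_p <- ca_of(partner_resno)
  v <- ca_p - ca_a; v <- v / sqrt(sum(v^2))
  perp <- c(-v[2], v[1], 0)
  if (sqrt(sum(perp^2)) < 1e-6) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  ne <- ca_a + 2.0 * v
  nh1 <- ca_a + 3.0 * v
  nh2 <- ca_a + 2.6 * v + 1.0 * perp
  o1 <- nh1 + distance * v
  o2 <- o1 + 1.0 * perp
  o_names <- if (partner_resname == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
  atoms$resname[!atoms$het & atoms$resno == arg_resno] <- "ARG"
  atoms$resname[!atoms$het & atoms$resno == partner_resno] <- partner_resname
  extra <- data.frame(
    atom_name = c("NE", "NH1", "NH2", o_names),
    element = c("N", "N", "N", "O", "O"),
    x = c(ne[1], nh1[1], nh2[1], o1[1], o2[1]),
    y = c(ne[2], nh1[2], nh2[2], o1[2], o2[2]),
    z = c(ne[3], nh1[3], nh2[3], o1[3], o2[3]),
    occupancy = 1, altloc = "",
    resno = c(rep(arg_resno, 3L), rep(partner_resno, 2L)), icode = "",
    resname = c(rep("ARG", 3L), rep(partner_resname, 2L)),
    chain_id = chain$chain_id, het = FALSE,
    stringsAsFactors = FALSE
  )
  out <- chain
  out$atoms <- rbind(atoms, extra)
  out$atoms <- out$atoms[order(out$atoms$resno), , drop = FALSE]
  rownames(out$atoms) <- NULL
  out
}

#' Generate an ensemble of synthetic bundles with known ground truth
#'
#' Writes `n_chains` perturbed copies of a synthetic bundle as PDB files,
#' together with the chain ledger, the receptor maps, and a truth table
#' of the injected rigid-body displacements — the offline stand-in for a
#' set of crystallographic chains.
#'
#' @param n_chains Number of chains (>= 2).
#' @param dir Output directory (created).
#' @param receptor_ids Receptor label per chain (recycled); chains of the
#'   same receptor share a sequence.
#' @param perturbations Optional data frame with columns `chain` (1-based
#'   index), `helix`, `dx`, `dy`, `dz`, `angle`; omitted chains are
#'   unperturbed.
#' @param sigma Coordinate noise per atom, angstrom.
#' @param seed Master seed; chain i uses `seed + i`.
#' @param with_backbone Build full backbones.
#' @return List with `dir`, `files`, `ledger` (data frame), `maps`
#'   (named list of `ReceptorMap`s), and `truth` (data frame of injected
#'   displacements).
#' @export
make_ensemble <- function(n_chains, dir, receptor_ids = "syn",
                          perturbations = NULL, sigma = 0.1, seed = 1L,
                          with_backbone = FALSE) {
  if (n_chains < 2L) stop("an ensemble needs at least 2 chains")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "maps"), showWarnings = FALSE)
  receptor_ids <- rep_len(receptor_ids, n_chains)
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  seqs <- new.env()
  for (r in unique(receptor_ids)) {
    set.seed(seed + 7919L * match(r, unique(receptor_ids)))
    assign(r, paste(sample(aa20, 200, replace = TRUE), collapse = ""),
           envir = seqs)
  }
  files <- character(n_chains)
  ledger <- data.frame(entry_id = character(), chain_id = character(),
                       receptor_id = character(), ligand_class = character(),
                       notes = character(), stringsAsFactors = FALSE)
  truth <- data.frame(entry = character(), chain = character(),
                      helix = integer(), dx = numeric(), dy = numeric(),
                      dz = numeric(), angle = numeric(), sigma = numeric(),
                      seed = integer(), stringsAsFactors = FALSE)
  maps <- list()
  for (i in seq_len(n_chains)) {
    rid <- receptor_ids[i]
    entry <- sprintf("SN%02d", i)
    built <- build_bundle(receptor_id = rid, sequence = get(rid, seqs),
                          entry_id = entry, chain_id = "A",
                          with_backbone = with_backbone)
    maps[[rid]] <- built$map
    chain <- built$chain
    p <- if (!is.null(perturbations))
      perturbations[perturbations$chain == i, , drop = FALSE] else
      perturbations
    h <- 3L; tr <- c(0, 0, 0); ang <- 0
    if (!is.null(p) && nrow(p) > 0L) {
      h <- as.integer(p$helix[1L])
      tr <- c(p$dx[1L], p$dy[1L], p$dz[1L])
      ang <- if ("angle" %in% names(p)) p$angle[1L] else 0
    }
    chain <- perturb(chain, built$map, helix = h, translation = tr,
                     rot_angle = ang, sigma = sigma, seed = seed + i)
    files[i] <- file.path(dir, paste0(entry, ".pdb"))
    write_chain_pdb(chain, files[i])
    ledger <- rbind(ledger, data.frame(
      entry_id = entry, chain_id = "A", receptor_id = rid,
      ligand_class = "antagonist", notes = "synthetic",
      stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      entry = entry, chain = "A", helix = h, dx = tr[1], dy = tr[2],
      dz = tr[3], angle = ang, sigma = sigma, seed = seed + i,
      stringsAsFactors = FALSE))
  }
  utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (rid in names(maps))
    write_receptor_map(maps[[rid]], file.path(dir, "maps",
                                              paste0(rid, ".map")))
  list(dir = dir, files = files, ledger = ledger, maps = maps, truth = truth)
}
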