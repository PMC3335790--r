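#' Classify a chain by its bound ligand
#'
#' Chains are classified into two activation-state groups purely by the
#' class of bound ligand: antagonist or inverse-agonist bound chains are
#' inactivated; agonist bound or ligand-free chains are activated.  The
#' label describes the ligand condition, not a verified conformation.
#'
#' @param ligand_class One of `"antagonist"`, `"inverse_agonist"`,
#'   `"agonist"`, `"ligand_free"` (vectorised).
#' @return `"inactivated"` or `"activated"`; unknown classes are an error,
#'   never a silent default.
#' @export
classify_chain <- function(ligand_class) {
  map <- c(antagonist = "inactivated", inverse_agonist = "inactivated",
           agonist = "activated", ligand_free = "activated")
  out <- map[ligand_class]
  if (anyNA(out))
    stop("unknown ligand class(es): ",
         paste(unique(ligand_class[is.na(out)]), collapse = ", "),
         " (expected antagonist, inverse_agonist, agonist, ligand_free)")
  unname(out)
}

#' Read a chain ledger
#'
#' Tab-separated with header `entry_id`, `chain_id`, `receptor_id`,
#' `ligand_class`, `notes`.  A derived `state` column is added via
#' [classify_chain()].
#'
#' @param path TSV file path.
#' @return Data frame.
#' @export
read_chain_ledger <- function(path) {
  led <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  need <- c("entry_id", "chain_id", "receptor_id", "ligand_class")
  missing <- setdiff(need, names(led))
  if (length(missing))
    stop("chain ledger missing column(s): ", paste(missing, collapse = ", "))
  led$state <- classify_chain(led$ligand_class)
  led
}

#' Pairwise RMSD matrix over a set of bundles
#'
#' @param bundles List of `Bundle`s.
#' @param method Superposition method, `"ssm"` or `"kabsch"`.
#' @return Symmetric n x n matrix (zero diagonal), dimnames
#'   `entry-chain`.  n bundles give n(n-1)/2 unique values.
#' @export
pairwise_rmsd_matrix <- function(bundles, method = c("ssm", "kabsch")) {
  method <- match.arg(method)
  n <- length(bundles)
  if (n < 2L) stop("at least 2 bundles are required")
  ids <- vapply(bundles, function(b) paste0(b$entry_id, "-", b$chain_id), "")
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- rmsd_between(bundles[[i]], bundles[[j]], method)
    }
  }
  m
}

#' Pairwise sequence-identity matrix
#'
#' @param bundles List of `Bundle`s.
#' @return Symmetric matrix of identities in percent (diagonal 100).
#' @export
pairwise_identity_matrix <- function(bundles) {
  n <- length(bundles)
  ids <- vapply(bundles, function(b) paste0(b$entry_id, "-", b$chain_id), "")
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- sequence_identity(bundles[[i]], bundles[[j]])
    }
  }
  m
}

#' Sequence identity between two bundles
#'
#' Percent of matching residues over the 200 aligned BW positions: the
#' bundle positions are the alignment, so no sequence alignment is run.
#'
#' @param a,b `Bundle` objects.
#' @return Identity in percent (0-100).
#' @export
sequence_identity <- function(a, b) {
  stopifnot(inherits(a, "Bundle"), inherits(b, "Bundle"))
  100 * mean(a$positions$aa == b$positions$aa)
}

#' Group a pairwise matrix by receptor pair and average
#'
#' All chain-level pairwise values are grouped by unordered receptor pair
#' and averaged arithmetically; self-pairs exist only for receptors with
#' at least two chains.  With chain counts n_r, the pair (r, s) collects
#' n_r * n_s values for r != s and n_r (n_r - 1) / 2 for r = s.
#'
#' @param matrix Symmetric chain-level matrix (e.g. from
#'   [pairwise_rmsd_matrix()]).
#' @param receptors Receptor label per matrix row.
#' @param identity Optional matching identity matrix to average alongside.
#' @return An object of class `ReceptorPairGrid`: data frame with columns
#'   `receptor_a`, `receptor_b`, `mean`, `sd`, `n` (and `mean_identity`
#'   when supplied), one row per realizable unordered pair.
#' @export
average_by_receptor_pair <- function(matrix, receptors, identity = NULL) {
  n <- nrow(matrix)
  stopifnot(length(receptors) == n)
  recs <- unique(receptors)
  rows <- list()
  for (a_i in seq_along(recs)) {
    for (b_i in a_i:length(recs)) {
      ra <- recs[a_i]; rb <- recs[b_i]
      ia <- which(receptors == ra); ib <- which(receptors == rb)
      if (ra == rb) {
        if (length(ia) < 2L) next
        pairs <- utils::combn(ia, 2L)
        vals <- matrix[t(pairs)]
        idv <- if (!is.null(identity)) identity[t(pairs)] else NULL
      } else {
        grid <- expand.grid(i = ia, j = ib)
        vals <- matrix[cbind(grid$i, grid$j)]
        idv <- if (!is.null(identity)) identity[cbind(grid$i, grid$j)] else NULL
      }
      row <- data.frame(receptor_a = ra, receptor_b = rb,
                        mean = mean(vals),
                        sd = if (length(vals) > 1L) stats::sd(vals) else NA_real_,
                        n = length(vals), stringsAsFactors = FALSE)
      if (!is.null(idv)) row$mean_identity <- mean(idv)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("ReceptorPairGrid", "data.frame"))
}

#' Number of realizable receptor-pair groups for given chain counts
#'
#' Cross pairs for every unordered receptor pair, plus a self pair for
#' each receptor with at least two chains.
#'
#' @param counts Integer chain counts per receptor.
#' @return Integer group count.
#' @export
receptor_pair_group_count <- function(counts) {
  k <- length(counts)
  as.integer(choose(k, 2) + sum(counts >= 2L))
}

#' Averaged per-position deviation profile
#'
#' Averages the per-position C-alpha deviations over all unordered pairs
#' of bundles.  In `common_reference` mode (the default) every bundle is
#' first fitted once onto `reference` and distances are measured in that
#' shared frame; in `pairwise` mode each pair is fitted freshly.
#'
#' @param bundles List of `Bundle`s (>= 2).
#' @param reference Reference `Bundle` (required for `common_reference`).
#' @param frame `"common_reference"` or `"pairwise"`.
#' @param method Superposition method for the fits.
#' @return An object of class `DeviationProfile`: data frame with 200
#'   rows (`serial`, `bw`, `helix`, `mean_dev`, `n_pairs`).
#' @export
deviation_profile <- function(bundles, reference = NULL,
                              frame = c("common_reference", "pairwise"),
                              method = c("ssm", "kabsch")) {
  frame <- match.arg(frame)
  method <- match.arg(method)
  if (length(bundles) < 2L) stop("at least 2 bundles are required")
  if (frame == "common_reference") {
    if (is.null(reference)) stop("common_reference frame needs a reference")
    bundles <- fit_to_reference(bundles, reference, method)
  }
  n <- length(bundles)
  acc <- numeric(200)
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- bundles[[i]]; b <- bundles[[j]]
      if (frame == "pairwise") {
        sup <- if (method == "ssm") ssm_fit(b, a) else kabsch_fit(b$xyz, a$xyz)
        b <- transform_bundle(b, sup)
      }
      acc <- acc + per_position_deviation(a, b)
      npairs <- npairs + 1L
    }
  }
  pos <- bundles[[1L]]$positions
  structure(
    data.frame(serial = pos$serial, bw = pos$bw, helix = pos$helix,
               mean_dev = acc / npairs, n_pairs = npairs,
               stringsAsFactors = FALSE),
    class = c("DeviationProfile", "data.frame")
  )
}

#' Deviation at a named BW position
#'
#' @param profile A `DeviationProfile`.
#' @param bw BW label(s).
#' @return Mean deviation(s) in angstrom.
#' @export
profile_at <- function(profile, bw) {
  stopifnot(inherits(profile, "DeviationProfile"))
  i <- match(bw, profile$bw)
  if (anyNA(i)) stop("BW position(s) not in profile: ",
                     paste(bw[is.na(i)], collapse = ", "))
  profile$mean_dev[i]
}

#' Sectional RMSDs between two bundles
#'
#' Superposes `b` onto `a` over the whole bundle (no per-section refit),
#' then computes the RMSD restricted to each of the five membrane
#' sections in that single frame.  Because the frame is shared, the
#' whole-bundle RMSD obeys the exact identity
#' `rmsd_total^2 = sum(n_s * rmsd_s^2) / 200`.
#'
#' @param a,b `Bundle` objects.
#' @param sections A `SectionDefinition`.
#' @param method Superposition method.
#' @return Named numeric vector of five RMSDs plus attribute `total`
#'   (the all-200 RMSD in the same frame).
#' @export
sectional_rmsd <- function(a, b, sections, method = c("ssm", "kabsch")) {
  method <- match.arg(method)
  stopifnot(inherits(a, "Bundle"), inherits(b, "Bundle"))
  sup <- if (method == "ssm") ssm_fit(b, a) else kabsch_fit(b$xyz, a$xyz)
  bt <- transform_bundle(b, sup)
  d2 <- rowSums((a$xyz - bt$xyz)^2)
  sec <- assign_section(a$positions$bw, sections)
  out <- vapply(1:5, function(s) sqrt(mean(d2[sec == s])), 0)
  names(out) <- paste0("section", 1:5)
  attr(out, "total") <- sqrt(mean(d2))
  out
}

#' Isolated-helix rigid-body comparison
#'
#' For one helix, contrasts (a) each chain's mean C-alpha deviation from
#' the reference at that helix's positions in the whole-bundle common
#' frame with (b) the RMSD after fitting the helix alone onto the
#' reference helix.  A helix whose internal shape is conserved but whose
#' placement differs shows (a) high and (b) near zero — the rigid-body
#' displacement signature.
#'
#' @param bundles List of `Bundle`s.
#' @param helix Helix 1-7.
#' @param reference Reference `Bundle`.
#' @param method Whole-bundle superposition method.
#' @return Data frame with one row per bundle: `id`, `receptor_id`,
#'   `bundle_frame_dev` (mean per-position C-alpha deviation, angstrom),
#'   `rigid_disp` (norm of the vector-mean displacement of the helix in
#'   the common frame — the rigid-body displacement estimate, robust to
#'   isotropic coordinate noise), and `isolated_rmsd` (angstrom).
#' @export
isolated_helix_comparison <- function(bundles, helix, reference,
                                      method = c("ssm", "kabsch")) {
  method <- match.arg(method)
  if (!helix %in% 1:7) stop("helix must be in 1..7")
  fitted <- fit_to_reference(bundles, reference, method)
  sel <- reference$positions$helix == helix
  ref_h <- reference$xyz[sel, , drop = FALSE]
  rows <- lapply(seq_along(bundles), function(i) {
    b <- fitted[[i]]
    diff <- b$xyz[sel, , drop = FALSE] - ref_h
    dev <- mean(sqrt(rowSums(diff^2)))
    disp <- sqrt(sum(colMeans(diff)^2))
    iso <- kabsch_fit(bundles[[i]]$xyz[sel, , drop = FALSE], ref_h)$rmsd
    data.frame(id = paste0(b$entry_id, "-", b$chain_id),
               receptor_id = b$receptor_id,
               bundle_frame_dev = dev, rigid_disp = disp,
               isolated_rmsd = iso,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Ionic-lock state of a chain
#'
#' Tests the salt bridge between the conserved arginine 3.50 of the
#' D/ERY motif and an acidic residue at 6.30: locked iff 6.30 is Glu or
#' Asp and the minimum distance from the arginine's guanidinium nitrogens
#' (NE, NH1, NH2) to the carboxylate oxygens (OE1/OE2 or OD1/OD2) is at
#' most `cutoff`.  The 4.0 angstrom default is the conventional
#' salt-bridge threshold.
#'
#' @param chain A `ChainModel` (side chains required).
#' @param map The receptor's `ReceptorMap`.
#' @param cutoff Maximum N-O distance, angstrom.
#' @return List of class `IonicLockState`: `state` in `"locked"`,
#'   `"unlocked"`, `"no_acidic_partner"`, `"indeterminate"`, plus
#'   `min_distance` (NA when not measurable) and `warning` text.
#' @export
ionic_lock_state <- function(chain, map, cutoff = 4.0) {
  stopifnot(inherits(chain, "ChainModel"), inherits(map, "ReceptorMap"))
  res_350 <- bw_to_author(map, "3.50")
  res_630 <- bw_to_author(map, "6.30")
  atoms <- chain$atoms[!chain$atoms$het, , drop = FALSE]
  a350 <- atoms[atoms$resno == res_350, , drop = FALSE]
  a630 <- atoms[atoms$resno == res_630, , drop = FALSE]
  if (nrow(a350) == 0L || nrow(a630) == 0L)
    stop("residues at 3.50/6.30 not resolvable in ",
         chain$entry_id, "-", chain$chain_id)
  warn <- character()
  if (!any(toupper(a350$resname) == "ARG")) {
    warn <- sprintf("residue at 3.50 is %s, not Arg", a350$resname[1L])
    warning(warn, call. = FALSE)
    return(structure(list(state = "unlocked", min_distance = NA_real_,
                          warning = warn), class = "IonicLockState"))
  }
  partner <- toupper(a630$resname[1L])
  if (!partner %in% c("GLU", "ASP"))
    return(structure(list(state = "no_acidic_partner",
                          min_distance = NA_real_, warning = ""),
                     class = "IonicLockState"))
  n_atoms <- a350[a350$atom_name %in% c("NE", "NH1", "NH2"), , drop = FALSE]
  o_names <- if (partner == "GLU") c("OE1", "OE2") else c("OD1", "OD2")
  o_atoms <- a630[a630$atom_name %in% o_names, , drop = FALSE]
  if (nrow(n_atoms) == 0L || nrow(o_atoms) == 0L)
    return(structure(list(state = "indeterminate", min_distance = NA_real_,
                          warning = "side-chain atoms missing"),
                     class = "IonicLockState"))
  nd <- as.matrix(n_atoms[, c("x", "y", "z")])
  od <- as.matrix(o_atoms[, c("x", "y", "z")])
  dmin <- min(sqrt(outer(rowSums(nd^2), rep(1, nrow(od))) +
                   outer(rep(1, nrow(nd)), rowSums(od^2)) -
                   2 * nd %*% t(od)))
  structure(list(state = if (dmin <= cutoff) "locked" else "unlocked",
                 min_distance = dmin, warning = ""),
            class = "IonicLockState")
}

#' @export
print.IonicLockState <- function(x, ...) {
  cat("ionic lock:", x$state,
      if (!is.na(x$min_distance))
        sprintf("(min N-O %.2f A)", x$min_distance) else "", "\n")
  invisible(x)
}

#' Screen a receptor's chains for regional outliers
#'
#' Within one receptor's chains, finds the medoid chain (minimum summed
#' RMSD to the others) and flags any chain whose mean C-alpha deviation
#' from the medoid, within a stated BW region and after whole-bundle
#' superposition, exceeds `threshold`.  This reproduces, as a method, the
#' kind of exclusion applied to chains deviating at the N-terminal part
#' of helix I or at helix VI.
#'
#' @param bundles List of `Bundle`s of one receptor (>= 2).
#' @param region Character vector of two BW labels, start and end of the
#'   screened region (inclusive, serial order).
#' @param threshold Mean-deviation threshold, angstrom (default 2.0).
#' @param method Superposition method.
#' @return Data frame: `id`, `mean_dev`, `flagged`, plus attribute
#'   `medoid` (the medoid id).
#' @export
outlier_screen <- function(bundles, region, threshold = 2.0,
                           method = c("ssm", "kabsch")) {
  method <- match.arg(method)
  if (length(bundles) < 2L) stop("at least 2 chains are required")
  s <- serial_of(region)
  sel <- bundles[[1L]]$positions$serial >= min(s) &
         bundles[[1L]]$positions$serial <= max(s)
  m <- pairwise_rmsd_matrix(bundles, method)
  medoid <- which.min(rowSums(m))
  ref <- bundles[[medoid]]
  fitted <- fit_to_reference(bundles, ref, method)
  rows <- lapply(seq_along(bundles), function(i) {
    b <- fitted[[i]]
    dev <- if (i == medoid) 0 else
      mean(sqrt(rowSums((b$xyz[sel, , drop = FALSE] -
                         ref$xyz[sel, , drop = FALSE])^2)))
    data.frame(id = paste0(b$entry_id, "-", b$chain_id),
               mean_dev = dev, flagged = i != medoid & dev > threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "medoid") <- out$id[medoid]
  out
}
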