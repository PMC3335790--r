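#' Read a structure file into per-chain models
#'
#' Parses a PDB or mmCIF file (via bio3d) and returns one `ChainModel` per
#' polypeptide chain of the first model.  Heteroatoms are retained in the
#' atom table but flagged, so ligands never enter the C-alpha trace.
#'
#' @param path Path to a structure file.
#' @param format `"pdb"` or `"mmcif"`; `"auto"` guesses from the extension.
#' @param entry_id Accession recorded on the chains; defaults to the
#'   upper-cased file stem.
#' @return A list of `ChainModel` objects, one per polymer chain.  Each is
#'   a list with `entry_id`, `chain_id`, `model_index` and an `atoms` data
#'   frame (`atom_name`, `element`, `x`, `y`, `z`, `occupancy`, `altloc`,
#'   `resno`, `icode`, `resname`, `het`).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           entry_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  if (is.null(entry_id))
    entry_id <- toupper(sub("\\.[^.]*(\\.gz)?$", "", basename(path)))
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse ", path, " as ", format,
                             ": ", conditionMessage(e), call. = FALSE)
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0L) stop("no atoms found in ", path)
  atoms <- data.frame(
    atom_name = trimws(at$elety),
    element = if (!is.null(at$elesy)) trimws(at$elesy) else
      substr(trimws(at$elety), 1L, 1L),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resno = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    resname = trimws(at$resid),
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    het = at$type == "HETATM" & trimws(at$resid) != "MSE",
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in ", path)
  # polymer chains: at least one standard-residue CA
  is_poly_atom <- !atoms$het & atoms$atom_name == "CA"
  chains <- unique(atoms$chain_id[is_poly_atom])
  if (length(chains) == 0L) stop("no polymer chains in ", path)
  out <- lapply(chains, function(ch) {
    a <- atoms[atoms$chain_id == ch, , drop = FALSE]
    ord <- order(a$resno, a$icode)
    a <- a[ord, , drop = FALSE]
    rownames(a) <- NULL
    structure(
      list(entry_id = entry_id, chain_id = ch, model_index = 1L, atoms = a),
      class = "ChainModel"
    )
  })
  names(out) <- chains
  out
}

#' @export
print.ChainModel <- function(x, ...) {
  tr <- ca_trace(x)
  cat(sprintf("%s %s %d residues, %d CA\n", x$entry_id, x$chain_id,
              length(unique(paste(x$atoms$resno[!x$atoms$het],
                                  x$atoms$icode[!x$atoms$het]))),
              nrow(tr)))
  invisible(x)
}

#' Select one chain from a parsed structure
#'
#' @param chains List of `ChainModel`s from [read_structure()].
#' @param entry_id,chain_id Identifiers of the requested chain.
#' @return The matching `ChainModel`.
#' @export
select_chain <- function(chains, entry_id, chain_id) {
  hits <- Filter(function(c) c$entry_id == entry_id &&
                   c$chain_id == chain_id, chains)
  if (length(hits) == 0L) {
    avail <- vapply(chains, function(c)
      paste0(c$entry_id, "-", c$chain_id), "")
    stop("chain not found: ", entry_id, "-", chain_id,
         " (available: ", paste(avail, collapse = ", "), ")")
  }
  hits[[1L]]
}

#' C-alpha trace of a chain
#'
#' One entry per residue possessing a CA atom.  Alternate locations are
#' resolved by highest occupancy; ties prefer altloc "A", then blank.
#' Residues lacking a CA are silently omitted.
#'
#' @param chain A `ChainModel`.
#' @return Data frame with columns `resno`, `icode`, `resname`, `aa`
#'   (one-letter code; MSE reads as M, unknown residues as X), `x`, `y`,
#'   `z`, in residue order.
#' @export
ca_trace <- function(chain) {
  stopifnot(inherits(chain, "ChainModel"))
  a <- chain$atoms
  ca <- a[!a$het & a$atom_name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L)
    return(data.frame(resno = integer(), icode = character(),
                      resname = character(), aa = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  key <- paste(ca$resno, ca$icode, sep = "|")
  pick <- unlist(lapply(split(seq_len(nrow(ca)), factor(key, unique(key))),
                        function(i) {
    if (length(i) == 1L) return(i)
    occ <- ca$occupancy[i]
    best <- i[occ == max(occ)]
    if (length(best) > 1L) {
      # tie: prefer altloc "A", then blank, then first
      alts <- ca$altloc[best]
      best <- if ("A" %in% alts) best[alts == "A"][1L]
              else if ("" %in% alts) best[alts == ""][1L]
              else best[1L]
    }
    best[1L]
  }), use.names = FALSE)
  ca <- ca[sort(pick), , drop = FALSE]
  data.frame(
    resno = ca$resno, icode = ca$icode, resname = ca$resname,
    aa = residue_one_letter(ca$resname),
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
}

# MSE (selenomethionine) counts as MET; other nonstandard residues -> X
residue_one_letter <- function(resname) {
  resname <- ifelse(toupper(resname) == "MSE", "MET", toupper(resname))
  out <- suppressWarnings(bio3d::aa321(resname))
  ifelse(is.na(out), "X", out)
}

#' Fetch a PDB entry into a local cache
#'
#' Downloads `<accession>.pdb` from the RCSB file server once; later calls
#' with the same accession return the cached file without network access.
#' All analyses in this package run equally well on local files; fetching
#' is a convenience only.
#'
#' @param accession 4-character PDB id.
#' @param cache_dir Directory for cached files (created if needed).
#' @param base_url Download URL prefix.
#' @return Path to the cached file.
#' @export
fetch_entry <- function(accession, cache_dir,
                        base_url = "https://files.rcsb.org/download/") {
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", accession))
    stop("malformed PDB accession: ", accession)
  accession <- toupper(accession)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(cache_dir, paste0(accession, ".pdb"))
  if (file.exists(dest) && file.size(dest) > 0) return(dest)
  url <- paste0(base_url, accession, ".pdb")
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !file.exists(dest) || file.size(dest) == 0) {
    unlink(dest)
    stop("failed to fetch ", accession, " from ", url)
  }
  dest
}

#' Write a chain model as a fixed-column PDB file
#'
#' @param chain A `ChainModel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain_pdb <- function(chain, path) {
  stopifnot(inherits(chain, "ChainModel"))
  a <- chain$atoms
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = ifelse(a$het, "HETATM", "ATOM"),
    resno = a$resno, resid = a$resname, eleno = seq_len(nrow(a)),
    elety = a$atom_name, chain = rep(chain$chain_id, nrow(a)),
    insert = ifelse(a$icode == "", NA, a$icode),
    alt = ifelse(a$altloc == "", NA, a$altloc),
    o = a$occupancy, b = rep(0, nrow(a))
  )
  invisible(path)
}
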