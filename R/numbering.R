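#' Ballesteros-Weinstein bundle definition and residue numbering
#'
#' Class A GPCRs share a bundle of seven transmembrane helices.  Positions
#' within the bundle are labelled with generic Ballesteros-Weinstein (BW)
#' numbers "h.ii", where `h` is the helix (1-7) and `ii` is the position
#' relative to the most conserved residue of that helix, defined as h.50.
#' The bundle analysed here is a fixed 200-residue selection:
#' helix I 1.35-1.59 (25 aa), II 2.38-2.67 (30), III 3.22-3.55 (34),
#' IV 4.39-4.63 (25), V 5.36-5.65 (30), VI 6.29-6.60 (32),
#' VII 7.32-7.55 (24).
#'
#' @return A data frame with one row per helix and columns `helix`,
#'   `start`, `end` (BW indices) and `length`, summing to 200 positions.
#' @export
#' @examples
#' def <- bundle_definition()
#' sum(def$length)  # 200
bundle_definition <- function() {
  def <- data.frame(
    helix  = 1:7,
    start  = c(35L, 38L, 22L, 39L, 36L, 29L, 32L),
    end    = c(59L, 67L, 55L, 63L, 65L, 60L, 55L)
  )
  def$length <- def$end - def$start + 1L
  stopifnot(sum(def$length) == 200L)
  def
}

#' Parse and render BW numbers
#'
#' BW numbers are carried as strings "h.ii" (e.g. "3.50").  `bw_parse`
#' splits them into helix and index; `bw_format` renders them back.
#'
#' @param bw Character vector of BW labels such as "3.50".
#' @return `bw_parse`: a data frame with integer columns `helix`, `index`.
#' @export
bw_parse <- function(bw) {
  m <- regmatches(bw, regexec("^([1-7])\\.([0-9]{1,2})$", bw))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed BW number(s): ", paste(bw[bad], collapse = ", "))
  data.frame(
    helix = as.integer(vapply(m, `[`, "", 2L)),
    index = as.integer(vapply(m, `[`, "", 3L))
  )
}

#' @rdname bw_parse
#' @param helix,index Integer vectors.
#' @export
bw_format <- function(helix, index) sprintf("%d.%d", helix, index)

#' All 200 BW positions of the bundle, in serial order
#'
#' @param def A bundle definition, see [bundle_definition()].
#' @return Data frame with columns `serial` (0-199), `bw`, `helix`, `index`.
#' @export
bundle_positions <- function(def = bundle_definition()) {
  rows <- lapply(seq_len(nrow(def)), function(h) {
    idx <- def$start[h]:def$end[h]
    data.frame(helix = def$helix[h], index = idx)
  })
  out <- do.call(rbind, rows)
  out$bw <- bw_format(out$helix, out$index)
  out$serial <- seq_len(nrow(out)) - 1L
  out[, c("serial", "bw", "helix", "index")]
}

#' Serial position of a BW number within the bundle
#'
#' The bundle is indexed serially 0-199 in helix order I to VII.  `serial_of`
#' maps a BW label to its serial; `bw_of` is the inverse.
#'
#' @param bw Character vector of BW labels.
#' @param def Bundle definition.
#' @return Integer serial(s) in 0-199.
#' @export
#' @examples
#' serial_of("1.35")  # 0
#' serial_of("3.50")  # 83
serial_of <- function(bw, def = bundle_definition()) {
  pos <- bundle_positions(def)
  i <- match(bw, pos$bw)
  if (anyNA(i))
    stop("BW position(s) outside the bundle: ",
         paste(bw[is.na(i)], collapse = ", "))
  pos$serial[i]
}

#' @rdname serial_of
#' @param serial Integer vector of serial positions (0-199).
#' @export
bw_of <- function(serial, def = bundle_definition()) {
  pos <- bundle_positions(def)
  i <- match(serial, pos$serial)
  if (anyNA(i))
    stop("serial position(s) outside 0-199: ",
         paste(serial[is.na(i)], collapse = ", "))
  pos$bw[i]
}

#' Receptor anchor maps: BW position to author residue number
#'
#' A receptor map records, for one receptor, the author (PDB) residue
#' number of each helix's most conserved position h.50.  Because all seven
#' helix ranges of the bundle are contiguous in BW space, these seven
#' anchors determine the author number of every bundle position by a
#' constant offset: `author = anchor + (index - 50)`.
#'
#' @param receptor_id Short receptor label (e.g. "brh", "b2").
#' @param anchors Named or unnamed integer vector of length 7: the author
#'   residue numbers of 1.50 ... 7.50.
#' @param source_note Free-text provenance note.
#' @return An object of class `ReceptorMap`.
#' @export
#' @examples
#' m <- receptor_map("brh", c(55, 83, 135, 161, 215, 267, 303))
#' bw_to_author(m, "3.28")  # 113
receptor_map <- function(receptor_id, anchors, source_note = "") {
  anchors <- as.integer(anchors)
  if (length(anchors) != 7L || anyNA(anchors))
    stop("a receptor map needs exactly 7 integer anchors (1.50 ... 7.50)")
  names(anchors) <- paste0("helix", 1:7, ".50")
  structure(
    list(receptor_id = receptor_id, anchors = anchors,
         source_note = source_note),
    class = "ReceptorMap"
  )
}

#' @export
print.ReceptorMap <- function(x, ...) {
  cat("ReceptorMap:", x$receptor_id, "\n")
  for (h in 1:7) cat(sprintf("  %d.50 -> %d\n", h, x$anchors[h]))
  if (nzchar(x$source_note)) cat("  note:", x$source_note, "\n")
  invisible(x)
}

#' Translate a BW position to an author residue number
#'
#' @param map A [receptor_map()].
#' @param bw BW label(s), e.g. "3.28".
#' @param def Bundle definition; positions outside it are an error.
#' @return Integer author residue number(s).
#' @export
bw_to_author <- function(map, bw, def = bundle_definition()) {
  stopifnot(inherits(map, "ReceptorMap"))
  p <- bw_parse(bw)
  in_range <- p$index >= def$start[p$helix] & p$index <= def$end[p$helix]
  if (!all(in_range))
    stop("BW position(s) outside the bundle definition: ",
         paste(bw[!in_range], collapse = ", "))
  unname(map$anchors[p$helix] + (p$index - 50L))
}

#' Invert an anchor map: author residue number to BW label
#'
#' @inheritParams bw_to_author
#' @param author Integer author residue number(s).
#' @return BW label(s); NA where the author number lies in no helix range.
#' @export
author_to_bw <- function(map, author, def = bundle_definition()) {
  stopifnot(inherits(map, "ReceptorMap"))
  out <- rep(NA_character_, length(author))
  for (h in 1:7) {
    idx <- author - map$anchors[h] + 50L
    hit <- idx >= def$start[h] & idx <= def$end[h]
    out[hit] <- bw_format(h, idx[hit])
  }
  out
}

#' Read / write receptor map config files
#'
#' Plain-text format, one anchor per line: `helix<k>.50 = <author_number>`.
#' Blank lines and `#` comments are ignored; an optional
#' `receptor = <id>` line names the receptor (else the file stem is used).
#'
#' @param path File path.
#' @return A `ReceptorMap`.
#' @export
read_receptor_map <- function(path) {
  if (!file.exists(path)) stop("receptor map file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed line(s) in ", path, ": ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  rid <- if ("receptor" %in% keys) vals[keys == "receptor"][1L] else
    sub("\\.[^.]*$", "", basename(path))
  note <- if ("note" %in% keys) vals[keys == "note"][1L] else ""
  anchors <- integer(7)
  for (h in 1:7) {
    key <- sprintf("helix%d.50", h)
    if (!key %in% keys) stop("missing anchor ", key, " in ", path)
    anchors[h] <- as.integer(vals[keys == key][1L])
  }
  receptor_map(rid, anchors, source_note = note)
}

#' @rdname read_receptor_map
#' @param map A `ReceptorMap` to write.
#' @export
write_receptor_map <- function(map, path) {
  stopifnot(inherits(map, "ReceptorMap"))
  lines <- c(
    paste0("receptor = ", map$receptor_id),
    sprintf("helix%d.50 = %d", 1:7, map$anchors),
    if (nzchar(map$source_note)) paste0("note = ", map$source_note)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Extract the 200-residue 7TM bundle from a chain
#'
#' Uses the receptor's anchor map to locate the author residue number of
#' each of the 200 BW positions and collects the corresponding C-alpha
#' coordinates and one-letter codes.  Chains missing a C-alpha at any
#' bundle position are rejected: partial bundles are never produced, which
#' mirrors the exclusion of short chains from comparative analysis.
#'
#' @param chain A `ChainModel`, see [read_structure()].
#' @param map The receptor's [receptor_map()].
#' @param state Chain state label, `"inactivated"` or `"activated"`.
#' @param def Bundle definition.
#' @return An object of class `Bundle`: a list with `receptor_id`,
#'   `entry_id`, `chain_id`, `state`, and a 200-row `positions` data frame
#'   (`serial`, `bw`, `helix`, `resno`, `aa`) plus a 200 x 3 coordinate
#'   matrix `xyz` of C-alpha positions in angstroms.
#' @export
extract_bundle <- function(chain, map, state = "inactivated",
                           def = bundle_definition()) {
  stopifnot(inherits(chain, "ChainModel"), inherits(map, "ReceptorMap"))
  state <- match.arg(state, c("inactivated", "activated"))
  pos <- bundle_positions(def)
  pos$resno <- bw_to_author(map, pos$bw, def)
  trace <- ca_trace(chain)
  i <- match(pos$resno, trace$resno)
  if (anyNA(i)) {
    missing_bw <- pos$bw[is.na(i)]
    stop("incomplete bundle for ", chain$entry_id, "-", chain$chain_id,
         ": no C-alpha at BW position(s) ",
         paste(missing_bw, collapse = ", "))
  }
  xyz <- as.matrix(trace[i, c("x", "y", "z")])
  dimnames(xyz) <- list(pos$bw, c("x", "y", "z"))
  structure(
    list(
      receptor_id = map$receptor_id,
      entry_id = chain$entry_id,
      chain_id = chain$chain_id,
      state = state,
      positions = data.frame(
        serial = pos$serial, bw = pos$bw, helix = pos$helix,
        resno = pos$resno, aa = trace$aa[i]
      ),
      xyz = xyz
    ),
    class = "Bundle"
  )
}

#' @export
print.Bundle <- function(x, ...) {
  cat(sprintf("7TM Bundle %s (%s-%s, %s): 200 C-alpha positions\n",
              x$receptor_id, x$entry_id, x$chain_id, x$state))
  invisible(x)
}

#' One-letter sequence of a bundle
#' @param bundle A `Bundle`.
#' @return A single 200-character string.
#' @export
bundle_sequence <- function(bundle) {
  stopifnot(inherits(bundle, "Bundle"))
  paste(bundle$positions$aa, collapse = "")
}

# ---- membrane sections -----------------------------------------------------

#' Partition the bundle into five membrane sections
#'
#' The bundle is cut into five slabs stacked along the membrane normal,
#' each spanning five residues of helix IV (whose axis is taken as
#' perpendicular to the membrane plane).  Section 1 is the extracellular
#' surface layer and section 5 the cytoplasmic one; since helix IV runs
#' cytoplasm-to-extracellular, its C-terminal block 4.59-4.63 defines
#' section 1 and 4.39-4.43 defines section 5.  Every other bundle position
#' is assigned to the section whose helix IV block is nearest along the
#' helix IV axis.  The construction is purely geometric and deterministic
#' given a reference bundle; an explicit per-position table may be supplied
#' instead via [read_section_config()].
#'
#' @param reference A `Bundle` providing the geometry (typically the common
#'   superposition reference).
#' @param def Bundle definition.
#' @return An object of class `SectionDefinition`: an integer vector of
#'   section labels 1-5, named by BW position, length 200.
#' @export
section_definition <- function(reference, def = bundle_definition()) {
  stopifnot(inherits(reference, "Bundle"))
  pos <- reference$positions
  h4 <- pos$helix == 4L
  ca4 <- reference$xyz[h4, , drop = FALSE]
  axis <- principal_axis(ca4)           # oriented N -> C (cyto -> extracellular)
  z <- drop(reference$xyz %*% axis)     # coordinate along the membrane normal
  z4 <- z[h4]
  # blocks of 5 along helix IV, C-terminal block first (section 1 extracellular)
  block_of <- rev(rep(1:5, each = 5))   # residue 1..25 of helix IV -> 5..1
  block_z <- tapply(z4, block_of, mean)
  sec <- vapply(z, function(zi) as.integer(names(block_z)[
    which.min(abs(block_z - zi))]), 1L)
  names(sec) <- pos$bw
  structure(sec, class = "SectionDefinition")
}

#' Look up section labels for BW positions
#'
#' @param bw BW label(s).
#' @param sections A `SectionDefinition`.
#' @return Integer section label(s) in 1-5.
#' @export
assign_section <- function(bw, sections) {
  stopifnot(inherits(sections, "SectionDefinition"))
  i <- match(bw, names(sections))
  if (anyNA(i))
    stop("BW position(s) not in the section definition: ",
         paste(bw[is.na(i)], collapse = ", "))
  unname(unclass(sections)[i])
}

#' Read / write explicit section tables
#'
#' Plain text, one line per bundle position: `<bw> = <section>`.  All 200
#' positions must be present and labels must lie in 1-5.
#'
#' @param path File path.
#' @param def Bundle definition used to validate completeness.
#' @return A `SectionDefinition`.
#' @export
read_section_config <- function(path, def = bundle_definition()) {
  if (!file.exists(path)) stop("section config not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bw <- vapply(kv, `[`, "", 1L)
  sec <- as.integer(vapply(kv, `[`, "", 2L))
  if (any(is.na(sec) | sec < 1L | sec > 5L))
    stop("section labels must be integers 1-5 in ", path)
  want <- bundle_positions(def)$bw
  if (!setequal(bw, want) || anyDuplicated(bw))
    stop("section config must cover each of the 200 bundle positions once")
  out <- sec[match(want, bw)]
  names(out) <- want
  structure(out, class = "SectionDefinition")
}

#' @rdname read_section_config
#' @param sections A `SectionDefinition` to write.
#' @export
write_section_config <- function(sections, path) {
  stopifnot(inherits(sections, "SectionDefinition"))
  writeLines(sprintf("%s = %d", names(sections), unclass(sections)), path)
  invisible(path)
}
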