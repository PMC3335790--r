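#' Read a run configuration
#'
#' Plain `key = value` text.  Recognised keys: `structure_dir`, `ledger`,
#' `map_dir`, `section_config` (optional), `reference` (entry or
#' entry-chain id, default "2RH1"), `method` (default "ssm"),
#' `ionic_lock_cutoff` (default 4.0), `output_dir`, `seed`.
#'
#' @param path Config file, or a named list to validate directly.
#' @return A validated list of class `RunConfig`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    kv <- strsplit(lines, "\\s*=\\s*")
    stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
  }
  defaults <- list(reference = "2RH1", method = "ssm",
                   ionic_lock_cutoff = 4.0, seed = 1L,
                   section_config = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  need <- c("structure_dir", "ledger", "map_dir", "output_dir")
  miss <- need[!vapply(need, function(k) !is.null(cfg[[k]]), TRUE)]
  if (length(miss)) stop("run config missing: ", paste(miss, collapse = ", "))
  cfg$ionic_lock_cutoff <- as.numeric(cfg$ionic_lock_cutoff)
  cfg$seed <- as.integer(cfg$seed)
  for (k in c("structure_dir", "ledger", "map_dir"))
    if (!file.exists(cfg[[k]]))
      stop("run config path does not exist: ", k, " = ", cfg[[k]])
  structure(cfg, class = c("RunConfig", "list"))
}

#' Run the full bundle-comparison pipeline
#'
#' Reads every chain named in the ledger, extracts 200-residue bundles
#' (recording incomplete-bundle exclusions rather than failing), fits all
#' complete bundles onto the reference, and computes the receptor-pair
#' RMSD/identity grid, the averaged per-position deviation profile, the
#' per-pair sectional RMSDs against the reference, the isolated-helix
#' comparison for helix III, and the ionic-lock census.  Outputs are
#' written as TSV plus one JSON summary; on error all partial outputs are
#' removed.
#'
#' @param config A `RunConfig`, config file path, or named list.
#' @return Invisibly, a list with the computed objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) config <- read_run_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  log_lines <- character()
  log <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  led <- read_chain_ledger(config$ledger)
  log("ledger: ", nrow(led), " chains listed")

  maps <- list()
  for (f in list.files(config$map_dir, pattern = "\\.map$",
                       full.names = TRUE)) {
    m <- read_receptor_map(f)
    maps[[m$receptor_id]] <- m
  }
  if (length(maps) == 0L) stop("stage maps: no .map files in ",
                               config$map_dir)

  bundles <- list()
  excluded <- character()
  for (i in seq_len(nrow(led))) {
    row <- led[i, ]
    path <- file.path(config$structure_dir, paste0(row$entry_id, ".pdb"))
    if (!file.exists(path)) {
      path2 <- file.path(config$structure_dir,
                         paste0(tolower(row$entry_id), ".pdb"))
      if (file.exists(path2)) path <- path2 else
        stop("stage read: structure file missing for ", row$entry_id)
    }
    chains <- read_structure(path, entry_id = row$entry_id)
    chain <- select_chain(chains, row$entry_id, row$chain_id)
    m <- maps[[row$receptor_id]]
    if (is.null(m)) stop("stage extract: no receptor map for ",
                         row$receptor_id)
    b <- tryCatch(extract_bundle(chain, m, state = row$state),
                  error = function(e) conditionMessage(e))
    if (is.character(b)) {
      excluded <- c(excluded, paste0(row$entry_id, "-", row$chain_id,
                                     ": ", b))
    } else {
      bundles[[length(bundles) + 1L]] <- b
    }
  }
  log("extract: ", length(bundles), " complete bundles, ",
      length(excluded), " excluded (<200 residues)")
  if (length(bundles) < 2L) stop("stage extract: fewer than 2 bundles")

  ids <- vapply(bundles, function(b)
    paste0(b$entry_id, "-", b$chain_id), "")
  ref_idx <- match(TRUE, ids == config$reference |
                     vapply(bundles, function(b)
                       b$entry_id == config$reference, TRUE))
  if (is.na(ref_idx)) stop("stage superpose: reference ", config$reference,
                           " not among extracted bundles")
  reference <- bundles[[ref_idx]]
  log("superpose: reference ", ids[ref_idx], ", method ", config$method)

  sections <- if (!is.null(config$section_config))
    read_section_config(config$section_config) else
    section_definition(reference)

  rmat <- pairwise_rmsd_matrix(bundles, config$method)
  imat <- pairwise_identity_matrix(bundles)
  receptors <- vapply(bundles, function(b) b$receptor_id, "")
  grid <- average_by_receptor_pair(rmat, receptors, imat)
  log("pairwise: ", length(bundles) * (length(bundles) - 1L) / 2L,
      " chain pairs, ", nrow(grid), " receptor-pair groups")

  profile <- deviation_profile(bundles, reference,
                               frame = "common_reference",
                               method = config$method)
  log("profile: averaged over ", profile$n_pairs[1L], " pairs")

  sec_rows <- lapply(bundles[-ref_idx], function(b) {
    v <- sectional_rmsd(reference, b, sections, config$method)
    data.frame(id = paste0(b$entry_id, "-", b$chain_id),
               t(v), total = attr(v, "total"))
  })
  sec_tab <- if (length(sec_rows)) do.call(rbind, sec_rows) else NULL

  helix3 <- isolated_helix_comparison(bundles, 3L, reference, config$method)

  locks <- lapply(seq_len(nrow(led)), function(i) {
    row <- led[i, ]
    if (!paste0(row$entry_id, "-", row$chain_id) %in% ids) return(NULL)
    path <- file.path(config$structure_dir, paste0(row$entry_id, ".pdb"))
    chain <- select_chain(read_structure(path, entry_id = row$entry_id),
                          row$entry_id, row$chain_id)
    st <- withCallingHandlers(
      ionic_lock_state(chain, maps[[row$receptor_id]],
                       config$ionic_lock_cutoff),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(id = paste0(row$entry_id, "-", row$chain_id),
               state = st$state, min_distance = st$min_distance,
               stringsAsFactors = FALSE)
  })
  lock_tab <- do.call(rbind, locks)
  log("ionic lock: ", sum(lock_tab$state == "locked"), " locked of ",
      nrow(lock_tab))

  # ---- outputs ----
  p <- function(f) file.path(out_dir, f)
  written <- c(p("grid.tsv"), p("grid_sd.tsv"), p("profile.tsv"),
               p("sections.tsv"), p("helix3.tsv"), p("ionic_lock.tsv"),
               p("summary.json"), p("run.log"), p("excluded.txt"),
               p("config_echo.txt"))
  write_grid(grid, p("grid.tsv"))
  write_profile(profile, sections, p("profile.tsv"))
  if (!is.null(sec_tab))
    utils::write.table(format(sec_tab, digits = 4), p("sections.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format(helix3, digits = 4), p("helix3.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(lock_tab, p("ionic_lock.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(excluded, p("excluded.txt"))
  writeLines(vapply(names(config), function(k)
    paste0(k, " = ", config[[k]]), ""), p("config_echo.txt"))
  jsonlite::write_json(
    list(n_chains = nrow(led), n_bundles = length(bundles),
         n_excluded = length(excluded),
         n_pairs = length(bundles) * (length(bundles) - 1L) / 2L,
         reference = ids[ref_idx], method = config$method,
         grid = as.data.frame(grid),
         ionic_lock = lock_tab,
         profile = profile[, c("serial", "bw", "mean_dev")]),
    p("summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  writeLines(log_lines, p("run.log"))
  ok <- TRUE
  invisible(list(bundles = bundles, grid = grid, profile = profile,
                 sections = sections, sectional = sec_tab,
                 helix3 = helix3, ionic_lock = lock_tab,
                 excluded = excluded, output_dir = out_dir))
}

#' Write a receptor-pair grid as a lower-triangular table
#'
#' Cells are `mean (identity)` with RMSD to 2 decimals and identity to 1
#' decimal; a companion `<path>_sd.tsv`-style standard-deviation table is
#' written alongside (path derived by inserting `_sd`).  Receptors with a
#' single chain have an empty diagonal cell.
#'
#' @param grid A `ReceptorPairGrid`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "ReceptorPairGrid"))
  recs <- unique(c(grid$receptor_a, grid$receptor_b))
  k <- length(recs)
  cell <- matrix("", k, k, dimnames = list(recs, recs))
  sdm <- matrix("", k, k, dimnames = list(recs, recs))
  for (i in seq_len(nrow(grid))) {
    a <- grid$receptor_a[i]; b <- grid$receptor_b[i]
    lo <- recs[max(match(c(a, b), recs))]; hi <- recs[min(match(c(a, b), recs))]
    txt <- if ("mean_identity" %in% names(grid))
      sprintf("%.2f (%.1f)", grid$mean[i], grid$mean_identity[i]) else
      sprintf("%.2f", grid$mean[i])
    cell[lo, hi] <- txt
    sdm[lo, hi] <- if (is.na(grid$sd[i])) "" else sprintf("%.3f", grid$sd[i])
  }
  write_tri <- function(m, f) {
    con <- file(f, "w")
    on.exit(close(con))
    writeLines(paste(c("", recs), collapse = "\t"), con)
    for (r in seq_len(k))
      writeLines(paste(c(recs[r], m[r, seq_len(r)]), collapse = "\t"), con)
  }
  write_tri(cell, path)
  write_tri(sdm, sub("(\\.[^.]*)?$", "_sd\\1", path))
  invisible(path)
}

#' Write a deviation profile as a 200-row table
#'
#' Columns: serial, bw, helix, section, mean_dev (2 decimals), n_pairs.
#'
#' @param profile A `DeviationProfile`.
#' @param sections A `SectionDefinition`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, sections, path) {
  stopifnot(inherits(profile, "DeviationProfile"))
  out <- data.frame(
    serial = profile$serial, bw = profile$bw, helix = profile$helix,
    section = assign_section(profile$bw, sections),
    mean_dev = sprintf("%.2f", profile$mean_dev),
    n_pairs = profile$n_pairs
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot a deviation profile in the style of a serial-position trace
#'
#' Base-graphics plot of mean deviation against serial position, points
#' coloured by membrane section, helix borders as vertical lines and the
#' seven h.50 anchors ticked at the baseline.
#'
#' @param profile A `DeviationProfile`.
#' @param sections A `SectionDefinition`.
#' @param ... Passed to [plot()].
#' @return Invisibly, NULL.
#' @export
plot_profile <- function(profile, sections, ...) {
  stopifnot(inherits(profile, "DeviationProfile"))
  sec <- assign_section(profile$bw, sections)
  cols <- c("red", "pink", "green3", "cyan3", "blue")
  plot(profile$serial, profile$mean_dev, col = cols[sec], pch = 16,
       xlab = "serial position in 7TM bundle",
       ylab = "averaged C-alpha deviation (A)", ...)
  borders <- cumsum(bundle_definition()$length)
  graphics::abline(v = borders[-7] - 0.5, col = "gray")
  anchors <- serial_of(bw_format(1:7, 50))
  graphics::rug(anchors, col = "black", lwd = 2)
  invisible(NULL)
}
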