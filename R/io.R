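# Readers and writers for the interchange formats used by the pipeline:
# activity CSV, multi-molecule SDF V2000 (with charges in a property
# block), model/report JSON, contour pseudo-atom PDB and OpenDX scalar
# fields.  All numeric text output is printed at 6 decimals so that
# table-style comparisons are diff-able.

SPLIT_LEVELS <- c("train", "test", "validation")

#' Read an activity table
#'
#' Expects a header with at least `compound_id` and `ki_nM` (nanomolar);
#' optional `scaffold`, `r1_name` and per-model split columns are carried
#' through, and split values are validated.  pKi is always recomputed from
#' Ki.
#'
#' @param path CSV file path.
#' @return `data.frame` with a recomputed `pki` column.
#' @export
read_activity_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "ki_nM")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("activity table missing column(s): ", paste(miss, collapse = ", "))
  ki <- suppressWarnings(as.numeric(d$ki_nM))
  bad <- which(!is.finite(ki) | ki <= 0)
  if (length(bad)) {
    stop("non-positive or non-numeric Ki at row(s): ", paste(bad, collapse = ", "))
  }
  d$ki_nM <- ki
  d$pki <- ki_to_pki(ki)
  for (col in grep("_split$", names(d), value = TRUE)) {
    if (!all(d[[col]] %in% SPLIT_LEVELS)) {
      stop("invalid split label in column ", col)
    }
  }
  d
}

#' Write an activity table
#'
#' Inverse of [read_activity_csv()]: emits a stable column order and drops
#' the derived `pki`/`smiles` columns so that a read/write cycle
#' round-trips the stored fields exactly.
#'
#' @param d Activity `data.frame`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(d, path) {
  keep <- intersect(c("compound_id", "scaffold", "r1_name", "ki_nM",
                      "comfa_split", "comfarf_split", "comsia_split"), names(d))
  write.csv(d[, keep, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write molecules to an SDF (V2000) file
#'
#' Coordinates at 4 decimals; Gasteiger charges and per-atom flags are
#' stored in `PARTIAL_CHARGES` / `ATOM_FLAGS` data fields so that a
#' qsar3d-written SDF reloads losslessly.
#'
#' @param mols List of `qsar_mol`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "qsar_mol")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    a <- mol$atoms; b <- mol$bonds
    writeLines(c(as.character(mol$id), "  qsar3d", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       nrow(a), nrow(b)), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       a$x, a$y, a$z, a$element), con)
    if (nrow(b)) {
      writeLines(sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j,
                         pmax(1L, round(ifelse(b$order == 1.5, 4, b$order)))), con)
    }
    writeLines("M  END", con)
    writeLines("> <SMILES>", con); writeLines(c(mol$smiles, ""), con)
    writeLines("> <PARTIAL_CHARGES>", con)
    writeLines(c(paste(sprintf("%.6f", a$charge), collapse = " "), ""), con)
    writeLines("> <ATOM_FLAGS>", con)
    writeLines(c(paste(paste0(as.integer(a$aromatic), as.integer(a$hbd),
                              as.integer(a$hba)), collapse = " "), ""), con)
    writeLines("$$$$", con)
  }
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' Parsing goes through [ChemmineR::read.SDFset()]; charges and atom flags
#' written by [write_sdf()] are restored when present.
#'
#' @param path SDF file path.
#' @return List of `qsar_mol`.
#' @export
read_sdf <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfs))
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    element <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(element = element, x = ab[, 1], y = ab[, 2], z = ab[, 3],
                        stringsAsFactors = FALSE)
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = ifelse(bb[, 3] == 4, 1.5, as.numeric(bb[, 3])))
    dat <- ChemmineR::datablock(sdf)
    if (!is.null(dat) && "PARTIAL_CHARGES" %in% names(dat)) {
      atoms$charge <- as.numeric(strsplit(dat[["PARTIAL_CHARGES"]], " ")[[1]])
    }
    if (!is.null(dat) && "ATOM_FLAGS" %in% names(dat)) {
      fl <- strsplit(dat[["ATOM_FLAGS"]], " ")[[1]]
      atoms$aromatic <- substr(fl, 1, 1) == "1"
      atoms$hbd <- substr(fl, 2, 2) == "1"
      atoms$hba <- substr(fl, 3, 3) == "1"
    }
    smiles <- if (!is.null(dat) && "SMILES" %in% names(dat)) dat[["SMILES"]] else NA_character_
    id <- ChemmineR::sdfid(sdf)
    out[[k]] <- qsar_mol(id = id, smiles = smiles, atoms = atoms, bonds = bonds,
                         net_charge = round(sum(atoms$charge %||% 0)))
  }
  names(out) <- vapply(out, function(m) as.character(m$id), character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a validation report
#'
#' Emits the statistics table both as CSV (6-decimal fixed formatting) and,
#' with `json = TRUE`, as a JSON sidecar carrying the full-precision values
#' and the configuration hash.
#'
#' @param report Named list or single-row `data.frame` of statistics.
#' @param path Output CSV path (a `.json` twin is written alongside).
#' @param config Optional [qsar_config()] whose hash is embedded.
#' @param json Also write the JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, config = NULL, json = TRUE) {
  flat <- unlist(report)
  df <- data.frame(statistic = names(flat),
                   value = ifelse(is.na(suppressWarnings(as.numeric(flat))),
                                  as.character(flat),
                                  sprintf("%.6f", suppressWarnings(as.numeric(flat)))))
  if (!is.null(config)) {
    df <- rbind(df, data.frame(statistic = "config_hash", value = config_hash(config)))
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (json) {
    payload <- as.list(report)
    if (!is.null(config)) payload$config_hash <- config_hash(config)
    jsonlite::write_json(payload, sub("\\.csv$", ".json", path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Export contour points as PDB pseudo-atoms
#'
#' One HETATM per selected lattice point; the occupancy column carries the
#' point's contribution share, favoured points get residue name FAV and
#' disfavoured DIS, for display in any molecular viewer.
#'
#' @param contours A `qsar_contours` object from [extract_contours()].
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_contours_pdb <- function(contours, path) {
  lines <- character(0)
  serial <- 0L
  emit <- function(pts, resn) {
    if (!nrow(pts)) return(invisible())
    for (r in seq_len(nrow(pts))) {
      serial <<- serial + 1L
      lines <<- c(lines, sprintf(
        "HETATM%5d  DU  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          DU",
        serial, resn, serial, pts$x[r], pts$y[r], pts$z[r],
        min(9.99, pts$contribution[r]), 0))
    }
  }
  for (kind in names(contours$sets)) {
    emit(contours$sets[[kind]]$favored, "FAV")
    emit(contours$sets[[kind]]$disfavored, "DIS")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Export one field column block as an OpenDX scalar field
#'
#' Writes the values of a single field kind for a single compound on the
#' full lattice in OpenDX "regular positions" format (x-fastest index
#' ordering as used by the field engine, converted to the DX z-fastest
#' convention on output).
#'
#' @param values Numeric vector over the full lattice (x-fastest order).
#' @param grid A [make_grid()] spec.
#' @param path Output `.dx` path.
#' @return `path`, invisibly.
#' @export
write_field_dx <- function(values, grid, path) {
  sh <- grid$shape
  if (length(values) != prod(sh)) stop("value count does not match the grid")
  arr <- array(values, dim = sh)              # x-fastest storage
  zfast <- as.vector(aperm(arr, c(3, 2, 1)))  # DX wants z fastest
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("object 1 class gridpositions counts %d %d %d", sh[1], sh[2], sh[3]), con)
  writeLines(sprintf("origin %.6f %.6f %.6f", grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("delta %.6f 0 0", grid$spacing), con)
  writeLines(sprintf("delta 0 %.6f 0", grid$spacing), con)
  writeLines(sprintf("delta 0 0 %.6f", grid$spacing), con)
  writeLines(sprintf("object 2 class gridconnections counts %d %d %d", sh[1], sh[2], sh[3]), con)
  writeLines(sprintf("object 3 class array type double rank 0 items %d data follows", prod(sh)), con)
  full <- length(zfast) %/% 3L
  if (full > 0) {
    m <- matrix(zfast[seq_len(full * 3L)], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%.6e %.6e %.6e", m[, 1], m[, 2], m[, 3]), con)
  }
  if (length(zfast) %% 3L) {
    rest <- zfast[(full * 3L + 1L):length(zfast)]
    writeLines(paste(sprintf("%.6e", rest), collapse = " "), con)
  }
  writeLines('attribute "dep" string "positions"', con)
  writeLines('object "field" class field', con)
  writeLines('component "positions" value 1', con)
  writeLines('component "connections" value 2', con)
  writeLines('component "data" value 3', con)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable settings shared by the preparation, field, PLS and
#' screening stages, with the study's defaults: 2.0 A lattice spacing,
#' +/-30 kcal/mol steric cutoff, 0.3 kcal/mol column filtering, Gaussian
#' attenuation 0.3, distance-dependent dielectric, template compound 26.
#'
#' @param grid,pls,alignment,screening,seeds Named lists overriding
#'   individual defaults.
#' @return A `qsar_config` list.
#' @export
qsar_config <- function(grid = list(), pls = list(), alignment = list(),
                        screening = list(), seeds = list()) {
  cfg <- list(
    grid = modifyList(list(spacing = 2.0, margin = 4.0, cutoff = 30.0,
                           column_filter_threshold = 0.3, alpha = 0.3,
                           dielectric = "distance"), grid),
    pls = modifyList(list(n_components = 3L, max_components = 6L,
                          focus_exponents = c(0.3, 0.6, 1.0),
                          focus_rounds = 3L), pls),
    alignment = modifyList(list(template_id = 26L, aos_step = 30), alignment),
    screening = modifyList(list(tolerance = 1.0, merge_radius = 1.5,
                                min_features = 4L, max_features = 10L), screening),
    seeds = modifyList(list(embed = 1L), seeds)
  )
  stopifnot(cfg$grid$spacing > 0, cfg$grid$cutoff > 0,
            cfg$grid$column_filter_threshold >= 0, cfg$grid$alpha > 0,
            cfg$screening$tolerance > 0)
  class(cfg) <- "qsar_config"
  cfg
}

#' Short stable hash of a configuration
#'
#' MD5 over the serialised object, truncated to 8 hex digits; embedded in
#' report artifacts so re-runs can be matched to their settings.
#'
#' @param cfg A [qsar_config()] (or any serialisable object).
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(cfg, NULL, version = 2L), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}
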