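# Lattice field engine.
#
# Steric (Lennard-Jones 12-6) and electrostatic (Coulomb with
# distance-dependent dielectric) probe interaction energies, and Gaussian
# similarity indices (steric / electrostatic / hydrophobic / H-bond donor
# / H-bond acceptor), sampled for every molecule at every point of a
# shared rectangular lattice.  Columns are indexed x-fastest, 0-based,
# points at origin + index * spacing.

COULOMB_K <- 332.0636   # kcal mol^-1 Angstrom e^-2

#' Probe atom specification
#'
#' The interaction probe: +1 elementary charge everywhere; for the
#' energy-based fields an sp3 carbon (UFF radius and well depth), for the
#' similarity fields a 1 Angstrom sphere with all property values +1.
#'
#' @param method `"comfa"` (energy probe) or `"comsia"` (similarity probe).
#' @return List with `charge`, `vdw_radius`, `eps`, `w`.
#' @export
probe_spec <- function(method = c("comfa", "comsia")) {
  method <- match.arg(method)
  if (method == "comfa") {
    list(charge = 1.0, vdw_radius = UFF_VDW$rmin[UFF_VDW$element == "C"] / 2,
         eps = UFF_VDW$eps[UFF_VDW$element == "C"], w = 1.0)
  } else {
    list(charge = 1.0, vdw_radius = 1.0, eps = 0, w = 1.0)
  }
}

#' Build the shared lattice around an aligned molecule set
#'
#' Axis-aligned box: union of all atom positions expanded by `margin` on
#' every side, snapped outward to whole `spacing` steps and centred on the
#' aggregate centroid of the box.
#'
#' @param mols List of aligned `qsar_mol` (or a single molecule).
#' @param spacing Lattice spacing in Angstrom (study setting: 2.0).
#' @param margin Extension beyond the atom envelope, Angstrom.
#' @return A `qsar_grid`: `origin`, `spacing`, `shape`, `margin`.
#' @export
make_grid <- function(mols, spacing = 2.0, margin = 4.0) {
  if (inherits(mols, "qsar_mol")) mols <- list(mols)
  if (!length(mols)) stop("empty molecule list")
  xyz <- do.call(rbind, lapply(mols, mol_coords))
  lo <- apply(xyz, 2, min) - margin
  hi <- apply(xyz, 2, max) + margin
  centre <- (lo + hi) / 2
  nstep <- ceiling((hi - lo) / spacing - 1e-9)
  origin <- unname(centre - nstep * spacing / 2)
  structure(list(origin = origin, spacing = spacing,
                 shape = as.integer(nstep + 1L), margin = margin),
            class = "qsar_grid")
}

#' Lattice point coordinates
#' @param grid A `qsar_grid`.
#' @return Matrix (points x 3), x-fastest ordering.
#' @export
grid_points <- function(grid) {
  ax <- lapply(1:3, function(d) grid$origin[d] + grid$spacing * (seq_len(grid$shape[d]) - 1L))
  as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
}

# points x atoms distance matrix
.dist_pa <- function(pts, xyz) {
  d2 <- outer(rowSums(pts^2), rowSums(xyz^2), "+") - 2 * pts %*% t(xyz)
  sqrt(pmax(d2, 0))
}

#' Energy-based probe fields for one molecule
#'
#' Steric: Lennard-Jones 12-6 with Lorentz-Berthelot-combined probe/atom
#' parameters, `A = eps * rmin^12`, `C = 2 eps * rmin^6` (minimum exactly
#' `-eps` at `r = rmin`).  Electrostatic: Coulomb with distance-dependent
#' dielectric `D(r) = r` (or a constant).  Both clipped to `[-cutoff,
#' +cutoff]`; at sterically excluded points (steric at `+cutoff`) the
#' electrostatic value is replaced by the molecule's mean electrostatic
#' over non-excluded points, and those points are reported.
#'
#' @param mol A charged `qsar_mol`.
#' @param grid Shared lattice.
#' @param probe [probe_spec()] (energy probe by default).
#' @param cutoff Truncation in kcal/mol (study setting: 30).
#' @param dielectric `"distance"` for D(r)=r, `"constant"` for D=eps_const.
#' @param eps_const Constant dielectric value when selected.
#' @return List with vectors `steric`, `electrostatic` and logical
#'   `excluded` over the lattice.
#' @export
comfa_fields <- function(mol, grid, probe = probe_spec("comfa"), cutoff = 30,
                         dielectric = c("distance", "constant"), eps_const = 1) {
  dielectric <- match.arg(dielectric)
  pts <- grid_points(grid)
  xyz <- mol_coords(mol)
  r <- pmax(.dist_pa(pts, xyz), 1e-10)
  rmin <- mol$atoms$vdw_radius + probe$vdw_radius
  eps <- sqrt(mol$atoms$eps * probe$eps)
  a <- eps * rmin^12
  cc <- 2 * eps * rmin^6
  steric <- sweep(r^-12, 2, a, "*") - sweep(r^-6, 2, cc, "*")
  steric <- pmin(pmax(rowSums(steric), -cutoff), cutoff)
  denom <- if (dielectric == "distance") r^2 else eps_const * r
  elec <- rowSums(sweep(1 / denom, 2, COULOMB_K * mol$atoms$charge * probe$charge, "*"))
  elec <- pmin(pmax(elec, -cutoff), cutoff)
  excluded <- steric >= cutoff
  if (any(excluded)) {
    elec[excluded] <- if (all(excluded)) 0 else mean(elec[!excluded])
  }
  list(steric = steric, electrostatic = elec, excluded = excluded)
}

#' Gaussian similarity-index fields for one molecule
#'
#' `A_k(q) = -sum_i W_probe,k W_ik exp(-alpha r_iq^2)` for the five
#' property kinds: steric (`W = r_vdw^3`), electrostatic (Gasteiger
#' charge), hydrophobic (pinned atomic contributions), H-bond donor and
#' acceptor (indicator flags).  No cutoff is needed: the Gaussian is
#' finite everywhere and `|A_k| <= sum_i |W_ik|`.
#'
#' @param mol A `qsar_mol` with property values populated.
#' @param grid Shared lattice.
#' @param probe [probe_spec()] (`w` multiplies every field).
#' @param alpha Attenuation factor (study setting: 0.3).
#' @return List of five vectors: `steric`, `electrostatic`, `hydrophobic`,
#'   `hbd`, `hba`.
#' @export
comsia_fields <- function(mol, grid, probe = probe_spec("comsia"), alpha = 0.3) {
  pts <- grid_points(grid)
  xyz <- mol_coords(mol)
  g <- exp(-alpha * .dist_pa(pts, xyz)^2)
  w <- list(steric = mol$atoms$vdw_radius^3,
            electrostatic = mol$atoms$charge,
            hydrophobic = mol$atoms$w_hyd,
            hbd = as.numeric(mol$atoms$hbd),
            hba = as.numeric(mol$atoms$hba))
  lapply(w, function(wk) -probe$w * as.vector(g %*% wk))
}

#' Compute the compounds-by-columns field matrix
#'
#' Stacks the per-molecule fields of every kind into one descriptor block
#' with per-column lattice/kind metadata, an all-true filter mask and unit
#' focus weights.
#'
#' @param mols Aligned molecule list.
#' @param grid Shared lattice (default: built from `mols`).
#' @param method `"comfa"` (steric + electrostatic energies) or
#'   `"comsia"` (five similarity kinds).
#' @param config [qsar_config()] supplying cutoff/attenuation/dielectric.
#' @return A `qsar_field_matrix`: `values` (compounds x columns), `meta`
#'   (kind, 0-based lattice indices, `any_excluded` flag), `mask`,
#'   `focus_weights`, `grid`, `method`.
#' @export
compute_field_matrix <- function(mols, grid = NULL, method = c("comfa", "comsia"),
                                 config = qsar_config()) {
  method <- match.arg(method)
  if (inherits(mols, "qsar_mol")) mols <- list(mols)
  if (is.null(grid)) grid <- make_grid(mols, config$grid$spacing, config$grid$margin)
  np <- prod(grid$shape)
  kinds <- if (method == "comfa") c("steric", "electrostatic") else
    c("steric", "electrostatic", "hydrophobic", "hbd", "hba")
  probe <- probe_spec(method)
  values <- matrix(NA_real_, length(mols), np * length(kinds))
  excl <- matrix(FALSE, length(mols), np)
  for (m in seq_along(mols)) {
    f <- if (method == "comfa") {
      comfa_fields(mols[[m]], grid, probe, cutoff = config$grid$cutoff,
                   dielectric = config$grid$dielectric)
    } else {
      comsia_fields(mols[[m]], grid, probe, alpha = config$grid$alpha)
    }
    if (method == "comfa") excl[m, ] <- f$excluded
    values[m, ] <- unlist(f[kinds], use.names = FALSE)
  }
  idx <- arrayInd(seq_len(np), grid$shape) - 1L
  meta <- data.frame(kind = rep(kinds, each = np),
                     ix = rep(idx[, 1], length(kinds)),
                     iy = rep(idx[, 2], length(kinds)),
                     iz = rep(idx[, 3], length(kinds)),
                     point = rep(seq_len(np), length(kinds)),
                     any_excluded = rep(apply(excl, 2, any), length(kinds)))
  colnames(values) <- paste(meta$kind, meta$ix, meta$iy, meta$iz, sep = ":")
  rownames(values) <- names(mols)
  structure(list(values = values, meta = meta,
                 mask = rep(TRUE, ncol(values)),
                 focus_weights = rep(1, ncol(values)),
                 grid = grid, method = method),
            class = "qsar_field_matrix")
}

#' @export
print.qsar_field_matrix <- function(x, ...) {
  cat("<qsar_field_matrix> ", nrow(x$values), " compounds x ", ncol(x$values),
      " columns (", sum(x$mask), " active), method ", x$method, "\n", sep = "")
  invisible(x)
}

#' Active (unmasked) descriptor block
#' @param fm A `qsar_field_matrix`.
#' @return Numeric matrix restricted to unmasked columns.
#' @export
field_values <- function(fm) {
  fm$values[, fm$mask, drop = FALSE]
}

#' Minimum-variation column filtering
#'
#' Masks every column whose variation across compounds (max - min) falls
#' below `threshold`; values are left untouched.  The study setting is
#' 0.3 kcal/mol.
#'
#' @param fm A `qsar_field_matrix`.
#' @param threshold Nonnegative variation threshold.
#' @return The filtered `qsar_field_matrix`.
#' @export
column_filter <- function(fm, threshold = 0.3) {
  stopifnot(inherits(fm, "qsar_field_matrix"), threshold >= 0)
  if (nrow(fm$values) < 2L) stop("column filtering needs >= 2 compounds")
  variation <- apply(fm$values, 2, function(v) diff(range(v)))
  fm$mask <- fm$mask & (variation >= threshold)
  fm
}

#' Block-level field scaling
#'
#' Divides every active column of each field kind by the kind's pooled
#' standard deviation (square root of the mean column variance), the
#' lattice-field convention that puts field blocks of different physical
#' units on a common footing before PLS -- individual columns keep their
#' relative scale within the block, so this is not per-column autoscaling.
#'
#' @param fm A `qsar_field_matrix` (after column filtering).
#' @param rows Optional row subset (e.g. the training compounds) on which
#'   the block scales are estimated; scaling is applied to all rows.
#' @return The scaled `qsar_field_matrix` with a `block_scales` element.
#' @export
block_scale <- function(fm, rows = NULL) {
  stopifnot(inherits(fm, "qsar_field_matrix"))
  if (is.null(rows)) rows <- seq_len(nrow(fm$values))
  scales <- numeric(0)
  for (kind in unique(fm$meta$kind)) {
    cols <- which(fm$mask & fm$meta$kind == kind)
    if (!length(cols)) next
    b <- sqrt(mean(apply(fm$values[rows, cols, drop = FALSE], 2, var)))
    if (!is.finite(b) || b <= 0) b <- 1
    fm$values[, cols] <- fm$values[, cols, drop = FALSE] / b
    scales[kind] <- b
  }
  fm$block_scales <- scales
  fm
}

#' Region focusing
#'
#' Reweights the active lattice columns by their contribution to a fitted
#' PLS model -- `(sd(column) * |coefficient|)` normalised to a maximum of
#' 1, raised to `exponent` -- and rescales the descriptor block so that a
#' subsequent refit concentrates on the model-relevant lattice regions.
#' `exponent = 0` leaves the matrix unchanged.
#'
#' @param fm A filtered `qsar_field_matrix`.
#' @param model A `qsar_pls` fitted on the same active columns.
#' @param exponent Nonnegative focusing strength.
#' @return The reweighted `qsar_field_matrix`.
#' @export
region_focus <- function(fm, model, exponent = 0.6) {
  stopifnot(inherits(fm, "qsar_field_matrix"), inherits(model, "qsar_pls"))
  if (exponent < 0) stop("focusing exponent must be >= 0")
  active <- which(fm$mask)
  if (length(model$coefficients) != length(active)) {
    stop("model was not fitted on this matrix's active columns")
  }
  contrib <- apply(fm$values[, active, drop = FALSE], 2, sd) * abs(model$coefficients)
  w <- if (max(contrib) > 0) contrib / max(contrib) else rep(0, length(contrib))
  w <- w^exponent
  fm$values[, active] <- sweep(fm$values[, active, drop = FALSE], 2, w, "*")
  fm$focus_weights[active] <- fm$focus_weights[active] * w
  fm
}
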