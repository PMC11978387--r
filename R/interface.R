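#' @keywords internal
.read_ref_table <- function(name) {
  path <- system.file("extdata", name, package = "abdocktools")
  if (path == "") path <- file.path("inst", "extdata", name)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged reference tables
#'
#' Lookup tables used by the interface panel: van der Waals radii per
#' element, fully-exposed (Gly-X-Gly) reference areas per residue type, and
#' the 20-residue interface-propensity (stickiness) scale. Shipped as CSV
#' with provenance headers under `inst/extdata` and swappable through the
#' `radii` / `reference` / `scale` arguments of the consuming functions.
#'
#' @return named numeric vector.
#' @export
#' @rdname reference_tables
vdw_radii <- function() {
  t <- .read_ref_table("vdw_radii.csv")
  stats::setNames(t$radius, t$element)
}

#' @export
#' @rdname reference_tables
max_asa_reference <- function() {
  t <- .read_ref_table("max_asa.csv")
  stats::setNames(t$max_asa, t$residue_name)
}

#' @export
#' @rdname reference_tables
stickiness_scale <- function() {
  t <- .read_ref_table("stickiness.csv")
  stats::setNames(t$stickiness, t$residue_name)
}

# deterministic near-uniform unit sphere point set (golden-spiral lattice);
# fixed orientation so SASA values are bit-reproducible
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# core Shrake-Rupley: accessible area per atom (vector, Angstrom^2)
.atom_sasa <- function(xyz, radii, probe, n_points) {
  n <- nrow(xyz)
  pts <- .sphere_points(n_points)
  rr <- radii + probe
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cutoff2 <- (rr[i] + rr)^2
    nb <- which(d2[i, ] < cutoff2 & seq_len(n) != i)
    if (!length(nb)) {
      out[i] <- 4 * pi * rr[i]^2
      next
    }
    sp <- pts * rr[i]
    sp <- sweep(sp, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= rr[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rr[i]^2 * sum(acc) / n_points
  }
  out
}

#' Solvent-accessible surface area
#'
#' Numerical accessible-surface estimate per residue (or atom) using
#' Shrake--Rupley sphere sampling with a deterministic golden-spiral point
#' set, so results are bit-reproducible for a fixed `sphere_points`.
#' Hydrogens are excluded; residue areas are sums over heavy atoms.
#'
#' @param model a `complex_model`.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4).
#' @param sphere_points quadrature points per atom (default 960).
#' @param level `"residue"` (default) or `"atom"`.
#' @param radii named vdW radius table, element -> Angstrom.
#' @return for `level = "residue"` a data.frame `chain_id`,
#'   `residue_number`, `insertion_code`, `residue_name`, `sa`; for
#'   `level = "atom"` the model's atom table plus an `sa` column.
#' @export
compute_sasa <- function(model, probe_radius = 1.4, sphere_points = 960,
                         level = c("residue", "atom"),
                         radii = vdw_radii()) {
  level <- match.arg(level)
  a <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
  unknown <- setdiff(unique(toupper(a$element)), names(radii))
  if (length(unknown))
    stop("no vdW radius for element(s): ", paste(unknown, collapse = ", "))
  r <- unname(radii[toupper(a$element)])
  sa <- .atom_sasa(as.matrix(a[, c("x", "y", "z")]), r, probe_radius,
                   sphere_points)
  if (level == "atom") {
    a$sa <- sa
    rownames(a) <- NULL
    return(a)
  }
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, sep = "|")
  agg <- rowsum(sa, key)
  first <- !duplicated(key)
  out <- data.frame(chain_id = a$chain_id[first],
                    residue_number = a$residue_number[first],
                    insertion_code = a$insertion_code[first],
                    residue_name = a$residue_name[first],
                    sa = agg[match(key[first], rownames(agg)), 1],
                    row.names = NULL)
  out
}

#' Relative surface area
#'
#' rSA = 100 * SA / fully-exposed reference area of the residue type.
#' Values may exceed 100 for terminal residues; no clamping is applied.
#'
#' @param sa_table data.frame from [compute_sasa()] (residue level).
#' @param reference named vector residue type -> reference area.
#' @return `sa_table` with an `rsa` column (percent).
#' @export
relative_sa <- function(sa_table, reference = max_asa_reference()) {
  miss <- setdiff(unique(sa_table$residue_name), names(reference))
  if (length(miss))
    stop("no reference area for residue type(s): ",
         paste(miss, collapse = ", "))
  sa_table$rsa <- 100 * sa_table$sa / unname(reference[sa_table$residue_name])
  sa_table
}

# split a model into its antibody and antigen sides
.side_model <- function(model, side) {
  roles <- if (side == "antibody") c("heavy", "light") else "antigen"
  keep <- .atom_roles(model) %in% roles
  if (!any(keep)) stop("model has no ", side, " atoms")
  cr <- model$chain_roles[model$chain_roles %in% roles]
  # atoms come pre-validated from the parent model; bypass the constructor,
  # whose antibody-presence invariant does not apply to a bare side
  structure(list(atoms = model$atoms[keep, , drop = FALSE],
                 chain_roles = cr,
                 model_id = paste0(model$model_id, ":", side),
                 source_tool = model$source_tool),
            class = "complex_model")
}

#' Per-residue surface-area records in complexed and uncomplexed states
#'
#' Computes residue SA and rSA in the complexed state and in the
#' uncomplexed state obtained by rigidly separating the two sides (each
#' side's SA recomputed in isolation), plus the buried difference
#' delta_rsa = rsa_u - rsa_c. With the deterministic quadrature the
#' uncomplexed area can never fall below the complexed one.
#'
#' @inheritParams compute_sasa
#' @param reference fully-exposed reference table.
#' @return data.frame with `chain_id`, `residue_number`, `insertion_code`,
#'   `residue_name`, `role`, `sa_complexed`, `sa_uncomplexed`, `rsa_c`,
#'   `rsa_u`, `delta_rsa`, `delta_sa`.
#' @export
sa_records <- function(model, probe_radius = 1.4, sphere_points = 960,
                       radii = vdw_radii(), reference = max_asa_reference()) {
  comp <- relative_sa(compute_sasa(model, probe_radius, sphere_points,
                                   radii = radii), reference)
  parts <- lapply(c("antibody", "antigen"), function(s)
    relative_sa(compute_sasa(.side_model(model, s), probe_radius,
                             sphere_points, radii = radii), reference))
  unc <- do.call(rbind, parts)
  key <- function(d) paste(d$chain_id, d$residue_number, d$insertion_code,
                           sep = "|")
  m <- match(key(comp), key(unc))
  roles <- model$chain_roles[comp$chain_id]
  out <- data.frame(comp[, c("chain_id", "residue_number", "insertion_code",
                             "residue_name")],
                    role = unname(roles),
                    sa_complexed = comp$sa, sa_uncomplexed = unc$sa[m],
                    rsa_c = comp$rsa, rsa_u = unc$rsa[m])
  out$delta_sa <- out$sa_uncomplexed - out$sa_complexed
  out$delta_rsa <- out$rsa_u - out$rsa_c
  out
}

#' Classify residues into interface regions
#'
#' Applies the rSA-transition classification: `interior` (rsa_c < 25 and
#' no area change on binding), `surface` (rsa_c > 25, no change), and for
#' residues that lose area on binding `support` (rsa_c < 25, buried before
#' binding), `rim` (rsa_c > 25) and `core` (exposed when free, rsa_u > 25,
#' buried in the complex, rsa_c < 25). A residue meeting both support and
#' core conditions is classed core (the more specific refinement). Area
#' change is tested on raw SA with a 1e-6 Angstrom^2 tolerance to absorb
#' quadrature noise; a residue sitting exactly on the 25% boundary with no
#' area change is classed surface, and rim when it loses area.
#'
#' @param records data.frame from [sa_records()].
#' @param rsa_threshold boundary between buried and exposed, percent.
#' @param delta_sa_tol raw-SA tolerance for "changes on binding".
#' @return object of class `interface_regions`: `records` with a `class`
#'   column plus residue-key vectors `support`, `rim`, `core`.
#' @export
classify_residues <- function(records, rsa_threshold = 25,
                              delta_sa_tol = 1e-6) {
  buried_change <- records$delta_sa > delta_sa_tol
  cls <- character(nrow(records))
  cls[!buried_change & records$rsa_c < rsa_threshold] <- "interior"
  cls[!buried_change & records$rsa_c >= rsa_threshold] <- "surface"
  int <- buried_change
  cls[int & records$rsa_c >= rsa_threshold] <- "rim"
  cls[int & records$rsa_c < rsa_threshold &
        records$rsa_u > rsa_threshold] <- "core"
  cls[int & records$rsa_c < rsa_threshold &
        records$rsa_u <= rsa_threshold] <- "support"
  records$class <- cls
  keys <- .residue_key(records$role, records$residue_number,
                       records$insertion_code)
  structure(list(records = records,
                 support = keys[cls == "support"],
                 rim = keys[cls == "rim"],
                 core = keys[cls == "core"]),
            class = "interface_regions")
}

#' @export
print.interface_regions <- function(x, ...) {
  cat("interface_regions:",
      paste(sprintf("%s=%d", c("support", "rim", "core"),
                    c(length(x$support), length(x$rim), length(x$core))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Summed stickiness of a residue set
#'
#' Sums the per-residue-type interface-propensity scale over the members of
#' a region; duplicated residues count every time.
#'
#' @param residue_names character vector of 3-letter residue types.
#' @param scale named stickiness scale covering the 20 standard types.
#' @param on_missing `"error"` (default) or `"skip"` (drop with a warning)
#'   for types absent from the scale.
#' @return unitless sum.
#' @export
stickiness_sum <- function(residue_names, scale = stickiness_scale(),
                           on_missing = c("error", "skip")) {
  on_missing <- match.arg(on_missing)
  miss <- !(residue_names %in% names(scale))
  if (any(miss)) {
    if (on_missing == "error")
      stop("no stickiness value for residue type(s): ",
           paste(unique(residue_names[miss]), collapse = ", "))
    warning("skipping residue(s) without stickiness value: ",
            paste(unique(residue_names[miss]), collapse = ", "))
    residue_names <- residue_names[!miss]
  }
  sum(unname(scale[residue_names]))
}

#' Interface atoms of a complex
#'
#' Atoms whose atom-level accessible area strictly decreases on
#' complexation (uncomplexed side alone vs in the complex).
#'
#' @inheritParams compute_sasa
#' @param delta_sa_tol strictness tolerance on the raw area difference.
#' @return the model's heavy-atom table restricted to interface atoms, with
#'   `sa_complexed`, `sa_uncomplexed` and `role` columns.
#' @export
interface_atoms <- function(model, probe_radius = 1.4, sphere_points = 960,
                            radii = vdw_radii(), delta_sa_tol = 1e-6) {
  comp <- compute_sasa(model, probe_radius, sphere_points, level = "atom",
                       radii = radii)
  parts <- lapply(c("antibody", "antigen"), function(s) {
    sm <- .side_model(model, s)
    cbind(compute_sasa(sm, probe_radius, sphere_points, level = "atom",
                       radii = radii), role_side = s)
  })
  unc <- do.call(rbind, parts)
  key <- function(d) paste(d$chain_id, d$residue_number, d$insertion_code,
                           d$atom_name, sep = "|")
  m <- match(key(comp), key(unc))
  comp$sa_complexed <- comp$sa
  comp$sa_uncomplexed <- unc$sa[m]
  comp$role <- unname(model$chain_roles[comp$chain_id])
  comp$sa <- NULL
  out <- comp[comp$sa_uncomplexed - comp$sa_complexed > delta_sa_tol, ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global density of an interface atom cloud
#'
#' Packing proxy for the interface: the principal moments of the centered
#' coordinate covariance define an equivalent uniform ellipsoid (semi-axis
#' `a_i = sqrt(5 * lambda_i)`), and the atom count is divided by the area of
#' the ellipse spanned by the two largest axes: `GD = N / (pi a b)`. The
#' measure is invariant to rigid transforms and scales as 1/s^2 under a
#' uniform coordinate scaling by s. `mode = "volume"` instead divides by the
#' full ellipsoid volume (atoms per Angstrom^3), for the alternative
#' moment-of-inertia convention.
#'
#' @param coords numeric matrix (n x 3) of interface atom coordinates, or a
#'   data.frame with `x`, `y`, `z` columns.
#' @param mode `"ellipse"` (default) or `"volume"`.
#' @return atoms per Angstrom^2 (or Angstrom^3 for `mode = "volume"`).
#' @export
global_density <- function(coords, mode = c("ellipse", "volume")) {
  mode <- match.arg(mode)
  if (is.data.frame(coords)) coords <- as.matrix(coords[, c("x", "y", "z")])
  n <- nrow(coords)
  if (n < 3) stop("geometry error: need at least 3 interface atoms")
  cen <- sweep(coords, 2, colMeans(coords))
  ev <- sort(eigen(crossprod(cen) / n, symmetric = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  ax <- sqrt(5 * ev)
  if (ax[2] < 1e-8 * max(ax[1], 1))
    stop("geometry error: interface atoms are collinear")
  if (mode == "ellipse") n / (pi * ax[1] * ax[2])
  else {
    if (ax[3] < 1e-8 * max(ax[1], 1))
      stop("geometry error: coplanar atoms have no ellipsoid volume")
    n / (4 / 3 * pi * ax[1] * ax[2] * ax[3])
  }
}

# tessellated contact surface of one side alone, restricted to given atoms.
# Accessibility is decided on the probe-expanded sphere (solvent test) but
# the surface element itself sits on the vdW sphere, so the contact
# surfaces of two touching sides meet instead of interpenetrating.
# Returns points, outward normals and per-point areas.
.dot_surface <- function(side, atom_keys, probe, n_points, radii) {
  a <- side$atoms[toupper(side$atoms$element) != "H", , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rv <- unname(radii[toupper(a$element)])
  r <- rv + probe
  key <- paste(a$chain_id, a$residue_number, a$insertion_code, a$atom_name,
               sep = "|")
  sel <- which(key %in% atom_keys)
  pts <- .sphere_points(n_points)
  P <- N <- matrix(numeric(0), 0, 3)
  w <- numeric(0)
  for (i in sel) {
    sp <- sweep(pts * r[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      if (sum((xyz[i, ] - xyz[j, ])^2) >= (r[i] + r[j])^2) next
      dj2 <- (sp[, 1] - xyz[j, 1])^2 + (sp[, 2] - xyz[j, 2])^2 +
        (sp[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 >= r[j]^2
    }
    if (!any(acc)) next
    contact <- sweep(pts[acc, , drop = FALSE] * rv[i], 2, xyz[i, ], `+`)
    P <- rbind(P, contact)
    N <- rbind(N, pts[acc, , drop = FALSE])
    w <- c(w, rep(4 * pi * rv[i]^2 / n_points, sum(acc)))
  }
  list(points = P, normals = N, areas = w)
}

#' Surface complementarity index
#'
#' Geometric fit of the two sides of an interface. Each side's accessible
#' dot surface (computed for the side in isolation) is restricted to its
#' interface atoms; every surface element is paired with the nearest element
#' on the opposing side and scored by the anti-alignment of their outward
#' normals, `-(n_a . n_b)`, damped by a Gaussian distance decay
#' (half-maximum at `half_width`). The index is the decayed-area-weighted
#' mean of the per-element scores, averaged over the two sides; it is
#' bounded in \[-1, 1\] and higher for better-fitting interfaces.
#'
#' @inheritParams compute_sasa
#' @param half_width distance at which the decay reaches one half, Angstrom.
#' @param interface optional result of [interface_atoms()] to reuse.
#' @return unitless index in \[-1, 1\].
#' @export
surface_complementarity <- function(model, probe_radius = 1.4,
                                    sphere_points = 240, half_width = 1.0,
                                    radii = vdw_radii(), interface = NULL) {
  if (is.null(interface))
    interface <- interface_atoms(model, probe_radius, sphere_points,
                                 radii = radii)
  if (!nrow(interface)) stop("geometry error: empty interface")
  akey <- paste(interface$chain_id, interface$residue_number,
                interface$insertion_code, interface$atom_name, sep = "|")
  ab_keys <- akey[interface$role %in% c("heavy", "light")]
  ag_keys <- akey[interface$role == "antigen"]
  if (!length(ab_keys) || !length(ag_keys))
    stop("geometry error: one side contributes no interface atoms")
  sa <- .dot_surface(.side_model(model, "antibody"), ab_keys, probe_radius,
                     sphere_points, radii)
  sb <- .dot_surface(.side_model(model, "antigen"), ag_keys, probe_radius,
                     sphere_points, radii)
  if (!nrow(sa$points) || !nrow(sb$points))
    stop("geometry error: empty interface surface")
  lam <- log(2) / half_width^2
  score_side <- function(from, to) {
    n <- nrow(from$points)
    sc <- numeric(n); dd <- numeric(n)
    step <- 512L
    for (s in seq(1, n, by = step)) {
      idx <- s:min(s + step - 1, n)
      d2 <- outer(rowSums(from$points[idx, , drop = FALSE]^2),
                  rowSums(to$points^2), `+`) -
        2 * from$points[idx, , drop = FALSE] %*% t(to$points)
      j <- max.col(-d2, ties.method = "first")
      dd[idx] <- pmax(d2[cbind(seq_along(idx), j)], 0)
      sc[idx] <- -rowSums(from$normals[idx, , drop = FALSE] *
                            to$normals[j, , drop = FALSE])
    }
    wgt <- from$areas * exp(-lam * dd)
    sum(wgt * sc) / sum(wgt)
  }
  (score_side(sa, sb) + score_side(sb, sa)) / 2
}

#' Interface property panel for one complex
#'
#' Bundles the per-complex interface descriptors: buried surface area in
#' total and per region (support/rim/core, summed over both sides),
#' per-region and whole-interface stickiness sums, global density of the
#' interface atoms, and the surface complementarity index.
#'
#' @inheritParams compute_sasa
#' @param sc_sphere_points quadrature density for the complementarity
#'   surfaces (coarser than SASA by default).
#' @return object of class `interface_property_panel` (a list; also
#'   flattenable with [as.data.frame()]).
#' @export
interface_property_panel <- function(model, probe_radius = 1.4,
                                     sphere_points = 960,
                                     sc_sphere_points = 240,
                                     radii = vdw_radii()) {
  rec <- sa_records(model, probe_radius, sphere_points, radii = radii)
  regions <- classify_residues(rec)
  r <- regions$records
  buried <- r$delta_sa
  region_sa <- vapply(c("support", "rim", "core"), function(cl)
    sum(buried[r$class == cl]), numeric(1))
  sticky <- vapply(c("support", "rim", "core"), function(cl)
    stickiness_sum(r$residue_name[r$class == cl]), numeric(1))
  iface <- r$class %in% c("support", "rim", "core")
  ia <- interface_atoms(model, probe_radius, sphere_points, radii = radii)
  gd <- global_density(ia)
  sc <- surface_complementarity(model, probe_radius, sc_sphere_points,
                                radii = radii, interface = ia)
  structure(list(sa_total = sum(buried[iface]),
                 sa_support = region_sa[["support"]],
                 sa_rim = region_sa[["rim"]],
                 sa_core = region_sa[["core"]],
                 stickiness_support = sticky[["support"]],
                 stickiness_rim = sticky[["rim"]],
                 stickiness_core = sticky[["core"]],
                 stickiness_interface = stickiness_sum(
                   r$residue_name[iface]),
                 global_density = gd,
                 surface_complementarity = sc,
                 regions = regions),
            class = "interface_property_panel")
}

#' @export
as.data.frame.interface_property_panel <- function(x, ...) {
  as.data.frame(x[setdiff(names(x), "regions")])
}

#' @export
print.interface_property_panel <- function(x, ...) {
  df <- as.data.frame(x)
  cat("interface_property_panel:\n")
  print(round(unlist(df), 3))
  invisible(x)
}

#' Write an interface property panel
#'
#' @param panel an `interface_property_panel`.
#' @param path output path; `.json` or TSV by extension.
#' @param complex_id row identifier for the TSV form.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, complex_id = "complex") {
  df <- cbind(complex_id = complex_id, as.data.frame(panel))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(df), path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
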