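#' Construct a complex model
#'
#' A `complex_model` holds the ATOM records of one antibody--antigen complex
#' (or a free antibody) together with the role of each chain. Roles are
#' `"heavy"`, `"light"` or `"antigen"`; all geometric operators in the package
#' match residues across models by `(role, residue_number, insertion_code)`,
#' so models of the same molecule are expected to share author numbering.
#'
#' @param atoms data.frame with columns `chain_id`, `residue_number`,
#'   `insertion_code` (`""` when absent), `residue_name` (3-letter code),
#'   `atom_name`, `element`, `x`, `y`, `z`, `b_factor`. The B-factor column
#'   carries per-residue predicted errors when the model comes from a
#'   structure predictor.
#' @param chain_roles named character vector mapping chain id to one of
#'   `"heavy"`, `"light"`, `"antigen"`.
#' @param model_id identifier for the model.
#' @param source_tool optional tag naming the generator of the model.
#' @return An object of class `complex_model`.
#' @export
complex_model <- function(atoms, chain_roles, model_id = "model",
                          source_tool = NULL) {
  req <- c("chain_id", "residue_number", "insertion_code", "residue_name",
           "atom_name", "element", "x", "y", "z", "b_factor")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  atoms <- as.data.frame(atoms)[req]
  atoms$chain_id <- as.character(atoms$chain_id)
  atoms$insertion_code <- as.character(atoms$insertion_code)
  atoms$insertion_code[is.na(atoms$insertion_code)] <- ""
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite atom coordinates")
  key <- paste(atoms$chain_id, atoms$residue_number, atoms$insertion_code,
               atoms$atom_name, sep = "|")
  if (anyDuplicated(key))
    stop("duplicated (chain, residue, insertion, atom) records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = "; "))
  if (is.null(names(chain_roles)) || any(names(chain_roles) == ""))
    stop("chain_roles must be a named vector (chain id -> role)")
  bad_role <- setdiff(unique(chain_roles), c("heavy", "light", "antigen"))
  if (length(bad_role))
    stop("unknown chain role(s): ", paste(bad_role, collapse = ", "))
  orphan <- setdiff(unique(atoms$chain_id), names(chain_roles))
  if (length(orphan))
    stop("chains without an assigned role: ", paste(orphan, collapse = ", "))
  if (!any(chain_roles %in% c("heavy", "light")))
    stop("model has no antibody (heavy/light) chain")
  structure(list(atoms = atoms, chain_roles = chain_roles,
                 model_id = model_id, source_tool = source_tool),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain_id", "residue_number",
                                  "insertion_code")]))
  cat("complex_model '", x$model_id, "': ", nrow(x$atoms), " atoms, ",
      nres, " residues, chains [",
      paste(sprintf("%s=%s", names(x$chain_roles), x$chain_roles),
            collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# role of every atom, in atom order
.atom_roles <- function(model) {
  unname(model$chain_roles[model$atoms$chain_id])
}

# residue-level key used for cross-model correspondence
.residue_key <- function(role, resno, ins) {
  paste(role, resno, ifelse(ins == "" | is.na(ins), "-", ins), sep = ":")
}

.atom_residue_keys <- function(model) {
  a <- model$atoms
  .residue_key(.atom_roles(model), a$residue_number, a$insertion_code)
}

.model_xyz <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Residue keys of a model
#'
#' Returns the unique residue identifiers (`role:number:insertion`) of a
#' model, optionally restricted to given roles. These keys are the currency
#' of all selection arguments (`fit_selection`, `measure_region`, ...).
#'
#' @param model a `complex_model`.
#' @param roles optional character vector of roles to keep.
#' @return character vector of residue keys in atom order.
#' @export
residue_keys <- function(model, roles = NULL) {
  keys <- .atom_residue_keys(model)
  if (!is.null(roles)) {
    keep <- .atom_roles(model) %in% roles
    keys <- keys[keep]
  }
  unique(keys)
}

.BACKBONE_ATOMS <- c("N", "CA", "C", "O")

.subset_atom_idx <- function(model, atom_subset) {
  a <- model$atoms
  switch(atom_subset,
         backbone = which(a$atom_name %in% .BACKBONE_ATOMS),
         heavy = which(toupper(a$element) != "H"),
         all = seq_len(nrow(a)),
         stop("unknown atom_subset: ", atom_subset))
}

#' Read a structure file into a complex model
#'
#' Parses PDB or mmCIF through bio3d, keeping ATOM records of the first model
#' only (HETATM and waters are excluded) and collapsing alternate locations
#' to the highest-occupancy conformer. Chain roles are taken from
#' `chain_roles` when given; otherwise chains named `H`/`L` are assumed to be
#' the antibody heavy/light chains and every other chain the antigen.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension).
#' @param chain_roles optional named vector chain id -> role, overriding the
#'   heuristic.
#' @return a [complex_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           chain_roles = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    suppressWarnings(
      if (format == "mmcif") bio3d::read.cif(path, multi = FALSE)
      else bio3d::read.pdb(path, multi = FALSE)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  a <- parsed$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  if (!nrow(a)) stop("no ATOM records in ", path)
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  # alt-loc: keep the highest-occupancy conformer, first on ties
  altkey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  if (anyDuplicated(altkey)) {
    occ <- a$o
    occ[is.na(occ)] <- 1
    ord <- order(altkey, -occ)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(altkey[ord]), , drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- sub("^[0-9]*", "", a$elety)
    elem <- substr(elem, 1, 1)
  }
  elem <- toupper(trimws(elem))
  atoms <- data.frame(chain_id = a$chain, residue_number = a$resno,
                      insertion_code = a$insert, residue_name = a$resid,
                      atom_name = a$elety, element = elem,
                      x = a$x, y = a$y, z = a$z,
                      b_factor = ifelse(is.na(a$b), 0, a$b),
                      stringsAsFactors = FALSE)
  chains <- unique(atoms$chain_id)
  if (is.null(chain_roles)) {
    chain_roles <- ifelse(chains == "H", "heavy",
                          ifelse(chains == "L", "light", "antigen"))
    names(chain_roles) <- chains
    if (!any(chain_roles %in% c("heavy", "light")))
      stop("cannot assign chain roles for ", path,
           ": no chain named H or L; pass chain_roles explicitly")
  }
  complex_model(atoms, chain_roles,
                model_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a complex model as PDB
#'
#' @param model a `complex_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  name <- ifelse(nchar(a$atom_name) < 4, paste0(" ", a$atom_name),
                 a$atom_name)
  lines <- sprintf(
    "ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name, " ", a$residue_name, substr(a$chain_id, 1, 1),
    a$residue_number, ifelse(a$insertion_code == "", " ", a$insertion_code),
    a$x, a$y, a$z, 1.00, a$b_factor, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Chothia CDR windows (inclusive author numbering on the given chain role)
.CDR_WINDOWS <- list(
  chothia = list(
    "CDR-H1" = list(role = "heavy", from = 26, to = 32),
    "CDR-H2" = list(role = "heavy", from = 52, to = 56),
    "CDR-H3" = list(role = "heavy", from = 95, to = 102),
    "CDR-L1" = list(role = "light", from = 24, to = 34),
    "CDR-L2" = list(role = "light", from = 50, to = 56),
    "CDR-L3" = list(role = "light", from = 89, to = 97)))

#' Annotate framework and CDR regions of the antibody
#'
#' Partitions the antibody (Fv) residues of a model into the framework and
#' the six CDR loops using fixed residue-number windows of the chosen
#' numbering scheme (Chothia-style windows by default). Antigen residues are
#' not annotated. Models lacking a light chain are annotated on the heavy
#' chain only.
#'
#' @param model a `complex_model` numbered under `scheme`.
#' @param scheme numbering scheme tag; only `"chothia"` windows ship.
#' @return object of class `cdr_annotation`: list with `scheme`, `regions`
#'   (named list of residue-key vectors, `FR` plus present CDRs) and
#'   `h3_length`.
#' @export
annotate_cdrs <- function(model, scheme = "chothia") {
  windows <- .CDR_WINDOWS[[scheme]]
  if (is.null(windows)) stop("unknown numbering scheme: ", scheme)
  a <- model$atoms
  roles <- .atom_roles(model)
  ab <- roles %in% c("heavy", "light")
  res <- unique(data.frame(role = roles[ab],
                           resno = a$residue_number[ab],
                           ins = a$insertion_code[ab],
                           stringsAsFactors = FALSE))
  if (!any(res$role == "heavy"))
    stop("annotation requires a heavy chain")
  dup <- duplicated(res[, c("role", "resno", "ins")])
  if (any(dup))
    stop("numbering inconsistent with scheme '", scheme, "': duplicated ",
         paste(.residue_key(res$role[dup], res$resno[dup], res$ins[dup]),
               collapse = ", "))
  res <- res[order(match(res$role, c("heavy", "light")), res$resno,
                   res$ins), ]
  keys <- .residue_key(res$role, res$resno, res$ins)
  assigned <- rep(NA_character_, nrow(res))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    hit <- res$role == w$role & res$resno >= w$from & res$resno <= w$to
    if (any(hit)) assigned[hit] <- nm
  }
  regions <- split(keys, factor(assigned, levels = names(windows)))
  regions <- regions[vapply(regions, length, 1L) > 0]
  regions <- c(list(FR = keys[is.na(assigned)]), regions)
  structure(list(scheme = scheme, regions = regions,
                 h3_length = length(regions[["CDR-H3"]])),
            class = "cdr_annotation")
}

#' @export
print.cdr_annotation <- function(x, ...) {
  cat("cdr_annotation (", x$scheme, "): ",
      paste(sprintf("%s=%d", names(x$regions),
                    vapply(x$regions, length, 1L)), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Kabsch: rotation R (row-vector convention) and translation such that
# X %*% R + t is optimally fitted onto Y; reflection guarded.
.kabsch <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  sv <- svd(crossprod(Xc, Yc))
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  t_vec <- cy - as.numeric(cx %*% R)
  fitted <- sweep(Xc %*% R, 2, cy, `+`)
  list(rotation = R, translation = t_vec,
       rmsd = sqrt(mean(rowSums((fitted - Y)^2))))
}

# match atoms between two models on (residue key, atom name) restricted to a
# residue selection and an atom subset; returns paired coordinate matrices
.matched_coords <- function(mobile, reference, selection, atom_subset) {
  mi <- .subset_atom_idx(mobile, atom_subset)
  ri <- .subset_atom_idx(reference, atom_subset)
  mk <- paste(.atom_residue_keys(mobile), mobile$atoms$atom_name)[mi]
  rk <- paste(.atom_residue_keys(reference), reference$atoms$atom_name)[ri]
  if (!is.null(selection)) {
    mi <- mi[.atom_residue_keys(mobile)[mi] %in% selection]
    ri <- ri[.atom_residue_keys(reference)[ri] %in% selection]
    mk <- paste(.atom_residue_keys(mobile), mobile$atoms$atom_name)[mi]
    rk <- paste(.atom_residue_keys(reference), reference$atoms$atom_name)[ri]
    got_mob <- unique(.atom_residue_keys(mobile)[mi])
    got_ref <- unique(.atom_residue_keys(reference)[ri])
    miss <- union(setdiff(selection, got_mob), setdiff(selection, got_ref))
    if (length(miss))
      stop("selection residues absent from one structure: ",
           paste(utils::head(miss, 5), collapse = ", "))
  }
  common <- intersect(mk, rk)
  if (!length(common)) stop("no corresponding atoms between structures")
  mi <- mi[match(common, mk)]
  ri <- ri[match(common, rk)]
  list(X = .model_xyz(mobile)[mi, , drop = FALSE],
       Y = .model_xyz(reference)[ri, , drop = FALSE])
}

.check_degenerate <- function(X) {
  if (nrow(X) < 3) stop("degenerate fit: fewer than 3 atoms")
  sv <- svd(sweep(X, 2, colMeans(X)))$d
  if (sv[2] < 1e-8 * max(sv[1], 1))
    stop("degenerate fit: atoms are collinear")
}

#' Least-squares superposition of two models
#'
#' Computes the optimal rigid transform (Kabsch, reflection-guarded) fitting
#' `mobile` onto `reference` over the atoms selected by `fit_selection` and
#' `atom_subset`. Atoms are paired by `(role, residue number, insertion
#' code, atom name)`.
#'
#' @param mobile,reference `complex_model` objects.
#' @param fit_selection character vector of residue keys (see
#'   [residue_keys()]); `NULL` fits on all shared residues.
#' @param atom_subset `"backbone"` (N, CA, C, O), `"heavy"` or `"all"`.
#' @return list of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length 3) and `rmsd` (Angstrom over the fitted atoms);
#'   apply with [apply_transform()].
#' @export
superpose <- function(mobile, reference, fit_selection = NULL,
                      atom_subset = c("backbone", "heavy", "all")) {
  atom_subset <- match.arg(atom_subset)
  mc <- .matched_coords(mobile, reference, fit_selection, atom_subset)
  .check_degenerate(mc$X)
  out <- .kabsch(mc$X, mc$Y)
  out$n_atoms <- nrow(mc$X)
  class(out) <- "superposition"
  out
}

#' Apply a rigid transform to a model
#'
#' @param model a `complex_model`.
#' @param transform a `superposition` from [superpose()].
#' @return the transformed `complex_model`.
#' @export
apply_transform <- function(model, transform) {
  xyz <- .model_xyz(model) %*% transform$rotation
  xyz <- sweep(xyz, 2, transform$translation, `+`)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

#' RMSD of a region after fitting on another region
#'
#' Superposes `model` onto `reference` using the residues in `fit_region`,
#' then reports the RMSD over `measure_region` without refitting. With
#' `fit_region = NULL` no fit is performed (identity transform), giving the
#' raw coordinate RMSD of the measured region.
#'
#' @inheritParams superpose
#' @param measure_region residue keys over which the RMSD is reported.
#' @param fit_region residue keys used for the superposition, or `NULL`.
#' @return RMSD in Angstrom.
#' @export
region_rmsd <- function(model, reference, measure_region, fit_region,
                        atom_subset = c("backbone", "heavy", "all")) {
  atom_subset <- match.arg(atom_subset)
  if (!is.null(fit_region)) {
    tr <- superpose(model, reference, fit_region, atom_subset)
    model <- apply_transform(model, tr)
  }
  mc <- .matched_coords(model, reference, measure_region, atom_subset)
  sqrt(mean(rowSums((mc$X - mc$Y)^2)))
}

#' Ensemble RMSD diagnostics
#'
#' For an ensemble of free-antibody models, computes per region: the
#' free-RMSD (mean of the region RMSD over all unordered model pairs), and,
#' when a bound reference is supplied, the bound-RMSD of each model to the
#' reference and the best (minimum) bound-RMSD. All RMSDs are measured after
#' best-fit superposition of the framework region on backbone atoms.
#'
#' @param ensemble list of at least two `complex_model` objects sharing
#'   numbering.
#' @param bound_reference optional `complex_model` of the antigen-bound
#'   antibody crystal structure.
#' @param annotation a `cdr_annotation`; its `FR` region is the fit region.
#' @param regions named list of residue-key vectors to report on; defaults
#'   to the annotation's regions plus the pooled `CDR` union.
#' @param atom_subset atoms used throughout (default backbone).
#' @return list of class `ensemble_rmsd_report` with `free_rmsd`,
#'   `bound_rmsd` (per-model matrix) and `best_bound_rmsd`.
#' @export
ensemble_rmsd_report <- function(ensemble, bound_reference = NULL,
                                 annotation, regions = NULL,
                                 atom_subset = "backbone") {
  if (length(ensemble) < 2)
    stop("free-RMSD requires an ensemble of at least 2 models")
  fit <- annotation$regions$FR
  if (is.null(regions)) {
    regions <- annotation$regions
    cdr <- unlist(regions[grepl("^CDR-", names(regions))], use.names = FALSE)
    if (length(cdr)) regions$CDR <- cdr
  }
  free_rmsd <- vapply(regions, function(reg) {
    pr <- utils::combn(length(ensemble), 2)
    mean(apply(pr, 2, function(ij)
      region_rmsd(ensemble[[ij[1]]], ensemble[[ij[2]]], reg, fit,
                  atom_subset)))
  }, numeric(1))
  bound <- best <- NULL
  if (!is.null(bound_reference)) {
    bound <- sapply(regions, function(reg)
      vapply(ensemble, function(m)
        region_rmsd(m, bound_reference, reg, fit, atom_subset), numeric(1)))
    bound <- matrix(bound, nrow = length(ensemble),
                    dimnames = list(NULL, names(regions)))
    best <- apply(bound, 2, min)
  }
  structure(list(free_rmsd = free_rmsd, bound_rmsd = bound,
                 best_bound_rmsd = best),
            class = "ensemble_rmsd_report")
}

#' Export region definitions as JSON
#'
#' @param annotation a `cdr_annotation`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_regions_json <- function(annotation, path) {
  jsonlite::write_json(list(scheme = annotation$scheme,
                            h3_length = annotation$h3_length,
                            regions = annotation$regions),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
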