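# DockQ constants: contact cutoff, interface-residue cutoff, and the two
# RMSD scaling lengths of the published score
.DOCKQ_CONTACT <- 5.0
.DOCKQ_INTERFACE <- 10.0
.DOCKQ_D1 <- 1.5
.DOCKQ_D2 <- 8.5

# cross-interface residue pairs of a model within a heavy-atom cutoff
.cross_pairs <- function(model, cutoff) {
  a <- model$atoms[toupper(model$atoms$element) != "H", , drop = FALSE]
  roles <- model$chain_roles[a$chain_id]
  ab <- roles %in% c("heavy", "light")
  ag <- roles == "antigen"
  if (!any(ag)) stop("model has no antigen chain")
  keys <- .residue_key(unname(roles), a$residue_number, a$insertion_code)
  Xab <- as.matrix(a[ab, c("x", "y", "z")])
  Xag <- as.matrix(a[ag, c("x", "y", "z")])
  d2 <- outer(rowSums(Xab^2), rowSums(Xag^2), `+`) - 2 * Xab %*% t(Xag)
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hit))
    return(data.frame(ab = character(0), ag = character(0)))
  unique(data.frame(ab = keys[ab][hit[, 1]], ag = keys[ag][hit[, 2]],
                    stringsAsFactors = FALSE))
}

#' Native cross-interface contacts
#'
#' Residue pairs across the antibody--antigen interface with any heavy-atom
#' distance within the cutoff (DockQ convention, default 5 Angstrom).
#'
#' @param native a `complex_model` with antibody and antigen chains.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @return data.frame with residue-key columns `ab`, `ag`; empty (with a
#'   warning) when the chains do not touch.
#' @export
native_contacts <- function(native, cutoff = .DOCKQ_CONTACT) {
  pairs <- .cross_pairs(native, cutoff)
  if (!nrow(pairs)) warning("no cross-interface contacts at ", cutoff, " A")
  pairs
}

#' DockQ from its three components
#'
#' `DockQ = (fnat + 1 / (1 + (irms / 1.5)^2) + 1 / (1 + (lrms / 8.5)^2)) / 3`
#'
#' @param fnat fraction of native contacts preserved, in \[0, 1\].
#' @param irms interface backbone RMSD, Angstrom.
#' @param lrms ligand (antigen) backbone RMSD after receptor fit, Angstrom.
#' @return scalar in \[0, 1\].
#' @export
dockq_from_components <- function(fnat, irms, lrms) {
  (fnat + 1 / (1 + (irms / .DOCKQ_D1)^2) +
     1 / (1 + (lrms / .DOCKQ_D2)^2)) / 3
}

#' Quality class of a DockQ score
#'
#' Application-oriented thresholds: `acceptable` at DockQ >= 0.23 (epitope
#' mapping), `medium` at >= 0.49 (antibody design), `high` at >= 0.80,
#' `incorrect` below 0.23.
#'
#' @param dockq numeric vector of DockQ scores.
#' @return character vector of classes.
#' @export
dockq_class <- function(dockq) {
  cut_labels <- c("incorrect", "acceptable", "medium", "high")
  cut_labels[findInterval(dockq, c(0.23, 0.49, 0.80)) + 1]
}

#' Score a docked pose against its native complex
#'
#' Computes the DockQ components: `fnat`, the preserved fraction of native
#' cross-interface contacts (5 Angstrom heavy-atom cutoff); `irms`, the
#' backbone RMSD over the native interface residues (10 Angstrom
#' definition) after fitting on those residues; and `lrms`, the antigen
#' backbone RMSD after fitting on the antibody (receptor) backbone. Pose
#' and native must share residue numbering per chain role.
#'
#' @param pose,native `complex_model` objects.
#' @param contact_cutoff heavy-atom contact cutoff for fnat, Angstrom.
#' @param interface_cutoff residue-inclusion cutoff for irms, Angstrom.
#' @return list of class `pose_quality`: `fnat`, `irms`, `lrms`, `dockq`,
#'   `quality_class`.
#' @export
dockq_score <- function(pose, native, contact_cutoff = .DOCKQ_CONTACT,
                        interface_cutoff = .DOCKQ_INTERFACE) {
  nat <- native_contacts(native, contact_cutoff)
  if (!nrow(nat)) stop("native complex has no interface contacts")
  pos <- .cross_pairs(pose, contact_cutoff)
  nat_key <- paste(nat$ab, nat$ag)
  fnat <- if (nrow(pos)) mean(nat_key %in% paste(pos$ab, pos$ag)) else 0
  # interface residues: both partners of any 10-A cross pair in the native
  wide <- .cross_pairs(native, interface_cutoff)
  iface_res <- unique(c(wide$ab, wide$ag))
  irms <- tryCatch(
    region_rmsd(pose, native, iface_res, iface_res, "backbone"),
    error = function(e) stop("correspondence error computing irms: ",
                             conditionMessage(e), call. = FALSE))
  rec_res <- residue_keys(native, c("heavy", "light"))
  lig_res <- residue_keys(native, "antigen")
  lrms <- tryCatch(
    region_rmsd(pose, native, lig_res, rec_res, "backbone"),
    error = function(e) stop("correspondence error computing lrms: ",
                             conditionMessage(e), call. = FALSE))
  dq <- dockq_from_components(fnat, irms, lrms)
  structure(list(fnat = fnat, irms = irms, lrms = lrms, dockq = dq,
                 quality_class = dockq_class(dq)),
            class = "pose_quality")
}

#' @export
print.pose_quality <- function(x, ...) {
  cat(sprintf(
    "pose_quality: fnat %.3f | irms %.2f A | lrms %.2f A | DockQ %.3f (%s)\n",
    x$fnat, x$irms, x$lrms, x$dockq, x$quality_class))
  invisible(x)
}
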