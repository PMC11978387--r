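#' Specification for a toy antibody--antigen complex
#'
#' Parameters of the deterministic toy-complex generator. The toy geometry
#' is an idealized extended backbone (3.8 Angstrom CA--CA spacing) with
#' N/C/O backbone atoms and a CB pseudo-side-chain per residue; contacts
#' are engineered by pointing the CB atoms of the designated interface
#' residues of the two chains at each other across the chain gap.
#'
#' @param n_antibody_residues,n_antigen_residues chain sizes.
#' @param interface_size number of engineered cross-chain residue pairs.
#' @param h3_length residues in the designated CDR-H3 window (Chothia-style
#'   numbering 95--102, insertion codes at 100 for lengths above 8).
#' @param seed geometry seed for the small coordinate jitter.
#' @param contact_distance heavy-atom distance (Angstrom) at which the
#'   engineered pairs touch; designated CB--CB pairs sit 1 Angstrom inside
#'   it.
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_antibody_residues = 24,
                             n_antigen_residues = 18, interface_size = 6,
                             h3_length = 8, seed = 1,
                             contact_distance = 5) {
  spec <- list(n_antibody_residues = n_antibody_residues,
               n_antigen_residues = n_antigen_residues,
               interface_size = interface_size, h3_length = h3_length,
               seed = seed, contact_distance = contact_distance)
  if (interface_size > min(n_antibody_residues, n_antigen_residues))
    stop("spec error: interface_size exceeds a chain size")
  if (h3_length < 1 || h3_length >= n_antibody_residues)
    stop("spec error: h3_length must leave framework residues")
  nf1 <- floor((n_antibody_residues - h3_length) / 2)
  if (nf1 > 25)
    stop("spec error: antibody too large for the fixed numbering windows ",
         "(n_antibody_residues - h3_length must be <= 51)")
  if (nf1 + interface_size > n_antibody_residues)
    stop("spec error: interface patch runs past the antibody chain")
  if (contact_distance < 4)
    stop("spec error: contact_distance below the toy geometry minimum (4)")
  structure(spec, class = "toy_complex_spec")
}

# Chothia-style heavy-chain numbering for a toy chain: FR1 (1..nf1), the H3
# window 95-102 with insertions at 100, FR tail from 103
.toy_heavy_numbering <- function(n_res, h3_length) {
  nf1 <- floor((n_res - h3_length) / 2)
  nf2 <- n_res - nf1 - h3_length
  h3_no <- if (h3_length <= 8) {
    list(no = 94 + seq_len(h3_length), ins = rep("", h3_length))
  } else {
    n_ins <- h3_length - 8
    list(no = c(95:100, rep(100L, n_ins), 101L, 102L),
         ins = c(rep("", 6), LETTERS[seq_len(n_ins)], "", ""))
  }
  list(resno = c(seq_len(nf1), h3_no$no, 102L + seq_len(nf2)),
       ins = c(rep("", nf1), h3_no$ins, rep("", nf2)),
       nf1 = nf1)
}

.TOY_RESNAMES <- c("ALA", "SER", "TYR", "GLY", "LEU", "THR", "VAL", "ASP",
                   "LYS", "PHE")

# one toy chain: backbone + CB, with CB flipped toward the partner for
# designated patch residues. `side` is +1 (partner lies at higher y) or -1.
.toy_chain <- function(chain_id, resno, ins, x_pos, y0, z_phase, side,
                       patch) {
  n <- length(resno)
  z <- 0.3 * sin(0.7 * seq_len(n) + z_phase)
  cb_y <- ifelse(seq_len(n) %in% patch, y0 + side * 1.5, y0 - side * 1.5)
  per_atom <- function(name, dx, dy, dz, yy = NULL) {
    data.frame(chain_id = chain_id, residue_number = resno,
               insertion_code = ins,
               residue_name = rep_len(.TOY_RESNAMES, n),
               atom_name = name,
               element = substr(name, 1, 1),
               x = x_pos + dx,
               y = if (is.null(yy)) y0 + dy else yy,
               z = z + dz, b_factor = 0)
  }
  rbind(per_atom("N", -1.2, -side * 0.3, 0.2),
        per_atom("CA", 0, 0, 0),
        per_atom("C", 1.2, -side * 0.3, -0.2),
        per_atom("O", 1.5, -side * 1.4, -0.2),
        per_atom("CB", 0, 0, 0.1, yy = cb_y))
}

#' Generate a toy antibody--antigen complex
#'
#' Builds a deterministic two-chain complex from a [toy_complex_spec()]:
#' heavy chain `H` and antigen chain `A` as idealized extended backbones
#' with CB pseudo-side-chains. Exactly `interface_size` residue pairs touch
#' within `contact_distance` (through their CB atoms); all other
#' cross-chain atom distances stay above it. The heavy chain carries a
#' designated CDR-H3 window of `h3_length` residues, and the interface
#' patch starts at that window. A small seeded jitter (<= 0.05 Angstrom per
#' coordinate) breaks exact degeneracies; output is bit-reproducible per
#' seed.
#'
#' @param spec a [toy_complex_spec()].
#' @return list: `model` (a `complex_model`), `annotation` (its
#'   [annotate_cdrs()] result), `interface_pairs` (data.frame of designated
#'   residue-key pairs `ab`, `ag`).
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  num <- .toy_heavy_numbering(spec$n_antibody_residues, spec$h3_length)
  nf1 <- num$nf1
  patch_ab <- if (spec$interface_size > 0)
    nf1 + seq_len(spec$interface_size) else integer(0)
  x_ab <- 3.8 * seq_len(spec$n_antibody_residues)
  heavy <- .toy_chain("H", num$resno, num$ins, x_ab, y0 = 0,
                      z_phase = 0, side = +1, patch = patch_ab)
  ygap <- if (spec$interface_size > 0) spec$contact_distance + 2 else 25
  patch_ag <- if (spec$interface_size > 0) seq_len(spec$interface_size)
              else integer(0)
  x_ag <- 3.8 * (nf1 + seq_len(spec$n_antigen_residues))
  antigen <- .toy_chain("A", seq_len(spec$n_antigen_residues),
                        rep("", spec$n_antigen_residues), x_ag, y0 = ygap,
                        z_phase = 1.3, side = -1, patch = patch_ag)
  atoms <- rbind(heavy, antigen)
  set.seed(spec$seed)
  jit <- matrix(stats::runif(3 * nrow(atoms), -0.05, 0.05), ncol = 3)
  atoms$x <- atoms$x + jit[, 1]
  atoms$y <- atoms$y + jit[, 2]
  atoms$z <- atoms$z + jit[, 3]
  model <- complex_model(atoms, c(H = "heavy", A = "antigen"),
                         model_id = sprintf("toy_seed%d", spec$seed),
                         source_tool = "synthetic")
  pairs <- if (spec$interface_size > 0) {
    data.frame(ab = .residue_key("heavy", num$resno[patch_ab],
                                 num$ins[patch_ab]),
               ag = .residue_key("antigen", patch_ag, ""))
  } else data.frame(ab = character(0), ag = character(0))
  list(model = model, annotation = annotate_cdrs(model),
       interface_pairs = pairs)
}

#' Graded pose decoys from a native complex
#'
#' Rigidly perturbs the antigen body of a native complex with a graded
#' schedule of rotations (about the antigen centroid, seeded random axis)
#' followed by translations away from the antibody, and records each
#' decoy's true DockQ against the native. The default schedule spans the
#' quality classes from high (zero perturbation) to incorrect.
#'
#' @param native a `complex_model` with an interface.
#' @param n_decoys number of decoys.
#' @param schedule optional data.frame `rotation_deg`, `translation_A`;
#'   defaults to a smooth ramp 0..60 degrees and 0..25 Angstrom.
#' @param seed RNG seed for the rotation axes.
#' @return list of class `decoy_set`: `models` (list of `complex_model`)
#'   and `summary` (data.frame `decoy_id`, `rotation_deg`,
#'   `translation_A`, `fnat`, `irms`, `lrms`, `dockq`, `quality_class`).
#' @export
make_pose_decoys <- function(native, n_decoys = 20, schedule = NULL,
                             seed = 1) {
  if (is.null(schedule)) {
    f <- if (n_decoys == 1) 0 else (seq_len(n_decoys) - 1) / (n_decoys - 1)
    schedule <- data.frame(rotation_deg = 60 * f^1.5,
                           translation_A = 25 * f^1.5)
  }
  stopifnot(nrow(schedule) == n_decoys)
  roles <- .atom_roles(native)
  ag <- roles == "antigen"
  if (!any(ag)) stop("native has no antigen body to perturb")
  xyz <- .model_xyz(native)
  cen_ag <- colMeans(xyz[ag, , drop = FALSE])
  cen_ab <- colMeans(xyz[!ag, , drop = FALSE])
  away <- cen_ag - cen_ab
  away <- away / sqrt(sum(away^2))
  set.seed(seed)
  models <- vector("list", n_decoys)
  rows <- vector("list", n_decoys)
  for (i in seq_len(n_decoys)) {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    th <- schedule$rotation_deg[i] * pi / 180
    K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                  axis[2], -axis[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
    m <- native
    pg <- sweep(xyz[ag, , drop = FALSE], 2, cen_ag)
    pg <- pg %*% R
    pg <- sweep(pg, 2, cen_ag + schedule$translation_A[i] * away, `+`)
    m$atoms$x[ag] <- pg[, 1]; m$atoms$y[ag] <- pg[, 2]
    m$atoms$z[ag] <- pg[, 3]
    m$model_id <- sprintf("decoy%03d", i)
    q <- suppressWarnings(dockq_score(m, native))
    models[[i]] <- m
    rows[[i]] <- data.frame(decoy_id = m$model_id,
                            rotation_deg = schedule$rotation_deg[i],
                            translation_A = schedule$translation_A[i],
                            fnat = q$fnat, irms = q$irms, lrms = q$lrms,
                            dockq = q$dockq, quality_class = q$quality_class)
  }
  structure(list(models = models, summary = do.call(rbind, rows)),
            class = "decoy_set")
}

# discretized Gaussian over bin centers, rows normalized
.binned_gaussian <- function(mu, centers, sd = 1.5) {
  w <- exp(-(outer(mu, centers, `-`))^2 / (2 * sd^2))
  w / rowSums(w)
}

#' Synthetic confidence bundle correlated with true quality
#'
#' Draws a full confidence bundle (pLDDT, pTM, aligned-error probability
#' tensor, physics score) as noisy monotone transforms of a pose's true
#' DockQ. Each metric sees its own effective quality `rho * q + (1 - rho) *
#' u` with independent uniform noise `u`, so `fidelity = 1` yields metrics
#' that rank poses exactly as their true quality and `fidelity = 0` yields
#' quality-independent noise.
#'
#' @param true_quality the pose's true DockQ in \[0, 1\].
#' @param fidelity correlation parameter rho in \[0, 1\].
#' @param seed RNG seed.
#' @param n_res residues in scope (PAE tensor size).
#' @param n_antibody residues assigned to the antibody chain group.
#' @param engine physics-engine tag (sets the score orientation).
#' @param pose_id identifier.
#' @return a [confidence_bundle()].
#' @export
make_confidence_bundle <- function(true_quality, fidelity, seed = 1,
                                   n_res = 20, n_antibody = 12,
                                   engine = "zdock", pose_id = "pose") {
  stopifnot(fidelity >= 0, fidelity <= 1,
            true_quality >= 0, true_quality <= 1)
  set.seed(seed)
  qe <- fidelity * true_quality + (1 - fidelity) * stats::runif(4)
  plddt <- pmin(pmax(40 + 55 * qe[1] + 5 * sin(seq_len(n_res)), 0), 100)
  ptm <- 0.1 + 0.85 * qe[2]
  centers <- seq(1, 31, by = 2)
  mu_inter <- 1 + 27 * (1 - qe[3])
  part <- c(rep("antibody", n_antibody), rep("antigen", n_res - n_antibody))
  inter <- outer(part, part, `!=`)
  mu <- matrix(1.5, n_res, n_res)
  mu[inter] <- mu_inter
  probs_flat <- .binned_gaussian(as.vector(mu), centers)
  probs <- array(probs_flat, c(n_res, n_res, length(centers)))
  phys <- if (engine == "propose") -40 * qe[4] else 60 * qe[4]
  confidence_bundle(plddt, ptm, probs, centers, part, phys, engine,
                    pose_id)
}

#' Jitter pseudo-side-chain atoms
#'
#' Displaces side-chain (non-backbone) atoms with isotropic Gaussian noise
#' whose RMS displacement equals `magnitude`; backbone atoms (N, CA, C, O)
#' are untouched. A stand-in for side-chain rearrangement on toy models;
#' no rotamer repacking is attempted.
#'
#' @param model a `complex_model` carrying side-chain atoms.
#' @param magnitude target RMS displacement, Angstrom.
#' @param seed RNG seed.
#' @return the perturbed `complex_model`.
#' @export
perturb_sidechain_proxy <- function(model, magnitude, seed = 1) {
  if (magnitude == 0) return(model)
  sc <- !(model$atoms$atom_name %in% .BACKBONE_ATOMS)
  if (!any(sc)) stop("model carries no side-chain atoms")
  set.seed(seed)
  n <- sum(sc)
  d <- matrix(stats::rnorm(3 * n, sd = magnitude / sqrt(3)), ncol = 3)
  model$atoms$x[sc] <- model$atoms$x[sc] + d[, 1]
  model$atoms$y[sc] <- model$atoms$y[sc] + d[, 2]
  model$atoms$z[sc] <- model$atoms$z[sc] + d[, 3]
  model
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits a toy native complex as PDB together with per-decoy confidence
#' JSON and a physics-score TSV in the same dialects the readers consume,
#' so the full command-line path is exercisable offline.
#'
#' @param dir output directory (created if needed).
#' @param spec a [toy_complex_spec()].
#' @param n_decoys decoys to generate.
#' @param fidelity confidence fidelity rho.
#' @param seed RNG seed.
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_fixture <- function(dir, spec = toy_complex_spec(),
                                    n_decoys = 10, fidelity = 0.8,
                                    seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  toy <- make_toy_complex(spec)
  native_path <- file.path(dir, "native.pdb")
  write_structure(toy$model, native_path)
  decoys <- make_pose_decoys(toy$model, n_decoys, seed = seed)
  paths <- c(native_path)
  scores <- NULL
  for (i in seq_len(n_decoys)) {
    m <- decoys$models[[i]]
    pp <- file.path(dir, sprintf("%s.pdb", m$model_id))
    write_structure(m, pp)
    b <- make_confidence_bundle(decoys$summary$dockq[i], fidelity,
                                seed = seed + i, pose_id = m$model_id)
    cj <- file.path(dir, sprintf("%s_confidence.json", m$model_id))
    jsonlite::write_json(list(plddt = b$plddt, ptm = b$ptm,
                              pae_probs = b$pae_probs,
                              bin_centers = b$bin_centers,
                              chain_partition = b$chain_partition),
                         cj, auto_unbox = TRUE, digits = NA)
    scores <- rbind(scores, data.frame(pose_id = m$model_id,
                                       engine = b$engine,
                                       score = b$phys_score))
    paths <- c(paths, pp, cj)
  }
  sp <- file.path(dir, "phys_scores.tsv")
  utils::write.table(scores, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, sp))
}
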