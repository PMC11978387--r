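# Shared fixture builders: point-cloud models, atom slabs, and an
# independent quaternion superposition oracle.

# single-atom-per-residue model from a coordinate matrix
mk_point_model <- function(xyz, chain = "H", roles = c(H = "heavy"),
                           atom_name = "CA", element = "C",
                           resname = "ALA") {
  n <- nrow(xyz)
  complex_model(data.frame(
    chain_id = chain, residue_number = seq_len(n), insertion_code = "",
    residue_name = resname, atom_name = atom_name, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], b_factor = 0), roles)
}

# two-chain model from two coordinate matrices (antibody H, antigen A)
mk_two_chain <- function(xyz_ab, xyz_ag, element = "C") {
  at <- function(xyz, ch) data.frame(
    chain_id = ch, residue_number = seq_len(nrow(xyz)),
    insertion_code = "", residue_name = "ALA", atom_name = "CA",
    element = element, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    b_factor = 0)
  complex_model(rbind(at(xyz_ab, "H"), at(xyz_ag, "A")),
                c(H = "heavy", A = "antigen"))
}

# flat square slab of atoms in the z = 0 plane, centered at the origin
mk_slab_xyz <- function(nx, ny, spacing = 1.2) {
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  cbind((g$x - mean(g$x)) * spacing, (g$y - mean(g$y)) * spacing, 0)
}

shift_xyz <- function(xyz, dx = 0, dy = 0, dz = 0) {
  sweep(xyz, 2, c(dx, dy, dz), `+`)
}

rotate_xyz <- function(xyz, axis = c(0, 0, 1), deg = 90) {
  axis <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz %*% R
}

# rigidly transform a whole model
transform_model <- function(model, axis = c(0, 0, 1), deg = 0,
                            dx = 0, dy = 0, dz = 0) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- shift_xyz(rotate_xyz(xyz, axis, deg), dx, dy, dz)
  model$atoms$x <- xyz[, 1]; model$atoms$y <- xyz[, 2]
  model$atoms$z <- xyz[, 3]
  model
}

# Horn's quaternion method: independent closed-form superposition oracle
quaternion_fit_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  msd <- (sum(Pc^2) + sum(Qc^2) - 2 * lam) / nrow(P)
  sqrt(max(msd, 0))
}
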