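pdb_text <- c(
  "MODEL        1",
  "ATOM      1  N   ALA H   1       1.000   2.000   3.000  1.00 10.00           N",
  "ATOM      2  CA  ALA H   1       2.400   2.100   3.200  1.00 10.00           C",
  "ATOM      3  CA  GLY H   2       5.100   2.800   3.900  1.00 11.00           C",
  "ATOM      4  CA  SER A   1       8.000   6.000   3.500  1.00 12.00           C",
  "ENDMDL",
  "MODEL        2",
  "ATOM      1  N   ALA H   1      11.000  12.000  13.000  1.00 10.00           N",
  "ATOM      2  CA  ALA H   1      12.400  12.100  13.200  1.00 10.00           C",
  "ATOM      3  CA  GLY H   2      15.100  12.800  13.900  1.00 11.00           C",
  "ATOM      4  CA  SER A   1      18.000  16.000  13.500  1.00 12.00           C",
  "ENDMDL", "END")

cif_text <- c(
  "data_mini", "loop_",
  paste0("_atom_site.",
         c("group_PDB", "id", "type_symbol", "label_atom_id",
           "label_alt_id", "label_comp_id", "label_asym_id",
           "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
           "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
           "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
           "auth_comp_id", "auth_asym_id", "auth_atom_id",
           "pdbx_PDB_model_num")),
  "ATOM 1 N N . ALA H 1 1 ? 1.000 2.000 3.000 1.00 10.00 ? 1 ALA H N 1",
  "ATOM 2 C CA . ALA H 1 1 ? 2.400 2.100 3.200 1.00 10.00 ? 1 ALA H CA 1",
  "ATOM 3 C CA . GLY H 1 2 ? 5.100 2.800 3.900 1.00 11.00 ? 2 GLY H CA 1",
  "ATOM 4 C CA . SER A 2 1 ? 8.000 6.000 3.500 1.00 12.00 ? 1 SER A CA 1")

test_that("PDB parsing returns first-model ATOM records with exact fields", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb_text, pdb)
  m <- read_structure(pdb)
  expect_s3_class(m, "complex_model")
  expect_equal(nrow(m$atoms), 4)  # model 2 dropped
  expect_equal(m$atoms$x, c(1.0, 2.4, 5.1, 8.0), tolerance = 1e-3)
  expect_equal(m$atoms$b_factor, c(10, 10, 11, 12))
  expect_equal(unname(m$chain_roles[c("H", "A")]), c("heavy", "antigen"))
})

test_that("mmCIF parse matches the PDB parse on chain/resno/atom/xyz", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(pdb_text, pdb)
  writeLines(cif_text, cif)
  mp <- read_structure(pdb)
  mc <- read_structure(cif)
  cols <- c("chain_id", "residue_number", "atom_name", "x", "y", "z")
  expect_equal(mc$atoms[cols], mp$atoms[cols], tolerance = 1e-6)
})

test_that("written PDB round-trips through the reader", {
  toy <- make_toy_complex(toy_complex_spec(seed = 11))
  out <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy$model, out)
  back <- read_structure(out)
  expect_equal(back$atoms$residue_number, toy$model$atoms$residue_number)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(toy$model$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("parse and role-assignment failures are reported", {
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines("not a structure", bad)
  expect_error(read_structure(bad), "no ATOM records|failed to parse")
  noHL <- withr::local_tempfile(fileext = ".pdb")
  writeLines(gsub(" H ", " X ", pdb_text[2:5]), noHL)
  expect_error(read_structure(noHL), "chain_roles")
})

test_that("CDR annotation partitions the Fv and reports H3 length", {
  toy <- make_toy_complex(toy_complex_spec(h3_length = 12))
  ann <- toy$annotation
  expect_equal(ann$h3_length, 12)
  # regions are disjoint and cover all antibody residues
  all_keys <- unlist(ann$regions, use.names = FALSE)
  expect_equal(anyDuplicated(all_keys), 0)
  expect_setequal(all_keys, residue_keys(toy$model, c("heavy", "light")))
  # heavy-only antibody annotates without error, heavy entries only
  expect_true(all(grepl("^heavy:", all_keys)))
})

test_that("CDR windows match an independent hand lookup", {
  # Chothia heavy windows: H1 26-32, H2 52-56, H3 95-102. Build one chain
  # numbered 20..60 plus 90..105 and tabulate by hand.
  resno <- c(20:60, 90:105)
  xyz <- cbind(3.8 * seq_along(resno), sin(seq_along(resno)),
               cos(seq_along(resno)))
  m <- mk_point_model(xyz)
  m$atoms$residue_number <- resno
  ann <- annotate_cdrs(m)
  num_of <- function(reg) as.integer(sub("^heavy:(\\d+):.*", "\\1",
                                         ann$regions[[reg]]))
  expect_setequal(num_of("CDR-H1"), 26:32)
  expect_setequal(num_of("CDR-H2"), 52:56)
  expect_setequal(num_of("CDR-H3"), 95:102)
  expect_setequal(num_of("FR"), setdiff(resno, c(26:32, 52:56, 95:102)))
})

test_that("superposition recovers rigid transforms and matches the
           quaternion oracle", {
  toy <- make_toy_complex(toy_complex_spec(seed = 3))
  ref <- toy$model
  # identity
  sp0 <- superpose(ref, ref)
  expect_equal(sp0$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp0$rotation, diag(3), tolerance = 1e-9)
  # 90-degree rotation + translation is inverted exactly
  mob <- transform_model(ref, axis = c(0, 1, 0), deg = 90,
                         dx = 5, dy = -3, dz = 7)
  sp <- superpose(mob, ref)
  expect_equal(sp$rmsd, 0, tolerance = 1e-6)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-9)
  back <- apply_transform(mob, sp)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(ref$atoms[, c("x", "y", "z")]),
               tolerance = 1e-6, ignore_attr = TRUE)
  # random cloud vs jittered copy: equals Horn quaternion RMSD to 1e-6
  set.seed(42)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  Q <- shift_xyz(rotate_xyz(P + matrix(rnorm(30, sd = 0.3), 10, 3),
                            c(1, 2, 3), 37), 1, 2, 3)
  mp <- mk_point_model(P); mq <- mk_point_model(Q)
  expect_equal(superpose(mp, mq, atom_subset = "all")$rmsd,
               quaternion_fit_rmsd(P, Q), tolerance = 1e-6)
  # cross-check against bio3d's fitting machinery
  fit <- bio3d::fit.xyz(as.vector(t(Q)), as.vector(t(P)),
                        fixed.inds = 1:30, mobile.inds = 1:30)
  expect_equal(superpose(mp, mq, atom_subset = "all")$rmsd,
               sqrt(mean(colSums(matrix((as.vector(fit) -
                 as.vector(t(Q)))^2, nrow = 3)))),
               tolerance = 1e-6)
})

test_that("superposition degeneracy and correspondence errors", {
  P <- cbind(1:5, 0, 0)  # collinear
  expect_error(superpose(mk_point_model(P), mk_point_model(P),
                         atom_subset = "all"), "collinear")
  toy <- make_toy_complex(toy_complex_spec())
  expect_error(superpose(toy$model, toy$model,
                         fit_selection = "heavy:999:-"), "absent")
})

test_that("region RMSD: constructed displacement and hand arithmetic", {
  toy <- make_toy_complex(toy_complex_spec())
  ref <- toy$model
  h3 <- toy$annotation$regions[["CDR-H3"]]
  fr <- toy$annotation$regions$FR
  # identical structures
  expect_equal(region_rmsd(ref, ref, h3, fr), 0, tolerance = 1e-9)
  # H3 translated +2 A along x, framework untouched
  mob <- ref
  in_h3 <- abdocktools:::.atom_residue_keys(ref) %in% h3
  mob$atoms$x[in_h3] <- mob$atoms$x[in_h3] + 2
  expect_equal(region_rmsd(mob, ref, h3, fr), 2.0, tolerance = 1e-6)
  # per-atom displacements {1,1,2,2,3} under identity fit
  P <- cbind(3.8 * (1:5), 0.5 * sin(1:5), 0.5 * cos(1:5))
  m1 <- mk_point_model(P)
  m2 <- mk_point_model(P + cbind(c(1, 1, 2, 2, 3), 0, 0))
  expect_equal(region_rmsd(m2, m1, residue_keys(m1), NULL, "all"),
               sqrt(mean(c(1, 1, 4, 4, 9))), tolerance = 1e-12)
})

test_that("RMSD is symmetric, rigid-invariant, and fitting never hurts", {
  toy1 <- make_toy_complex(toy_complex_spec(seed = 1))
  toy2 <- perturb_sidechain_proxy(toy1$model, 1.0, seed = 9)
  keys <- residue_keys(toy1$model)
  r12 <- region_rmsd(toy1$model, toy2, keys, NULL, "all")
  r21 <- region_rmsd(toy2, toy1$model, keys, NULL, "all")
  expect_equal(r12, r21, tolerance = 1e-9)
  both <- lapply(list(toy1$model, toy2), transform_model,
                 axis = c(1, 1, 0), deg = 55, dx = 3, dy = 1, dz = -2)
  expect_equal(region_rmsd(both[[1]], both[[2]], keys, NULL, "all"), r12,
               tolerance = 1e-6)
  # superposed RMSD <= unfitted RMSD on the same atom set
  fitted <- superpose(toy2, toy1$model, atom_subset = "all")$rmsd
  expect_lte(fitted, r12 + 1e-12)
})

test_that("ensemble report: degenerate, pairwise, and exhaustive oracle", {
  base <- make_toy_complex(toy_complex_spec(seed = 2))
  ann <- base$annotation
  # identical copies: free-RMSD 0 everywhere
  rep0 <- ensemble_rmsd_report(list(base$model, base$model), NULL, ann)
  expect_true(all(abs(rep0$free_rmsd) < 1e-9))
  # ensemble of 4 jittered models vs exhaustive pair average
  ens <- c(list(base$model), lapply(2:4, function(s)
    perturb_sidechain_proxy(base$model, 0.8, seed = s)))
  rep4 <- ensemble_rmsd_report(ens, bound_reference = base$model, ann,
                               atom_subset = "all")
  fr <- ann$regions$FR
  h3 <- ann$regions[["CDR-H3"]]
  pair_vals <- apply(utils::combn(4, 2), 2, function(ij)
    region_rmsd(ens[[ij[1]]], ens[[ij[2]]], h3, fr, "all"))
  expect_equal(unname(rep4$free_rmsd[["CDR-H3"]]), mean(pair_vals),
               tolerance = 1e-9)
  # two models: free-RMSD equals the single pair distance
  rep2 <- ensemble_rmsd_report(ens[1:2], NULL, ann, atom_subset = "all")
  expect_equal(unname(rep2$free_rmsd[["CDR-H3"]]),
               region_rmsd(ens[[1]], ens[[2]], h3, fr, "all"),
               tolerance = 1e-9)
  # best bound <= every per-model bound value
  expect_true(all(rep4$best_bound_rmsd <=
                    apply(rep4$bound_rmsd, 2, min) + 1e-12))
  expect_error(ensemble_rmsd_report(ens[1], NULL, ann), "at least 2")
})
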