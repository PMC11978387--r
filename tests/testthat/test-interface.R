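test_that("SASA matches single-sphere and two-sphere closed forms", {
  R <- 1.70 + 1.4  # carbon + probe
  m1 <- mk_point_model(matrix(c(0, 0, 0), 1))
  sa1 <- compute_sasa(m1, level = "atom")$sa
  expect_equal(sa1, 4 * pi * R^2, tolerance = 0.01 * 4 * pi * R^2)
  # two far-separated atoms: additivity
  m2 <- mk_point_model(rbind(c(0, 0, 0), c(50, 0, 0)))
  expect_equal(sum(compute_sasa(m2, level = "atom")$sa), 2 * sa1,
               tolerance = 1e-9)
  # two overlapping equal spheres at distance d: each loses a spherical
  # cap of height h = R - d/2, area 2 pi R h
  d <- 3
  m3 <- mk_point_model(rbind(c(0, 0, 0), c(d, 0, 0)))
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_equal(sum(compute_sasa(m3, level = "atom")$sa), analytic,
               tolerance = 0.01 * analytic)
  expect_error(compute_sasa(mk_point_model(matrix(0, 1, 3),
                                           element = "ZZ")),
               "radius")
})

test_that("SASA is translation-exact and rotation-stable", {
  toy <- make_toy_complex(toy_complex_spec(seed = 6))
  base <- compute_sasa(toy$model, sphere_points = 480)
  shifted <- compute_sasa(transform_model(toy$model, dx = 11, dy = -4,
                                          dz = 2), sphere_points = 480)
  expect_identical(base$sa, shifted$sa)  # bit-identical under translation
  rot <- compute_sasa(transform_model(toy$model, axis = c(1, 2, 3),
                                      deg = 73), sphere_points = 480)
  # rotation re-samples the fixed quadrature directions: small relative
  # wobble bounded by the point density
  expect_equal(rot$sa, base$sa, tolerance = 0.03)
})

test_that("relative SA: identity, zero, half, and missing reference", {
  tab <- data.frame(chain_id = "H", residue_number = 1:3,
                    insertion_code = "", residue_name = "ALA",
                    sa = c(129, 0, 64.5))
  r <- relative_sa(tab)
  expect_equal(r$rsa, c(100, 0, 50))
  tab$residue_name <- "XYZ"
  expect_error(relative_sa(tab), "reference")
})

test_that("region classifier reproduces the definitional truth table", {
  rec <- data.frame(
    chain_id = "H", residue_number = 1:7, insertion_code = "",
    residue_name = "ALA", role = "heavy",
    rsa_c = c(10, 40, 10, 40, 10, 25, 25),
    rsa_u = c(10, 40, 20, 50, 50, 25, 60),
    delta_sa = c(0, 0, 5, 5, 5, 0, 5))
  rec$sa_complexed <- rec$sa_uncomplexed <- 0
  rec$delta_rsa <- rec$rsa_u - rec$rsa_c
  cls <- classify_residues(rec)$records$class
  expect_equal(cls[1], "interior")   # rsa_c < 25, no burial
  expect_equal(cls[2], "surface")    # rsa_c > 25, no burial
  expect_equal(cls[3], "support")    # buried, rsa_c < 25, rsa_u <= 25
  expect_equal(cls[4], "rim")        # buried, rsa_c > 25
  expect_equal(cls[5], "core")       # rsa_u > 25, rsa_c < 25, buried
  # boundary ties: exactly 25% -> surface (no burial) / rim (buried)
  expect_equal(cls[6], "surface")
  expect_equal(cls[7], "rim")
})

test_that("classification partitions by burial on real toy records", {
  toy <- make_toy_complex(toy_complex_spec(seed = 8))
  rec <- sa_records(toy$model, sphere_points = 240)
  expect_true(all(rec$delta_sa >= 0))
  regions <- classify_residues(rec)
  r <- regions$records
  buried <- r$delta_sa > 1e-6
  expect_true(all(r$class[buried] %in% c("support", "rim", "core")))
  expect_true(all(r$class[!buried] %in% c("interior", "surface")))
  # region key sets are pairwise disjoint
  expect_equal(anyDuplicated(c(regions$support, regions$rim,
                               regions$core)), 0)
})

test_that("stickiness sums: empty, singleton, hand-summed, additive", {
  sc <- stickiness_scale()
  expect_equal(stickiness_sum(character(0)), 0)
  expect_equal(stickiness_sum("TRP"), unname(sc["TRP"]))
  five <- c("ALA", "TYR", "LYS", "LEU", "TYR")
  expect_equal(stickiness_sum(five),
               0.0062 + 0.8806 - 1.1806 + 0.9138 + 0.8806,
               tolerance = 1e-9)
  # additive over disjoint regions
  expect_equal(stickiness_sum(c("ALA", "TYR")) + stickiness_sum("LYS"),
               stickiness_sum(c("ALA", "TYR", "LYS")), tolerance = 1e-12)
  expect_error(stickiness_sum("XXX"), "stickiness")
  expect_warning(out <- stickiness_sum(c("ALA", "XXX"),
                                       on_missing = "skip"), "skipping")
  expect_equal(out, 0.0062, tolerance = 1e-9)
})

test_that("interface atoms: empty when apart, exact by brute force", {
  # non-contacting chains
  far <- mk_two_chain(mk_slab_xyz(3, 3, 2),
                      shift_xyz(mk_slab_xyz(3, 3, 2), dz = 60))
  expect_equal(nrow(interface_atoms(far, sphere_points = 120)), 0)
  # toy dimer: brute-force per-atom SA difference scan gives the same set
  toy <- make_toy_complex(toy_complex_spec(seed = 4))
  ia <- interface_atoms(toy$model, sphere_points = 240)
  comp <- compute_sasa(toy$model, sphere_points = 240, level = "atom")
  ab <- abdocktools:::.side_model(toy$model, "antibody")
  ag <- abdocktools:::.side_model(toy$model, "antigen")
  unc <- rbind(compute_sasa(ab, sphere_points = 240, level = "atom"),
               compute_sasa(ag, sphere_points = 240, level = "atom"))
  key <- function(d) paste(d$chain_id, d$residue_number, d$atom_name)
  buried <- key(comp)[unc$sa[match(key(comp), key(unc))] - comp$sa > 1e-6]
  expect_setequal(key(ia), buried)
  expect_gt(nrow(ia), 0)
  # the engineered contact CBs are buried on complexation
  expect_true(any(ia$atom_name == "CB"))
})

test_that("global density: disk oracle, scaling law, rigid invariance", {
  # Monte-Carlo uniform filled disk: covariance eigenvalues R^2/4 ->
  # equivalent-ellipsoid semi-axes sqrt(5)R/2, GD -> N / (pi R^2 5/4)
  set.seed(9)
  N <- 4000; R <- 10
  r <- R * sqrt(runif(N)); th <- runif(N, 0, 2 * pi)
  disk <- cbind(r * cos(th), r * sin(th), 0)
  expect_equal(global_density(disk), N / (pi * R^2 * 5 / 4),
               tolerance = 0.15)
  # scaling: coordinates x2 -> density / 4 (exact)
  any_cfg <- matrix(rnorm(60), 20, 3)
  expect_equal(global_density(any_cfg * 2), global_density(any_cfg) / 4,
               tolerance = 1e-9)
  # rigid invariance
  rot <- shift_xyz(rotate_xyz(any_cfg, c(2, 1, 1), 63), 5, -2, 8)
  expect_equal(global_density(rot), global_density(any_cfg),
               tolerance = 1e-9)
  expect_error(global_density(cbind(1:5, 0, 0)), "collinear")
  expect_error(global_density(disk[1:2, ]), "at least 3")
  # volume convention: planar sets have no ellipsoid volume
  expect_error(global_density(disk, mode = "volume"), "volume")
  expect_gt(global_density(matrix(rnorm(300), 100, 3), mode = "volume"), 0)
})

test_that("surface complementarity orders geometric fits correctly", {
  A <- mk_slab_xyz(11, 11, 1.2)
  B <- shift_xyz(mk_slab_xyz(6, 6, 1.2), dz = 3.5)
  par <- surface_complementarity(mk_two_chain(A, B), sphere_points = 480)
  expect_gt(par, 0.8)  # ideal-complementarity limit
  expect_lte(par, 1)
  # rotate the upper slab so the facing normals become orthogonal
  Brot <- shift_xyz(rotate_xyz(mk_slab_xyz(6, 6, 1.2), c(1, 0, 0), 90),
                    dz = 3.5 + 3)
  orth <- surface_complementarity(mk_two_chain(A, Brot),
                                  sphere_points = 480)
  expect_lt(orth, par)
  # nested sphere-in-shell beats sphere-on-flat-slab
  sph <- function(n, R0) abdocktools:::.sphere_points(n) * R0
  nested <- surface_complementarity(mk_two_chain(sph(80, 6.8),
                                                 sph(40, 3)),
                                    sphere_points = 240)
  ball <- surface_complementarity(
    mk_two_chain(mk_slab_xyz(9, 9, 2),
                 shift_xyz(sph(40, 3), dz = 6.4)), sphere_points = 240)
  expect_gt(nested, ball)
  expect_error(surface_complementarity(
    mk_two_chain(mk_slab_xyz(3, 3, 2),
                 shift_xyz(mk_slab_xyz(3, 3, 2), dz = 60)),
    sphere_points = 120), "geometry error")
})

test_that("interface panel is rigid-invariant and internally consistent", {
  toy <- make_toy_complex(toy_complex_spec(seed = 12))
  p <- interface_property_panel(toy$model, sphere_points = 240,
                                sc_sphere_points = 120)
  expect_equal(p$sa_support + p$sa_rim + p$sa_core, p$sa_total,
               tolerance = 1e-9)
  expect_equal(p$stickiness_support + p$stickiness_rim +
                 p$stickiness_core, p$stickiness_interface,
               tolerance = 1e-9)
  # GD invariance under a rigid transform of the whole complex
  moved <- transform_model(toy$model, axis = c(0, 1, 1), deg = 40,
                           dx = 7, dy = 7, dz = -3)
  ia0 <- interface_atoms(toy$model, sphere_points = 240)
  ia1 <- interface_atoms(moved, sphere_points = 240)
  expect_setequal(paste(ia0$chain_id, ia0$residue_number, ia0$atom_name),
                  paste(ia1$chain_id, ia1$residue_number, ia1$atom_name))
  expect_equal(global_density(ia1), global_density(ia0), tolerance = 1e-9)
  # flat export carries every descriptor
  out <- withr::local_tempfile(fileext = ".tsv")
  write_panel(p, out, "toy")
  back <- read.delim(out)
  expect_equal(back$global_density, p$global_density, tolerance = 1e-9)
})
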