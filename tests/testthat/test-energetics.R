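# Energy kernels: closed forms, oracle equivalence, invariances.

test_that("LJ pair energy reproduces its closed-form landmarks", {
  eps_i <- 0.21; eps_j <- 0.11; ri <- 1.7; rj <- 1.9
  eps_ij <- sqrt(eps_i * eps_j); rmin <- ri + rj
  expect_equal(lj_pair_energy(rmin, eps_i, eps_j, ri, rj), -eps_ij,
               tolerance = 1e-12)
  expect_equal(lj_pair_energy(rmin / 2^(1 / 6), eps_i, eps_j, ri, rj), 0,
               tolerance = 1e-12)
  expect_lt(abs(lj_pair_energy(5 * rmin, eps_i, eps_j, ri, rj)),
            1e-3 * eps_ij)
  expect_error(lj_pair_energy(0.05, eps_i, eps_j, ri, rj), "0.1")
})

test_that("Coulomb pair energy scales with charge, distance and dielectric", {
  expect_equal(coulomb_pair_energy(3.32, 1, 1, 1), 332.0637 / 3.32,
               tolerance = 1e-12)
  expect_equal(coulomb_pair_energy(2.5, 0, 0.4, 1), 0)
  e1 <- coulomb_pair_energy(4.1, 0.3, -0.2, 1)
  expect_equal(coulomb_pair_energy(4.1, 0.3, -0.2, 2), e1 / 2,
               tolerance = 1e-12)
  expect_equal(coulomb_pair_energy(4.1, 0.3, -0.2, 10), e1 / 10,
               tolerance = 1e-12)
})

one_atom_top <- function(q = 1, gb_radius = 1.5, screen = 0.8) {
  topology(tibble::tibble(
    serial = 1L, name = "X", element = "C", residue_index = 0L,
    residue_name = "UNK", chain_id = "A", resno = 1L, charge = q,
    lj_epsilon = 0.1, lj_rmin_half = 1.7, gb_radius = gb_radius,
    gb_screen = screen))
}

test_that("an isolated atom's effective radius is its offset-corrected intrinsic radius", {
  top <- one_atom_top(gb_radius = 1.5)
  expect_equal(effective_born_radii(top, matrix(0, 1, 3)), 1.5 - 0.09,
               tolerance = 1e-12)
})

test_that("descreening shrinks with separation: radii approach the isolated value monotonically", {
  rp <- random_pair_topology(1, 1, sep = 3, seed = 3)
  top <- rp$topology
  seps <- c(3, 4, 6, 9, 14, 25)
  radii <- sapply(seps, function(s) {
    xyz <- rbind(c(0, 0, 0), c(0, 0, s))
    effective_born_radii(top, xyz)[1]
  })
  # descreening inflates the radius; it relaxes monotonically from above
  # toward the isolated (offset-corrected intrinsic) value
  expect_true(all(diff(radii) < 0))
  expect_true(all(radii > top$atoms$gb_radius[1] - 0.09))
  expect_lt(abs(radii[length(seps)] - (top$atoms$gb_radius[1] - 0.09)), 0.01)
})

test_that("pairwise descreening matches direct quadrature of the 1/r^4 integral", {
  # non-overlapping geometry: the analytic descreening term is exact there
  rho_i <- 1.5 - 0.09
  for (case in list(c(r = 4.0, a = 1.2), c(r = 3.2, a = 1.0),
                    c(r = 5.5, a = 1.4))) {
    r <- case[["r"]]; a <- case[["a"]]
    L <- r - a; U <- r + a
    analytic <- 0.5 * (1 / L - 1 / U +
                         0.25 * (r - a^2 / r) * (1 / U^2 - 1 / L^2) +
                         0.5 * log(L / U) / r)
    numeric <- oracle_descreen_integral(r, a, rho = rho_i)
    expect_equal(analytic, numeric, tolerance = 1e-4)
  }
  # and the full OBC radii agree with the scalar-loop oracle on a 3-atom toy
  rp <- random_pair_topology(2, 1, sep = 4, seed = 11)
  expect_equal(effective_born_radii(rp$topology, rp$xyz),
               oracle_born_radii(rp$topology, rp$xyz), tolerance = 1e-10)
})

test_that("GB energy reduces to the Born formula for a single ion", {
  for (q in c(1, -0.5)) for (R0 in c(1.2, 2.0)) {
    top <- one_atom_top(q = q, gb_radius = R0 + 0.09)
    # isolated atom: effective radius is exactly R0
    expect_equal(gb_polar_energy(top, matrix(0, 1, 3)),
                 -166.03 * q^2 / R0 * (1 - 1 / 78.5), tolerance = 1e-6)
  }
})

test_that("GB energy matches the hand-computable two-sphere Still value", {
  rp <- random_pair_topology(1, 1, sep = 4, seed = 7)
  top <- rp$topology
  xyz <- rbind(c(0, 0, 0), c(0, 0, 4))
  R <- effective_born_radii(top, xyz)
  q <- top$atoms$charge
  fgb <- sqrt(16 + R[1] * R[2] * exp(-16 / (4 * R[1] * R[2])))
  hand <- -166.03 * (1 - 1 / 78.5) *
    (q[1]^2 / R[1] + q[2]^2 / R[2] + 2 * q[1] * q[2] / fgb)
  expect_equal(gb_polar_energy(top, xyz), hand, tolerance = 1e-10)
  # all charges zero -> 0
  top0 <- top; top0$atoms$charge <- c(0, 0)
  expect_equal(gb_polar_energy(top0, xyz), 0)
})

test_that("same-sign pair GB energy decays smoothly in magnitude with separation", {
  rp <- random_pair_topology(1, 1, sep = 3, seed = 9)
  top <- rp$topology
  top$atoms$charge <- c(0.5, 0.5)
  seps <- seq(2.5, 12, by = 0.05)
  e <- sapply(seps, function(s)
    gb_polar_energy(top, rbind(c(0, 0, 0), c(0, 0, s))))
  expect_true(all(abs(diff(abs(e))) < 1))     # no jumps on a fine grid
  expect_true(all(diff(abs(e)) < 1e-12))      # magnitude strictly decreasing
})

test_that("SASA matches the isolated-sphere closed form and is additive at large separation", {
  top <- one_atom_top()
  r <- top$atoms$lj_rmin_half
  area <- sasa_atomic(top, matrix(0, 1, 3))
  expect_equal(area, 4 * pi * (r + 1.4)^2, tolerance = 0.01)
  # two far atoms: sum of isolated values
  rp <- random_pair_topology(1, 1, sep = 50, seed = 2)
  xyz <- rbind(c(0, 0, 0), c(0, 0, 50))
  areas <- sasa_atomic(rp$topology, xyz)
  iso <- 4 * pi * (rp$topology$atoms$lj_rmin_half + 1.4)^2
  expect_equal(areas, iso, tolerance = 1e-9)
  # a fully buried atom has zero accessible area
  shell <- tibble::tibble(
    serial = 1:9, name = paste0("X", 1:9), element = "C",
    residue_index = 0:8, residue_name = "UNK", chain_id = "A", resno = 1:9,
    charge = 0, lj_epsilon = 0.1,
    lj_rmin_half = c(1.0, rep(3.5, 8)), gb_radius = 1.5, gb_screen = 0.8)
  corners <- as.matrix(expand.grid(c(-1.3, 1.3), c(-1.3, 1.3), c(-1.3, 1.3)))
  buried <- sasa_atomic(topology(shell), rbind(c(0, 0, 0), corners))
  expect_equal(buried[1], 0)
})

test_that("vectorized pair sums match the O(N^2) double-loop oracle and are rigid-motion invariant", {
  rp <- random_pair_topology(28, 14, sep = 6, seed = 21)
  top <- rp$topology
  rec <- which(top$atoms$side == "receptor")
  lig <- which(top$atoms$side == "ligand")
  fast <- alascan:::gas_cross_energy(top, rp$xyz, rec, lig, dielectric = 3)
  slow <- oracle_gas_cross(top, rp$xyz, rec, lig, dielectric = 3)
  expect_equal(unname(fast["vdw"]), unname(slow["vdw"]), tolerance = 1e-10)
  expect_equal(unname(fast["ele"]), unname(slow["ele"]), tolerance = 1e-10)
  # rigid motion leaves every component invariant
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  moved <- rp$xyz %*% R + matrix(c(11, -4, 7), nrow(rp$xyz), 3, byrow = TRUE)
  fast2 <- alascan:::gas_cross_energy(top, moved, rec, lig, dielectric = 3)
  expect_equal(fast2, fast, tolerance = 1e-9)
  expect_equal(gb_polar_energy(top, moved), gb_polar_energy(top, rp$xyz),
               tolerance = 1e-9)
  # SASA: exact under translation (points ride with the atoms), invariant
  # only to point-set discretization under rotation
  shifted <- rp$xyz + matrix(c(11, -4, 7), nrow(rp$xyz), 3, byrow = TRUE)
  expect_equal(sum(sasa_atomic(top, shifted)), sum(sasa_atomic(top, rp$xyz)),
               tolerance = 1e-9)
  expect_equal(sum(sasa_atomic(top, moved)), sum(sasa_atomic(top, rp$xyz)),
               tolerance = 0.01)
})

ddg_fixture <- function(seed, ligand = c("VAL", "THR", "PHE"), n_frames = 2) {
  spec <- toy_complex_spec(receptor = c("LEU", "SER"), ligand = ligand,
                           contacts = tibble::tibble(
                             receptor_pos = 1:2, ligand_pos = 1:2,
                             well_depth = c(2.5, 1.5)),
                           seed = seed)
  cx <- build_toy_complex(spec)
  ens <- perturbation_ensemble(cx$topology, cx$frame, n_frames = n_frames,
                               amplitude = 0.07, seed = seed)
  list(cx = cx, ens = ens, params = toy_parameter_table())
}

test_that("component differences equal the naive four-end-state oracle", {
  s <- ddg_fixture(seed = 31)
  top <- s$cx$topology
  lig_idx <- top$residues$residue_index[top$residues$side == "ligand"]
  v <- truncate_to_alanine(top, s$ens, lig_idx[1], s$params)
  dd <- residue_ddG_components(top, s$ens, v, sasa_points = 240)
  for (k in seq_along(dd$frames)) {
    f <- dd$frames[k]
    o <- oracle_ddg_frame(top, frame_coords(s$ens, f), v, f,
                          dielectric = dd$dielectric, sasa_points = 240)
    expect_equal(dd$per_frame$dd_e_vdw[k], unname(o["e_vdw"]), tolerance = 1e-9)
    expect_equal(dd$per_frame$dd_e_ele[k], unname(o["e_ele"]), tolerance = 1e-9)
    expect_equal(dd$per_frame$dd_g_polar[k], unname(o["g_polar"]), tolerance = 1e-9)
    expect_equal(dd$per_frame$dd_g_nonpolar[k], unname(o["g_nonpolar"]), tolerance = 1e-9)
  }
})

test_that("zeroing ligand charges kills the electrostatic difference but not the vdW one", {
  s <- ddg_fixture(seed = 33)
  top <- s$cx$topology
  lig_idx <- top$residues$residue_index[top$residues$side == "ligand"]
  v <- truncate_to_alanine(top, s$ens, lig_idx[1], s$params)
  dd <- residue_ddG_components(top, s$ens, v, components = c("vdw", "ele"))
  topz <- top
  lig_atoms <- which(top$atoms$side == "ligand")
  topz$atoms$charge[lig_atoms] <- 0
  vz <- truncate_to_alanine(topz, s$ens, lig_idx[1], s$params)
  vz$topology$atoms$charge[which(vz$topology$atoms$side == "ligand")] <- 0
  ddz <- residue_ddG_components(topz, s$ens, vz, components = c("vdw", "ele"))
  expect_equal(unname(ddz$mean["dd_e_ele"]), 0, tolerance = 1e-12)
  expect_equal(unname(ddz$mean["dd_e_vdw"]), unname(dd$mean["dd_e_vdw"]),
               tolerance = 1e-9)
})

test_that("the electrostatic difference scales exactly as 1/dielectric", {
  s <- ddg_fixture(seed = 35)
  top <- s$cx$topology
  lig_idx <- top$residues$residue_index[top$residues$side == "ligand"]
  v <- truncate_to_alanine(top, s$ens, lig_idx[1], s$params)
  e1 <- residue_ddG_components(top, s$ens, v, dielectric = 1,
                               components = c("vdw", "ele"))
  e3 <- residue_ddG_components(top, s$ens, v, dielectric = 3,
                               components = c("vdw", "ele"))
  e10 <- residue_ddG_components(top, s$ens, v, dielectric = 10,
                                components = c("vdw", "ele"))
  expect_equal(unname(e3$mean["dd_e_ele"]), unname(e1$mean["dd_e_ele"]) / 3,
               tolerance = 1e-9)
  expect_equal(unname(e10$mean["dd_e_ele"]), unname(e1$mean["dd_e_ele"]) / 10,
               tolerance = 1e-9)
  expect_equal(unname(e10$mean["dd_e_vdw"]), unname(e1$mean["dd_e_vdw"]),
               tolerance = 1e-12)
})

test_that("the atom-pair vdW map conserves the total and ranks the designed contact first", {
  s <- ddg_fixture(seed = 37)
  top <- s$cx$topology
  rec_res <- top$residues$residue_index[top$residues$side == "receptor"]
  lig_res <- top$residues$residue_index[top$residues$side == "ligand"]
  m <- atom_pair_vdw_map(top, s$ens, rec_res, lig_res)
  rec <- which(top$atoms$side == "receptor")
  lig <- which(top$atoms$side == "ligand")
  direct <- mean(sapply(seq_len(n_frames(s$ens)), function(f)
    oracle_gas_cross(top, frame_coords(s$ens, f), rec, lig)["vdw"]))
  expect_equal(m$total, direct, tolerance = 1e-9)
  expect_equal(sum(m$pairs$energy), m$total, tolerance = 1e-9)
  # strongest designed contact (well depth 2.5 between tips) ranks first
  best <- m$pairs[1, ]
  expect_equal(best$atom_a, s$cx$contact_atoms$receptor_atom[1])
  expect_equal(best$atom_b, s$cx$contact_atoms$ligand_atom[1])
  expect_lt(best$energy, -2)
  # disjointness is enforced
  expect_error(atom_pair_vdw_map(top, s$ens, rec_res, rec_res), "disjoint")
})

test_that("far-separated selections have vanishing pair energies", {
  rp <- random_pair_topology(6, 6, sep = 40, seed = 41)
  ens <- ensemble(rp$xyz)
  m <- atom_pair_vdw_map(rp$topology, ens,
                         unique(rp$topology$atoms$residue_index[1:6]),
                         unique(rp$topology$atoms$residue_index[7:12]))
  expect_lt(max(abs(m$pairs$energy)), 1e-3)
})

test_that("the whole-interface enthalpy equals the summed end-state components", {
  s <- ddg_fixture(seed = 39)
  top <- s$cx$topology
  res <- mmgbsa_enthalpy(top, s$ens, sasa_points = 240)
  for (k in seq_len(nrow(res$per_frame))) {
    f <- res$per_frame$frame[k]
    b <- alascan:::bind_components(top, frame_coords(s$ens, f), 1,
                                   sasa_points = 240)
    expect_equal(res$per_frame$e_vdw[k], unname(b["e_vdw"]), tolerance = 1e-12)
    expect_equal(res$per_frame$g_polar[k], unname(b["g_polar"]), tolerance = 1e-12)
  }
  expect_equal(res$dh, sum(res$components), tolerance = 1e-12)
  # binding is favorable for the designed complex
  expect_lt(res$components[["e_vdw"]], 0)
})

hb_topology <- function() {
  topology(tibble::tibble(
    serial = 1:3, name = c("N", "H", "O"), element = c("N", "H", "O"),
    residue_index = c(0L, 0L, 1L), residue_name = c("UNK", "UNK", "UNK"),
    chain_id = c("A", "A", "B"), resno = c(1L, 1L, 1L),
    charge = 0, lj_epsilon = 0.1, lj_rmin_half = 1.5,
    gb_radius = 1.5, gb_screen = 0.8))
}

test_that("hydrogen-bond occupancy counts satisfying frames", {
  top <- hb_topology()
  ideal <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))
  broken <- rbind(c(0, 0, 0), c(1, 0, 0), c(8, 0, 0))
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  # static ideal geometry: occupancy 1
  occ1 <- hydrogen_bond_occupancy(top, ensemble(ideal), donors, 3L)
  expect_equal(occ1$occupancy, 1)
  # all frames beyond the cutoff: occupancy 0
  occ0 <- hydrogen_bond_occupancy(top, ensemble(broken), donors, 3L)
  expect_equal(occ0$occupancy, 0)
  # k of n frames satisfying -> k/n
  k <- 3; n <- 5
  coords <- array(NA_real_, dim = c(n, 3, 3))
  for (f in 1:n) coords[f, , ] <- if (f <= k) ideal else broken
  occ <- hydrogen_bond_occupancy(top, ensemble(coords), donors, 3L)
  expect_equal(occ$occupancy, k / n)
  # bent geometry below the angle cutoff does not count
  bent <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.0, 2.6, 0))
  occb <- hydrogen_bond_occupancy(top, ensemble(bent), donors, 3L)
  expect_equal(occb$occupancy, 0)
  # no hydrogens: error suggests distance-only mode, which then works
  expect_error(
    hydrogen_bond_occupancy(top, ensemble(ideal),
                            data.frame(donor = 1L, hydrogen = NA), 3L),
    "distance-only")
  occd <- hydrogen_bond_occupancy(top, ensemble(ideal),
                                  data.frame(donor = 1L, hydrogen = NA), 3L,
                                  angle_cut = NULL)
  expect_equal(occd$occupancy, 1)
})
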