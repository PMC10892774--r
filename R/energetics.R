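# Molecular-mechanics and implicit-solvation energy kernels.
#
# Units throughout: kcal/mol, Angstrom, elementary charges. All pair sums are
# evaluated without distance cutoffs: the truncated end-state systems are
# small and determinism is preferred over speed.

#' Lennard-Jones pair energy
#'
#' `eps_ij * ((rmin_ij/r)^12 - 2 (rmin_ij/r)^6)` with Lorentz-Berthelot
#' combination `eps_ij = sqrt(eps_i eps_j)`, `rmin_ij = rmin_half_i +
#' rmin_half_j`. Vectorized over all arguments.
#'
#' @param r Distance(s), Angstrom; values below 0.1 A are an error (a clash
#'   at that range indicates broken input).
#' @param eps_i,eps_j Well depths, kcal/mol.
#' @param rmin_half_i,rmin_half_j Half minimum-energy distances, Angstrom.
#' @return Energy in kcal/mol.
#' @export
lj_pair_energy <- function(r, eps_i, eps_j, rmin_half_i, rmin_half_j) {
  if (any(r < 0.1)) abort("interatomic distance below 0.1 A: broken input")
  eps <- sqrt(eps_i * eps_j)
  s6 <- ((rmin_half_i + rmin_half_j) / r)^6
  eps * (s6^2 - 2 * s6)
}

#' Coulomb pair energy with a uniform dielectric
#'
#' `332.0637 q_i q_j / (dielectric r)`. The dielectric is the interior
#' dielectric of the mutated residue's class (1, 3 or 10) during a scan.
#'
#' @param r Distance(s), Angstrom (values below 0.1 A are an error).
#' @param q_i,q_j Partial charges, e.
#' @param dielectric Relative dielectric constant.
#' @return Energy in kcal/mol.
#' @export
coulomb_pair_energy <- function(r, q_i, q_j, dielectric = 1) {
  if (any(r < 0.1)) abort("interatomic distance below 0.1 A: broken input")
  .kcoul * q_i * q_j / (dielectric * r)
}

# Cross-set LJ + Coulomb sums for one frame. a_idx/b_idx are atom rows.
gas_cross_energy <- function(top, xyz, a_idx, b_idx, dielectric = 1,
                             components = c("vdw", "ele")) {
  at <- top$atoms
  d <- sqrt(pmax(cross_dist2(xyz[a_idx, , drop = FALSE],
                             xyz[b_idx, , drop = FALSE]), 0))
  out <- c(vdw = 0, ele = 0)
  if ("vdw" %in% components) {
    eps <- sqrt(outer(at$lj_epsilon[a_idx], at$lj_epsilon[b_idx]))
    rmin <- outer(at$lj_rmin_half[a_idx], at$lj_rmin_half[b_idx], "+")
    if (any(d < 0.1)) abort("interatomic distance below 0.1 A: broken input")
    s6 <- (rmin / d)^6
    out["vdw"] <- sum(eps * (s6^2 - 2 * s6))
  }
  if ("ele" %in% components) {
    qq <- outer(at$charge[a_idx], at$charge[b_idx])
    out["ele"] <- .kcoul * sum(qq / d) / dielectric
  }
  out
}

# Effective Born radii ---------------------------------------------------------

#' Effective Born radii (OBC-style)
#'
#' Pairwise Hawkins-Cramer-Truhlar descreening integrals with per-atom
#' screening factors, rescaled through the OBC tanh form with coefficients
#' alpha = 1.0, beta = 0.8, gamma = 4.85. Intrinsic radii are offset by
#' 0.09 A; an isolated atom returns its offset-corrected intrinsic radius.
#' Non-positive computed radii are clamped to 0.1 A with a warning.
#'
#' @param top A parameterized [topology()] (or any object with an `atoms`
#'   table carrying `gb_radius` and `gb_screen`).
#' @param xyz An `atoms x 3` coordinate matrix for one frame.
#' @return Numeric vector of effective radii, Angstrom.
#' @export
effective_born_radii <- function(top, xyz) {
  at <- top$atoms
  n <- nrow(at)
  if (anyNA(at$gb_radius) || anyNA(at$gb_screen)) {
    abort("gb_radius/gb_screen must be set for all atoms")
  }
  rho <- at$gb_radius - .gb_offset
  sr <- at$gb_screen * rho
  if (n == 1) {
    return(rho)
  }
  d <- sqrt(pmax(cross_dist2(xyz, xyz), 0))
  # integral of 1/r^4 over the screened sphere of atom j as seen by atom i
  RHO <- matrix(rho, n, n)          # rho_i by row
  SR <- matrix(sr, n, n, byrow = TRUE)  # s_j rho_j by column index j
  U <- d + SR
  L <- pmax(RHO, abs(d - SR))
  with_diag0 <- function(m) { diag(m) <- 0; m }
  active <- (RHO < U) & (diag(n) == 0)
  I <- matrix(0, n, n)
  if (any(active)) {
    Li <- L[active]; Ui <- U[active]; ri <- d[active]; sri <- SR[active]
    I[active] <- 0.5 * (1 / Li - 1 / Ui +
                          0.25 * (ri - sri^2 / ri) * (1 / Ui^2 - 1 / Li^2) +
                          0.5 * log(Li / Ui) / ri)
    # atom i buried inside atom j's screened sphere
    inside <- active & (RHO < (SR - d))
    if (any(inside)) {
      I[inside] <- I[inside] + (1 / RHO[inside] - 1 / L[inside])
    }
  }
  I <- with_diag0(I)
  psi <- rho * rowSums(I)
  tanh_term <- tanh(.obc_alpha * psi - .obc_beta * psi^2 + .obc_gamma * psi^3)
  inv_r <- 1 / rho - tanh_term / at$gb_radius
  r_eff <- 1 / inv_r
  bad <- !is.finite(r_eff) | r_eff <= 0
  if (any(bad)) {
    warn(sprintf("%d non-positive effective Born radii clamped to 0.1 A",
                 sum(bad)))
    r_eff[bad] <- 0.1
  }
  r_eff
}

# Exact descreening integral of a single non-overlapping sphere, used as a
# reference in documentation examples; tests integrate numerically instead.
# (kept internal)

#' Generalized Born polar solvation energy (Still pairwise form)
#'
#' `-166.03 (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` over all ordered
#' pairs including self terms, with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 /
#' (4 R_i R_j)))` and `f_GB = R_i` for `i = j`. For a single ion this is the
#' Born formula `-166.03 q^2 / R (1/eps_in - 1/eps_out)`.
#'
#' @param top A parameterized [topology()].
#' @param xyz An `atoms x 3` coordinate matrix.
#' @param solute_dielectric Interior dielectric (per mutated-residue class
#'   during a scan; default 1).
#' @param solvent_dielectric Exterior dielectric (default 78.5).
#' @param born_radii Optional precomputed effective radii.
#' @return Energy in kcal/mol.
#' @export
gb_polar_energy <- function(top, xyz, solute_dielectric = 1,
                            solvent_dielectric = .eps_solvent,
                            born_radii = NULL) {
  q <- top$atoms$charge
  if (anyNA(q)) abort("charges must be set for all atoms")
  if (all(q == 0)) return(0)
  R <- born_radii %||% effective_born_radii(top, xyz)
  n <- length(q)
  if (n == 1) {
    fgb <- matrix(R, 1, 1)
  } else {
    d2 <- pmax(cross_dist2(xyz, xyz), 0)
    RR <- outer(R, R)
    fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
    diag(fgb) <- R
  }
  -.kgb * (1 / solute_dielectric - 1 / solvent_dielectric) *
    sum(outer(q, q) / fgb)
}

# Solvent-accessible surface area ----------------------------------------------

# Deterministic Fibonacci sphere point set (unit vectors), fixed count.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley style: each atom's sphere of radius `radius + probe` is
#' sampled on a fixed deterministic point set; a point is accessible when it
#' lies outside every neighbour's probe-expanded sphere.
#'
#' @param top A parameterized [topology()].
#' @param xyz An `atoms x 3` coordinate matrix.
#' @param radii Per-atom radii in Angstrom; defaults to `lj_rmin_half`.
#' @param probe Probe radius (default 1.4 A).
#' @param n_points Points per sphere (default 960).
#' @return Numeric vector of atomic SASA values, Angstrom^2.
#' @export
sasa_atomic <- function(top, xyz, radii = NULL, probe = .sasa_probe,
                        n_points = 960) {
  radii <- radii %||% top$atoms$lj_rmin_half
  if (anyNA(radii)) abort("atomic radii must be set")
  n <- length(radii)
  pts <- fibonacci_sphere(n_points)
  rext <- radii + probe
  out <- numeric(n)
  if (n > 1) d2 <- cross_dist2(xyz, xyz)
  for (i in seq_len(n)) {
    sphere <- pts * rext[i]
    sphere <- sweep(sphere, 2, xyz[i, ], "+")
    if (n > 1) {
      nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    } else nb <- integer(0)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sphere[, 1] - xyz[j, 1])^2 + (sphere[, 2] - xyz[j, 2])^2 +
        (sphere[, 3] - xyz[j, 3])^2
      acc <- acc & (dj2 > rext[j]^2)
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * rext[i]^2
  }
  out
}

#' Nonpolar solvation energy from surface area
#'
#' `gamma * SASA + beta` with documented defaults gamma = 0.00542
#' kcal/(mol A^2), beta = 0.92 kcal/mol.
#'
#' @inheritParams sasa_atomic
#' @param gamma Surface tension coefficient, kcal/(mol A^2).
#' @param beta Constant offset, kcal/mol.
#' @return A list with `energy` (kcal/mol), `sasa` (total, A^2) and
#'   `atom_area`.
#' @export
sasa_nonpolar <- function(top, xyz, gamma = .sasa_gamma, beta = .sasa_beta,
                          probe = .sasa_probe, radii = NULL, n_points = 960) {
  area <- sasa_atomic(top, xyz, radii = radii, probe = probe,
                      n_points = n_points)
  list(energy = gamma * sum(area) + beta, sasa = sum(area), atom_area = area)
}

# Binding components of one view ----------------------------------------------

# Binding energy components (complex minus isolated receptor and ligand) for
# one topology+frame. Gas terms reduce exactly to cross-partition pair sums
# (pairwise additivity: intra-side and bonded terms cancel in the
# difference); solvation terms are full three-end-state differences.
bind_components <- function(top, xyz, dielectric = 1,
                            components = c("vdw", "ele", "gb", "sasa"),
                            solvent_dielectric = .eps_solvent,
                            gamma = .sasa_gamma, beta = .sasa_beta,
                            sasa_points = 960) {
  rec <- side_atoms(top, "receptor")
  lig <- side_atoms(top, "ligand")
  out <- c(e_vdw = 0, e_ele = 0, g_polar = 0, g_nonpolar = 0)
  gas <- intersect(components, c("vdw", "ele"))
  if (length(gas) > 0) {
    g <- gas_cross_energy(top, xyz, rec, lig, dielectric, gas)
    out["e_vdw"] <- g["vdw"]
    out["e_ele"] <- g["ele"]
  }
  if ("gb" %in% components) {
    top_r <- topology_subset(top, rec)
    top_l <- topology_subset(top, lig)
    out["g_polar"] <-
      gb_polar_energy(top, xyz, dielectric, solvent_dielectric) -
      gb_polar_energy(top_r, xyz[rec, , drop = FALSE], dielectric, solvent_dielectric) -
      gb_polar_energy(top_l, xyz[lig, , drop = FALSE], dielectric, solvent_dielectric)
  }
  if ("sasa" %in% components) {
    s_c <- sum(sasa_atomic(top, xyz, n_points = sasa_points))
    s_r <- sum(sasa_atomic(topology_subset(top, rec), xyz[rec, , drop = FALSE],
                           n_points = sasa_points))
    s_l <- sum(sasa_atomic(topology_subset(top, lig), xyz[lig, , drop = FALSE],
                           n_points = sasa_points))
    out["g_nonpolar"] <- gamma * (s_c - s_r - s_l) - beta
  }
  out
}

# frame subsample: m equally spaced indices from 1..nf
equally_spaced_frames <- function(nf, m) {
  if (m >= nf) return(seq_len(nf))
  unique(round(seq(1, nf, length.out = m)))
}

#' Per-residue binding free-energy component differences upon x -> Ala
#'
#' For each sampled frame, evaluates the binding-energy components of the
#' wild-type and alanine-mutant views (complex minus isolated receptor and
#' ligand) and returns the mutational difference, with the sign convention
#' that positive values mean the wild-type side chain contributes favorably
#' to binding (mutant binding energy minus wild-type binding energy). The
#' internal (bonded) term is omitted as identically zero: both views share
#' one trajectory, so it cancels exactly and is never evaluated.
#'
#' @param top Wild-type parameterized, partitioned [topology()].
#' @param ens Wild-type [ensemble()].
#' @param view A `mutant_view` from [truncate_to_alanine()].
#' @param dielectric Interior dielectric; defaults to the mutated residue's
#'   class dielectric.
#' @param frames Frame indices to use; default an equally spaced subsample of
#'   at most `max_frames`.
#' @param max_frames Default enthalpy subsample size (100).
#' @param components Which components to evaluate: subset of
#'   `c("vdw", "ele", "gb", "sasa")`.
#' @param solvent_dielectric Exterior dielectric (default 78.5).
#' @param sasa_points Sphere points for the surface-area term.
#' @return A list of class `ddg_components` with `per_frame` (tibble of
#'   per-frame differences), `mean` (named vector), `dielectric` and
#'   `frames`.
#' @export
residue_ddG_components <- function(top, ens, view, dielectric = NULL,
                                   frames = NULL, max_frames = 100,
                                   components = c("vdw", "ele", "gb", "sasa"),
                                   solvent_dielectric = .eps_solvent,
                                   sasa_points = 960) {
  check_compatible(top, ens)
  if (inherits(view, "mutant_skip")) {
    abort("cannot evaluate components for a skipped residue")
  }
  res_name <- top$residues$name[top$residues$residue_index == view$residue_index]
  dielectric <- dielectric %||% classify_residue(res_name)$dielectric
  frames <- frames %||% equally_spaced_frames(n_frames(ens), max_frames)
  if (length(frames) == 0) abort("zero usable frames")
  rows <- purrr::map(frames, function(f) {
    wt <- bind_components(top, frame_coords(ens, f), dielectric, components,
                          solvent_dielectric, sasa_points = sasa_points)
    mt <- if (view$identity) wt else
      bind_components(view$topology, frame_coords(view$ensemble, f),
                      dielectric, components, solvent_dielectric,
                      sasa_points = sasa_points)
    dd <- mt - wt
    tibble(frame = f,
           dd_e_vdw = dd[["e_vdw"]], dd_e_ele = dd[["e_ele"]],
           dd_g_polar = dd[["g_polar"]], dd_g_nonpolar = dd[["g_nonpolar"]])
  }) |> list_rbind()
  means <- colMeans(rows[, -1])
  structure(
    list(per_frame = rows,
         mean = c(means, dd_g_sol = unname(means["dd_g_polar"] +
                                             means["dd_g_nonpolar"])),
         dielectric = dielectric, frames = frames,
         components = components),
    class = "ddg_components")
}

#' @export
print.ddg_components <- function(x, ...) {
  cat("<ddg_components> ", length(x$frames), " frames, dielectric ",
      x$dielectric, "\n", sep = "")
  print(round(x$mean, 4))
  invisible(x)
}

#' Whole-interface MM/GBSA binding enthalpy
#'
#' The conventional end-state estimate without any alanine scanning: the
#' trajectory mean of the full binding-energy components (gas-phase van der
#' Waals and electrostatics plus GB polar and surface-area nonpolar
#' solvation) of the unmutated complex, `complex - receptor - ligand`.
#' Provided as the baseline the residue-wise decomposition is compared
#' against.
#'
#' @param top Parameterized, partitioned [topology()].
#' @param ens An [ensemble()].
#' @param dielectric Interior dielectric (default 1).
#' @param frames Frame indices; default an equally spaced subsample of at
#'   most `max_frames`.
#' @param max_frames Subsample size (default 100).
#' @param sasa_points Sphere points for the surface-area term.
#' @return A list with `dh` (kcal/mol), the per-frame tibble and the
#'   component means.
#' @export
mmgbsa_enthalpy <- function(top, ens, dielectric = 1, frames = NULL,
                            max_frames = 100, sasa_points = 960) {
  check_compatible(top, ens)
  frames <- frames %||% equally_spaced_frames(n_frames(ens), max_frames)
  rows <- purrr::map(frames, function(f) {
    b <- bind_components(top, frame_coords(ens, f), dielectric,
                         sasa_points = sasa_points)
    tibble(frame = f, e_vdw = b[["e_vdw"]], e_ele = b[["e_ele"]],
           g_polar = b[["g_polar"]], g_nonpolar = b[["g_nonpolar"]])
  }) |> list_rbind()
  means <- colMeans(rows[, -1])
  list(dh = sum(means), per_frame = rows, components = means)
}

# Atom-pair maps and hydrogen bonds --------------------------------------------

#' Trajectory-mean atom-pair van der Waals interaction map
#'
#' Mean LJ energy per atom pair between two disjoint residue selections,
#' ranked by energy, with a per-residue-pair aggregate and a side-chain vs
#' main-chain split (backbone atoms: N, H, CA, HA, C, O and terminal
#' variants).
#'
#' @param top A parameterized [topology()].
#' @param ens An [ensemble()].
#' @param residues_a,residues_b Disjoint 0-based residue index vectors.
#' @param frames Frame indices (default all).
#' @return A list with `pairs` (ranked atom-pair tibble), `residue_pairs`
#'   and `split` (side-chain/main-chain decomposition of the total).
#' @export
atom_pair_vdw_map <- function(top, ens, residues_a, residues_b, frames = NULL) {
  if (length(intersect(residues_a, residues_b)) > 0) {
    abort("residue selections must be disjoint")
  }
  check_compatible(top, ens)
  frames <- frames %||% seq_len(n_frames(ens))
  at <- top$atoms
  ia <- which(at$residue_index %in% residues_a)
  ib <- which(at$residue_index %in% residues_b)
  eps <- sqrt(outer(at$lj_epsilon[ia], at$lj_epsilon[ib]))
  rmin <- outer(at$lj_rmin_half[ia], at$lj_rmin_half[ib], "+")
  acc <- matrix(0, length(ia), length(ib))
  for (f in frames) {
    xyz <- frame_coords(ens, f)
    d <- sqrt(pmax(cross_dist2(xyz[ia, , drop = FALSE],
                               xyz[ib, , drop = FALSE]), 0))
    if (any(d < 0.1)) abort("interatomic distance below 0.1 A: broken input")
    s6 <- (rmin / d)^6
    acc <- acc + eps * (s6^2 - 2 * s6)
  }
  acc <- acc / length(frames)
  backbone <- c("N", "H", "H1", "H2", "H3", "CA", "HA", "HA2", "HA3", "C",
                "O", "OXT")
  pairs <- tibble(
    atom_a = rep(ia, times = length(ib)),
    atom_b = rep(ib, each = length(ia)),
    energy = as.vector(acc)
  ) |>
    mutate(
      name_a = at$name[.data$atom_a], name_b = at$name[.data$atom_b],
      residue_a = at$residue_index[.data$atom_a],
      residue_b = at$residue_index[.data$atom_b],
      sidechain_a = !(.data$name_a %in% backbone),
      sidechain_b = !(.data$name_b %in% backbone)
    ) |>
    arrange(.data$energy)
  residue_pairs <- pairs |>
    group_by(residue_a = .data$residue_a, residue_b = .data$residue_b) |>
    summarise(energy = sum(.data$energy), .groups = "drop") |>
    arrange(.data$energy)
  split <- pairs |>
    group_by(sidechain = .data$sidechain_a | .data$sidechain_b) |>
    summarise(energy = sum(.data$energy), .groups = "drop")
  list(pairs = pairs, residue_pairs = residue_pairs, split = split,
       total = sum(acc))
}

#' Hydrogen-bond occupancy over an ensemble
#'
#' Fraction of frames in which a donor-hydrogen...acceptor pair satisfies a
#' donor-acceptor distance cutoff and a donor-H-acceptor angle cutoff.
#' Donors are given as (donor heavy atom, hydrogen) pairs; with no hydrogens
#' available, an error suggests the distance-only fallback
#' (`angle_cut = NULL`).
#'
#' @param top A [topology()].
#' @param ens An [ensemble()].
#' @param donors Integer matrix or data frame with columns `donor` and
#'   `hydrogen` (atom rows); `hydrogen` may be `NA` only in distance-only
#'   mode.
#' @param acceptors Integer vector of acceptor atom rows.
#' @param d_cut Donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut Minimum donor-H-acceptor angle in degrees (default 135);
#'   `NULL` for distance-only mode.
#' @return A tibble with one row per donor/acceptor pair and its `occupancy`.
#' @export
hydrogen_bond_occupancy <- function(top, ens, donors, acceptors,
                                    d_cut = 3.5, angle_cut = 135) {
  check_compatible(top, ens)
  donors <- as_tibble(as.data.frame(donors))
  if (!all(c("donor", "hydrogen") %in% names(donors))) {
    abort("donors needs columns 'donor' and 'hydrogen'")
  }
  if (!is.null(angle_cut) && anyNA(donors$hydrogen)) {
    abort(paste0("no hydrogens for some donors; either supply them or use ",
                 "distance-only mode (angle_cut = NULL)"))
  }
  nf <- n_frames(ens)
  grid <- tidyr::expand_grid(di = seq_len(nrow(donors)),
                             acceptor = acceptors)
  hits <- matrix(0, nrow(grid), 1)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    for (k in seq_len(nrow(grid))) {
      d_atom <- donors$donor[grid$di[k]]
      h_atom <- donors$hydrogen[grid$di[k]]
      a_atom <- grid$acceptor[k]
      dda <- sqrt(sum((xyz[d_atom, ] - xyz[a_atom, ])^2))
      ok <- dda <= d_cut
      if (ok && !is.null(angle_cut)) {
        v1 <- xyz[d_atom, ] - xyz[h_atom, ]
        v2 <- xyz[a_atom, ] - xyz[h_atom, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        ok <- ang >= angle_cut
      }
      hits[k] <- hits[k] + as.numeric(ok)
    }
  }
  grid |>
    mutate(donor = donors$donor[.data$di],
           hydrogen = donors$hydrogen[.data$di],
           occupancy = as.vector(hits) / nf) |>
    select("donor", "hydrogen", "acceptor", "occupancy")
}
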