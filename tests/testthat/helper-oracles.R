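# Independent brute-force oracles used across the suite. These are written
# as plain double loops / direct quadrature so they share no code path with
# the package's vectorized kernels.

ORACLE_KCOUL <- 332.0637
ORACLE_KGB <- 166.03
ORACLE_KB <- 0.0019872

# all-pairs LJ + Coulomb between two atom index sets (double loop)
oracle_gas_cross <- function(top, xyz, ia, ib, dielectric = 1) {
  at <- top$atoms
  vdw <- 0; ele <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    vdw <- vdw + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    ele <- ele + ORACLE_KCOUL * at$charge[i] * at$charge[j] / (dielectric * r)
  }
  c(vdw = vdw, ele = ele)
}

# total nonbonded gas energy of one state (every unordered pair)
oracle_gas_total <- function(top, xyz, dielectric = 1) {
  n <- nrow(top$atoms)
  idx <- seq_len(n)
  tot <- c(vdw = 0, ele = 0)
  for (i in idx) {
    if (i < n) {
      e <- oracle_gas_cross(top, xyz, i, (i + 1):n, dielectric)
      tot <- tot + e
    }
  }
  tot
}

# scalar-loop OBC radii (Hawkins-Cramer-Truhlar descreening, tanh rescale)
oracle_born_radii <- function(top, xyz, offset = 0.09,
                              alpha = 1.0, beta = 0.8, gamma = 4.85) {
  at <- top$atoms
  n <- nrow(at)
  rho <- at$gb_radius - offset
  out <- numeric(n)
  for (i in seq_len(n)) {
    I <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      sr <- at$gb_screen[j] * (at$gb_radius[j] - offset)
      if (rho[i] >= r + sr) next
      L <- max(rho[i], abs(r - sr))
      U <- r + sr
      term <- 0.5 * (1 / L - 1 / U +
                       0.25 * (r - sr^2 / r) * (1 / U^2 - 1 / L^2) +
                       0.5 * log(L / U) / r)
      if (rho[i] < sr - r) term <- term + (1 / rho[i] - 1 / L)
      I <- I + term
    }
    psi <- rho[i] * I
    out[i] <- 1 / (1 / rho[i] -
                     tanh(alpha * psi - beta * psi^2 + gamma * psi^3) /
                       at$gb_radius[i])
  }
  out
}

# direct 2D quadrature of the descreening integral of a sphere of radius a
# at center distance R from the probe atom, excluding the region inside the
# probe's own radius rho: (1/4pi) * int dV / r^4
oracle_descreen_integral <- function(R, a, rho, nr = 600, nt = 600) {
  rr <- seq(0, a, length.out = nr + 1); rr <- (rr[-1] + rr[-(nr + 1)]) / 2
  dr <- a / nr
  ct <- seq(-1, 1, length.out = nt + 1); ct <- (ct[-1] + ct[-(nt + 1)]) / 2
  dct <- 2 / nt
  total <- 0
  for (s in rr) {
    d2 <- R^2 + s^2 - 2 * R * s * ct   # squared distance to probe atom
    keep <- d2 > rho^2
    total <- total + sum(1 / d2[keep]^2) * s^2 * dr * dct
  }
  total * 2 * pi / (4 * pi)
}

# scalar-loop Still GB energy from given radii
oracle_gb_energy <- function(top, xyz, radii, eps_in = 1, eps_out = 78.5) {
  q <- top$atoms$charge
  n <- length(q)
  acc <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) {
      fgb <- radii[i]
    } else {
      r2 <- sum((xyz[i, ] - xyz[j, ])^2)
      rr <- radii[i] * radii[j]
      fgb <- sqrt(r2 + rr * exp(-r2 / (4 * rr)))
    }
    acc <- acc + q[i] * q[j] / fgb
  }
  -ORACLE_KGB * (1 / eps_in - 1 / eps_out) * acc
}

# independent Shrake-Rupley on the same deterministic point-set definition
oracle_sasa <- function(top, xyz, probe = 1.4, n_points = 960) {
  radii <- top$atoms$lj_rmin_half
  n <- length(radii)
  i_seq <- seq_len(n_points) - 0.5
  phi <- pi * (1 + sqrt(5)) * i_seq
  z <- 1 - 2 * i_seq / n_points
  rad <- sqrt(pmax(1 - z^2, 0))
  unit <- cbind(rad * cos(phi), rad * sin(phi), z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ri <- radii[i] + probe
    acc_count <- 0
    for (p in seq_len(n_points)) {
      pt <- xyz[i, ] + ri * unit[p, ]
      free <- TRUE
      for (j in seq_len(n)) {
        if (j == i) next
        if (sum((pt - xyz[j, ])^2) <= (radii[j] + probe)^2) { free <- FALSE; break }
      }
      if (free) acc_count <- acc_count + 1
    }
    out[i] <- acc_count / n_points * 4 * pi * ri^2
  }
  out
}

# naive four-end-state recomputation of the per-frame mutational component
# differences (mutant binding components minus wild-type binding components)
oracle_ddg_frame <- function(top, xyz_wt, view, frame_idx, dielectric,
                             components = c("vdw", "ele", "gb", "sasa"),
                             eps_out = 78.5, gamma = 0.00542, beta = 0.92,
                             sasa_points = 960) {
  states <- function(topo, xyz) {
    rec <- which(topo$atoms$side == "receptor")
    lig <- which(topo$atoms$side == "ligand")
    top_r <- alascan::topology_subset(topo, rec)
    top_l <- alascan::topology_subset(topo, lig)
    out <- c(e_vdw = 0, e_ele = 0, g_polar = 0, g_nonpolar = 0)
    if (any(c("vdw", "ele") %in% components)) {
      full <- oracle_gas_total(topo, xyz, dielectric)
      er <- oracle_gas_total(top_r, xyz[rec, , drop = FALSE], dielectric)
      el <- oracle_gas_total(top_l, xyz[lig, , drop = FALSE], dielectric)
      d <- full - er - el
      if ("vdw" %in% components) out["e_vdw"] <- d["vdw"]
      if ("ele" %in% components) out["e_ele"] <- d["ele"]
    }
    if ("gb" %in% components) {
      gb <- function(t2, x2) oracle_gb_energy(t2, x2,
                                              oracle_born_radii(t2, x2),
                                              eps_in = dielectric,
                                              eps_out = eps_out)
      out["g_polar"] <- gb(topo, xyz) - gb(top_r, xyz[rec, , drop = FALSE]) -
        gb(top_l, xyz[lig, , drop = FALSE])
    }
    if ("sasa" %in% components) {
      s <- function(t2, x2) sum(oracle_sasa(t2, x2, n_points = sasa_points))
      out["g_nonpolar"] <- gamma * (s(topo, xyz) -
                                      s(top_r, xyz[rec, , drop = FALSE]) -
                                      s(top_l, xyz[lig, , drop = FALSE])) - beta
    }
    out
  }
  wt <- states(top, xyz_wt)
  mt <- if (view$identity) wt else {
    xyz_mt <- matrix(view$ensemble$coords[frame_idx, , ], ncol = 3)
    states(view$topology, xyz_mt)
  }
  mt - wt
}

# direct textbook Pearson / Spearman on a small vector pair
oracle_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# naive (overflow-prone) interaction-entropy path
oracle_ie_naive <- function(values, temperature = 300) {
  kt <- ORACLE_KB * temperature
  kt * log(mean(exp((values - mean(values)) / kt)))
}

# small fixture builders -------------------------------------------------

# a tiny random two-chain system with random parameters (no templates):
# na/nb atoms in two blobs `sep` apart, each atom its own residue
random_pair_topology <- function(na, nb, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    n <- na + nb
    atoms <- tibble::tibble(
      serial = seq_len(n),
      name = sprintf("X%d", seq_len(n)),
      element = sample(c("C", "N", "O"), n, replace = TRUE),
      residue_index = seq_len(n) - 1L,
      residue_name = "UNK",
      chain_id = rep(c("A", "B"), c(na, nb)),
      resno = c(seq_len(na), seq_len(nb)),
      charge = runif(n, -0.5, 0.5),
      lj_epsilon = runif(n, 0.05, 0.3),
      lj_rmin_half = runif(n, 1.2, 2.0),
      gb_radius = runif(n, 1.2, 1.9),
      gb_screen = runif(n, 0.7, 0.9)
    )
    xyz <- rbind(matrix(rnorm(na * 3, 0, 2.5), ncol = 3),
                 cbind(matrix(rnorm(nb * 2, 0, 2.5), ncol = 2),
                       rnorm(nb, sep, 1.5)))
    # push apart any clashing pair deterministically
    repeat {
      d2 <- as.matrix(dist(xyz))^2; diag(d2) <- Inf
      if (min(d2) >= 1.2^2) break
      w <- which(d2 == min(d2), arr.ind = TRUE)[1, ]
      shift <- xyz[w[1], ] - xyz[w[2], ]
      xyz[w[1], ] <- xyz[w[1], ] + 0.8 * shift / sqrt(sum(shift^2))
    }
    top <- alascan::topology(atoms, partition = c(A = "receptor", B = "ligand"))
    list(topology = top, xyz = xyz)
  })
}

expect_scan_quiet <- function(expr) {
  suppressWarnings(expr)
}
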