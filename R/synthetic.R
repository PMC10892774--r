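# Synthetic fixture generation: toy two-chain complexes with designed
# contacts, Gaussian perturbation ensembles, designed variant families and
# Gaussian interaction-energy series. Everything is reproducible from
# (spec, seed) and serializes through the package's standard formats.

#' Specification for a toy two-chain complex
#'
#' Describes a small receptor/ligand system built from residue templates:
#' which residues each chain carries, which residue pairs form designed
#' contacts and with what Lennard-Jones well depth (the contact tip atoms
#' are placed at their pair minimum-energy distance, so each contact
#' contributes exactly `-well_depth` to the inter-chain energy at the
#' reference geometry).
#'
#' @param receptor Character vector of template residue names (chain A).
#' @param ligand Character vector of template residue names (chain B).
#' @param contacts Tibble with columns `receptor_pos`, `ligand_pos`
#'   (1-based), `well_depth` (kcal/mol).
#' @param spacing Backbone spacing along x between residues (default 7 A).
#' @param noncontact_gap Extra tip-tip separation for ligand residues
#'   without a designed contact (default 4 A).
#' @param charge_scale Multiplier applied to every partial charge
#'   (0 = charge-free system).
#' @param seed Seed recorded in the spec; fixture geometry is deterministic,
#'   the seed feeds downstream ensemble generation.
#' @return An object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(receptor = c("LEU", "SER", "ARG", "GLN"),
                             ligand = c("VAL", "THR", "PHE"),
                             contacts = tibble(receptor_pos = c(1L, 2L, 4L),
                                               ligand_pos = c(1L, 2L, 3L),
                                               well_depth = c(3.0, 2.0, 1.5)),
                             spacing = 7, noncontact_gap = 4,
                             charge_scale = 1, seed = 1) {
  tmpl <- toy_residue_templates()
  bad <- setdiff(c(receptor, ligand), names(tmpl))
  if (length(bad) > 0) {
    abort(paste0("no template for residue(s): ", paste(bad, collapse = ", ")))
  }
  contacts <- as_tibble(contacts)
  stopifnot(all(contacts$receptor_pos %in% seq_along(receptor)),
            all(contacts$ligand_pos %in% seq_along(ligand)),
            all(contacts$well_depth > 0),
            !any(duplicated(contacts$ligand_pos)))
  # contact well depths are carried by the parameter table keyed on
  # (residue_name, atom_name), so every contact residue's type must occur
  # exactly once in the whole complex for the design to serialize losslessly
  contact_types <- c(receptor[contacts$receptor_pos],
                     ligand[contacts$ligand_pos])
  counts <- table(c(receptor, ligand))
  if (any(duplicated(contact_types)) ||
      any(counts[contact_types] > 1)) {
    abort("contact residues must each have a residue type unique in the complex")
  }
  structure(list(receptor = receptor, ligand = ligand, contacts = contacts,
                 spacing = spacing, noncontact_gap = noncontact_gap,
                 charge_scale = charge_scale, seed = seed),
            class = "toy_complex_spec")
}

#' Build a parameterized toy complex from a spec
#'
#' Deterministic: the same spec always yields bit-identical coordinates.
#' Receptor residues sit along x with side chains pointing +z; each ligand
#' residue is flipped to face its receptor partner with the two contact tip
#' atoms separated by exactly the sum of their Lennard-Jones half-minimum
#' distances (designed contacts) or by that sum plus `noncontact_gap`.
#' Contact tip atoms receive the designed well depth as their LJ epsilon.
#' Geometries with any interatomic distance below 0.8 A are an error.
#'
#' @param spec A [toy_complex_spec()].
#' @return A list with the parameterized, partitioned `topology`, the
#'   reference `frame` (atoms x 3 matrix), `designed_dg`
#'   (`-sum(well_depth)`, kcal/mol) and the `contact_atoms` bookkeeping.
#' @export
build_toy_complex <- function(spec) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  tmpl <- toy_residue_templates()
  params <- toy_parameter_table()
  flip <- diag(c(1, -1, -1))  # 180 degrees about x: side chain -> -z

  place <- function(resnames, chain, flip_mat = NULL, origins) {
    purrr::imap(resnames, function(rn, k) {
      t <- tmpl[[rn]]
      xyz <- as.matrix(t[, c("x", "y", "z")])
      if (!is.null(flip_mat)) xyz <- xyz %*% t(flip_mat)
      xyz <- sweep(xyz, 2, origins[[k]], "+")
      tibble(name = t$name, element = t$element, residue_name = rn,
             chain_id = chain, resno = k,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
    }) |> list_rbind()
  }

  rec_origins <- purrr::map(seq_along(spec$receptor),
                            function(k) c(spec$spacing * (k - 1), 0, 0))
  rec <- place(spec$receptor, "A", NULL, rec_origins)

  # tip atom positions/parameters on the receptor
  tip_of <- function(tbl, resname, k) {
    tip <- .tip_atoms[[resname]]
    row <- tbl[tbl$resno == k & tbl$name == tip, ]
    c(row$x, row$y, row$z)
  }
  rmin_of <- function(resname, atom) {
    params$lj_rmin_half[params$residue_name == resname &
                          params$atom_name == atom]
  }

  lig_origins <- purrr::map(seq_along(spec$ligand), function(j) {
    hit <- spec$contacts[spec$contacts$ligand_pos == j, ]
    rpos <- if (nrow(hit) == 1) hit$receptor_pos else min(j, length(spec$receptor))
    gap_extra <- if (nrow(hit) == 1) 0 else spec$noncontact_gap
    r_name <- spec$receptor[rpos]
    l_name <- spec$ligand[j]
    r_tip <- tip_of(rec, r_name, rpos)
    d <- rmin_of(r_name, .tip_atoms[[r_name]]) +
      rmin_of(l_name, .tip_atoms[[l_name]]) + gap_extra
    target_tip <- r_tip + c(0, 0, d)
    # flipped template tip position (before translation)
    t <- tmpl[[l_name]]
    tip_local <- as.numeric(t[t$name == .tip_atoms[[l_name]],
                              c("x", "y", "z")])
    tip_flipped <- as.numeric(flip %*% tip_local)
    target_tip - tip_flipped
  })
  lig <- place(spec$ligand, "B", flip, lig_origins)

  atoms_df <- bind_rows(rec, lig)
  res_key <- paste(atoms_df$chain_id, atoms_df$resno)
  atoms <- tibble(
    serial = seq_len(nrow(atoms_df)),
    name = atoms_df$name, element = atoms_df$element,
    residue_index = match(res_key, unique(res_key)) - 1L,
    residue_name = atoms_df$residue_name,
    chain_id = atoms_df$chain_id, resno = atoms_df$resno
  )

  # designed contact well depths live in the parameter table (keyed on
  # residue and atom name) so the fixture serializes losslessly
  for (k in seq_len(nrow(spec$contacts))) {
    for (nm in c(spec$receptor[spec$contacts$receptor_pos[k]],
                 spec$ligand[spec$contacts$ligand_pos[k]])) {
      row <- params$residue_name == nm & params$atom_name == .tip_atoms[[nm]]
      params$lj_epsilon[row] <- spec$contacts$well_depth[k]
    }
  }
  params$charge <- params$charge * spec$charge_scale

  top <- topology(atoms) |>
    attach_parameters(params) |>
    set_partition(c(A = "receptor", B = "ligand"))

  contact_atoms <- purrr::pmap(spec$contacts, function(receptor_pos,
                                                       ligand_pos, well_depth) {
    r_name <- spec$receptor[receptor_pos]
    l_name <- spec$ligand[ligand_pos]
    ri <- which(top$atoms$chain_id == "A" & top$atoms$resno == receptor_pos &
                  top$atoms$name == .tip_atoms[[r_name]])
    li <- which(top$atoms$chain_id == "B" & top$atoms$resno == ligand_pos &
                  top$atoms$name == .tip_atoms[[l_name]])
    tibble(receptor_atom = ri, ligand_atom = li, well_depth = well_depth)
  }) |> list_rbind()

  frame <- as.matrix(atoms_df[, c("x", "y", "z")])
  dimnames(frame) <- list(NULL, c("x", "y", "z"))
  d2 <- cross_dist2(frame, frame)
  diag(d2) <- Inf
  if (min(d2) < 0.8^2) {
    abort(sprintf("spec produces a steric clash: minimum distance %.3f A",
                  sqrt(min(d2))))
  }
  list(topology = top, frame = frame,
       designed_dg = -sum(spec$contacts$well_depth),
       contact_atoms = contact_atoms, parameter_table = params, spec = spec)
}

#' Gaussian perturbation ensemble around a reference frame
#'
#' Frames are the reference plus independent isotropic Gaussian atomic
#' displacements of the given amplitude; amplitude 0 gives a constant
#' ensemble. Not physical dynamics: the generator reproduces fluctuation
#' statistics, which is what the post-processing contracts depend on.
#'
#' @param top A [topology()] (for the atom count check).
#' @param frame Reference `atoms x 3` matrix.
#' @param n_frames Number of frames.
#' @param amplitude Per-coordinate displacement standard deviation, A.
#' @param seed RNG seed (fixtures are reproducible from spec + seed).
#' @return An [ensemble()].
#' @export
perturbation_ensemble <- function(top, frame, n_frames, amplitude = 0.06,
                                  seed = 1) {
  stopifnot(amplitude >= 0, n_frames >= 1)
  na <- n_atoms(top)
  stopifnot(nrow(frame) == na)
  coords <- withr::with_seed(seed, {
    arr <- array(rnorm(n_frames * na * 3, 0, amplitude),
                 dim = c(n_frames, na, 3))
    ref <- aperm(array(frame, dim = c(na, 3, n_frames)), c(3, 1, 2))
    if (amplitude == 0) ref else ref + arr
  })
  ensemble(coords, source_label = sprintf("perturbation(seed=%d)", seed))
}

#' Designed variant family with a known affinity order
#'
#' Starting from a base complex spec, generates variants that weaken the
#' designed ligand contacts by prescribed effect sizes: the first portion of
#' each effect is taken from the first contact's well depth, the remainder
#' (if the first contact is exhausted) from the second, producing a mix of
#' single- and double-contact variants. Each variant's designed binding
#' free energy is the analytic sum of its contact minima,
#' `-sum(well_depth)`.
#'
#' @param base_spec A [toy_complex_spec()].
#' @param n_variants Number of variants (default 10; the first is the
#'   unmodified base).
#' @param effect_sizes Destabilization per variant, kcal/mol; default spans
#'   0 to 4.5.
#' @param seed Base seed stored in each variant spec.
#' @return A tibble with `variant`, `spec` (list column), `designed_dg`,
#'   `effect` and `n_contacts_hit`.
#' @export
designed_variant_family <- function(base_spec, n_variants = 10,
                                    effect_sizes = NULL, seed = 1) {
  stopifnot(inherits(base_spec, "toy_complex_spec"))
  effect_sizes <- effect_sizes %||% seq(0, 4.5, length.out = n_variants)
  stopifnot(length(effect_sizes) == n_variants)
  if (n_variants >= 2 && diff(range(effect_sizes)) < 3) {
    warn("designed effect sizes span less than 3 kcal/mol; ranking tests may be weak")
  }
  floor_depth <- 0.05
  purrr::imap(effect_sizes, function(eff, i) {
    contacts <- base_spec$contacts
    remaining <- eff
    hit <- 0L
    for (k in seq_len(nrow(contacts))) {
      if (remaining <= 0) break
      take <- min(remaining, contacts$well_depth[k] - floor_depth)
      if (take > 0) {
        contacts$well_depth[k] <- contacts$well_depth[k] - take
        remaining <- remaining - take
        hit <- hit + 1L
      }
    }
    if (remaining > 1e-9) {
      abort(sprintf("effect size %.2f exceeds the available contact depth", eff))
    }
    spec <- base_spec
    spec$contacts <- contacts
    spec$seed <- seed + i
    tibble(variant = sprintf("V%02d", i), spec = list(spec),
           designed_dg = -sum(contacts$well_depth), effect = eff,
           n_contacts_hit = hit)
  }) |> list_rbind()
}

#' Gaussian interaction-energy series with optional injected outliers
#'
#' @param n Number of frames (>= 2).
#' @param mean Series mean, kcal/mol.
#' @param sigma Standard deviation, kcal/mol (>= 0).
#' @param outliers Optional data frame with columns `index` and `magnitude`;
#'   frame `index` is set to `mean + magnitude * sigma`.
#' @param seed RNG seed.
#' @param temperature Temperature in K.
#' @return An [ie_series()].
#' @export
gaussian_series <- function(n, mean = 0, sigma = 1, outliers = NULL,
                            seed = 1, temperature = 300) {
  stopifnot(n >= 2, sigma >= 0)
  vals <- withr::with_seed(seed, rnorm(n, mean, sigma))
  if (!is.null(outliers)) {
    outliers <- as.data.frame(outliers)
    stopifnot(all(outliers$index >= 1), all(outliers$index <= n))
    vals[outliers$index] <- mean + outliers$magnitude * sigma
  }
  ie_series(vals, temperature)
}

#' Write a complete synthetic benchmark fixture to disk
#'
#' Builds a designed variant family and serializes everything the pipeline
#' consumes through the package's standard formats: one multi-model PDB per
#' variant and trajectory, the parameter table, an experiment table whose
#' ID50 values encode the designed free energies, and a run config.
#'
#' @param dir Output directory (created if needed).
#' @param base_spec Base [toy_complex_spec()].
#' @param n_variants,effect_sizes Passed to [designed_variant_family()].
#' @param n_trajectories Independent ensembles per variant (default 2).
#' @param n_frames Frames per ensemble (default 25).
#' @param amplitude Perturbation amplitude, A (default 0.06).
#' @param temperature Temperature in K (default 300).
#' @param seed Master seed; per-ensemble seeds are derived from it.
#' @return The path of the written config file, invisibly; the family
#'   tibble is attached as attribute `family`.
#' @export
write_benchmark_fixture <- function(dir, base_spec = toy_complex_spec(),
                                    n_variants = 10, effect_sizes = NULL,
                                    n_trajectories = 2, n_frames = 25,
                                    amplitude = 0.06, temperature = 300,
                                    seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  family <- designed_variant_family(base_spec, n_variants, effect_sizes,
                                    seed = seed)
  write_parameter_table(toy_parameter_table(), file.path(dir, "params.tsv"))

  variants <- purrr::pmap(family, function(variant, spec, designed_dg, ...) {
    cx <- build_toy_complex(spec)
    # per-variant table carrying that variant's designed contact depths
    par_file <- sprintf("params_%s.tsv", variant)
    write_parameter_table(cx$parameter_table, file.path(dir, par_file))
    ens_files <- purrr::map_chr(seq_len(n_trajectories), function(t) {
      s <- spec$seed * 1000L + t
      ens <- perturbation_ensemble(cx$topology, cx$frame, n_frames,
                                   amplitude, seed = s)
      f <- file.path(dir, sprintf("%s_traj%d.pdb", variant, t))
      write_multimodel_pdb(cx$topology, ens, f)
      basename(f)
    })
    list(label = variant, parameter_table = par_file,
         ensembles = as.list(ens_files))
  })

  rt <- kT(temperature)
  experiments <- family |>
    mutate(id50 = exp(.data$designed_dg / rt), temperature = temperature) |>
    select("variant", "id50", "temperature")
  readr::write_tsv(experiments, file.path(dir, "experiments.tsv"))

  config <- list(
    parameter_table = "params.tsv",
    experiment_table = "experiments.tsv",
    partition = list(A = "receptor", B = "ligand"),
    interface_cutoff = 5.0,
    enthalpy_frames = 100L,
    temperature = temperature,
    side = "both",
    components = list("vdw", "ele"),
    seed = seed,
    output_dir = "out",
    variants = variants
  )
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  invisible(structure(cfg_path, family = family))
}
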