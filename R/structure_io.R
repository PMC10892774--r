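#' Read a multi-model PDB into a topology skeleton and an ensemble
#'
#' Each `MODEL` block becomes one frame; a file without `MODEL` records is a
#' one-frame ensemble. All models must contain the same atom sequence; the
#' first offending model is named otherwise. PDB serial and residue numbers
#' are retained as display metadata next to the 0-based internal indices.
#'
#' @param path Path to a PDB file.
#' @param partition Optional named chain partition passed to
#'   [set_partition()].
#' @return A list with `topology` (parameter-free skeleton) and `ensemble`.
#' @export
read_multimodel_pdb <- function(path, partition = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  # cheap pre-scan: per-MODEL atom counts must agree before handing to bio3d
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    model_ends <- which(startsWith(lines, "ENDMDL"))
    if (length(model_ends) != length(model_starts)) {
      abort("unbalanced MODEL/ENDMDL records")
    }
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(is_atom[model_starts[k]:model_ends[k]])
    }, integer(1))
    bad <- which(counts != counts[1])
    if (length(bad) > 0) {
      abort(sprintf(
        "inconsistent atom counts across models: model %d has %d atoms, model 1 has %d",
        bad[1], counts[bad[1]], counts[1]))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
    warn("PDB has no element column; inferring elements from atom names")
    element <- infer_element(at$elety)
  } else {
    blank <- is.na(element) | !nzchar(trimws(element))
    if (any(blank)) {
      warn(sprintf("inferring element from atom name for %d atoms", sum(blank)))
      element[blank] <- infer_element(at$elety[blank])
    }
  }
  chain <- at$chain
  chain[is.na(chain)] <- "A"
  res_key <- paste(chain, at$resno, at$insert %||% "", sep = "|")
  residue_index <- match(res_key, unique(res_key)) - 1L
  atoms <- tibble(
    serial = at$eleno,
    name = trimws(at$elety),
    element = trimws(element),
    residue_index = residue_index,
    residue_name = trimws(at$resid),
    chain_id = chain,
    resno = at$resno
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(nf, na, 3))
  for (f in seq_len(nf)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  top <- topology(atoms, partition = partition)
  list(topology = top, ensemble = ensemble(coords, source_label = basename(path)))
}

infer_element <- function(atom_names) {
  nm <- gsub("[0-9']", "", trimws(atom_names))
  two <- toupper(substr(nm, 1, 2))
  one <- toupper(substr(nm, 1, 1))
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN", "FE", "SE"), two, one)
}

#' Write a topology and ensemble as a multi-model PDB
#'
#' @param top A [topology()].
#' @param ens An [ensemble()] (or a single frame matrix).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(top, ens, path) {
  if (is.matrix(ens)) ens <- ensemble(ens)
  check_compatible(top, ens)
  nf <- n_frames(ens)
  xyz <- matrix(NA_real_, nrow = nf, ncol = 3 * n_atoms(top))
  for (f in seq_len(nf)) {
    xyz[f, ] <- as.vector(t(frame_coords(ens, f)))
  }
  a <- top$atoms
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = a$resno, resid = a$residue_name, eleno = a$serial,
    elety = a$name, chain = a$chain_id, elesy = a$element,
    o = rep(1, nrow(a)), b = rep(0, nrow(a))
  )
  invisible(path)
}

# Parameter tables -------------------------------------------------------------

#' Read a per-atom force-field parameter table
#'
#' The table is whitespace/tab separated text with a header row and the
#' columns `residue_name`, `atom_name`, `charge` (e), `lj_epsilon` (kcal/mol),
#' `lj_rmin_half` (Angstrom), `gb_radius` (Angstrom), `gb_screen`
#' (dimensionless). Lines starting with `#` are comments.
#'
#' @param path Path to the table.
#' @return A tibble of parameters.
#' @export
read_parameter_table <- function(path) {
  tbl <- readr::read_table(path, comment = "#", show_col_types = FALSE)
  needed <- c("residue_name", "atom_name", "charge", "lj_epsilon",
              "lj_rmin_half", "gb_radius", "gb_screen")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("parameter table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_parameter_table(tbl)
  tbl
}

#' Write a parameter table
#'
#' @param params Parameter tibble (see [read_parameter_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(params, path) {
  validate_parameter_table(params)
  readr::write_tsv(params, path)
  invisible(path)
}

validate_parameter_table <- function(params) {
  if (any(params$lj_epsilon < 0, na.rm = TRUE)) abort("lj_epsilon must be >= 0")
  if (any(params$lj_rmin_half <= 0, na.rm = TRUE)) abort("lj_rmin_half must be > 0")
  if (any(params$gb_radius <= 0, na.rm = TRUE)) abort("gb_radius must be > 0")
  invisible(params)
}

#' Attach force-field parameters to a topology skeleton
#'
#' Joins the parameter table on `(residue_name, atom_name)`. Under the strict
#' policy (default) any unmatched atom is an error listing every miss; with
#' `policy = "fallback"` unmatched atoms receive `fallback` values with a
#' warning.
#'
#' @param top A [topology()] skeleton.
#' @param params Parameter tibble (see [read_parameter_table()]).
#' @param policy `"strict"` or `"fallback"`.
#' @param fallback Named list of default parameter values used under the
#'   fallback policy.
#' @return The topology with all parameter columns populated.
#' @export
attach_parameters <- function(top, params,
                              policy = c("strict", "fallback"),
                              fallback = list(charge = 0, lj_epsilon = 0.05,
                                              lj_rmin_half = 1.7,
                                              gb_radius = 1.5, gb_screen = 0.8)) {
  policy <- match.arg(policy)
  validate_parameter_table(params)
  key <- paste(top$atoms$residue_name, top$atoms$name, sep = "|")
  pkey <- paste(params$residue_name, params$atom_name, sep = "|")
  if (any(duplicated(pkey))) abort("duplicate (residue_name, atom_name) rows in parameter table")
  hit <- match(key, pkey)
  if (anyNA(hit)) {
    misses <- unique(key[is.na(hit)])
    if (policy == "strict") {
      abort(paste0("no parameters for atom(s): ",
                   paste(gsub("\\|", ":", misses), collapse = ", ")))
    }
    warn(paste0("fallback parameters used for atom(s): ",
                paste(gsub("\\|", ":", misses), collapse = ", ")))
  }
  for (col in c("charge", "lj_epsilon", "lj_rmin_half", "gb_radius", "gb_screen")) {
    vals <- params[[col]][hit]
    if (policy == "fallback") vals[is.na(hit)] <- fallback[[col]]
    top$atoms[[col]] <- vals
  }
  top
}

# Interface selection ----------------------------------------------------------

#' Select interface residues by a heavy-atom distance cutoff
#'
#' A receptor residue is selected iff any of its heavy atoms lies within
#' `cutoff` of any ligand heavy atom in the reference frame (or in any frame
#' with `mode = "any-frame"`). The ligand side defaults to all ligand
#' residues, the convention for short peptide ligands scanned in full;
#' `ligand_all = FALSE` applies the symmetric distance criterion.
#'
#' @param top A partitioned [topology()].
#' @param ens An [ensemble()].
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @param reference_frame Frame used for the distance test (default 1).
#' @param mode `"reference"` (default, deterministic single frame) or
#'   `"any-frame"`.
#' @param ligand_all Keep all ligand residues (default `TRUE`).
#' @return A list with integer residue-index vectors `receptor` and `ligand`.
#' @export
interface_residues <- function(top, ens, cutoff = 5,
                               reference_frame = 1,
                               mode = c("reference", "any-frame"),
                               ligand_all = TRUE) {
  mode <- match.arg(mode)
  stopifnot(cutoff > 0)
  check_compatible(top, ens)
  heavy <- top$atoms$element != "H"
  rec <- side_atoms(top, "receptor")
  lig <- side_atoms(top, "ligand")
  rec_h <- intersect(rec, which(heavy))
  lig_h <- intersect(lig, which(heavy))
  frames <- if (mode == "reference") reference_frame else seq_len(n_frames(ens))
  near_rec <- rep(FALSE, length(rec_h))
  near_lig <- rep(FALSE, length(lig_h))
  for (f in frames) {
    xyz <- frame_coords(ens, f)
    d2 <- cross_dist2(xyz[rec_h, , drop = FALSE], xyz[lig_h, , drop = FALSE])
    near <- d2 <= cutoff^2
    near_rec <- near_rec | apply(near, 1, any)
    near_lig <- near_lig | apply(near, 2, any)
  }
  rec_res <- sort(unique(top$atoms$residue_index[rec_h[near_rec]]))
  lig_res <- if (ligand_all) {
    sort(unique(top$atoms$residue_index[lig]))
  } else {
    sort(unique(top$atoms$residue_index[lig_h[near_lig]]))
  }
  if (length(rec_res) == 0 && length(lig_res) == 0) {
    warn("empty interface selection")
  }
  list(receptor = rec_res, ligand = lig_res)
}

# squared distances between two coordinate sets (na x 3, nb x 3)
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
}

# RMSD -------------------------------------------------------------------------

#' Per-frame RMSD of a selection against a reference frame
#'
#' With `fit = TRUE` (default) each frame is optimally superposed on the
#' reference over the selection (least-squares rigid-body fit) before the
#' RMSD is taken, so the series is invariant under global rigid motion.
#'
#' @param ens An [ensemble()].
#' @param top A [topology()].
#' @param selection Integer vector of atom rows; defaults to all atoms.
#' @param reference_frame Frame index of the reference (default 1).
#' @param fit Superpose before measuring (default `TRUE`).
#' @return A tibble with `frame` and `rmsd` (Angstrom).
#' @export
rmsd_series <- function(ens, top, selection = NULL, reference_frame = 1,
                        fit = TRUE) {
  check_compatible(top, ens)
  if (is.null(selection)) selection <- seq_len(n_atoms(top))
  if (length(selection) == 0) abort("empty selection")
  if (fit && length(selection) < 3) {
    abort("rigid-body fit needs at least 3 selected atoms")
  }
  nf <- n_frames(ens)
  sel_xyz_ind <- as.vector(t(outer(selection, 1:3, function(i, k) 3 * (i - 1) + k)))
  flat <- matrix(NA_real_, nrow = nf, ncol = 3 * n_atoms(top))
  for (f in seq_len(nf)) flat[f, ] <- as.vector(t(frame_coords(ens, f)))
  ref <- flat[reference_frame, ]
  if (fit) {
    # Kabsch superposition on the selection (bio3d), RMSD taken unrounded
    flat <- bio3d::fit.xyz(ref, flat, fixed.inds = sel_xyz_ind,
                           mobile.inds = sel_xyz_ind)
  }
  dx <- sweep(flat[, sel_xyz_ind, drop = FALSE], 2, ref[sel_xyz_ind])
  vals <- sqrt(rowSums(dx^2) / length(selection))
  tibble(frame = seq_len(nf), rmsd = as.numeric(vals))
}
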