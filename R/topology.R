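#' Build a topology from an atom table
#'
#' A topology is the fixed atom bookkeeping shared by every frame of an
#' ensemble: one row per atom (in coordinate order) with residue and chain
#' assignments and, once [attach_parameters()] has run, the per-atom
#' force-field parameters (partial charge, Lennard-Jones well depth and
#' half-minimum distance, intrinsic Born radius, screening factor).
#'
#' @param atoms A data frame with one row per atom, in coordinate order.
#'   Required columns: `serial`, `name`, `element`, `residue_index` (0-based),
#'   `residue_name`, `chain_id`, `resno` (original author residue numbering,
#'   kept as display metadata). Parameter columns (`charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `gb_radius`, `gb_screen`) may be `NA` on a skeleton.
#' @param partition Named character vector mapping chain id to `"receptor"`
#'   or `"ligand"`, or `NULL` for an unpartitioned skeleton.
#' @return An object of class `topology`: a list with `atoms` (tibble),
#'   `residues` (tibble with atom spans) and `partition`.
#' @export
topology <- function(atoms, partition = NULL) {
  atoms <- as_tibble(atoms)
  needed <- c("serial", "name", "element", "residue_index", "residue_name",
              "chain_id", "resno")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("atom table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (p in c("charge", "lj_epsilon", "lj_rmin_half", "gb_radius", "gb_screen")) {
    if (!p %in% names(atoms)) atoms[[p]] <- NA_real_
  }
  if (any(duplicated(atoms$serial))) abort("duplicate atom serials")
  # residue spans must be contiguous in atom order
  ri <- atoms$residue_index
  if (any(ri != cummax(ri)) || any(diff(unique(ri)) != 1L)) {
    abort("residue_index must be non-decreasing and contiguous in atom order")
  }
  residues <- atoms |>
    mutate(.row = row_number()) |>
    group_by(residue_index = .data$residue_index) |>
    summarise(
      name = .data$residue_name[1],
      chain = .data$chain_id[1],
      resno = .data$resno[1],
      first_atom = min(.data$.row),
      last_atom = max(.data$.row),
      n_atoms = n(),
      .groups = "drop"
    )
  top <- structure(
    list(atoms = atoms, residues = residues, partition = NULL),
    class = "topology"
  )
  if (!is.null(partition)) top <- set_partition(top, partition)
  top
}

#' Declare the receptor/ligand chain partition
#'
#' @param top A [topology()].
#' @param partition Named character vector, e.g. `c(A = "receptor",
#'   B = "ligand")`. Every chain in the topology must be labelled and both
#'   sides must be nonempty.
#' @return The topology with `partition` set and a per-atom `side` column.
#' @export
set_partition <- function(top, partition) {
  stopifnot(inherits(top, "topology"))
  chains <- unique(top$atoms$chain_id)
  if (!all(chains %in% names(partition))) {
    abort(paste0("partition must label every chain; missing: ",
                 paste(setdiff(chains, names(partition)), collapse = ", ")))
  }
  labels <- partition[chains]
  if (!all(labels %in% c("receptor", "ligand"))) {
    abort("partition labels must be 'receptor' or 'ligand'")
  }
  if (!any(labels == "receptor") || !any(labels == "ligand")) {
    abort("partition must assign at least one chain to each side")
  }
  top$partition <- partition[chains]
  top$atoms$side <- unname(partition[top$atoms$chain_id])
  top$residues$side <- unname(partition[top$residues$chain])
  top
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, ", nrow(x$residues),
      " residues, chains: ", paste(unique(x$atoms$chain_id), collapse = ","),
      "\n", sep = "")
  if (!is.null(x$partition)) {
    cat("  partition: ",
        paste(names(x$partition), x$partition, sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Restrict a topology to a subset of atoms
#'
#' Used internally to form receptor-only and ligand-only end states; keeps
#' residue bookkeeping consistent.
#'
#' @param top A [topology()].
#' @param atom_idx Integer vector of atom rows to keep (in order).
#' @return A `topology` for the subset.
#' @export
topology_subset <- function(top, atom_idx) {
  atoms <- top$atoms[atom_idx, ]
  # re-pack residue indices to stay contiguous
  atoms$residue_index <- match(atoms$residue_index, unique(atoms$residue_index)) - 1L
  part <- top$partition
  if (!is.null(part)) part <- part[names(part) %in% unique(atoms$chain_id)]
  if (!is.null(part) && !all(c("receptor", "ligand") %in% part)) part <- NULL
  out <- topology(atoms)
  if (!is.null(part)) out <- set_partition(out, part)
  if (!is.null(top$partition)) {
    out$atoms$side <- top$atoms$side[atom_idx]
  }
  out
}

side_atoms <- function(top, side) {
  if (is.null(top$partition)) abort("topology has no receptor/ligand partition")
  which(top$atoms$side == side)
}

#' Build a conformational ensemble
#'
#' @param coords A `frames x atoms x 3` numeric array of coordinates in
#'   Angstrom, or an `atoms x 3` matrix for a single frame.
#' @param frame_times Optional numeric vector of frame times (ps).
#' @param source_label Optional trajectory identifier.
#' @return An object of class `ensemble`.
#' @export
ensemble <- function(coords, frame_times = NULL, source_label = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, dim(coords)))
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[1] < 1) abort("ensemble needs at least one frame")
  if (!all(is.finite(coords))) abort("ensemble coordinates must be finite")
  structure(
    list(coords = coords, frame_times = frame_times,
         source_label = source_label),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$coords)
  cat("<ensemble> ", d[1], " frames x ", d[2], " atoms",
      if (!is.null(x$source_label)) paste0(" [", x$source_label, "]"), "\n",
      sep = "")
  invisible(x)
}

n_frames <- function(ens) dim(ens$coords)[1]

frame_coords <- function(ens, i) {
  matrix(ens$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

check_compatible <- function(top, ens) {
  if (n_atoms(top) != dim(ens$coords)[2]) {
    abort(sprintf("topology has %d atoms but ensemble frames have %d",
                  n_atoms(top), dim(ens$coords)[2]))
  }
  invisible(TRUE)
}
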