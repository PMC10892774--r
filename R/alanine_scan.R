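# Residue classification and side-chain truncation.

.default_class_table <- c(
  ARG = "charged", LYS = "charged", ASP = "charged", GLU = "charged",
  HIP = "charged",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar", TYR = "polar",
  CYS = "polar", HIS = "polar", HIE = "polar", HID = "polar", TRP = "polar",
  ALA = "nonpolar", GLY = "nonpolar", VAL = "nonpolar", LEU = "nonpolar",
  ILE = "nonpolar", PRO = "nonpolar", PHE = "nonpolar", MET = "nonpolar",
  CYX = "nonpolar"
)

#' Classify a residue as nonpolar, polar or charged
#'
#' The three classes carry the interior dielectrics 1, 3 and 10 used for the
#' electrostatic and polar-solvation terms of a scan of that residue.
#' Histidine tautomers HIE/HID map to polar and the doubly protonated HIP to
#' charged; the table is overridable.
#'
#' @param residue_name Standard 3-letter code (protonation variants allowed).
#' @param class_table Named character vector overriding the default mapping.
#' @return A list with `label` and `dielectric`.
#' @export
classify_residue <- function(residue_name, class_table = NULL) {
  tbl <- .default_class_table
  if (!is.null(class_table)) tbl[names(class_table)] <- class_table
  if (length(residue_name) != 1) abort("classify_residue takes one residue name")
  label <- unname(tbl[residue_name])
  if (is.na(label)) abort(paste0("unknown residue code: ", residue_name))
  list(label = label, dielectric = unname(.class_dielectrics[label]))
}

#' Interior dielectric for a residue class
#'
#' @param label One of `"nonpolar"`, `"polar"`, `"charged"`.
#' @return 1, 3 or 10.
#' @export
residue_dielectric <- function(label) {
  if (!label %in% names(.class_dielectrics)) {
    abort(paste0("unknown residue class: ", label))
  }
  unname(.class_dielectrics[label])
}

# Atoms retained on truncation (besides appended methyl hydrogens)
.ala_backbone <- c("N", "H", "CA", "HA", "C", "O")

#' Truncate a residue's side chain to alanine
#'
#' Implements the single-trajectory mutant: all atoms outside the mutated
#' residue, and the residue's backbone + CB, keep the parent coordinates
#' frame-by-frame; side-chain atoms beyond CB are removed and three methyl
#' hydrogens are appended on CB with ideal tetrahedral geometry (1.09 A
#' bonds, 109.47 degree angles), the first oriented along the azimuth of the
#' deleted CB->CG bond (a deterministic perpendicular seed is used when CG is
#' absent). The residue's partial charges are replaced by the alanine
#' template from the parameter table.
#'
#' Glycine (no side chain) and proline (ring into the backbone) are not
#' truncatable: `truncate_to_alanine` returns a skip marker with a warning,
#' and drivers record a zero contribution.
#'
#' @param top A parameterized [topology()].
#' @param ens An [ensemble()] over `top`.
#' @param residue_index 0-based residue index to mutate.
#' @param params Parameter table containing the ALA template rows.
#' @return An object of class `mutant_view`: list with the mutant `topology`,
#'   mutant `ensemble`, `keep_idx` (parent atom rows retained), appended-atom
#'   metadata and flags; or a `mutant_skip` object for GLY/PRO/missing-CB.
#' @export
truncate_to_alanine <- function(top, ens, residue_index, params) {
  check_compatible(top, ens)
  res <- top$residues[top$residues$residue_index == residue_index, ]
  if (nrow(res) != 1) abort(paste0("no residue with index ", residue_index))
  rows <- seq(res$first_atom, res$last_atom)
  a <- top$atoms
  if (res$name %in% c("GLY", "PRO") || !"CB" %in% a$name[rows]) {
    reason <- if (res$name == "GLY") "glycine has no side chain to truncate"
      else if (res$name == "PRO") "proline ring cannot be truncated"
      else "residue has no CB atom"
    warn(sprintf("skipping %s %s%s: %s", res$name, res$chain, res$resno, reason))
    return(structure(list(residue_index = residue_index, reason = reason),
                     class = "mutant_skip"))
  }

  if (res$name == "ALA") {
    # identity mutation: the view is the parent itself
    return(structure(
      list(topology = top, ensemble = ens,
           keep_idx = seq_len(n_atoms(top)), appended = integer(0),
           residue_index = residue_index, identity = TRUE,
           n_removed = 0L),
      class = "mutant_view"))
  }

  keep_in_res <- rows[a$name[rows] %in% c(.ala_backbone, "CB")]
  removed <- setdiff(rows, keep_in_res)
  keep_idx <- sort(c(setdiff(seq_len(n_atoms(top)), rows), keep_in_res))

  # alanine parameter template
  ala <- params[params$residue_name == "ALA", ]
  need <- c(a$name[keep_in_res], "HB1", "HB2", "HB3")
  miss <- setdiff(need, ala$atom_name)
  if (length(miss) > 0) {
    abort(paste0("parameter table ALA template missing atom(s): ",
                 paste(miss, collapse = ", ")))
  }
  ala_row <- function(nm) ala[match(nm, ala$atom_name), ]

  atoms <- a[keep_idx, ]
  mut_rows <- which(keep_idx %in% keep_in_res)
  for (k in mut_rows) {
    atoms$charge[k] <- ala_row(atoms$name[k])$charge
  }
  hb <- purrr::map(c("HB1", "HB2", "HB3"), function(nm) {
    r <- ala_row(nm)
    tibble(serial = NA_integer_, name = nm, element = "H",
           residue_index = residue_index, residue_name = "ALA",
           chain_id = res$chain, resno = res$resno,
           charge = r$charge, lj_epsilon = r$lj_epsilon,
           lj_rmin_half = r$lj_rmin_half, gb_radius = r$gb_radius,
           gb_screen = r$gb_screen)
  }) |> list_rbind()
  if ("side" %in% names(atoms)) hb$side <- atoms$side[mut_rows[1]]
  atoms$residue_name[mut_rows] <- "ALA"
  # insert the three hydrogens at the end of the mutated residue's span
  insert_after <- max(mut_rows)
  atoms <- bind_rows(atoms[seq_len(insert_after), ], hb,
                     if (insert_after < nrow(atoms))
                       atoms[(insert_after + 1):nrow(atoms), ])
  atoms$serial <- seq_len(nrow(atoms))

  # coordinates: parent frames for retained atoms + constructed methyl H
  idx <- function(nm) rows[match(nm, a$name[rows])]
  i_ca <- idx("CA"); i_cb <- idx("CB")
  i_cg <- rows[match(c("CG", "CG1", "OG", "OG1", "SG"), a$name[rows])]
  i_cg <- i_cg[!is.na(i_cg)][1]
  i_n <- idx("N")
  nf <- n_frames(ens)
  n_keep <- length(keep_idx)
  coords <- array(NA_real_, dim = c(nf, n_keep + 3L, 3L))
  pre <- seq_len(insert_after)
  post <- if (insert_after < n_keep) (insert_after + 1):n_keep else integer(0)
  for (f in seq_len(nf)) {
    xyz <- frame_coords(ens, f)
    hxyz <- methyl_hydrogens(
      ca = xyz[i_ca, ], cb = xyz[i_cb, ],
      seed_dir = if (!is.na(i_cg)) xyz[i_cg, ] - xyz[i_cb, ]
                 else xyz[i_ca, ] - xyz[i_n, ])
    kept <- xyz[keep_idx, , drop = FALSE]
    coords[f, pre, ] <- kept[pre, ]
    coords[f, insert_after + 1:3, ] <- hxyz
    if (length(post) > 0) coords[f, insert_after + 3L + seq_along(post), ] <- kept[post, ]
  }

  mtop <- topology(atoms)
  if (!is.null(top$partition)) mtop <- set_partition(mtop, top$partition)
  mens <- ensemble(coords, frame_times = ens$frame_times,
                   source_label = ens$source_label)
  view <- structure(
    list(topology = mtop, ensemble = mens, keep_idx = keep_idx,
         appended = insert_after + 1:3, residue_index = residue_index,
         identity = FALSE, n_removed = length(removed)),
    class = "mutant_view")
  check_methyl_clashes(view)
  view
}

# Ideal tetrahedral methyl construction: three unit directions at 109.47
# degrees from the CA->CB axis, 120 degrees apart in azimuth, the first
# sharing the azimuthal plane of `seed_dir`.
methyl_hydrogens <- function(ca, cb, seed_dir, bond = 1.09) {
  axis <- cb - ca
  axis <- axis / sqrt(sum(axis^2))
  p <- seed_dir - sum(seed_dir * axis) * axis
  if (sqrt(sum(p^2)) < 1e-8) {
    # degenerate seed: deterministic perpendicular from the smallest axis
    # component
    e <- diag(3)[, which.min(abs(axis))]
    p <- e - sum(e * axis) * axis
  }
  p <- p / sqrt(sum(p^2))
  q <- c(axis[2] * p[3] - axis[3] * p[2],
         axis[3] * p[1] - axis[1] * p[3],
         axis[1] * p[2] - axis[2] * p[1])
  # polar angle from the CA->CB axis: 180 - 109.471 deg, so that the
  # CA-CB-H angles are tetrahedral
  theta <- acos(1 / 3)
  phi <- c(0, 2 * pi / 3, 4 * pi / 3)
  t(vapply(phi, function(ph) {
    dir <- cos(theta) * axis + sin(theta) * (cos(ph) * p + sin(ph) * q)
    cb + bond * dir
  }, numeric(3)))
}

# Appended hydrogens must not clash with retained atoms (reference frame).
check_methyl_clashes <- function(view, min_dist = 0.8, frame = 1) {
  if (length(view$appended) == 0) return(invisible(TRUE))
  xyz <- frame_coords(view$ensemble, frame)
  h <- xyz[view$appended, , drop = FALSE]
  others <- xyz[-view$appended, , drop = FALSE]
  # exclude the bonded CB itself from the clash test radius? CB-H is 1.09 > 0.8
  d2 <- cross_dist2(h, others)
  if (any(d2 < min_dist^2)) {
    warn(sprintf(
      "methyl hydrogen within %.2f A of a retained atom for residue %d (min %.3f A)",
      min_dist, view$residue_index, sqrt(min(d2))))
  }
  invisible(TRUE)
}

#' @export
print.mutant_view <- function(x, ...) {
  cat("<mutant_view> residue ", x$residue_index,
      if (x$identity) " (identity: already ALA)" else
        sprintf(" (%d side-chain atoms removed, 3 methyl H appended)",
                x$n_removed),
      "\n", sep = "")
  invisible(x)
}

#' Scan manifest for a set of residues
#'
#' Tabulates, for each candidate residue, its class, dielectric, and whether
#' it can be truncated (GLY/PRO/missing-CB are skipped with a reason).
#'
#' @param top A [topology()].
#' @param residue_indices 0-based residue indices.
#' @return A tibble with one row per residue.
#' @export
scan_manifest <- function(top, residue_indices) {
  purrr::map(residue_indices, function(ri) {
    res <- top$residues[top$residues$residue_index == ri, ]
    rows <- seq(res$first_atom, res$last_atom)
    cls <- classify_residue(res$name)
    skip_reason <- NA_character_
    if (res$name == "GLY") skip_reason <- "glycine has no side chain to truncate"
    else if (res$name == "PRO") skip_reason <- "proline ring cannot be truncated"
    else if (!"CB" %in% top$atoms$name[rows]) skip_reason <- "no CB atom"
    tibble(residue_index = ri, residue_name = res$name, chain = res$chain,
           resno = res$resno, side = res$side %||% NA_character_,
           class = cls$label, dielectric = cls$dielectric,
           scanned = is.na(skip_reason), reason = skip_reason)
  }) |> list_rbind()
}
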