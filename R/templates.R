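# Synthetic residue templates and the toy parameter table.
#
# Small idealized amino-acid templates used by the fixture generator: a
# shared backbone (N, H, CA, HA, C, O) plus side chains extending roughly
# along +z from CB. Geometry is plausible but synthetic; it exists to
# exercise the scanning/energetics contracts, not to mimic a force field.

.backbone_template <- function() {
  tibble(
    name = c("N", "H", "CA", "HA", "C", "O"),
    element = c("N", "H", "C", "H", "C", "O"),
    x = c(-1.46, -1.96, 0.00, 0.62, 0.72, 1.95),
    y = c(0.00, 0.87, 0.00, -0.76, 1.33, 1.40),
    z = c(0.00, 0.00, 0.00, -0.48, 0.00, 0.00)
  )
}

.sidechain_templates <- function() {
  sc <- function(name, element, x, y, z) tibble(name = name, element = element,
                                                x = x, y = y, z = z)
  cb <- c(0.45, -0.70, 1.26)
  list(
    GLY = sc(character(0), character(0), numeric(0), numeric(0), numeric(0)),
    ALA = sc(c("CB", "HB1", "HB2", "HB3"), c("C", "H", "H", "H"),
             c(0.45, 1.50, -0.12, 0.28), c(-0.70, -0.93, -1.56, -0.04),
             c(1.26, 1.36, 1.38, 2.13)),
    SER = sc(c("CB", "OG", "HG"), c("C", "O", "H"),
             c(0.45, 0.55, 1.40), c(-0.70, -1.15, -1.35), c(1.26, 2.58, 2.88)),
    THR = sc(c("CB", "OG1", "CG2"), c("C", "O", "C"),
             c(0.45, 1.40, -0.60), c(-0.70, -0.90, -1.25), c(1.26, 2.26, 2.21)),
    VAL = sc(c("CB", "CG1", "CG2"), c("C", "C", "C"),
             c(0.45, 0.50, 1.80), c(-0.70, -1.15, -1.65), c(1.26, 2.71, 1.61)),
    LEU = sc(c("CB", "CG", "CD1", "CD2"), c("C", "C", "C", "C"),
             c(0.45, 0.45, 1.70, -0.85), c(-0.70, -1.20, -1.65, -1.60),
             c(1.26, 2.71, 3.36, 3.31)),
    ASP = sc(c("CB", "CG", "OD1", "OD2"), c("C", "C", "O", "O"),
             c(0.45, 0.45, 1.55, -0.65), c(-0.70, -1.20, -1.50, -1.55),
             c(1.26, 2.71, 3.26, 3.21)),
    GLN = sc(c("CB", "CG", "CD", "OE1", "NE2"), c("C", "C", "C", "O", "N"),
             c(0.45, 0.45, 0.45, 1.55, -0.65), c(-0.70, -1.20, -1.65, -1.90, -1.95),
             c(1.26, 2.71, 4.16, 4.61, 4.61)),
    ARG = sc(c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
             c("C", "C", "C", "N", "C", "N", "N"),
             c(0.45, 0.45, 0.45, 0.45, 0.45, 1.60, -0.70),
             c(-0.70, -1.20, -1.65, -2.05, -2.40, -2.65, -2.65),
             c(1.26, 2.71, 4.16, 5.56, 6.86, 7.31, 7.31)),
    PHE = sc(c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             c("C", "C", "C", "C", "C", "C", "C"),
             c(0.45, 0.45, 1.65, -0.75, 1.65, -0.75, 0.45),
             c(-0.70, -1.20, -1.40, -1.40, -1.80, -1.80, -2.00),
             c(1.26, 2.71, 3.31, 3.31, 4.61, 4.61, 5.11))
  )
}

# contact tip atom (farthest +z side-chain atom used for designed contacts)
.tip_atoms <- c(GLY = "CA", ALA = "CB", SER = "OG", THR = "CG2", VAL = "CG1",
                LEU = "CD1", ASP = "OD1", GLN = "NE2", ARG = "NH1",
                PHE = "CZ")

#' Residue templates available to the fixture generator
#'
#' @return A named list of per-residue atom tibbles (`name`, `element`,
#'   `x`, `y`, `z`).
#' @export
toy_residue_templates <- function() {
  bb <- .backbone_template()
  purrr::map(.sidechain_templates(), function(sc) bind_rows(bb, sc))
}

# per-residue side-chain charge assignments (synthetic values; ALA uses the
# conventional ff14SB charges so its template is realistic)
.sidechain_charges <- list(
  GLY = c(),
  ALA = c(CB = -0.1825, HB1 = 0.0603, HB2 = 0.0603, HB3 = 0.0603),
  SER = c(CB = 0.2271, OG = -0.6546, HG = 0.4275),
  THR = c(CB = 0.35, OG1 = -0.55, CG2 = 0.20),
  VAL = c(CB = -0.05, CG1 = 0.02, CG2 = 0.03),
  LEU = c(CB = -0.06, CG = 0.20, CD1 = -0.07, CD2 = -0.07),
  ASP = c(CB = -0.18, CG = 0.80, OD1 = -0.81, OD2 = -0.81),
  GLN = c(CB = -0.06, CG = 0.00, CD = 0.695, OE1 = -0.608, NE2 = -0.027),
  ARG = c(CB = -0.08, CG = 0.00, CD = 0.09, NE = -0.54, CZ = 0.81,
          NH1 = 0.36, NH2 = 0.36),
  PHE = c(CB = -0.03, CG = 0.03, CD1 = 0.00, CD2 = 0.00, CE1 = 0.00,
          CE2 = 0.00, CZ = 0.00)
)

# element-typed LJ/GB defaults
.element_params <- tibble::tibble(
  element = c("C", "N", "O", "H"),
  lj_epsilon = c(0.1094, 0.1700, 0.2100, 0.0157),
  lj_rmin_half = c(1.9080, 1.8240, 1.6612, 1.3870),
  gb_radius = c(1.70, 1.55, 1.50, 1.20),
  gb_screen = c(0.72, 0.79, 0.85, 0.85)
)

.backbone_charges <- c(N = -0.4157, H = 0.2719, CA = 0.0337, HA = 0.0823,
                       C = 0.5973, O = -0.5679)

#' Toy force-field parameter table covering every template residue
#'
#' One row per (residue, atom) with partial charge, Lennard-Jones well
#' depth and half-minimum distance, intrinsic Born radius and screening
#' factor. Backbone charges follow the conventional alanine values; side
#' chain charges are synthetic but sum to the residue's formal charge
#' (ARG +1, ASP -1, others ~0). Amide hydrogens get the reduced polar-H
#' Lennard-Jones radius.
#'
#' @return A parameter tibble (see [read_parameter_table()] for the format).
#' @export
toy_parameter_table <- function() {
  tmpl <- toy_residue_templates()
  purrr::imap(tmpl, function(atoms, resname) {
    q <- c(.backbone_charges, .sidechain_charges[[resname]])
    tbl <- atoms |>
      left_join(.element_params, by = "element") |>
      mutate(residue_name = resname,
             charge = unname(q[.data$name])) |>
      select("residue_name", atom_name = "name", "charge", "lj_epsilon",
             "lj_rmin_half", "gb_radius", "gb_screen")
    # amide/hydroxyl hydrogens: small polar-H radius
    polar_h <- tbl$atom_name %in% c("H", "HG")
    tbl$lj_rmin_half[polar_h] <- 0.6
    tbl
  }) |> list_rbind()
}
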