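# High-level residue scan driver: interface selection -> truncation ->
# component and entropy evaluation -> tidy contribution table.

#' Residue-wise alanine scan of a protein-peptide complex
#'
#' Runs the full per-residue decomposition for one trajectory: selects the
#' interface (receptor residues within `cutoff` of the ligand; all ligand
#' residues by default), truncates each scannable residue to alanine within
#' the single-trajectory approximation, and evaluates the mutational change
#' of every requested binding-energy component plus the interaction-entropy
#' term. Enthalpy components are evaluated on an equally spaced subsample of
#' at most `enthalpy_frames` frames; the entropy series uses every frame.
#'
#' Components are reported in the positive-equals-favorable sign convention:
#' `dd_g_total = dd_e_vdw + dd_e_ele + dd_g_sol + minus_t_dd_s`, and the
#' per-side binding free energy is the negated sum over scanned residues
#' (see [sum_binding_energy()]). Skipped residues (GLY, PRO, missing CB)
#' carry zero contributions with `scanned = FALSE` and a reason.
#'
#' @param top Parameterized, partitioned [topology()].
#' @param ens An [ensemble()].
#' @param params Parameter table (needed for the ALA template).
#' @param side `"both"` (default), `"receptor"` or `"ligand"`.
#' @param cutoff Interface cutoff in Angstrom (default 5).
#' @param reference_frame Frame for interface selection (default 1).
#' @param enthalpy_frames Enthalpy subsample size (default 100).
#' @param temperature Temperature in K (default 300).
#' @param components Energy components to evaluate: subset of
#'   `c("vdw", "ele", "gb", "sasa")`; components left out are reported as 0.
#' @param sigma_k Entropy noise-filter multiplier (default 3).
#' @param ie_mode Entropy mode, see [residue_entropy()].
#' @param dielectric_override Named numeric vector overriding class
#'   dielectrics, e.g. `c(polar = 2)`.
#' @param sasa_points Sphere points for the surface-area term.
#' @return A tibble of class `ala_scan`, one row per candidate residue.
#' @export
alanine_scan <- function(top, ens, params,
                         side = c("both", "receptor", "ligand"),
                         cutoff = 5, reference_frame = 1,
                         enthalpy_frames = 100, temperature = 300,
                         components = c("vdw", "ele", "gb", "sasa"),
                         sigma_k = 3,
                         ie_mode = c("differenced", "series_difference"),
                         dielectric_override = NULL, sasa_points = 960) {
  side <- match.arg(side)
  ie_mode <- match.arg(ie_mode)
  check_compatible(top, ens)
  iface <- interface_residues(top, ens, cutoff = cutoff,
                              reference_frame = reference_frame)
  targets <- switch(side,
    both = list(receptor = iface$receptor, ligand = iface$ligand),
    receptor = list(receptor = iface$receptor),
    ligand = list(ligand = iface$ligand))

  diel_for <- function(label) {
    if (!is.null(dielectric_override) && label %in% names(dielectric_override)) {
      unname(dielectric_override[[label]])
    } else residue_dielectric(label)
  }

  rows <- purrr::imap(targets, function(res_set, side_label) {
    purrr::map(res_set, function(ri) {
      res <- top$residues[top$residues$residue_index == ri, ]
      cls <- classify_residue(res$name)
      diel <- diel_for(cls$label)
      base <- tibble(
        residue_index = ri, residue_name = res$name, chain = res$chain,
        resno = res$resno, side = side_label, class = cls$label,
        dielectric = diel, scanned = TRUE, reason = NA_character_,
        dd_e_vdw = 0, dd_e_ele = 0, dd_g_sol = 0, minus_t_dd_s = 0,
        dd_g_total = 0, n_frames_enthalpy = 0L, n_frames_entropy = 0L,
        n_outliers_dropped = 0L, ie_half_split = NA_real_
      )
      view <- withCallingHandlers(
        truncate_to_alanine(top, ens, ri, params),
        warning = function(w) invokeRestart("muffleWarning"))
      if (inherits(view, "mutant_skip")) {
        base$scanned <- FALSE
        base$reason <- view$reason
        return(base)
      }
      dd <- residue_ddG_components(top, ens, view, dielectric = diel,
                                   max_frames = enthalpy_frames,
                                   components = components,
                                   sasa_points = sasa_points)
      ent <- residue_entropy(top, ens, view, dielectric = diel,
                             temperature = temperature, k = sigma_k,
                             ie_mode = ie_mode)
      base$dd_e_vdw <- unname(dd$mean[["dd_e_vdw"]])
      base$dd_e_ele <- unname(dd$mean[["dd_e_ele"]])
      base$dd_g_sol <- unname(dd$mean[["dd_g_sol"]])
      base$minus_t_dd_s <- ent$minus_t_dd_s
      base$dd_g_total <- base$dd_e_vdw + base$dd_e_ele + base$dd_g_sol +
        base$minus_t_dd_s
      base$n_frames_enthalpy <- length(dd$frames)
      base$n_frames_entropy <- ent$n_frames
      base$n_outliers_dropped <- ent$n_dropped
      base$ie_half_split <- ent$half_split
      base
    }) |> list_rbind()
  }) |> list_rbind()

  structure(rows, class = c("ala_scan", class(rows)),
            temperature = temperature, components = components,
            cutoff = cutoff, ie_mode = ie_mode)
}

#' Tidy long-format view of a scan's component decomposition
#'
#' @param x An `ala_scan` tibble.
#' @param ... Unused.
#' @return A long tibble with `residue`, `component`, `value`.
#' @export
tidy.ala_scan <- function(x, ...) {
  as_tibble(x) |>
    mutate(residue = paste0(.data$residue_name, .data$resno)) |>
    select("residue", "side", "class", "scanned",
           dd_e_vdw = "dd_e_vdw", dd_e_ele = "dd_e_ele",
           dd_g_sol = "dd_g_sol", minus_t_dd_s = "minus_t_dd_s",
           dd_g_total = "dd_g_total") |>
    tidyr::pivot_longer(cols = dplyr::starts_with(c("dd_", "minus_")),
                        names_to = "component", values_to = "value")
}
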