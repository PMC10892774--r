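# Interaction-entropy estimator and the 3-sigma noise filter.

#' Construct an interaction-energy series
#'
#' @param values Per-frame interaction energies, kcal/mol.
#' @param temperature Temperature in K (default 300).
#' @return An object of class `ie_series`.
#' @export
ie_series <- function(values, temperature = 300) {
  values <- as.numeric(values)
  if (!all(is.finite(values))) abort("interaction energies must be finite")
  if (temperature <= 0) abort("temperature must be positive")
  structure(list(values = values, temperature = temperature,
                 n = length(values)),
            class = "ie_series")
}

#' @export
print.ie_series <- function(x, ...) {
  cat("<ie_series> ", x$n, " frames at ", x$temperature, " K, mean ",
      round(mean(x$values), 4), " kcal/mol, sd ",
      round(stats::sd(x$values), 4), "\n", sep = "")
  invisible(x)
}

#' Interaction entropy of an energy series
#'
#' The entropic penalty `-T dS = kT ln < exp(beta (E - <E>)) >` over the
#' ensemble of frames, with `beta = 1/kT` and `kT = 0.0019872 T` kcal/mol.
#' Evaluated on a log-sum-exp stable path so large fluctuations never
#' overflow. By Jensen's inequality the result is non-negative, and zero
#' exactly for a constant series; it depends only on the fluctuations, not
#' the mean.
#'
#' @param series An [ie_series()] (or numeric vector).
#' @param temperature Temperature in K; defaults to the series temperature.
#' @return `-T dS` in kcal/mol.
#' @export
interaction_entropy <- function(series, temperature = NULL) {
  if (is.numeric(series)) series <- ie_series(series, temperature %||% 300)
  temperature <- temperature %||% series$temperature
  if (series$n < 2) abort("interaction entropy needs at least 2 frames")
  kt <- kT(temperature)
  x <- (series$values - mean(series$values)) / kt
  m <- max(x)
  val <- kt * (m + log(mean(exp(x - m))))
  max(val, 0)
}

#' Single-pass k-sigma outlier filter for an energy series
#'
#' Computes the series mean and standard deviation once and drops every
#' frame deviating by more than `k` standard deviations (default 3, the
#' conventional noise cutoff for the interaction-entropy average). The pass
#' is not iterated, which keeps the filter deterministic.
#'
#' @param series An [ie_series()] (or numeric vector).
#' @param k Cutoff multiplier (default 3).
#' @return A list with the filtered `series`, integer `dropped` frame
#'   indices and `n_dropped`.
#' @export
sigma_filter <- function(series, k = 3) {
  if (is.numeric(series)) series <- ie_series(series)
  if (series$n < 2) abort("sigma filter needs at least 2 frames")
  m <- mean(series$values)
  s <- stats::sd(series$values)
  drop <- if (s > 0) which(abs(series$values - m) > k * s) else integer(0)
  if (length(drop) == series$n) abort("sigma filter dropped every frame")
  kept <- series$values[setdiff(seq_len(series$n), drop)]
  list(series = ie_series(kept, series$temperature),
       dropped = drop, n_dropped = length(drop))
}

#' Per-residue interaction-energy difference series
#'
#' For every frame of the ensemble, the gas-phase interaction energy
#' (van der Waals plus electrostatics at the mutated residue's class
#' dielectric) between receptor and ligand is evaluated for the wild-type
#' view and the alanine-mutant view; the series of differences
#' `E_int(wild) - E_int(mutant)` isolates the scanned side chain's
#' interaction with the partner. The interaction entropy of this differenced
#' series measures the entropic penalty attributable to the residue. All
#' frames are used (no enthalpy-style subsampling).
#'
#' @param top Wild-type parameterized, partitioned [topology()].
#' @param ens Wild-type [ensemble()].
#' @param view A `mutant_view` from [truncate_to_alanine()].
#' @param dielectric Interior dielectric; defaults to the mutated residue's
#'   class dielectric.
#' @param temperature Temperature in K (default 300).
#' @return An [ie_series()] of per-frame differences.
#' @export
residue_interaction_series <- function(top, ens, view, dielectric = NULL,
                                       temperature = 300) {
  check_compatible(top, ens)
  if (inherits(view, "mutant_skip")) {
    abort("cannot evaluate an interaction series for a skipped residue")
  }
  res_name <- top$residues$name[top$residues$residue_index == view$residue_index]
  dielectric <- dielectric %||% classify_residue(res_name)$dielectric
  if (view$identity) {
    return(ie_series(rep(0, n_frames(ens)), temperature))
  }
  rec_w <- side_atoms(top, "receptor")
  lig_w <- side_atoms(top, "ligand")
  rec_m <- side_atoms(view$topology, "receptor")
  lig_m <- side_atoms(view$topology, "ligand")
  vals <- vapply(seq_len(n_frames(ens)), function(f) {
    w <- gas_cross_energy(top, frame_coords(ens, f), rec_w, lig_w, dielectric)
    m <- gas_cross_energy(view$topology, frame_coords(view$ensemble, f),
                          rec_m, lig_m, dielectric)
    sum(w) - sum(m)
  }, numeric(1))
  ie_series(vals, temperature)
}

#' Per-residue entropic contribution with noise filtering
#'
#' Applies the k-sigma filter to the residue's differenced interaction
#' series and returns the entropy component of the residue contribution in
#' the positive-equals-favorable sign convention: the residue's own
#' interaction-energy fluctuation is an entropic penalty, so the component
#' is `-IE(filtered series)` (non-positive, zero for an identity mutation).
#' `ie_mode = "series_difference"` instead forms the difference of the two
#' entropies, `IE(mutant series) - IE(wild series)`, each filtered
#' separately.
#'
#' @inheritParams residue_interaction_series
#' @param k Sigma-filter multiplier (default 3).
#' @param ie_mode `"differenced"` (default) or `"series_difference"`.
#' @return A list with `minus_t_dd_s` (kcal/mol), `n_frames`, `n_dropped`,
#'   and `half_split` (absolute difference of the first- and second-half
#'   estimates, a convergence diagnostic).
#' @export
residue_entropy <- function(top, ens, view, dielectric = NULL,
                            temperature = 300, k = 3,
                            ie_mode = c("differenced", "series_difference")) {
  ie_mode <- match.arg(ie_mode)
  if (ie_mode == "differenced") {
    s <- residue_interaction_series(top, ens, view, dielectric, temperature)
    if (stats::sd(s$values) == 0) {
      return(list(minus_t_dd_s = 0, n_frames = s$n, n_dropped = 0L,
                  half_split = 0))
    }
    f <- sigma_filter(s, k)
    v <- f$series$values
    half <- floor(length(v) / 2)
    hs <- if (half >= 2) {
      abs(interaction_entropy(ie_series(v[seq_len(half)], temperature)) -
            interaction_entropy(ie_series(v[(half + 1):length(v)],
                                          temperature)))
    } else NA_real_
    list(minus_t_dd_s = -interaction_entropy(f$series),
         n_frames = f$series$n, n_dropped = f$n_dropped, half_split = hs)
  } else {
    dielectric <- dielectric %||%
      classify_residue(top$residues$name[
        top$residues$residue_index == view$residue_index])$dielectric
    wt_vals <- raw_interaction_series(top, ens, dielectric)
    if (view$identity) {
      return(list(minus_t_dd_s = 0, n_frames = length(wt_vals),
                  n_dropped = 0L, half_split = 0))
    }
    mt_vals <- raw_interaction_series(view$topology, view$ensemble, dielectric)
    fw <- sigma_filter(ie_series(wt_vals, temperature), k)
    fm <- sigma_filter(ie_series(mt_vals, temperature), k)
    list(minus_t_dd_s = interaction_entropy(fm$series) -
           interaction_entropy(fw$series),
         n_frames = fw$series$n,
         n_dropped = fw$n_dropped + fm$n_dropped, half_split = NA_real_)
  }
}

# per-frame total gas-phase receptor-ligand interaction energy
raw_interaction_series <- function(top, ens, dielectric = 1) {
  rec <- side_atoms(top, "receptor")
  lig <- side_atoms(top, "ligand")
  vapply(seq_len(n_frames(ens)), function(f) {
    sum(gas_cross_energy(top, frame_coords(ens, f), rec, lig, dielectric))
  }, numeric(1))
}
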