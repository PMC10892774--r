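# Assembling per-residue contributions into binding free energies and
# scoring them against experiment.

.scheme_components <- list(
  full = c("dd_e_vdw", "dd_e_ele", "dd_g_sol", "minus_t_dd_s"),
  enthalpy = c("dd_e_vdw", "dd_e_ele", "dd_g_sol"),
  vdw_entropy = c("dd_e_vdw", "minus_t_dd_s"),
  vdw = "dd_e_vdw"
)

#' Binding free energy from per-residue contributions of one side
#'
#' The negated sum of per-residue contributions over the scanned residues of
#' one binding partner: a residue contributing +2 kcal/mol (favorable)
#' lowers the binding free energy by 2 kcal/mol. The component mask selects
#' which decomposition terms enter: `"full"` (all four), `"enthalpy"`
#' (van der Waals + electrostatic + solvation), `"vdw_entropy"`
#' (van der Waals + entropy, the scheme that drops the electrostatic and
#' solvation terms), or an explicit character vector of contribution
#' columns.
#'
#' @param contribs An `ala_scan` contribution tibble (single trajectory).
#' @param side `"receptor"` or `"ligand"`.
#' @param components Mask name or explicit column vector.
#' @return Binding free energy, kcal/mol.
#' @export
sum_binding_energy <- function(contribs, side = c("receptor", "ligand"),
                               components = "full") {
  side <- match.arg(side)
  cols <- if (length(components) == 1 && components %in% names(.scheme_components)) {
    .scheme_components[[components]]
  } else components
  bad <- setdiff(cols, c("dd_e_vdw", "dd_e_ele", "dd_g_sol", "minus_t_dd_s"))
  if (length(bad) > 0) {
    abort(paste0("unknown contribution component(s): ",
                 paste(bad, collapse = ", ")))
  }
  rows <- contribs[contribs$side == side, , drop = FALSE]
  if (nrow(rows) == 0) abort(paste0("no contributions for side: ", side))
  -sum(as.matrix(rows[, cols, drop = FALSE]))
}

#' Average of the receptor-side and ligand-side estimates
#'
#' @param dg_receptor_as,dg_ligand_as Binding free energies from the
#'   receptor-side and ligand-side scans, kcal/mol.
#' @return Their arithmetic mean.
#' @export
average_scheme <- function(dg_receptor_as, dg_ligand_as) {
  stopifnot(is.finite(dg_receptor_as), is.finite(dg_ligand_as))
  (dg_receptor_as + dg_ligand_as) / 2
}

#' Per-scheme binding free energies for one variant
#'
#' Evaluates every scheme on each trajectory's scan: receptor-side
#' (`mhc_as`) and ligand-side (`peptide_as`) full contributions, their
#' average (`average`), the enthalpy-only variants (`dh_*`) and the
#' van der Waals + entropy variants (`vdw_*`, with `vdw_only` the averaged
#' one).
#'
#' @param scans One `ala_scan` tibble or a list of them (one per
#'   trajectory).
#' @param variant Variant label.
#' @return A long tibble `variant, trajectory, scheme, dg` of class
#'   `binding_prediction`.
#' @export
binding_prediction <- function(scans, variant = "WT") {
  if (is.data.frame(scans)) scans <- list(scans)
  rows <- purrr::imap(scans, function(sc, t) {
    has_rec <- any(sc$side == "receptor")
    has_lig <- any(sc$side == "ligand")
    out <- list()
    grab <- function(side, mask) sum_binding_energy(sc, side, mask)
    for (mask in c("full", "enthalpy", "vdw_entropy")) {
      pre <- switch(mask, full = "", enthalpy = "dh_", vdw_entropy = "vdw_")
      r <- if (has_rec) grab("receptor", mask) else NA_real_
      l <- if (has_lig) grab("ligand", mask) else NA_real_
      nm_r <- paste0(pre, "mhc_as"); nm_l <- paste0(pre, "peptide_as")
      if (mask == "full") { nm_r <- "mhc_as"; nm_l <- "peptide_as" }
      out[[nm_r]] <- r
      out[[nm_l]] <- l
      avg_nm <- switch(mask, full = "average", enthalpy = "dh_average",
                       vdw_entropy = "vdw_only")
      out[[avg_nm]] <- if (has_rec && has_lig) average_scheme(r, l) else NA_real_
    }
    tibble(variant = variant, trajectory = t,
           scheme = names(out), dg = unname(unlist(out)))
  }) |> list_rbind()
  structure(filter(rows, !is.na(.data$dg)),
            class = c("binding_prediction", class(rows)))
}

#' Aggregate per-trajectory predictions into mean and spread
#'
#' Unweighted mean and sample standard deviation per variant and scheme.
#' With a single trajectory the standard deviation is reported as 0 and
#' flagged. Trajectories must cover identical variant sets.
#'
#' @param predictions A long tibble `variant, trajectory, scheme, dg`
#'   (rows from [binding_prediction()], possibly several variants bound
#'   together).
#' @return A tibble `variant, scheme, dg_mean, dg_sd, n_trajectories,
#'   sd_defined`.
#' @export
aggregate_trajectories <- function(predictions) {
  if (nrow(predictions) == 0) abort("no predictions to aggregate")
  sets <- predictions |>
    group_by(.data$trajectory) |>
    summarise(vs = list(sort(unique(.data$variant))), .groups = "drop")
  ref <- sets$vs[[1]]
  for (k in seq_len(nrow(sets))) {
    if (!identical(sets$vs[[k]], ref)) {
      abort(sprintf(
        "trajectory %s covers variants {%s} but trajectory %s covers {%s}",
        sets$trajectory[k], paste(sets$vs[[k]], collapse = ","),
        sets$trajectory[1], paste(ref, collapse = ",")))
    }
  }
  predictions |>
    group_by(.data$variant, .data$scheme) |>
    summarise(dg_mean = mean(.data$dg),
              dg_sd = if (n() > 1) stats::sd(.data$dg) else 0,
              n_trajectories = n(),
              sd_defined = n() > 1,
              .groups = "drop")
}

#' Experimental binding free energy from an ID50 ratio
#'
#' `dG_exp = RT ln(ID50)` with `R = 0.0019872` kcal/(mol K). Monotone in
#' ID50 and zero at ID50 = 1.
#'
#' @param id50 Positive dimensionless ID50 value(s).
#' @param temperature Temperature in K (default 300).
#' @return Free energy, kcal/mol.
#' @export
dg_from_id50 <- function(id50, temperature = 300) {
  if (any(id50 <= 0)) abort("ID50 must be positive")
  .kB * temperature * log(id50)
}

#' Read an experimental affinity table
#'
#' Tab-separated with columns `variant`, exactly one of `id50` / `dg_exp`,
#' and optional `temperature` (K, default 300). ID50 values are converted
#' with [dg_from_id50()].
#'
#' @param path File path.
#' @return A tibble `variant, dg_exp, temperature`.
#' @export
read_experiment_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!"variant" %in% names(tbl)) abort("experiment table needs a 'variant' column")
  has_id50 <- "id50" %in% names(tbl)
  has_dg <- "dg_exp" %in% names(tbl)
  if (has_id50 == has_dg) {
    abort("experiment table needs exactly one of 'id50' or 'dg_exp'")
  }
  if (!"temperature" %in% names(tbl)) tbl$temperature <- 300
  if (has_id50) tbl$dg_exp <- dg_from_id50(tbl$id50, tbl$temperature)
  tbl[, c("variant", "dg_exp", "temperature")]
}

#' Correlation of predicted against experimental affinities
#'
#' Pearson correlation on values, Spearman on ranks (average-rank ties) and
#' the least-squares line of predicted on experimental. `mode = "relative"`
#' mean-centers both sides first (for relative-energy comparisons); the
#' correlations are unchanged by centering, the fit intercept is not.
#'
#' @param predictions Tibble with `variant` and a predicted-energy column
#'   (`dg_mean` or `dg`); typically one scheme's rows of an aggregated
#'   prediction table, selected with `scheme`.
#' @param experiments Tibble with `variant` and `dg_exp` (or `id50` +
#'   `temperature`).
#' @param scheme Optional scheme filter applied to `predictions`.
#' @param mode `"absolute"` (default) or `"relative"`.
#' @return An object of class `binding_correlation`; see [glance()] and
#'   [tidy()] methods.
#' @export
correlation_report <- function(predictions, experiments, scheme = NULL,
                               mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  preds <- as_tibble(predictions)
  if (!is.null(scheme)) {
    if (!"scheme" %in% names(preds)) abort("predictions have no 'scheme' column")
    preds <- preds[preds$scheme == scheme, ]
  }
  val_col <- intersect(c("dg_mean", "dg"), names(preds))[1]
  if (is.na(val_col)) abort("predictions need a 'dg' or 'dg_mean' column")
  ex <- as_tibble(experiments)
  if (!"dg_exp" %in% names(ex)) {
    if ("id50" %in% names(ex)) {
      ex$dg_exp <- dg_from_id50(ex$id50, ex$temperature %||% 300)
    } else abort("experiments need 'dg_exp' or 'id50'")
  }
  data <- dplyr::inner_join(
    preds |> select("variant", dg_calc = dplyr::all_of(val_col)),
    ex |> select("variant", "dg_exp"),
    by = "variant")
  if (nrow(data) < 3) abort("need at least 3 paired variants")
  if (stats::sd(data$dg_calc) == 0 || stats::sd(data$dg_exp) == 0) {
    abort("zero variance in predictions or experiments")
  }
  if (mode == "relative") {
    data$dg_calc <- data$dg_calc - mean(data$dg_calc)
    data$dg_exp <- data$dg_exp - mean(data$dg_exp)
  }
  fit <- stats::lm(dg_calc ~ dg_exp, data = data)
  structure(
    list(data = data,
         pearson = stats::cor(data$dg_calc, data$dg_exp),
         spearman = stats::cor(data$dg_calc, data$dg_exp, method = "spearman"),
         fit = fit, mode = mode, scheme = scheme, n = nrow(data)),
    class = "binding_correlation")
}

#' @export
print.binding_correlation <- function(x, ...) {
  cat("<binding_correlation> n = ", x$n,
      if (!is.null(x$scheme)) paste0(", scheme = ", x$scheme),
      ", mode = ", x$mode, "\n",
      "  Pearson r = ", round(x$pearson, 4),
      ", Spearman rho = ", round(x$spearman, 4), "\n",
      "  fit: dg_calc = ", round(coef(x$fit)[2], 4), " * dg_exp + ",
      round(coef(x$fit)[1], 4), "\n", sep = "")
  invisible(x)
}

#' @describeIn correlation_report One-row summary (broom-style).
#' @param x A `binding_correlation`.
#' @param ... Unused.
#' @export
glance.binding_correlation <- function(x, ...) {
  tibble(pearson = x$pearson, spearman = x$spearman,
         slope = unname(coef(x$fit)[2]), intercept = unname(coef(x$fit)[1]),
         r.squared = summary(x$fit)$r.squared, n = x$n, mode = x$mode,
         scheme = x$scheme %||% NA_character_)
}

#' @describeIn correlation_report Paired scatter data (broom-style).
#' @export
tidy.binding_correlation <- function(x, ...) {
  x$data |>
    mutate(residual = stats::residuals(x$fit),
           fitted = stats::fitted(x$fit))
}

#' Seeded bootstrap confidence intervals for the correlations
#'
#' Resamples variant pairs with replacement and reports percentile
#' confidence intervals for the Pearson and Spearman correlations. Fully
#' reproducible given the seed. Degenerate resamples (zero variance in
#' either resampled vector) are redrawn and counted.
#'
#' @param x A `binding_correlation`, or a numeric vector of predictions.
#' @param y Numeric vector of experimental values (when `x` is numeric).
#' @param rounds Bootstrap rounds (>= 100; default 10000).
#' @param seed RNG seed (required).
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per statistic: `estimate`, `lower`,
#'   `upper`, `rounds`, `n_redrawn`.
#' @export
bootstrap_correlation <- function(x, y = NULL, rounds = 10000, seed,
                                  conf = 0.95) {
  if (missing(seed)) abort("bootstrap_correlation requires an explicit seed")
  if (rounds < 100) abort("use at least 100 bootstrap rounds")
  if (inherits(x, "binding_correlation")) {
    a <- x$data$dg_calc; b <- x$data$dg_exp
  } else {
    a <- as.numeric(x); b <- as.numeric(y)
  }
  n <- length(a)
  stopifnot(n == length(b), n >= 3)
  alpha <- (1 - conf) / 2
  res <- withr::with_seed(seed, {
    rp <- numeric(rounds); rs <- numeric(rounds); redrawn <- 0L
    for (k in seq_len(rounds)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (stats::sd(a[idx]) > 0 && stats::sd(b[idx]) > 0) break
        redrawn <- redrawn + 1L
      }
      rp[k] <- stats::cor(a[idx], b[idx])
      rs[k] <- stats::cor(a[idx], b[idx], method = "spearman")
    }
    list(rp = rp, rs = rs, redrawn = redrawn)
  })
  tibble(
    statistic = c("pearson", "spearman"),
    estimate = c(stats::cor(a, b), stats::cor(a, b, method = "spearman")),
    lower = c(quantile(res$rp, alpha, names = FALSE),
              quantile(res$rs, alpha, names = FALSE)),
    upper = c(quantile(res$rp, 1 - alpha, names = FALSE),
              quantile(res$rs, 1 - alpha, names = FALSE)),
    rounds = rounds, n_redrawn = res$redrawn)
}

#' Ranked hotspot table
#'
#' Residues whose mean total contribution exceeds the threshold (default
#' 2 kcal/mol), ranked descending, with the component breakdown retained.
#'
#' @param contribs An `ala_scan` contribution tibble.
#' @param threshold Hotspot threshold, kcal/mol (default 2).
#' @return The filtered, ranked tibble.
#' @export
hotspot_table <- function(contribs, threshold = 2) {
  as_tibble(contribs) |>
    filter(.data$scanned, .data$dd_g_total > threshold) |>
    arrange(desc(.data$dd_g_total)) |>
    mutate(rank = row_number()) |>
    relocate("rank")
}
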