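# Scheme sums, trajectory aggregation, experiment conversion, statistics.

fake_scan <- function(dd, side = "receptor", entropy = NULL) {
  n <- length(dd)
  tibble::tibble(
    residue_index = seq_len(n) - 1L, residue_name = "LEU", chain = "A",
    resno = seq_len(n), side = side, class = "nonpolar", dielectric = 1,
    scanned = TRUE, reason = NA_character_,
    dd_e_vdw = dd * 0.6, dd_e_ele = dd * 0.3, dd_g_sol = dd * 0.1,
    minus_t_dd_s = entropy %||% rep(0, n),
    dd_g_total = dd + (entropy %||% rep(0, n)))
}

test_that("binding energies are negated sums with the right component masks", {
  sc <- fake_scan(c(2, 1, 4))
  expect_equal(sum_binding_energy(sc, "receptor", "full"), -7)
  expect_equal(sum_binding_energy(sc, "receptor", "enthalpy"), -7)
  expect_equal(sum_binding_energy(sc, "receptor", "vdw_entropy"), -7 * 0.6)
  expect_equal(sum_binding_energy(fake_scan(2), "receptor"), -2)
  # five-residue fixture against hand summation
  dd <- c(1.1, -0.4, 2.2, 0.7, 3.0)
  expect_equal(sum_binding_energy(fake_scan(dd), "receptor"), -sum(dd),
               tolerance = 1e-12)
  expect_error(sum_binding_energy(sc, "ligand"), "no contributions")
  expect_error(sum_binding_energy(sc, "receptor", "bogus"), "unknown")
})

test_that("vdW-plus-entropy predictions ignore every charge-driven column", {
  sc <- fake_scan(c(2, 1, 4), entropy = c(-0.2, -0.1, -0.3))
  base <- sum_binding_energy(sc, "receptor", "vdw_entropy")
  perturbed <- sc
  perturbed$dd_e_ele <- rnorm(3, 0, 10)
  perturbed$dd_g_sol <- rnorm(3, 0, 10)
  expect_identical(sum_binding_energy(perturbed, "receptor", "vdw_entropy"),
                   base)
})

test_that("the averaged scheme is exactly the arithmetic mean", {
  expect_equal(average_scheme(-10, -10), -10)
  expect_equal(average_scheme(-8, -12), -10)
  withr::with_seed(77, {
    for (k in 1:50) {
      a <- rnorm(1, -10, 4); b <- rnorm(1, -10, 4)
      expect_equal(average_scheme(a, b), mean(c(a, b)), tolerance = 1e-12)
    }
  })
})

test_that("per-variant predictions satisfy the averaging identity on every scheme", {
  sc <- dplyr::bind_rows(fake_scan(c(2, 1, 4), "receptor",
                                   entropy = c(-0.3, -0.1, -0.2)),
                         fake_scan(c(3, 2), "ligand",
                                   entropy = c(-0.2, -0.4)))
  pred <- binding_prediction(sc, variant = "WT")
  g <- function(s) pred$dg[pred$scheme == s]
  expect_equal(g("average"), (g("mhc_as") + g("peptide_as")) / 2,
               tolerance = 1e-12)
  expect_equal(g("vdw_only"), (g("vdw_mhc_as") + g("vdw_peptide_as")) / 2,
               tolerance = 1e-12)
  expect_equal(g("mhc_as"), g("dh_mhc_as") - sum(c(-0.3, -0.1, -0.2)),
               tolerance = 1e-12)
})

test_that("trajectory aggregation gives mean, spread, and order invariance", {
  sc1 <- fake_scan(3); sc2 <- fake_scan(5)
  pred <- binding_prediction(list(sc1, sc2), variant = "V1")
  agg <- aggregate_trajectories(pred)
  mhc <- agg[agg$scheme == "mhc_as", ]
  expect_equal(mhc$dg_mean, -4)
  expect_equal(mhc$dg_sd, sd(c(-3, -5)))
  # {-9, -11} -> mean -10, sd sqrt(2)
  expect_equal(sd(c(-9, -11)), sqrt(2))
  # single trajectory: sd 0 and flagged
  agg1 <- aggregate_trajectories(binding_prediction(sc1, variant = "V1"))
  expect_true(all(agg1$dg_sd == 0))
  expect_true(all(!agg1$sd_defined))
  # permuting trajectory order changes nothing
  pred_swapped <- binding_prediction(list(sc2, sc1), variant = "V1")
  agg_swapped <- aggregate_trajectories(pred_swapped)
  expect_equal(agg_swapped$dg_mean, agg$dg_mean)
  expect_equal(agg_swapped$dg_sd, agg$dg_sd)
  # mismatched variant sets across trajectories are an error
  bad <- dplyr::bind_rows(
    binding_prediction(sc1, variant = "V1") |> dplyr::mutate(trajectory = 1L),
    binding_prediction(sc1, variant = "V2") |> dplyr::mutate(trajectory = 2L))
  expect_error(aggregate_trajectories(bad), "V2")
})

test_that("ID50 conversion follows RT ln ID50", {
  expect_equal(dg_from_id50(1), 0)
  expect_equal(dg_from_id50(exp(1), 300), 0.0019872 * 300, tolerance = 1e-12)
  x <- c(0.2, 1, 3, 10)
  expect_true(all(diff(dg_from_id50(x)) > 0))
  expect_error(dg_from_id50(0), "positive")
})

test_that("correlations match the textbook formulas on a hand-sized set", {
  pred <- tibble::tibble(variant = paste0("V", 1:5),
                         dg_mean = c(-9.1, -7.4, -8.2, -5.9, -6.6))
  ex <- tibble::tibble(variant = paste0("V", 1:5),
                       dg_exp = c(-8.7, -7.9, -8.5, -6.1, -6.2))
  rep <- correlation_report(pred, ex)
  expect_equal(rep$pearson, oracle_pearson(pred$dg_mean, ex$dg_exp),
               tolerance = 1e-12)
  expect_equal(rep$spearman, oracle_spearman(pred$dg_mean, ex$dg_exp),
               tolerance = 1e-12)
  fit <- coef(rep$fit)
  bx <- sum((ex$dg_exp - mean(ex$dg_exp)) * (pred$dg_mean - mean(pred$dg_mean))) /
    sum((ex$dg_exp - mean(ex$dg_exp))^2)
  expect_equal(unname(fit[2]), bx, tolerance = 1e-12)
  # identity and anti-identity
  same <- correlation_report(
    tibble::tibble(variant = ex$variant, dg_mean = ex$dg_exp), ex)
  expect_equal(same$pearson, 1, tolerance = 1e-12)
  expect_equal(same$spearman, 1, tolerance = 1e-12)
  anti <- correlation_report(
    tibble::tibble(variant = ex$variant, dg_mean = -ex$dg_exp), ex)
  expect_equal(anti$pearson, -1, tolerance = 1e-12)
  # relative mode preserves correlations, centers the fit
  rel <- correlation_report(pred, ex, mode = "relative")
  expect_equal(rel$pearson, rep$pearson, tolerance = 1e-12)
  expect_equal(unname(coef(rel$fit)[1]), 0, tolerance = 1e-10)
  # degenerate inputs
  expect_error(correlation_report(pred[1:2, ], ex), "3 paired")
  flat <- pred; flat$dg_mean <- -7
  expect_error(correlation_report(flat, ex), "variance")
  # broom-style accessors
  gl <- glance(rep)
  expect_equal(gl$pearson, rep$pearson)
  expect_equal(nrow(tidy(rep)), 5)
})

test_that("bootstrap intervals are seeded, reproducible, and collapse for perfect data", {
  x <- c(-9, -8, -7, -6, -5, -4)
  ci1 <- bootstrap_correlation(x, x * 1.3 - 2, rounds = 500, seed = 9)
  expect_equal(ci1$lower, c(1, 1), tolerance = 1e-12)
  expect_equal(ci1$upper, c(1, 1), tolerance = 1e-12)
  withr::with_seed(3, {
    y <- x + rnorm(6, 0, 1)
  })
  a <- bootstrap_correlation(x, y, rounds = 400, seed = 11)
  b <- bootstrap_correlation(x, y, rounds = 400, seed = 11)
  expect_identical(a, b)
  c2 <- bootstrap_correlation(x, y, rounds = 400, seed = 12)
  expect_false(identical(a$lower, c2$lower))
  expect_true(all(a$lower <= a$estimate & a$estimate <= a$upper))
  expect_error(bootstrap_correlation(x, y, rounds = 400), "seed")
  expect_error(bootstrap_correlation(x, y, rounds = 50, seed = 1), "100")
})

test_that("the hotspot table ranks residues above the threshold", {
  sc <- fake_scan(c(0.5, 6, 2.4, 1.9))
  hot <- hotspot_table(sc)
  expect_equal(nrow(hot), 2)
  expect_equal(hot$dd_g_total[1], 6)
  expect_equal(hot$rank, 1:2)
  expect_equal(nrow(hotspot_table(fake_scan(c(0.1, 0.3)))), 0)
  expect_equal(nrow(hotspot_table(sc, threshold = 0)), 4)
  # skipped residues never appear
  sc$scanned[2] <- FALSE
  expect_false(2 %in% hotspot_table(sc)$resno)
})

test_that("experiment tables accept exactly one affinity column", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(variant = c("A", "B"), id50 = c(1, 10)), f)
  tbl <- read_experiment_table(f)
  expect_equal(tbl$dg_exp, dg_from_id50(c(1, 10)))
  readr::write_tsv(tibble::tibble(variant = "A", id50 = 1, dg_exp = 0), f)
  expect_error(read_experiment_table(f), "exactly one")
})
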