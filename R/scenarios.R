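#' Built-in design scenario grids
#'
#' The canonical simulation grid for cluster-randomized three-level trials:
#' subcluster sizes `m` in {20, 50}, subclusters per cluster `n_s` in
#' {4, 8}, small and moderate conditional outcome ICCs
#' `(alpha0, alpha1)` in {(0.015, 0.01), (0.1, 0.05)}, and small, moderate,
#' and large covariate ICCs `(rho0, rho1)` in {(0.15, 0.1), (0.3, 0.15),
#' (0.5, 0.3)} — 24 HTE scenarios (interaction effect 0.1) and 24 ATE
#' scenarios (treatment effect 0.2), all with unit conditional outcome and
#' modifier variances, 5% two-sided tests and 80% target power, plus the two
#' worked examples: a literacy trial with cluster-level randomization
#' (`hali`: `n_s = 4`, `m = 25`, `alpha0 = 0.104`, `alpha1 = 0.008`,
#' `rho0 = 0.2`, `rho1 = 0.1`, standardized interaction effect 0.12) and a
#' fall-prevention trial with subcluster-level randomization (`stride`:
#' `n_s = 8`, `m = 63`, `alpha0 = 0.01`, `alpha1 = 0.005`, `rho0 = 0.1`,
#' binary modifier with prevalence 0.8, effect 0.2).
#'
#' @return A tibble with one row per scenario: `scenario_id`, `estimand`,
#'   `rand_level`, design dimensions, ICCs, variances, `effect`, `type1`,
#'   `target_power`, and the generative fixed effects `beta1..beta4`,
#'   `mu_x`.
#' @export
builtin_scenarios <- function() {
  grid <- tidyr::expand_grid(
    m = c(20L, 50L), n_s = c(4L, 8L),
    icc_y = list(c(0.015, 0.01), c(0.1, 0.05)),
    icc_x = list(c(0.15, 0.10), c(0.30, 0.15), c(0.50, 0.30))
  ) |>
    dplyr::mutate(
      alpha0 = purrr::map_dbl(.data$icc_y, 1L),
      alpha1 = purrr::map_dbl(.data$icc_y, 2L),
      rho0 = purrr::map_dbl(.data$icc_x, 1L),
      rho1 = purrr::map_dbl(.data$icc_x, 2L)
    ) |>
    dplyr::select(-"icc_y", -"icc_x")
  common <- function(g, kind, eff) {
    dplyr::mutate(
      g,
      estimand = kind, rand_level = "cluster", alloc = 0.5,
      sigma2_y = 1, sigma2_x = 1, mu_x = 1, effect = eff, type1 = 0.05,
      target_power = 0.8, beta1 = 1, beta3 = 0.3,
      beta2 = if (kind == "hte") 0.2 else NA_real_,
      beta4 = if (kind == "hte") eff else 0.05,
      scenario_id = paste0(kind, "_m", .data$m, "_ns", .data$n_s,
                           "_a", .data$alpha0, "_r", .data$rho0)
    )
  }
  hte <- common(grid, "hte", 0.1)
  ate <- common(grid, "ate", 0.2) |>
    # ATE generative model: beta2 chosen so beta2 + beta4 * mu_x = effect
    dplyr::mutate(beta2 = .data$effect - .data$beta4 * .data$mu_x)
  examples <- tibble::tibble(
    scenario_id = c("hali", "stride"),
    estimand = "hte",
    rand_level = c("cluster", "subcluster"),
    m = c(25L, 63L), n_s = c(4L, 8L), alloc = 0.5,
    alpha0 = c(0.104, 0.01), alpha1 = c(0.008, 0.005),
    rho0 = c(0.2, 0.1), rho1 = c(0.1, 0.05),
    sigma2_y = 1, sigma2_x = c(1, 0.16), mu_x = c(1, 0.8),
    effect = c(0.12, 0.2), type1 = 0.05, target_power = 0.8,
    beta1 = 1, beta2 = 0.2, beta3 = 0.3, beta4 = c(0.12, 0.2)
  )
  dplyr::bind_rows(hte, ate, examples) |>
    dplyr::relocate("scenario_id", "estimand", "rand_level")
}

#' Analytic and empirical report over a scenario grid
#'
#' For every scenario: computes the unit variance, solves the required
#' number of clusters (even-rounded normal criterion for HTE; iterated
#' between-within t criterion for the ATE under cluster randomization), and
#' records the predicted power at the solved size. With `reps > 0` it also
#' simulates that many trials at the solved size, fits each by REML, and
#' reports empirical size (fitting under the null) and power with Monte
#' Carlo standard errors. Deterministic given `seed`.
#'
#' @param grid A scenario tibble as from [builtin_scenarios()] (any subset
#'   of rows).
#' @param reps Simulated replicates per scenario (0 = analytic columns
#'   only).
#' @param seed Master seed for the empirical columns.
#' @param out Optional CSV path; written with [utils::write.csv()].
#' @param empirical_size Also estimate empirical type I error (doubles the
#'   simulation work).
#' @return A tibble with one row per scenario: `n_c`, `predicted_power`,
#'   and (when `reps > 0`) `emp_power`, `emp_power_se`, optionally
#'   `emp_size`, `emp_size_se`, and failure counts.
#' @export
run_report <- function(grid, reps = 0L, seed = 1L, out = NULL,
                       empirical_size = FALSE) {
  stopifnot(is.data.frame(grid))
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    sc <- dplyr::slice(grid, i)
    o <- outcome_model(sc$sigma2_y, sc$alpha0, sc$alpha1)
    mm <- modifier_model(mu_x = sc$mu_x, sigma2_x = sc$sigma2_x,
                         rho0 = sc$rho0, rho1 = sc$rho1)
    d0 <- design_spec(n_s = sc$n_s, m = sc$m, rand_level = sc$rand_level,
                      alloc = sc$alloc)
    if (sc$estimand == "hte") {
      uv <- hte_unit_variance(d0, o, mm)
      ss <- required_clusters(uv, sc$n_s, sc$m, sc$effect, sc$type1,
                              sc$target_power, sc$alloc, "normal",
                              sc$rand_level)
    } else {
      uv <- ate_unit_variance(d0, o)
      ref <- if (sc$rand_level == "cluster") "t" else "normal"
      ss <- required_clusters(uv, sc$n_s, sc$m, sc$effect, sc$type1,
                              sc$target_power, sc$alloc, ref, sc$rand_level)
    }
    row <- tibble::tibble(
      scenario_id = sc$scenario_id, estimand = sc$estimand,
      rand_level = sc$rand_level, m = sc$m, n_s = sc$n_s,
      alpha0 = sc$alpha0, alpha1 = sc$alpha1, rho0 = sc$rho0,
      rho1 = sc$rho1, effect = sc$effect,
      unit_variance = if (inherits(uv, "variance_result")) uv$unit_variance
      else uv,
      n_c = ss$rounded, predicted_power = ss$achieved_power
    )
    if (reps > 0L) {
      d <- design_spec(ss$rounded, sc$n_s, sc$m, sc$rand_level, sc$alloc)
      beta_alt <- c(sc$beta1, if (sc$estimand == "hte") sc$beta2 else
        sc$effect - sc$beta4 * sc$mu_x, sc$beta3, sc$beta4)
      ref <- if (sc$estimand == "ate" && sc$rand_level == "cluster") "t"
      else "normal"
      oc <- operating_characteristics(d, o, mm, beta_alt, sc$estimand,
                                      reps, seed + i * 10000L,
                                      sc$type1, ref)
      row$emp_power <- oc$power
      row$emp_power_se <- oc$mc_se
      row$power_fail <- oc$n_fail
      if (empirical_size) {
        beta_null <- beta_alt
        if (sc$estimand == "hte") beta_null[4L] <- 0 else {
          beta_null[2L] <- -beta_null[4L] * sc$mu_x # ATE = 0, interaction kept
        }
        ocs <- operating_characteristics(d, o, mm, beta_null, sc$estimand,
                                         reps, seed + i * 10000L + 5000L,
                                         sc$type1, ref)
        row$emp_size <- ocs$power
        row$emp_size_se <- ocs$mc_se
        row$size_fail <- ocs$n_fail
      }
    }
    row
  })
  res <- dplyr::bind_rows(rows)
  if (!is.null(out)) {
    utils::write.csv(res, out, row.names = FALSE, quote = FALSE)
  }
  res
}

#' Round-trip scenario grids through YAML
#'
#' Scenario grids are plain tabular configurations; these helpers serialize
#' them as a YAML list of records and read them back.
#'
#' @param grid A scenario tibble.
#' @param path YAML file path.
#' @return `write_scenarios` returns `path` invisibly; `read_scenarios` the
#'   tibble.
#' @export
write_scenarios <- function(grid, path) {
  recs <- purrr::pmap(grid, function(...) list(...))
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  recs <- yaml::read_yaml(path)
  dplyr::bind_rows(purrr::map(recs, tibble::as_tibble))
}
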