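d_cl <- function(ns = 4, m = 20) design_spec(n_s = ns, m = m,
                                             rand_level = "cluster")

test_that("HTE unit variance reproduces reference values", {
  v <- hte_unit_variance(d_cl(), outcome_model(alpha0 = 0.015, alpha1 = 0.01),
                         modifier_model(rho0 = 0.15, rho1 = 0.10))
  # frozen from the exact expected-information oracle (see oracle test below)
  expect_equal(v$unit_variance, 4.2147173, tolerance = 1e-6)

  # no clustering anywhere: plain interaction variance 1 / (w(1-w) sx2) = 4
  for (lev in c("cluster", "subcluster", "participant")) {
    v0 <- hte_unit_variance(design_spec(n_s = 3, m = 7, rand_level = lev),
                            outcome_model(), modifier_model())
    expect_equal(v0$unit_variance, 4)
    expect_equal(v0$design_effect, 1)
  }

  # cluster-level modifier: design effect collapses to lambda3, matching the
  # ATE design effect scaled by the modifier variance
  o <- outcome_model(alpha0 = 0.1, alpha1 = 0.04)
  vcl <- hte_unit_variance(d_cl(), o,
                           modifier_model(level = "cluster", sigma2_x = 0.5))
  expect_equal(vcl$design_effect, nex_eigen(nex_spec(4, 20, 0.1, 0.04))[[3]])
  expect_equal(vcl$unit_variance,
               ate_unit_variance(d_cl(), o)$unit_variance / 0.5)
})

test_that("design effects follow the printed forms and limits", {
  # participant randomization: theta = lambda1 = 1 - alpha0
  th <- hte_design_effect(design_spec(n_s = 3, m = 5,
                                      rand_level = "participant"),
                          outcome_model(alpha0 = 0.2, alpha1 = 0.05),
                          modifier_model(rho0 = 0.3, rho1 = 0.1))
  expect_equal(th, 0.8)

  # literacy-trial configuration
  th3 <- hte_design_effect(d_cl(4, 25),
                           outcome_model(alpha0 = 0.104, alpha1 = 0.008),
                           modifier_model(rho0 = 0.2, rho1 = 0.1))
  expect_equal(th3, 1.0874, tolerance = 1e-4)

  # large-m limits: theta_(3) and theta_(2) approach (1-a0)/(1-r0)
  o <- outcome_model(alpha0 = 0.104, alpha1 = 0.008)
  mm <- modifier_model(rho0 = 0.2, rho1 = 0.1)
  lim <- (1 - 0.104) / (1 - 0.2)
  expect_equal(hte_design_effect(design_spec(n_s = 4, m = 1e6,
                                             rand_level = "cluster"), o, mm),
               lim, tolerance = 1e-4)
  expect_equal(hte_design_effect(design_spec(n_s = 4, m = 1e6,
                                             rand_level = "subcluster"), o, mm),
               lim, tolerance = 1e-4)
})

test_that("ATE unit variances are the eigenvalue-scaled base variance", {
  o <- outcome_model(alpha0 = 0.015, alpha1 = 0.01)
  expect_equal(ate_unit_variance(d_cl(), o)$unit_variance, 4 * 1.885)
  expect_equal(ate_unit_variance(design_spec(n_s = 4, m = 20,
                                             rand_level = "participant"),
                                 outcome_model())$unit_variance, 4)
  # alpha1 = 0: cluster and subcluster randomization coincide
  o0 <- outcome_model(alpha0 = 0.1, alpha1 = 0)
  expect_equal(
    ate_unit_variance(d_cl(), o0)$unit_variance,
    ate_unit_variance(design_spec(n_s = 4, m = 20,
                                  rand_level = "subcluster"), o0)$unit_variance
  )
})

test_that("binary modifier variance is p(1-p) and maximal at one half", {
  expect_equal(binary_modifier_variance(0.5), 0.25)
  expect_equal(binary_modifier_variance(0.8), 0.16)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_equal(p[which.max(binary_modifier_variance(p))], 0.5)
  expect_error(binary_modifier_variance(0), "strictly inside")
  expect_error(binary_modifier_variance(1.2), "strictly inside")
})

test_that("variance orderings across randomization levels hold", {
  set.seed(13)
  for (i in 1:200) {
    ns <- sample(2:8, 1); m <- sample(2:30, 1)
    ao <- draw_icc(ns, m, 0.3); ax <- draw_icc(ns, m, 0.6)
    o <- outcome_model(alpha0 = ao[["a0"]], alpha1 = ao[["a1"]])
    mm <- modifier_model(rho0 = ax[["a0"]], rho1 = ax[["a1"]])
    v <- vapply(c("cluster", "subcluster", "participant"), function(lev) {
      hte_unit_variance(design_spec(n_s = ns, m = m, rand_level = lev),
                        o, mm)$unit_variance
    }, numeric(1))
    expect_true(v[1] >= v[2] - 1e-10 && v[2] >= v[3] - 1e-10)
    va <- vapply(c("cluster", "subcluster", "participant"), function(lev) {
      ate_unit_variance(design_spec(n_s = ns, m = m, rand_level = lev),
                        o)$unit_variance
    }, numeric(1))
    expect_true(va[1] >= va[2] - 1e-10 && va[2] >= va[3] - 1e-10)
  }
  # equality in the absence of residual clustering
  o0 <- outcome_model()
  mm <- modifier_model(rho0 = 0.3, rho1 = 0.1)
  v <- vapply(c("cluster", "subcluster", "participant"), function(lev) {
    hte_unit_variance(design_spec(n_s = 4, m = 6, rand_level = lev),
                      o0, mm)$unit_variance
  }, numeric(1))
  expect_equal(unname(v), rep(4, 3))
})

test_that("ICC monotonicity relationships hold on parameter grids", {
  grid <- seq(0.02, 0.4, by = 0.02)
  o <- outcome_model(alpha0 = 0.1, alpha1 = 0.05)
  # cluster randomization: nondecreasing in rho0 and rho1
  v_r0 <- vapply(grid, function(r) {
    hte_unit_variance(d_cl(4, 10), o,
                      modifier_model(rho0 = r, rho1 = 0.01))$unit_variance
  }, numeric(1))
  expect_true(all(diff(v_r0) >= -1e-12))
  v_r1 <- vapply(grid / 2, function(r) {
    hte_unit_variance(d_cl(4, 10), o,
                      modifier_model(rho0 = 0.45, rho1 = r))$unit_variance
  }, numeric(1))
  expect_true(all(diff(v_r1) >= -1e-12))
  # subcluster randomization: nondecreasing in rho0, nonincreasing in alpha1
  v2_r0 <- vapply(grid, function(r) {
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "subcluster"),
                      o, modifier_model(rho0 = r, rho1 = 0.01))$unit_variance
  }, numeric(1))
  expect_true(all(diff(v2_r0) >= -1e-12))
  v2_a1 <- vapply(seq(0.005, 0.095, by = 0.005), function(a) {
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "subcluster"),
                      outcome_model(alpha0 = 0.1, alpha1 = a),
                      modifier_model(rho0 = 0.3, rho1 = 0.1))$unit_variance
  }, numeric(1))
  expect_true(all(diff(v2_a1) <= 1e-12))
  # subcluster randomization is free of rho1
  expect_equal(
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "subcluster"),
                      o, modifier_model(rho0 = 0.3, rho1 = 0.0))$unit_variance,
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "subcluster"),
                      o, modifier_model(rho0 = 0.3, rho1 = 0.25))$unit_variance
  )
  # participant randomization: nonincreasing in alpha0, free of the rest
  v1_a0 <- vapply(grid, function(a) {
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "participant"),
                      outcome_model(alpha0 = a, alpha1 = 0.01),
                      modifier_model(rho0 = 0.3, rho1 = 0.1))$unit_variance
  }, numeric(1))
  expect_true(all(diff(v1_a0) <= 1e-12))
  expect_equal(
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "participant"),
                      outcome_model(alpha0 = 0.1, alpha1 = 0.02),
                      modifier_model(rho0 = 0.4, rho1 = 0.3))$unit_variance,
    hte_unit_variance(design_spec(n_s = 4, m = 10, rand_level = "participant"),
                      outcome_model(alpha0 = 0.1, alpha1 = 0.08),
                      modifier_model(rho0 = 0.05, rho1 = 0.01))$unit_variance
  )
})

test_that("HTE and ATE variances coincide when the modifier sits at or above
          the randomization level (unit modifier variance)", {
  o <- outcome_model(alpha0 = 0.12, alpha1 = 0.05)
  # participant randomization: always equal
  expect_equal(
    hte_unit_variance(design_spec(n_s = 3, m = 8, rand_level = "participant"),
                      o, modifier_model(rho0 = 0.3, rho1 = 0.2))$unit_variance,
    ate_unit_variance(design_spec(n_s = 3, m = 8,
                                  rand_level = "participant"), o)$unit_variance
  )
  # subcluster randomization with a subcluster-level modifier
  expect_equal(
    hte_unit_variance(design_spec(n_s = 3, m = 8, rand_level = "subcluster"),
                      o, modifier_model(level = "subcluster",
                                        rho1 = 0.2))$unit_variance,
    ate_unit_variance(design_spec(n_s = 3, m = 8,
                                  rand_level = "subcluster"), o)$unit_variance
  )
  # cluster randomization with a cluster-level modifier
  expect_equal(
    hte_unit_variance(design_spec(n_s = 3, m = 8, rand_level = "cluster"),
                      o, modifier_model(level = "cluster"))$unit_variance,
    ate_unit_variance(design_spec(n_s = 3, m = 8,
                                  rand_level = "cluster"), o)$unit_variance
  )
})

test_that("subcluster-level modifier special case matches the general form", {
  # rho0 = 1 turns the general cluster-randomization formula into
  # ns / (lambda3^{-1} (1 + (ns-1) rho1) + lambda2^{-1} (ns-1)(1-rho1))
  o <- outcome_model(alpha0 = 0.08, alpha1 = 0.03)
  lam <- nex_eigen(nex_spec(4, 6, 0.08, 0.03))
  for (r1 in c(0, 0.2, 0.7)) {
    v <- hte_unit_variance(d_cl(4, 6),
                           o, modifier_model(level = "subcluster", rho1 = r1))
    special <- 4 * 4 / (
      (1 + 3 * r1) / lam[[3]] + 3 * (1 - r1) / lam[[2]])
    expect_equal(v$unit_variance, special, tolerance = 1e-12)
  }
})

test_that("contextual decomposition is exact, orthogonal, and guarded", {
  dat <- make_small_trial(n_c = 4, n_s = 2, m = 3, seed = 5)
  dec <- contextual_decompose(dat)
  expect_equal(dec$x_within + dec$x_subcluster + dec$x_cluster, dat$X)

  # constant modifier: only the cluster column survives
  datc <- dplyr::mutate(dat, X = 2.5)
  decc <- contextual_decompose(datc)
  expect_equal(decc$x_within, rep(0, nrow(datc)))
  expect_equal(decc$x_subcluster, rep(0, nrow(datc)))
  expect_equal(decc$x_cluster, rep(2.5, nrow(datc)))

  # within-cluster orthogonality under balance (exact, per cluster)
  for (cl in unique(dec$cluster)) {
    sub <- dec[dec$cluster == cl, ]
    expect_equal(sum(sub$x_within * sub$x_subcluster), 0, tolerance = 1e-10)
    expect_equal(sum(sub$x_within * sub$x_cluster), 0, tolerance = 1e-10)
    expect_equal(sum(sub$x_subcluster * sub$x_cluster), 0, tolerance = 1e-10)
  }

  expect_error(contextual_decompose(dat[-1, ]), "balanced")
})

test_that("expected-information oracle matches the exact closed forms", {
  set.seed(29)
  for (i in 1:10) {
    ns <- sample(c(2L, 4L), 1); m <- sample(c(2L, 4L, 6L), 1)
    ao <- draw_icc(ns, m, 0.35); ax <- draw_icc(ns, m, 0.5)
    o <- outcome_model(sigma2_y = 1.7, alpha0 = ao[["a0"]], alpha1 = ao[["a1"]])
    mm <- modifier_model(mu_x = 0.7, sigma2_x = 1.3,
                         rho0 = ax[["a0"]], rho1 = ax[["a1"]])
    # cluster-randomized HTE variance: closed form is exact
    d3 <- design_spec(n_s = ns, m = m, rand_level = "cluster")
    expect_equal(gls_unit_variance(d3, o, mm, "hte"),
                 hte_unit_variance(d3, o, mm)$unit_variance,
                 tolerance = 1e-8)
    # ATE variance: exact at every randomization level
    for (lev in c("cluster", "subcluster", "participant")) {
      d <- design_spec(n_s = ns, m = m, rand_level = lev)
      expect_equal(gls_unit_variance(d, o, mm, "ate"),
                   ate_unit_variance(d, o)$unit_variance,
                   tolerance = 1e-8)
    }
  }
})

test_that("subcluster/participant HTE closed forms converge to the oracle as
          randomization units grow", {
  o <- outcome_model(alpha0 = 0.1, alpha1 = 0.04)
  mm <- modifier_model(mu_x = 1, rho0 = 0.3, rho1 = 0.1)
  rel_gap <- function(lev, ns, m) {
    d <- design_spec(n_s = ns, m = m, rand_level = lev)
    cf <- hte_unit_variance(d, o, mm)$unit_variance
    or <- gls_unit_variance(d, o, mm, "hte")
    abs(cf - or) / or
  }
  # the closed forms are design approximations that neglect allocation
  # coupling; the gap shrinks as the number of randomization units grows
  g_sub <- c(rel_gap("subcluster", 2, 4), rel_gap("subcluster", 8, 4),
             rel_gap("subcluster", 32, 4))
  expect_true(all(diff(g_sub) < 0))
  expect_lt(g_sub[3], 0.01)
  g_par <- c(rel_gap("participant", 3, 2), rel_gap("participant", 3, 8),
             rel_gap("participant", 3, 32))
  expect_true(all(diff(g_par) < 0))
  expect_lt(g_par[3], 0.02)
})

test_that("scenario-table verbs append variance columns", {
  tab <- tibble::tibble(n_s = c(4, 8), m = c(20, 50),
                        alpha0 = 0.015, alpha1 = 0.01,
                        rho0 = 0.15, rho1 = 0.10)
  out <- add_hte_variance(tab)
  expect_equal(out$sigma2_hte[1], 4.2147173, tolerance = 1e-6)
  out2 <- add_ate_variance(tab)
  expect_equal(out2$sigma2_ate[1], 7.54)
  expect_error(add_hte_variance(tab[, -1]), "lacks column")
})
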