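#' Unit variance of the heterogeneous-treatment-effect estimator
#'
#' Computes `sigma4^2 = lim n_c n_s m var(beta4_hat)`, the limit variance of
#' the treatment-by-covariate interaction estimator in the linear mixed
#' ANCOVA model, standardized by the total sample size. The result is the
#' variance of the same interaction estimator in an unclustered individually
#' randomized ANCOVA,
#' `sigma2_y / (alloc * (1 - alloc) * sigma2_x)`, multiplied by a design
#' effect that depends on the randomization level:
#'
#' * cluster: `theta = n_s m / (zeta3/lambda3 + (n_s-1) zeta2/lambda2 +
#'   n_s (m-1) zeta1/lambda1)`;
#' * subcluster: `theta = m / (m/lambda1 - (1 + (m-1) rho0) (1/lambda1 -
#'   1/lambda2))`, free of `rho1`;
#' * participant: `theta = lambda1 = 1 - alpha0`, free of all covariate ICCs.
#'
#' Here `lambda` are the outcome-ICC eigenvalues and `zeta` the covariate-ICC
#' eigenvalues of the nested exchangeable structures. When the modifier is
#' measured at the subcluster level (`rho0 = 1`) the cluster-level formula
#' reduces to
#' `n_s / (lambda3^{-1} (1 + (n_s-1) rho1) + lambda2^{-1} (n_s-1)(1-rho1))`,
#' and at the cluster level (`rho0 = rho1 = 1`) to `lambda3`, the same design
#' effect as for the average treatment effect.
#'
#' @param design A [design_spec()] (only `n_s`, `m`, `rand_level`, `alloc`
#'   are used).
#' @param outcome An [outcome_model()].
#' @param modifier A [modifier_model()].
#' @return An object of class `variance_result`: list with `unit_variance`,
#'   `design_effect`, `base_variance`, `eigen_outcome`, `eigen_covariate`,
#'   `estimand = "hte"`, and the echoed inputs. [generics::tidy()] returns it
#'   as a one-row tibble.
#' @examples
#' d <- design_spec(n_s = 4, m = 20, rand_level = "cluster")
#' o <- outcome_model(alpha0 = 0.015, alpha1 = 0.01)
#' x <- modifier_model(rho0 = 0.15, rho1 = 0.10)
#' hte_unit_variance(d, o, x)$unit_variance  # ~ 4.215
#' @export
hte_unit_variance <- function(design, outcome, modifier) {
  stopifnot(inherits(design, "design_spec"), inherits(outcome, "outcome_model"),
            inherits(modifier, "modifier_model"))
  ns <- design$n_s; m <- design$m; wb <- design$alloc
  lam <- icc_eigen(ns, m, outcome$alpha0, outcome$alpha1)
  zet <- icc_eigen(ns, m, modifier$rho0, modifier$rho1)
  check_outcome_eigen(lam)
  check_modifier_eigen(zet)
  theta <- switch(
    design$rand_level,
    cluster = ns * m / (zet[[3L]] / lam[[3L]] +
                          (ns - 1) * zet[[2L]] / lam[[2L]] +
                          ns * (m - 1) * zet[[1L]] / lam[[1L]]),
    subcluster = m / (m / lam[[1L]] -
                        (1 + (m - 1) * modifier$rho0) *
                        (1 / lam[[1L]] - 1 / lam[[2L]])),
    participant = lam[[1L]]
  )
  base <- outcome$sigma2_y / (wb * (1 - wb) * modifier$sigma2_x)
  structure(
    list(unit_variance = base * theta, design_effect = theta,
         base_variance = base, eigen_outcome = lam, eigen_covariate = zet,
         estimand = "hte", design = design, outcome = outcome,
         modifier = modifier),
    class = "variance_result"
  )
}

#' Design effect for the heterogeneous-treatment-effect test
#'
#' The dimensionless factor by which residual clustering inflates (or, when
#' the covariate ICCs are small relative to the outcome ICCs, deflates) the
#' interaction-estimator variance relative to an unclustered design. See
#' [hte_unit_variance()] for the closed forms. As the subcluster size grows,
#' the cluster- and subcluster-randomized design effects for a
#' participant-level modifier share the bounded limit
#' `(1 - alpha0) / (1 - rho0)`.
#'
#' @inheritParams hte_unit_variance
#' @return The design effect (scalar).
#' @export
hte_design_effect <- function(design, outcome, modifier) {
  hte_unit_variance(design, outcome, modifier)$design_effect
}

#' Unit variance of the covariate-adjusted average-treatment-effect estimator
#'
#' Computes `sigma2^2 = lim n_c n_s m var(beta2_hat)` for the
#' covariate-adjusted ATE in the linear mixed ANCOVA with globally
#' mean-centered modifiers. The design effect is a single eigenvalue of the
#' conditional outcome-ICC structure: `lambda3`, `lambda2`, or `lambda1` for
#' cluster-, subcluster-, or participant-level randomization, times the base
#' variance `sigma2_y / (alloc * (1 - alloc))`.
#'
#' @inheritParams hte_unit_variance
#' @return A `variance_result` with `estimand = "ate"`.
#' @examples
#' d <- design_spec(n_s = 4, m = 20, rand_level = "cluster")
#' ate_unit_variance(d, outcome_model(alpha0 = 0.015, alpha1 = 0.01))
#' @export
ate_unit_variance <- function(design, outcome) {
  stopifnot(inherits(design, "design_spec"), inherits(outcome, "outcome_model"))
  lam <- icc_eigen(design$n_s, design$m, outcome$alpha0, outcome$alpha1)
  check_outcome_eigen(lam)
  theta <- switch(design$rand_level,
                  cluster = lam[[3L]], subcluster = lam[[2L]],
                  participant = lam[[1L]])
  base <- outcome$sigma2_y / (design$alloc * (1 - design$alloc))
  structure(
    list(unit_variance = base * theta, design_effect = theta,
         base_variance = base, eigen_outcome = lam, eigen_covariate = NULL,
         estimand = "ate", design = design, outcome = outcome,
         modifier = NULL),
    class = "variance_result"
  )
}

#' @export
print.variance_result <- function(x, ...) {
  cat("Unit variance (", toupper(x$estimand), ", ", x$design$rand_level,
      " randomization): ", signif(x$unit_variance, 6),
      "  [design effect ", signif(x$design_effect, 6), "]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.variance_result <- function(x, ...) {
  tibble::tibble(
    estimand = x$estimand, rand_level = x$design$rand_level,
    n_s = x$design$n_s, m = x$design$m, alloc = x$design$alloc,
    unit_variance = x$unit_variance, design_effect = x$design_effect,
    base_variance = x$base_variance,
    lambda1 = x$eigen_outcome[[1L]], lambda2 = x$eigen_outcome[[2L]],
    lambda3 = x$eigen_outcome[[3L]],
    zeta1 = if (is.null(x$eigen_covariate)) NA_real_ else x$eigen_covariate[[1L]],
    zeta2 = if (is.null(x$eigen_covariate)) NA_real_ else x$eigen_covariate[[2L]],
    zeta3 = if (is.null(x$eigen_covariate)) NA_real_ else x$eigen_covariate[[3L]]
  )
}

#' Add HTE unit variances to a scenario table
#'
#' Data-frame-first wrapper around [hte_unit_variance()]: takes a tibble of
#' design scenarios and appends `sigma2_hte` (unit variance) and `theta_hte`
#' (design effect) columns.
#'
#' @param data A data frame with columns `n_s`, `m`, `alpha0`, `alpha1`,
#'   `rho0`, `rho1`, and optionally `rand_level` (default `"cluster"`),
#'   `alloc` (default 0.5), `sigma2_y` (default 1), `sigma2_x` (default 1).
#' @return The input as a tibble with `sigma2_hte` and `theta_hte` appended.
#' @examples
#' tibble::tibble(n_s = 4, m = 20, alpha0 = 0.015, alpha1 = 0.01,
#'                rho0 = 0.15, rho1 = 0.10) |>
#'   add_hte_variance()
#' @export
add_hte_variance <- function(data) {
  data <- scenario_defaults(data)
  res <- rowwise_pair_dbl(
    data,
    function(row) {
      v <- hte_unit_variance(
        design_spec(n_s = row$n_s, m = row$m, rand_level = row$rand_level,
                    alloc = row$alloc),
        outcome_model(row$sigma2_y, row$alpha0, row$alpha1),
        modifier_model(sigma2_x = row$sigma2_x, rho0 = row$rho0,
                       rho1 = row$rho1)
      )
      c(v$unit_variance, v$design_effect)
    })
  dplyr::mutate(tibble::as_tibble(data),
                sigma2_hte = res[1L, ], theta_hte = res[2L, ])
}

#' Add ATE unit variances to a scenario table
#'
#' @param data A data frame with columns `n_s`, `m`, `alpha0`, `alpha1`, and
#'   optionally `rand_level`, `alloc`, `sigma2_y` (defaults as in
#'   [add_hte_variance()]).
#' @return The input as a tibble with `sigma2_ate` and `theta_ate` appended.
#' @export
add_ate_variance <- function(data) {
  data <- scenario_defaults(data, need_modifier = FALSE)
  res <- rowwise_pair_dbl(
    data,
    function(row) {
      v <- ate_unit_variance(
        design_spec(n_s = row$n_s, m = row$m, rand_level = row$rand_level,
                    alloc = row$alloc),
        outcome_model(row$sigma2_y, row$alpha0, row$alpha1)
      )
      c(v$unit_variance, v$design_effect)
    })
  dplyr::mutate(tibble::as_tibble(data),
                sigma2_ate = res[1L, ], theta_ate = res[2L, ])
}

# fill in the optional scenario columns with their conventional defaults
scenario_defaults <- function(data, need_modifier = TRUE) {
  stopifnot(is.data.frame(data))
  need <- c("n_s", "m", "alpha0", "alpha1",
            if (need_modifier) c("rho0", "rho1"))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("scenario table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"rand_level" %in% names(data)) data$rand_level <- "cluster"
  if (!"alloc" %in% names(data)) data$alloc <- 0.5
  if (!"sigma2_y" %in% names(data)) data$sigma2_y <- 1
  if (need_modifier && !"sigma2_x" %in% names(data)) data$sigma2_x <- 1
  data
}

# row-wise apply returning a 2 x nrow matrix; avoids tidy-eval name clashes
# with columns the caller may carry
rowwise_pair_dbl <- function(data, f) {
  vapply(seq_len(nrow(data)), function(i) f(dplyr::slice(data, i)),
         numeric(2L))
}

#' Contextual decomposition of a participant-level modifier
#'
#' Splits a participant-level covariate into three orthogonal (under
#' balance) components: the within-subcluster deviation `x_within`, the
#' subcluster-mean deviation from the cluster mean `x_subcluster`, and the
#' cluster mean `x_cluster`. The three columns sum to the original values,
#' enabling separate interaction terms for participant-, subcluster-, and
#' cluster-level effect modification (contextual effects).
#'
#' @param data A balanced long-format data frame with columns `cluster`,
#'   `subcluster`, and the modifier column named by `x`.
#' @param x Name of the modifier column (string).
#' @return The input tibble with `x_within`, `x_subcluster`, `x_cluster`
#'   appended.
#' @export
contextual_decompose <- function(data, x = "X") {
  stopifnot(is.data.frame(data), x %in% names(data),
            all(c("cluster", "subcluster") %in% names(data)))
  counts <- dplyr::count(data, .data$cluster, .data$subcluster)
  if (length(unique(counts$n)) != 1L ||
      length(unique(table(counts$cluster))) != 1L) {
    stop("contextual decomposition requires balanced data ",
         "(equal subclusters per cluster and participants per subcluster)",
         call. = FALSE)
  }
  xv <- rlang::sym(x)
  data |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(x_cluster = mean(!!xv)) |>
    dplyr::group_by(.data$cluster, .data$subcluster) |>
    dplyr::mutate(x_subcluster = mean(!!xv) - .data$x_cluster,
                  x_within = !!xv - mean(!!xv)) |>
    dplyr::ungroup() |>
    dplyr::relocate("x_within", "x_subcluster", "x_cluster",
                    .after = dplyr::last_col())
}

#' Exact expected-information (GLS) unit variance
#'
#' Dense numeric oracle for the limit variance of the interaction or ATE
#' estimator: builds the working correlation of one cluster, takes the
#' expectation of the per-cluster GLS information `Z' R^{-1} Z` analytically
#' over the Gaussian modifier distribution and exactly over the balanced
#' treatment allocations at the randomized level, inverts it, and scales by
#' the cluster size. For cluster-level randomization (and for the ATE at
#' every level) this agrees with the closed forms to machine precision; for
#' the interaction estimator under subcluster- and participant-level
#' randomization the closed forms neglect allocation coupling terms that
#' vanish as the number of randomization units per enclosing unit grows, so
#' the oracle is the exact reference while the closed forms are the design
#' approximations (see the methods vignette).
#'
#' @inheritParams hte_unit_variance
#' @param estimand `"hte"` (interaction coefficient) or `"ate"` (treatment
#'   main effect).
#' @param max_units Guard: error when `n_s * m` exceeds it (dense algebra).
#' @return The oracle unit variance (scalar).
#' @export
gls_unit_variance <- function(design, outcome, modifier,
                              estimand = c("hte", "ate"), max_units = 400L) {
  estimand <- match.arg(estimand)
  ns <- design$n_s; m <- design$m; wb <- design$alloc
  N <- ns * m
  if (N > max_units) stop("dense oracle limited to n_s * m <= ", max_units)
  k <- switch(design$rand_level, cluster = NA_real_, subcluster = ns,
              participant = m)
  if (!is.na(k) && !is_whole(k * wb)) {
    stop("infeasible exact balance: ", design$rand_level, " count times ",
         "alloc is not an integer", call. = FALSE)
  }
  Q <- nex_inverse(nex_spec(ns, m, outcome$alpha0, outcome$alpha1))
  # the covariate-adjusted ATE is defined under globally mean-centered
  # modifiers; the interaction variance is centering-invariant
  mu <- if (estimand == "ate") 0 else modifier$mu_x
  M <- modifier$sigma2_x * nex_mat_raw(ns, m, modifier$rho0, modifier$rho1) +
    mu^2 # E[x x']
  # second moments of the centered allocation under exact balance:
  # E[w_t] = 0; E[w_t w_t'] = alloc(1-alloc) within a randomization unit and
  # -alloc(1-alloc)/(K-1) across the K units of the enclosing unit (sampling
  # without replacement); all odd-in-w information entries vanish.
  v <- wb * (1 - wb)
  same_sub <- nex_mat_raw(ns, m, 1, 0)
  V <- switch(
    design$rand_level,
    cluster = matrix(v, N, N),
    subcluster = v * same_sub -
      (if (ns > 1) v / (ns - 1) else 0) * (1 - same_sub),
    participant = {
      W <- diag(v, N)
      off <- (if (m > 1) -v / (m - 1) else 0)
      W + off * (same_sub - diag(1, N))
    }
  )
  info <- matrix(0, 4L, 4L)
  info[1L, 1L] <- sum(Q)
  info[1L, 3L] <- info[3L, 1L] <- mu * sum(Q)
  info[3L, 3L] <- sum(Q * M)
  info[2L, 2L] <- sum(Q * V)
  info[2L, 4L] <- info[4L, 2L] <- mu * sum(Q * V)
  info[4L, 4L] <- sum(Q * M * V)
  Sig <- outcome$sigma2_y * solve(info)
  idx <- if (estimand == "hte") 4L else 2L
  N * Sig[idx, idx]
}

# dense nested exchangeable correlation without validity checks
nex_mat_raw <- function(ns, m, a0, a1) {
  n <- ns * m
  R <- matrix(a1, n, n)
  for (j in seq_len(ns)) {
    idx <- ((j - 1L) * m + 1L):(j * m)
    R[idx, idx] <- a0
  }
  diag(R) <- 1
  R
}
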