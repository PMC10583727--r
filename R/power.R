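#' Power of the two-sided Wald test
#'
#' Analytic power for testing a scalar interaction (HTE) or treatment main
#' effect (ATE) with a two-sided Wald test. With standard error
#' `SE = sqrt(unit_variance / (n_c * n_s * m))` the normal-reference power is
#' `pnorm(|effect|/SE - z_{1-alpha/2}) + pnorm(-|effect|/SE - z_{1-alpha/2})`
#' (the second, minor tail is analytically part of a two-sided test and is
#' numerically negligible at design-relevant effect sizes). The
#' between-within `t` reference replaces the normal tail with noncentral-t
#' tail probabilities beyond `t_{1-alpha/2, n_c - 2}`, the small-sample
#' correction used for the ATE under cluster randomization.
#'
#' @param unit_variance Unit variance `sigma4^2` or `sigma2^2` (from
#'   [hte_unit_variance()] / [ate_unit_variance()], their `$unit_variance`,
#'   or a bare number).
#' @param n_c,n_s,m Trial dimensions.
#' @param effect Effect size (interaction slope per unit modifier, or ATE),
#'   nonzero.
#' @param alpha Two-sided type I error rate.
#' @param reference `"normal"` or `"t"` (between-within degrees of freedom
#'   `n_c - 2`; requires `n_c > 2`).
#' @return Power in (0, 1).
#' @examples
#' wald_power(4.2147, n_c = 42, n_s = 4, m = 20, effect = 0.1)  # ~0.806
#' @export
wald_power <- function(unit_variance, n_c, n_s, m, effect, alpha = 0.05,
                       reference = c("normal", "t")) {
  reference <- match.arg(reference)
  if (inherits(unit_variance, "variance_result")) {
    unit_variance <- unit_variance$unit_variance
  }
  stopifnot(unit_variance > 0, n_c > 0, n_s >= 1, m >= 1, alpha > 0,
            alpha < 1)
  se <- sqrt(unit_variance / (n_c * n_s * m))
  ncp <- abs(effect) / se
  if (reference == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  } else {
    if (n_c <= 2) stop("t reference requires n_c > 2", call. = FALSE)
    df <- n_c - 2
    tc <- stats::qt(1 - alpha / 2, df)
    stats::pt(tc, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, df, ncp = ncp)
  }
}

#' Required number of clusters
#'
#' Solves the sample-size inequality
#' `n_c n_s m >= unit_variance (z_{1-alpha/2} + z_{power})^2 / effect^2`
#' for `n_c` under the normal reference, or finds the smallest feasible
#' `n_c` whose noncentral-t power reaches the target under the `"t"`
#' reference (upward integer search: the t criterion is not available in
#' closed form). The real-valued requirement is then rounded up to
#' feasibility: under cluster-level randomization the treated count
#' `n_c * alloc` must be an integer, so with `alloc = 1/2` the result is the
#' smallest even integer at or above the solution; for subcluster- or
#' participant-level randomization any integer `n_c` is feasible.
#'
#' @inheritParams wald_power
#' @param power Target power (e.g. 0.8).
#' @param alloc Treated fraction.
#' @param rand_level Randomization level, used only for feasibility rounding.
#' @param max_clusters Search/feasibility cap; exceeding it is an error.
#' @return An object of class `sample_size_result`: list with
#'   `solved_dimension = "n_c"`, `raw_solution`, `rounded`,
#'   `achieved_power`, plus the echoed inputs. [generics::tidy()] gives a
#'   one-row tibble.
#' @examples
#' # ~4.215 unit variance: 41.35 clusters raw, 42 after even rounding
#' required_clusters(4.2147, n_s = 4, m = 20, effect = 0.1)
#' @export
required_clusters <- function(unit_variance, n_s, m, effect, alpha = 0.05,
                              power = 0.8, alloc = 0.5,
                              reference = c("normal", "t"),
                              rand_level = "cluster",
                              max_clusters = 1e6) {
  reference <- match.arg(reference)
  if (inherits(unit_variance, "variance_result")) {
    unit_variance <- unit_variance$unit_variance
  }
  stopifnot(unit_variance > 0, effect != 0, power > 0, power < 1)
  step <- feasibility_step(rand_level, alloc)
  if (reference == "normal") {
    raw <- unit_variance * (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2 /
      (effect^2 * n_s * m)
    rounded <- round_up_feasible(raw, step)
    if (rounded > max_clusters) {
      stop("required clusters ", rounded, " exceeds max_clusters",
           call. = FALSE)
    }
  } else {
    # smallest feasible n_c (> 2 for the t df) reaching the target
    nc <- max(step, round_up_feasible(3, step))
    while (wald_power(unit_variance, nc, n_s, m, effect, alpha, "t") < power) {
      nc <- nc + step
      if (nc > max_clusters) {
        stop("no feasible n_c below max_clusters reaches the target power",
             call. = FALSE)
      }
    }
    rounded <- nc
    raw <- t_raw_solution(unit_variance, n_s, m, effect, alpha, power, rounded)
  }
  ach <- wald_power(unit_variance, rounded, n_s, m, effect, alpha, reference)
  structure(
    list(solved_dimension = "n_c", raw_solution = raw, rounded = rounded,
         achieved_power = ach, unit_variance = unit_variance, n_s = n_s,
         m = m, effect = effect, alpha = alpha, target_power = power,
         alloc = alloc, reference = reference, rand_level = rand_level),
    class = "sample_size_result"
  )
}

# allocation feasibility: the randomized-level count times alloc must be an
# integer; for cluster randomization that constrains n_c itself
feasibility_step <- function(rand_level, alloc) {
  if (rand_level != "cluster") return(1L)
  for (k in 1:1000) if (is_whole(k * alloc)) return(k)
  stop("no feasible cluster count for alloc = ", alloc, call. = FALSE)
}

round_up_feasible <- function(x, step) {
  as.integer(step * ceiling(x / step - 1e-9))
}

# continuous root of the t-based criterion near the integer solution (for
# reporting only); falls back to the normal raw solution if bracketing fails
t_raw_solution <- function(unit_variance, n_s, m, effect, alpha, power, nc_int) {
  f <- function(nc) {
    wald_power(unit_variance, nc, n_s, m, effect, alpha, "t") - power
  }
  lo <- max(2.001, nc_int - 2)
  if (f(lo) > 0) return(lo)
  tryCatch(stats::uniroot(f, c(lo, nc_int + 1e-9))$root,
           error = function(e) nc_int)
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat("Required ", x$solved_dimension, ": ", x$rounded,
      " (raw ", signif(x$raw_solution, 5), ", achieved power ",
      round(x$achieved_power, 3), ", ", x$reference, " reference)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.sample_size_result <- function(x, ...) {
  tibble::tibble(
    solved_dimension = x$solved_dimension, raw_solution = x$raw_solution,
    rounded = x$rounded, achieved_power = x$achieved_power,
    unit_variance = x$unit_variance, effect = x$effect, alpha = x$alpha,
    target_power = x$target_power, reference = x$reference,
    rand_level = x$rand_level
  )
}

#' Solve any one trial dimension for target power
#'
#' Fixes two of `n_c`, `n_s`, `m` and finds the smallest feasible integer
#' value of the third achieving the target power. Because the HTE unit
#' variance itself depends on `n_s` and `m`, the variance is re-evaluated at
#' every candidate. The search is an upward integer scan from 1 (or the
#' smallest feasible value); if power plateaus below the target before
#' `cap` — which happens for HTE designs whose large-`m` design-effect bound
#' `(1 - alpha0)/(1 - rho0)` keeps the variance too large — an
#' "unattainable" error is raised.
#'
#' @param free Which dimension to solve: `"n_c"`, `"n_s"`, or `"m"`.
#' @param design A [design_spec()]; the `free` entry is ignored.
#' @param outcome An [outcome_model()].
#' @param modifier A [modifier_model()] (HTE) or `NULL` for the ATE.
#' @param effect Effect size.
#' @param alpha,power Test size and target power.
#' @param reference `"normal"` or `"t"` (the latter only with
#'   `free = "n_c"`).
#' @param estimand `"hte"` or `"ate"`.
#' @param cap Upper search bound.
#' @return A `sample_size_result` (with `solved_dimension = free`).
#' @export
solve_dimension <- function(free = c("n_c", "n_s", "m"), design, outcome,
                            modifier = NULL, effect, alpha = 0.05,
                            power = 0.8, reference = c("normal", "t"),
                            estimand = c("hte", "ate"), cap = 1e6) {
  free <- match.arg(free)
  reference <- match.arg(reference)
  estimand <- match.arg(estimand)
  uv <- function(ns, m) {
    d <- design_spec(n_s = ns, m = m, rand_level = design$rand_level,
                     alloc = design$alloc)
    if (estimand == "hte") {
      hte_unit_variance(d, outcome, modifier)$unit_variance
    } else {
      ate_unit_variance(d, outcome)$unit_variance
    }
  }
  if (free == "n_c") {
    return(required_clusters(uv(design$n_s, design$m), design$n_s, design$m,
                             effect, alpha, power, design$alloc, reference,
                             design$rand_level, cap))
  }
  if (reference == "t") {
    stop("the between-within t reference solves n_c only", call. = FALSE)
  }
  step <- if ((free == "n_s" && design$rand_level == "subcluster") ||
              (free == "m" && design$rand_level == "participant")) {
    feasibility_step("cluster", design$alloc) # same integrality logic
  } else 1L
  pw <- function(k) {
    ns <- if (free == "n_s") k else design$n_s
    m <- if (free == "m") k else design$m
    wald_power(uv(ns, m), design$n_c, ns, m, effect, alpha, "normal")
  }
  k <- step
  best <- -Inf
  while (k <= cap) {
    p <- tryCatch(pw(k), error = function(e) NA_real_)
    if (!is.na(p)) {
      if (p >= power) {
        return(structure(
          list(solved_dimension = free, raw_solution = k, rounded = k,
               achieved_power = p, unit_variance = uv(
                 if (free == "n_s") k else design$n_s,
                 if (free == "m") k else design$m),
               n_s = if (free == "n_s") k else design$n_s,
               m = if (free == "m") k else design$m, effect = effect,
               alpha = alpha, target_power = power, alloc = design$alloc,
               reference = reference, rand_level = design$rand_level),
          class = "sample_size_result"
        ))
      }
      # detect a plateau: power stops improving meaningfully far from target
      if (k > 1000L && p < power && p - best < 1e-10) {
        stop("target power unattainable: power plateaus at ",
             round(p, 4), " as ", free, " grows", call. = FALSE)
      }
      best <- max(best, p)
    }
    k <- k + step
  }
  stop("target power unattainable below cap = ", cap, call. = FALSE)
}

#' Covariance of multivariate interaction estimators
#'
#' For `p` jointly tested effect modifiers, `Omega4` is the asymptotic
#' covariance of `sqrt(n_c) * beta4_hat`, the `p x p` generalization of
#' `sigma4^2 / (n_s m)`. It is assembled from the block nested exchangeable
#' eigen-matrices of the modifiers (`Z1`, `Z2`, `Z3`; see [nex_block()]) by
#' substituting them for the scalar `zeta` terms in the univariate design
#' formulas:
#' \deqn{\Omega_{4,(3)} = \frac{\sigma^2_{y|x}}{\bar W(1-\bar W)}
#'   \left[\lambda_3^{-1} Z_3 + (n_s-1)\lambda_2^{-1} Z_2 +
#'   n_s(m-1)\lambda_1^{-1} Z_1\right]^{-1}}
#' for cluster randomization, and analogously
#' `[n_s (lambda1^{-1} (m St - K) + lambda2^{-1} K)]^{-1}` with
#' `K = St + (m-1) S0` (subcluster) and `[n_s m lambda1^{-1} St]^{-1}`
#' (participant), where `St`, `S0` are the total and within-subcluster
#' modifier covariance blocks. With `p = 1` each case reduces exactly to the
#' corresponding univariate unit variance divided by `n_s m`.
#'
#' @inheritParams hte_unit_variance
#' @param block A [nex_block()] describing the modifier covariance; its
#'   dimensions must match the design.
#' @return A `p x p` covariance matrix.
#' @export
mv_omega4 <- function(design, outcome, block) {
  stopifnot(inherits(design, "design_spec"), inherits(outcome, "outcome_model"),
            inherits(block, "nex_block"),
            block$n_mid == design$n_s, block$size_low == design$m)
  ns <- design$n_s; m <- design$m; wb <- design$alloc
  lam <- icc_eigen(ns, m, outcome$alpha0, outcome$alpha1)
  check_outcome_eigen(lam)
  D <- switch(
    design$rand_level,
    cluster = block$Z3 / lam[[3L]] + (ns - 1) * block$Z2 / lam[[2L]] +
      ns * (m - 1) * block$Z1 / lam[[1L]],
    subcluster = {
      K <- block$Sigma_total + (m - 1) * block$Sigma_within
      ns * ((m * block$Sigma_total - K) / lam[[1L]] + K / lam[[2L]])
    },
    participant = ns * m * block$Sigma_total / lam[[1L]]
  )
  ev <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev))) {
    vec <- eigen((D + t(D)) / 2, symmetric = TRUE)$vectors[, which.min(ev)]
    stop("singular expected information; deficient modifier direction (",
         paste(signif(vec, 3), collapse = ", "), ")", call. = FALSE)
  }
  outcome$sigma2_y / (wb * (1 - wb)) * solve(D)
}

#' Power of the joint (noncentral chi-square) interaction test
#'
#' The quadratic Wald statistic `n_c beta4' Omega4^{-1} beta4` is compared
#' with the `1 - alpha` quantile of the central chi-square with `p` degrees
#' of freedom; under the alternative it follows a noncentral chi-square with
#' noncentrality `n_c * effect' Omega4^{-1} effect`.
#'
#' @param omega4 Covariance from [mv_omega4()] (or a `1 x 1` matrix /
#'   scalar).
#' @param n_c Number of clusters.
#' @param effect Effect vector of length `p`.
#' @param alpha Type I error rate.
#' @return Power in (0, 1).
#' @export
mv_power <- function(omega4, n_c, effect, alpha = 0.05) {
  omega4 <- as.matrix(omega4)
  p <- length(effect)
  stopifnot(all(dim(omega4) == p), n_c > 0)
  ncp <- n_c * drop(crossprod(effect, solve(omega4, effect)))
  crit <- stats::qchisq(1 - alpha, df = p)
  stats::pchisq(crit, df = p, ncp = ncp, lower.tail = FALSE)
}

#' Required clusters for the joint interaction test
#'
#' Root-solves the noncentral chi-square power equation in `n_c` (the
#' covariance `Omega4` does not depend on `n_c`), then applies the same
#' feasibility rounding as [required_clusters()].
#'
#' @inheritParams mv_power
#' @param power Target power.
#' @param alloc,rand_level Allocation and randomization level (feasibility
#'   rounding).
#' @param cap Upper bracket for the root solve.
#' @return A `sample_size_result`.
#' @export
mv_required_clusters <- function(omega4, effect, alpha = 0.05, power = 0.8,
                                 alloc = 0.5, rand_level = "cluster",
                                 cap = 1e6) {
  f <- function(nc) mv_power(omega4, nc, effect, alpha) - power
  if (f(cap) < 0) {
    stop("target power unattainable below cap = ", cap, call. = FALSE)
  }
  raw <- stats::uniroot(f, c(1e-6, cap), tol = 1e-10)$root
  step <- feasibility_step(rand_level, alloc)
  rounded <- round_up_feasible(raw, step)
  structure(
    list(solved_dimension = "n_c", raw_solution = raw, rounded = rounded,
         achieved_power = mv_power(omega4, rounded, effect, alpha),
         unit_variance = NA_real_, effect = effect, alpha = alpha,
         target_power = power, alloc = alloc, reference = "noncentral_chisq",
         rand_level = rand_level),
    class = "sample_size_result"
  )
}

#' Power contour grid over ICC parameters
#'
#' Evaluates HTE power on a grid of within-subcluster covariate ICC `rho0`
#' and ratio `rho1/rho0` (or outcome ICC `alpha0` and ratio `alpha1/alpha0`)
#' at a fixed design, the sensitivity display used when reported ICC
#' estimates are uncertain. Grid points whose correlation structure is
#' invalid are flagged (`feasible = FALSE`, power `NA`), never dropped.
#'
#' @param design A [design_spec()] with `n_c` set.
#' @param outcome An [outcome_model()].
#' @param modifier A [modifier_model()]; its ICCs are overridden on the grid
#'   when `vary = "covariate"`.
#' @param effect Interaction effect size.
#' @param alpha Type I error rate.
#' @param vary `"covariate"` (grid over `rho0`, `rho1/rho0`) or `"outcome"`
#'   (grid over `alpha0`, `alpha1/alpha0`).
#' @param icc0,ratio Numeric grid vectors for the varied within-subcluster
#'   ICC and the between/within ratio.
#' @return A long tibble: one row per grid point with the varied ICCs, all
#'   fixed inputs echoed, `power`, and `feasible`.
#' @examples
#' d <- design_spec(n_c = 24, n_s = 4, m = 25, rand_level = "cluster")
#' o <- outcome_model(alpha0 = 0.104, alpha1 = 0.008)
#' x <- modifier_model(rho0 = 0.2, rho1 = 0.1)
#' power_contour(d, o, x, effect = 0.12, icc0 = c(0.1, 0.3),
#'               ratio = c(0, 0.5, 1))
#' @export
power_contour <- function(design, outcome, modifier, effect, alpha = 0.05,
                          vary = c("covariate", "outcome"),
                          icc0 = seq(0, 0.5, by = 0.05),
                          ratio = seq(0, 1, by = 0.1)) {
  vary <- match.arg(vary)
  stopifnot(!is.na(design$n_c))
  grid <- tidyr::expand_grid(icc0 = icc0, ratio = ratio)
  res <- purrr::pmap(grid, function(icc0, ratio) {
    o <- outcome; mm <- modifier
    if (vary == "covariate") {
      mm <- modifier_model(level = modifier$level, mu_x = modifier$mu_x,
                           sigma2_x = modifier$sigma2_x, rho0 = icc0,
                           rho1 = icc0 * ratio)
    } else {
      o <- outcome_model(outcome$sigma2_y, alpha0 = icc0,
                         alpha1 = icc0 * ratio)
    }
    tryCatch({
      v <- hte_unit_variance(design, o, mm)
      list(power = wald_power(v, design$n_c, design$n_s, design$m, effect,
                              alpha),
           feasible = TRUE)
    }, error = function(e) list(power = NA_real_, feasible = FALSE))
  })
  dplyr::mutate(
    grid,
    varied = vary,
    n_c = design$n_c, n_s = design$n_s, m = design$m,
    rand_level = design$rand_level, alloc = design$alloc,
    alpha0 = if (vary == "outcome") icc0 else outcome$alpha0,
    alpha1 = if (vary == "outcome") icc0 * ratio else outcome$alpha1,
    rho0 = if (vary == "covariate") icc0 else modifier$rho0,
    rho1 = if (vary == "covariate") icc0 * ratio else modifier$rho1,
    effect = effect, type1 = alpha,
    power = purrr::map_dbl(res, "power"),
    feasible = purrr::map_lgl(res, "feasible")
  )
}
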