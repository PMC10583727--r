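#' Exactly balanced treatment assignment
#'
#' Permutation randomization at the configured level: exactly
#' `n_c * alloc` treated clusters, or `n_s * alloc` treated subclusters in
#' every cluster, or `m * alloc` treated participants in every subcluster.
#'
#' @param design A [design_spec()] with all dimensions set.
#' @return A tibble with columns `cluster`, `subcluster`, `participant`,
#'   `W` (0/1).
#' @export
assign_treatment <- function(design) {
  stopifnot(inherits(design, "design_spec"), !is.na(design$n_c))
  nc <- design$n_c; ns <- design$n_s; m <- design$m; wb <- design$alloc
  k <- switch(design$rand_level, cluster = nc, subcluster = ns,
              participant = m)
  if (!is_whole(k * wb)) {
    stop("infeasible allocation: ", design$rand_level, " count ", k,
         " times alloc ", wb, " is not an integer", call. = FALSE)
  }
  base <- tidyr::expand_grid(cluster = seq_len(nc), subcluster = seq_len(ns),
                             participant = seq_len(m))
  treat_perm <- function(n) {
    w <- rep(0L, n); w[sample.int(n, round(n * wb))] <- 1L; w
  }
  W <- switch(
    design$rand_level,
    cluster = rep(treat_perm(nc), each = ns * m),
    subcluster = as.vector(vapply(seq_len(nc),
                                  function(i) rep(treat_perm(ns), each = m),
                                  integer(ns * m))),
    participant = as.vector(vapply(seq_len(nc * ns),
                                   function(i) treat_perm(m), integer(m)))
  )
  dplyr::mutate(base, W = W)
}

#' Generate nested-correlated effect modifier values
#'
#' Continuous modifiers follow the nested random-effects model
#' `X = mu_x + a_i + b_ij + c_ijk` with
#' `a_i ~ N(0, sigma2_x * rho1)`, `b_ij ~ N(0, sigma2_x * (rho0 - rho1))`,
#' `c_ijk ~ N(0, sigma2_x * (1 - rho0))`, which has marginal variance
#' `sigma2_x` and nested exchangeable correlations `(rho0, rho1)`.
#'
#' Binary modifiers use a shared-response construction: each participant
#' copies a cluster-level Bernoulli(`prevalence`) draw with probability
#' `sqrt(rho1)`, otherwise copies a subcluster-level draw with a probability
#' chosen so the within-subcluster correlation is `rho0`, otherwise draws
#' independently. All draws are Bernoulli(`prevalence`), so the margins are
#' exact and the design formulas (which use second moments only) apply with
#' `sigma2_x = prevalence * (1 - prevalence)`.
#'
#' @param design A [design_spec()] with all dimensions set.
#' @param modifier A [modifier_model()].
#' @return A tibble `cluster`, `subcluster`, `participant`, `X`.
#' @export
generate_modifier <- function(design, modifier) {
  stopifnot(inherits(design, "design_spec"), !is.na(design$n_c),
            inherits(modifier, "modifier_model"))
  nc <- design$n_c; ns <- design$n_s; m <- design$m
  r0 <- modifier$rho0; r1 <- modifier$rho1
  base <- tidyr::expand_grid(cluster = seq_len(nc), subcluster = seq_len(ns),
                             participant = seq_len(m))
  if (modifier$kind == "continuous") {
    v <- modifier$sigma2_x * c(r1, r0 - r1, 1 - r0)
    if (any(v < -1e-12)) {
      stop("negative implied variance component: requires ",
           "0 <= rho1 <= rho0 <= 1", call. = FALSE)
    }
    v <- pmax(v, 0)
    a <- stats::rnorm(nc, 0, sqrt(v[1L]))
    b <- stats::rnorm(nc * ns, 0, sqrt(v[2L]))
    cc <- stats::rnorm(nc * ns * m, 0, sqrt(v[3L]))
    X <- modifier$mu_x + a[base$cluster] +
      b[(base$cluster - 1L) * ns + base$subcluster] + cc
  } else {
    p <- modifier$prevalence
    pc <- sqrt(max(r1, 0))
    ps2 <- (r0 - r1) / (1 - pc)^2
    if (r1 < 0 || r0 < r1 || ps2 > 1 + 1e-12) {
      stop("binary modifier requires 0 <= rho1 <= rho0 and ",
           "(rho0 - rho1) <= (1 - sqrt(rho1))^2", call. = FALSE)
    }
    ps <- sqrt(min(max(ps2, 0), 1))
    clus_draw <- stats::rbinom(nc, 1L, p)
    sub_draw <- stats::rbinom(nc * ns, 1L, p)
    own <- stats::rbinom(nc * ns * m, 1L, p)
    u <- stats::runif(nc * ns * m)
    sub_idx <- (base$cluster - 1L) * ns + base$subcluster
    X <- ifelse(u < pc, clus_draw[base$cluster],
                ifelse(u < pc + (1 - pc) * ps, sub_draw[sub_idx], own))
  }
  dplyr::mutate(base, X = as.numeric(X))
}

#' Generate outcomes from the linear mixed ANCOVA model
#'
#' `Y = beta1 + beta2 W + beta3 X + beta4 W X + gamma_i + u_ij + eps_ijk`
#' with `gamma_i ~ N(0, sigma2_y * alpha1)`,
#' `u_ij ~ N(0, sigma2_y * (alpha0 - alpha1))`,
#' `eps ~ N(0, sigma2_y * (1 - alpha0))`, so the conditional outcome
#' variance is `sigma2_y` with nested ICCs `(alpha0, alpha1)`.
#'
#' @param data A tibble with `cluster`, `subcluster`, `W`, `X` (e.g. the
#'   join of [assign_treatment()] and [generate_modifier()]).
#' @param outcome An [outcome_model()].
#' @param beta Fixed effects `c(beta1, beta2, beta3, beta4)`.
#' @return `data` with a `Y` column appended.
#' @export
generate_outcome <- function(data, outcome, beta) {
  stopifnot(length(beta) == 4L, all(c("cluster", "subcluster", "W", "X")
                                    %in% names(data)))
  v <- outcome$sigma2_y *
    c(outcome$alpha1, outcome$alpha0 - outcome$alpha1, 1 - outcome$alpha0)
  if (any(v < -1e-12)) {
    stop("negative implied variance component: requires ",
         "0 <= alpha1 <= alpha0 <= 1", call. = FALSE)
  }
  v <- pmax(v, 0)
  nc <- max(data$cluster); ns <- max(data$subcluster)
  g <- stats::rnorm(nc, 0, sqrt(v[1L]))
  u <- stats::rnorm(nc * ns, 0, sqrt(v[2L]))
  e <- stats::rnorm(nrow(data), 0, sqrt(v[3L]))
  dplyr::mutate(
    data,
    Y = beta[1L] + beta[2L] * .data$W + beta[3L] * .data$X +
      beta[4L] * .data$W * .data$X + g[.data$cluster] +
      u[(.data$cluster - 1L) * ns + .data$subcluster] + e
  )
}

#' Simulate one three-level trial
#'
#' Convenience wrapper: assigns treatment, draws modifiers, generates
#' outcomes, optionally globally mean-centers the modifier (the
#' parameterization under which the treatment main effect is the
#' covariate-adjusted ATE).
#'
#' @inheritParams assign_treatment
#' @param outcome An [outcome_model()].
#' @param modifier A [modifier_model()].
#' @param beta Fixed effects `c(beta1, beta2, beta3, beta4)`.
#' @param seed Optional integer seed (set before any draws).
#' @param center_x Globally mean-center `X` after generation.
#' @return A tibble `cluster`, `subcluster`, `participant`, `W`, `X`, `Y`.
#' @examples
#' d <- design_spec(6, 4, 20, "cluster")
#' dat <- simulate_trial(d, outcome_model(alpha0 = 0.015, alpha1 = 0.01),
#'                       modifier_model(mu_x = 1, rho0 = 0.15, rho1 = 0.1),
#'                       beta = c(1, 0.2, 0.3, 0.1), seed = 1)
#' @export
simulate_trial <- function(design, outcome, modifier, beta, seed = NULL,
                           center_x = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  dat <- assign_treatment(design)
  dat$X <- generate_modifier(design, modifier)$X
  dat <- generate_outcome(dat, outcome, beta)
  if (center_x) dat$X <- dat$X - mean(dat$X)
  dat
}

#' Marginal (unadjusted) outcome ICC approximation
#'
#' When the modifier is omitted from the analysis, the relevant outcome
#' variance and ICCs are marginal over the modifier. Conditioning on
#' treatment, the modifier contributes
#' `c2 = (b3^2 + b4^2 * alloc * (1 - alloc)) * sigma2_x` with
#' `b3 = beta3 + beta4 * alloc` to the total variance, so
#' `sigma2_y_marginal = sigma2_y + c2`, and the marginal ICCs are the
#' weighted averages `omega * alpha + (1 - omega) * rho` with weight
#' `omega = sigma2_y / sigma2_y_marginal`. This is the quantity needed to
#' apply unadjusted (no-covariate) three-level ATE design formulas under the
#' covariate-generating model, and is exact for cluster-level randomization
#' (treatment constant within clusters).
#'
#' @param outcome An [outcome_model()].
#' @param modifier A [modifier_model()].
#' @param beta3,beta4 Covariate main effect and interaction.
#' @param alloc Treated fraction.
#' @return A list with `omega`, `alpha0_marginal`, `alpha1_marginal`,
#'   `sigma2_y_marginal`.
#' @export
marginal_icc <- function(outcome, modifier, beta3, beta4, alloc = 0.5) {
  b3 <- beta3 + beta4 * alloc
  c2 <- (b3^2 + beta4^2 * alloc * (1 - alloc)) * modifier$sigma2_x
  s2m <- outcome$sigma2_y + c2
  omega <- outcome$sigma2_y / s2m
  list(
    omega = omega,
    alpha0_marginal = omega * outcome$alpha0 + (1 - omega) * modifier$rho0,
    alpha1_marginal = omega * outcome$alpha1 + (1 - omega) * modifier$rho1,
    sigma2_y_marginal = s2m
  )
}

#' Empirical operating characteristics by simulation
#'
#' Simulates `reps` trials, fits the linear mixed ANCOVA by REML to each,
#' applies the requested Wald test, and reports the rejection fraction with
#' its Monte Carlo standard error. Per-replicate seeds are derived from the
#' master seed by a counter (`seed + replicate index`), so any replicate can
#' be reproduced in isolation. Replicates whose REML fit fails to converge
#' are refit once from independence starting values; remaining failures are
#' counted and excluded, never silently dropped.
#'
#' @inheritParams simulate_trial
#' @param test `"hte"` (interaction) or `"ate"` (treatment main effect; the
#'   modifier is globally mean-centered before fitting).
#' @param reps Number of simulated trials.
#' @param seed Master seed (integer).
#' @param alpha Test size.
#' @param reference Reference distribution for the ATE test (`"normal"` or
#'   `"t"` with `n_c - 2` df); the HTE test always uses the standard normal.
#' @return A one-row tibble: `test`, `reps`, `rejections`, `power`, `mc_se`,
#'   `n_fail`, plus the design dimensions.
#' @examples
#' \donttest{
#' d <- design_spec(10, 4, 10, "cluster")
#' operating_characteristics(d, outcome_model(alpha0 = 0.05, alpha1 = 0.01),
#'                           modifier_model(mu_x = 1, rho0 = 0.15, rho1 = 0.1),
#'                           beta = c(1, 0.2, 0.3, 0), test = "hte",
#'                           reps = 50, seed = 42)
#' }
#' @export
operating_characteristics <- function(design, outcome, modifier, beta,
                                      test = c("hte", "ate"), reps, seed,
                                      alpha = 0.05,
                                      reference = c("normal", "t")) {
  test <- match.arg(test)
  reference <- match.arg(reference)
  stopifnot(reps >= 1)
  n_fail <- 0L
  reject <- logical(0L)
  for (r in seq_len(reps)) {
    dat <- simulate_trial(design, outcome, modifier, beta,
                          seed = seed + r, center_x = (test == "ate"))
    fit <- fit_lm_ancova(dat)
    if (!fit$converged) { # one retry from independence starting values
      fit <- fit_lm_ancova(dat, start = c(0, 0))
    }
    if (!fit$converged) {
      n_fail <- n_fail + 1L
      next
    }
    wt <- if (test == "hte") {
      wald_hte(fit)
    } else {
      wald_ate(fit, reference = reference, n_c = design$n_c)
    }
    reject <- c(reject, wt$p_value < alpha)
  }
  n_ok <- length(reject)
  phat <- if (n_ok) mean(reject) else NA_real_
  tibble::tibble(
    test = test, reps = reps, converged = n_ok,
    rejections = sum(reject), power = phat,
    mc_se = if (n_ok) sqrt(phat * (1 - phat) / n_ok) else NA_real_,
    n_fail = n_fail, n_c = design$n_c, n_s = design$n_s, m = design$m,
    rand_level = design$rand_level, alpha = alpha, reference = reference
  )
}

#' Write / read a trial dataset as headered CSV
#'
#' The canonical on-disk form of a simulated trial:
#' `cluster,subcluster,participant,W,X,Y`.
#'
#' @param data A trial tibble.
#' @param path File path.
#' @return `write_trial` returns `path` invisibly; `read_trial` a tibble.
#' @export
write_trial <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
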