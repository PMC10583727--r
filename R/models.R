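#' Trial design specification
#'
#' Dimensions and randomization scheme of a balanced three-level trial:
#' `n_c` clusters, each with `n_s` subclusters of `m` participants.
#' Randomization is at one of three levels with treated fraction `alloc`
#' (exact balance at the randomized level).
#'
#' Integrality of the treated count at the randomized level (`n_c * alloc`,
#' `n_s * alloc`, or `m * alloc`) is checked only when `finalized = TRUE`;
#' during sample-size search intermediate designs may be fractional.
#'
#' @param n_c Number of clusters (may be `NA` while solving for it).
#' @param n_s Subclusters per cluster.
#' @param m Participants per subcluster.
#' @param rand_level `"cluster"`, `"subcluster"`, or `"participant"`.
#' @param alloc Treated fraction in (0, 1); 1/2 gives a balanced design.
#' @param finalized Enforce integral treated counts at the randomized level.
#' @return An object of class `design_spec`.
#' @examples
#' design_spec(n_c = 42, n_s = 4, m = 20, rand_level = "cluster")
#' @export
design_spec <- function(n_c = NA_integer_, n_s, m,
                        rand_level = c("cluster", "subcluster", "participant"),
                        alloc = 0.5, finalized = FALSE) {
  rand_level <- match.arg(rand_level)
  stopifnot(n_s >= 1, m >= 1, alloc > 0, alloc < 1)
  if (finalized) {
    k <- switch(rand_level, cluster = n_c, subcluster = n_s, participant = m)
    if (is.na(k) || !is_whole(k * alloc)) {
      stop("infeasible allocation: ", rand_level, " count times alloc (",
           k, " * ", alloc, ") is not an integer", call. = FALSE)
    }
  }
  structure(list(n_c = n_c, n_s = n_s, m = m, rand_level = rand_level,
                 alloc = alloc),
            class = "design_spec")
}

is_whole <- function(x, tol = 1e-8) abs(x - round(x)) < tol

#' Conditional outcome model parameters
#'
#' Total outcome variance conditional on the effect modifiers,
#' `sigma2_y`, together with the conditional outcome ICCs: `alpha0`
#' (within-subcluster) and `alpha1` (between-subcluster). These determine the
#' variance components of the linear mixed ANCOVA model:
#' cluster `sigma2_y * alpha1`, subcluster `sigma2_y * (alpha0 - alpha1)`,
#' residual `sigma2_y * (1 - alpha0)`.
#'
#' @param sigma2_y Conditional total outcome variance (> 0), outcome units^2.
#' @param alpha0,alpha1 Conditional outcome ICCs.
#' @return An object of class `outcome_model`.
#' @export
outcome_model <- function(sigma2_y = 1, alpha0 = 0, alpha1 = 0) {
  stopifnot(sigma2_y > 0)
  structure(list(sigma2_y = sigma2_y, alpha0 = alpha0, alpha1 = alpha1),
            class = "outcome_model")
}

#' Effect modifier model
#'
#' Measurement level, type, moments, and ICCs of a univariate effect
#' modifier. A subcluster-level modifier is constant within subclusters,
#' which forces `rho0 = 1`; a cluster-level modifier forces
#' `rho0 = rho1 = 1`. A binary modifier has variance `prevalence * (1 -
#' prevalence)`, which overrides `sigma2_x`.
#'
#' @param level Measurement level: `"participant"`, `"subcluster"`, or
#'   `"cluster"`.
#' @param kind `"continuous"` or `"binary"`.
#' @param mu_x Mean of the modifier.
#' @param sigma2_x Marginal variance (> 0); ignored with a message-free
#'   override when `kind = "binary"`.
#' @param rho0,rho1 Within- and between-subcluster covariate ICCs.
#' @param prevalence Bernoulli mean for a binary modifier.
#' @return An object of class `modifier_model`.
#' @examples
#' modifier_model(rho0 = 0.15, rho1 = 0.10)
#' modifier_model(kind = "binary", prevalence = 0.8, rho0 = 0.1)
#' @export
modifier_model <- function(level = c("participant", "subcluster", "cluster"),
                           kind = c("continuous", "binary"),
                           mu_x = 0, sigma2_x = 1, rho0 = 0, rho1 = 0,
                           prevalence = NULL) {
  level <- match.arg(level)
  kind <- match.arg(kind)
  if (kind == "binary") {
    if (is.null(prevalence)) {
      stop("a binary modifier requires `prevalence`", call. = FALSE)
    }
    sigma2_x <- binary_modifier_variance(prevalence)
    mu_x <- prevalence
  }
  if (level == "subcluster") rho0 <- 1
  if (level == "cluster") { rho0 <- 1; rho1 <- 1 }
  stopifnot(sigma2_x > 0)
  structure(list(level = level, kind = kind, mu_x = mu_x,
                 sigma2_x = sigma2_x, rho0 = rho0, rho1 = rho1,
                 prevalence = if (kind == "binary") prevalence else NULL),
            class = "modifier_model")
}

#' Variance of a binary effect modifier
#'
#' For a binary modifier with prevalence `p` the marginal variance is
#' `p * (1 - p)`, maximized at `p = 0.5`; since the interaction variance is
#' inversely proportional to the modifier variance, power for effect
#' modification by a binary trait is highest at prevalence one half.
#'
#' @param prevalence Bernoulli mean in (0, 1).
#' @return `prevalence * (1 - prevalence)`.
#' @export
binary_modifier_variance <- function(prevalence) {
  if (!is.numeric(prevalence) || any(prevalence <= 0) || any(prevalence >= 1)) {
    stop("prevalence must lie strictly inside (0, 1)", call. = FALSE)
  }
  prevalence * (1 - prevalence)
}

# Eigenvalue triple of a nested exchangeable structure without validity
# enforcement: covariate structures may be degenerate (rho0 = 1 makes the
# first eigenvalue exactly zero), which is legitimate for modifiers measured
# at the subcluster or cluster level.
icc_eigen <- function(n_s, m, a0, a1) {
  c(lambda1 = 1 - a0,
    lambda2 = 1 + (m - 1) * a0 - m * a1,
    lambda3 = 1 + (m - 1) * a0 + (n_s - 1) * m * a1)
}

# Outcome eigenvalues must be strictly positive (the working covariance is
# inverted); covariate eigenvalues only nonnegative (PSD suffices).
check_outcome_eigen <- function(ev) {
  bad <- which(ev <= 0)
  if (length(bad)) {
    stop("invalid outcome ICCs: eigenvalue lambda", bad[1L], " = ",
         format(ev[bad[1L]]), " is not positive", call. = FALSE)
  }
  invisible(ev)
}

check_modifier_eigen <- function(ev) {
  bad <- which(ev < -1e-12)
  if (length(bad)) {
    stop("invalid covariate ICCs: eigenvalue zeta", bad[1L], " = ",
         format(ev[bad[1L]]), " is negative", call. = FALSE)
  }
  invisible(ev)
}
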