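#' Nested exchangeable correlation specification
#'
#' A nested exchangeable correlation structure describes a balanced two-stage
#' grouping: `size_low` low-level units (participants) in each of `n_mid`
#' mid-level units (subclusters), all within one top-level unit (cluster).
#' Any two low-level units in the same mid-level unit have correlation
#' `within_corr`; units in different mid-level units of the same top unit
#' have correlation `between_corr`. For outcomes the two correlations are the
#' within- and between-subcluster outcome ICCs; for an effect modifier they
#' are the covariate ICCs.
#'
#' Validity is enforced through positivity of the three distinct eigenvalues
#' of the implied correlation matrix (the necessary and sufficient condition
#' for positive definiteness), not through `0 <= between_corr <= within_corr`.
#' A warning (not an error) is emitted when `between_corr > within_corr`,
#' which is atypical but not algebraically forbidden.
#'
#' @param n_mid Number of mid-level units per top-level unit (e.g. subclusters
#'   per cluster), an integer >= 1.
#' @param size_low Number of low-level units per mid-level unit (e.g.
#'   participants per subcluster), an integer >= 1.
#' @param within_corr Correlation within a mid-level unit (dimensionless).
#' @param between_corr Correlation across mid-level units within the same
#'   top-level unit (dimensionless).
#'
#' @return An object of class `nex_spec`: a list with elements `n_mid`,
#'   `size_low`, `within_corr`, `between_corr`.
#' @examples
#' sp <- nex_spec(n_mid = 4, size_low = 20, within_corr = 0.015,
#'                between_corr = 0.01)
#' nex_eigen(sp)
#' @export
nex_spec <- function(n_mid, size_low, within_corr, between_corr) {
  stopifnot(
    is.numeric(n_mid), length(n_mid) == 1L, n_mid >= 1, n_mid == round(n_mid),
    is.numeric(size_low), length(size_low) == 1L, size_low >= 1,
    size_low == round(size_low),
    is.numeric(within_corr), length(within_corr) == 1L, is.finite(within_corr),
    is.numeric(between_corr), length(between_corr) == 1L, is.finite(between_corr)
  )
  spec <- structure(
    list(n_mid = as.integer(n_mid), size_low = as.integer(size_low),
         within_corr = within_corr, between_corr = between_corr),
    class = "nex_spec"
  )
  ev <- nex_eigen_raw(spec)
  bad <- which(ev <= 0)
  if (length(bad)) {
    stop("invalid correlation structure: eigenvalue lambda", bad[1L],
         " = ", format(ev[bad[1L]]), " is not positive", call. = FALSE)
  }
  if (between_corr > within_corr) {
    warning("between-unit correlation exceeds within-unit correlation; ",
            "structure is valid but atypical", call. = FALSE)
  }
  spec
}

#' @export
print.nex_spec <- function(x, ...) {
  cat("Nested exchangeable correlation: ", x$n_mid, " x ", x$size_low,
      " units, within = ", x$within_corr, ", between = ", x$between_corr,
      "\n", sep = "")
  ev <- nex_eigen(x)
  cat("eigenvalues:", paste(signif(ev, 6), collapse = ", "),
      " (multiplicities", paste(attr(ev, "multiplicities"), collapse = ", "),
      ")\n")
  invisible(x)
}

# eigenvalues without validity checks (used by the validator itself)
nex_eigen_raw <- function(spec) {
  m <- spec$size_low; ns <- spec$n_mid
  a0 <- spec$within_corr; a1 <- spec$between_corr
  c(lambda1 = 1 - a0,
    lambda2 = 1 + (m - 1) * a0 - m * a1,
    lambda3 = 1 + (m - 1) * a0 + (ns - 1) * m * a1)
}

#' Eigenvalues of a nested exchangeable correlation matrix
#'
#' The correlation matrix of one top-level unit has exactly three distinct
#' eigenvalues: `lambda1 = 1 - a0` with multiplicity `n_mid * (size_low - 1)`,
#' `lambda2 = 1 + (size_low - 1) * a0 - size_low * a1` with multiplicity
#' `n_mid - 1`, and
#' `lambda3 = 1 + (size_low - 1) * a0 + (n_mid - 1) * size_low * a1` with
#' multiplicity 1, where `a0`, `a1` are the within and between correlations.
#'
#' @param spec A [nex_spec()].
#' @return A named numeric vector `(lambda1, lambda2, lambda3)` with an
#'   integer attribute `multiplicities`.
#' @export
nex_eigen <- function(spec) {
  stopifnot(inherits(spec, "nex_spec"))
  ev <- nex_eigen_raw(spec)
  attr(ev, "multiplicities") <- c(spec$n_mid * (spec$size_low - 1L),
                                  spec$n_mid - 1L, 1L)
  ev
}

#' Dense nested exchangeable correlation matrix
#'
#' Materializes the `n_mid * size_low` square correlation matrix: unit
#' diagonal, `within_corr` inside each mid-level block, `between_corr`
#' elsewhere. Intended for small structures (testing, REML oracles); all
#' production formulas in the package use the eigenvalue algebra instead.
#'
#' @inheritParams nex_eigen
#' @param max_dim Guard against accidental huge allocations; error if
#'   `n_mid * size_low` exceeds it.
#' @return A symmetric matrix of side `n_mid * size_low`.
#' @export
nex_matrix <- function(spec, max_dim = 5000L) {
  stopifnot(inherits(spec, "nex_spec"))
  n <- spec$n_mid * spec$size_low
  if (n > max_dim) {
    stop("matrix dimension ", n, " exceeds max_dim = ", max_dim, call. = FALSE)
  }
  R <- matrix(spec$between_corr, n, n)
  for (j in seq_len(spec$n_mid)) {
    idx <- ((j - 1L) * spec$size_low + 1L):(j * spec$size_low)
    R[idx, idx] <- spec$within_corr
  }
  diag(R) <- 1
  R
}

#' Explicit inverse of a nested exchangeable correlation matrix
#'
#' Uses the closed form
#' \deqn{R^{-1} = \lambda_1^{-1} I - \frac{\lambda_2-\lambda_1}{m\lambda_1\lambda_2}
#'   I_{n_s}\otimes J_m - \frac{\lambda_3-\lambda_2}{n_s m\lambda_2\lambda_3} J_{n_s m}}
#' with `m = size_low`, `n_s = n_mid`.
#'
#' @inheritParams nex_matrix
#' @return The dense inverse matrix.
#' @export
nex_inverse <- function(spec, max_dim = 5000L) {
  stopifnot(inherits(spec, "nex_spec"))
  n <- spec$n_mid * spec$size_low
  if (n > max_dim) {
    stop("matrix dimension ", n, " exceeds max_dim = ", max_dim, call. = FALSE)
  }
  ev <- nex_eigen(spec)
  m <- spec$size_low; ns <- spec$n_mid
  l1 <- ev[["lambda1"]]; l2 <- ev[["lambda2"]]; l3 <- ev[["lambda3"]]
  out <- diag(1 / l1, n)
  bsub <- (l2 - l1) / (m * l1 * l2)
  btot <- (l3 - l2) / (ns * m * l2 * l3)
  for (j in seq_len(ns)) {
    idx <- ((j - 1L) * m + 1L):(j * m)
    out[idx, idx] <- out[idx, idx] - bsub
  }
  out - btot
}

#' Block nested exchangeable covariance for multivariate effect modifiers
#'
#' For `p` jointly measured effect modifiers, the stacked
#' `n_mid * size_low * p` covariance generalizes the scalar nested
#' exchangeable structure: `Sigma_total` is the covariance of one
#' participant's modifier vector, `Sigma_within` the cross-covariance between
#' two participants in the same subcluster, and `Sigma_between` the
#' cross-covariance between participants in different subclusters of the same
#' cluster.
#'
#' The three block "eigen-matrices", the matrix analogues of the scalar
#' eigenvalues, are
#' `Z1 = Sigma_total - Sigma_within`,
#' `Z2 = Sigma_total + (size_low - 1) Sigma_within - size_low Sigma_between`,
#' `Z3 = Sigma_total + (size_low - 1) Sigma_within +
#'       (n_mid - 1) size_low Sigma_between`;
#' the stacked covariance is positive definite iff all three are.
#'
#' @param Sigma_total,Sigma_within,Sigma_between `p x p` symmetric blocks.
#' @param n_mid,size_low Structure dimensions as in [nex_spec()].
#' @return An object of class `nex_block`: list with the three blocks, the
#'   eigen-matrices `Z1`, `Z2`, `Z3`, and dimensions.
#' @examples
#' # p = 1 reduces to sigma2_x * nex_matrix()
#' b <- nex_block(matrix(2), matrix(2 * 0.3), matrix(2 * 0.1), 2, 3)
#' nex_block_matrix(b)
#' @export
nex_block <- function(Sigma_total, Sigma_within, Sigma_between, n_mid, size_low) {
  Sigma_total <- as.matrix(Sigma_total)
  Sigma_within <- as.matrix(Sigma_within)
  Sigma_between <- as.matrix(Sigma_between)
  p <- nrow(Sigma_total)
  stopifnot(
    ncol(Sigma_total) == p, all(dim(Sigma_within) == p),
    all(dim(Sigma_between) == p),
    isTRUE(all.equal(Sigma_total, t(Sigma_total))),
    n_mid >= 1, size_low >= 1
  )
  m <- as.integer(size_low); ns <- as.integer(n_mid)
  Z1 <- Sigma_total - Sigma_within
  Z2 <- Sigma_total + (m - 1) * Sigma_within - m * Sigma_between
  Z3 <- Sigma_total + (m - 1) * Sigma_within + (ns - 1) * m * Sigma_between
  for (nm in c("Z1", "Z2", "Z3")) {
    Z <- get(nm)
    ev <- eigen((Z + t(Z)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("block structure is not positive definite: eigen-matrix ", nm,
           " has minimum eigenvalue ", format(min(ev)), call. = FALSE)
    }
  }
  structure(
    list(Sigma_total = Sigma_total, Sigma_within = Sigma_within,
         Sigma_between = Sigma_between, Z1 = Z1, Z2 = Z2, Z3 = Z3,
         n_mid = ns, size_low = m, p = p),
    class = "nex_block"
  )
}

#' Dense covariance matrix of a block nested exchangeable structure
#'
#' Assembles the `(n_mid * size_low * p)` square covariance of the stacked
#' modifier vectors via Kronecker products, ordering observations fastest
#' over the `p` coordinates.
#'
#' @param block A [nex_block()].
#' @param max_dim Dimension guard as in [nex_matrix()].
#' @return A dense symmetric matrix.
#' @export
nex_block_matrix <- function(block, max_dim = 5000L) {
  stopifnot(inherits(block, "nex_block"))
  ns <- block$n_mid; m <- block$size_low; p <- block$p
  n <- ns * m * p
  if (n > max_dim) {
    stop("matrix dimension ", n, " exceeds max_dim = ", max_dim, call. = FALSE)
  }
  Im <- diag(m); Jm <- matrix(1, m, m)
  Ins <- diag(ns); Jns <- matrix(1, ns, ns)
  kronecker(Ins, kronecker(Im, block$Sigma_total - block$Sigma_within)) +
    kronecker(Ins, kronecker(Jm, block$Sigma_within - block$Sigma_between)) +
    kronecker(Jns, kronecker(Jm, block$Sigma_between))
}
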