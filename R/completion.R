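#' Parameters for singular value thresholding
#'
#' @param tau Singular-value shrinkage threshold (> 0), or `"auto"` which
#'   resolves to `5 * s` where `s` is the matrix side length — `m + n` for
#'   the heterogeneous system — following the standard recommendation from
#'   the SVT literature (mean dimension for rectangular input).
#' @param delta Gradient step size (> 0), or `"auto"` which resolves to
#'   `s / |Omega|` (i.e. `(m + n) / |Omega|` for the heterogeneous system,
#'   the published choice), or `"auto-literature"` for `1.2 * s^2 /
#'   |Omega|`, the step size recommended in the SVT literature, kept for
#'   comparison.
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the relative residual
#'   `||P_Omega(M - X^k)||_F / ||P_Omega(M)||_F`.
#' @param y0_norm Norm used in the kick-start multiplier: `"spectral"`
#'   (default) or `"frobenius"`.
#' @return An object of class `svt_params`.
#' @export
svt_params <- function(tau = "auto", delta = "auto", max_iter = 500L,
                       tol = 1e-4, y0_norm = c("spectral", "frobenius")) {
  if (!identical(tau, "auto")) stopifnot(is.numeric(tau), tau > 0)
  if (is.character(delta)) {
    if (!delta %in% c("auto", "auto-literature")) {
      stop("delta must be numeric, \"auto\" or \"auto-literature\"")
    }
  } else {
    stopifnot(is.numeric(delta), delta > 0)
  }
  stopifnot(max_iter >= 1L, tol > 0)
  structure(list(tau = tau, delta = delta, max_iter = as.integer(max_iter),
                 tol = tol, y0_norm = match.arg(y0_norm)),
            class = "svt_params")
}

#' Project a matrix onto an observation set
#'
#' Keeps entries whose index is observed and zeroes the rest. Linear and
#' idempotent.
#'
#' @param X Numeric matrix.
#' @param omega Either a logical mask of the same shape as `X`, or a
#'   two-column integer matrix of (row, col) indices.
#' @return Matrix of the same shape as `X`.
#' @export
project_omega <- function(X, omega) {
  mask <- as_omega_mask(omega, dim(X))
  X * mask
}

# Normalize the two accepted omega representations to a logical mask.
as_omega_mask <- function(omega, dims) {
  if (is.logical(omega) && is.matrix(omega)) {
    if (!identical(dim(omega), as.integer(dims))) {
      stop("omega mask shape does not match the matrix")
    }
    return(omega)
  }
  if (is.matrix(omega) && ncol(omega) == 2L) {
    if (nrow(omega) > 0L &&
        (min(omega) < 1L || max(omega[, 1L]) > dims[1L] || max(omega[, 2L]) > dims[2L])) {
      stop("omega index out of range")
    }
    mask <- matrix(FALSE, dims[1L], dims[2L])
    mask[omega] <- TRUE
    return(mask)
  }
  stop("omega must be a logical mask or a two-column index matrix")
}

#' Singular-value soft-thresholding operator
#'
#' Computes the SVD `X = U diag(sigma) V'` and returns
#' `U diag(max(sigma - tau, 0)) V'`, shrinking every singular value toward
#' zero by `tau`. This is the proximal operator of `tau * ||.||_*` (nuclear
#' norm) and never increases the nuclear norm.
#'
#' @param X Numeric matrix with finite entries.
#' @param tau Nonnegative shrinkage threshold.
#' @return Matrix of the same shape as `X`.
#' @export
soft_threshold <- function(X, tau) {
  stopifnot(is.matrix(X), tau >= 0)
  if (!all(is.finite(X))) stop("matrix has non-finite entries")
  sv <- svd(X)
  d <- pmax(sv$d - tau, 0)
  keep <- which(d > 0)
  if (length(keep) == 0L) {
    return(matrix(0, nrow(X), ncol(X), dimnames = dimnames(X)))
  }
  out <- sv$u[, keep, drop = FALSE] %*%
    (d[keep] * t(sv$v[, keep, drop = FALSE]))
  dimnames(out) <- dimnames(X)
  out
}

#' Matrix completion by singular value thresholding
#'
#' Approximately solves the nuclear-norm relaxation
#' `min tau*||X||_* + 1/2*||X||_F^2  s.t.  P_Omega(X) = P_Omega(M)`
#' by the SVT iteration
#' `X^k = D_tau(Y^{k-1})`, `Y^k = Y^{k-1} + delta * P_Omega(M - X^k)`,
#' kick-started at `Y^0 = ceil(tau / (delta * ||P_Omega(M)||)) * delta *
#' P_Omega(M)` (spectral norm by default). Iteration stops when the
#' relative residual on observed entries drops below `tol` or `max_iter`
#' is reached; a residual exceeding ten times its initial value aborts
#' with a divergence error.
#'
#' @param M Numeric matrix (or a `hetero_system`, see [svt_complete()]).
#' @param omega Observation mask or index matrix (see [project_omega()]);
#'   must be nonempty.
#' @param params An [svt_params()] object.
#' @return List with `M_star` (final `X^k`), `iterations`,
#'   `residual_trace`, `converged`.
#' @export
svt <- function(M, omega, params = svt_params()) {
  stopifnot(is.matrix(M))
  if (!all(is.finite(M))) stop("matrix has non-finite entries")
  mask <- as_omega_mask(omega, dim(M))
  n_obs <- sum(mask)
  if (n_obs == 0L) stop("omega is empty; nothing to fit")
  n1 <- nrow(M); n2 <- ncol(M)
  # problem size for the auto rules: the side length for square systems
  # (the (m+n) x (m+n) heterogeneous matrix has size m+n), generalized to
  # the mean dimension for rectangular input
  size <- (n1 + n2) / 2
  tau <- if (identical(params$tau, "auto")) 5 * size else params$tau
  delta <- if (identical(params$delta, "auto")) {
    size / n_obs
  } else if (identical(params$delta, "auto-literature")) {
    1.2 * size^2 / n_obs
  } else {
    params$delta
  }
  PM <- M * mask
  norm_PM_F <- norm(PM, "F")
  norm_PM <- if (params$y0_norm == "spectral") norm(PM, "2") else norm_PM_F
  k0 <- ceiling(tau / (delta * norm_PM))
  Y <- (k0 * delta) * PM
  trace <- numeric(params$max_iter)
  converged <- FALSE
  X <- Y
  for (k in seq_len(params$max_iter)) {
    X <- soft_threshold(Y, tau)
    R <- (M - X) * mask
    resid <- norm(R, "F") / norm_PM_F
    trace[k] <- resid
    if (resid < params$tol) {
      converged <- TRUE
      break
    }
    if (resid > 10 * trace[1L]) {
      stop(sprintf("SVT diverged at iteration %d (relative residual %.3g, initial %.3g); try a smaller delta",
                   k, resid, trace[1L]))
    }
    Y <- Y + delta * R
  }
  iterations <- min(k, params$max_iter)
  list(M_star = X, iterations = iterations,
       residual_trace = trace[seq_len(iterations)], converged = converged,
       tau = tau, delta = delta)
}

#' Complete a heterogeneous kinase-substrate system
#'
#' Runs [svt()] on the block matrix of a `hetero_system` and extracts the
#' kinase-substrate score block. Symmetry of the input matrix and mask is
#' verified, and the completed matrix is checked to be symmetric as well
#' (the iteration preserves symmetry exactly up to floating-point error).
#'
#' @param hs A `hetero_system` from [assemble_hetero()].
#' @param params An [svt_params()] object.
#' @return An object of class `completion_result`: list with `M_star`,
#'   `score_block` (m x n matrix of prediction scores, dimnames from the
#'   system ids), `iterations`, `residual_trace`, `converged`, and the
#'   resolved `tau` and `delta`.
#' @export
svt_complete <- function(hs, params = svt_params()) {
  stopifnot(inherits(hs, "hetero_system"))
  if (max(abs(hs$M - t(hs$M))) > 1e-10) stop("hetero matrix is not symmetric")
  if (!identical(hs$omega, t(hs$omega))) stop("omega mask is not symmetric")
  fit <- svt(hs$M, hs$omega, params)
  asym <- max(abs(fit$M_star - t(fit$M_star)))
  if (asym > 1e-8) {
    stop("completed matrix lost symmetry (max asymmetry ", format(asym), ")")
  }
  score_block <- extract_scores(fit$M_star, hs$m, hs$n)
  dimnames(score_block) <- list(hs$kinase_ids, hs$substrate_ids)
  structure(c(fit["M_star"], list(score_block = score_block),
              fit[c("iterations", "residual_trace", "converged", "tau", "delta")]),
            class = "completion_result")
}

#' Extract the kinase-substrate score block
#'
#' Averages the two off-diagonal blocks of a completed (m+n) x (m+n)
#' matrix: `score(i,j) = (M*(i, m+j) + M*(m+j, i)) / 2`. For an exactly
#' symmetric completion this equals the top-right block; the average makes
#' the extraction invariant under transposition.
#'
#' @param M_star Completed square matrix of dimension m + n.
#' @param m Number of kinases (leading block size).
#' @param n Number of substrates (trailing block size).
#' @return m x n numeric score matrix.
#' @export
extract_scores <- function(M_star, m, n) {
  stopifnot(is.matrix(M_star), nrow(M_star) == m + n, ncol(M_star) == m + n)
  top_right <- M_star[seq_len(m), m + seq_len(n), drop = FALSE]
  bottom_left <- M_star[m + seq_len(n), seq_len(m), drop = FALSE]
  (top_right + t(bottom_left)) / 2
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("completion_result: %d x %d scores; %d iterations; %s (final residual %.3g)\n",
              nrow(x$score_block), ncol(x$score_block), x$iterations,
              if (x$converged) "converged" else "not converged",
              x$residual_trace[length(x$residual_trace)]))
  invisible(x)
}
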