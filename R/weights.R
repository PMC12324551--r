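#' Build the input-fraction-normalised weight matrix
#'
#' Each directed connection's weight is its synapse count divided by the
#' postsynaptic cell's total input synapse count: for presynaptic cell j
#' onto postsynaptic cell i, `w[i, j] = c[i, j] / N[i]` with
#' `N[i] = sum_j c[i, j]` over the retained edges. Rows index postsynaptic
#' cells; a cell with no inputs has an all-zero row. Weights are
#' nonnegative and every row with at least one input sums to 1.
#'
#' @param cn A [connectome].
#' @return An object of class `weight_matrix`: list with `W` (sparse
#'   dgCMatrix, rows = postsynaptic), `order` (cell ids fixing indices),
#'   `input_totals`, `scale_factor` (1 until rescaling) and
#'   `spectral_radius_after` (NA until rescaling).
#' @export
build_weight_matrix <- function(cn) {
  stopifnot(inherits(cn, "connectome"))
  if (nrow(cn$edges) == 0) stop("connectome has no edges", call. = FALSE)
  ids <- cn$cells$id
  n <- length(ids)
  i <- match(cn$edges$post, ids)
  j <- match(cn$edges$pre, ids)
  C <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(cn$edges$count),
                            dims = c(n, n), dimnames = list(ids, ids))
  totals <- Matrix::rowSums(C)
  inv <- ifelse(totals > 0, 1 / totals, 0)
  W <- Matrix::Diagonal(n, inv) %*% C
  dimnames(W) <- list(ids, ids)
  structure(
    list(
      W = methods::as(W, "CsparseMatrix"),
      order = ids,
      input_totals = totals,
      scale_factor = 1,
      spectral_radius_after = NA_real_
    ),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> %d cells, %d nonzero weights, scale_factor %.4g, radius %s\n",
    length(x$order), Matrix::nnzero(x$W), x$scale_factor,
    ifelse(is.na(x$spectral_radius_after), "unset",
           format(x$spectral_radius_after, digits = 6))
  ))
  invisible(x)
}

#' Largest real eigenvalue of a nonnegative matrix
#'
#' For a nonnegative matrix this is the Perron root (equal to the
#' spectral radius and guaranteed real). Computed densely for small
#' matrices and with a sparse Arnoldi solver for larger ones, with a
#' power-iteration fallback if the sparse solver does not converge
#' (e.g. nilpotent matrices, where the result is 0).
#'
#' @param W A square nonnegative matrix (sparse or dense).
#' @return The largest real eigenvalue (>= 0).
#' @export
largest_real_eigenvalue <- function(W) {
  n <- nrow(W)
  if (n <= 600) {
    vals <- eigen(as.matrix(W), only.values = TRUE)$values
    return(max(Re(vals)))
  }
  res <- tryCatch(
    RSpectra::eigs(W, k = 1, which = "LR",
                   opts = list(retvec = FALSE, maxitr = 5000)),
    error = function(e) NULL
  )
  if (!is.null(res) && length(res$values) >= 1 && !is.na(res$values[1])) {
    return(max(Re(res$values)))
  }
  power_iteration_radius(W)
}

# Power-iteration estimate of the spectral radius; converges for
# nonnegative matrices with a dominant eigenvalue, returns ~0 for
# nilpotent ones (iterate collapses to zero).
power_iteration_radius <- function(W, max_iter = 2000, tol = 1e-12) {
  n <- nrow(W)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(W %*% v)
    nrm <- sqrt(sum(v_new^2))
    if (nrm < 1e-300) return(0)
    lambda_new <- nrm
    v <- v_new / nrm
    if (abs(lambda_new - lambda) < tol * max(1, lambda_new)) return(lambda_new)
    lambda <- lambda_new
  }
  lambda
}

#' Rescale the weight matrix for stable linear dynamics
#'
#' Multiplies all weights by a common factor so that the largest real
#' eigenvalue equals `target_radius` (default 0.99), guaranteeing the
#' linear rate dynamics have a finite steady state. Acyclic (nilpotent)
#' graphs have spectral radius 0, which no scaling can move, and their
#' dynamics are already stable: such matrices are returned unchanged with
#' `scale_factor = 1`.
#'
#' @param wm A `weight_matrix` from [build_weight_matrix()].
#' @param target_radius Target largest real eigenvalue (default 0.99).
#' @param tol Radius below which the matrix is treated as nilpotent.
#' @return The rescaled `weight_matrix`; `spectral_radius_after` records
#'   the recomputed post-rescale largest real eigenvalue.
#' @export
rescale_to_stability <- function(wm, target_radius = 0.99, tol = 1e-9) {
  stopifnot(inherits(wm, "weight_matrix"))
  if (any(wm$W@x < 0)) stop("weight matrix has negative entries", call. = FALSE)
  rho <- largest_real_eigenvalue(wm$W)
  if (rho > tol) {
    wm$scale_factor <- target_radius / rho
    wm$W <- wm$W * wm$scale_factor
    wm$spectral_radius_after <- largest_real_eigenvalue(wm$W)
  } else {
    wm$scale_factor <- 1
    wm$spectral_radius_after <- rho
  }
  wm
}
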