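#' Non-negative least squares for many right-hand sides
#'
#' Solves `min ||b_k - A s||^2` subject to `s >= 0` for every column `b_k`
#' of `B`, all sharing the design matrix `A`. For a small number of
#' coefficients (P <= 12, the regime of pure-component estimation, where P
#' is the number of chemical species) the solver works support-wise: the
#' unconstrained full-support solution is accepted where it is already
#' non-negative (making agreement with ordinary least squares exact in
#' that case), and the remaining columns are resolved by enumerating
#' candidate active sets, largest support first, with column-scaled
#' Karush-Kuhn-Tucker checks. This solves all right-hand sides (one per
#' wavelength) in a handful of vectorized linear solves. Degenerate
#' columns, and any problem with P > 12, fall back to the Lawson-Hanson
#' solver in \pkg{pracma}.
#'
#' @param A numeric design matrix, n x P.
#' @param B numeric right-hand-side matrix, n x K (or a length-n vector).
#' @return A P x K matrix of non-negative coefficients.
#' @export
#' @examples
#' A <- matrix(c(1, 0, 0, 1), 2)
#' nnls_multi(A, c(-0.5, 1)) # c(0, 1): negative coefficient clipped
nnls_multi <- function(A, B) {
  A <- as.matrix(A)
  if (is.vector(B)) B <- matrix(B, ncol = 1L)
  B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("A and B must have equal row counts", call. = FALSE)
  P <- ncol(A)
  K <- ncol(B)
  if (P > 12L) {
    out <- vapply(seq_len(K), function(k) pracma::lsqnonneg(A, B[, k])$x,
                  numeric(P))
    return(matrix(out, nrow = P))
  }
  G <- crossprod(A)                    # P x P
  C <- crossprod(A, B)                 # P x K
  d <- sqrt(pmax(diag(G), 0))          # column norms of A
  dmin <- max(min(d), 1e-300)
  bnorm <- sqrt(colSums(B^2))
  S <- matrix(0, P, K)
  unsolved <- rep(TRUE, K)

  # Full support first: where the unconstrained solution is already
  # non-negative it IS the NNLS solution (exact agreement with OLS).
  full <- tryCatch(solve(G, C), error = function(e) NULL)
  if (!is.null(full)) {
    stol <- 1e-11 * bnorm / dmin       # coefficient-scale tolerance
    ok <- colSums(full < rep(-stol, each = P)) == 0L
    if (any(ok)) {
      S[, ok] <- pmax(full[, ok, drop = FALSE], 0)
      unsolved[ok] <- FALSE
    }
  }

  # Empty support: s = 0 is optimal iff the gradient -C is >= 0
  # (|grad_j| is bounded by ||a_j|| * ||b||, hence the scaling).
  if (any(unsolved)) {
    gtol <- 1e-10 * outer(d, bnorm)
    feas0 <- colSums(C > gtol) == 0L & unsolved
    unsolved[feas0] <- FALSE
  }

  # Remaining columns: enumerate proper supports, largest first (the
  # non-degenerate NNLS optimum has maximal support), verifying primal and
  # dual KKT conditions with column-scaled tolerances.
  if (any(unsolved) && P > 1L) {
    for (Fset in .proper_subsets_desc(P)) {
      if (!any(unsolved)) break
      cols <- which(unsolved)
      sol <- tryCatch(solve(G[Fset, Fset, drop = FALSE],
                            C[Fset, cols, drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      sol <- matrix(sol, nrow = length(Fset))
      stol <- 1e-9 * bnorm[cols] / dmin
      ok <- colSums(sol < rep(-stol, each = length(Fset))) == 0L
      if (any(ok)) {
        comp <- setdiff(seq_len(P), Fset)
        g <- G[comp, Fset, drop = FALSE] %*% sol -
          C[comp, cols, drop = FALSE]
        gtol <- 1e-9 * outer(d[comp], bnorm[cols])
        ok <- ok & colSums(g < -gtol) == 0L
      }
      if (!any(ok)) next
      hit <- cols[ok]
      S[Fset, hit] <- pmax(sol[, ok, drop = FALSE], 0)
      unsolved[hit] <- FALSE
    }
  }
  if (any(unsolved)) {
    # Degenerate columns (rank deficiency at the tolerance): defer to the
    # Lawson-Hanson solver.
    for (k in which(unsolved)) S[, k] <- pracma::lsqnonneg(A, B[, k])$x
  }
  S
}

# All proper non-empty subsets of 1:P ordered by decreasing size.
.proper_subsets_desc <- function(P) {
  out <- list()
  for (size in seq(P - 1L, 1L)) {
    cmb <- utils::combn(P, size)
    for (j in seq_len(ncol(cmb))) out[[length(out) + 1L]] <- cmb[, j]
  }
  out
}
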