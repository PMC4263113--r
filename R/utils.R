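# Internal numerical helpers shared across modules.

# Relative tolerance used for every numerical rank / null-space decision.
RANK_RTOL <- 1e-10

#' @noRd
numerical_rank <- function(M, rtol = RANK_RTOL) {
  if (length(M) == 0L) return(0L)
  d <- svd(M, nu = 0, nv = 0)$d
  if (length(d) == 0L || d[1] == 0) return(0L)
  sum(d > rtol * d[1])
}

# Orthonormal basis (columns) of the null space of M.
#' @noRd
null_space <- function(M, rtol = RANK_RTOL) {
  n <- ncol(M)
  if (n == 0L) return(matrix(0, nrow = 0, ncol = 0))
  s <- svd(M, nu = 0, nv = n)
  r <- if (length(s$d) == 0L || s$d[1] == 0) 0L else sum(s$d > rtol * s$d[1])
  if (r == n) return(matrix(0, nrow = n, ncol = 0))
  s$v[, (r + 1L):n, drop = FALSE]
}

# Orthonormal basis (columns) of the column space of M.
#' @noRd
range_space <- function(M, rtol = RANK_RTOL) {
  s <- svd(M)
  r <- if (length(s$d) == 0L || s$d[1] == 0) 0L else sum(s$d > rtol * s$d[1])
  if (r == 0L) return(matrix(0, nrow = nrow(M), ncol = 0))
  U <- s$u[, seq_len(r), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each column is positive
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  U
}

# Turn an orthonormal null-space basis into a human-readable one: Gauss-Jordan
# elimination brings the transposed basis to reduced echelon form, after which
# each vector is rescaled by its smallest nonzero magnitude and snapped to
# integers when all entries are within `itol` of integers.  Falls back to the
# orthonormal basis for vectors that do not integerize.
#' @noRd
nice_basis <- function(V, itol = 1e-8) {
  if (ncol(V) == 0L) return(V)
  R <- t(V)                                   # rows span the space
  nr <- nrow(R); nc <- ncol(R)
  piv <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    i <- which.max(abs(R[row:nr, col])) + row - 1L
    if (abs(R[i, col]) < 1e-12) next
    if (i != row) R[c(i, row), ] <- R[c(row, i), ]
    R[row, ] <- R[row, ] / R[row, col]
    for (j in seq_len(nr)) {
      if (j != row) R[j, ] <- R[j, ] - R[j, col] * R[row, ]
    }
    piv <- c(piv, col)
    row <- row + 1L
  }
  out <- matrix(0, nrow = nc, ncol = ncol(V))
  for (j in seq_len(nrow(R))) {
    v <- R[j, ]
    nz <- abs(v) > 1e-10
    if (!any(nz)) { out[, j] <- V[, j]; next }
    w <- v / min(abs(v[nz]))
    if (all(abs(w - round(w)) < itol * pmax(1, abs(w)))) {
      w <- round(w)
      # leading (first nonzero) entry positive
      if (w[which(w != 0)[1]] < 0) w <- -w
      out[, j] <- w
    } else {
      out[, j] <- v / sqrt(sum(v^2))
    }
  }
  out
}

# Determinant of G after row/column max-norm equilibration, so the value is
# insensitive to the units the concentrations are expressed in.  Returns the
# equilibrated determinant together with a reciprocal condition estimate that
# lets callers tell "small because singular" from "small because ill-scaled".
#' @noRd
equilibrated_det <- function(G) {
  n <- nrow(G)
  r <- apply(abs(G), 1, max)
  r[r == 0] <- 1
  Gs <- G / r
  cs <- apply(abs(Gs), 2, max)
  cs[cs == 0] <- 1
  Gs <- sweep(Gs, 2, cs, "/")
  dt <- det(Gs)
  rc <- tryCatch(rcond(Gs), error = function(e) 0)
  list(det = dt, rcond = rc, row_scale = r, col_scale = cs)
}

# Evaluate a function while temporarily seeding R's RNG, restoring the
# previous state afterwards so callers' RNG streams are not disturbed.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic sub-seed derivation: one root seed feeds every stage.
#' @noRd
derive_seed <- function(seed, stage) {
  (seed * 48271 + sum(utf8ToInt(stage)) * 9973) %% 2147483399 + 1
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
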