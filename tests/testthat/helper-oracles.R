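# Dense, loop-assembled reference solver for the upwind discrete-ordinates
# system.  Deliberately naive (dense matrix, explicit loops) so it shares no
# code with the package's sparse assembly.
dense_rte_solve <- function(grid, sigma, epsilon, phi) {
  nn <- grid$n_nodes
  nv <- grid$n_angles
  n <- nn * nv
  A <- matrix(0, n, n)
  b <- numeric(n)
  idx <- function(node, m) (m - 1L) * nn + node
  for (m in seq_len(nv)) {
    mu <- grid$mu[m]; eta <- grid$eta[m]
    for (nd in seq_len(nn)) {
      i <- grid$nodes$i[nd]
      j <- if (grid$dim == 2L) grid$nodes$j[nd] else NA
      r <- idx(nd, m)
      incoming <- (i == 1L && mu > 0) || (i == grid$nx && mu < 0)
      if (grid$dim == 2L) {
        incoming <- incoming || (j == 1L && eta > 0) || (j == grid$nx && eta < 0)
      }
      if (incoming) {
        A[r, r] <- 1
        b[r] <- phi[nd, m]
        next
      }
      nid <- function(ii, jj) if (grid$dim == 1L) ii else (jj - 1L) * grid$nx + ii
      if (mu > 0) {
        A[r, idx(nid(i, j), m)] <- A[r, idx(nid(i, j), m)] + mu / grid$dx
        A[r, idx(nid(i - 1L, j), m)] <- A[r, idx(nid(i - 1L, j), m)] - mu / grid$dx
      } else {
        A[r, idx(nid(i, j), m)] <- A[r, idx(nid(i, j), m)] - mu / grid$dx
        A[r, idx(nid(i + 1L, j), m)] <- A[r, idx(nid(i + 1L, j), m)] + mu / grid$dx
      }
      if (grid$dim == 2L) {
        if (eta > 0) {
          A[r, idx(nid(i, j), m)] <- A[r, idx(nid(i, j), m)] + eta / grid$dx
          A[r, idx(nid(i, j - 1L), m)] <- A[r, idx(nid(i, j - 1L), m)] - eta / grid$dx
        } else {
          A[r, idx(nid(i, j), m)] <- A[r, idx(nid(i, j), m)] - eta / grid$dx
          A[r, idx(nid(i, j + 1L), m)] <- A[r, idx(nid(i, j + 1L), m)] + eta / grid$dx
        }
      }
      s <- sigma[nd] / epsilon
      for (mm in seq_len(nv)) {
        A[r, idx(nd, mm)] <- A[r, idx(nd, mm)] - s * grid$weights[mm]
      }
      A[r, r] <- A[r, r] + s
    }
  }
  matrix(solve(A, b), nrow = nn)
}

# random piecewise-constant slab medium
random_bumps <- function() {
  k <- sample(1:3, 1)
  a <- sort(runif(k, 0, 0.8))
  media_bumps(runif(1, 0.5, 2),
              tibble::tibble(a = a, b = pmin(a + runif(k, 0.05, 0.2), 1),
                             h = runif(k, 0, 10)))
}

# one-level Metropolis transition matrix built by the textbook formula
mh_kernel_oracle <- function(target, q) {
  n <- length(target)
  P <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    alpha <- min(1, (q[y, x] * target[y]) / (q[x, y] * target[x]))
    P[x, y] <- q[x, y] * alpha
  }
  diag(P) <- 1 - rowSums(P)
  P
}

# delayed-acceptance transition matrix: pre-accept under the surrogate, then
# the closed-form second-stage test under the target
two_level_kernel_oracle <- function(surrogate, target, q) {
  n <- length(target)
  P <- matrix(0, n, n)
  for (x in seq_len(n)) for (y in seq_len(n)) {
    if (x == y) next
    alpha <- min(1, (q[y, x] * surrogate[y]) / (q[x, y] * surrogate[x]))
    beta <- min(1, (surrogate[x] * target[y]) / (surrogate[y] * target[x]))
    P[x, y] <- q[x, y] * alpha * beta
  }
  diag(P) <- 1 - rowSums(P)
  P
}
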