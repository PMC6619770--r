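# Modified direct inversion in the iterative subspace (MDIIS).
#
# Residual-subspace acceleration of a damped Picard iteration: the next
# trial vector is the residual-norm-minimising linear combination of the
# stored trial vectors plus `step` times the same combination of their
# residuals.  If the residual grows by more than `restartFactor` over the
# best stored residual, the subspace is flushed and iteration restarts from
# the best point.  This is solver plumbing shared by the 1D and 3D solvers.

.mdiisNew <- function(nvec = 10, step = 0.7, restartFactor = 10) {
  env <- new.env(parent = emptyenv())
  env$x <- list(); env$r <- list()
  env$nvec <- nvec; env$step <- step
  env$restartFactor <- restartFactor
  env$best <- Inf; env$bestX <- NULL
  env
}

# x: current trial vector; res: residual F(x) - x.  Returns the next trial.
.mdiisUpdate <- function(st, x, res) {
  rms <- sqrt(mean(res^2))
  if (rms < st$best) {
    st$best <- rms
    st$bestX <- x
    st$bestR <- res
  } else if (rms > st$restartFactor * st$best && length(st$x) > 1) {
    x <- st$bestX; res <- st$bestR
    st$x <- list(); st$r <- list()
  }
  st$x[[length(st$x) + 1]] <- x
  st$r[[length(st$r) + 1]] <- res
  if (length(st$x) > st$nvec) {
    st$x <- st$x[-1]; st$r <- st$r[-1]
  }
  m <- length(st$x)
  if (m == 1) return(x + st$step * res)
  R <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in i:m) {
    R[i, j] <- R[j, i] <- sum(st$r[[i]] * st$r[[j]])
  }
  # minimise |sum a_i r_i| subject to sum a_i = 1 (Lagrange system)
  A <- rbind(cbind(R, 1), c(rep(1, m), 0))
  rhs <- c(rep(0, m), 1)
  a <- tryCatch(solve(A, rhs)[seq_len(m)], error = function(e) NULL)
  if (is.null(a) || any(!is.finite(a))) {
    st$x <- st$x[m]; st$r <- st$r[m]
    return(x + st$step * res)
  }
  xnew <- 0; rnew <- 0
  for (i in seq_len(m)) {
    xnew <- xnew + a[i] * st$x[[i]]
    rnew <- rnew + a[i] * st$r[[i]]
  }
  xnew + st$step * rnew
}
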