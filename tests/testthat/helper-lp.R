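## Independent two-phase dense tableau simplex: min c'x s.t. Ax = b, x >= 0.
## Written as a test oracle, separate from the package's transportation code.
lp_solve_dense <- function(cost, A, b, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]; b[neg] <- -b[neg]
  ## phase 1: artificial variables
  Tb <- cbind(A, diag(m), b)
  cost1 <- c(rep(0, n), rep(1, m))
  basis <- n + seq_len(m)
  run_simplex <- function(Tb, basis, cz) {
    repeat {
      zrow <- -cz
      for (i in seq_along(basis)) zrow <- zrow + cz[basis[i]] * Tb[i, seq_along(cz)]
      ent <- which(zrow > tol)
      if (!length(ent)) return(list(T = Tb, basis = basis))
      j <- ent[1]  # Bland's rule
      ratios <- ifelse(Tb[, j] > tol, Tb[, ncol(Tb)] / Tb[, j], Inf)
      if (all(!is.finite(ratios))) stop("unbounded")
      i <- which(ratios == min(ratios))
      i <- i[which.min(basis[i])]  # Bland tie-break
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(nrow(Tb))) if (r != i)
        Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      basis[i] <- j
      Tb -> Tb
    }
  }
  r1 <- run_simplex(Tb, basis, cost1)
  obj1 <- sum(cost1[r1$basis] * r1$T[, ncol(r1$T)])
  if (obj1 > 1e-7) stop("infeasible")
  ## drive artificials out / drop their columns
  Tb <- r1$T[, c(seq_len(n), ncol(r1$T)), drop = FALSE]
  basis <- r1$basis
  for (i in which(basis > n)) {
    j <- which(abs(Tb[i, seq_len(n)]) > tol)[1]
    if (is.na(j)) next
    piv <- Tb[i, j]; Tb[i, ] <- Tb[i, ] / piv
    for (r in seq_len(nrow(Tb))) if (r != i) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
    basis[i] <- j
  }
  keep <- basis <= n
  r2 <- run_simplex(Tb[keep, , drop = FALSE], basis[keep], cost)
  x <- numeric(n)
  x[r2$basis] <- r2$T[, ncol(r2$T)]
  list(x = x, objective = sum(cost * x))
}
lp_transport_oracle <- function(cost, supply, demand) {
  m <- length(supply); n <- length(demand)
  nv <- m * n
  A <- matrix(0, m + n, nv)
  for (i in seq_len(m)) A[i, (seq_len(n) - 1) * m + i] <- 1
  for (j in seq_len(n)) A[m + j, (j - 1) * m + seq_len(m)] <- 1
  r <- lp_solve_dense(as.vector(cost), A[-(m + n), , drop = FALSE],
                      c(supply, demand)[-(m + n)])
  list(plan = matrix(r$x, m, n), objective = r$objective)
}
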