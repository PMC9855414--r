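# Independent brute-force oracle for the linear nu one-class SVM:
# exact KKT active-set enumeration of the dual
#   min 1/2 a' K a   s.t.  sum(a) = s,  0 <= a_i <= u_i
# (libsvm parameterization: u_i = 1 and s = nu * n for n unit-weight points;
# duplicated training points are grouped, giving integer caps u_i).
# Every partition of the points into {zero, free, capped} is tried; the KKT
# system of each candidate is solved exactly and checked for primal and dual
# feasibility. Any feasible KKT point of this convex QP is a global optimum.
ocsvm_dual_enum <- function(K, u, s) {
  n <- nrow(K)
  best <- NULL
  for (code in 0:(3^n - 1)) {
    cfg <- (code %/% 3^(0:(n - 1))) %% 3  # 0 = zero, 1 = free, 2 = capped
    Fr <- which(cfg == 1)
    Up <- which(cfg == 2)
    a <- numeric(n)
    a[Up] <- u[Up]
    if (length(Fr)) {
      M <- rbind(cbind(K[Fr, Fr, drop = FALSE], -1),
                 c(rep(1, length(Fr)), 0))
      rhs <- c(if (length(Up)) -K[Fr, Up, drop = FALSE] %*% u[Up]
               else rep(0, length(Fr)),
               s - sum(a))
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aF <- sol[seq_along(Fr)]
      rho <- sol[length(sol)]
      if (any(aF < -1e-9) || any(aF > u[Fr] + 1e-9)) next
      a[Fr] <- aF
    } else {
      if (abs(sum(a) - s) > 1e-9) next
      g <- as.numeric(K %*% a)
      lo <- if (length(Up)) max(g[Up]) else -Inf
      hi <- if (any(cfg == 0)) min(g[cfg == 0]) else Inf
      if (lo > hi + 1e-9) next
      # no free support vector: rho is only interval-determined; libsvm
      # reports the interval midpoint, so the oracle does the same
      rho <- if (is.finite(lo) && is.finite(hi)) (lo + hi) / 2
             else max(lo, min(hi, 0))
    }
    g <- as.numeric(K %*% a)
    Ze <- which(cfg == 0)
    if (length(Ze) && any(g[Ze] < rho - 1e-7)) next
    if (length(Up) && any(g[Up] > rho + 1e-7)) next
    obj <- 0.5 * sum(a * g)
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(alpha = a, rho = rho, obj = obj)
    }
  }
  if (!is.null(best)) {
    # rho can be non-unique when every support vector sits at a bound;
    # recompute it from the optimal alpha exactly the way libsvm does:
    # mean gradient over free SVs, else the bound-interval midpoint
    a <- best$alpha
    g <- as.numeric(K %*% a)
    free <- a > 1e-8 & a < u - 1e-8
    best$rho <- if (any(free)) {
      mean(g[free])
    } else {
      (max(g[a >= u - 1e-8]) + min(g[a <= 1e-8])) / 2
    }
  }
  best
}

# decision values of the enumeration oracle on query points
oracle_decision <- function(X_train, u, nu, X_query) {
  K <- X_train %*% t(X_train)
  o <- ocsvm_dual_enum(K, u, nu * sum(u))
  w <- as.numeric(t(o$alpha) %*% X_train)
  list(w = w, rho = o$rho,
       decision = as.numeric(X_query %*% w) - o$rho)
}
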