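# Log-barrier interior-point method for convex quadratically constrained
# programs of the form
#   minimize    x' Q0 x + l0' x
#   subject to  Aeq x = beq,  lb <= x <= ub,
#               x' Qk x + lk' x <= uk       (k = 1..K, Qk PSD)
# with a phase-I stage that finds a strictly feasible point or certifies
# infeasibility. Problem sizes here are a few hundred variables, so dense
# Newton KKT solves are used throughout.

.qp_eval <- function(con, x) {
  v <- sum(con$l * x)
  if (!is.null(con$Q)) v <- v + drop(crossprod(x, con$Q %*% x))
  v - con$ub
}

.qp_grad <- function(con, x) {
  g <- con$l
  if (!is.null(con$Q)) g <- g + 2 * drop(con$Q %*% x)
  g
}

# Newton barrier minimization of t*f0 + phi(x) subject to Aeq x = beq.
# x0 must be strictly feasible. Returns the centered point.
.barrier_center <- function(x0, t, Q0, l0, cons, lb, ub, Aeq,
                            max_iter = 500L, tol_dec = 1e-10) {
  x <- x0
  n <- length(x)
  r <- nrow(Aeq)
  fin_lb <- is.finite(lb)
  fin_ub <- is.finite(ub)
  merit <- function(x) {
    f <- sum(l0 * x)
    if (!is.null(Q0)) f <- f + drop(crossprod(x, Q0 %*% x))
    phi <- -sum(log(x[fin_lb] - lb[fin_lb])) -
      sum(log(ub[fin_ub] - x[fin_ub]))
    for (con in cons) phi <- phi - log(-.qp_eval(con, x))
    t * f + phi
  }
  for (it in seq_len(max_iter)) {
    sl <- x - lb
    su <- ub - x
    grad <- t * l0
    if (!is.null(Q0)) grad <- grad + t * 2 * drop(Q0 %*% x)
    hdiag <- numeric(n)
    grad[fin_lb] <- grad[fin_lb] - 1 / sl[fin_lb]
    grad[fin_ub] <- grad[fin_ub] + 1 / su[fin_ub]
    hdiag[fin_lb] <- hdiag[fin_lb] + 1 / sl[fin_lb]^2
    hdiag[fin_ub] <- hdiag[fin_ub] + 1 / su[fin_ub]^2
    H <- diag(hdiag, n)
    if (!is.null(Q0)) H <- H + 2 * t * Q0
    for (con in cons) {
      g <- .qp_eval(con, x)
      dg <- .qp_grad(con, x)
      H <- H + tcrossprod(dg) / g^2
      if (!is.null(con$Q)) H <- H + 2 * con$Q / (-g)
      grad <- grad + dg / (-g)
    }
    rhs <- c(-grad, rep(0, r))
    scale <- mean(abs(diag(H))) + 1
    dx <- NULL
    dec <- -Inf
    # escalate a Hessian-block ridge until the step is a descent direction
    for (ridge in c(0, 1e-12, 1e-8, 1e-4, 1e-2) * scale) {
      KKT <- rbind(cbind(H + diag(ridge, n), t(Aeq)),
                   cbind(Aeq, matrix(0, r, r)))
      sol <- tryCatch(solve(KKT, rhs, tol = 1e-300),
                      error = function(e) NULL)
      if (is.null(sol) || !all(is.finite(sol))) next
      cand <- sol[seq_len(n)]
      dd <- -sum(grad * cand)
      if (dd > 0) {
        dx <- cand
        dec <- dd
        break
      }
    }
    if (is.null(dx)) break
    if (dec / 2 < tol_dec) break
    # largest step keeping the box strictly feasible
    amax <- 1
    neg <- fin_lb & dx < 0
    if (any(neg)) amax <- min(amax, 0.99 * min(sl[neg] / -dx[neg]))
    pos <- fin_ub & dx > 0
    if (any(pos)) amax <- min(amax, 0.99 * min(su[pos] / dx[pos]))
    m0 <- merit(x)
    a <- amax
    ok <- FALSE
    for (ls in seq_len(60L)) {
      xn <- x + a * dx
      feas <- all(vapply(cons, function(con) .qp_eval(con, xn) < 0,
                         logical(1)))
      if (feas && merit(xn) <= m0 - 0.01 * a * dec) {
        ok <- TRUE
        break
      }
      a <- a / 2
    }
    if (!ok) break
    x <- x + a * dx
  }
  x
}

.barrier_solve <- function(Q0, l0, cons, lb, ub, Aeq, beq, x0,
                           gap_tol = 1e-8, mu = 20, stop_fn = NULL,
                           t0 = NULL) {
  m <- sum(is.finite(lb)) + sum(is.finite(ub)) + length(cons)
  if (is.null(t0)) {
    f0 <- abs(sum(l0 * x0) +
                if (!is.null(Q0)) drop(crossprod(x0, Q0 %*% x0)) else 0)
    t0 <- max(1, m / max(1, f0))
  }
  t <- t0
  x <- x0
  repeat {
    x <- .barrier_center(x, t, Q0, l0, cons, lb, ub, Aeq)
    if (!is.null(stop_fn) && stop_fn(x)) break
    if (m / t < gap_tol) break
    t <- t * mu
  }
  x
}

# Phase I: minimize s subject to g_k(x) <= s and the box/equality
# constraints. Declares infeasibility when the optimal s is >= -margin.
.phase1 <- function(cons, lb, ub, Aeq, beq, x0, margin = 1e-9) {
  if (!length(cons)) return(list(x = x0, feasible = TRUE))
  g0 <- vapply(cons, .qp_eval, numeric(1), x = x0)
  if (max(g0) < -1e-7) return(list(x = x0, feasible = TRUE))
  n <- length(x0)
  s0 <- max(g0) + 1
  cons1 <- lapply(cons, function(con) {
    Q <- if (!is.null(con$Q)) {
      Qx <- matrix(0, n + 1, n + 1)
      Qx[seq_len(n), seq_len(n)] <- con$Q
      Qx
    } else NULL
    list(Q = Q, l = c(con$l, -1), ub = con$ub)
  })
  z <- .barrier_solve(
    Q0 = NULL, l0 = c(rep(0, n), 1), cons = cons1,
    lb = c(lb, -Inf), ub = c(ub, Inf),
    Aeq = cbind(Aeq, 0), beq = beq,
    x0 = c(x0, s0), gap_tol = 1e-10, t0 = 1,
    stop_fn = function(z) z[n + 1] < -1e-4)
  s <- z[n + 1]
  if (s >= -margin) {
    g <- vapply(cons, .qp_eval, numeric(1), x = z[seq_len(n)])
    return(list(x = z[seq_len(n)], feasible = FALSE,
                worst = which.max(g), violation = max(g)))
  }
  list(x = z[seq_len(n)], feasible = TRUE)
}

# Front end: solves the male-contribution program. `obj` is a list(Q, l)
# (Q may be NULL for linear objectives); `cons` a list of list(Q, l, ub,
# name). Returns list(x, status, ...).
.solve_convex <- function(obj, cons, n, total = 0.5, xmax = 0.5,
                          x0 = NULL, gap_tol = 1e-8) {
  if (n == 1L) {
    x <- total
    viol <- vapply(cons, .qp_eval, numeric(1), x = x)
    if (any(viol > 1e-6)) {
      return(list(x = x, status = "infeasible",
                  violated = cons[[which.max(viol)]]$name))
    }
    return(list(x = x, status = "optimal"))
  }
  lb <- rep(0, n)
  ub <- rep(xmax, n)
  Aeq <- matrix(1, 1, n)
  beq <- total
  if (is.null(x0)) x0 <- rep(total / n, n)
  p1 <- .phase1(cons, lb, ub, Aeq, beq, x0)
  if (!p1$feasible) {
    return(list(x = p1$x, status = "infeasible",
                violated = cons[[p1$worst]]$name,
                violation = p1$violation))
  }
  x <- .barrier_solve(obj$Q, obj$l, cons, lb, ub, Aeq, beq, p1$x,
                      gap_tol = gap_tol)
  list(x = x, status = "optimal")
}
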