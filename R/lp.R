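#' @title Dense linear and mixed-integer linear programming
#'
#' @description
#' A small, deterministic LP/MILP kernel used by the thermodynamic flux
#' sampler and the network-response-analysis design MILP. Problems in this
#' package are dense and small (tens of variables), so a two-phase
#' bounded-variable simplex with an explicit basis factorization is adequate
#' and keeps results bit-reproducible across platforms.
#'
#' @param obj numeric objective coefficients.
#' @param A constraint matrix (may have zero rows).
#' @param sense character vector of "<=", ">=", "=" per row.
#' @param rhs right-hand sides.
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param vtype "C" (continuous) or "B" (binary) per variable.
#' @param maximize logical; maximize the objective?
#' @param names optional variable names.
#' @return an object of class `lp_problem`.
#' @keywords internal
lp_problem <- function(obj, A = NULL, sense = NULL, rhs = NULL,
                       lb = NULL, ub = NULL, vtype = NULL,
                       maximize = TRUE, names = NULL) {
  n <- length(obj)
  if (is.null(A)) A <- matrix(0, 0, n)
  A <- as.matrix(A)
  if (ncol(A) != n) stop("lp_problem: A has ", ncol(A), " columns, expected ", n)
  m <- nrow(A)
  if (is.null(sense)) sense <- rep("=", m)
  if (is.null(rhs)) rhs <- numeric(m)
  if (is.null(lb)) lb <- rep(0, n)
  if (is.null(ub)) ub <- rep(Inf, n)
  if (is.null(vtype)) vtype <- rep("C", n)
  if (any(!is.finite(lb))) stop("lp_problem: lower bounds must be finite")
  if (any(ub < lb)) stop("lp_problem: ub < lb for variable(s) ",
                         paste(which(ub < lb), collapse = ","))
  stopifnot(length(rhs) == m, length(sense) == m, length(lb) == n,
            length(ub) == n, length(vtype) == n)
  if (is.null(names)) names <- paste0("x", seq_len(n))
  structure(list(obj = as.numeric(obj), A = A, sense = sense,
                 rhs = as.numeric(rhs), lb = as.numeric(lb),
                 ub = as.numeric(ub), vtype = vtype,
                 maximize = isTRUE(maximize), names = names),
            class = "lp_problem")
}

#' Add rows to an LP problem
#' @keywords internal
lp_add_rows <- function(prob, A, sense, rhs) {
  A <- matrix(A, ncol = length(prob$obj))
  prob$A <- rbind(prob$A, A)
  prob$sense <- c(prob$sense, sense)
  prob$rhs <- c(prob$rhs, rhs)
  prob
}

# Bounded-variable two-phase primal simplex on
#   min c'x  s.t.  A x = b,  l <= x <= u
# after slacks convert inequalities. Returns list(status, x, objval).
simplex_core <- function(c0, A, b, l, u, tol = 1e-9, max_iter = 20000L,
                         init_basis = NULL) {
  m <- nrow(A); n <- ncol(A)
  if (m == 0L) {                      # pure bound-constrained problem
    x <- ifelse(c0 < 0, u, l)
    if (any(c0 < 0 & !is.finite(u)))
      return(list(status = "unbounded", x = NULL, objval = -Inf))
    return(list(status = "optimal", x = x, objval = sum(c0 * x)))
  }
  # artificial variables give a trivial starting basis; nonbasics start at lb.
  # Rows with a caller-supplied feasible basic column (e.g. slacks of
  # inequality rows) skip their artificial, and when no artificials are
  # needed phase 1 is skipped entirely.
  x <- l
  resid <- b - as.numeric(A %*% x)
  sg <- ifelse(resid >= 0, 1, -1)
  Afull <- cbind(A, diag(sg, m))
  nt <- n + m
  lfull <- c(l, rep(0, m))
  ufull <- c(u, rep(Inf, m))
  basis <- n + seq_len(m)
  need_art <- rep(TRUE, m)
  if (!is.null(init_basis)) {
    ok <- !is.na(init_basis)
    basis[ok] <- init_basis[ok]
    need_art <- !ok
    ufull[n + which(ok)] <- 0          # unused artificials pinned at zero
  }
  # status of nonbasic vars: 1 at lower, 2 at upper
  at_up <- rep(FALSE, nt)
  phase1 <- c(rep(0, n), rep(1, m))

  run_phase <- function(cvec, basis, at_up, allow_art) {
    it <- 0L
    bland <- FALSE
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration_limit", basis = basis, at_up = at_up))
      if (it > 5000L) bland <- TRUE
      B <- Afull[, basis, drop = FALSE]
      nb <- setdiff(seq_len(nt), basis)
      if (!allow_art) nb <- nb[nb <= n]          # artificials fixed out in phase 2
      xN <- ifelse(at_up[nb], ufull[nb], lfull[nb])
      rhsB <- b - as.numeric(Afull[, nb, drop = FALSE] %*% xN)
      xB <- tryCatch(solve(B, rhsB), error = function(e) NULL)
      if (is.null(xB)) return(list(status = "singular", basis = basis, at_up = at_up))
      y <- solve(t(B), cvec[basis])
      d <- cvec[nb] - as.numeric(crossprod(Afull[, nb, drop = FALSE], y))
      # candidate entering variables; variables fixed by l == u cannot move
      movable <- (ufull[nb] - lfull[nb]) > tol
      viol_lo <- !at_up[nb] & d < -tol & movable
      viol_hi <- at_up[nb] & d > tol & movable
      cand <- which(viol_lo | viol_hi)
      if (length(cand) == 0L) {
        return(list(status = "optimal", basis = basis, at_up = at_up,
                    xB = xB, nb = nb, xN = xN))
      }
      if (bland) {
        e_i <- cand[which.min(nb[cand])]
      } else {
        e_i <- cand[which.max(abs(d[cand]))]
      }
      e <- nb[e_i]
      dirn <- if (at_up[e]) -1 else 1          # entering moves up from l or down from u
      w <- solve(B, Afull[, e]) * dirn         # xB changes by -w * t, t >= 0
      # ratio test
      tmax <- ufull[e] - lfull[e]              # bound-flip limit
      leave <- 0L; lv_to_up <- FALSE
      for (i in seq_len(m)) {
        wi <- w[i]
        if (wi > tol) {
          lim <- (xB[i] - lfull[basis[i]]) / wi
          if (lim < tmax) { tmax <- lim; leave <- i; lv_to_up <- FALSE }
        } else if (wi < -tol) {
          ubi <- ufull[basis[i]]
          if (is.finite(ubi)) {
            lim <- (ubi - xB[i]) / (-wi)
            if (lim < tmax) { tmax <- lim; leave <- i; lv_to_up <- TRUE }
          }
        }
      }
      if (!is.finite(tmax)) return(list(status = "unbounded", basis = basis, at_up = at_up))
      if (tmax < 0) tmax <- 0
      if (leave == 0L) {
        at_up[e] <- !at_up[e]                  # bound flip
      } else {
        lv <- basis[leave]
        at_up[lv] <- lv_to_up
        basis[leave] <- e
        at_up[e] <- FALSE                      # entering becomes basic
      }
    }
  }

  if (any(need_art)) {
    r1 <- run_phase(phase1, basis, at_up, allow_art = TRUE)
    if (r1$status != "optimal")
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    art_val <- sum(r1$xB[r1$basis > n])
    if (art_val > 1e-7)
      return(list(status = "infeasible", x = NULL, objval = NA_real_))
    basis <- r1$basis; at_up <- r1$at_up
  }
  # pin artificials at zero
  ufull[(n + 1):nt] <- 0
  c2 <- c(c0, rep(0, m))
  r2 <- run_phase(c2, basis, at_up, allow_art = TRUE)
  if (r2$status %in% c("iteration_limit", "singular"))
    return(list(status = r2$status, x = NULL, objval = NA_real_))
  if (r2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = -Inf))
  xfull <- numeric(nt)
  xfull[r2$nb] <- r2$xN
  xfull[r2$basis] <- r2$xB
  x <- xfull[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(c0 * x))
}

#' Solve a linear program (continuous relaxation of `lp_problem`)
#' @param prob an `lp_problem`.
#' @return list with `status` ("optimal"/"infeasible"/"unbounded"), solution
#'   vector `x` (named) and `objval` on the original (possibly maximizing)
#'   scale.
#' @keywords internal
lp_solve <- function(prob) {
  n <- length(prob$obj)
  m <- nrow(prob$A)
  c0 <- if (prob$maximize) -prob$obj else prob$obj
  nslack <- sum(prob$sense != "=")
  A <- cbind(prob$A, matrix(0, m, nslack))
  k <- 0
  slack_lb <- numeric(0); slack_ub <- numeric(0)
  for (i in seq_len(m)) {
    if (prob$sense[i] == "=") next
    k <- k + 1
    A[i, n + k] <- if (prob$sense[i] == "<=") 1 else -1
  }
  l <- c(prob$lb, rep(0, nslack))
  u <- c(prob$ub, rep(Inf, nslack))
  # slack columns whose value at x = lb is feasible can start in the basis
  init_basis <- rep(NA_integer_, m)
  resid <- prob$rhs - as.numeric(prob$A %*% prob$lb)
  k <- 0
  for (i in seq_len(m)) {
    if (prob$sense[i] == "=") next
    k <- k + 1
    sval <- if (prob$sense[i] == "<=") resid[i] else -resid[i]
    if (sval >= 0) init_basis[i] <- n + k
  }
  res <- simplex_core(c(c0, rep(0, nslack)), A, prob$rhs, l, u,
                      init_basis = init_basis)
  if (res$status == "optimal") {
    x <- res$x[seq_len(n)]
    names(x) <- prob$names
    objval <- sum(prob$obj * x)
    list(status = "optimal", x = x, objval = objval)
  } else {
    list(status = res$status, x = NULL, objval = NA_real_)
  }
}

#' Solve a mixed-integer linear program by branch-and-bound
#'
#' Depth-first branch-and-bound over the binary/integer variables declared in
#' the problem's `vtype`, with best-bound pruning at a relative gap of
#' `gap`. Branching order and tie-breaks are deterministic.
#'
#' @param prob an `lp_problem` with some `vtype == "B"`.
#' @param int_tol integrality tolerance.
#' @param gap relative optimality gap for pruning.
#' @return as [lp_solve()].
#' @keywords internal
milp_solve <- function(prob, int_tol = 1e-6, gap = 1e-6) {
  ivars <- which(prob$vtype == "B")
  if (length(ivars) == 0L) return(lp_solve(prob))
  best <- NULL
  best_obj <- if (prob$maximize) -Inf else Inf
  better <- function(a, b) if (prob$maximize) a > b + 1e-12 else a < b - 1e-12
  # node stack: list of (lb, ub)
  stack <- list(list(lb = prob$lb, ub = prob$ub))
  any_feasible_relax <- FALSE
  while (length(stack) > 0L) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    p <- prob; p$lb <- node$lb; p$ub <- node$ub
    rel <- lp_solve(p)
    if (rel$status != "optimal") next
    any_feasible_relax <- TRUE
    # prune by bound
    if (!is.null(best)) {
      bnd <- rel$objval
      tolv <- gap * max(1, abs(best_obj))
      if (prob$maximize && bnd <= best_obj + tolv) next
      if (!prob$maximize && bnd >= best_obj - tolv) next
    }
    frac <- abs(rel$x[ivars] - round(rel$x[ivars]))
    if (all(frac <= int_tol)) {
      if (is.null(best) || better(rel$objval, best_obj)) {
        best <- rel
        best$x[ivars] <- round(best$x[ivars])
        best_obj <- rel$objval
      }
      next
    }
    j <- ivars[which.max(frac)]          # most fractional, deterministic
    v <- rel$x[j]
    lo <- node; lo$ub[j] <- floor(v)
    hi <- node; hi$lb[j] <- ceiling(v)
    # explore the "round up" child first (tends to fix active interventions)
    stack[[length(stack) + 1L]] <- lo
    stack[[length(stack) + 1L]] <- hi
  }
  if (is.null(best)) {
    status <- if (any_feasible_relax) "infeasible" else "infeasible"
    return(list(status = status, x = NULL, objval = NA_real_))
  }
  best
}
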