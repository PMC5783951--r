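# Linear and quadratic solvers behind the three flux-prediction problems.
#
# FBA is solved with a package-local dense two-phase simplex using Bland's
# rule (exact at vertices, anti-cycling); MOMA and MOMA-b are strictly convex
# quadratic programs solved with the Goldfarb-Idnani dual active-set method
# (quadprog::solve.QP). Both sit behind the same contract: a flux vector, an
# objective value, a solver status, and a steady-state residual.

# --- dense two-phase simplex -------------------------------------------------

# min cost'z s.t. A z = b (b >= 0 after row flips), z >= 0.
# `A` must contain an identity in the columns listed in `basis`.
# `allowed` masks columns permitted to enter the basis (used to freeze
# artificial columns after phase 1).
simplex_core <- function(A, b, cost, basis, allowed = rep(TRUE, ncol(A)),
                         tol = 1e-9, maxit = 50000L) {
  m <- nrow(A)
  for (it in seq_len(maxit)) {
    red <- cost - as.vector(crossprod(A, cost[basis]))
    red[basis] <- 0
    enter <- which(red < -tol & allowed)
    if (!length(enter)) {
      z <- numeric(ncol(A))
      z[basis] <- b
      return(list(status = "optimal", z = z, basis = basis, A = A, b = b,
                  value = sum(cost[basis] * b)))
    }
    j <- min(enter)                          # Bland's rule: lowest index enters
    col <- A[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(status = "unbounded"))
    ratio <- b[pos] / col[pos]
    cand <- pos[ratio <= min(ratio) + tol]
    i <- cand[which.min(basis[cand])]        # lowest basic index leaves
    piv <- A[i, j]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(m), i)
    b[other] <- b[other] - A[other, j] * b[i]
    A[other, ] <- A[other, ] - outer(A[other, j], A[i, ])
    basis[i] <- j
  }
  list(status = "maxit")
}

# min cvec'z s.t. A z = b, z >= 0. Two-phase with artificial variables.
solve_lp_eq <- function(cvec, A, b, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  A1 <- cbind(A, diag(m))
  r1 <- simplex_core(A1, b, c(numeric(n), rep(1, m)), basis = n + seq_len(m),
                     tol = tol)
  if (r1$status != "optimal") return(list(status = r1$status))
  if (r1$value > 1e-7) return(list(status = "infeasible"))
  # pivot any residual artificial out of the (degenerate) basis when possible
  basis <- r1$basis; A2 <- r1$A; b2 <- r1$b
  for (i in which(basis > n)) {
    j <- setdiff(which(abs(A2[i, seq_len(n)]) > 1e-8), basis)
    if (!length(j)) next                      # redundant row; artificial stays 0
    j <- j[1]
    piv <- A2[i, j]
    A2[i, ] <- A2[i, ] / piv
    b2[i] <- b2[i] / piv
    other <- setdiff(seq_len(m), i)
    b2[other] <- b2[other] - A2[other, j] * b2[i]
    A2[other, ] <- A2[other, ] - outer(A2[other, j], A2[i, ])
    basis[i] <- j
  }
  allowed <- c(rep(TRUE, n), rep(FALSE, m))   # artificials may never re-enter
  r2 <- simplex_core(A2, b2, c(cvec, numeric(m)), basis, allowed, tol = tol)
  if (r2$status != "optimal") return(list(status = r2$status))
  list(status = "optimal", z = r2$z[seq_len(n)], value = r2$value)
}

# Maximize obj'v s.t. S v = 0, lb <= v <= ub (all bounds finite).
solve_lp_bounded <- function(obj, S, lb, ub) {
  n <- length(obj)
  m <- nrow(S)
  # v = x + lb, x >= 0; slack s for x <= ub - lb
  A <- rbind(cbind(S, matrix(0, m, n)), cbind(diag(n), diag(n)))
  b <- c(-as.vector(S %*% lb), ub - lb)
  r <- solve_lp_eq(c(-obj, numeric(n)), A, b)
  if (r$status != "optimal") return(r)
  v <- r$z[seq_len(n)] + lb
  list(status = "optimal", v = v, value = sum(obj * v))
}

# Rows of S that are linearly independent (Goldfarb-Idnani rejects redundant
# equality constraints).
independent_rows <- function(S, tol = 1e-9) {
  if (nrow(S) <= 1) return(seq_len(nrow(S)))
  q <- qr(t(S), tol = tol)
  sort(q$pivot[seq_len(q$rank)])
}

# min ||v - v0||^2 s.t. S v = 0 [, obj'v = b_fix], lb <= v <= ub.
solve_qp_moma <- function(v0, S, lb, ub, obj = NULL, b_fix = NULL) {
  n <- length(v0)
  Seq <- S[independent_rows(S), , drop = FALSE]
  if (!is.null(b_fix)) {
    Seq <- rbind(Seq, obj)
    rhs_eq <- c(numeric(nrow(Seq) - 1L), b_fix)
  } else {
    rhs_eq <- numeric(nrow(Seq))
  }
  Amat <- t(rbind(Seq, diag(n), -diag(n)))
  bvec <- c(rhs_eq, lb, -ub)
  res <- tryCatch(
    quadprog::solve.QP(Dmat = 2 * diag(n), dvec = 2 * v0,
                       Amat = Amat, bvec = bvec, meq = nrow(Seq)),
    error = function(e) e
  )
  if (inherits(res, "error")) {
    status <- if (grepl("inconsistent", conditionMessage(res)))
      "infeasible" else "error"
    return(list(status = status, message = conditionMessage(res)))
  }
  v <- res$solution
  list(status = "optimal", v = v, distance = sum((v - v0)^2))
}

# --- flux-solution container -------------------------------------------------

new_flux_solution <- function(model, v, status, objective = NA_real_,
                              distance = NA_real_, tol = flux_tolerance()) {
  if (status != "optimal") {
    return(structure(list(flux = NULL, objective = NA_real_,
                          biomass = NA_real_, distance = NA_real_,
                          residual = NA_real_, status = status),
                     class = "flux_solution"))
  }
  names(v) <- model$rxn_id
  residual <- max(abs(model$S %*% v))
  bound_viol <- max(0, max(model$lb - v), max(v - model$ub))
  if (residual > tol || bound_viol > tol)
    return(new_flux_solution(model, v, "error"))
  structure(list(flux = v,
                 objective = objective,
                 biomass = sum(model$obj * v),
                 distance = distance,
                 residual = residual,
                 status = "optimal"),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> status: %s", x$status))
  if (x$status == "optimal")
    cat(sprintf(", biomass %.6g, residual %.2g", x$biomass, x$residual))
  cat("\n")
  invisible(x)
}

# --- the three optimization problems ----------------------------------------

#' Flux balance analysis
#'
#' Maximizes the biomass production rate `c'v` subject to the steady-state
#' constraint `S v = 0` and the flux bounds `lb <= v <= ub`. This is the
#' flux prediction for an organism fully adapted to the model's current
#' environment.
#'
#' @param model a [metabolic_model()], typically after
#'   [apply_environment()].
#' @param tol numeric tolerance for residual checks (default
#'   [flux_tolerance()]).
#' @return A `flux_solution`: the flux vector `flux`, `objective` and
#'   `biomass` (equal for FBA), the maximal steady-state `residual`, and a
#'   `status` of `"optimal"`, `"infeasible"` or `"error"`. The optimum may be
#'   degenerate; [shuffle_reaction_order()] exposes the effect of the
#'   vertex choice.
#' @export
fba <- function(model, tol = flux_tolerance()) {
  r <- solve_lp_bounded(model$obj, model$S, model$lb, model$ub)
  if (r$status != "optimal")
    return(new_flux_solution(model, NULL, r$status))
  new_flux_solution(model, r$v, "optimal", objective = r$value, tol = tol)
}

#' Minimization of metabolic adjustment (MOMA)
#'
#' Finds the feasible flux vector closest (in squared Euclidean distance) to
#' a reference flux `v0`, subject to `S v = 0` and the bounds. Because the
#' objective is strictly convex the solution is unique. MOMA models the
#' immediate, pre-mutation ("plastic") metabolic state after a perturbation:
#' the cell keeps its flux distribution as close as possible to the old one
#' while satisfying the new constraints.
#'
#' @inheritParams fba
#' @param v0 reference flux vector, one entry per reaction (usually the FBA
#'   solution in the original environment).
#' @return A `flux_solution`; `objective` is the squared distance to `v0`
#'   (also in `distance`) and `biomass` is reported alongside.
#' @export
moma <- function(model, v0, tol = flux_tolerance()) {
  if (length(v0) != length(model$rxn_id))
    stopf("v0 has length %d but the model has %d reactions",
          length(v0), length(model$rxn_id))
  if (!is.null(names(v0))) v0 <- v0[model$rxn_id]
  r <- solve_qp_moma(as.numeric(v0), model$S, model$lb, model$ub)
  if (r$status != "optimal")
    return(new_flux_solution(model, NULL, r$status))
  new_flux_solution(model, r$v, "optimal", objective = r$distance,
                    distance = r$distance, tol = tol)
}

#' Biomass-constrained MOMA (MOMA-b)
#'
#' MOMA with one extra equality constraint fixing the biomass production
#' rate, `c'v = b`. With `b` set to the FBA optimum of the same environment
#' this predicts the fully adapted flux state through the same quadratic
#' program as the plastic state, removing any bias from comparing solutions
#' of a linear and a quadratic solver. The added constraint means the
#' distance objective is never below the plain [moma()] distance.
#'
#' @inheritParams moma
#' @param b target biomass production rate; values above the FBA optimum
#'   make the problem infeasible.
#' @return A `flux_solution`, as for [moma()].
#' @export
moma_b <- function(model, v0, b, tol = flux_tolerance()) {
  if (length(v0) != length(model$rxn_id))
    stopf("v0 has length %d but the model has %d reactions",
          length(v0), length(model$rxn_id))
  if (!is.null(names(v0))) v0 <- v0[model$rxn_id]
  r <- solve_qp_moma(as.numeric(v0), model$S, model$lb, model$ub,
                     obj = model$obj, b_fix = b)
  if (r$status != "optimal")
    return(new_flux_solution(model, NULL, r$status))
  sol <- new_flux_solution(model, r$v, "optimal", objective = r$distance,
                           distance = r$distance, tol = tol)
  if (sol$status == "optimal" && abs(sol$biomass - b) > tol)
    return(new_flux_solution(model, NULL, "error"))
  sol
}

#' Serialize a flux solution
#'
#' `write_flux_tsv()` writes one row per reaction (`reaction_id`, `flux`,
#' `lower`, `upper`); `write_flux_json()` writes the solver metadata
#' (`status`, `objective`, `residual`).
#'
#' @param sol a `flux_solution`.
#' @param model the [metabolic_model()] it was solved on.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(sol, model, path) {
  stopifnot(sol$status == "optimal")
  df <- data.frame(reaction_id = model$rxn_id, flux = as.numeric(sol$flux),
                   lower = model$lb, upper = model$ub)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flux_tsv
#' @export
write_flux_json <- function(sol, path) {
  jsonlite::write_json(list(status = sol$status, objective = sol$objective,
                            residual = sol$residual),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
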