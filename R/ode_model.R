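#' Build the vectorized ODE model from a reaction system
#'
#' Assembles the net stoichiometry matrix H (element x reaction; +1 per
#' product occurrence, -1 per reactant occurrence, so a catalyst nets 0
#' while still entering the rate product) and fixed-width reactant /
#' product index tables.  Unused table slots point at a reserved
#' constant-one pseudo-state (index n+1), which keeps rate evaluation a
#' fixed chain of element-wise products regardless of reaction arity.
#' States are ordered by ascending element id; reaction order is
#' preserved.
#'
#' @param sys a [ReactionSystem-class].
#' @param max_arity structural cap on reactant/product multiplicity; a
#'   reaction wider than this is a structural error.
#' @return an [OdeModel-class].
#' @export
buildOdeModel <- function(sys, max_arity = 6L) {
  stopifnot(is(sys, "ReactionSystem"))
  el <- elementTable(sys)
  rx <- reactionTable(sys)
  n <- nrow(el)
  m <- nrow(rx)
  arR <- if (m) max(1L, max(vapply(rx$reactants, length, 1L))) else 1L
  arP <- if (m) max(1L, max(vapply(rx$products, length, 1L))) else 1L
  if (arR > max_arity || arP > max_arity) {
    stop("reaction arity exceeds the structural cap of ", max_arity)
  }
  pad <- n + 1L
  XR <- matrix(pad, nrow = m, ncol = arR)
  XP <- matrix(pad, nrow = m, ncol = arP)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (j in seq_len(m)) {
    r <- rx$reactants[[j]]; p <- rx$products[[j]]
    if (length(r)) XR[j, seq_along(r)] <- r
    if (length(p)) XP[j, seq_along(p)] <- p
    touched <- unique(c(r, p))
    net <- vapply(touched, function(k) sum(p == k) - sum(r == k), 0)
    keep <- net != 0
    if (any(keep)) {
      ti <- c(ti, touched[keep])
      tj <- c(tj, rep(j, sum(keep)))
      tx <- c(tx, net[keep])
    }
  }
  H <- Matrix::sparseMatrix(i = ti, j = tj, x = tx, dims = c(n, m))
  new("OdeModel",
    n = n, m = m, H = methods::as(H, "CsparseMatrix"),
    XR = XR, XP = XP,
    kf_idx = as.integer(rx$kf),
    kb_idx = as.integer(ifelse(is.na(rx$kb), 0L, rx$kb)),
    rate_law = as.character(rx$rate_law),
    hill_n = as.numeric(rx$hill_n),
    element_names = el$name,
    n_parameters = nParameters(sys)
  )
}

.kfkb <- function(model, K) {
  if (length(K) != model@n_parameters) {
    stop("parameter vector has length ", length(K), ", expected ",
         model@n_parameters)
  }
  kb <- numeric(model@m)
  has <- model@kb_idx > 0L
  kb[has] <- K[model@kb_idx[has]]
  list(kf = K[model@kf_idx], kb = kb)
}

#' Reaction rate vector
#'
#' Mass-action rates evaluated by the vectorized element-wise-product
#' formulation: `V = K_F * X[R1] * X[R2] * ... - K_B * X[P1] * X[P2] *
#' ...` with padding slots contributing a factor of one.
#' Michaelis-Menten reactions (reactants enzyme, substrate) use
#' `v = kcat * E * S / (Km + S)` with `kcat` in the forward slot and `Km`
#' in the backward slot; Hill reactions (single substrate) use
#' `v = Vmax * S^h / (K^h + S^h)`.
#'
#' @param model an [OdeModel-class].
#' @param x state vector (length n, nonnegative).
#' @param K parameter vector (length `nParameters(model)`).
#' @param tol negativity tolerance on `x`.
#' @return numeric rate vector of length m.
#' @export
reactionRates <- function(model, x, K, tol = 1e-8) {
  if (length(x) != model@n) stop("state vector must have length ", model@n)
  if (any(x < -tol)) stop("negative state entries beyond tolerance")
  xa <- c(x, 1)
  kk <- .kfkb(model, K)
  fwd <- kk$kf
  for (j in seq_len(ncol(model@XR))) fwd <- fwd * xa[model@XR[, j]]
  bwd <- kk$kb
  for (j in seq_len(ncol(model@XP))) bwd <- bwd * xa[model@XP[, j]]
  v <- fwd - bwd
  special <- which(model@rate_law != "mass_action")
  for (j in special) {
    if (model@rate_law[j] == "michaelis_menten") {
      E <- xa[model@XR[j, 1]]; S <- xa[model@XR[j, 2]]
      v[j] <- kk$kf[j] * E * S / (K[model@kb_idx[j]] + S)
    } else if (model@rate_law[j] == "hill") {
      S <- xa[model@XR[j, 1]]
      h <- model@hill_n[j]
      Kh <- K[model@kb_idx[j]]^h
      v[j] <- kk$kf[j] * S^h / (Kh + S^h)
    }
  }
  v
}

#' State derivatives via the stoichiometry matrix
#'
#' `Xdot = H %*% V(X, K)`.
#'
#' @inheritParams reactionRates
#' @return numeric derivative vector of length n.
#' @export
stateDerivatives <- function(model, x, K, tol = 1e-8) {
  as.vector(model@H %*% reactionRates(model, x, K, tol = tol))
}

#' Naive per-reaction derivative oracle
#'
#' Reference implementation that loops over the reaction list of a
#' [ReactionSystem-class], computes each rate from first principles, and
#' accumulates +rate per product occurrence and -rate per reactant
#' occurrence.  Deliberately unvectorized and independent of
#' [buildOdeModel()]; used to verify the matrix formulation.
#'
#' @param sys a [ReactionSystem-class].
#' @param x state vector (length `nElements(sys)`).
#' @param K parameter vector (length `nParameters(sys)`).
#' @return numeric derivative vector.
#' @export
naiveDerivatives <- function(sys, x, K) {
  stopifnot(is(sys, "ReactionSystem"))
  rx <- reactionTable(sys)
  dx <- numeric(nElements(sys))
  for (i in seq_len(nrow(rx))) {
    r <- rx$reactants[[i]]; p <- rx$products[[i]]
    if (rx$rate_law[i] == "michaelis_menten") {
      E <- x[r[1]]; S <- x[r[2]]
      v <- K[rx$kf[i]] * E * S / (K[rx$kb[i]] + S)
    } else if (rx$rate_law[i] == "hill") {
      S <- x[r[1]]; h <- rx$hill_n[i]
      v <- K[rx$kf[i]] * S^h / (K[rx$kb[i]]^h + S^h)
    } else {
      v <- K[rx$kf[i]] * prod(x[r])
      if (rx$reversible[i]) v <- v - K[rx$kb[i]] * prod(x[p])
    }
    for (k in p) dx[k] <- dx[k] + v
    for (k in r) dx[k] <- dx[k] - v
  }
  dx
}

#' Analytic Jacobian of the derivative field
#'
#' d(H V)/dx for pure mass-action models: per index-table slot holding a
#' real state k, the partial of that reaction's term w.r.t. x_k is the
#' product over the remaining slots; repeated reactants (A + A)
#' accumulate across slots.  This is the Jacobian supplied to the stiff
#' solver.
#'
#' @inheritParams reactionRates
#' @return dense n x n Jacobian matrix.
#' @export
odeJacobian <- function(model, x, K) {
  if (!all(model@rate_law == "mass_action")) {
    stop("analytic Jacobian is available for pure mass-action models only")
  }
  XR <- model@XR; XP <- model@XP
  storage.mode(XR) <- "integer"; storage.mode(XP) <- "integer"
  kk <- .kfkb(model, K)
  .Call(C_ma_jac, as.numeric(x), as.numeric(kk$kf), as.numeric(kk$kb),
        XR, XP, as.matrix(model@H))
}

#' Simulate a trajectory
#'
#' Integrates the model with a stiff implicit multistep method (BDF /
#' numerical-differentiation-formula class) at relative tolerance 1e-6
#' and absolute tolerance 1e-9 by default.  For pure mass-action models
#' an analytic Jacobian assembled from H and the index tables is supplied
#' to the solver.  Small negative excursions (within `-abs_clip`) are
#' clipped to zero in the reported states.
#'
#' @param model an [OdeModel-class].
#' @param x0 initial state (length n, nonnegative).
#' @param times strictly increasing sampling times (hours), starting at
#'   the initial time.
#' @param K parameter vector.
#' @param rtol,atol integration tolerances.
#' @param method a [deSolve::ode()] method; default `"bdf"`.
#' @param abs_clip reporting clip for tiny negative states.
#' @return a [Trajectory-class]; on integrator failure, an error naming
#'   the fastest reactions at the last successful state (stiffness
#'   report).
#' @export
simulateModel <- function(model, x0, times, K,
                          rtol = 1e-6, atol = 1e-9, method = "bdf",
                          abs_clip = 1e-9) {
  stopifnot(is(model, "OdeModel"))
  if (length(x0) != model@n) stop("x0 must have length ", model@n)
  if (any(x0 < 0)) stop("x0 must be nonnegative")
  if (length(times) < 2 || any(diff(times) <= 0)) {
    stop("times must be strictly increasing with at least two points")
  }
  # hot path: local dense copies, no S4 access inside the solver loop;
  # pure mass-action models run through the compiled kernels with the
  # analytic Jacobian
  Hd <- as.matrix(model@H)
  XR <- model@XR; XP <- model@XP
  storage.mode(XR) <- "integer"; storage.mode(XP) <- "integer"
  kk <- .kfkb(model, K)
  kf <- as.numeric(kk$kf); kb <- as.numeric(kk$kb)
  use_jac <- all(model@rate_law == "mass_action")
  out <- if (use_jac) {
    rhs <- function(t, y, parms) {
      list(.Call(C_ma_deriv, y, kf, kb, XR, XP, Hd))
    }
    jac <- function(t, y, parms) .Call(C_ma_jac, y, kf, kb, XR, XP, Hd)
    # ode(method = "bdf") does not forward a user jacobian; call the
    # BDF driver directly so the analytic jacobian is actually used
    suppressWarnings(
      if (identical(method, "bdf")) {
        deSolve::lsode(y = x0, times = times, func = rhs, parms = NULL,
                       rtol = rtol, atol = atol,
                       jacfunc = jac, jactype = "fullusr")
      } else {
        deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                     method = method, rtol = rtol, atol = atol,
                     jacfunc = jac, jactype = "fullusr")
      }
    )
  } else {
    rhs <- function(t, y, parms) {
      list(stateDerivatives(model, y, K, tol = Inf))
    }
    suppressWarnings(
      deSolve::ode(y = x0, times = times, func = rhs, parms = NULL,
                   method = method, rtol = rtol, atol = atol)
    )
  }
  ok <- is.matrix(out) && nrow(out) == length(times) && !anyNA(out)
  if (!ok) {
    last <- if (is.matrix(out) && nrow(out)) {
      as.numeric(out[nrow(out), -1])
    } else x0
    last[is.na(last) | last < 0] <- 0
    v <- tryCatch(abs(reactionRates(model, last, K, tol = Inf)),
                  error = function(e) rep(NA_real_, model@m))
    top <- order(v, decreasing = TRUE)[seq_len(min(3, model@m))]
    stop("integration failed; fastest reactions at last state: ",
         paste(sprintf("#%d (|v|=%.3g)", top, v[top]), collapse = ", "))
  }
  states <- out[, -1, drop = FALSE]
  states[states < 0 & states > -abs_clip] <- 0
  colnames(states) <- model@element_names
  rownames(states) <- NULL
  new("Trajectory", times = as.numeric(times), states = unname0(states))
}

unname0 <- function(m) {
  dimnames(m) <- list(NULL, colnames(m))
  m
}

#' Left-null conservation check helpers
#'
#' Total DNA of a regulated gene (free + all bound forms) is untouched by
#' every reaction, so it is conserved along any trajectory; this helper
#' returns those totals for inspection/testing.
#'
#' @param sys a [ReactionSystem-class].
#' @param traj a [Trajectory-class] simulated from it.
#' @return matrix time x regulated-gene of total DNA concentrations.
#' @export
dnaTotals <- function(sys, traj) {
  el <- elementTable(sys)
  genes <- unique(el$gene[el$form == "dna_free"])
  if (!length(genes)) {
    return(matrix(numeric(0), nrow = length(trajectoryTimes(traj)), ncol = 0))
  }
  out <- sapply(genes, function(g) {
    idx <- which(el$form %in% DNA_FORMS & el$gene == g)
    rowSums(trajectoryStates(traj)[, idx, drop = FALSE])
  })
  matrix(out, nrow = length(trajectoryTimes(traj)),
         dimnames = list(NULL, genes))
}

#' Export a trajectory as tidy data
#'
#' @param traj a [Trajectory-class].
#' @return data.frame with columns `time_h`, `element`, `value`.
#' @export
trajectoryToTidy <- function(traj) {
  st <- trajectoryStates(traj)
  data.frame(
    time_h = rep(trajectoryTimes(traj), ncol(st)),
    element = rep(colnames(st), each = nrow(st)),
    value = as.vector(st),
    stringsAsFactors = FALSE
  )
}
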