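# Hill-function ODE models of motif circuits and their assemblies.
#
# Every dynamical node X obeys
#   dX/dt = beta_X * G_X(regulators) - alpha_X * X,
# where each activating regulator Y contributes Y^n / (k^n + Y^n), each
# repressing regulator contributes k^n / (k^n + Y^n), and G_X combines the
# contributions with AND logic (product) or OR logic (1 - prod(1 - h)).
# Nodes may instead be declared external inputs: they are not integrated but
# held at a prescribed level (a step that rises at t = 0).

#' Hill regulation function
#'
#' Saturating regulatory response with half-effect level `k` and cooperativity
#' `n`: `x^n / (k^n + x^n)` for activation (`sign = "+"`) and
#' `k^n / (k^n + x^n)` for repression (`sign = "-"`). The two branches are
#' complementary: they sum to 1 for any input.
#'
#' @param x regulator level (>= 0; vectorized).
#' @param k half-effect level (> 0).
#' @param n cooperativity (>= 1).
#' @param sign `"+"` (activation) or `"-"` (repression).
#' @return value in `[0, 1]`.
#' @export
hill <- function(x, k, n, sign = "+") {
  if (any(x < 0)) stop("regulator level must be nonnegative")
  stopifnot(k > 0, n >= 1)
  xn <- x^n
  kn <- k^n
  if (sign == "+") xn / (kn + xn) else kn / (kn + xn)
}

#' Build a Hill-function circuit model
#'
#' @param nodes character vector of node names.
#' @param edges data frame (or list of rows) with columns `from`, `to`,
#'   `sign` (`"+"`/`"-"`), and optional `k`, `n` (defaults 0.5 and 2);
#'   self-edges describe autoregulation.
#' @param beta,alpha maximal production and linear removal rates: scalars or
#'   named vectors over dynamical nodes (defaults 1).
#' @param gate `"AND"` or `"OR"`, scalar or named vector per node.
#' @param inputs named numeric vector of external input nodes and their step
#'   levels; input nodes are not integrated.
#' @return an object of class `hm_circuit`.
#' @export
build_model <- function(nodes, edges, beta = 1, alpha = 1, gate = "AND",
                        inputs = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    if (is.null(edges$k)) edges$k <- 0.5
    if (is.null(edges$n)) edges$n <- 2
    edges$k <- as.numeric(edges$k)
    edges$n <- as.numeric(edges$n)
    bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(bad) > 0) stop("edge references unknown node(s): ",
                              paste(bad, collapse = ", "))
    if (any(edges$k <= 0)) stop("half-effect level k must be positive")
    if (any(edges$n < 1)) stop("cooperativity n must be at least 1")
    if (!all(edges$sign %in% c("+", "-"))) stop("edge sign must be '+' or '-'")
  }
  input_names <- names(inputs)
  dynamic <- setdiff(nodes, input_names)
  expand <- function(x, default) {
    out <- setNames(rep(default, length(dynamic)), dynamic)
    if (is.null(names(x))) {
      out[] <- x
    } else {
      out[names(x)] <- x
    }
    out
  }
  beta <- expand(beta, 1)
  alpha <- expand(alpha, 1)
  gate <- expand(gate, "AND")
  if (any(beta <= 0) || any(alpha <= 0)) {
    stop("beta and alpha must be positive")
  }
  if (!all(gate %in% c("AND", "OR"))) stop("gate must be 'AND' or 'OR'")
  model <- structure(list(
    nodes = nodes, dynamic = dynamic,
    inputs = if (is.null(inputs)) setNames(numeric(0), character(0)) else inputs,
    edges = edges, beta = beta, alpha = alpha, gate = gate
  ), class = "hm_circuit")
  model$rhs <- compile_rhs(model)
  model
}

#' @export
print.hm_circuit <- function(x, ...) {
  cat(sprintf("hm_circuit: %d nodes (%d dynamic), %d edges\n",
              length(x$nodes), length(x$dynamic), nrow(x$edges)))
  invisible(x)
}

compile_rhs <- function(model) {
  dynamic <- model$dynamic
  reg <- lapply(dynamic, function(nd) {
    e <- model$edges[model$edges$to == nd, , drop = FALSE]
    list(from = e$from, sign = e$sign, k = e$k, n = e$n)
  })
  names(reg) <- dynamic
  inputs <- model$inputs
  beta <- model$beta
  alpha <- model$alpha
  gate <- model$gate
  function(t, y) {
    level <- function(nm) {
      if (nm %in% names(inputs)) inputs[[nm]] else max(y[[nm]], 0)
    }
    d <- numeric(length(dynamic))
    for (i in seq_along(dynamic)) {
      nd <- dynamic[i]
      r <- reg[[nd]]
      if (length(r$from) == 0) {
        prod_term <- 0
      } else {
        h <- vapply(seq_along(r$from), function(j) {
          hill(level(r$from[j]), r$k[j], r$n[j], r$sign[j])
        }, numeric(1))
        prod_term <- if (gate[[nd]] == "AND") prod(h) else 1 - prod(1 - h)
      }
      d[i] <- beta[[nd]] * prod_term - alpha[[nd]] * y[[nd]]
    }
    d
  }
}

#' Simulate a circuit model
#'
#' Integrates the model with a stiff-capable solver ([deSolve::ode()],
#' `lsoda`). States are kept nonnegative: small solver undershoots are
#' clipped at zero (with a warning if the undershoot exceeds the tolerance).
#'
#' @param model an [build_model()] circuit.
#' @param x0 named numeric vector of initial levels for dynamical nodes
#'   (missing nodes start at 0).
#' @param t_end end time.
#' @param n_steps output grid resolution.
#' @param rtol,atol solver tolerances.
#' @return an object of class `hm_trajectory`: list with `time`, `states`
#'   (matrix time x variables, input nodes included as constant columns) and
#'   `model`.
#' @export
simulate_circuit <- function(model, x0 = NULL, t_end = 50, n_steps = 2000,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "hm_circuit"), t_end > 0)
  y0 <- setNames(rep(0, length(model$dynamic)), model$dynamic)
  if (!is.null(x0)) {
    if (any(x0 < 0)) stop("initial state must be nonnegative")
    y0[names(x0)[names(x0) %in% model$dynamic]] <-
      x0[names(x0) %in% model$dynamic]
  }
  times <- seq(0, t_end, length.out = n_steps)
  f <- model$rhs
  sol <- deSolve::ode(y = y0, times = times,
                      func = function(t, y, parms) list(f(t, y)),
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) stop("ODE solver failed to converge")
  states <- unclass(sol)[, -1, drop = FALSE]
  if (any(states < -1e-6)) {
    warning("solver undershoot below -1e-6 clipped to zero")
  }
  states[states < 0] <- 0
  for (nm in names(model$inputs)) {
    states <- cbind(states, rep(model$inputs[[nm]], nrow(states)))
    colnames(states)[ncol(states)] <- nm
  }
  structure(list(time = times, states = states, model = model),
            class = "hm_trajectory")
}

#' @export
print.hm_trajectory <- function(x, ...) {
  cat(sprintf("hm_trajectory: %d time points over [0, %g], variables: %s\n",
              length(x$time), max(x$time),
              paste(colnames(x$states), collapse = ", ")))
  invisible(x)
}

# numerical Jacobian of the RHS (central differences)
numeric_jacobian <- function(f, y, h = 1e-6) {
  d <- length(y)
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    hj <- h * max(1, abs(y[j]))
    yp <- y; yp[j] <- yp[j] + hj
    ym <- y; ym[j] <- ym[j] - hj
    J[, j] <- (f(0, yp) - f(0, ym)) / (2 * hj)
  }
  J
}

#' Find fixed points of a circuit model
#'
#' Multi-start damped-Newton root finding on the model right-hand side (with
#' external inputs frozen at their levels), followed by deduplication and
#' linear stability analysis: the Jacobian is evaluated numerically at each
#' root and the eigenvalues classify the point as a stable node, spiral
#' (stable with complex eigenvalues, i.e. damped-oscillatory), saddle or
#' unstable point.
#'
#' @param model an [build_model()] circuit.
#' @param grid_points per-dimension starting levels (scaled by each node's
#'   beta/alpha ratio when `scale = TRUE`).
#' @param extra_starts optional matrix of additional starting states.
#' @param ftol residual norm for acceptance (default 1e-9).
#' @param dedup_tol state-space deduplication tolerance (default 1e-6).
#' @param max_starts cap on the number of Newton starts.
#' @return list of fixed points, each with `state` (named), `eigenvalues`,
#'   `classification` and `stable`; empty (with a warning) if no start
#'   converges.
#' @export
find_fixed_points <- function(model, grid_points = c(0, 0.05, 0.2, 0.5, 0.9, 1.3),
                              extra_starts = NULL, ftol = 1e-9,
                              dedup_tol = 1e-6, max_starts = 20000) {
  stopifnot(inherits(model, "hm_circuit"))
  d <- length(model$dynamic)
  f <- model$rhs
  scale <- model$beta / model$alpha
  grids <- lapply(seq_len(d), function(i) grid_points * max(scale[i], 1))
  starts <- as.matrix(expand.grid(grids))
  if (nrow(starts) > max_starts) {
    starts <- starts[seq(1, nrow(starts), length.out = max_starts), , drop = FALSE]
  }
  if (!is.null(extra_starts)) starts <- rbind(starts, as.matrix(extra_starts))
  found <- list()
  for (s in seq_len(nrow(starts))) {
    y <- setNames(as.numeric(starts[s, ]), model$dynamic)
    root <- newton_root(f, y, ftol = ftol)
    if (is.null(root)) next
    if (any(root < -1e-6)) next
    root[root < 0] <- 0
    if (length(found) > 0) {
      dists <- vapply(found, function(fp) max(abs(fp$state - root)), numeric(1))
      if (any(dists < dedup_tol)) next
    }
    J <- numeric_jacobian(f, root)
    ev <- eigen(J, only.values = TRUE)$values
    found[[length(found) + 1]] <- list(
      state = setNames(root, model$dynamic),
      eigenvalues = ev,
      classification = classify_eigenvalues(ev),
      stable = all(Re(ev) < 0)
    )
  }
  if (length(found) == 0) warning("no fixed point found from any start")
  found[order(vapply(found, function(fp) sum(fp$state), numeric(1)))]
}

classify_eigenvalues <- function(ev, tol = 1e-6) {
  re <- Re(ev)
  has_imag <- any(abs(Im(ev)) > tol)
  if (all(re < -tol)) {
    if (has_imag) "spiral" else "stable node"
  } else if (all(re > tol)) {
    "unstable"
  } else if (any(re > tol) && any(re < -tol)) {
    "saddle"
  } else {
    "marginal"
  }
}

newton_root <- function(f, y, ftol = 1e-9, max_iter = 80) {
  fy <- f(0, pmax(y, 0))
  for (it in seq_len(max_iter)) {
    nrm <- sqrt(sum(fy^2))
    if (nrm < ftol) return(pmax(y, 0))
    J <- numeric_jacobian(f, pmax(y, 0))
    step <- tryCatch(solve(J, -fy), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      ynew <- y + lambda * step
      fnew <- f(0, pmax(ynew, 0))
      if (sqrt(sum(fnew^2)) < nrm || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (lambda < 1e-6 && sqrt(sum(fnew^2)) >= nrm) return(NULL)
    y <- ynew
    fy <- fnew
  }
  NULL
}

# local maxima of x (interior), filtered by a minimal amplitude relative to
# the signal range; plateaus count once
find_peaks <- function(x, min_frac = 0.02) {
  n <- length(x)
  if (n < 3) return(integer(0))
  rng <- diff(range(x))
  if (rng == 0) return(integer(0))
  dx <- diff(x)
  sgn <- sign(dx)
  # carry the last nonzero slope through plateaus
  for (i in seq_along(sgn)) if (sgn[i] == 0 && i > 1) sgn[i] <- sgn[i - 1]
  idx <- which(diff(sgn) < 0) + 1L
  if (length(idx) == 0) return(integer(0))
  keep <- vapply(idx, function(i) {
    lo <- max(1, i - 1)
    left_min <- min(x[seq_len(i)])
    right_min <- min(x[seq.int(i, n)])
    (x[i] - max(min(left_min, right_min), -Inf)) > min_frac * rng &&
      (x[i] - min(left_min, right_min)) > min_frac * rng
  }, logical(1))
  idx[keep]
}

#' Classify the dynamical behavior of one variable
#'
#' Labels a trajectory variable as `monotone-converge`, `pulse` (single
#' interior maximum with the final level below half the peak),
#' `damped-oscillation` or `sustained-oscillation` (repeated peaks after the
#' transient window, discriminated by the trend of successive peak-to-trough
#' amplitudes). The first `transient` fraction of the trajectory is ignored
#' when judging oscillations.
#'
#' @param traj an [simulate_circuit()] trajectory.
#' @param variable variable (column) name.
#' @param transient fraction of the trajectory treated as transient.
#' @param sustain_ratio minimum late/early amplitude ratio to call
#'   oscillations sustained.
#' @return one of `"monotone-converge"`, `"pulse"`, `"damped-oscillation"`,
#'   `"sustained-oscillation"`, `"inconclusive"`.
#' @export
classify_dynamics <- function(traj, variable, transient = 0.3,
                              sustain_ratio = 0.9) {
  stopifnot(inherits(traj, "hm_trajectory"))
  x <- traj$states[, variable]
  n <- length(x)
  if (n < 50) return("inconclusive")
  peaks <- find_peaks(x)
  post_start <- ceiling(transient * n)
  peaks_post <- peaks[peaks >= post_start]
  if (length(peaks_post) >= 2 || length(peaks) >= 3) {
    # oscillatory: measure successive peak-to-trough amplitudes after the
    # transient (fall back to all peaks when the transient window is empty)
    pk <- if (length(peaks_post) >= 2) peaks_post else peaks
    amps <- vapply(seq_len(length(pk) - 1), function(i) {
      x[pk[i]] - min(x[pk[i]:pk[i + 1]])
    }, numeric(1))
    amps <- amps[amps > 0]
    if (length(amps) == 0) return("monotone-converge")
    if (length(amps) >= 2 &&
        amps[length(amps)] >= sustain_ratio * amps[1] &&
        amps[length(amps)] > 1e-3 * max(abs(x))) {
      return("sustained-oscillation")
    }
    return("damped-oscillation")
  }
  if (length(peaks) == 1) {
    pk <- peaks[1]
    if (pk > 1 && pk < n && x[n] < 0.5 * x[pk]) return("pulse")
  }
  "monotone-converge"
}

#' Phase relation between two oscillating variables
#'
#' Estimates the oscillation period from the peak spacing of the first
#' variable and the lag between the two variables from the peak of their
#' cross-correlation (post-transient, demeaned). A relative lag below 0.1 of
#' the period is called in-phase; within 0.1 of half a period, anti-phase.
#'
#' @param traj an [simulate_circuit()] trajectory.
#' @param var_a,var_b variable names.
#' @param transient fraction of the trajectory dropped as transient.
#' @return list with `phase` (`"in-phase"`, `"anti-phase"` or `"none"`),
#'   `lag` (time units, NA when not oscillatory), `period`.
#' @export
synchronization_metrics <- function(traj, var_a, var_b, transient = 0.3) {
  stopifnot(inherits(traj, "hm_trajectory"))
  cls_a <- classify_dynamics(traj, var_a, transient = transient)
  cls_b <- classify_dynamics(traj, var_b, transient = transient)
  osc <- c("damped-oscillation", "sustained-oscillation")
  if (!(cls_a %in% osc) || !(cls_b %in% osc)) {
    return(list(phase = "none", lag = NA_real_, period = NA_real_))
  }
  n <- length(traj$time)
  w <- seq.int(ceiling(transient * n), n)
  a <- traj$states[w, var_a]
  b <- traj$states[w, var_b]
  tt <- traj$time[w]
  dt <- mean(diff(tt))
  pk <- find_peaks(a)
  if (length(pk) < 2) {
    return(list(phase = "none", lag = NA_real_, period = NA_real_))
  }
  period <- mean(diff(tt[pk]))
  max_lag <- min(length(a) - 2, ceiling(period / dt))
  a0 <- a - mean(a)
  b0 <- b - mean(b)
  lags <- seq.int(-max_lag, max_lag)
  cc <- vapply(lags, function(L) {
    if (L >= 0) {
      ia <- seq.int(1 + L, length(a0))
      ib <- seq.int(1, length(b0) - L)
    } else {
      ia <- seq.int(1, length(a0) + L)
      ib <- seq.int(1 - L, length(b0))
    }
    sum(a0[ia] * b0[ib]) / sqrt(sum(a0[ia]^2) * sum(b0[ib]^2))
  }, numeric(1))
  lag_time <- lags[which.max(cc)] * dt
  rel <- ((lag_time / period) %% 1)
  phase <- if (min(rel, 1 - rel) < 0.1) {
    "in-phase"
  } else if (abs(rel - 0.5) < 0.1) {
    "anti-phase"
  } else {
    "none"
  }
  list(phase = phase, lag = lag_time, period = period)
}
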