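#' Parameters of the S-phase receptor-kinetics model
#'
#' The core oscillator model: cytosolic Plk4 binds unphosphorylated centriolar
#' Asl receptors with effective rate `k1 = k * [P]`; bound Plk4 phosphorylates
#' the receptor `N` times at per-site rate `k2`; from the fully phosphorylated
#' state Plk4 is released at rate `k3`, leaving a low-affinity receptor that
#' can no longer bind. The gradual conversion of receptors to the low-affinity
#' state is a time-delayed negative feedback that shapes a single S-phase pulse
#' of centriolar Plk4.
#'
#' Default rate values are the package's reference parameter set: `k3` is the
#' cycle-12 best-fit value 0.06906 and `N = 9` (ten receptor states: unbound
#' plus nine bound phospho-states); the remaining defaults give a
#' well-formed ~10 min S-phase pulse.
#'
#' @param k1 binding rate, 1/s (`k * [P]`); must be in (0, 1] when fitted.
#' @param k2 per-site phosphorylation rate, 1/s.
#' @param k3 release rate from the fully phosphorylated receptor, 1/s.
#' @param N integer number of phosphorylation steps (>= 1).
#' @param A0_init initial unbound receptor pool (receptor units).
#' @param Abound_init initial Plk4-bound unphosphorylated pool at CS.
#' @param scale a.u. per receptor unit mapping total bound Plk4 to fluorescence.
#' @return an object of class `model1_params`.
#' @export
model1_params <- function(k1 = 0.005, k2 = 0.04, k3 = 0.06906, N = 9,
                          A0_init = 1, Abound_init = 0.05, scale = 1) {
  if (any(c(k1, k2, k3) < 0)) stop_validation("rates must be >= 0")
  if (N < 1) stop_validation("N must be >= 1")
  if (A0_init < 0 || Abound_init < 0) stop_validation("initial pools must be >= 0")
  structure(list(k1 = k1, k2 = k2, k3 = k3, N = as.integer(N),
                 A0_init = A0_init, Abound_init = Abound_init, scale = scale),
            class = "model1_params")
}

#' @rdname model1_params
#' @param k4 dephosphorylation rate, 1/s; active only while the mitotic
#'   phosphatase is on. Default is the printed multi-cycle best-fit value.
#' @param ... arguments passed to [model1_params()].
#' @export
model2_params <- function(k4 = 0.0708, ...) {
  p <- model1_params(...)
  if (k4 < 0) stop_validation("k4 must be >= 0")
  p$k4 <- k4
  class(p) <- c("model2_params", "model1_params")
  p
}

#' @rdname model1_params
#' @param NP total Plk4 molecules in the embryo (conserved-pool variant).
#' @param NR Asl receptors per centriole.
#' @param NC0 centriole count in cycle 1.
#' @export
conserved_params <- function(NP = 1e5, NR = 30, NC0 = 1, k4 = 0.0612, ...) {
  p <- model2_params(k4 = k4, ...)
  if (NP < 1 || NR < 1 || NC0 < 1) stop_validation("NP, NR, NC0 must be >= 1")
  p$NP <- NP; p$NR <- NR; p$NC0 <- NC0
  class(p) <- c("conserved_params", class(p))
  p
}

#' Cell-cycle schedule for multi-cycle simulations
#'
#' Each nuclear cycle of period `T` is split into S-phase (first
#' `s_fraction` of the period; phosphatase off), mitosis (remainder;
#' phosphatase on), and a final `separation_fraction` of the period in which
#' duplicated centrioles separate nearly synchronously.
#'
#' @param T cycle period in seconds.
#' @param s_fraction fraction of the period outside mitosis (default 0.7, i.e.
#'   the embryo is in mitosis 30% of the time).
#' @param n_cycles number of nuclear cycles (fly embryos: 14).
#' @param separation_fraction final fraction of each cycle in which centrioles
#'   separate (default 0.1).
#' @return an object of class `cycle_schedule`.
#' @export
cycle_schedule <- function(T = 720, s_fraction = 0.7, n_cycles = 14,
                           separation_fraction = 0.1) {
  if (s_fraction <= 0 || s_fraction >= 1) stop_validation("s_fraction must be in (0,1)")
  if (separation_fraction <= 0 || separation_fraction >= 1)
    stop_validation("separation_fraction must be in (0,1)")
  structure(list(T = T, s_fraction = s_fraction, n_cycles = as.integer(n_cycles),
                 separation_fraction = separation_fraction),
            class = "cycle_schedule")
}

# Generator matrix of the S-phase linear chain on states
# (A0, A0*, A1*, ..., AN*); x' = M x.
model1_matrix <- function(p) {
  n <- p$N + 2L
  M <- matrix(0, n, n)
  M[1, 1] <- -p$k1              # A0 depleted by binding
  M[2, 1] <- p$k1               # A0 -> A0*
  M[2, 2] <- -p$k2
  for (i in seq_len(p$N - 1L)) { # Ai* for i = 1..N-1
    M[2 + i, 1 + i] <- p$k2
    M[2 + i, 2 + i] <- -p$k2
  }
  M[p$N + 2L, p$N + 1L] <- p$k2
  M[p$N + 2L, p$N + 2L] <- -p$k3
  M
}

model1_init <- function(p) c(p$A0_init, p$Abound_init, rep(0, p$N))

#' Exact solution of the S-phase oscillator model
#'
#' The S-phase chain is linear with constant coefficients, so its solution is
#' a sum of exponentials. Because the phosphorylation chain carries the
#' repeated eigenvalue `-k2`, the solution is confluent (polynomial-times-
#' exponential, Erlang-type); it is evaluated here exactly via the matrix
#' exponential of the chain's generator, which handles repeated eigenvalues
#' without special-casing.
#'
#' @param params a [model1_params] object.
#' @param t_grid times in seconds within `[0, S]` (S-phase).
#' @return a data.frame with columns `time`, `bound` (scaled total bound Plk4,
#'   `scale * sum_i [Ai*]`), `A0` (unbound receptors), `released` (cumulative
#'   Plk4 released, `A_tot - A0 - sum_i [Ai*]`), and one column per bound
#'   state `Astar0..AstarN`.
#' @seealso [model1_numeric()] for the independent adaptive-integration route.
#' @export
model1_analytic <- function(params, t_grid) {
  stopifnot(inherits(params, "model1_params"))
  if (any(t_grid < 0)) stop_validation("t_grid must be non-negative")
  M <- model1_matrix(params)
  x0 <- model1_init(params)
  dts <- diff(t_grid)
  uniform <- length(t_grid) > 2 && all(abs(dts - dts[1]) < 1e-9 * max(dts[1], 1))
  if (uniform) {
    # propagate with a single step matrix: x(t+dt) = expm(M dt) x(t)
    E <- as.matrix(Matrix::expm(M * dts[1]))
    states <- matrix(NA_real_, length(t_grid), length(x0))
    x <- as.numeric(Matrix::expm(M * t_grid[1]) %*% x0)
    states[1, ] <- x
    for (i in seq_along(dts)) {
      x <- as.numeric(E %*% x)
      states[i + 1, ] <- x
    }
  } else {
    states <- t(vapply(t_grid, function(t)
      as.numeric(Matrix::expm(M * t) %*% x0), numeric(length(x0))))
  }
  assemble_model1_trajectory(t_grid, states, params)
}

assemble_model1_trajectory <- function(t_grid, states, params) {
  bound_states <- states[, -1, drop = FALSE]
  bound <- rowSums(bound_states)
  a_tot <- params$A0_init + params$Abound_init
  out <- data.frame(time = t_grid, bound = params$scale * bound,
                    A0 = states[, 1], released = a_tot - states[, 1] - bound)
  colnames(bound_states) <- paste0("Astar", 0:params$N)
  cbind(out, bound_states)
}

#' Numerical solution of the S-phase oscillator model
#'
#' Independent route to the same trajectory as [model1_analytic()], via
#' adaptive stiff integration (`deSolve::ode`, lsoda) at tight tolerances.
#' A `released` state (`d released/dt = k3 [AN*]`) is carried explicitly so
#' that total receptor-associated material can be checked for conservation.
#'
#' @inheritParams model1_analytic
#' @param rtol,atol integration tolerances.
#' @return same layout as [model1_analytic()].
#' @export
model1_numeric <- function(params, t_grid, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "model1_params"))
  M <- model1_matrix(params)
  rhs <- function(t, y, parms) {
    x <- y[seq_len(nrow(M))]
    list(c(as.numeric(M %*% x), parms$k3 * x[length(x)]))
  }
  y0 <- c(model1_init(params), 0)
  times <- t_grid
  prepend <- times[1] != 0
  if (prepend) times <- c(0, times)
  sol <- deSolve::ode(y0, times, rhs, params, rtol = rtol, atol = atol)
  sol <- sol[, -1, drop = FALSE]
  if (prepend) sol <- sol[-1, , drop = FALSE]
  states <- sol[, seq_len(nrow(M)), drop = FALSE]
  out <- assemble_model1_trajectory(t_grid, states, params)
  out$released <- sol[, ncol(sol)]  # integrated release flux
  out
}

# Right-hand side of the multi-cycle model. States: unbound A0..AN then bound
# A0*..AN*. Dephosphorylation (rate k4, mitosis only) steps both the unbound
# and the bound chain down one phospho-state; release (k3) moves AN* -> AN;
# only A0 binds Plk4. In the conserved variant binding is k1*[P] with [P]
# computed from the sequestered fraction, and centriole duplication dilutes
# bound states into unbound ones while the centriole count NC(t) ramps.
model2_rhs <- function(t, y, ctx) {
  p <- ctx$params; N <- p$N
  A <- y[1:(N + 1)]; As <- y[(N + 2):(2 * N + 2)]
  phase <- (t %% ctx$T) / ctx$T
  k4 <- if (phase >= ctx$s_fraction) p$k4 else 0
  if (ctx$conserved) {
    cyc <- floor(t / ctx$T)
    nc_base <- p$NC0 * 2^cyc
    sep_start <- 1 - ctx$sep_frac
    if (phase >= sep_start) {
      ramp <- (phase - sep_start) / ctx$sep_frac
      NC <- nc_base * (1 + ramp)
      dNC <- nc_base / (ctx$sep_frac * ctx$T)
    } else { NC <- nc_base; dNC <- 0 }
    P <- 1 - (p$NR * NC / p$NP) * sum(As)
    P <- max(P, 0)
    k1eff <- p$k1 * P
    dil <- dNC / NC
  } else { k1eff <- p$k1; dil <- 0 }
  dA <- numeric(N + 1); dAs <- numeric(N + 1)
  # bound chain: bind, phosphorylate up, dephosphorylate down, release, dilute
  dAs[1] <- k1eff * A[1] - p$k2 * As[1] + k4 * As[2] - dil * As[1]
  for (j in seq(2, length.out = N - 1))  # Ai*, i = 1..N-1
    dAs[j] <- p$k2 * As[j - 1] - p$k2 * As[j] - k4 * As[j] + k4 * As[j + 1] -
      dil * As[j]
  dAs[N + 1] <- p$k2 * As[N] - p$k3 * As[N + 1] - k4 * As[N + 1] - dil * As[N + 1]
  # unbound chain: dephosphorylate down, receive Plk4-released receptors at AN,
  # receive diluted bound material at the same phospho-index
  dA[1] <- k4 * A[2] - k1eff * A[1] + dil * As[1]
  for (j in seq(2, length.out = N - 1))  # Ai, i = 1..N-1
    dA[j] <- k4 * A[j + 1] - k4 * A[j] + dil * As[j]
  dA[N + 1] <- p$k3 * As[N + 1] - k4 * A[N + 1] + dil * As[N + 1]
  list(c(dA, dAs))
}

#' Simulate the multi-cycle oscillator with mitotic phosphatase resetting
#'
#' Extends the S-phase chain over many nuclear cycles by letting a phosphatase
#' (rate `k4`) dephosphorylate receptors during mitosis only, resetting them to
#' the high-affinity state for the next cycle. Initial condition: all receptors
#' unbound and unphosphorylated. Two variants:
#' \describe{
#'   \item{constant-pool (default)}{cytosolic Plk4 is held constant, so the
#'     binding rate is simply `k1`; the model produces one sustained pulse of
#'     bound Plk4 per cycle.}
#'   \item{conserved (`conserved = TRUE`, requires [conserved_params()])}{the
#'     total number of Plk4 molecules `NP` is fixed; the free fraction `[P]`
#'     falls as receptors sequester Plk4, the centriole count doubles each
#'     cycle (continuously over the separation window, splitting bound Plk4
#'     between mother and daughter), and late-cycle pulse amplitudes decline
#'     as the exponentially growing receptor pool dilutes cytosolic Plk4.}
#' }
#'
#' @param params a [model2_params] (or [conserved_params]) object.
#' @param schedule a [cycle_schedule].
#' @param conserved logical; use the conserved total-Plk4 variant.
#' @param dt_out output sampling interval, seconds.
#' @return a data.frame with columns `time`, `cycle` (1-based), `bound_frac`
#'   (fraction of receptors in any bound state), `mass` (total receptor mass,
#'   conserved at 1); for the conserved variant also `P_frac` (free cytosolic
#'   Plk4 fraction), `bound_plk4_pct` (% of all Plk4 bound) and `NC`.
#' @export
model2_simulate <- function(params, schedule = cycle_schedule(),
                            conserved = inherits(params, "conserved_params"),
                            dt_out = 2) {
  stopifnot(inherits(params, "model2_params"), inherits(schedule, "cycle_schedule"))
  if (conserved && !inherits(params, "conserved_params"))
    stop_validation("conserved = TRUE requires conserved_params()")
  N <- params$N
  ctx <- list(params = params, T = schedule$T, s_fraction = schedule$s_fraction,
              sep_frac = schedule$separation_fraction, conserved = conserved)
  y0 <- c(1, rep(0, N), rep(0, N + 1))  # all receptors unbound, unphosphorylated
  t_end <- schedule$T * schedule$n_cycles
  # integrate phase-by-phase so the k4 / separation switches are never crossed
  # inside an adaptive step
  brk <- sort(unique(c(
    outer(c(0, schedule$s_fraction, 1 - schedule$separation_fraction),
          seq_len(schedule$n_cycles) - 1, function(f, c) (c + f) * schedule$T),
    t_end)))
  brk <- brk[brk <= t_end + 1e-9]
  out_t <- numeric(0); out_y <- NULL
  y <- y0
  for (i in seq_len(length(brk) - 1)) {
    tt <- unique(c(brk[i], seq(brk[i], brk[i + 1], by = dt_out), brk[i + 1]))
    tt <- sort(tt)
    # keep the evaluation strictly inside the phase for the switch functions
    ctx_i <- ctx
    sol <- deSolve::ode(y, tt, function(t, y, parms)
      model2_rhs(min(t, brk[i + 1] - 1e-9), y, parms), ctx_i,
      rtol = 1e-8, atol = 1e-10)
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- if (i == 1) seq_len(nrow(sol)) else -1L
    out_t <- c(out_t, sol[keep, 1])
    out_y <- rbind(out_y, sol[keep, -1, drop = FALSE])
  }
  As <- out_y[, (N + 2):(2 * N + 2), drop = FALSE]
  res <- data.frame(time = out_t,
                    cycle = pmin(floor(out_t / schedule$T) + 1L, schedule$n_cycles),
                    bound_frac = rowSums(As),
                    mass = rowSums(out_y))
  if (conserved) {
    cyc0 <- floor(res$time / schedule$T)
    phase <- (res$time %% schedule$T) / schedule$T
    sep_start <- 1 - schedule$separation_fraction
    nc_base <- params$NC0 * 2^cyc0
    NC <- ifelse(phase >= sep_start,
                 nc_base * (1 + (phase - sep_start) / schedule$separation_fraction),
                 nc_base)
    P <- pmax(1 - (params$NR * NC / params$NP) * res$bound_frac, 0)
    res$P_frac <- P
    res$bound_plk4_pct <- 100 * (1 - P)
    res$NC <- NC
  }
  res
}

#' Stochastic receptor-state ensemble
#'
#' Configuration for the discrete per-receptor model: each Asl receptor is an
#' independent Markov chain over the states (A0..AN, A0*..AN*) - exactly one
#' state is occupied at any time. Transition probabilities per step of length
#' `dt` follow the single-rate form `P = 1 - exp(-k dt)` and, for states with
#' two outgoing rates, the competing-rates form
#' `P_ij = k_i/(k_i+k_j) * (1 - exp(-(k_i+k_j) dt))`.
#'
#' @param n_centrioles number of centrioles.
#' @param n_receptors receptors per centriole (~30 at the assembly site).
#' @param params a [model2_params] object (rates k1, k2, k3, k4; chain length N).
#' @param pptase_mode `"mitotic_burst"` (k4 on only during mitosis, requires a
#'   schedule at simulation time) or `"constant_fraction"` (non-cycling
#'   embryos: a constant phosphatase level, default 10% of mitotic activity).
#' @param pptase_constant_frac constant phosphatase level as a fraction of k4.
#' @param dt time step in seconds.
#' @param seed RNG seed.
#' @return an object of class `receptor_ensemble`.
#' @export
receptor_ensemble <- function(n_centrioles = 10, n_receptors = 30,
                              params = model2_params(),
                              pptase_mode = c("mitotic_burst", "constant_fraction"),
                              pptase_constant_frac = 0.10, dt = 1, seed = NULL) {
  pptase_mode <- match.arg(pptase_mode)
  stopifnot(inherits(params, "model2_params"))
  rates <- c(params$k1, params$k2, params$k3, params$k4)
  if (any(1 - exp(-rates * dt) >= 1 - 1e-12) && any(rates * dt > 30))
    stop_validation("dt too large for the given rates")
  structure(list(n_centrioles = as.integer(n_centrioles),
                 n_receptors = as.integer(n_receptors), params = params,
                 pptase_mode = pptase_mode,
                 pptase_constant_frac = pptase_constant_frac,
                 dt = dt, seed = seed),
            class = "receptor_ensemble")
}

#' Simulate the stochastic per-receptor model
#'
#' Runs every receptor's discrete-time Markov chain and reports, per centriole,
#' the fraction of its receptors in any Plk4-bound state over time. Under a
#' cycling schedule the phosphatase fires in mitosis and, during the last
#' `separation_fraction` of each cycle, each bound receptor releases its Plk4
#' with total probability 50% over the window (mother-daughter separation).
#' In `"constant_fraction"` mode (non-cycling embryos) the phosphatase runs at
#' a constant fraction of its mitotic level and there are no separation events.
#'
#' @param ensemble a [receptor_ensemble].
#' @param duration total simulated time, seconds.
#' @param schedule a [cycle_schedule] (required for `"mitotic_burst"` mode).
#' @param init initial state for every receptor: `"unbound"` (A0) or
#'   `"bound"` (A0*).
#' @param method `"discrete"` (the model's fixed-step chain) or `"gillespie"`
#'   (exact continuous-time jumps; constant-rate oracle, no schedule).
#' @param separation logical; apply the 50% separation-window unbinding under
#'   a cycling schedule (disable to compare against the mean-field ODE model,
#'   which has no separation events in its constant-pool form).
#' @return list with `time` (vector), `bound_frac` (time x centriole matrix),
#'   `mean_bound` (ensemble mean over all receptors), `states` (final state
#'   index per receptor) and the `ensemble`.
#' @export
model3_simulate <- function(ensemble, duration, schedule = NULL,
                            init = c("unbound", "bound"),
                            method = c("discrete", "gillespie"),
                            separation = TRUE) {
  stopifnot(inherits(ensemble, "receptor_ensemble"))
  init <- match.arg(init); method <- match.arg(method)
  p <- ensemble$params; N <- p$N; dt <- ensemble$dt
  nrec <- ensemble$n_centrioles * ensemble$n_receptors
  centriole <- rep(seq_len(ensemble$n_centrioles), each = ensemble$n_receptors)
  if (ensemble$pptase_mode == "mitotic_burst" && is.null(schedule))
    stop_validation("mitotic_burst mode needs a cycle_schedule")
  if (method == "gillespie")
    return(model3_gillespie(ensemble, duration, init))
  steps <- floor(duration / dt)
  times <- seq(0, by = dt, length.out = steps + 1)
  # state encoding: 0..N unbound A_i; N+1 .. 2N+1 bound A*_{i-(N+1)}
  state0 <- if (init == "unbound") 0L else N + 1L
  local_seed(ensemble$seed, {
    state <- rep(state0, nrec)
    bf <- matrix(NA_real_, steps + 1, ensemble$n_centrioles)
    bound_now <- function(s) {
      b <- s > N
      vapply(split(b, centriole), mean, numeric(1))
    }
    bf[1, ] <- bound_now(state)
    p_single <- function(k) 1 - exp(-k * dt)
    for (st in seq_len(steps)) {
      t_now <- times[st]
      if (ensemble$pptase_mode == "mitotic_burst") {
        phase <- (t_now %% schedule$T) / schedule$T
        k4 <- if (phase >= schedule$s_fraction) p$k4 else 0
        in_sep <- separation && phase >= 1 - schedule$separation_fraction
        sep_hazard <- if (in_sep)
          1 - 0.5^(dt / (schedule$separation_fraction * schedule$T)) else 0
      } else {
        k4 <- p$k4 * ensemble$pptase_constant_frac
        sep_hazard <- 0
      }
      u <- stats::runif(nrec)
      new <- state
      # unbound A0: bind
      sel <- state == 0L
      new[sel & u < p_single(p$k1)] <- N + 1L
      # unbound Ai, i>=1: dephosphorylate one step down
      sel <- state >= 1L & state <= N
      if (k4 > 0) {
        mv <- sel & u < p_single(k4)
        new[mv] <- state[mv] - 1L
      }
      # bound A0*: phosphorylate up
      sel <- state == N + 1L
      new[sel & u < p_single(p$k2)] <- N + 2L
      # bound intermediate Ai*, 1 <= i <= N-1: k2 up vs k4 down
      sel <- state > N + 1L & state < 2L * N + 1L
      if (any(sel)) {
        ktot <- p$k2 + k4
        pmove <- 1 - exp(-ktot * dt)
        pup <- pmove * p$k2 / ktot
        up <- sel & u < pup
        dn <- sel & u >= pup & u < pmove
        new[up] <- state[up] + 1L
        new[dn] <- state[dn] - 1L
      }
      # bound AN*: k3 release (-> unbound AN) vs k4 down
      sel <- state == 2L * N + 1L
      if (any(sel)) {
        ktot <- p$k3 + k4
        pmove <- 1 - exp(-ktot * dt)
        prel <- pmove * p$k3 / ktot
        rel <- sel & u < prel
        dn <- sel & u >= prel & u < pmove
        new[rel] <- N
        new[dn] <- state[dn] - 1L
      }
      # mother-daughter separation: bound receptors release with 50% total
      # probability over the separation window
      if (sep_hazard > 0) {
        b <- new > N
        u2 <- stats::runif(nrec)
        unb <- b & u2 < sep_hazard
        new[unb] <- new[unb] - (N + 1L)
      }
      state <- new
      bf[st + 1, ] <- bound_now(state)
    }
    list(time = times, bound_frac = bf, mean_bound = rowMeans(bf),
         states = state, ensemble = ensemble)
  })
}

# Exact continuous-time jump simulation with constant rates (oracle for the
# fixed-step chain). k4 is held at its constant-fraction level.
model3_gillespie <- function(ensemble, duration, init) {
  p <- ensemble$params; N <- p$N
  k4 <- if (ensemble$pptase_mode == "constant_fraction")
    p$k4 * ensemble$pptase_constant_frac else p$k4
  nrec <- ensemble$n_centrioles * ensemble$n_receptors
  centriole <- rep(seq_len(ensemble$n_centrioles), each = ensemble$n_receptors)
  grid <- seq(0, duration, by = ensemble$dt)
  state0 <- if (init == "unbound") 0L else N + 1L
  local_seed(ensemble$seed, {
    occupancy <- matrix(0L, length(grid), nrec)
    final <- integer(nrec)
    for (r in seq_len(nrec)) {
      t <- 0; s <- state0
      path_t <- t; path_s <- s
      while (t < duration) {
        rates <- if (s == 0L) c(bind = p$k1)
        else if (s <= N) c(down = k4)
        else if (s == N + 1L) c(up = p$k2)
        else if (s < 2L * N + 1L) c(up = p$k2, down = k4)
        else c(release = p$k3, down = k4)
        tot <- sum(rates)
        if (tot <= 0) break
        t <- t + stats::rexp(1, tot)
        if (t >= duration) break
        what <- sample(names(rates), 1, prob = rates)
        s <- switch(what, bind = N + 1L, up = s + 1L, down = s - 1L, release = N)
        path_t <- c(path_t, t); path_s <- c(path_s, s)
      }
      idx <- findInterval(grid, path_t)
      occupancy[, r] <- as.integer(path_s[idx] > N)
      final[r] <- s
    }
    bf <- t(apply(occupancy, 1, function(row)
      vapply(split(row, centriole), mean, numeric(1))))
    if (ensemble$n_centrioles == 1L) bf <- matrix(rowMeans(occupancy), ncol = 1)
    list(time = grid, bound_frac = bf, mean_bound = rowMeans(occupancy),
         states = final, ensemble = ensemble)
  })
}
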