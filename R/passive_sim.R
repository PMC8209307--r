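# Passive cable compartmental model of a morphology and the response
# metrics used to compare original and predicted diameters: membrane time
# constants from a double-exponential fit of the transient after a brief
# current pulse, steady-state deflection under a prolonged step, and the
# peak depolarization from a dual-exponential synaptic conductance.
#
# Units: user interfaces are mV / ms / um / nA / pS; internally everything
# is SI (V, s, m, A, S, F).  Conversion happens at the module boundary.

#' Passive membrane and cytosolic parameters
#'
#' @param RM specific membrane resistance, Ohm m^2 (default 1.6).
#' @param CM specific membrane capacitance, F/m^2 (default 0.0186).
#' @param RA axial resistivity, Ohm m (default 1.98).
#' @param Em resting potential, mV (default -65; the response metrics for
#'   current steps are Em-invariant, the synaptic driving force is not).
#' @return List of class `passive_params`.  The defaults are the
#'   hippocampal-pyramidal parameter set used throughout the package
#'   examples; the membrane time constant they imply is
#'   `RM * CM = 29.76 ms`.
#' @export
passive_params <- function(RM = 1.6, CM = 0.0186, RA = 1.98, Em = -65) {
  stopifnot(RM > 0, CM > 0, RA > 0, is.finite(Em))
  structure(list(RM = RM, CM = CM, RA = RA, Em = Em),
            class = "passive_params")
}

#' Current-step stimulus
#'
#' @param amplitude nA.
#' @param duration ms (> 0).
#' @param onset ms.
#' @param site `"soma"` or an SWC node id.
#' @return List of class `stimulus` (kind `current_step`).  The two
#'   canonical protocols are the brief pulse (1 ms, 1.5 nA) used for the
#'   time-constant fit and the prolonged step (800 ms, 0.03 nA) used for
#'   the steady-state deflection.
#' @export
current_step <- function(amplitude, duration, onset = 1, site = "soma") {
  stopifnot(duration > 0)
  structure(list(kind = "current_step", amplitude = amplitude,
                 duration = duration, onset = onset, site = site),
            class = "stimulus")
}

#' Dual-exponential synaptic conductance stimulus
#'
#' `g(t) = gmax * N * (exp(-t/tau_decay) - exp(-t/tau_rise))`, with N
#' chosen so that the peak conductance equals `gmax`.
#'
#' @param gmax peak conductance, pS (default 10).
#' @param tau_rise,tau_decay rise and decay time constants, ms (defaults
#'   1 and 5; rise must be faster than decay).
#' @param reversal synaptic reversal potential, mV absolute (default 5,
#'   i.e. strongly depolarizing from rest).
#' @param onset ms.
#' @param site `"soma"` or an SWC node id (the dendritic input site).
#' @return List of class `stimulus` (kind `synaptic`).
#' @export
synaptic_input <- function(gmax = 10, tau_rise = 1, tau_decay = 5,
                           reversal = 5, onset = 1, site = "soma") {
  stopifnot(tau_rise < tau_decay, gmax >= 0)
  structure(list(kind = "synaptic", gmax = gmax, tau_rise = tau_rise,
                 tau_decay = tau_decay, reversal = reversal,
                 onset = onset, site = site),
            class = "stimulus")
}

#' Discretize a morphology into a passive compartmental model
#'
#' One compartment per SWC segment (the frustum between a node and its
#' parent), lumped at the node; the soma becomes a single
#' sphere-equivalent compartment of area `pi d^2`.  Membrane conductance
#' and capacitance come from the frustum's slant lateral area; the axial
#' resistance between a compartment and its parent is the exact frustum
#' form `RA L / (pi r1 r2)`.  Segments attached directly to the soma are
#' treated as cylinders of the node's own radius (the soma's bulk adds no
#' dendritic membrane).  Zero-length segments are merged into the parent
#' compartment with a warning.
#'
#' @param m a `morphology`; the soma is normalised to its 3-point form
#'   first (a no-op when already normalised).
#' @param p a [passive_params()] object.
#' @return Object of class `compartmental_model` with per-compartment
#'   membrane conductance `gm` (S), capacitance `cm` (F), area (m^2),
#'   parent links, axial conductances `ga` (S) and the node-to-compartment
#'   map.
#' @export
build_compartments <- function(m, p) {
  stopifnot(inherits(p, "passive_params"))
  m <- normalize_soma(m, "three_point")
  nd <- m$nodes
  pidx <- parent_index(m)
  soma <- nd$type == SWC_SOMA
  root <- which(nd$parent == -1L)
  um <- 1e-6

  n_node <- nrow(nd)
  comp_of <- integer(n_node)        # compartment index per node row
  comp_of[soma] <- 1L

  soma_d <- 2 * nd$radius[root[1]] * um
  area <- pi * soma_d^2             # sphere-equivalent soma area, m^2
  parent <- 0L
  ga <- NA_real_
  ncomp <- 1L

  ord <- traversal_order(m)
  seg_area <- numeric(n_node); seg_ga <- numeric(n_node)
  seg_parent <- integer(n_node)
  nseg <- 0L
  for (i in ord) {
    if (soma[i]) next
    pr <- pidx[i]
    L <- sqrt((nd$x[i] - nd$x[pr])^2 + (nd$y[i] - nd$y[pr])^2 +
                (nd$z[i] - nd$z[pr])^2) * um
    r2 <- nd$radius[i] * um
    r1 <- if (soma[pr]) r2 else nd$radius[pr] * um
    if (L < 1e-12) {
      warning("zero-length segment at node ", nd$id[i],
              " merged into its parent compartment", call. = FALSE)
      comp_of[i] <- comp_of[pr]
      next
    }
    ncomp <- ncomp + 1L
    comp_of[i] <- ncomp
    nseg <- nseg + 1L
    seg_area[nseg] <- pi * (r1 + r2) * sqrt((r2 - r1)^2 + L^2)
    seg_ga[nseg] <- pi * r1 * r2 / (p$RA * L)
    seg_parent[nseg] <- comp_of[pr]
  }
  area <- c(area, seg_area[seq_len(nseg)])
  parent <- c(parent, seg_parent[seq_len(nseg)])
  ga <- c(ga, seg_ga[seq_len(nseg)])
  node2comp <- stats::setNames(comp_of, nd$id)
  structure(list(n = ncomp, parent = parent, ga = ga,
                 gm = area / p$RM, cm = area * p$CM, area = area,
                 Em = p$Em * 1e-3, params = p,
                 node2comp = node2comp,
                 soma_comp = 1L),
            class = "compartmental_model")
}

#' @export
print.compartmental_model <- function(x, ...) {
  cat(sprintf(
    "<compartmental_model> %d compartments, total area %.4g um^2, Em %.1f mV\n",
    x$n, sum(x$area) * 1e12, x$Em * 1e3))
  invisible(x)
}

# resolve a stimulus/recording site to a compartment index
site_to_comp <- function(model, site) {
  if (identical(site, "soma")) return(model$soma_comp)
  comp <- model$node2comp[as.character(site)]
  if (is.na(comp)) stop("unknown site (node id): ", site)
  unname(comp)
}

# sparse conductance matrix: membrane leak on the diagonal plus the
# axial graph Laplacian (symmetric by construction)
conductance_matrix <- function(model) {
  n <- model$n
  k <- which(model$parent > 0)
  pk <- model$parent[k]
  g <- model$ga[k]
  i <- c(seq_len(n), k, pk, k, pk)
  j <- c(seq_len(n), k, pk, pk, k)
  x <- c(model$gm, g, g, -g, -g)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

#' Steady-state voltage under constant current injection
#'
#' Solves the passive system `G V = gm Em + I` directly (no time
#' stepping); the exact plateau of the discretized model.
#'
#' @param model a `compartmental_model`.
#' @param amplitude injected current, nA.
#' @param site `"soma"` or node id.
#' @return Numeric vector of compartment voltages, mV.
#' @export
steady_state_voltage <- function(model, amplitude, site = "soma") {
  G <- conductance_matrix(model)
  b <- model$gm * model$Em
  b[site_to_comp(model, site)] <- b[site_to_comp(model, site)] +
    amplitude * 1e-9
  as.numeric(Matrix::solve(G, b)) * 1e3
}

#' Simulate the passive response to a stimulus
#'
#' Backward-Euler (implicit, unconditionally stable) integration of the
#' passive cable tree, with a single sparse Cholesky factorization reused
#' across steps.  Synaptic conductance enters as an explicit current
#' `g(t) (E_rev - V_n)` evaluated at the previous step, which is accurate
#' for the picosiemens-scale conductances used here.
#'
#' @param model a `compartmental_model`.
#' @param stim a [current_step()] or [synaptic_input()] stimulus.
#' @param dt time step, ms (default 0.01).
#' @param t_end total simulated time, ms.
#' @param record compartment sites to record: vector of `"soma"`/node ids.
#' @return List of class `passive_trace`: `time` (ms), `v` (matrix, mV,
#'   one column per recorded site), `sites`, `stim`, `dt`.
#' @export
simulate_passive <- function(model, stim, dt = 0.01, t_end,
                             record = "soma") {
  stopifnot(inherits(model, "compartmental_model"),
            inherits(stim, "stimulus"), dt > 0, t_end > dt)
  n <- model$n
  G <- conductance_matrix(model)
  dts <- dt * 1e-3
  A <- G + Matrix::Diagonal(n, model$cm / dts)
  ch <- Matrix::Cholesky(methods::as(Matrix::forceSymmetric(A),
                                     "CsparseMatrix"), LDL = FALSE)
  rec <- vapply(record, function(s) site_to_comp(model, s), integer(1))
  scomp <- site_to_comp(model, stim$site)

  nstep <- ceiling(t_end / dt)
  times <- seq(0, by = dt, length.out = nstep + 1)
  v <- rep(model$Em, n)
  out <- matrix(NA_real_, nstep + 1, length(rec))
  out[1, ] <- v[rec]
  b0 <- model$gm * model$Em
  if (stim$kind == "synaptic") {
    tp <- (stim$tau_rise * stim$tau_decay / (stim$tau_decay -
             stim$tau_rise)) * log(stim$tau_decay / stim$tau_rise)
    gnorm <- 1 / (exp(-tp / stim$tau_decay) - exp(-tp / stim$tau_rise))
    erev <- stim$reversal * 1e-3
  }
  for (s in seq_len(nstep)) {
    t_new <- times[s + 1]
    b <- b0 + model$cm / dts * v
    if (stim$kind == "current_step") {
      if (t_new > stim$onset && t_new <= stim$onset + stim$duration)
        b[scomp] <- b[scomp] + stim$amplitude * 1e-9
    } else {
      trel <- times[s] - stim$onset
      if (trel >= 0) {
        g <- stim$gmax * 1e-12 * gnorm *
          (exp(-trel / stim$tau_decay) - exp(-trel / stim$tau_rise))
        b[scomp] <- b[scomp] + g * (erev - v[scomp])
      }
    }
    v <- as.numeric(Matrix::solve(ch, b))
    if (any(!is.finite(v)))
      stop("solver divergence: non-finite voltage at t = ", t_new, " ms")
    out[s + 1, ] <- v[rec]
  }
  structure(list(time = times, v = out * 1e3,
                 sites = record, stim = stim, dt = dt),
            class = "passive_trace")
}

#' Fit a double exponential to a voltage transient
#'
#' Fits `V(t) = Vinf + A1 exp(-t/tau1) + A2 exp(-t/tau2)` to the decay
#' following a brief pulse, by nonlinear least squares initialized by
#' log-linear peeling (slow component from the tail, fast component from
#' the early residual).  Time constants are returned slow-first
#' (`tau1 >= tau2`), the convention used for reporting.
#'
#' @param time time vector, ms.
#' @param v voltage vector, mV (same length).
#' @param window optional `c(t0, t1)` restricting the fit (ms); default
#'   uses the whole trace.
#' @return List: `tau1`, `tau2` (ms), `A1`, `A2`, `Vinf` (mV),
#'   `degenerate` (TRUE when the two components are indistinguishable).
#' @export
fit_double_exponential <- function(time, v, window = NULL) {
  if (!is.null(window)) {
    keep <- time >= window[1] & time <= window[2]
    time <- time[keep]; v <- v[keep]
  }
  if (length(time) < 8) stop("fit error: too few samples in window")
  t0 <- time - time[1]
  vinf0 <- mean(v[t0 >= 0.9 * max(t0)])
  w <- v - vinf0
  sgn <- sign(w[1])
  if (sgn == 0) sgn <- 1
  w <- w * sgn
  amp_head <- mean(abs(w[t0 <= 0.02 * max(t0)]))
  sd_tail <- stats::sd(w[t0 >= 0.8 * max(t0)])
  if (max(w) <= 0 ||
      mean(w[t0 <= 0.1 * max(t0)]) < mean(w[t0 >= 0.8 * max(t0)]) ||
      (is.finite(sd_tail) && amp_head < 5 * sd_tail))
    stop("fit error: window is not a decaying transient")
  # peel: slow tau from the tail
  tail_i <- which(t0 >= 0.4 * max(t0) & w > 0)
  tau1_0 <- if (length(tail_i) >= 3)
    -1 / stats::coef(stats::lm(log(w[tail_i]) ~ t0[tail_i]))[[2]]
  else max(t0) / 3
  if (!is.finite(tau1_0) || tau1_0 <= 0) tau1_0 <- max(t0) / 3
  a1_0 <- max(w[1] * 0.7, 1e-9)
  early <- w - a1_0 * exp(-t0 / tau1_0)
  tau2_0 <- max(tau1_0 / 10, min(diff(time)) * 2)
  df <- data.frame(t = t0, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ v0 + a1 * exp(-t / tau1) + a2 * exp(-t / tau2), data = df,
      start = list(v0 = 0, a1 = a1_0, a2 = max(w[1] - a1_0, 1e-9),
                   tau1 = tau1_0, tau2 = tau2_0),
      lower = c(-Inf, 0, 0, 1e-6, 1e-6),
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # pure single-exponential transients make the 5-parameter problem
    # singular; fall back to one component and flag it degenerate
    f1 <- minpack.lm::nlsLM(w ~ v0 + a1 * exp(-t / tau1), data = df,
                            start = list(v0 = 0, a1 = max(w[1], 1e-9),
                                         tau1 = tau1_0),
                            lower = c(-Inf, 0, 1e-6),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 1000, ftol = 1e-12))
    co <- stats::coef(f1)
    return(list(tau1 = co[["tau1"]], tau2 = co[["tau1"]],
                A1 = co[["a1"]] * sgn, A2 = 0,
                Vinf = vinf0 + co[["v0"]] * sgn,
                degenerate = TRUE))
  }
  co <- stats::coef(fit)
  vinf0 <- vinf0 + co[["v0"]] * sgn
  taus <- c(co[["tau1"]], co[["tau2"]])
  amps <- c(co[["a1"]], co[["a2"]]) * sgn
  o <- order(taus, decreasing = TRUE)
  taus <- taus[o]; amps <- amps[o]
  degenerate <- taus[1] / taus[2] < 1.05 ||
    abs(amps[2]) < 1e-6 * abs(amps[1])
  list(tau1 = taus[1], tau2 = taus[2], A1 = amps[1], A2 = amps[2],
       Vinf = vinf0, degenerate = degenerate)
}

#' Steady-state deflection from a prolonged current step
#'
#' @param time,v trace vectors (ms, mV).
#' @param baseline_window,plateau_window `c(t0, t1)` windows (ms).
#' @param slope_tol plateau criterion: warn when |dV/dt| in the plateau
#'   window exceeds this (mV/ms, default 1e-4).
#' @return `deltaV` in mV: mean(plateau) - mean(baseline).
#' @export
steady_state_deflection <- function(time, v, baseline_window,
                                    plateau_window, slope_tol = 1e-4) {
  bw <- time >= baseline_window[1] & time <= baseline_window[2]
  pw <- time >= plateau_window[1] & time <= plateau_window[2]
  if (!any(bw) || !any(pw)) stop("empty baseline or plateau window")
  slope <- abs(stats::coef(stats::lm(v[pw] ~ time[pw]))[[2]])
  if (slope > slope_tol)
    warning("plateau not reached (|dV/dt| = ", format(slope, digits = 3),
            " mV/ms); deflection estimate flagged", call. = FALSE)
  mean(v[pw]) - mean(v[bw])
}

#' Peak depolarization in response to synaptic input
#'
#' Simulates the dual-exponential synaptic conductance at a dendritic
#' site and reports the peak depolarization from rest at the input site
#' and at the soma.
#'
#' @param model a `compartmental_model`.
#' @param syn a [synaptic_input()] stimulus (its `site` is the dendritic
#'   input compartment).
#' @param dt,t_end integration settings, ms.
#' @return List: `dendrite` and `soma` peak depolarizations (mV), plus
#'   the full `trace`.
#' @export
synaptic_response <- function(model, syn, dt = 0.025, t_end = 60) {
  if (syn$reversal < model$Em * 1e3)
    warning("synaptic reversal below rest: response will hyperpolarize",
            call. = FALSE)
  tr <- simulate_passive(model, syn, dt = dt, t_end = t_end,
                         record = list(syn$site, "soma"))
  em <- model$Em * 1e3
  list(dendrite = max(tr$v[, 1]) - em,
       soma = max(tr$v[, 2]) - em,
       trace = tr)
}

#' Normalized difference between predicted and original response metrics
#'
#' `|predicted - original| / |original|` per metric; the paper-standard
#' dimensionless ratio for comparing morphologies electrically.
#'
#' @param pred_metrics,orig_metrics named numeric vectors (or lists) with
#'   matching names, e.g. `c(tau1 = ..., tau2 = ..., deltaV = ...)`.
#' @return Named numeric vector of ratios (>= 0).
#' @export
normalized_difference <- function(pred_metrics, orig_metrics) {
  p <- unlist(pred_metrics); o <- unlist(orig_metrics)
  common <- intersect(names(p), names(o))
  if (!length(common)) stop("no shared metric names")
  if (any(o[common] == 0))
    stop("undefined: original metric is zero for ",
         paste(common[o[common] == 0], collapse = ", "))
  abs(p[common] - o[common]) / abs(o[common])
}

#' Full passive characterization of a morphology
#'
#' Convenience wrapper running the three canonical protocols: brief soma
#' pulse (1 ms, 1.5 nA) for the double-exponential time constants,
#' prolonged soma step (800 ms, 0.03 nA) for the steady-state deflection,
#' and, optionally, a dendritic synaptic input (10 pS, 1/5 ms, +5 mV)
#' for the synaptic peaks.
#'
#' @param m a `morphology`.
#' @param p a [passive_params()] object.
#' @param syn_site optional SWC node id for the synaptic input site;
#'   `NULL` skips the synaptic protocol.
#' @param dt integration step, ms (default 0.025).
#' @return Named list: `tau1`, `tau2`, `deltaV`, and when `syn_site` is
#'   given `syn_dend`, `syn_soma`.
#' @export
response_metrics <- function(m, p = passive_params(), syn_site = NULL,
                             dt = 0.025) {
  model <- build_compartments(m, p)
  tau_ceiling <- p$RM * p$CM * 1e3          # isopotential limit, ms
  t_end <- max(8 * tau_ceiling, 60)
  brief <- current_step(amplitude = 1.5, duration = 1, onset = 1)
  tr <- simulate_passive(model, brief, dt = dt, t_end = t_end)
  off <- brief$onset + brief$duration
  fit <- fit_double_exponential(tr$time, tr$v[, 1],
                                window = c(off + 0.2, t_end))
  long <- current_step(amplitude = 0.03, duration = 800, onset = 20)
  tr2 <- simulate_passive(model, long, dt = max(dt, 0.05), t_end = 900)
  dv <- steady_state_deflection(tr2$time, tr2$v[, 1],
                                baseline_window = c(0, 19),
                                plateau_window = c(700, 810))
  out <- list(tau1 = fit$tau1, tau2 = fit$tau2, deltaV = dv)
  if (!is.null(syn_site)) {
    syn <- synaptic_input(site = syn_site)
    sr <- synaptic_response(model, syn, dt = dt)
    out$syn_dend <- sr$dendrite
    out$syn_soma <- sr$soma
  }
  out
}
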