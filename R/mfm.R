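#' Reduced Wong-Wang mean-field model parameters
#'
#' One neural-mass per region with a single synaptic gating variable S. The
#' total input current to region i is
#' x_i = w J_N S_i + J_N G sum_j C_ij S_j + I0, the firing rate follows the
#' sigmoidal transfer R(x) = (a x - b) / (1 - exp(-d (a x - b))), and the
#' gating evolves as dS/dt = -S/tau_S + (1 - S) gamma R + sigma eta(t).
#' The free parameters explored during working-point fitting are the global
#' coupling G and the synaptic decay time tau_S; the remaining constants
#' are frozen at their standard values.
#'
#' @param G global coupling scale of long-range connectivity.
#' @param tau_s_ms NMDA synaptic decay time constant, ms.
#' @param w relative strength of local recurrent connections (0.9).
#' @param I0 external input current, nA (0.32).
#' @param J_N synaptic current intensity scale, nA (0.2609).
#' @param gamma_k kinetic rate parameter of gating activation (0.641).
#' @param a,b,d transfer-function constants: a = 270 (V nC)^-1,
#'   b = 108 Hz, d = 0.154 s.
#' @param sigma noise amplitude of the gating equation.
#' @param dt_ms integration step, ms; must be <= tau_s_ms / 10.
#' @param T_ms total simulated time, ms.
#' @param transient_fraction initial fraction of steps discarded.
#' @return an object of class \code{mfm_params}.
#' @export
mfm_params <- function(G = 1.5, tau_s_ms = 25, w = 0.9, I0 = 0.32,
                       J_N = 0.2609, gamma_k = 0.641, a = 270, b = 108,
                       d = 0.154, sigma = 0.03, dt_ms = 1,
                       T_ms = 4e5, transient_fraction = 0.1) {
  stopifnot(G >= 0, tau_s_ms > 0, sigma > 0, dt_ms > 0, T_ms > 0,
            transient_fraction >= 0, transient_fraction < 1)
  if (dt_ms > tau_s_ms / 10)
    stop("dt_ms must be at most tau_s_ms / 10 for a stable integration")
  structure(list(G = G, tau_s_ms = tau_s_ms, w = w, I0 = I0, J_N = J_N,
                 gamma_k = gamma_k, a = a, b = b, d = d, sigma = sigma,
                 dt_ms = dt_ms, T_ms = T_ms,
                 transient_fraction = transient_fraction),
            class = "mfm_params")
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Canonical constants of the single-compartment hemodynamic model linking
#' neural activity to BOLD: signal decay kappa = 0.65 1/s, flow feedback
#' gamma = 0.41 1/s, transit time tau = 0.98 s, vessel stiffness
#' alpha = 0.32, resting oxygen extraction rho = 0.34, resting blood volume
#' fraction V0 = 0.02.
#'
#' @param signal_decay_kappa,feedback_gamma,transit_tau,stiffness_alpha,oxygen_extraction_rho,v0
#'   positive reals, see description.
#' @param TR_seconds BOLD sampling period (volume repetition time), s.
#' @return an object of class \code{hemo_params}.
#' @export
hemo_params <- function(signal_decay_kappa = 0.65, feedback_gamma = 0.41,
                        transit_tau = 0.98, stiffness_alpha = 0.32,
                        oxygen_extraction_rho = 0.34, v0 = 0.02,
                        TR_seconds = 2) {
  vals <- c(signal_decay_kappa, feedback_gamma, transit_tau,
            stiffness_alpha, oxygen_extraction_rho, v0, TR_seconds)
  stopifnot(all(vals > 0))
  structure(list(signal_decay_kappa = signal_decay_kappa,
                 feedback_gamma = feedback_gamma, transit_tau = transit_tau,
                 stiffness_alpha = stiffness_alpha,
                 oxygen_extraction_rho = oxygen_extraction_rho, v0 = v0,
                 TR_seconds = TR_seconds),
            class = "hemo_params")
}

#' Firing rate from input current
#'
#' The Wong-Wang transfer function R(x) = (a x - b)/(1 - exp(-d (a x - b))),
#' evaluated as 1/d at the removable singularity a x = b. Monotone
#' nondecreasing and nonnegative.
#'
#' @param x input current (vectorized).
#' @param p [mfm_params()] supplying a, b, d.
#' @return firing rate(s), Hz.
#' @export
rate_from_current <- function(x, p = mfm_params()) {
  u <- p$a * x - p$b
  out <- ifelse(abs(u) < 1e-9, 1 / p$d, u / (1 - exp(-p$d * u)))
  as.numeric(out)
}

#' Simulate the mean-field network model
#'
#' Euler-Maruyama integration of the reduced Wong-Wang network on an SC
#' graph; the gating variable is clipped to [0, 1] after each step and the
#' initial \code{transient_fraction} of steps is discarded.
#'
#' @param sc a [connectome()] of kind SC, spectrally normalized (applied
#'   internally if not).
#' @param p [mfm_params()].
#' @param seed integer RNG seed.
#' @return list of class \code{neural_trajectory}: \code{S} (steps x
#'   regions gating), \code{dt_ms}, \code{region_labels}, \code{params}.
#' @export
simulate_mfm <- function(sc, p = mfm_params(), seed = 0) {
  stopifnot(inherits(sc, "connectome"), sc$kind == "SC")
  if (!is_normalized(sc)) sc <- spectral_normalize(sc)
  n <- nrow(sc$values)
  n_steps <- as.integer(round(p$T_ms / p$dt_ms))
  set.seed(seed)
  S0 <- stats::runif(n, 0.0, 0.2)
  S <- .sim_mfm_cpp(sc$values, p$G, p$tau_s_ms, p$w, p$I0, p$J_N,
                    p$gamma_k, p$a, p$b, p$d, p$sigma, p$dt_ms, n_steps, S0)
  drop_n <- floor(p$transient_fraction * n_steps)
  if (drop_n > 0) S <- S[-seq_len(drop_n), , drop = FALSE]
  structure(list(S = S, dt_ms = p$dt_ms,
                 region_labels = sc$region_labels, params = p),
            class = "neural_trajectory")
}

#' @export
print.neural_trajectory <- function(x, ...) {
  cat(sprintf("<neural_trajectory> %d steps x %d regions, dt = %g ms\n",
              nrow(x$S), ncol(x$S), x$dt_ms))
  invisible(x)
}

#' Noise-free uncoupled fixed point of the gating equation
#'
#' Solves 0 = -S/tau_S + (1 - S) gamma R(x(S)) for a single isolated region
#' by root bracketing; used as the deterministic reference the simulator
#' must relax to when sigma = 0 and G = 0.
#'
#' @param p [mfm_params()].
#' @return the stationary gating level S* in [0, 1].
#' @export
mfm_fixed_point <- function(p = mfm_params()) {
  fun <- function(S) {
    x <- p$w * p$J_N * S + p$I0
    -S / p$tau_s_ms + (1 - S) * p$gamma_k * rate_from_current(x, p) * 1e-3
  }
  stats::uniroot(fun, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

#' Emulate BOLD from simulated neural activity
#'
#' Integrates the four-state Balloon-Windkessel system (vasodilatory
#' signal, inflow, venous volume, deoxyhemoglobin) per region, driven by
#' the synaptic gating variable, and decimates the BOLD output to one
#' sample per TR. Hemodynamic states start at the fixed point matching the
#' first drive sample, so a constant drive yields a constant baseline.
#'
#' @param traj a \code{neural_trajectory} from [simulate_mfm()] (or any
#'   list with \code{S} and \code{dt_ms}).
#' @param h [hemo_params()].
#' @return a [bold_ts()] sampled at \code{h$TR_seconds}.
#' @export
bold_from_activity <- function(traj, h = hemo_params()) {
  S <- traj$S
  if (nrow(S) * traj$dt_ms / 1000 < 2 * h$TR_seconds)
    stop("trajectory shorter than 2 TRs")
  bold <- .bold_bw_cpp(S, traj$dt_ms, h$signal_decay_kappa,
                       h$feedback_gamma, h$transit_tau, h$stiffness_alpha,
                       h$oxygen_extraction_rho, h$v0, h$TR_seconds)
  bold_ts(bold, h$TR_seconds, traj$region_labels %||% default_labels(ncol(S)))
}

#' Spatial heterogeneity of activation
#'
#' Ratio between the variance and the mean, across regions, of the
#' time-averaged signal. Near the model's best-fit zone some regions ignite
#' to high activity while others stay low, maximizing this spatial
#' coefficient; far from it activity is homogeneous and the score drops.
#' Computed on raw (not demeaned) signals.
#'
#' @param bold a [bold_ts()] (or a \code{neural_trajectory}, in which case
#'   the gating variable is used directly).
#' @param type \code{"var_over_mean"} (default) or \code{"cv"}
#'   (SD over mean).
#' @return a nonnegative real.
#' @export
spatial_heterogeneity <- function(bold, type = c("var_over_mean", "cv")) {
  type <- match.arg(type)
  x <- if (inherits(bold, "bold_ts")) bold$samples else bold$S
  if (ncol(x) < 2L) stop("need at least 2 regions")
  mu <- colMeans(x)
  m <- mean(mu)
  if (m <= 0)
    stop("mean activation is not positive; heterogeneity needs raw signals")
  v <- mean((mu - m)^2)  # population variance across regions
  if (type == "var_over_mean") v / m else sqrt(v) / m
}
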