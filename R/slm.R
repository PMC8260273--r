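#' Stochastic linear model parameters
#'
#' The SLM describes regional activity as coupled Ornstein-Uhlenbeck
#' processes, dx = A x dt + sigma dW with A = -I + G W, where W is the
#' (spectrally normalized) structural connectome. The system is stable for
#' G below the critical coupling 1/max(lambda), and its stationary
#' covariance has the closed form C = -(sigma^2/2) A^(-1).
#'
#' @param G global coupling (>= 0). The default is the reference value
#'   \code{G_ref}, usable for any spectrally normalized SC.
#' @param sigma noise standard deviation; the default 1 is a pure scale
#'   choice that cancels in the correlation normalization.
#' @param G_ref reference coupling used when completing without a fitting
#'   target; 0.83 is the median best-fit coupling across subjects reported
#'   for this model family on normalized connectomes.
#' @param epsilon subcritical safety margin as a fraction of the critical
#'   coupling: couplings G >= (1 - epsilon) / max eigenvalue are rejected.
#' @return an object of class \code{slm_params}.
#' @export
slm_params <- function(G = G_ref, sigma = 1, G_ref = 0.83, epsilon = 1e-3) {
  stopifnot(G >= 0, sigma > 0, epsilon > 0, epsilon < 1)
  structure(list(G = G, sigma = sigma, G_ref = G_ref, epsilon = epsilon),
            class = "slm_params")
}

#' Critical coupling of the linear model
#'
#' Reciprocal of the largest eigenvalue of the weight matrix: the coupling
#' at which the linear system -I + G W loses stability. Equal to 1 for a
#' spectrally normalized SC.
#'
#' @param sc a [connectome()] of kind SC.
#' @return the critical coupling, a positive real.
#' @export
critical_coupling <- function(sc) {
  stopifnot(inherits(sc, "connectome"), sc$kind == "SC")
  lam <- max_eigenvalue(sc$values)
  if (lam <= 0) stop("largest eigenvalue is not positive (all-zero SC?)")
  1 / lam
}

slm_coupling_matrix <- function(sc, p) {
  g_crit <- critical_coupling(sc)
  if (p$G >= g_crit * (1 - p$epsilon))
    stop(sprintf("supercritical coupling: G = %.4g >= (1 - eps) G_critic = %.4g",
                 p$G, g_crit * (1 - p$epsilon)))
  -diag(nrow(sc$values)) + p$G * sc$values
}

#' Analytic stationary covariance of the linear model
#'
#' For subcritical coupling the stationary covariance of the coupled
#' Ornstein-Uhlenbeck system is C = -(sigma^2 / 2) A^(-1) with
#' A = -I + G W; it is symmetric positive definite. Its correlation
#' normalization is the model's prediction of functional connectivity.
#'
#' @param sc a [connectome()] of kind SC.
#' @param p [slm_params()].
#' @return list with \code{values} (the covariance matrix) and
#'   \code{scale_note} documenting the arbitrary noise scaling.
#' @export
analytic_covariance <- function(sc, p = slm_params()) {
  A <- slm_coupling_matrix(sc, p)
  C <- -(p$sigma^2 / 2) * solve(A)
  C <- (C + t(C)) / 2
  structure(list(values = C,
                 scale_note = paste0("absolute scale arbitrary (sigma = ",
                                     p$sigma, ")")),
            class = "covariance_matrix")
}

#' Simulate the stochastic linear model
#'
#' Euler-Maruyama integration of the coupled Ornstein-Uhlenbeck system; the
#' first 10% of steps are discarded as transient. Determinism is governed
#' by \code{seed}.
#'
#' @param sc a [connectome()] of kind SC.
#' @param p [slm_params()].
#' @param T_steps number of integration steps (before transient discard).
#' @param dt integration step in model time units; must satisfy
#'   dt < 2/|min eigenvalue of A| for stability.
#' @param seed integer RNG seed.
#' @param transient_fraction initial fraction discarded.
#' @return a [bold_ts()] (dt in the model's arbitrary time units).
#' @export
simulate_slm <- function(sc, p = slm_params(), T_steps = 10000, dt = 0.01,
                         seed = 0, transient_fraction = 0.1) {
  A <- slm_coupling_matrix(sc, p)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (dt >= 2 / max(abs(ev)))
    stop(sprintf("unstable dt: need dt < %.4g", 2 / max(abs(ev))))
  n <- nrow(A)
  set.seed(seed)
  x <- .sim_slm_cpp(A, p$sigma, dt, as.integer(T_steps), numeric(n))
  drop_n <- floor(transient_fraction * nrow(x))
  if (drop_n > 0) x <- x[-seq_len(drop_n), , drop = FALSE]
  bold_ts(x, dt, sc$region_labels)
}

#' Linear SC-to-FC completion
#'
#' Evaluates the analytic covariance of the linear model on the (spectrally
#' normalized) SC at the reference coupling and normalizes it into a
#' Pearson correlation matrix. The noise amplitude cancels, so the result
#' is independent of sigma.
#'
#' @param sc a [connectome()] of kind SC (normalized internally if needed).
#' @param p [slm_params()]; \code{p$G} defaults to \code{G_ref} = 0.83.
#' @return a [connectome()] of kind FC, provenance \code{virtual_slm}.
#' @export
linear_sc_to_fc <- function(sc, p = slm_params()) {
  if (!is_normalized(sc)) sc <- spectral_normalize(sc)
  C <- analytic_covariance(sc, p)$values
  fc <- stats::cov2cor(C)
  fc <- pmin(pmax(fc, -1), 1)
  diag(fc) <- 1
  connectome(fc, kind = "FC", provenance = "virtual_slm",
             region_labels = sc$region_labels,
             meta = list(method = "slm", G = p$G, sigma = p$sigma))
}

#' Linear FC-to-SC completion
#'
#' Inverts the analytic covariance relation: W* = -C^(-1) / G_ref, with the
#' diagonal zeroed to avoid offsets. The absolute scale of the result is
#' arbitrary; only relative connection strengths are meaningful. An FC
#' correlation matrix is accepted as a covariance surrogate (unit
#' variances); a [bold_ts()] input is first turned into its sample
#' covariance.
#'
#' @param source a [connectome()] of kind FC, a \code{covariance_matrix},
#'   or a [bold_ts()] (requires more timepoints than regions).
#' @param p [slm_params()].
#' @param clip_negative clip negative off-diagonal entries of W* to zero so
#'   the result is a valid SC (default). With \code{FALSE} the raw signed
#'   inversion is returned (entry checks relaxed), which preserves the
#'   exact algebraic round trip with [analytic_covariance()].
#' @return a [connectome()] of kind SC, provenance \code{virtual_slm}.
#' @export
linear_fc_to_sc <- function(source, p = slm_params(), clip_negative = TRUE) {
  labels <- NULL
  if (inherits(source, "bold_ts")) {
    if (nrow(source$samples) <= ncol(source$samples))
      stop("need more timepoints than regions to estimate covariance")
    C <- stats::cov(source$samples)
    labels <- source$region_labels
  } else if (inherits(source, "covariance_matrix")) {
    C <- source$values
  } else if (inherits(source, "connectome")) {
    stopifnot(source$kind == "FC")
    C <- source$values
    labels <- source$region_labels
  } else stop("unsupported source type")
  if (kappa_cond(C) > 1e12)
    stop("covariance is singular or ill-conditioned")
  W <- -solve(C) / p$G_ref
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (clip_negative) W[W < 0] <- 0
  connectome(W, kind = "SC", provenance = "virtual_slm",
             region_labels = labels,
             meta = list(method = "slm", G_ref = p$G_ref,
                         clipped = clip_negative,
                         scale_note = "absolute scale arbitrary"),
             check = clip_negative)
}

kappa_cond <- function(m) {
  ev <- abs(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (min(ev) == 0) return(Inf)
  max(ev) / min(ev)
}
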