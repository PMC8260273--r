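#' Grid specification for working-point search
#'
#' Ranges and resolution of the (G, tau) exploration used to locate the
#' model's best-fit zone: coupling G in [1, 3], synaptic decay tau in
#' [1, 100] ms by default.
#'
#' @param g_min,g_max coupling range.
#' @param tau_min_ms,tau_max_ms synaptic time-constant range, ms.
#' @param n_g,n_tau grid resolution (>= 3 each).
#' @return an object of class \code{grid_spec}.
#' @export
grid_spec <- function(g_min = 1, g_max = 3, tau_min_ms = 1,
                      tau_max_ms = 100, n_g = 9, n_tau = 9) {
  stopifnot(g_min < g_max, tau_min_ms < tau_max_ms, n_g >= 3, n_tau >= 3)
  structure(list(g_min = g_min, g_max = g_max, tau_min_ms = tau_min_ms,
                 tau_max_ms = tau_max_ms, n_g = as.integer(n_g),
                 n_tau = as.integer(n_tau)),
            class = "grid_spec")
}

#' Effective-connectivity iteration parameters
#'
#' Controls the nonlinear FC-to-SC inversion: starting from a random
#' symmetric matrix, the candidate SC is nudged along the FC mismatch,
#' SC(k+1) = SC(k) + lambda (FC_target - FC(k)), where FC(k) is simulated
#' from SC(k) at a frozen working point; iteration stops when the
#' correlation between simulated and target FC reaches \code{cc_target}.
#'
#' @param learning_rate_lambda step size of the update (> 0). The default
#'   0.01 keeps the approach to the stop threshold monotone; larger rates
#'   (e.g. 0.05) oscillate around the solution manifold and can orbit for
#'   thousands of iterations before a lucky crossing.
#' @param cc_target stop threshold on the FC fit correlation, default 0.7.
#' @param max_iterations iteration cap, default 2000.
#' @param mfm [mfm_params()] at the frozen working point used for every
#'   inner simulation; inner runs use 0.2 of its \code{T_ms} (the
#'   short-run convention), with a final full-length confirmation run.
#' @param hemo [hemo_params()] for the BOLD stage.
#' @param init_mode \code{"random_symmetric"} or \code{"provided"}.
#' @param init_sc starting SC when \code{init_mode = "provided"}.
#' @param seed integer RNG seed (initial matrix and inner simulations).
#' @return an object of class \code{ec_params}.
#' @export
ec_params <- function(learning_rate_lambda = 0.01, cc_target = 0.7,
                      max_iterations = 2000, mfm = mfm_params(),
                      hemo = hemo_params(),
                      init_mode = c("random_symmetric", "provided"),
                      init_sc = NULL, seed = 0) {
  init_mode <- match.arg(init_mode)
  stopifnot(learning_rate_lambda > 0, cc_target > 0, cc_target <= 1,
            max_iterations >= 1)
  if (init_mode == "provided" && is.null(init_sc))
    stop("init_mode = 'provided' needs init_sc")
  structure(list(learning_rate_lambda = learning_rate_lambda,
                 cc_target = cc_target,
                 max_iterations = as.integer(max_iterations),
                 mfm = mfm, hemo = hemo, init_mode = init_mode,
                 init_sc = init_sc, seed = as.integer(seed)),
            class = "ec_params")
}

mfm_bold <- function(sc, p, hemo, seed) {
  traj <- simulate_mfm(sc, p, seed = seed)
  bold_from_activity(traj, hemo)
}

short_params <- function(p, fraction = 0.2) {
  q <- p
  q$T_ms <- p$T_ms * fraction
  q
}

grid_cell_criteria <- function(sc, p, hemo, seed, window_s, step_s) {
  bold <- mfm_bold(sc, short_params(p), hemo, seed)
  crit1 <- spatial_heterogeneity(bold)
  fc <- pearson_fc(bold, provenance = "virtual_mfm")
  crit2 <- mean(weighted_clustering(fc))
  stream <- sliding_window_fc(bold, window_s, step_s)
  dfc <- dfc_matrix(stream)
  crit3 <- mean(weighted_clustering(dfc$values))
  c(crit1 = crit1, crit2 = crit2, crit3 = crit3)
}

minmax_norm <- function(m) {
  fin <- is.finite(m)
  lo <- min(m[fin]); hi <- max(m[fin])
  if (hi == lo) return(ifelse(fin, 1, -Inf))
  out <- (m - lo) / (hi - lo)
  out[!fin] <- -Inf
  out
}

#' Grid search for the mean-field working point
#'
#' Scans the (G, tau) grid; in each cell a short simulation (0.2 of the
#' full duration) is run with a cell-specific seed and three criteria are
#' scored: spatial heterogeneity of activation, mean weighted clustering of
#' the time-averaged FC, and mean weighted clustering of the dFC matrix.
#' The selected working point maximizes the product of the min-max
#' normalized criteria ("jointly optimum"). Cells whose simulation fails
#' are scored -Inf and the search continues.
#'
#' @param sc a [connectome()] of kind SC (normalized internally).
#' @param grid a [grid_spec()].
#' @param p [mfm_params()] providing the frozen constants and full T.
#' @param hemo [hemo_params()].
#' @param seed master seed; each cell uses a distinct stride-derived seed
#'   (recorded in \code{cell_seeds}).
#' @param window_s,step_s dFC window and step, seconds.
#' @return an object of class \code{grid_search_result} with criterion maps
#'   \code{crit1..crit3}, \code{combined_score}, \code{g_star},
#'   \code{tau_star}, \code{g_values}, \code{tau_values},
#'   \code{cell_seeds}.
#' @export
grid_search_working_point <- function(sc, grid = grid_spec(),
                                      p = mfm_params(),
                                      hemo = hemo_params(), seed = 0,
                                      window_s = 60, step_s = 10) {
  if (!is_normalized(sc)) sc <- spectral_normalize(sc)
  gs <- seq(grid$g_min, grid$g_max, length.out = grid$n_g)
  taus <- seq(grid$tau_min_ms, grid$tau_max_ms, length.out = grid$n_tau)
  crit1 <- crit2 <- crit3 <- matrix(NA_real_, grid$n_g, grid$n_tau,
                                    dimnames = list(signif(gs, 4),
                                                    signif(taus, 4)))
  cell_seeds <- matrix(NA_integer_, grid$n_g, grid$n_tau)
  idx <- 0L
  failures <- character(0)
  for (i in seq_along(gs)) for (j in seq_along(taus)) {
    idx <- idx + 1L
    cell_seeds[i, j] <- seed + 1009L * idx
    pij <- p
    pij$G <- gs[i]
    pij$tau_s_ms <- taus[j]
    pij$dt_ms <- min(p$dt_ms, taus[j] / 10)
    res <- tryCatch(
      grid_cell_criteria(sc, pij, hemo, cell_seeds[i, j], window_s, step_s),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("G=%.3g tau=%.3g: %s", gs[i],
                                      taus[j], conditionMessage(res)))
      crit1[i, j] <- crit2[i, j] <- crit3[i, j] <- -Inf
    } else {
      crit1[i, j] <- res["crit1"]
      crit2[i, j] <- res["crit2"]
      crit3[i, j] <- res["crit3"]
    }
  }
  if (all(!is.finite(crit1))) stop("all grid cells failed")
  combined <- minmax_norm(crit1) * minmax_norm(crit2) * minmax_norm(crit3)
  best <- which(combined == max(combined), arr.ind = TRUE)[1, ]
  structure(list(crit1 = crit1, crit2 = crit2, crit3 = crit3,
                 combined_score = combined,
                 g_star = gs[best[1]], tau_star = taus[best[2]],
                 g_values = gs, tau_values = taus,
                 cell_seeds = cell_seeds, failures = failures),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %dx%d grid, G* = %.4g, tau* = %.4g ms\n",
              length(x$g_values), length(x$tau_values), x$g_star,
              x$tau_star))
  if (length(x$failures))
    cat("  failed cells:", length(x$failures), "\n")
  invisible(x)
}

#' Nonlinear SC-to-FC completion
#'
#' Simulates the mean-field model embedding the SC at the working point
#' (G*, tau*) for the full duration, emulates BOLD, and returns the Pearson
#' FC of the simulated signals. With \code{working_point = NULL} the grid
#' search is run first.
#'
#' @param sc a [connectome()] of kind SC.
#' @param working_point numeric c(G, tau_ms), or NULL for automatic search.
#' @param p [mfm_params()] (G and tau are overridden by the working point).
#' @param hemo [hemo_params()].
#' @param seed integer RNG seed for the final simulation.
#' @param grid [grid_spec()] used when searching automatically.
#' @return a [connectome()] of kind FC, provenance \code{virtual_mfm}, with
#'   the working point and seed in \code{meta}.
#' @export
nonlinear_sc_to_fc <- function(sc, working_point = NULL, p = mfm_params(),
                               hemo = hemo_params(), seed = 0,
                               grid = grid_spec()) {
  if (!is_normalized(sc)) sc <- spectral_normalize(sc)
  if (is.null(working_point)) {
    gsr <- grid_search_working_point(sc, grid, p, hemo, seed = seed)
    working_point <- c(gsr$g_star, gsr$tau_star)
  }
  p$G <- working_point[1]
  p$tau_s_ms <- working_point[2]
  p$dt_ms <- min(p$dt_ms, p$tau_s_ms / 10)
  bold <- mfm_bold(sc, p, hemo, seed)
  fc <- pearson_fc(bold, provenance = "virtual_mfm")
  fc$region_labels <- sc$region_labels
  dimnames(fc$values) <- list(sc$region_labels, sc$region_labels)
  fc$meta <- list(method = "mfm", G = p$G, tau_ms = p$tau_s_ms, seed = seed,
                  T_ms = p$T_ms)
  fc
}

project_sc <- function(W) {
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W[W < 0] <- 0
  lam <- max_eigenvalue(W)
  if (lam <= 0) stop("candidate SC collapsed to zero")
  W / lam
}

#' Nonlinear FC-to-SC completion (effective-connectivity inversion)
#'
#' Grows a structural connectome compatible with a target FC: starting from
#' a random symmetric matrix, each iteration simulates the mean-field model
#' on the current candidate (short run), measures the mismatch to the
#' target FC, and updates SC(k+1) = SC(k) + lambda (FC_target - FC(k)).
#' After each update the candidate is symmetrized, diagonal-zeroed,
#' negative-clipped and spectrally normalized. Iteration stops when the
#' simulated-vs-target FC correlation reaches \code{cc_target} (then a
#' full-length confirmation run is recorded) or at the iteration cap. A
#' sustained decrease of the fit over 50 consecutive iterations aborts with
#' a diagnostic.
#'
#' @param fc_target a [connectome()] of kind FC.
#' @param ec [ec_params()].
#' @param truth_sc optional ground-truth SC; when supplied, the fit of the
#'   candidate to it is recorded per iteration (benchmarking only; it never
#'   influences the iteration).
#' @return list with \code{sc} (a [connectome()] of kind SC, provenance
#'   \code{virtual_mfm}) and \code{trace} (class \code{ec_trace}:
#'   \code{cc_to_target_fc}, optional \code{cc_to_truth_sc},
#'   \code{stop_reason}, \code{iterations_run}, \code{cc_final_full}).
#' @export
nonlinear_fc_to_sc <- function(fc_target, ec = ec_params(),
                               truth_sc = NULL) {
  stopifnot(inherits(fc_target, "connectome"), fc_target$kind == "FC")
  n <- nrow(fc_target$values)
  target <- fc_target$values
  set.seed(ec$seed)
  if (ec$init_mode == "random_symmetric") {
    W <- matrix(stats::runif(n * n), n, n)
    W <- project_sc(W)
  } else {
    W <- project_sc(ec$init_sc$values)
  }
  p_short <- short_params(ec$mfm)
  lam <- ec$learning_rate_lambda
  cc_hist <- numeric(0)
  truth_hist <- if (is.null(truth_sc)) NULL else numeric(0)
  stop_reason <- "max_iter"
  decline <- 0L
  fc_k <- NULL
  for (k in seq_len(ec$max_iterations)) {
    sck <- connectome(W, kind = "SC", provenance = "virtual_mfm",
                      region_labels = fc_target$region_labels)
    bold <- mfm_bold(sck, p_short, ec$hemo, seed = ec$seed + 100003L * k)
    fc_k <- pearson_fc(bold, provenance = "virtual_mfm")
    cc <- fit_correlation(fc_k$values, target)
    cc_hist <- c(cc_hist, cc)
    if (!is.null(truth_sc))
      truth_hist <- c(truth_hist, fit_correlation(W, truth_sc$values))
    prev <- if (k > 1) cc_hist[k - 1] else -Inf
    if (cc < prev) decline <- decline + 1L else decline <- 0L
    if (decline >= 50L)
      stop(sprintf(
        "effective-connectivity iteration diverging: fit decreasing for 50 iterations (last cc = %.3f at iteration %d)",
        cc, k))
    if (cc >= ec$cc_target) { stop_reason <- "target_reached"; break }
    W <- project_sc(W + lam * (target - fc_k$values))
  }
  iterations_run <- length(cc_hist)
  # full-length confirmation run at the final iterate
  sc_final <- connectome(W, kind = "SC", provenance = "virtual_mfm",
                         region_labels = fc_target$region_labels,
                         meta = list(method = "mfm_ec",
                                     G = ec$mfm$G, tau_ms = ec$mfm$tau_s_ms,
                                     lambda = lam, cc_target = ec$cc_target,
                                     seed = ec$seed,
                                     iterations = iterations_run,
                                     stop_reason = stop_reason))
  bold_full <- mfm_bold(sc_final, ec$mfm, ec$hemo, seed = ec$seed)
  cc_full <- fit_correlation(pearson_fc(bold_full)$values, target)
  trace <- structure(list(cc_to_target_fc = cc_hist,
                          cc_to_truth_sc = truth_hist,
                          stop_reason = stop_reason,
                          iterations_run = iterations_run,
                          cc_final_full = cc_full),
                     class = "ec_trace")
  list(sc = sc_final, trace = trace)
}

#' @export
print.ec_trace <- function(x, ...) {
  cat(sprintf(
    "<ec_trace> %d iterations, stop = %s, final cc(FC*, FC_target) = %.3f\n",
    x$iterations_run, x$stop_reason,
    x$cc_to_target_fc[x$iterations_run]))
  invisible(x)
}

#' Bivirtual dual of a connectome
#'
#' Chains both completion directions with one model family to return to the
#' original kind: SC -> virtual FC -> bivirtual SC, or FC -> virtual SC ->
#' bivirtual FC. The result is a fully synthetic surrogate of the input
#' carrying comparable network information.
#'
#' @param c a [connectome()] of either kind.
#' @param method \code{"slm"} (linear, closed form) or \code{"mfm"}
#'   (nonlinear, simulation based).
#' @param seed integer RNG seed for the nonlinear legs.
#' @param slm [slm_params()] for the linear legs.
#' @param working_point numeric c(G, tau_ms) for the nonlinear legs (NULL
#'   runs the grid search on the first leg's input).
#' @param ec [ec_params()] for the nonlinear FC-to-SC leg.
#' @param p,hemo [mfm_params()] and [hemo_params()] for nonlinear legs.
#' @return a [connectome()] of the same kind as the input, provenance
#'   \code{bivirtual_slm} or \code{bivirtual_mfm}, with both legs recorded
#'   in \code{meta}.
#' @export
bivirtual_dual <- function(c, method = c("slm", "mfm"), seed = 0,
                           slm = slm_params(), working_point = NULL,
                           ec = NULL, p = mfm_params(),
                           hemo = hemo_params()) {
  method <- match.arg(method)
  stopifnot(inherits(c, "connectome"))
  if (method == "slm") {
    if (c$kind == "SC") {
      leg1 <- linear_sc_to_fc(c, slm)
      out <- linear_fc_to_sc(leg1, slm)
    } else {
      leg1 <- linear_fc_to_sc(c, slm)
      out <- linear_sc_to_fc(leg1, slm)
    }
    out$provenance <- "bivirtual_slm"
    out$meta <- list(method = "slm_chain", G = slm$G, G_ref = slm$G_ref)
    return(out)
  }
  if (c$kind == "SC") {
    sc_in <- if (is_normalized(c)) c else spectral_normalize(c)
    if (is.null(working_point)) {
      gsr <- grid_search_working_point(sc_in, p = p, hemo = hemo,
                                       seed = seed)
      working_point <- c(gsr$g_star, gsr$tau_star)
    }
    leg1 <- nonlinear_sc_to_fc(sc_in, working_point, p, hemo, seed = seed)
    if (is.null(ec)) {
      p_wp <- p
      p_wp$G <- working_point[1]
      p_wp$tau_s_ms <- working_point[2]
      p_wp$dt_ms <- min(p$dt_ms, p_wp$tau_s_ms / 10)
      ec <- ec_params(mfm = p_wp, hemo = hemo, seed = seed + 1)
    }
    res <- nonlinear_fc_to_sc(leg1, ec)
    out <- res$sc
    out$provenance <- "bivirtual_mfm"
    out$meta <- c(out$meta,
                  list(leg1 = "nonlinear_sc_to_fc",
                       leg2 = "nonlinear_fc_to_sc",
                       working_point = working_point, seed = seed))
    return(out)
  }
  # FC input: effective-connectivity inversion first, then forward run
  if (is.null(ec)) ec <- ec_params(mfm = p, hemo = hemo, seed = seed)
  res <- nonlinear_fc_to_sc(c, ec)
  wp <- c(ec$mfm$G, ec$mfm$tau_s_ms)
  out <- nonlinear_sc_to_fc(res$sc, wp, ec$mfm, ec$hemo, seed = seed)
  out$provenance <- "bivirtual_mfm"
  out$meta <- c(out$meta, list(leg1 = "nonlinear_fc_to_sc",
                               leg2 = "nonlinear_sc_to_fc", seed = seed))
  out
}

#' Virtual cohort of stochastic FC completions
#'
#' Runs the nonlinear SC-to-FC completion repeatedly with consecutive seeds
#' at a working point fitted once, yielding an ensemble of equally valid FC
#' surrogates for one subject (data augmentation).
#'
#' @param sc a [connectome()] of kind SC.
#' @param n_instances number of completions (>= 2); 100 reproduces the
#'   published cohort convention.
#' @param base_seed first seed; instance k uses \code{base_seed + k - 1}.
#' @param working_point numeric c(G, tau_ms) or NULL for automatic search
#'   (run once, shared by all instances).
#' @param p,hemo model parameter bundles.
#' @param cohort_id identifier stored in each instance's \code{meta}.
#' @return list of FC [connectome()]s, each with the shared working point,
#'   its seed and the cohort id in \code{meta}.
#' @export
generate_virtual_cohort <- function(sc, n_instances = 100, base_seed = 0,
                                    working_point = NULL, p = mfm_params(),
                                    hemo = hemo_params(),
                                    cohort_id = "cohort") {
  stopifnot(n_instances >= 2)
  if (!is_normalized(sc)) sc <- spectral_normalize(sc)
  if (is.null(working_point)) {
    gsr <- grid_search_working_point(sc, p = p, hemo = hemo,
                                     seed = base_seed)
    working_point <- c(gsr$g_star, gsr$tau_star)
  }
  lapply(seq_len(n_instances), function(k) {
    fc <- nonlinear_sc_to_fc(sc, working_point, p, hemo,
                             seed = base_seed + k - 1)
    fc$meta$cohort_id <- cohort_id
    fc$meta$instance <- k
    fc
  })
}
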