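#' Sliding-window stream of time-resolved FC
#'
#' Splits a BOLD time series into windows of \code{window_s} seconds
#' advancing by \code{step_s} seconds and computes the Pearson FC of each
#' window. The last partial window is dropped. Windows containing a
#' zero-variance region are kept but flagged (\code{flagged} indices) with
#' the offending correlations set to 0 rather than silently dropped.
#'
#' @param bold a [bold_ts()].
#' @param window_s window length, seconds (>= 3 samples).
#' @param step_s step between window starts, seconds.
#' @return an object of class \code{fc_stream}: \code{windows} (list of FC
#'   [connectome()]s), \code{window_length_samples}, \code{step_samples},
#'   \code{t_centers} (s), \code{flagged}.
#' @export
sliding_window_fc <- function(bold, window_s = 60, step_s = 10) {
  stopifnot(inherits(bold, "bold_ts"))
  wl <- as.integer(floor(window_s / bold$dt_seconds))
  st <- as.integer(floor(step_s / bold$dt_seconds))
  if (wl < 3L) stop("window too short: fewer than 3 samples")
  if (st < 1L) stop("step shorter than one sample")
  n_t <- nrow(bold$samples)
  if (n_t < wl) stop("time series shorter than one window")
  starts <- seq(1L, n_t - wl + 1L, by = st)
  flagged <- integer(0)
  windows <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    seg <- bold$samples[starts[k]:(starts[k] + wl - 1L), , drop = FALSE]
    v <- apply(seg, 2L, stats::var)
    if (any(v == 0)) {
      flagged <- c(flagged, k)
      fc <- suppressWarnings(stats::cor(seg))
      fc[!is.finite(fc)] <- 0
    } else {
      fc <- stats::cor(seg)
    }
    fc <- pmin(pmax(fc, -1), 1)
    diag(fc) <- 1
    windows[[k]] <- connectome(fc, kind = "FC",
                               region_labels = bold$region_labels)
  }
  if (length(windows) < 2L) stop("need at least 2 full windows")
  structure(list(windows = windows, window_length_samples = wl,
                 step_samples = st,
                 t_centers = (starts - 1 + (wl - 1) / 2) * bold$dt_seconds,
                 flagged = flagged),
            class = "fc_stream")
}

#' dFC matrix: similarity between time-resolved FC snapshots
#'
#' Entry (t1, t2) is the Pearson correlation between the strict
#' upper-triangular vectorizations of FC(t1) and FC(t2). Blocks of high
#' inter-window correlation ("knots") indicate transiently stable FC;
#' low-correlation stripes ("leaps") indicate fast network
#' reconfiguration. Negative entries are retained.
#'
#' @param stream an \code{fc_stream} from [sliding_window_fc()].
#' @return an object of class \code{dfc_matrix} with \code{values}
#'   (windows x windows, unit diagonal) and the window metadata.
#' @export
dfc_matrix <- function(stream) {
  stopifnot(inherits(stream, "fc_stream"))
  k <- length(stream$windows)
  if (k < 2L) stop("need at least 2 windows")
  uts <- vapply(stream$windows, function(w) upper_tri_vec(w$values),
                numeric(length(upper_tri_vec(stream$windows[[1]]$values))))
  if (any(apply(uts, 2L, stats::var) == 0))
    stop("constant upper triangle in a window")
  d <- stats::cor(uts)
  d <- pmin(pmax((d + t(d)) / 2, -1), 1)
  diag(d) <- 1
  structure(list(values = d, t_centers = stream$t_centers,
                 window_length_samples = stream$window_length_samples,
                 step_samples = stream$step_samples),
            class = "dfc_matrix")
}

#' @export
print.dfc_matrix <- function(x, ...) {
  cat(sprintf("<dfc_matrix> %d windows, mean off-diagonal %.3f\n",
              nrow(x$values), mean(upper_tri_vec(x$values))))
  invisible(x)
}
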