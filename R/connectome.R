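#' Connectome matrix container
#'
#' A `connectome` is a square, symmetric, weighted matrix tagged by kind
#' (structural, \code{"SC"}, or functional, \code{"FC"}) and provenance
#' (whether it is empirical, model-generated, or synthetic ground truth).
#' It is the universal currency of all completion pipelines: structural
#' connectomes are nonnegative with a zero diagonal, functional connectomes
#' are correlation matrices with a unit diagonal and entries in [-1, 1].
#'
#' Small asymmetries (max abs difference between the matrix and its
#' transpose below \code{tol}) are averaged away; larger asymmetries are an
#' error. The SC diagonal is forced to zero and the FC diagonal to one.
#'
#' @param values square numeric matrix, regions x regions.
#' @param kind \code{"SC"} or \code{"FC"}.
#' @param provenance one of \code{"empirical"}, \code{"virtual_slm"},
#'   \code{"virtual_mfm"}, \code{"bivirtual_slm"}, \code{"bivirtual_mfm"},
#'   \code{"synthetic_truth"}.
#' @param region_labels character vector of unique region names; defaults to
#'   \code{"R000"}, \code{"R001"}, ...
#' @param meta free-form list of provenance details (seed, method,
#'   parameters), carried along and written to the sidecar on disk.
#' @param tol symmetrization tolerance.
#' @param check if \code{FALSE}, skip range checks on the entries (used
#'   internally for raw, unclipped inversion output).
#' @return an object of class \code{connectome}.
#' @export
connectome <- function(values, kind = c("SC", "FC"),
                       provenance = "empirical",
                       region_labels = NULL, meta = list(),
                       tol = 1e-9, check = TRUE) {
  kind <- match.arg(kind)
  provenances <- c("empirical", "virtual_slm", "virtual_mfm",
                   "bivirtual_slm", "bivirtual_mfm", "synthetic_truth")
  provenance <- match.arg(provenance, provenances)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("connectome values must be a square matrix")
  n <- nrow(values)
  if (n < 2L) stop("a connectome needs at least 2 regions")
  if (any(!is.finite(values))) stop("connectome contains NaN/Inf entries")
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g", asym, tol))
  values <- (values + t(values)) / 2

  if (is.null(region_labels))
    region_labels <- default_labels(n)
  region_labels <- as.character(region_labels)
  if (length(region_labels) != n) stop("region_labels length mismatch")
  if (anyDuplicated(region_labels)) stop("region_labels must be unique")

  if (kind == "SC") {
    diag(values) <- 0
    if (check && any(values < 0))
      stop("SC entries must be nonnegative")
  } else {
    if (check && any(abs(values) > 1 + 1e-9))
      stop("FC entries must lie in [-1, 1]")
    if (check) values <- pmin(pmax(values, -1), 1)
    diag(values) <- 1
  }
  dimnames(values) <- list(region_labels, region_labels)
  structure(list(values = values, kind = kind, provenance = provenance,
                 region_labels = region_labels, meta = meta),
            class = "connectome")
}

default_labels <- function(n) sprintf("R%03d", seq_len(n) - 1L)

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> kind=%s provenance=%s regions=%d\n",
              x$kind, x$provenance, length(x$region_labels)))
  ut <- upper_tri_vec(x$values)
  cat(sprintf("  off-diagonal range [%.4g, %.4g], density %.2f\n",
              min(ut), max(ut), mean(ut != 0)))
  invisible(x)
}

#' @export
dim.connectome <- function(x) dim(x$values)

#' Multivariate BOLD-like time series
#'
#' Region-by-time signal container, either empirical resting-state BOLD or
#' the simulated output of one of the models, with its sampling period.
#'
#' @param samples numeric matrix, timepoints x regions.
#' @param dt_seconds sampling period in seconds (the TR for BOLD).
#' @param region_labels optional character vector of region names.
#' @return an object of class \code{bold_ts}.
#' @export
bold_ts <- function(samples, dt_seconds, region_labels = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("time series needs at least 2 timepoints")
  if (any(!is.finite(samples))) stop("time series contains NaN/Inf")
  if (!is.numeric(dt_seconds) || length(dt_seconds) != 1L || dt_seconds <= 0)
    stop("dt_seconds must be a positive scalar")
  if (is.null(region_labels)) region_labels <- default_labels(ncol(samples))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != ncol(samples))
    stop("region_labels length mismatch")
  colnames(samples) <- region_labels
  structure(list(samples = samples, dt_seconds = dt_seconds,
                 region_labels = region_labels),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %d timepoints x %d regions, dt = %g s\n",
              nrow(x$samples), ncol(x$samples), x$dt_seconds))
  invisible(x)
}

upper_tri_vec <- function(m) m[upper.tri(m, diag = FALSE)]

#' Read a connectome matrix from a delimited text file
#'
#' Accepts tab-delimited tables with a single header row of region labels
#' (the package's own output format) or headerless whitespace-delimited
#' square tables, in which case labels default to \code{"R000..."}. If a
#' sidecar \code{<basename>.meta.json} exists it is loaded into \code{meta}.
#'
#' @param path file path.
#' @param kind \code{"SC"} or \code{"FC"}.
#' @return a validated [connectome()].
#' @export
read_matrix <- function(path, kind = c("SC", "FC")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  tokens <- strsplit(trimws(first), "[\t ,]+")[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(tokens))))
  if (has_header) {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    labels <- colnames(tab)
  } else {
    tab <- utils::read.table(path, header = FALSE)
    labels <- NULL
  }
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (nrow(m) != ncol(m)) stop("table in ", path, " is not square")
  meta <- list()
  sidecar <- meta_path(path)
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  provenance <- meta$provenance %||% "empirical"
  connectome(m, kind = kind, provenance = provenance,
             region_labels = labels, meta = meta)
}

meta_path <- function(path) paste0(sub("\\.[^./]*$", "", path), ".meta.json")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a connectome matrix to a delimited text file
#'
#' Writes a tab-delimited table with a header row of region labels at full
#' precision (17 significant digits), plus a JSON sidecar
#' \code{<basename>.meta.json} recording kind, provenance and the free-form
#' \code{meta} entries (seed, method, parameters).
#'
#' @param m a [connectome()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(m$region_labels, collapse = "\t"), con)
  apply(m$values, 1L, function(row)
    writeLines(paste(formatC(row, digits = 17, format = "g"),
                     collapse = "\t"), con))
  side <- c(list(kind = m$kind, provenance = m$provenance),
            scrub_meta(m$meta))
  jsonlite::write_json(side, meta_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# sidecars hold scalars and short vectors only, not embedded matrices
scrub_meta <- function(meta) {
  if (length(meta) == 0L) return(list())
  meta[!vapply(meta, is.matrix, logical(1))]
}

#' Write a BOLD time series to TSV (dt in sidecar)
#' @param ts a [bold_ts()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "bold_ts"))
  utils::write.table(ts$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(list(dt_seconds = ts$dt_seconds), meta_path(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a BOLD time series from TSV
#' @param path file path (a sidecar \code{.meta.json} supplies
#'   \code{dt_seconds}; otherwise pass it explicitly).
#' @param dt_seconds sampling period override.
#' @return a [bold_ts()].
#' @export
read_timeseries <- function(path, dt_seconds = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (is.null(dt_seconds)) {
    sidecar <- meta_path(path)
    if (!file.exists(sidecar))
      stop("dt_seconds not given and no sidecar found for ", path)
    dt_seconds <- jsonlite::read_json(sidecar)$dt_seconds
  }
  bold_ts(as.matrix(tab), dt_seconds, colnames(tab))
}

#' Static functional connectivity by Pearson correlation
#'
#' Correlates every pair of regional time series; the result is a valid FC
#' connectome (symmetric, unit diagonal, entries in [-1, 1]).
#'
#' @param ts a [bold_ts()] with at least 3 timepoints.
#' @param provenance provenance tag for the result.
#' @return a [connectome()] of kind FC.
#' @export
pearson_fc <- function(ts, provenance = "empirical") {
  stopifnot(inherits(ts, "bold_ts"))
  x <- ts$samples
  if (nrow(x) < 3L) stop("need at least 3 timepoints for correlation")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ", paste(which(v == 0), collapse = ", "))
  fc <- stats::cor(x)
  fc <- pmin(pmax(fc, -1), 1)
  diag(fc) <- 1
  connectome(fc, kind = "FC", provenance = provenance,
             region_labels = ts$region_labels)
}

#' Rescale an SC so its largest eigenvalue is one
#'
#' Spectral normalization fixes the critical coupling of the linear model at
#' G = 1 and puts every structural connectome on a common dynamical scale.
#' The operation is idempotent and scale-equivariant.
#'
#' @param sc a [connectome()] of kind SC with at least one nonzero entry.
#' @return the rescaled SC.
#' @export
spectral_normalize <- function(sc) {
  stopifnot(inherits(sc, "connectome"), sc$kind == "SC")
  lam <- max_eigenvalue(sc$values)
  if (lam <= 0) stop("cannot normalize: largest eigenvalue is not positive")
  out <- sc
  out$values <- sc$values / lam
  out$meta$spectral_normalized <- TRUE
  out
}

max_eigenvalue <- function(m) {
  max(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
}

is_normalized <- function(sc, tol = 1e-9) {
  abs(max_eigenvalue(sc$values) - 1) <= tol
}

#' Fit correlation between two connectomes
#'
#' Pearson correlation of the strict upper-triangular vectorizations
#' (diagonal excluded), the standard quality-of-fit metric between
#' empirical and virtual connectomes.
#'
#' @param a,b [connectome()] objects (or plain square matrices) with the
#'   same number of regions (>= 3).
#' @return correlation in [-1, 1].
#' @export
fit_correlation <- function(a, b) {
  ma <- if (inherits(a, "connectome")) a$values else as.matrix(a)
  mb <- if (inherits(b, "connectome")) b$values else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("connectome shape mismatch")
  if (nrow(ma) < 3L) stop("need at least 3 regions")
  ua <- upper_tri_vec(ma)
  ub <- upper_tri_vec(mb)
  if (stats::var(ua) == 0 || stats::var(ub) == 0)
    stop("zero-variance upper triangle")
  stats::cor(ua, ub)
}
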