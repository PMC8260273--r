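#' Specification for a synthetic structural connectome
#'
#' Describes a ground-truth SC with the statistical character of
#' tractography-derived connectomes: sparse, modular (stochastic block
#' model topology) and with heavy-tailed (log-normal) weights, spectrally
#' normalized so the largest eigenvalue is one.
#'
#' @param n_regions number of regions (>= 4).
#' @param n_modules number of planted modules (>= 1).
#' @param density overall edge density in (0, 1].
#' @param intra_module_boost ratio of within- to between-module connection
#'   probability (>= 1).
#' @param weight_log_mu,weight_log_sigma parameters of the log-normal
#'   weight law.
#' @param seed integer RNG seed.
#' @return an object of class \code{synth_spec}.
#' @export
synth_spec <- function(n_regions = 20, n_modules = 2, density = 0.3,
                       intra_module_boost = 4, weight_log_mu = 0,
                       weight_log_sigma = 1, seed = 0) {
  stopifnot(n_regions >= 4, n_modules >= 1, density > 0, density <= 1,
            intra_module_boost >= 1, weight_log_sigma >= 0)
  if (density * n_regions * (n_regions - 1) / 2 < n_regions - 1)
    stop("density too low to aim for a connected graph")
  structure(list(n_regions = as.integer(n_regions),
                 n_modules = as.integer(n_modules),
                 density = density, intra_module_boost = intra_module_boost,
                 weight_log_mu = weight_log_mu,
                 weight_log_sigma = weight_log_sigma,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

planted_modules <- function(n_regions, n_modules) {
  sort(rep_len(seq_len(n_modules), n_regions))
}

#' Generate a synthetic ground-truth SC
#'
#' Samples a stochastic block model with within-module connection
#' probability boosted by \code{intra_module_boost}, draws i.i.d.
#' log-normal edge weights, symmetrizes, repairs connectivity by bridging
#' disconnected components with minimum-weight edges, and spectrally
#' normalizes. The planted module labels are stored in \code{meta$modules}.
#'
#' @param spec a [synth_spec()].
#' @return a [connectome()] of kind SC, provenance \code{synthetic_truth}.
#' @export
generate_sc <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_regions
  set.seed(spec$seed)
  modules <- planted_modules(n, spec$n_modules)
  same <- outer(modules, modules, "==")
  # solve p_between from density = f_in * p_in + (1 - f_in) * p_between
  ut <- upper.tri(same)
  f_in <- mean(same[ut])
  p_between <- spec$density / (f_in * spec$intra_module_boost + 1 - f_in)
  p_within <- min(1, p_between * spec$intra_module_boost)
  p_between <- min(1, p_between)
  pmat <- ifelse(same, p_within, p_between)
  W <- matrix(0, n, n)
  edges <- matrix(stats::runif(n * n), n, n) < pmat
  weights <- matrix(stats::rlnorm(n * n, spec$weight_log_mu,
                                  spec$weight_log_sigma), n, n)
  W[ut] <- ifelse(edges[ut], weights[ut], 0)
  W <- W + t(W)
  W <- repair_connectivity(W)
  lam <- max_eigenvalue(W)
  W <- W / lam
  connectome(W, kind = "SC", provenance = "synthetic_truth",
             meta = list(method = "sbm_lognormal", seed = spec$seed,
                         modules = modules, n_modules = spec$n_modules,
                         density = spec$density,
                         intra_module_boost = spec$intra_module_boost))
}

# add minimum-weight bridges between connected components
repair_connectivity <- function(W) {
  n <- nrow(W)
  comp <- components_of(W)
  while (max(comp) > 1L) {
    a <- which(comp == 1L)
    b <- which(comp == 2L)
    i <- a[1 + (length(a) - 1) %% length(a)]
    j <- b[1]
    pos <- W[W > 0]
    wmin <- if (length(pos)) min(pos) else 1
    W[i, j] <- W[j, i] <- wmin
    comp <- components_of(W)
  }
  W
}

components_of <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Specification for a synthetic multi-subject cohort
#'
#' A cohort shares one base SC backbone; each subject's connectome is a
#' jittered copy (Gaussian perturbation of log-weights plus partial edge
#' resampling), optionally with a group-specific multiplicative modulation
#' of a designated edge subset.
#'
#' @param base a [synth_spec()] for the shared backbone.
#' @param n_subjects number of subjects (>= 2).
#' @param subject_jitter fraction in [0, 1] controlling both the log-weight
#'   perturbation scale and the fraction of edges resampled per subject.
#' @param group_labels optional character vector, one label per subject.
#' @param group_effect multiplicative modulation (>= 0) applied to a seeded
#'   random edge subset for every group except the first.
#' @param seed integer RNG seed.
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(base = synth_spec(), n_subjects = 6,
                        subject_jitter = 0.2, group_labels = NULL,
                        group_effect = 0, seed = 0) {
  stopifnot(inherits(base, "synth_spec"), n_subjects >= 2,
            subject_jitter >= 0, subject_jitter <= 1, group_effect >= 0)
  if (!is.null(group_labels) && length(group_labels) != n_subjects)
    stop("group_labels must have one entry per subject")
  structure(list(base = base, n_subjects = as.integer(n_subjects),
                 subject_jitter = subject_jitter,
                 group_labels = group_labels, group_effect = group_effect,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of related SCs
#'
#' @param spec a [cohort_spec()].
#' @return list with \code{subjects} (list of SC [connectome()]s),
#'   \code{labels} (group labels or NULL) and \code{base} (the backbone SC).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  base_sc <- generate_sc(spec$base)
  W0 <- base_sc$values
  n <- nrow(W0)
  ut <- which(upper.tri(W0))
  edge_idx <- ut[W0[ut] > 0]
  set.seed(spec$seed)
  group_edges <- NULL
  groups <- spec$group_labels
  if (!is.null(groups) && spec$group_effect > 0) {
    group_edges <- sample(edge_idx, max(1L, round(0.2 * length(edge_idx))))
  }
  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    set.seed(spec$seed + 1000L * s)
    W <- W0
    j <- spec$subject_jitter
    if (j > 0 && length(edge_idx)) {
      lw <- log(W[edge_idx])
      lw <- lw + stats::rnorm(length(lw), 0, j)
      W[edge_idx] <- exp(lw)
      n_res <- round(j * length(edge_idx))
      if (n_res > 0) {
        res <- sample(edge_idx, n_res)
        W[res] <- stats::rlnorm(n_res, mean(log(W0[edge_idx])),
                                stats::sd(log(W0[edge_idx])))
      }
    }
    if (!is.null(group_edges) && groups[s] != groups[1]) {
      W[group_edges] <- W[group_edges] * (1 + spec$group_effect)
    }
    W[lower.tri(W)] <- 0
    W <- W + t(W)
    W <- W / max_eigenvalue(W)
    subjects[[s]] <- connectome(
      W, kind = "SC", provenance = "synthetic_truth",
      region_labels = base_sc$region_labels,
      meta = list(method = "cohort_jitter", seed = spec$seed, subject = s,
                  jitter = j, group = if (is.null(groups)) NA else groups[s]))
  }
  list(subjects = subjects, labels = groups, base = base_sc)
}
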