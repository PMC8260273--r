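#' Node strengths
#'
#' Row sums of the connectivity matrix excluding the diagonal, on signed
#' values: the total (possibly negative) coupling of each region to the
#' rest of the network.
#'
#' @param c a [connectome()] or square matrix.
#' @return numeric vector, one strength per region.
#' @export
node_strengths <- function(c) {
  m <- if (inherits(c, "connectome")) c$values else as.matrix(c)
  diag(m) <- 0
  rowSums(m)
}

#' Weighted clustering coefficient (geometric-mean triangle intensity)
#'
#' Per-node clustering of a weighted undirected graph: weights are rescaled
#' to [0, 1] by the maximum, triangles are scored by the geometric mean of
#' their three edge weights, and each node's triangle intensity is divided
#' by the number of pairs of its (binary) neighbors. Nodes with fewer than
#' two neighbors score 0. Negative weights are zeroed first (the geometric
#' mean is undefined for them); the diagonal is ignored.
#'
#' @param c a [connectome()] or square matrix.
#' @return numeric vector of clustering coefficients in [0, 1].
#' @export
weighted_clustering <- function(c) {
  m <- if (inherits(c, "connectome")) c$values else as.matrix(c)
  diag(m) <- 0
  m[m < 0] <- 0
  mx <- max(m)
  if (mx == 0) return(numeric(nrow(m)))
  w13 <- (m / mx)^(1 / 3)
  tri <- diag(w13 %*% w13 %*% w13)
  k <- rowSums(m > 0)
  out <- numeric(nrow(m))
  ok <- k >= 2
  out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  out
}

#' PageRank centrality of a weighted undirected graph
#'
#' Power iteration of the damped random walk
#' p <- damping * P p + (1 - damping)/n, where the transition matrix P
#' follows edge weights. Negative weights are zeroed (the walk needs
#' nonnegative weights) and the diagonal is ignored; columns with zero
#' strength are treated as teleporting uniformly. The result sums to one.
#'
#' @param c a [connectome()] or square matrix.
#' @param damping damping parameter, default 0.9.
#' @param tol convergence tolerance on the L1 change, default 1e-10.
#' @param max_iter iteration cap (error if exceeded).
#' @return numeric vector of centralities summing to 1.
#' @export
pagerank_centrality <- function(c, damping = 0.9, tol = 1e-10,
                                max_iter = 1e4) {
  m <- if (inherits(c, "connectome")) c$values else as.matrix(c)
  diag(m) <- 0
  m[m < 0] <- 0
  n <- nrow(m)
  s <- colSums(m)
  dangling <- s == 0
  P <- m
  P[, !dangling] <- sweep(m[, !dangling, drop = FALSE], 2L,
                          s[!dangling], "/")
  P[, dangling] <- 1 / n
  p <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    p_new <- damping * as.numeric(P %*% p) + (1 - damping) / n
    p_new <- p_new / sum(p_new)
    if (sum(abs(p_new - p)) < tol) return(p_new)
    p <- p_new
  }
  stop("PageRank power iteration did not converge")
}

# -- Louvain with "negative symmetric" treatment ----------------------------
# Quality Q = Q+ - (m-/(m+ + m-)) Q-, each layer a standard weighted
# modularity with resolution gamma; greedy local moving + aggregation.

layer_gain <- function(ki_in, ki, tot, m, gamma) {
  if (m == 0) return(0)
  (ki_in - gamma * ki * tot / (2 * m)) / (2 * m)
}

local_moving <- function(Wp, Wn, gamma, labels, rng_order) {
  n <- nrow(Wp)
  kp <- rowSums(Wp); kn <- rowSums(Wn)
  mp <- sum(kp) / 2; mn <- sum(kn) / 2
  neg_w <- if (mp + mn > 0) mn / (mp + mn) else 0
  totp <- tapply(kp, labels, sum)
  totn <- tapply(kn, labels, sum)
  tp <- numeric(max(labels)); tp[as.integer(names(totp))] <- totp
  tn <- numeric(max(labels)); tn[as.integer(names(totn))] <- totn
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in rng_order) {
      ci <- labels[i]
      # links of i into each community (excluding i itself)
      lp <- tapply(Wp[i, -i], labels[-i], sum)
      ln <- tapply(Wn[i, -i], labels[-i], sum)
      cand <- unique(c(as.integer(names(lp)), ci))
      tp[ci] <- tp[ci] - kp[i]; tn[ci] <- tn[ci] - kn[i]
      best_c <- ci; best_gain <- 0
      base_p <- layer_gain(lp_of(lp, ci), kp[i], tp[ci], mp, gamma)
      base_n <- layer_gain(ln_of(ln, ci), kn[i], tn[ci], mn, gamma)
      base <- base_p - neg_w * base_n
      for (cc in cand) {
        if (cc == ci) next
        gp <- layer_gain(lp_of(lp, cc), kp[i], tp[cc], mp, gamma)
        gn <- layer_gain(ln_of(ln, cc), kn[i], tn[cc], mn, gamma)
        g <- (gp - neg_w * gn) - base
        if (g > best_gain + 1e-12) { best_gain <- g; best_c <- cc }
      }
      tp[best_c] <- tp[best_c] + kp[i]; tn[best_c] <- tn[best_c] + kn[i]
      if (best_c != ci) { labels[i] <- best_c; moved <- TRUE }
    }
    if (!moved) break
    moved_any <- TRUE
  }
  list(labels = labels, moved = moved_any)
}

lp_of <- function(l, cc) {
  v <- l[as.character(cc)]
  if (is.na(v)) 0 else as.numeric(v)
}
ln_of <- lp_of

aggregate_graph <- function(W, labels) {
  K <- max(labels)
  B <- matrix(0, nrow(W), K)
  B[cbind(seq_len(nrow(W)), labels)] <- 1
  t(B) %*% W %*% B
}

#' Louvain community detection with signed weights
#'
#' Greedy modularity maximization (local moving plus graph aggregation)
#' with resolution \code{gamma}. Negative entries contribute through the
#' "negative symmetric" two-layer quality function
#' Q = Q+ - (m-/(m+ + m-)) Q-, so anticorrelated pairs are pushed into
#' different communities. Node visiting order is seeded for determinism.
#' The diagonal is ignored.
#'
#' @param c a [connectome()] or square matrix.
#' @param gamma resolution parameter, default 1.
#' @param seed integer seed for the node visiting order.
#' @return integer community labels (1-based, consecutive).
#' @export
louvain_partition <- function(c, gamma = 1, seed = 0) {
  m <- if (inherits(c, "connectome")) c$values else as.matrix(c)
  diag(m) <- 0
  Wp <- pmax(m, 0); Wn <- pmax(-m, 0)
  n <- nrow(m)
  set.seed(seed)
  labels <- seq_len(n)      # singletons at the finest level
  node_map <- seq_len(n)    # original node -> current super-node
  repeat {
    order <- sample.int(nrow(Wp))
    res <- local_moving(Wp, Wn, gamma, seq_len(nrow(Wp)), order)
    lab <- match(res$labels, sort(unique(res$labels)))
    if (!res$moved || max(lab) == nrow(Wp)) break
    node_map <- lab[node_map]
    Wp <- aggregate_graph(Wp, lab)
    Wn <- aggregate_graph(Wn, lab)
    if (nrow(Wp) == max(lab) && nrow(Wp) == 1L) break
  }
  match(node_map, sort(unique(node_map)))
}

#' Relative mutual information between two partitions
#'
#' Mutual information of the two labelings divided by the larger of the two
#' label entropies, giving a score in [0, 1] insensitive to label names and
#' to the number of communities. If both partitions are single-label the
#' score is 1 (they agree trivially); if exactly one is single-label the
#' score is 0.
#'
#' @param p1,p2 integer (or factor) label vectors of equal length >= 2.
#' @return RMI in [0, 1].
#' @export
relative_mutual_information <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("label vectors differ in length")
  if (length(p1) < 2L) stop("need at least 2 elements")
  tab <- table(p1, p2) / length(p1)
  px <- rowSums(tab); py <- colSums(tab)
  h1 <- -sum(px[px > 0] * log(px[px > 0]))
  h2 <- -sum(py[py > 0] * log(py[py > 0]))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(px, py)[nz]))
  max(0, min(1, mi / max(h1, h2)))
}

#' Chance level of relative mutual information by label permutation
#'
#' 99th percentile of [relative_mutual_information()] between \code{p1} and
#' seeded random shuffles of \code{p2}; an observed RMI above this level is
#' unlikely under independent labelings.
#'
#' @param p1,p2 label vectors of equal length.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer RNG seed.
#' @return the 99th-percentile RMI under shuffling.
#' @export
rmi_chance_level <- function(p1, p2, n_perm = 1000, seed = 0) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  set.seed(seed)
  vals <- vapply(seq_len(n_perm), function(k)
    relative_mutual_information(p1, sample(p2)), numeric(1))
  as.numeric(stats::quantile(vals, 0.99, type = 7))
}

#' Improvement over trivial completion, percent
#'
#' Percent change of the virtual connectome's fit to the actual connectome
#' relative to the fit achieved by simply reusing the other empirical
#' connectome (SC as a stand-in for FC or vice versa). Positive values mean
#' model-based completion beats the trivial shortcut.
#'
#' @param cc_virtual fit correlation of the virtual connectome.
#' @param cc_other fit correlation of the "other connectome" stand-in
#'   (nonzero).
#' @return percent improvement.
#' @export
delta_trivial <- function(cc_virtual, cc_other) {
  if (cc_other == 0) stop("cc_other must be nonzero")
  100 * (cc_virtual - cc_other) / cc_other
}

#' Improvement by personalization, percent
#'
#' Given the matrix of fit correlations with entry (i, j) comparing the
#' virtual connectome of subject i to the empirical connectome of subject
#' j, contrasts the mean same-subject (diagonal) fit against the mean
#' cross-subject (off-diagonal) fit. Positive values mean a subject's own
#' virtual dual resembles them more than a generic one would.
#'
#' @param cc_matrix square numeric matrix of fit correlations (n >= 2).
#' @return percent improvement 100 (CC_pers - CC_gen) / CC_gen.
#' @export
delta_pers <- function(cc_matrix) {
  cc_matrix <- as.matrix(cc_matrix)
  if (nrow(cc_matrix) != ncol(cc_matrix) || nrow(cc_matrix) < 2L)
    stop("cc_matrix must be square with n >= 2")
  cc_pers <- mean(diag(cc_matrix))
  off <- cc_matrix[row(cc_matrix) != col(cc_matrix)]
  cc_gen <- mean(off)
  if (cc_gen == 0) stop("generic fit is zero")
  100 * (cc_pers - cc_gen) / cc_gen
}

#' Correlation restricted to the interquartile range of x
#'
#' Pearson correlation over the pairs whose x value lies within [Q1, Q3] of
#' x, protecting the estimate from being dominated by extreme outliers in
#' the tails of the reference (empirical) variable.
#'
#' @param x,y numeric vectors of equal length >= 8; the restriction is
#'   applied on \code{x}.
#' @return correlation over the restricted subset.
#' @export
iqr_restricted_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 8L) stop("need at least 8 points")
  q <- stats::quantile(x, c(0.25, 0.75), type = 7)
  keep <- x >= q[1] & x <= q[2]
  if (sum(keep) < 3L) stop("fewer than 3 points survive the restriction")
  stats::cor(x[keep], y[keep])
}

#' Correspondence of inter-subject distances between two connectome sets
#'
#' For each subject pair, the correlation distance 1 - fit_correlation is
#' computed within each set (e.g., empirical connectomes versus their
#' bivirtual duals, matched by subject); the returned value is the Pearson
#' correlation between the two vectors of pairwise distances. A high value
#' means the virtual set preserves the relational geometry of the cohort.
#'
#' @param set_a,set_b lists of [connectome()]s of equal length >= 3, in
#'   matched subject order.
#' @return correlation between the pairwise-distance vectors.
#' @export
intersubject_distance_correspondence <- function(set_a, set_b) {
  if (length(set_a) != length(set_b)) stop("sets differ in length")
  n <- length(set_a)
  if (n < 3L) stop("need at least 3 subjects")
  dist_vec <- function(s) {
    out <- numeric(n * (n - 1) / 2); k <- 1L
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      out[k] <- 1 - fit_correlation(s[[i]], s[[j]]); k <- k + 1L
    }
    out
  }
  stats::cor(dist_vec(set_a), dist_vec(set_b))
}

#' Full feature vector of a connectome
#'
#' Convenience bundle of the node-level graph features used to compare
#' empirical connectomes with their virtual duals.
#'
#' @param c a [connectome()].
#' @param gamma Louvain resolution.
#' @param seed seed for the Louvain node order.
#' @return list with \code{strengths}, \code{clusterings},
#'   \code{centralities}, \code{partition}.
#' @export
feature_vector <- function(c, gamma = 1, seed = 0) {
  list(strengths = node_strengths(c),
       clusterings = weighted_clustering(c),
       centralities = pagerank_centrality(c),
       partition = louvain_partition(c, gamma = gamma, seed = seed))
}
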