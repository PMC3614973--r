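# All metrics operate on the weighted complete graph defined by a symmetric
# nonnegative SL matrix W with zero diagonal. Path-based metrics use edge
# lengths 1/w: strong synchronization = short functional distance.

check_connectivity <- function(W) {
  W <- unclass(W)
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("`W` must be a square matrix.", call. = FALSE)
  }
  if (max(abs(W - t(W))) > 1e-10) stop("`W` must be symmetric.", call. = FALSE)
  if (any(diag(W) != 0)) stop("`W` must have a zero diagonal.", call. = FALSE)
  if (any(W < 0) || any(W > 1)) {
    stop("SL weights must lie in [0, 1].", call. = FALSE)
  }
  W
}

node_labels <- function(W) {
  if (!is.null(rownames(W))) rownames(W) else paste0("ch", seq_len(nrow(W)))
}

summarize_nodes <- function(values) {
  list(values = values, min = min(values), mean = mean(values),
       max = max(values))
}

#' Node strength (weighted degree centrality)
#'
#' `s_i = sum_j w_ij`, the total synchronization a channel shares with the
#' rest of the network.
#'
#' @param W A symmetric SL `connectivity_matrix`.
#' @return List with `values` (named per-node vector), `min`, `mean`, `max`.
#' @examples
#' W <- matrix(c(0, .5, .2, .5, 0, .1, .2, .1, 0), 3, 3)
#' strength(W)
#' @export
strength <- function(W) {
  W <- check_connectivity(W)
  s <- rowSums(W)
  names(s) <- node_labels(W)
  summarize_nodes(s)
}

# relative tolerance for deciding that two path lengths tie
PATH_TIE_TOL <- 1e-12

path_lengths <- function(W) {
  W <- check_connectivity(W)
  n <- nrow(W)
  off <- W[upper.tri(W)]
  if (any(off == 0)) {
    stop(paste0(
      "Off-diagonal zero weight found: edge length 1/w is infinite. ",
      "Path metrics require a fully connected SL graph."
    ), call. = FALSE)
  }
  L <- 1 / W
  diag(L) <- 0
  L
}

#' Weighted shortest paths
#'
#' Edge lengths are `1/w`; pairwise distances come from the Floyd-Warshall
#' algorithm (exact on these small dense graphs). `L_i` is the mean distance
#' from node i to all others.
#'
#' @inheritParams strength
#' @return List with `distances` (matrix), `values` (per-node mean distance
#'   `L_i`), `min`, `mean`, `max`.
#' @export
weighted_shortest_paths <- function(W) {
  L <- path_lengths(W)
  n <- nrow(L)
  D <- L
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  Li <- rowSums(D) / (n - 1)
  names(Li) <- node_labels(W)
  dimnames(D) <- list(node_labels(W), node_labels(W))
  c(list(distances = D), summarize_nodes(Li))
}

#' Weighted closeness centrality
#'
#' `cc_i = (N - 1) / sum_j d_ij`, the reciprocal of the mean shortest-path
#' distance: channels functionally close to all others score high.
#'
#' @param distances Pairwise distance matrix, as in the `distances` element
#'   of [weighted_shortest_paths()].
#' @return List with `values`, `min`, `mean`, `max`.
#' @export
closeness <- function(distances) {
  if (any(!is.finite(distances))) {
    stop("Distances must all be finite.", call. = FALSE)
  }
  n <- nrow(distances)
  cc <- (n - 1) / rowSums(distances)
  summarize_nodes(cc)
}

# Shortest-path counts from source s given the distance row D_s and edge
# lengths L. sigma[t] = number of distinct shortest s->t paths; ties in
# path length are accepted within PATH_TIE_TOL relative tolerance.
path_counts_from <- function(s, D, L) {
  n <- nrow(L)
  sigma <- numeric(n)
  sigma[s] <- 1
  ord <- order(D[s, ])
  for (t in ord) {
    if (t == s) next
    preds <- which(abs(D[s, ] + L[, t] - D[s, t]) <=
                     PATH_TIE_TOL * pmax(1, D[s, t]) & seq_len(n) != t)
    sigma[t] <- sum(sigma[preds])
  }
  sigma
}

#' Weighted betweenness centrality
#'
#' Counts, for every ordered source-target pair `(s, t)` with both distinct
#' from node i, the fraction of shortest `1/w`-length paths passing through
#' i: `bc_i = sum σ_st(i) / σ_st`. Endpoints are excluded and counts are
#' unnormalized; path-length ties are resolved with a `1e-12` relative
#' tolerance.
#'
#' @inheritParams strength
#' @return List with `values`, `mean`, `max` (min is omitted from the
#'   feature set by design: on complete graphs it is almost always 0).
#' @export
betweenness <- function(W) {
  L <- path_lengths(W)
  n <- nrow(L)
  D <- L
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  sigma <- t(vapply(seq_len(n), function(s) path_counts_from(s, D, L),
                    numeric(n)))  # sigma[s, t]
  bc <- numeric(n)
  for (i in seq_len(n)) {
    for (s in seq_len(n)) {
      if (s == i) next
      for (t in seq_len(n)) {
        if (t == i || t == s) next
        on_path <- abs(D[s, i] + D[i, t] - D[s, t]) <=
          PATH_TIE_TOL * max(1, D[s, t])
        if (on_path) {
          bc[i] <- bc[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
    }
  }
  names(bc) <- node_labels(W)
  list(values = bc, mean = mean(bc), max = max(bc))
}

#' Eigenvector centrality
#'
#' The Perron eigenvector of the nonnegative symmetric weight matrix,
#' computed by power iteration, oriented nonnegative and scaled to unit
#' Euclidean norm; channels synchronized with other central channels score
#' high. The eigen equation residual is verified to 1e-10.
#'
#' @inheritParams strength
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the iterate change.
#' @return List with `values`, `min`, `mean`, `max`, and `lambda` (the
#'   leading eigenvalue).
#' @export
eigenvector_centrality <- function(W, max_iter = 10000L, tol = 1e-14) {
  W <- check_connectivity(W)
  n <- nrow(W)
  v <- rep(1 / sqrt(n), n)
  lambda <- 0
  for (it in seq_len(max_iter)) {
    v_new <- as.numeric(W %*% v)
    nv <- sqrt(sum(v_new^2))
    if (nv == 0) stop("Weight matrix annihilates the iterate; no principal eigenvector.",
                      call. = FALSE)
    v_new <- v_new / nv
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
    if (it == max_iter) {
      stop("Power iteration did not converge within the iteration cap.",
           call. = FALSE)
    }
  }
  if (sum(v) < 0) v <- -v
  lambda <- as.numeric(t(v) %*% W %*% v)
  resid <- sqrt(sum((as.numeric(W %*% v) - lambda * v)^2))
  if (resid > 1e-10) {
    stop(sprintf("Eigenvector residual %.2e exceeds 1e-10.", resid),
         call. = FALSE)
  }
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  names(v) <- node_labels(W)
  c(summarize_nodes(v), list(lambda = lambda))
}

#' Weighted clustering coefficient
#'
#' Geometric-mean (Onnela-type) triangle intensity on max-normalized
#' weights: with `wh = w / max(w)`,
#' `C_i = (1 / (k_i (k_i - 1))) * sum_{j != h} (wh_ij wh_jh wh_hi)^(1/3)`,
#' where `k_i` counts i's nonzero-weight neighbours. An alternative
#' normalization (`method = "zhang"`, the form surveyed by Saramaki and
#' colleagues) divides the triangle weight products by the maximum they
#' could attain given i's edge weights.
#'
#' @inheritParams strength
#' @param method `"onnela"` (default) or `"zhang"`.
#' @return List with `values`, `min`, `mean`, `max`.
#' @export
weighted_clustering <- function(W, method = c("onnela", "zhang")) {
  method <- match.arg(method)
  W <- check_connectivity(W)
  n <- nrow(W)
  if (n < 3) stop("Clustering needs at least 3 nodes.", call. = FALSE)
  wmax <- max(W)
  if (wmax == 0) {
    cvals <- rep(0, n)
    names(cvals) <- node_labels(W)
    return(summarize_nodes(cvals))
  }
  Wh <- W / wmax
  k <- rowSums(Wh > 0)
  if (method == "onnela") {
    W3 <- Wh^(1 / 3)
    tri <- diag(W3 %*% W3 %*% W3)  # sum over ordered (j, h) pairs
    cvals <- ifelse(k > 1, tri / (k * (k - 1)), 0)
  } else {
    num <- diag(Wh %*% Wh %*% Wh)
    denom <- rowSums(Wh)^2 - rowSums(Wh^2)
    cvals <- ifelse(denom > 0, num / denom, 0)
  }
  names(cvals) <- node_labels(W)
  summarize_nodes(cvals)
}

#' Power-law scaling index of the strength distribution
#'
#' Continuous maximum-likelihood estimate of the tail exponent:
#' `alpha = 1 + n_tail / sum(log(d_i / d_min))` over observations
#' `d_i >= d_min`. By default `d_min` is the smallest strength (a cutoff
#' scan is unstable on 17 nodes); `method = "ks"` instead scans candidate
#' cutoffs and picks the one minimizing the Kolmogorov-Smirnov distance
#' between the empirical tail and the fitted power law.
#'
#' @param strengths Positive per-node strengths (the `values` element of
#'   [strength()]).
#' @param d_min Lower cutoff; default `min(strengths)`.
#' @param method `"fixed"` (use `d_min` as given) or `"ks"` (scan).
#' @return An object of class `powerlaw_fit`: list with `alpha`, `d_min`,
#'   `n_tail`.
#' @examples
#' powerlaw_fit(c(1, exp(1), exp(2)))  # alpha = 2 exactly
#' @export
powerlaw_fit <- function(strengths, d_min = NULL,
                         method = c("fixed", "ks")) {
  method <- match.arg(method)
  strengths <- as.numeric(strengths)
  if (any(strengths <= 0)) {
    stop("All strengths must be positive for the power-law fit.", call. = FALSE)
  }
  if (length(unique(strengths)) == 1L) {
    stop("All strengths are equal: the scaling index is undefined (degenerate distribution).",
         call. = FALSE)
  }
  mle_at <- function(dm) {
    tail <- strengths[strengths >= dm]
    n <- length(tail)
    denom <- sum(log(tail / dm))
    if (n < 2 || denom <= 0) return(NULL)
    list(alpha = 1 + n / denom, d_min = dm, n_tail = n)
  }
  if (method == "fixed") {
    dm <- if (is.null(d_min)) min(strengths) else d_min
    fit <- mle_at(dm)
    if (is.null(fit)) {
      stop("Fewer than 2 observations above d_min, or degenerate tail.",
           call. = FALSE)
    }
  } else {
    cands <- sort(unique(strengths))
    cands <- cands[seq_len(max(1L, length(cands) - 1L))]
    best <- NULL
    best_ks <- Inf
    for (dm in cands) {
      f <- mle_at(dm)
      if (is.null(f)) next
      tail <- sort(strengths[strengths >= dm])
      emp <- seq_along(tail) / length(tail)
      theo <- 1 - (tail / dm)^(1 - f$alpha)
      ks <- max(abs(emp - theo))
      if (ks < best_ks) {
        best_ks <- ks
        best <- f
      }
    }
    if (is.null(best)) stop("No viable power-law cutoff found.", call. = FALSE)
    fit <- best
  }
  structure(fit, class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> alpha = %.4f, d_min = %.4g, n_tail = %d\n",
              x$alpha, x$d_min, x$n_tail))
  invisible(x)
}
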