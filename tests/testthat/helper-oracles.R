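# Independent brute-force oracles used to verify the implementation.
# Deliberately written as plain double loops over definitions, sharing no
# code with the package internals.

# --- synchronization likelihood -------------------------------------------

oracle_embed <- function(x, m, lag) {
  n_emb <- length(x) - (m - 1) * lag
  E <- matrix(NA_real_, n_emb, m)
  for (t in seq_len(n_emb)) {
    for (k in seq_len(m)) E[t, k] <- x[t + (k - 1) * lag]
  }
  E
}

oracle_recurrences <- function(E, p_ref, w1, w2) {
  n <- nrow(E)
  rec <- vector("list", n)
  for (i in seq_len(n)) {
    js <- integer(0)
    for (j in seq_len(n)) {
      if (abs(i - j) > w1 && abs(i - j) <= w2) js <- c(js, j)
    }
    d <- numeric(length(js))
    for (q in seq_along(js)) d[q] <- sum((E[i, ] - E[js[q], ])^2)
    k <- max(1, floor(p_ref * length(js) + 0.5))  # round half up, as documented
    eps2 <- sort(d)[k]
    rec[[i]] <- js[d <= eps2]
  }
  rec
}

# symmetrized SL between two series, straight from the definition
oracle_sl_pair <- function(x, y, m, lag, w1, w2, p_ref) {
  rx <- oracle_recurrences(oracle_embed(x, m, lag), p_ref, w1, w2)
  ry <- oracle_recurrences(oracle_embed(y, m, lag), p_ref, w1, w2)
  nx <- 0; ny <- 0; nxy <- 0
  for (i in seq_along(rx)) {
    nx <- nx + length(rx[[i]])
    ny <- ny + length(ry[[i]])
    nxy <- nxy + length(intersect(rx[[i]], ry[[i]]))
  }
  0.5 * (nxy / nx + nxy / ny)
}

# --- weighted graph metrics -----------------------------------------------

# all simple paths between a and b by depth-first enumeration; returns the
# minimal 1/w length and the list of minimizing paths (within tol)
oracle_shortest <- function(W, a, b, tol = 1e-12) {
  n <- nrow(W)
  L <- 1 / W
  best <- Inf
  paths <- list()
  recurse <- function(node, visited, len) {
    if (node == b) {
      if (!is.finite(best) || len < best - tol * max(1, best)) {
        best <<- len
        paths <<- list(visited)
      } else if (abs(len - best) <= tol * max(1, best)) {
        paths[[length(paths) + 1]] <<- visited
      }
      return()
    }
    for (nxt in seq_len(n)) {
      if (!(nxt %in% visited)) recurse(nxt, c(visited, nxt), len + L[node, nxt])
    }
  }
  recurse(a, a, 0)
  list(dist = best, paths = paths)
}

oracle_graph_metrics <- function(W, tol = 1e-12) {
  n <- nrow(W)
  s <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) s[i] <- s[i] + W[i, j]
  D <- matrix(0, n, n)
  all_paths <- vector("list", n * n)
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      if (a == b) next
      sp <- oracle_shortest(W, a, b, tol)
      D[a, b] <- sp$dist
      all_paths[[(a - 1) * n + b]] <- sp$paths
    }
  }
  Lmean <- rowSums(D) / (n - 1)
  cc <- (n - 1) / rowSums(D)
  bc <- numeric(n)
  for (i in seq_len(n)) {
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b || a == i || b == i) next
        paths <- all_paths[[(a - 1) * n + b]]
        through <- sum(vapply(paths, function(p) i %in% p, logical(1)))
        bc[i] <- bc[i] + through / length(paths)
      }
    }
  }
  ev <- eigen(W, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  if (sum(v) < 0) v <- -v
  wh <- W / max(W)
  cl <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        acc <- acc + (wh[i, j] * wh[j, h] * wh[h, i])^(1 / 3)
      }
    }
    k <- sum(W[i, ] > 0)
    cl[i] <- acc / (k * (k - 1))
  }
  list(strength = s, distances = D, path = Lmean, closeness = cc,
       betweenness = bc, eigenvector = v, clustering = cl)
}

random_sl_graph <- function(n, rng_min = 0.05, rng_max = 0.95) {
  W <- matrix(0, n, n)
  vals <- runif(n * (n - 1) / 2, rng_min, rng_max)
  W[upper.tri(W)] <- vals
  W <- W + t(W)
  W
}

# --- AUC ------------------------------------------------------------------

# concordant-pair fraction: P(case score > control score) + 0.5 P(tie)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "case"]
  neg <- scores[labels == "control"]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# --- shared fixtures -------------------------------------------------------

# small recording for I/O and filtering tests
tiny_recording <- function(n_ch = 3, n_samp = 256, fs = 128, n_ep = 2,
                           seed = 1) {
  set.seed(seed)
  eeg_recording(
    "t1", paste0("c", seq_len(n_ch)), fs,
    lapply(seq_len(n_ep), function(e) matrix(rnorm(n_ch * n_samp), n_ch))
  )
}

# quick cohort settings used by model-level tests: small recordings keep
# the SL stage fast while remaining full pipeline runs
quick_spec <- function(n_per_group, effect_size, seed,
                       fs = 256, epoch_seconds = 2, n_epochs = 2,
                       n_channels = 17) {
  cohort_spec(
    n_per_group = n_per_group, n_channels = n_channels, fs = fs,
    epoch_seconds = epoch_seconds, n_epochs = n_epochs,
    effect_size = effect_size, seed = seed
  )
}

quick_sl_params <- function(fs = 256) sl_params(fs = fs)

# synthetic null feature table (pure noise, exchangeable groups)
null_feature_table <- function(n_per_group, seed) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n_per_group * 18), ncol = 18)
  colnames(X) <- feature_names()
  out <- tibble::as_tibble(X)
  out$subject_id <- paste0("s", seq_len(2 * n_per_group))
  out$group <- factor(rep(c("control", "case"), each = n_per_group),
                      levels = c("control", "case"))
  out
}
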