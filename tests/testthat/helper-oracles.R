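# Independent oracles used across the suite. These deliberately share no
# code with the package: densities via solve()/det(), likelihoods by full
# path enumeration, BH by a literal quadratic scan, Wilcoxon by assignment
# enumeration, I-DT by a naive window rescan.

# 2-D Gaussian log-density, independent of the package's implementation
oracle_ldmvn <- function(x, mu, sigma) {
  d <- x - mu
  -log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * as.numeric(t(d) %*% solve(sigma) %*% d)
}

oracle_log_emission_matrix <- function(model, xy) {
  T_len <- nrow(xy)
  logB <- matrix(NA_real_, T_len, model$K)
  for (t in seq_len(T_len)) {
    for (k in seq_len(model$K)) {
      logB[t, k] <- oracle_ldmvn(xy[t, ], model$means[k, ], model$covs[[k]])
    }
  }
  logB
}

# all K^T paths as rows
oracle_all_paths <- function(K, T_len) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_len)))
}

# exact log-likelihood by summation over every hidden path
oracle_hmm_loglik <- function(model, xy) {
  logB <- oracle_log_emission_matrix(model, xy)
  paths <- oracle_all_paths(model$K, nrow(xy))
  lp <- apply(paths, 1, function(s) {
    v <- log(model$initial[s[1]]) + logB[1, s[1]]
    for (t in seq_along(s)[-1]) {
      v <- v + log(model$transition[s[t - 1], s[t]]) + logB[t, s[t]]
    }
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# maximum-probability path by enumeration (first maximum in row-major
# order of expand.grid, which increments earlier timepoints fastest; used
# only on instances whose optimum is unique)
oracle_hmm_viterbi <- function(model, xy) {
  logB <- oracle_log_emission_matrix(model, xy)
  paths <- oracle_all_paths(model$K, nrow(xy))
  lp <- apply(paths, 1, function(s) {
    v <- log(model$initial[s[1]]) + logB[1, s[1]]
    for (t in seq_along(s)[-1]) {
      v <- v + log(model$transition[s[t - 1], s[t]]) + logB[t, s[t]]
    }
    v
  })
  list(path = as.integer(paths[which.max(lp), ]), log_prob = max(lp))
}

# literal BH step-up: q_(i) = min_{j >= i} m * p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# exact two-sided Wilcoxon p by enumeration over all group assignments
oracle_wilcoxon_p <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  N <- length(pool)
  mu <- n1 * (N - n1) / 2
  idx <- utils::combn(N, n1)
  r <- rank(pool)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# naive I-DT: at each start, take the smallest window reaching the minimum
# duration, grow while dispersion stays within threshold
oracle_idt <- function(t, x, y, dispersion, min_duration) {
  n <- length(t)
  dt <- stats::median(diff(t))
  disp <- function(i, j) {
    (max(x[i:j]) - min(x[i:j])) + (max(y[i:j]) - min(y[i:j]))
  }
  fix <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && t[j] - t[i] < min_duration - 1e-12) j <- j + 1L
    if (j > n) break
    if (disp(i, j) <= dispersion) {
      while (j < n && disp(i, j + 1L) <= dispersion) j <- j + 1L
      fix[[length(fix) + 1L]] <-
        data.frame(onset = t[i], duration = t[j] - t[i] + dt,
                   x = mean(x[i:j]), y = mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(fix)) do.call(rbind, fix) else
    data.frame(onset = numeric(), duration = numeric(),
               x = numeric(), y = numeric())
}

# random small HMM with distinct Gaussian emissions, for oracle suites
random_toy_model <- function(K, seed) {
  set.seed(seed)
  means <- cbind(runif(K), runif(K))
  covs <- lapply(seq_len(K), function(k) {
    s <- runif(2, 0.02, 0.08)
    rho <- runif(1, -0.4, 0.4)
    matrix(c(s[1]^2, rho * s[1] * s[2], rho * s[1] * s[2], s[2]^2), 2, 2)
  })
  A <- matrix(runif(K * K, 0.2, 1), K, K)
  A <- A / rowSums(A)
  init <- runif(K, 0.2, 1)
  init <- init / sum(init)
  cc <- constraint_config(1e-6, 0.9, axis_clamp_n = 10)
  m <- make_ground_truth_model(K, constraints = cc, seed = seed)
  m$means <- means
  m$covs <- covs
  m$transition <- A
  m$initial <- init
  m
}

random_simplex <- function(K) {
  g <- -log(runif(K))
  g / sum(g)
}

# a small synthetic study used by several suites (ground-truth decoding)
tiny_study <- function(seed = 7, n_participants = 4, n_artworks = 4,
                       rate = 60, K = 6) {
  simulate_study(generative_config(
    n_participants = n_participants, n_artworks = n_artworks,
    sampling_rate_hz = rate, K_true = K, seed = seed
  ))
}
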