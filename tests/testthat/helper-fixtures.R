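# shared fixtures and independent oracles used across the suite

# small mixed pedigree: one MZ pair, one DZ pair, one 3-sib family,
# two singletons
toy_pedigree <- function() {
  pedigree(
    id = sprintf("p%02d", 1:9),
    famid = c("f1", "f1", "f2", "f2", "f3", "f3", "f3", "f4", "f5"),
    sex = c(1, 1, 2, 2, 1, 2, 1, 2, 1),
    group = c("MZ", "MZ", "DZ", "DZ", "SIB", "SIB", "SIB",
              "SINGLETON", "SINGLETON"),
    twinpair = c("t1", "t1", "t2", "t2", NA, NA, NA, NA, NA)
  )
}

toy_covariates <- function(ped) {
  set.seed(99)
  data.frame(id = ped$id,
             age = sample(25:34, nrow(ped), replace = TRUE),
             sex = ped$sex,
             handedness = sample(c(1, 1, 1, 2), nrow(ped), replace = TRUE),
             education = sample(12:18, nrow(ped), replace = TRUE))
}

# random pedigree of MZ/DZ/sib/singleton families (for property tests)
random_pedigree <- function(n_fam, seed) {
  set.seed(seed)
  id <- character(0); famid <- character(0); group <- character(0)
  twinpair <- character(0)
  k <- 0
  for (f in seq_len(n_fam)) {
    type <- sample(c("MZ", "DZ", "SIB", "SINGLETON"), 1)
    size <- switch(type, MZ = 2, DZ = 2, SIB = sample(2:4, 1), SINGLETON = 1)
    ids <- sprintf("r%04d", k + seq_len(size)); k <- k + size
    id <- c(id, ids)
    famid <- c(famid, rep(sprintf("rf%03d", f), size))
    group <- c(group, rep(type, size))
    twinpair <- c(twinpair,
                  if (type %in% c("MZ", "DZ")) rep(sprintf("rt%03d", f), 2)
                  else rep(NA_character_, size))
  }
  pedigree(id, famid, sex = 1, group = group, twinpair = twinpair)
}

# brute-force kinship oracle: enumerate pairs, apply the group rules
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  K <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (ped$famid[i] != ped$famid[j]) { K[i, j] <- 0; next }
    same_pair <- !is.na(ped$twinpair[i]) && !is.na(ped$twinpair[j]) &&
      ped$twinpair[i] == ped$twinpair[j]
    K[i, j] <- if (same_pair && ped$group[i] == "MZ") 1 else 0.5
  }
  dimnames(K) <- list(ped$id, ped$id)
  K
}

# dense multivariate-normal log-likelihood oracle (no family blocking)
dense_mvn_loglik <- function(y, Omega) {
  n <- length(y)
  L <- chol(Omega)
  -n / 2 * log(2 * pi) - sum(log(diag(L))) -
    0.5 * sum(backsolve(L, y, transpose = TRUE)^2)
}

# profile the dense likelihood over sigma_p2 at fixed unit-scale structure
dense_profile_loglik <- function(y, M) {
  n <- length(y)
  qf <- sum(y * solve(M, y))
  s2 <- qf / n
  dense_mvn_loglik(y, s2 * M)
}

# exhaustive Benjamini-Hochberg step-up oracle on significance flags
bh_oracle_flags <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (k in seq_len(n)) if (ps[k] <= alpha * k / n) kmax <- k
  flags <- rep(FALSE, n)
  if (kmax > 0) flags[o[seq_len(kmax)]] <- TRUE
  flags
}

# analytic autocovariance sequence of a stable VAR(1): Gamma_0 by the
# discrete Lyapunov equation (Kronecker solve), Gamma_h = A^h Gamma_0
var1_autocov <- function(A, Sigma, max_lag) {
  N <- nrow(A)
  vecG0 <- solve(diag(N^2) - kronecker(A, A), as.vector(Sigma))
  G0 <- matrix(vecG0, N, N)
  out <- list(G0)
  Ak <- A
  for (h in seq_len(max_lag)) {
    out[[h + 1]] <- Ak %*% G0
    Ak <- A %*% Ak
  }
  out
}

# reduced-AR brute-force GC oracle for a bivariate VAR(1): fit a long AR to
# the analytic autocovariance of the target alone and compare innovation
# variances
gc_oracle_bivar <- function(A, Sigma, target, q = 50) {
  G <- var1_autocov(A, Sigma, q + 1)
  g <- vapply(G, function(M) M[target, target], 0)
  Tm <- stats::toeplitz(g[seq_len(q)])
  a <- solve(Tm, g[2:(q + 1)])
  s2_red <- g[1] - sum(a * g[2:(q + 1)])
  log(s2_red / Sigma[target, target])
}

# wrap a true VAR(1) as a fitted model object
true_var1 <- function(A, Sigma = diag(nrow(A))) {
  structure(list(p = 1L, A = list(A), Sigma = Sigma, Sigma_ml = Sigma,
                 n_eff = Inf, stable = TRUE,
                 spectral_radius = max(Mod(eigen(A, only.values = TRUE)$values)),
                 order_criterion = NULL),
            class = "var_model")
}

# random stable bivariate VAR(1) with both couplings present
random_bivar <- function() {
  repeat {
    A <- matrix(c(stats::runif(1, 0.2, 0.6), stats::runif(1, -0.5, 0.5),
                  stats::runif(1, -0.5, 0.5), stats::runif(1, 0.2, 0.6)),
                2, 2)
    if (max(Mod(eigen(A, only.values = TRUE)$values)) < 0.95) return(A)
  }
}

# 2-node hemodynamic-confound experiment: coupling 1 -> 2, source HRF
# slower by 2 s; returns direction verdicts on raw and deconvolved series
hrf_confound_trial <- function(seed, n_sessions = 4, n_timepoints = 1200,
                               deconvolve = TRUE) {
  cfg <- sim_config(n_mz_pairs = 0, n_dz_pairs = 0, sib_sizes = integer(0),
                    n_singletons = 1, n_networks = 2,
                    n_sessions = n_sessions, n_timepoints = n_timepoints,
                    edges = matrix(c(1, 2), 1), base_coupling = 0.4,
                    noise_sd = 0.2, seed = seed)
  pc <- simulate_pedigree(cfg)
  tr <- matrix(0, 1, 2, dimnames = list(pc$ped$id, connection_keys(2)))
  nts <- generate_bold(pc$ped, tr, cfg, hrf_peaks = matrix(c(7, 5), 1))
  Graw <- gc_matrix(nts$subjects[[1]], order = "aic", p_max = 10)
  out <- c(raw = unname(Graw[1, 2] > Graw[2, 1]), dec = NA)
  if (deconvolve) {
    dec <- deconvolve_set(nts)
    Gdec <- gc_matrix(dec$nts$subjects[[1]], order = "aic", p_max = 10)
    out["dec"] <- Gdec[1, 2] > Gdec[2, 1]
  }
  out
}

# random stable VAR(1) on N nodes: diagonal AR plus sparse couplings
random_varN <- function(N = 5, n_edges = 6, rho_cap = 0.9) {
  A <- diag(0.5, N)
  idx <- which(row(A) != col(A))
  picks <- sample(idx, n_edges)
  A[picks] <- stats::runif(n_edges, 0.2, 0.4) *
    sample(c(-1, 1), n_edges, replace = TRUE)
  r <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (r > rho_cap) A <- A * (rho_cap / r)
  A
}

# model-based GC matrix of a true VAR(1) (no estimation)
gc_true_matrix <- function(A, Sigma = diag(nrow(A))) {
  ss <- var_to_state_space(true_var1(A, Sigma))
  N <- nrow(A)
  G <- matrix(NA_real_, N, N)
  for (j in seq_len(N)) G[j, ] <- gc_from_source(ss, j)
  diag(G) <- 0
  G
}
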