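#' Configuration of the synthetic twin-cohort generator
#'
#' Bundles everything needed to simulate a family cohort with network
#' time-series whose directed couplings carry a known ACE variance
#' decomposition. Defaults mirror a single HCP-like cohort: 62 MZ pairs,
#' 25 DZ pairs, 197 siblings, 78 singletons (449 individuals), N networks
#' observed over S sessions of T time-points at TR = 0.72 s.
#'
#' @param n_mz_pairs,n_dz_pairs number of MZ / DZ twin pairs.
#' @param sib_sizes integer vector of sibling-group sizes (one family each).
#'   `sib_sizes_for(k)` builds a default mix of 3s and 2s totalling `k`.
#' @param n_singletons number of singleton families.
#' @param n_networks,n_sessions,n_timepoints dimensions of the series.
#' @param TR sampling interval in seconds.
#' @param h2,c2 true additive-genetic and shared-environment variance shares
#'   of the latent coupling traits; scalar (all connections) or a vector of
#'   length `n_networks * (n_networks - 1)`.
#' @param base_coupling coupling magnitude on the designated edges of the
#'   ground-truth VAR.
#' @param ar_diag diagonal autoregression of each node.
#' @param edges two-column integer matrix (source, target) of coupled edges;
#'   `NULL` for a default directed ring `1 -> 2 -> ... -> N -> 1`.
#' @param hrf_latency_range range (s) of the uniform per-node/subject HRF
#'   peak-latency jitter.
#' @param noise_sd observation noise SD added to the unit-variance BOLD
#'   signal.
#' @param innovations `"burst"` (default) or `"gaussian"`. Burst innovations
#'   mix a Gaussian background with sparse positive spikes
#'   (`spike_prob`, exponential amplitudes), mimicking the spontaneous
#'   neural events that make blind HRF estimation possible in resting-state
#'   data; a purely Gaussian process carries no phase information about the
#'   hemodynamic kernel.
#' @param spike_prob per-sample spike probability of the burst model.
#' @param burn_in discarded initial VAR steps per session.
#' @param seed master seed of the generator.
#' @return object of class `"sim_config"` (a list).
#' @export
sim_config <- function(n_mz_pairs = 62L, n_dz_pairs = 25L,
                       sib_sizes = sib_sizes_for(197L),
                       n_singletons = 78L,
                       n_networks = 10L, n_sessions = 4L,
                       n_timepoints = 1200L, TR = 0.72,
                       h2 = 0.4, c2 = 0,
                       base_coupling = 0.35, ar_diag = 0.5,
                       edges = NULL,
                       hrf_latency_range = c(4, 7),
                       noise_sd = 0.5, innovations = "burst",
                       spike_prob = 0.04, burn_in = 200L, seed = 1L) {
  stopifnot(n_mz_pairs >= 0, n_dz_pairs >= 0, n_singletons >= 0,
            all(sib_sizes >= 2), n_networks >= 1, n_sessions >= 1,
            TR > 0, all(h2 >= 0), all(c2 >= 0), all(h2 + c2 <= 1),
            burn_in >= 0)
  if (is.null(edges) && n_networks > 1) {
    edges <- cbind(seq_len(n_networks),
                   c(seq_len(n_networks)[-1], 1L))
  }
  structure(list(
    n_mz_pairs = as.integer(n_mz_pairs), n_dz_pairs = as.integer(n_dz_pairs),
    sib_sizes = as.integer(sib_sizes), n_singletons = as.integer(n_singletons),
    n_networks = as.integer(n_networks), n_sessions = as.integer(n_sessions),
    n_timepoints = as.integer(n_timepoints), TR = TR,
    h2 = h2, c2 = c2, base_coupling = base_coupling, ar_diag = ar_diag,
    edges = edges, hrf_latency_range = hrf_latency_range,
    noise_sd = noise_sd,
    innovations = match.arg(innovations, c("burst", "gaussian")),
    spike_prob = spike_prob, burn_in = as.integer(burn_in),
    seed = as.integer(seed)), class = "sim_config")
}

#' @rdname sim_config
#' @param k total number of sibling individuals to distribute.
#' @export
sib_sizes_for <- function(k) {
  k <- as.integer(k)
  if (k == 0L) return(integer(0))
  if (k == 1L) stop("cannot form sibling groups from a single individual")
  n3 <- k %/% 3L
  while ((k - 3L * n3) %% 2L != 0L) n3 <- n3 - 1L
  c(rep(3L, n3), rep(2L, (k - 3L * n3) %/% 2L))
}

#' Simulate a pedigree and demographic covariates
#'
#' Draws a family cohort matching the configured MZ/DZ/sibling/singleton
#' composition, with ages around 29 +/- 4 years, education around 15 +/- 2
#' years, balanced sex and ~90% right-handedness — the demographic ranges of
#' a young-adult twin cohort.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `ped` ([pedigree()]) and `cov` (covariates).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(child_seed(cfg$seed, "pedigree"))
  fam <- list()
  add_family <- function(g, size, twins) {
    k <- length(fam) + 1L
    fid <- sprintf("F%04d", k)
    fam[[k]] <<- data.frame(
      famid = fid, group = g, n = size,
      twinpair = if (twins) sprintf("T%04d", k) else NA_character_)
  }
  for (i in seq_len(cfg$n_mz_pairs)) add_family("MZ", 2L, TRUE)
  for (i in seq_len(cfg$n_dz_pairs)) add_family("DZ", 2L, TRUE)
  for (s in cfg$sib_sizes) add_family("SIB", s, FALSE)
  for (i in seq_len(cfg$n_singletons)) add_family("SINGLETON", 1L, FALSE)
  if (!length(fam)) {
    ped <- pedigree(character(0), character(0), integer(0), character(0))
    return(list(ped = ped,
                cov = data.frame(id = character(0), age = numeric(0),
                                 sex = integer(0), handedness = integer(0),
                                 education = numeric(0))))
  }
  fam <- do.call(rbind, fam)
  n <- sum(fam$n)
  id <- sprintf("S%04d", seq_len(n))
  famid <- rep(fam$famid, fam$n)
  group <- rep(fam$group, fam$n)
  twinpair <- rep(fam$twinpair, fam$n)
  sex <- sample(c(1L, 2L), n, replace = TRUE)
  # co-twins share sex (always for MZ; simplification kept for DZ)
  for (p in unique(stats::na.omit(twinpair))) {
    m <- which(!is.na(twinpair) & twinpair == p)
    sex[m[2]] <- sex[m[1]]
  }
  ped <- pedigree(id, famid, sex, group, twinpair)
  # siblings cluster in age within a family
  fam_age <- stats::rnorm(nrow(fam), 29, 3.5)
  age <- round(rep(fam_age, fam$n) + stats::rnorm(n, 0, 1.5))
  age <- pmin(pmax(age, 22), 37)
  cov <- data.frame(
    id = id, age = age, sex = sex,
    handedness = ifelse(stats::runif(n) < 0.9, 1L, 2L),
    education = pmin(pmax(round(stats::rnorm(n, 15, 1.8)), 11), 18))
  list(ped = ped, cov = cov)
}

#' Simulate latent coupling traits with ACE structure
#'
#' For every directed connection draws one trait value per subject from a
#' zero-mean multivariate normal with covariance
#' `h2 * 2Phi + c2 * H + (1 - h2 - c2) * I` (unit total variance), where
#' 2Phi is the kinship matrix and H the household matrix of the pedigree.
#' Connections are independent. Families are independent blocks, so sampling
#' is done family-by-family.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()]; `cfg$h2` / `cfg$c2` may be scalars or
#'   per-connection vectors of length `n_networks * (n_networks - 1)`.
#' @return matrix subjects x connections with `dimnames` = (ids,
#'   "src->tgt" keys) and attributes `h2`, `c2`, `edges` (logical map of the
#'   connections that modulate the ground-truth VAR).
#' @export
simulate_ace_traits <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree_df"), inherits(cfg, "sim_config"))
  N <- cfg$n_networks
  keys <- connection_keys(N)
  m <- length(keys)
  h2 <- rep_len(cfg$h2, m); c2 <- rep_len(cfg$c2, m)
  if (any(h2 + c2 > 1)) stop("h2 + c2 must not exceed 1")
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(child_seed(cfg$seed, "traits"))
  n <- nrow(ped)
  out <- matrix(0, n, m, dimnames = list(ped$id, keys))
  fam_idx <- split(seq_len(n), ped$famid)
  # group families by identical (kinship, household) block structure so the
  # eigendecomposition is done once per structure and parameter setting
  kin <- build_kinship(ped); hh <- build_household(ped)
  sig <- vapply(fam_idx, function(ix)
    paste(c(kin[ix, ix], hh[ix, ix]), collapse = ","), character(1))
  for (pset in split(seq_len(m), paste(h2, c2))) {
    h <- h2[pset[1]]; cc <- c2[pset[1]]
    for (g in split(fam_idx, sig)) {
      ix1 <- g[[1]]
      S <- h * kin[ix1, ix1, drop = FALSE] + cc * hh[ix1, ix1, drop = FALSE] +
        (1 - h - cc) * diag(length(ix1))
      e <- eigen(S, symmetric = TRUE)
      L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(ix1))
      for (ix in g) {
        out[ix, pset] <- L %*% matrix(stats::rnorm(length(ix) * length(pset)),
                                      length(ix), length(pset))
      }
    }
  }
  onmap <- matrix(FALSE, N, N)
  if (!is.null(cfg$edges)) onmap[cfg$edges] <- TRUE
  attr(out, "h2") <- h2
  attr(out, "c2") <- c2
  attr(out, "edge_map") <- onmap
  out
}

#' Directed-connection column keys
#'
#' All `N * (N - 1)` ordered off-diagonal pairs as `"src->tgt"` strings, in
#' column-major order over the (source, target) matrix with the diagonal
#' removed.
#' @param N number of nodes.
#' @param labels optional node labels (default `n1..nN`).
#' @export
connection_keys <- function(N, labels = paste0("n", seq_len(N))) {
  src <- rep(seq_len(N), times = N); tgt <- rep(seq_len(N), each = N)
  keep <- src != tgt
  paste0(labels[src[keep]], "->", labels[tgt[keep]])
}

#' Ground-truth VAR(1) coefficients for one subject
#'
#' Diagonal autoregression plus trait-modulated couplings on the designated
#' edge set: the (source, target) coefficient is
#' `base_coupling * (1 + trait)` with the trait clipped to [-0.8, 0.8] so the
#' edge keeps its sign. The matrix is rescaled to spectral radius <= 0.95
#' whenever needed.
#'
#' @param trait_row named numeric vector of one subject's connection traits
#'   (keys as in [connection_keys()]).
#' @param cfg a [sim_config()].
#' @return N x N coefficient matrix `A` such that `x_t = x_{t-1} %*% t(A)`...
#'   conventions: `A[i, j]` is the effect of node j at t-1 on node i at t.
#' @export
build_subject_var <- function(trait_row, cfg) {
  N <- cfg$n_networks
  A <- diag(cfg$ar_diag, N)
  if (!is.null(cfg$edges) && nrow(cfg$edges)) {
    keys <- connection_keys(N)
    for (k in seq_len(nrow(cfg$edges))) {
      s <- cfg$edges[k, 1]; t <- cfg$edges[k, 2]
      key <- paste0("n", s, "->", "n", t)
      tr <- trait_row[[key]]
      tr <- min(max(tr, -0.8), 0.8)
      A[t, s] <- cfg$base_coupling * (1 + tr)
    }
  }
  r <- max(Mod(eigen(A, only.values = TRUE)$values))
  if (r > 0.95) A <- A * (0.95 / r)
  A
}

#' Double-gamma hemodynamic response function
#'
#' Canonical two-gamma kernel: a positive response gamma with configurable
#' peak latency and a later undershoot, sampled at `TR` over `[0, span]`
#' seconds and normalized to unit peak.
#'
#' @param TR sampling interval (s).
#' @param peak time-to-peak of the positive lobe (s).
#' @param undershoot time-to-trough of the undershoot (s).
#' @param ratio undershoot amplitude relative to the peak lobe.
#' @param span kernel support (s).
#' @return numeric kernel sampled at `0, TR, 2 TR, ...`.
#' @export
hrf_double_gamma <- function(TR, peak = 6, undershoot = 16, ratio = 1 / 6,
                             span = 24) {
  t <- seq(0, span, by = TR)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    ratio * stats::dgamma(t, shape = undershoot + 1, rate = 1)
  h / max(h)
}

causal_convolve <- function(x, h) {
  stats::convolve(x, rev(h), type = "open")[seq_along(x)]
}

#' Generate BOLD-like network time-series for a cohort
#'
#' For each subject: simulate the subject's stable VAR(1) neural dynamics
#' (independent sessions, burn-in discarded), convolve every node with a
#' double-gamma HRF whose peak latency is jittered uniformly per
#' node-by-subject within `cfg$hrf_latency_range`, add white observation
#' noise, and standardize each series. The HRF jitter induces the
#' inter-regional lag confound that deconvolution is meant to remove.
#'
#' @param ped a [pedigree()].
#' @param traits matrix from [simulate_ace_traits()].
#' @param cfg a [sim_config()].
#' @param hrf_peaks optional n x N matrix of fixed peak latencies (s)
#'   overriding the jitter (used by targeted experiments).
#' @return object of class `"nts_set"`: list with `subjects` (named list;
#'   each a list of T x N session matrices), `TR`, `labels`.
#' @export
generate_bold <- function(ped, traits, cfg, hrf_peaks = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- .Random.seed_safe(); on.exit(.Random.seed_restore(old))
  set.seed(child_seed(cfg$seed, "bold"))
  N <- cfg$n_networks; T <- cfg$n_timepoints
  subjects <- vector("list", nrow(ped))
  names(subjects) <- ped$id
  for (si in seq_len(nrow(ped))) {
    A <- build_subject_var(traits[si, ], cfg)
    peaks <- if (is.null(hrf_peaks)) {
      stats::runif(N, cfg$hrf_latency_range[1], cfg$hrf_latency_range[2])
    } else hrf_peaks[si, ]
    kernels <- lapply(peaks, function(p) hrf_double_gamma(cfg$TR, peak = p))
    sess <- vector("list", cfg$n_sessions)
    for (se in seq_len(cfg$n_sessions)) {
      E <- draw_innovations(T + cfg$burn_in, N, cfg$innovations,
                            cfg$spike_prob)
      X <- simulate_var(A, T + cfg$burn_in, E = E)
      X <- X[cfg$burn_in + seq_len(T), , drop = FALSE]
      Y <- X
      for (j in seq_len(N)) {
        y <- causal_convolve(X[, j], kernels[[j]])
        y <- y + stats::rnorm(T, 0, cfg$noise_sd * stats::sd(y))
        Y[, j] <- as.numeric(scale(y))
      }
      colnames(Y) <- paste0("n", seq_len(N))
      sess[[se]] <- Y
    }
    subjects[[si]] <- sess
  }
  structure(list(subjects = subjects, TR = cfg$TR,
                 labels = paste0("n", seq_len(N))),
            class = "nts_set")
}

#' Simulate a VAR(1) path
#'
#' `x_t = A x_{t-1} + eps_t`, `eps ~ N(0, I)` unless an innovation matrix is
#' supplied; zero start.
#' @param A N x N stable coefficient matrix.
#' @param T number of steps.
#' @param E optional T x N innovation matrix.
#' @return T x N matrix.
#' @export
simulate_var <- function(A, T, E = NULL) {
  N <- nrow(A)
  if (is.null(E)) E <- matrix(stats::rnorm(T * N), T, N)
  X <- matrix(0, T, N)
  X[1, ] <- E[1, ]
  for (t in 2:T) X[t, ] <- A %*% X[t - 1, ] + E[t, ]
  X
}

#' Draw VAR innovations
#'
#' `"gaussian"`: iid standard normal. `"burst"`: Gaussian background (SD
#' 0.5) plus sparse positive exponential spikes (per-sample probability
#' `spike_prob`, mean amplitude 4), centred and scaled to unit variance.
#' The spikes give the latent activity the event-like, heavy-tailed
#' character of spontaneous neural activity on which blind hemodynamic
#' deconvolution relies.
#'
#' @param T,N dimensions.
#' @param model `"burst"` or `"gaussian"`.
#' @param spike_prob spike probability per sample.
#' @return T x N matrix of unit-variance innovations.
#' @export
draw_innovations <- function(T, N, model = "burst", spike_prob = 0.04) {
  if (model == "gaussian") return(matrix(stats::rnorm(T * N), T, N))
  bg <- matrix(stats::rnorm(T * N, 0, 0.5), T, N)
  spikes <- matrix(stats::rbinom(T * N, 1, spike_prob) *
                     stats::rexp(T * N, rate = 1 / 4), T, N)
  E <- bg + spikes - spike_prob * 4
  v <- 0.25 + spike_prob * 2 * 16 - (spike_prob * 4)^2
  E / sqrt(v)
}

#' @export
print.nts_set <- function(x, ...) {
  ns <- length(x$subjects)
  s1 <- if (ns) x$subjects[[1]] else list()
  cat("Network time-series set:", ns, "subjects,",
      length(s1), "sessions,",
      if (length(s1)) paste(nrow(s1[[1]]), "x", ncol(s1[[1]])) else "",
      "(TR =", x$TR, "s)\n")
  invisible(x)
}
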