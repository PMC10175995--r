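#' Pooled multi-session VAR estimation
#'
#' Fits one vector autoregression to all sessions of a subject by stacking
#' lagged predictor/target rows across sessions — no row spans a session
#' boundary, so each session contributes `T - p` equations to the same
#' normal equations. Pooling the sessions into a single model borrows
#' strength across runs. Series are demeaned per session; no intercept is
#' fitted. With `order = "aic"` or `"bic"` the order minimizing the
#' criterion over `1..p_max` is selected.
#'
#' @param sessions list of T x N numeric matrices (one per session), or a
#'   single matrix.
#' @param order integer VAR order, or `"aic"` / `"bic"`.
#' @param p_max maximum order scanned during selection (default 20).
#' @return object of class `"var_model"`: list with `p`, `A` (list of N x N
#'   lag-coefficient matrices, `A[[k]][i, j]` = effect of node j at lag k on
#'   node i), `Sigma` (residual covariance, dof-corrected), `Sigma_ml`,
#'   `n_eff` (stacked rows), `stable`, `order_criterion`.
#' @export
fit_var_pooled <- function(sessions, order = "aic", p_max = 20L) {
  if (is.matrix(sessions)) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1)
  N <- ncol(sessions[[1]])
  stopifnot(all(vapply(sessions, ncol, 0L) == N))
  sessions <- lapply(sessions, function(S) scale(S, scale = FALSE))
  fit_p <- function(p) {
    Xs <- list(); Ys <- list()
    for (S in sessions) {
      T <- nrow(S)
      if (T <= p) next
      rows <- (p + 1):T
      Ys[[length(Ys) + 1L]] <- S[rows, , drop = FALSE]
      Xs[[length(Xs) + 1L]] <- do.call(cbind, lapply(seq_len(p), function(k)
        S[rows - k, , drop = FALSE]))
    }
    X <- do.call(rbind, Xs); Y <- do.call(rbind, Ys)
    M <- nrow(X)
    if (is.null(M) || M < 5 * N * p) {
      stop("insufficient pooled rows for VAR(", p, "): have ",
           if (is.null(M)) 0 else M, ", need >= ", 5 * N * p)
    }
    qrX <- qr(X)
    Bhat <- qr.coef(qrX, Y)                     # (N p) x N
    E <- Y - X %*% Bhat
    Sigma_ml <- crossprod(E) / M
    Sigma <- crossprod(E) / max(1, M - N * p)
    A <- lapply(seq_len(p), function(k)
      t(Bhat[(k - 1) * N + seq_len(N), , drop = FALSE]))
    list(p = p, A = A, Sigma = Sigma, Sigma_ml = Sigma_ml, n_eff = M)
  }
  crit <- NULL
  if (is.character(order)) {
    order <- match.arg(order, c("aic", "bic"))
    vals <- rep(NA_real_, p_max)
    fits <- vector("list", p_max)
    for (p in seq_len(p_max)) {
      f <- tryCatch(fit_p(p), error = function(e) NULL)
      if (is.null(f)) break
      pen <- if (order == "aic") 2 else log(f$n_eff)
      vals[p] <- determinant(f$Sigma_ml, logarithm = TRUE)$modulus +
        pen * p * N^2 / f$n_eff
      fits[[p]] <- f
    }
    if (all(is.na(vals))) stop("no VAR order could be fitted")
    pstar <- which.min(vals)
    f <- fits[[pstar]]
    crit <- list(method = order, values = vals, selected = pstar)
  } else {
    f <- fit_p(as.integer(order))
  }
  comp <- companion_matrix(f$A)
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  stable <- rho < 1
  if (!stable) {
    warning("fitted VAR is unstable (spectral radius ", round(rho, 4), ")")
  }
  structure(list(p = f$p, A = f$A, Sigma = f$Sigma, Sigma_ml = f$Sigma_ml,
                 n_eff = f$n_eff, stable = stable, spectral_radius = rho,
                 order_criterion = crit),
            class = "var_model")
}

#' @export
print.var_model <- function(x, ...) {
  cat("VAR(", x$p, ") on ", ncol(x$Sigma), " nodes, ", x$n_eff,
      " pooled rows, spectral radius ", round(x$spectral_radius, 3),
      if (x$stable) " (stable)\n" else " (UNSTABLE)\n", sep = "")
  invisible(x)
}

#' Companion matrix of a VAR coefficient list
#' @param A list of N x N lag-coefficient matrices.
#' @return (N p) x (N p) companion matrix.
#' @export
companion_matrix <- function(A) {
  N <- nrow(A[[1]]); p <- length(A)
  comp <- matrix(0, N * p, N * p)
  comp[seq_len(N), ] <- do.call(cbind, A)
  if (p > 1) {
    comp[N + seq_len(N * (p - 1)), seq_len(N * (p - 1))] <-
      diag(N * (p - 1))
  }
  comp
}

#' Innovations state-space form of a VAR
#'
#' Companion-form innovations representation: with the state holding the
#' stacked past `x_t = (y_{t-1}, ..., y_{t-p})`,
#' `x_{t+1} = A x_t + K e_t` and `y_t = C x_t + e_t`, where
#' `C = (A_1 ... A_p)`, `K` injects the innovation into the first block, and
#' the innovations covariance `V` equals the VAR residual covariance.
#'
#' @param var a `"var_model"` (must be stable).
#' @return object of class `"ss_model"`: list with `A` (m x m), `C` (N x m),
#'   `K` (m x N), `V` (N x N), `m`, `N`.
#' @export
var_to_state_space <- function(var) {
  stopifnot(inherits(var, "var_model"))
  if (!var$stable) stop("cannot build state space from an unstable VAR")
  N <- nrow(var$A[[1]]); p <- var$p; m <- N * p
  A <- companion_matrix(var$A)
  C <- do.call(cbind, var$A)
  K <- rbind(diag(N), matrix(0, m - N, N))
  structure(list(A = A, C = C, K = K, V = var$Sigma, m = m, N = N),
            class = "ss_model")
}

#' Autocovariance sequence implied by a state-space model
#'
#' `Gamma_0 = C P C' + V`, `Gamma_h = C A^{h-1} (A P C' + K V)` for
#' `h >= 1`, with `P` the stationary state covariance (discrete Lyapunov
#' solution).
#' @param ss an `"ss_model"`.
#' @param max_lag largest lag returned.
#' @return list of `max_lag + 1` N x N matrices (`Gamma_0` first).
#' @export
ss_autocov <- function(ss, max_lag = 10L) {
  P <- dlyap(ss$A, ss$K %*% ss$V %*% t(ss$K))
  G0 <- ss$C %*% P %*% t(ss$C) + ss$V
  out <- vector("list", max_lag + 1L)
  out[[1]] <- G0
  M <- ss$A %*% P %*% t(ss$C) + ss$K %*% ss$V
  Ak <- diag(nrow(ss$A))
  for (h in seq_len(max_lag)) {
    out[[h + 1]] <- ss$C %*% Ak %*% M
    Ak <- ss$A %*% Ak
  }
  out
}

#' Discrete Lyapunov equation solver
#'
#' Solves `X = A X A' + Q` by Smith/doubling iteration (quadratic
#' convergence for spectral radius < 1).
#' @param A square stable matrix.
#' @param Q symmetric matrix.
#' @param tol convergence tolerance.
#' @param max_iter iteration cap.
#' @export
dlyap <- function(A, Q, tol = 1e-14, max_iter = 200L) {
  X <- Q
  Ak <- A
  for (i in seq_len(max_iter)) {
    Xn <- X + Ak %*% X %*% t(Ak)
    Ak <- Ak %*% Ak
    if (max(abs(Xn - X)) <= tol * max(1, max(abs(Xn)))) {
      return((Xn + t(Xn)) / 2)
    }
    X <- Xn
  }
  (X + t(X)) / 2
}

#' Discrete algebraic Riccati equation (filter form)
#'
#' Solves
#' `P = A P A' + Q - (A P C' + S)(C P C' + R)^{-1}(A P C' + S)'`
#' by the structured doubling algorithm after eliminating the cross term,
#' giving the steady-state predicted state covariance of the Kalman filter.
#'
#' @param A state transition (m x m).
#' @param C observation matrix (q x m).
#' @param Q state-noise covariance (m x m).
#' @param R observation-noise covariance (q x q, PD).
#' @param S state/observation noise cross-covariance (m x q), default 0.
#' @param tol convergence tolerance (default 1e-12).
#' @param max_iter doubling-iteration cap (default 500).
#' @return symmetric m x m solution `P`.
#' @export
solve_dare <- function(A, C, Q, R, S = NULL, tol = 1e-12, max_iter = 500L) {
  m <- nrow(A)
  if (is.null(S)) S <- matrix(0, m, nrow(R))
  Rinv_S <- t(solve(R, t(S)))            # S R^{-1}
  Ah <- A - Rinv_S %*% C
  Qh <- Q - Rinv_S %*% t(S)
  Qh <- (Qh + t(Qh)) / 2
  # control-form doubling with A_d = Ah', B = C'
  Ad <- t(Ah)
  G <- t(C) %*% solve(R, C)
  H <- Qh
  I <- diag(m)
  for (i in seq_len(max_iter)) {
    IGH <- solve(I + G %*% H)
    An <- Ad %*% IGH %*% Ad
    Gn <- G + Ad %*% IGH %*% G %*% t(Ad)
    Hn <- H + t(Ad) %*% H %*% IGH %*% Ad
    delta <- max(abs(Hn - H))
    Ad <- An; G <- (Gn + t(Gn)) / 2; H <- (Hn + t(Hn)) / 2
    if (delta <= tol * max(1, max(abs(H)))) break
    if (i == max_iter) stop("DARE doubling did not converge in ",
                            max_iter, " iterations")
  }
  H
}

#' Granger causality from one source to all other nodes
#'
#' State-space Granger causality: the reduced model that withholds the
#' source's observations is the same state process observed through `C`
#' without the source row; its steady-state innovations covariance `V_R`
#' follows from one discrete algebraic Riccati equation. For each remaining
#' node i, `F(source -> i | rest) = ln(V_R[i, i] / V[i, i])` — the log ratio
#' of the target's innovation variance without and with the source's past.
#'
#' @param ss an `"ss_model"`.
#' @param source node index (column of the observation vector).
#' @return numeric vector of length N with `F` for every non-source node and
#'   `NA` at the source position; names = node indices.
#' @export
gc_from_source <- function(ss, source) {
  N <- ss$N
  stopifnot(source >= 1, source <= N)
  if (N < 2) return(rep(NA_real_, N))
  keep <- setdiff(seq_len(N), source)
  Cr <- ss$C[keep, , drop = FALSE]
  R <- ss$V[keep, keep, drop = FALSE]
  S <- ss$K %*% ss$V[, keep, drop = FALSE]
  Q <- ss$K %*% ss$V %*% t(ss$K)
  P <- solve_dare(ss$A, Cr, Q, R, S)
  VR <- Cr %*% P %*% t(Cr) + R
  F <- rep(NA_real_, N)
  F[keep] <- log(diag(VR) / diag(ss$V)[keep])
  F
}

#' Directed-connectivity matrix of one subject
#'
#' Runs the full chain pooled VAR -> innovations state space -> one Riccati
#' solve per source node, and assembles the non-symmetric N x N matrix of
#' conditional Granger-causality strengths, `G[source, target]`. Tiny
#' negative values (|F| <= 1e-10, numerical) are clipped to zero; more
#' negative values are also clipped but counted in attribute `n_clipped`.
#' Per-source Riccati failures yield NA rows, counted in `n_failed`. An
#' unstable fitted VAR (spectral radius >= 1, occasional at short series) is
#' stabilized before the state-space step by scaling each lag-k coefficient
#' matrix by `s^k` with `s = 0.98 / rho` — the unique rescaling of the lag
#' operator that shrinks every companion eigenvalue into the unit circle
#' while preserving the coefficient pattern; counted in `n_stabilized`.
#'
#' @param sessions list of T x N session matrices (one subject).
#' @param order,p_max passed to [fit_var_pooled()].
#' @param mode `"conditional"` (each F conditioned on all remaining nodes,
#'   default) or `"bivariate"` (pairwise unconditional, each pair reduced
#'   from the full state process).
#' @param labels node labels.
#' @return N x N `"gc_matrix"` (plain matrix with dimnames and attributes
#'   `n_clipped`, `n_failed`, `var_order`).
#' @export
gc_matrix <- function(sessions, order = "aic", p_max = 20L,
                      mode = c("conditional", "bivariate"),
                      labels = NULL) {
  mode <- match.arg(mode)
  if (is.matrix(sessions)) sessions <- list(sessions)
  N <- ncol(sessions[[1]])
  if (is.null(labels)) {
    labels <- colnames(sessions[[1]])
    if (is.null(labels)) labels <- paste0("n", seq_len(N))
  }
  G <- matrix(0, N, N, dimnames = list(labels, labels))
  if (N == 1) return(structure(G, n_clipped = 0L, n_failed = 0L,
                               n_stabilized = 0L, var_order = NA_integer_,
                               class = c("gc_matrix", "matrix", "array")))
  var <- suppressWarnings(fit_var_pooled(sessions, order = order,
                                         p_max = p_max))
  n_stabilized <- 0L
  if (!var$stable) {
    s <- 0.98 / var$spectral_radius
    var$A <- lapply(seq_along(var$A), function(k) var$A[[k]] * s^k)
    var$spectral_radius <- max(Mod(eigen(companion_matrix(var$A),
                                         only.values = TRUE)$values))
    var$stable <- var$spectral_radius < 1
    n_stabilized <- 1L
  }
  ss <- var_to_state_space(var)
  n_failed <- 0L
  if (mode == "conditional") {
    for (j in seq_len(N)) {
      F <- tryCatch(gc_from_source(ss, j), error = function(e) {
        rep(NaN, N)
      })
      if (any(is.nan(F))) n_failed <- n_failed + 1L
      G[j, -j] <- F[-j]
    }
  } else {
    Vsub <- function(keep) {
      Cr <- ss$C[keep, , drop = FALSE]
      R <- ss$V[keep, keep, drop = FALSE]
      S <- ss$K %*% ss$V[, keep, drop = FALSE]
      Q <- ss$K %*% ss$V %*% t(ss$K)
      P <- solve_dare(ss$A, Cr, Q, R, S)
      Cr %*% P %*% t(Cr) + R
    }
    for (i in seq_len(N)) {
      Vi <- tryCatch(Vsub(i), error = function(e) NULL)
      for (j in seq_len(N)) {
        if (i == j) next
        Vij <- tryCatch(Vsub(sort(c(i, j))), error = function(e) NULL)
        if (is.null(Vi) || is.null(Vij)) {
          G[j, i] <- NaN; n_failed <- n_failed + 1L; next
        }
        pos <- which(sort(c(i, j)) == i)
        G[j, i] <- log(Vi[1, 1] / Vij[pos, pos])
      }
    }
  }
  n_clipped <- sum(G < -1e-10, na.rm = TRUE)
  G[!is.na(G) & G < 0] <- 0
  structure(G, n_clipped = n_clipped, n_failed = n_failed,
            n_stabilized = n_stabilized, var_order = var$p,
            class = c("gc_matrix", "matrix", "array"))
}

#' Group aggregation of subject GC matrices
#'
#' Entrywise median across subjects (NaN-skipping) plus the upper-quartile
#' connection report: all directed connections whose median strength is at
#' or above the 75th percentile of the `N (N - 1)` off-diagonal medians,
#' sorted in decreasing strength.
#'
#' @param matrices non-empty list of N x N GC matrices sharing labels.
#' @return list with `median` (N x N matrix) and `upper_quartile` (data
#'   frame `source,target,median_gc`).
#' @export
aggregate_connectome <- function(matrices) {
  if (!length(matrices)) stop("no GC matrices to aggregate")
  N <- nrow(matrices[[1]])
  labels <- rownames(matrices[[1]])
  if (is.null(labels)) labels <- paste0("n", seq_len(N))
  stopifnot(all(vapply(matrices, nrow, 0L) == N))
  arr <- array(unlist(matrices), dim = c(N, N, length(matrices)))
  med <- apply(arr, c(1, 2), stats::median, na.rm = TRUE)
  dimnames(med) <- list(labels, labels)
  off <- med[row(med) != col(med)]
  thr <- stats::quantile(off, 0.75, na.rm = TRUE)
  idx <- which(med >= thr & row(med) != col(med), arr.ind = TRUE)
  rep_df <- data.frame(source = labels[idx[, 1]], target = labels[idx[, 2]],
                       median_gc = med[idx])
  rep_df <- rep_df[order(-rep_df$median_gc), ]
  rownames(rep_df) <- NULL
  list(median = med, upper_quartile = rep_df)
}

#' Write a GC matrix as CSV
#'
#' Layout: header comment line documenting the orientation
#' (rows = source, columns = target), then a labelled N x N table.
#' @param G GC matrix.
#' @param path output file.
#' @export
write_gc_matrix <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# directed connectivity; rows = source, columns = target", con)
  utils::write.csv(as.data.frame(G), con, row.names = TRUE, quote = FALSE)
  invisible(path)
}
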