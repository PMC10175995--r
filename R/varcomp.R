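#' Residualize traits against demographic covariates
#'
#' Replaces each trait column by its least-squares residual against an
#' intercept plus age, sex, handedness and education, removing covariates of
#' no interest before heritability estimation.
#'
#' @param traits numeric matrix (subjects x traits) with rownames = ids.
#' @param cov covariate data frame (`id,age,sex,handedness,education`).
#' @return residualized matrix of the same shape.
#' @export
adjust_covariates <- function(traits, cov) {
  traits <- as.matrix(traits)
  ids <- rownames(traits)
  if (is.null(ids)) stop("trait matrix must carry subject ids as rownames")
  mm <- cov[match(ids, cov$id), ]
  if (anyNA(mm$id)) stop("covariates missing for some subjects")
  X <- cbind(intercept = 1, age = mm$age, sex = as.numeric(factor(mm$sex)),
             handedness = as.numeric(factor(mm$handedness)),
             education = mm$education)
  # constant covariates carry no information beyond the intercept; drop them
  const <- c(FALSE, apply(X[, -1, drop = FALSE], 2, stats::sd) == 0)
  X <- X[, !const, drop = FALSE]
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  res <- as.matrix(stats::lm.fit(X, traits)$residuals)
  dimnames(res) <- dimnames(traits)
  res
}

#' Rank-based inverse normal transformation
#'
#' Blom scores: `qnorm((rank - 3/8) / (n + 1/4))` with mean ranks for ties;
#' enforces marginal normality of each trait before the Gaussian
#' variance-component likelihood is applied.
#'
#' @param values numeric vector (`n >= 3`, not all identical).
#' @return transformed vector, order-preserving.
#' @export
inverse_normal_transform <- function(values) {
  n <- length(values)
  if (n < 3) stop("inverse normal transform needs n >= 3")
  if (stats::sd(values) == 0) stop("all values identical: ranks undefined")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

# ---- blockwise Gaussian likelihood machinery ------------------------------

#' Precompute a variance-component design
#'
#' Families are independent blocks of the model covariance
#' `sigma_p^2 * M(h2, c2)` with `M = h2 * 2Phi + c2 * H + (1 - h2 - c2) I`.
#' Blocks with identical (kinship, household) structure share all matrix
#' work, so the profile-likelihood grid is evaluated once per unique
#' structure and reused across traits. The scale `sigma_p^2` is profiled out
#' analytically.
#'
#' @param kin kinship matrix (2Phi) with dimnames = ids.
#' @param house household matrix or `NULL` (AE designs).
#' @param famid family id per individual (same order as `kin`).
#' @param model `"AE"` or `"ACE"`.
#' @param grid_step profile-grid resolution in h2 / c2 (default 0.01).
#' @return `"vc_design"` list used by [fit_variance_components()] and
#'   [heritability_scan()].
#' @export
vc_design <- function(kin, house = NULL, famid, model = c("AE", "ACE"),
                      grid_step = 0.01) {
  model <- match.arg(model)
  n <- nrow(kin)
  stopifnot(length(famid) == n)
  if (model == "ACE" && is.null(house)) {
    stop("ACE model requires a household matrix")
  }
  fam_idx <- unname(split(seq_len(n), famid))
  sig <- vapply(fam_idx, function(ix) {
    paste(c(length(ix), round(kin[ix, ix], 6),
            if (!is.null(house)) round(house[ix, ix], 6)), collapse = ",")
  }, character(1))
  ustr <- unique(sig)
  structures <- lapply(ustr, function(s) {
    ix <- fam_idx[[match(s, sig)]]
    list(K = kin[ix, ix, drop = FALSE],
         H = if (is.null(house)) NULL else house[ix, ix, drop = FALSE],
         k = length(ix),
         members = fam_idx[sig == s])     # list of index vectors
  })
  # parameter grid on the (h2, c2) simplex, capped just inside the boundary
  # so M stays invertible for MZ blocks
  hmax <- 0.99
  if (model == "AE") {
    grid <- cbind(h2 = seq(0, hmax, by = grid_step), c2 = 0)
  } else {
    h <- seq(0, hmax, by = grid_step)
    grid <- expand.grid(h2 = h, c2 = h)
    grid <- as.matrix(grid[grid$h2 + grid$c2 <= hmax, ])
  }
  des <- list(model = model, n = n, grid = grid, structures = structures,
              grid_step = grid_step)
  # per grid point and structure: log|M| and M^{-1}
  des$grid_logdet <- numeric(nrow(grid))
  des$grid_minv <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ld <- 0
    minv <- vector("list", length(structures))
    for (s in seq_along(structures)) {
      st <- structures[[s]]
      M <- vc_block(st, grid[g, 1], grid[g, 2])
      ch <- chol(M)
      ld <- ld + 2 * sum(log(diag(ch))) * length(st$members)
      minv[[s]] <- chol2inv(ch)
    }
    des$grid_logdet[g] <- ld
    des$grid_minv[[g]] <- minv
  }
  class(des) <- "vc_design"
  des
}

vc_block <- function(st, h2, c2) {
  M <- h2 * st$K + (1 - h2 - c2) * diag(st$k)
  if (!is.null(st$H) && c2 != 0) M <- M + c2 * st$H
  M
}

# stack one trait into per-structure member matrices (k x n_families)
vc_stack <- function(des, y) {
  lapply(des$structures, function(st)
    matrix(y[unlist(st$members)], nrow = st$k))
}

# profile log-likelihood at a unit-scale correlation structure:
# given quadratic forms qf = sum_f y' M^{-1} y and logdet = sum_f log|M|,
# sigma_p^2-hat = qf / n and
# ll = -n/2 log(2 pi) - n/2 log(sigma2) - logdet/2 - n/2
vc_profile_ll <- function(n, qf, logdet) {
  sigma2 <- qf / n
  -n / 2 * log(2 * pi) - n / 2 * log(sigma2) - logdet / 2 - n / 2
}

# log-likelihood of a trait at arbitrary (h2, c2), computed on the fly
vc_ll_at <- function(des, Z, h2, c2) {
  ld <- 0; qf <- 0
  for (s in seq_along(des$structures)) {
    st <- des$structures[[s]]
    M <- vc_block(st, h2, c2)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    ld <- ld + 2 * sum(log(diag(ch))) * length(st$members)
    W <- backsolve(ch, forwardsolve(t(ch), Z[[s]]))
    qf <- qf + sum(Z[[s]] * W)
  }
  vc_profile_ll(des$n, qf, ld)
}

vc_ll_grid <- function(des, Z) {
  nG <- nrow(des$grid)
  qf <- numeric(nG)
  for (g in seq_len(nG)) {
    minv <- des$grid_minv[[g]]
    tot <- 0
    for (s in seq_along(Z)) tot <- tot + sum(Z[[s]] * (minv[[s]] %*% Z[[s]]))
    qf[g] <- tot
  }
  vc_profile_ll(des$n, qf, des$grid_logdet)
}

#' Fit AE/ACE variance components to one trait by maximum likelihood
#'
#' Zero-mean multivariate-normal likelihood with covariance
#' `sigma_g^2 2Phi + sigma_c^2 H + sigma_e^2 I`, evaluated blockwise per
#' family. The variance-share parameters (h2, and c2 for ACE) are profiled
#' on a simplex grid (step `grid_step`) with the total variance maximized
#' analytically, then refined by a nested local grid to resolution 1e-3;
#' boundary solutions are allowed. An (essentially) flat likelihood — e.g.
#' an all-singleton pedigree, where genetic and unique-environment variance
#' are not separable — is flagged `"unidentifiable"` and returned at the
#' h2 = 0 boundary.
#'
#' @param trait numeric vector aligned to the pedigree (non-zero variance).
#' @param kin kinship matrix (2Phi).
#' @param house household matrix (ACE) or `NULL`.
#' @param famid family ids aligned to `trait`.
#' @param model `"AE"` or `"ACE"`.
#' @param design optional precomputed [vc_design()] (overrides
#'   `kin`/`house`/`model`).
#' @param null_constraint for internal use: `"none"` (default) fits the
#'   requested model; `"no_genetic"` fixes `sigma_g^2 = 0` (E-only under AE,
#'   CE under ACE), giving the null of the heritability test.
#' @return object of class `"varcomp"`: list with `sigma_g2`, `sigma_c2`,
#'   `sigma_e2`, `sigma_p2`, `h2`, `c2`, `loglik`, `model`, `flag`.
#' @export
fit_variance_components <- function(trait, kin = NULL, house = NULL,
                                    famid = NULL, model = c("AE", "ACE"),
                                    design = NULL,
                                    null_constraint = c("none", "no_genetic")) {
  null_constraint <- match.arg(null_constraint)
  if (is.null(design)) {
    model <- match.arg(model)
    if (is.null(famid)) famid <- rownames(kin)
    design <- vc_design(kin, house, famid, model)
  }
  if (stats::var(trait) == 0) stop("trait has zero variance")
  n <- design$n
  stopifnot(length(trait) == n)
  y <- trait - mean(trait)
  Z <- vc_stack(design, y)
  flag <- "ok"
  if (null_constraint == "no_genetic") {
    if (design$model == "AE") {
      # E-only: closed form
      sigma2 <- sum(y^2) / n
      ll <- -n / 2 * (log(2 * pi) + log(sigma2) + 1)
      return(vc_result(0, 0, sigma2, ll, design$model, "ok"))
    }
    # CE: 1-D search over c2 with h2 = 0
    cs <- seq(0, 0.99, by = design$grid_step)
    lls <- vapply(cs, function(cc) vc_ll_at(design, Z, 0, cc), 0)
    c0 <- cs[which.max(lls)]
    ref <- refine_1d(function(cc) vc_ll_at(design, Z, 0, cc),
                     c0, design$grid_step, 0, 0.999)
    sigma2 <- vc_sigma2(design, Z, 0, ref$x)
    return(vc_result(0, ref$x * sigma2, (1 - ref$x) * sigma2, ref$ll,
                     design$model, "ok"))
  }
  lls <- vc_ll_grid(design, Z)
  if (max(lls) - min(lls) < 1e-8) {
    # flat likelihood: components not separable (e.g. all singletons)
    sigma2 <- sum(y^2) / n
    return(vc_result(0, 0, sigma2, vc_ll_at(design, Z, 0, 0),
                     design$model, "unidentifiable"))
  }
  g0 <- which.max(lls)
  h0 <- design$grid[g0, 1]; c0 <- design$grid[g0, 2]
  if (design$model == "AE") {
    ref <- refine_1d(function(h) vc_ll_at(design, Z, h, 0),
                     h0, design$grid_step, 0, 0.999)
    h2 <- ref$x; c2 <- 0; ll <- ref$ll
  } else {
    ref <- refine_2d(function(h, cc) vc_ll_at(design, Z, h, cc),
                     h0, c0, design$grid_step)
    h2 <- ref$x; c2 <- ref$y; ll <- ref$ll
  }
  sigma2 <- vc_sigma2(design, Z, h2, c2)
  vc_result(h2 * sigma2, c2 * sigma2, (1 - h2 - c2) * sigma2, ll,
            design$model, flag)
}

vc_sigma2 <- function(des, Z, h2, c2) {
  qf <- 0
  for (s in seq_along(des$structures)) {
    st <- des$structures[[s]]
    ch <- chol(vc_block(st, h2, c2))
    W <- backsolve(ch, forwardsolve(t(ch), Z[[s]]))
    qf <- qf + sum(Z[[s]] * W)
  }
  qf / des$n
}

vc_result <- function(sg, sc, se, ll, model, flag) {
  sp <- sg + sc + se
  structure(list(sigma_g2 = sg, sigma_c2 = sc, sigma_e2 = se,
                 sigma_p2 = sp,
                 h2 = if (sp > 0) sg / sp else 0,
                 c2 = if (sp > 0) sc / sp else 0,
                 loglik = ll, model = model, flag = flag),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf("%s fit: h2 = %.3f, c2 = %.3f, e2 = %.3f, logLik = %.3f [%s]\n",
              x$model, x$h2, x$c2,
              1 - x$h2 - x$c2, x$loglik, x$flag))
  invisible(x)
}

# nested 1-D grid refinement down to 1e-3 (then 1e-4) resolution
refine_1d <- function(f, x0, step, lo, hi) {
  x <- x0; ll <- f(x0)
  for (s in c(step / 10, step / 100)) {
    cand <- seq(max(lo, x - 10 * s), min(hi, x + 10 * s), by = s)
    vals <- vapply(cand, f, 0)
    if (max(vals) > ll) {
      x <- cand[which.max(vals)]; ll <- max(vals)
    }
  }
  list(x = x, ll = ll)
}

refine_2d <- function(f, x0, y0, step) {
  x <- x0; y <- y0; ll <- f(x0, y0)
  for (s in c(step / 10, step / 100)) {
    gx <- seq(max(0, x - 10 * s), min(0.999, x + 10 * s), by = s)
    gy <- seq(max(0, y - 10 * s), min(0.999, y + 10 * s), by = s)
    gr <- expand.grid(h = gx, c = gy)
    gr <- gr[gr$h + gr$c <= 0.999, ]
    vals <- mapply(f, gr$h, gr$c)
    if (max(vals) > ll) {
      k <- which.max(vals)
      x <- gr$h[k]; y <- gr$c[k]; ll <- max(vals)
    }
  }
  list(x = x, y = y, ll = ll)
}

#' Boundary-corrected likelihood-ratio test for heritability
#'
#' Tests `sigma_g^2 = 0`. Because the null value lies on the boundary of the
#' parameter space, the LRT statistic is asymptotically a 50:50 mixture of a
#' point mass at zero and chi-square(1):
#' `p = 0.5 * P(chisq_1 >= Lambda)`, and `p = 0.5` at `Lambda = 0`.
#'
#' @param full a `"varcomp"` fit of the unconstrained model.
#' @param null_loglik log-likelihood of the `sigma_g^2 = 0` fit.
#' @return list with `statistic` (Lambda, clipped at 0), `p`, and `flag`
#'   (`"optimizer_failure"` when the full likelihood falls below the null by
#'   more than 1e-6).
#' @export
lrt_heritability <- function(full, null_loglik) {
  ll_full <- if (inherits(full, "varcomp")) full$loglik else as.numeric(full)
  lambda <- 2 * (ll_full - null_loglik)
  flag <- if (lambda < -1e-6) "optimizer_failure" else "ok"
  lambda <- max(lambda, 0)
  p <- 0.5 * stats::pchisq(lambda, df = 1, lower.tail = FALSE)
  list(statistic = lambda, p = p, flag = flag)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up q-values (via [stats::p.adjust()]) and significance flags at
#' level `alpha`.
#'
#' @param pvals p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `q` and logical `significant`.
#' @export
fdr_bh <- function(pvals, alpha = 0.05) {
  if (!length(pvals)) return(list(q = numeric(0), significant = logical(0)))
  stopifnot(all(pvals > 0 & pvals <= 1))
  q <- stats::p.adjust(pvals, method = "BH")
  list(q = q, significant = q <= alpha)
}

#' Heritability scan over all directed connections
#'
#' The per-cohort endophenotype analysis: every directed connection's trait
#' vector is residualized against the demographic covariates, inverse-normal
#' transformed, fitted under the chosen variance-component model (full and
#' `sigma_g^2 = 0` null), tested with the boundary-corrected LRT, and the
#' p-values are FDR-corrected jointly across all connections of the cohort.
#' Connections whose optimizer fails are excluded from the FDR family (the
#' count is reported in attribute `n_failed`).
#'
#' @param traits subjects x connections matrix, rownames = ids, colnames =
#'   `"src->tgt"` keys.
#' @param ped a [pedigree()] covering the trait rows.
#' @param cov covariate data frame.
#' @param model `"AE"` or `"ACE"`.
#' @param alpha FDR level.
#' @return data frame (`source,target,model,h2,c2,loglik,lrt,p,q,significant`)
#'   with one row per connection, attribute `n_failed`.
#' @export
heritability_scan <- function(traits, ped, cov, model = c("AE", "ACE"),
                              alpha = 0.05) {
  model <- match.arg(model)
  traits <- as.matrix(traits)
  if (!ncol(traits)) {
    out <- data.frame(source = character(0), target = character(0),
                      model = character(0), h2 = numeric(0), c2 = numeric(0),
                      loglik = numeric(0), lrt = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0))
    attr(out, "n_failed") <- 0L
    return(out)
  }
  ok_subj <- apply(is.finite(traits), 1, all)
  if (!all(ok_subj)) {
    # subjects with failed connectivity estimates (NaN traits) are dropped
    traits <- traits[ok_subj, , drop = FALSE]
  }
  ids <- rownames(traits)
  ord <- match(ids, ped$id)
  if (anyNA(ord)) stop("trait subjects missing from pedigree")
  ped_sub <- ped[ord, , drop = FALSE]
  class(ped_sub) <- class(ped)
  kin <- build_kinship(ped_sub)
  house <- if (model == "ACE") build_household(ped_sub) else NULL
  design <- vc_design(kin, house, ped_sub$famid, model)
  adj <- adjust_covariates(traits, cov)
  adj <- apply(adj, 2, inverse_normal_transform)
  keys <- colnames(traits)
  st <- strsplit(keys, "->", fixed = TRUE)
  res <- vector("list", ncol(adj))
  for (j in seq_len(ncol(adj))) {
    full <- tryCatch(
      fit_variance_components(adj[, j], design = design),
      error = function(e) NULL)
    null <- tryCatch(
      fit_variance_components(adj[, j], design = design,
                              null_constraint = "no_genetic"),
      error = function(e) NULL)
    if (is.null(full) || is.null(null)) {
      res[[j]] <- data.frame(source = st[[j]][1], target = st[[j]][2],
                             model = model, h2 = NA_real_, c2 = NA_real_,
                             loglik = NA_real_, lrt = NA_real_, p = NA_real_,
                             q = NA_real_, significant = NA)
      next
    }
    lrt <- lrt_heritability(full, null$loglik)
    failed <- lrt$flag == "optimizer_failure"
    res[[j]] <- data.frame(
      source = st[[j]][1], target = st[[j]][2], model = model,
      h2 = full$h2, c2 = full$c2, loglik = full$loglik,
      lrt = lrt$statistic,
      p = if (failed) NA_real_ else lrt$p,
      q = NA_real_, significant = NA)
  }
  out <- do.call(rbind, res)
  ok <- !is.na(out$p)
  if (any(ok)) {
    fdr <- fdr_bh(out$p[ok], alpha)
    out$q[ok] <- fdr$q
    out$significant[ok] <- fdr$significant
  }
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Discovery/replication overlap of significant connections
#'
#' Counts connections significant in the discovery scan, in the replication
#' scan, and in both, and reports the replication percentage
#' `100 * both / discovery` (rounded to the nearest integer).
#'
#' @param scanA,scanB results of [heritability_scan()] on the two cohorts
#'   (same connection keys).
#' @return data frame `n_discovery,n_replication,n_both,pct_of_discovery`.
#' @export
replication_overlap <- function(scanA, scanB) {
  keyA <- paste0(scanA$source, "->", scanA$target)
  keyB <- paste0(scanB$source, "->", scanB$target)
  if (!setequal(keyA, keyB) || length(keyA) != length(keyB)) {
    stop("discovery and replication scans cover different connections")
  }
  sa <- keyA[which(scanA$significant)]
  sb <- keyB[which(scanB$significant)]
  nb <- length(intersect(sa, sb))
  data.frame(
    n_discovery = length(sa), n_replication = length(sb), n_both = nb,
    pct_of_discovery = if (length(sa)) round(100 * nb / length(sa)) else 0)
}
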