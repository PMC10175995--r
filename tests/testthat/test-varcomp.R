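test_that("covariate adjustment produces orthogonal residuals", {
  set.seed(51)
  n <- 40
  cov <- data.frame(id = sprintf("s%02d", 1:n),
                    age = rnorm(n, 29, 3), sex = sample(1:2, n, TRUE),
                    handedness = sample(c(1, 1, 1, 2), n, TRUE),
                    education = rnorm(n, 15, 2))
  traits <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(cov$id, c("a", "b", "c")))
  res <- adjust_covariates(traits, cov)
  X <- cbind(1, cov$age, as.numeric(factor(cov$sex)),
             as.numeric(factor(cov$handedness)), cov$education)
  expect_lt(max(abs(crossprod(X, res))), 1e-8)

  # a trait exactly linear in age residualizes to zero
  lin <- matrix(3 + 2 * cov$age, n, 1, dimnames = list(cov$id, "lin"))
  expect_lt(max(abs(adjust_covariates(lin, cov))), 1e-8)

  # constant covariates leave the trait mean-centred but otherwise intact
  cc <- transform(cov, age = 30, sex = 1, handedness = 1, education = 15)
  res2 <- adjust_covariates(traits, cc)
  expect_equal(res2, scale(traits, scale = FALSE), ignore_attr = TRUE)
})

test_that("3-subject adjustment matches closed-form normal equations", {
  cov <- data.frame(id = c("a", "b", "c"), age = c(20, 25, 33), sex = 1,
                    handedness = 1, education = 15)
  y <- matrix(c(1, 4, 2), 3, 1, dimnames = list(cov$id, "t"))
  X <- cbind(1, cov$age)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(as.numeric(adjust_covariates(y, cov)),
               as.numeric(y - X %*% beta), tolerance = 1e-12)
})

test_that("inverse normal transform yields Blom scores", {
  v <- c(3.2, -1, 0.5, 10, 7)                 # n = 5, distinct
  z <- inverse_normal_transform(v)
  r <- rank(v)
  expect_equal(z, qnorm((r - 3 / 8) / (5 + 1 / 4)), tolerance = 1e-12)
  # middle value of an odd-length vector maps to zero
  expect_equal(z[r == 3], 0)
  # invariance under strictly monotone transformations
  expect_equal(inverse_normal_transform(exp(v)), z)
  expect_error(inverse_normal_transform(rep(1, 10)), "identical")
  expect_error(inverse_normal_transform(c(1, 2)), "n >= 3")
})

test_that("blockwise likelihood equals the dense MVN oracle", {
  for (seed in 1:8) {
    ped <- random_pedigree(n_fam = 4, seed = 60 + seed)  # <= 12 members
    if (nrow(ped) > 12) next
    kin <- build_kinship(ped); hh <- build_household(ped)
    set.seed(seed)
    y <- as.numeric(rnorm(nrow(ped)))
    for (model in c("AE", "ACE")) {
      des <- vc_design(kin, if (model == "ACE") hh else NULL, ped$famid,
                       model, grid_step = 0.05)
      Z <- gcherit:::vc_stack(des, y - mean(y))
      for (theta in list(c(0.3, 0), c(0.6, 0.2), c(0, 0.4))) {
        if (model == "AE" && theta[2] != 0) next
        M <- theta[1] * kin + (1 - theta[1] - theta[2]) * diag(nrow(ped)) +
          theta[2] * hh
        ll_block <- gcherit:::vc_ll_at(des, Z, theta[1], theta[2])
        ll_dense <- dense_profile_loglik(y - mean(y), M)
        expect_equal(ll_block, ll_dense, tolerance = 1e-8)
      }
    }
  }
})

test_that("a single family's likelihood matches the dense density", {
  ped <- pedigree(c("a", "b", "c"), rep("f", 3),
                  group = c("MZ", "MZ", "SIB"),
                  twinpair = c("t", "t", NA))
  kin <- build_kinship(ped)
  y <- c(0.4, 0.6, -0.2)
  des <- vc_design(kin, NULL, ped$famid, "AE")
  fit <- fit_variance_components(y, design = des)
  M <- fit$h2 * kin + (1 - fit$h2) * diag(3)
  expect_equal(fit$loglik, dense_profile_loglik(y - mean(y), M),
               tolerance = 1e-8)
})

test_that("all-singleton pedigrees are flagged unidentifiable", {
  ped <- pedigree(sprintf("s%d", 1:30), sprintf("f%d", 1:30),
                  group = rep("SINGLETON", 30))
  kin <- build_kinship(ped)
  set.seed(52)
  fit <- fit_variance_components(rnorm(30), kin = kin, famid = ped$famid,
                                 model = "AE")
  expect_equal(fit$flag, "unidentifiable")
  expect_equal(fit$h2, 0)
})

test_that("AE heritability is recovered on a twin cohort", {
  cfg <- sim_config(n_mz_pairs = 100, n_dz_pairs = 100,
                    sib_sizes = integer(0), n_singletons = 0,
                    n_networks = 6, h2 = 0.4, c2 = 0, seed = 53)
  pc <- simulate_pedigree(cfg)
  tr <- simulate_ace_traits(pc$ped, cfg)   # 400 subjects x 30 traits
  des <- vc_design(build_kinship(pc$ped), NULL, pc$ped$famid, "AE")
  h2s <- apply(tr, 2, function(y)
    fit_variance_components(y, design = des)$h2)
  expect_lt(abs(mean(h2s) - 0.4), 0.05)
})

test_that("ACE fits on AE-generated data leave little shared variance", {
  cfg <- sim_config(n_mz_pairs = 60, n_dz_pairs = 40,
                    sib_sizes = sib_sizes_for(100), n_singletons = 0,
                    n_networks = 6, h2 = 0.5, c2 = 0, seed = 54)
  pc <- simulate_pedigree(cfg)
  tr <- simulate_ace_traits(pc$ped, cfg)[, 1:25]
  des <- vc_design(build_kinship(pc$ped), build_household(pc$ped),
                   pc$ped$famid, "ACE")
  c2s <- apply(tr, 2, function(y)
    fit_variance_components(y, design = des)$c2)
  expect_lte(mean(c2s), 0.05)
})

test_that("boundary-corrected LRT follows the mixture null", {
  # Lambda = 0 sits at the boundary mass
  expect_equal(lrt_heritability(list(loglik = 5), 5)$p, 0.5)
  # Lambda = 2.706 is the classical one-sided 5% point
  l <- lrt_heritability(structure(list(loglik = 1.353), class = "varcomp"),
                        0)
  expect_equal(l$statistic, 2.706)
  expect_equal(l$p, 0.5 * pchisq(2.706, 1, lower.tail = FALSE))
  expect_equal(l$p, 0.05, tolerance = 1e-3)
  # monotone in the statistic
  p1 <- lrt_heritability(list(loglik = 3), 0)$p
  p2 <- lrt_heritability(list(loglik = 1), 0)$p
  expect_lt(p1, p2)
  # an optimizer failure is flagged, not silently clipped
  expect_equal(lrt_heritability(list(loglik = 0), 1)$flag,
               "optimizer_failure")
})

test_that("BH correction matches the exhaustive step-up oracle", {
  got <- fdr_bh(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(got$significant, bh_oracle_flags(c(0.01, 0.02, 0.03, 0.5),
                                                0.05))
  set.seed(55)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    a <- runif(1, 0.01, 0.2)
    got <- fdr_bh(p, a)
    expect_equal(got$significant, bh_oracle_flags(p, a))
    expect_equal(got$q, p.adjust(p, "BH"))
    expect_true(all(got$q >= p - 1e-12))         # q never below p
    ord <- order(p)
    expect_true(all(diff(got$q[ord]) >= -1e-12)) # monotone after step-up
  }
  # step-up accepts everything at p = alpha / 2
  expect_true(all(fdr_bh(rep(0.025, 7), 0.05)$significant))
  # single p below alpha
  one <- fdr_bh(0.04, 0.05)
  expect_true(one$significant)
  expect_equal(one$q, 0.04)
  expect_length(fdr_bh(numeric(0))$q, 0)
})

test_that("heritability scan controls type-I error on null traits", {
  cfg <- sim_config(n_mz_pairs = 30, n_dz_pairs = 20,
                    sib_sizes = sib_sizes_for(60), n_singletons = 20,
                    n_networks = 5, h2 = 0, c2 = 0, seed = 56)
  pc <- simulate_pedigree(cfg)
  tr <- simulate_ace_traits(pc$ped, cfg)   # 20 null traits
  scan <- heritability_scan(tr, pc$ped, pc$cov, model = "AE")
  expect_equal(nrow(scan), 20)
  expect_lte(sum(scan$significant, na.rm = TRUE), 1)
})

test_that("heritability scan detects strongly heritable traits", {
  cfg <- sim_config(n_mz_pairs = 100, n_dz_pairs = 100,
                    sib_sizes = integer(0), n_singletons = 0,
                    n_networks = 5, h2 = 0.6, c2 = 0, seed = 57)
  pc <- simulate_pedigree(cfg)
  tr <- simulate_ace_traits(pc$ped, cfg)
  scan <- heritability_scan(tr, pc$ped, pc$cov, model = "AE")
  expect_gt(mean(scan$significant), 0.5)
  expect_true(all(scan$h2 >= 0 & scan$h2 <= 1))
  # empty trait table yields an empty result
  empty <- heritability_scan(tr[, 0, drop = FALSE], pc$ped, pc$cov)
  expect_equal(nrow(empty), 0)
})

test_that("replication overlap reproduces the published arithmetic", {
  mk <- function(n, sig) {
    data.frame(source = sprintf("n%03d", 1:n), target = "t",
               significant = seq_len(n) <= sig)
  }
  # AE analysis: 152 discovery-significant, 58 replicating -> 38%
  a <- mk(300, 152)
  b <- mk(300, 0)
  b$significant[c(1:58, 200:241)] <- TRUE   # 58 of them overlap discovery
  r <- replication_overlap(a, b)
  expect_equal(r$n_both, 58)
  expect_equal(r$pct_of_discovery, 38)
  # ACE analysis: 56 discovery-significant, 8 replicating -> 14%
  a2 <- mk(300, 56)
  b2 <- mk(300, 0); b2$significant[1:8] <- TRUE
  r2 <- replication_overlap(a2, b2)
  expect_equal(r2$n_both, 8)
  expect_equal(r2$pct_of_discovery, 14)
  # disjoint sets
  a3 <- mk(10, 5)
  b3 <- mk(10, 0); b3$significant[6:10] <- TRUE
  r3 <- replication_overlap(a3, b3)
  expect_equal(r3$n_both, 0)
  expect_equal(r3$pct_of_discovery, 0)
  expect_error(replication_overlap(a3, mk(8, 2)), "different connections")
})
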