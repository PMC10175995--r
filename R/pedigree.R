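#' Construct and validate a pedigree
#'
#' A pedigree records the family structure of a twin/sibling cohort: each
#' individual belongs to a family, carries a relatedness group label
#' (monozygotic twin \code{"MZ"}, dizygotic twin \code{"DZ"}, non-twin full
#' sibling \code{"SIB"}, or \code{"SINGLETON"}), optionally a twin-pair id
#' shared by exactly two co-twins, and a household id. By default the
#' household equals the family (cohorts such as the HCP provide no separate
#' household information); pass \code{hhid} to override.
#'
#' @param id character vector of unique individual ids.
#' @param famid character vector of family ids.
#' @param sex integer/character sex codes (stored as given).
#' @param group one of \code{"MZ"}, \code{"DZ"}, \code{"SIB"},
#'   \code{"SINGLETON"} per individual.
#' @param twinpair twin-pair id, \code{NA} for non-twins. Each non-missing
#'   value must occur exactly twice, within one family and one group.
#' @param hhid household id; defaults to \code{famid}.
#' @return An object of class \code{"pedigree_df"}: a data frame with columns
#'   \code{id, famid, sex, group, twinpair, hhid}.
#' @examples
#' ped <- pedigree(
#'   id = c("a", "b", "c"), famid = c("f1", "f1", "f2"),
#'   sex = c(1, 2, 1), group = c("MZ", "MZ", "SINGLETON"),
#'   twinpair = c("t1", "t1", NA)
#' )
#' build_kinship(ped)
#' @export
pedigree <- function(id, famid, sex = NA, group, twinpair = NA, hhid = famid) {
  id <- as.character(id)
  famid <- as.character(famid)
  group <- as.character(group)
  n <- length(id)
  stopifnot(length(famid) == n, length(group) == n)
  sex <- rep_len(sex, n)
  twinpair <- as.character(rep_len(twinpair, n))
  hhid <- as.character(rep_len(hhid, n))
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  bad <- setdiff(unique(group), c("MZ", "DZ", "SIB", "SINGLETON"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  if (any(group == "SINGLETON" & !is.na(twinpair))) {
    stop("singletons must not carry a twin-pair id")
  }
  tp <- twinpair[!is.na(twinpair)]
  if (length(tp)) {
    cnt <- table(tp)
    if (any(cnt != 2)) {
      stop("twin_pair_id must occur exactly twice: ",
           paste(names(cnt)[cnt != 2], collapse = ", "))
    }
    for (p in unique(tp)) {
      m <- which(twinpair == p & !is.na(twinpair))
      if (length(unique(famid[m])) != 1 || length(unique(group[m])) != 1) {
        stop("co-twins of pair ", p, " must share family id and group")
      }
      if (!group[m[1]] %in% c("MZ", "DZ")) {
        stop("twin pair ", p, " must have group MZ or DZ")
      }
    }
  }
  out <- data.frame(id = id, famid = famid, sex = sex, group = group,
                    twinpair = twinpair, hhid = hhid,
                    stringsAsFactors = FALSE)
  class(out) <- c("pedigree_df", "data.frame")
  out
}

#' @export
print.pedigree_df <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals in", length(unique(x$famid)),
      "families\n")
  print(table(group = x$group))
  invisible(x)
}

#' Read / write pedigree and covariate tables
#'
#' Plain CSV interchange. The pedigree file carries columns
#' `id,famid,sex,group,twinpair,hhid`; the covariate file carries
#' `id,age,sex,handedness,education`.
#'
#' @param path file path.
#' @return `read_pedigree` returns a validated [pedigree()] object;
#'   `read_covariates` a data frame with one row per individual.
#' @export
read_pedigree <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  need <- c("id", "famid", "sex", "group", "twinpair", "hhid")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("pedigree CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  tw <- d$twinpair
  tw[tw == ""] <- NA
  pedigree(d$id, d$famid, d$sex, d$group, tw, d$hhid)
}

#' @rdname read_pedigree
#' @param ped pedigree object.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$twinpair[is.na(out$twinpair)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_pedigree
#' @export
read_covariates <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "age", "sex", "handedness", "education")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("covariates CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(d[need])) stop("covariates contain missing values")
  d$id <- as.character(d$id)
  d
}

#' Kinship matrix from group labels
#'
#' Builds the matrix of doubled kinship coefficients 2*Phi used as the
#' genetic covariance structure of the polygenic model: 1 on the diagonal and
#' for MZ co-twins, 0.5 for DZ co-twins and full siblings within a family,
#' 0 between families. Cohorts consisting of twins, full siblings and
#' singletons need no genealogy beyond these labels.
#'
#' @param ped a [pedigree()] object.
#' @return symmetric n x n matrix with dimnames = individual ids.
#' @export
build_kinship <- function(ped) {
  stopifnot(inherits(ped, "pedigree_df"))
  n <- nrow(ped)
  K <- diag(1, n)
  dimnames(K) <- list(ped$id, ped$id)
  if (n < 2) return(K)
  for (f in unique(ped$famid)) {
    m <- which(ped$famid == f)
    if (length(m) < 2) next
    for (a in seq_along(m)[-length(m)]) {
      for (b in (a + 1):length(m)) {
        i <- m[a]; j <- m[b]
        mz <- !is.na(ped$twinpair[i]) && !is.na(ped$twinpair[j]) &&
          ped$twinpair[i] == ped$twinpair[j] && ped$group[i] == "MZ"
        K[i, j] <- K[j, i] <- if (mz) 1 else 0.5
      }
    }
  }
  K
}

#' Household-sharing matrix
#'
#' Binary structure matrix for the shared-environment (C) component: entry 1
#' iff two individuals share a household id (by default the family id),
#' 1 on the diagonal.
#'
#' @param ped a [pedigree()] object.
#' @return symmetric binary n x n matrix with dimnames = individual ids.
#' @export
build_household <- function(ped) {
  stopifnot(inherits(ped, "pedigree_df"))
  H <- outer(ped$hhid, ped$hhid, "==") * 1
  dimnames(H) <- list(ped$id, ped$id)
  H
}

# standardized mean difference with pooled SD; 0 when both groups constant
std_diff <- function(x, y) {
  sp <- sqrt((stats::var(x) * (length(x) - 1) +
                stats::var(y) * (length(y) - 1)) /
               (length(x) + length(y) - 2))
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

# families described by their group-size composition, e.g. "MZ:2", "SIB:3"
family_class <- function(ped) {
  vapply(split(ped$group, ped$famid), function(g) {
    t <- table(g)
    paste(paste0(names(t), ":", t), collapse = "+")
  }, character(1))
}

split_balance <- function(ped, cov, idsA, idsB) {
  ca <- cov[match(idsA, cov$id), ]
  cb <- cov[match(idsB, cov$id), ]
  c(age = abs(std_diff(ca$age, cb$age)),
    education = abs(std_diff(ca$education, cb$education)),
    sex = abs(std_diff(as.numeric(factor(ca$sex, levels = sort(unique(cov$sex)))),
                       as.numeric(factor(cb$sex, levels = sort(unique(cov$sex)))))),
    handedness = abs(std_diff(
      as.numeric(factor(ca$handedness, levels = sort(unique(cov$handedness)))),
      as.numeric(factor(cb$handedness, levels = sort(unique(cov$handedness)))))))
}

#' Kinship-aware discovery/replication split
#'
#' Halves a cohort into two demographically matched sets without ever
#' splitting a family: families are grouped by their exact group-size
#' composition (e.g. one MZ pair, three siblings) and each composition class
#' is randomly halved, which guarantees identical MZ/DZ/sibling/singleton
#' counts on both sides. The randomization is restarted until the absolute
#' standardized mean difference of every covariate (age, education, and coded
#' sex/handedness) is at most \code{max_std_diff}; if no restart succeeds,
#' matched family pairs (one per side, same composition class) that
#' contribute most to the imbalance are excluded until the tolerance is met.
#'
#' @param ped a [pedigree()] object.
#' @param cov covariate data frame (`id,age,sex,handedness,education`).
#' @param seed integer; the split is deterministic given the seed.
#' @param max_std_diff balance tolerance on absolute standardized differences
#'   (default 0.05).
#' @param max_restarts randomization restarts before excluding families.
#' @return list with character vectors `A`, `B`, `excluded`, the achieved
#'   `balance` (named vector of absolute standardized differences) and
#'   `n_restarts` used.
#' @export
split_cohort <- function(ped, cov, seed = 1L, max_std_diff = 0.05,
                         max_restarts = 200L) {
  stopifnot(inherits(ped, "pedigree_df"))
  if (anyNA(match(ped$id, cov$id))) stop("covariates missing for some ids")
  fc <- family_class(ped)
  cls <- split(names(fc), unname(fc))
  odd <- vapply(cls, function(f) length(f) %% 2L == 1L, logical(1))
  if (any(odd)) {
    stop("infeasible composition: odd number of families of class ",
         paste(names(cls)[odd], collapse = ", "))
  }
  fam_ids <- split(ped$id, ped$famid)
  one_split <- function() {
    A <- character(0); B <- character(0)
    famA <- character(0); famB <- character(0)
    for (f in cls) {
      f <- sample(f)
      h <- length(f) / 2
      famA <- c(famA, f[seq_len(h)])
      famB <- c(famB, f[h + seq_len(h)])
    }
    list(A = unlist(fam_ids[famA], use.names = FALSE),
         B = unlist(fam_ids[famB], use.names = FALSE),
         famA = famA, famB = famB)
  }
  old <- .Random.seed_safe()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  best <- NULL; best_score <- Inf; used <- 0L
  for (r in seq_len(max(1L, max_restarts))) {
    used <- r
    s <- one_split()
    bal <- split_balance(ped, cov, s$A, s$B)
    if (max(bal) < best_score) {
      best <- s; best_score <- max(bal)
    }
    if (best_score <= max_std_diff) break
  }
  s <- best
  excluded <- character(0)
  bal <- split_balance(ped, cov, s$A, s$B)
  # exclusion loop: drop the matched family pair whose removal improves the
  # worst covariate difference the most, keeping group counts identical
  while (max(bal) > max_std_diff &&
         length(s$famA) > 2) {
    cand <- NULL; cand_score <- max(bal)
    for (k in seq_along(s$famA)) {
      ka <- s$famA[k]
      # drop with a same-class partner on side B
      partners <- which(fc[s$famB] == fc[ka])
      for (kb in partners) {
        A2 <- setdiff(s$A, fam_ids[[ka]])
        B2 <- setdiff(s$B, fam_ids[[s$famB[kb]]])
        sc <- max(split_balance(ped, cov, A2, B2))
        if (sc < cand_score) {
          cand <- c(k, kb); cand_score <- sc
        }
      }
    }
    if (is.null(cand)) break
    excluded <- c(excluded, fam_ids[[s$famA[cand[1]]]],
                  fam_ids[[s$famB[cand[2]]]])
    s$A <- setdiff(s$A, fam_ids[[s$famA[cand[1]]]])
    s$B <- setdiff(s$B, fam_ids[[s$famB[cand[2]]]])
    s$famA <- s$famA[-cand[1]]
    s$famB <- s$famB[-cand[2]]
    bal <- split_balance(ped, cov, s$A, s$B)
  }
  list(A = sort(s$A), B = sort(s$B), excluded = sort(excluded),
       balance = bal, n_restarts = used)
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Covariate balance report for a two-way split
#'
#' One row per covariate: absolute standardized mean difference (pooled SD)
#' and a two-sample test p-value (Welch t for continuous age/education,
#' chi-square for categorical sex/handedness), followed by group-composition
#' rows counting individuals per relatedness group on each side.
#'
#' @param A,B character vectors of individual ids (disjoint, non-empty).
#' @param cov covariate data frame.
#' @param ped optional [pedigree()] for the composition rows.
#' @return data frame with columns
#'   `variable, type, n_A, n_B, std_diff, statistic, p`.
#' @export
balance_report <- function(A, B, cov, ped = NULL) {
  if (!length(A) || !length(B)) stop("both sets must be non-empty")
  if (length(intersect(A, B))) stop("sets A and B overlap")
  ca <- cov[match(A, cov$id), ]
  cb <- cov[match(B, cov$id), ]
  rows <- list()
  for (v in c("age", "education")) {
    x <- ca[[v]]; y <- cb[[v]]
    tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
    rows[[v]] <- data.frame(
      variable = v, type = "continuous", n_A = length(x), n_B = length(y),
      std_diff = abs(std_diff(x, y)),
      statistic = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) 1 else tt$p.value)
  }
  for (v in c("sex", "handedness")) {
    tab <- rbind(table(factor(ca[[v]], levels = sort(unique(cov[[v]])))),
                 table(factor(cb[[v]], levels = sort(unique(cov[[v]])))))
    keep <- colSums(tab) > 0
    tab <- tab[, keep, drop = FALSE]
    ct <- if (ncol(tab) > 1)
      suppressWarnings(stats::chisq.test(tab)) else NULL
    rows[[v]] <- data.frame(
      variable = v, type = "categorical", n_A = length(A), n_B = length(B),
      std_diff = abs(std_diff(
        as.numeric(factor(ca[[v]], levels = sort(unique(cov[[v]])))),
        as.numeric(factor(cb[[v]], levels = sort(unique(cov[[v]])))))),
      statistic = if (is.null(ct)) NA_real_ else unname(ct$statistic),
      p = if (is.null(ct)) 1 else ct$p.value)
  }
  out <- do.call(rbind, rows)
  if (!is.null(ped)) {
    ga <- table(factor(ped$group[match(A, ped$id)],
                       levels = c("MZ", "DZ", "SIB", "SINGLETON")))
    gb <- table(factor(ped$group[match(B, ped$id)],
                       levels = c("MZ", "DZ", "SIB", "SINGLETON")))
    comp <- data.frame(
      variable = paste0("n_", names(ga)), type = "composition",
      n_A = as.integer(ga), n_B = as.integer(gb),
      std_diff = NA_real_, statistic = NA_real_, p = NA_real_)
    out <- rbind(out, comp)
  }
  rownames(out) <- NULL
  out
}
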