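#' Per-stage child seeds
#'
#' Stage seeds are derived from the master seed as
#' `(master * 1009 + sum of the stage name's character codes) mod 2^31 - 1`,
#' so each stage is independently reproducible from the master seed and the
#' stage name alone.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
child_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 1009 +
                sum(utf8ToInt(stage))) %% (2^31 - 1))
}

#' Run configuration
#'
#' Everything a full run needs: mode, input paths (real mode), the synthetic
#' generator configuration, and the analysis switches.
#'
#' @param mode `"synthetic"` or `"real"`.
#' @param out_dir output directory (created if needed).
#' @param sim a [sim_config()] (synthetic mode).
#' @param manifest_path,pedigree_path,covariates_path input files (real
#'   mode).
#' @param deconvolve logical: blind HRF deconvolution before connectivity?
#' @param gc_order VAR order or `"aic"` / `"bic"`.
#' @param gc_p_max maximum order during selection.
#' @param gc_mode `"conditional"` or `"bivariate"`.
#' @param model heritability model, `"AE"` or `"ACE"`.
#' @param alpha FDR level.
#' @param max_std_diff split balance tolerance.
#' @param seed master seed.
#' @return `"run_config"` list.
#' @export
run_config <- function(mode = c("synthetic", "real"), out_dir,
                       sim = sim_config(),
                       manifest_path = NULL, pedigree_path = NULL,
                       covariates_path = NULL,
                       deconvolve = TRUE, gc_order = 1, gc_p_max = 20L,
                       gc_mode = "conditional", model = "AE",
                       alpha = 0.05, max_std_diff = 0.05, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(alpha > 0, alpha < 1)
  if (mode == "real") {
    for (p in c(manifest_path, pedigree_path, covariates_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("real mode requires existing input files; missing: ",
             if (is.null(p)) "(unset path)" else p)
      }
    }
  }
  structure(list(mode = mode, out_dir = out_dir, sim = sim,
                 manifest_path = manifest_path,
                 pedigree_path = pedigree_path,
                 covariates_path = covariates_path,
                 deconvolve = isTRUE(deconvolve), gc_order = gc_order,
                 gc_p_max = as.integer(gc_p_max), gc_mode = gc_mode,
                 model = model, alpha = alpha,
                 max_std_diff = max_std_diff, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a time-series set as delimited text plus a manifest
#'
#' One tab-separated file per subject and session (T rows x N columns, with
#' a header of node labels) and a `manifest.csv` with columns
#' `subject_id,session_id,timeseries_path,TR`.
#'
#' @param nts an `"nts_set"`.
#' @param dir output directory.
#' @return path of the manifest file.
#' @export
write_timeseries <- function(nts, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sid in names(nts$subjects)) {
    for (se in seq_along(nts$subjects[[sid]])) {
      f <- file.path(dir, sprintf("%s_sess%d.tsv", sid, se))
      utils::write.table(nts$subjects[[sid]][[se]], f, sep = "\t",
                         row.names = FALSE, col.names = TRUE, quote = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, session_id = se,
        timeseries_path = basename(f), TR = nts$TR)
    }
  }
  man <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(man, mp, row.names = FALSE, quote = FALSE)
  mp
}

#' Load a time-series set from a manifest
#'
#' Validates that every file is rectangular and numeric and that all
#' sessions share the same node count; each series is standardized
#' (zero mean, unit SD).
#'
#' @param manifest_path path to a manifest CSV
#'   (`subject_id,session_id,timeseries_path,TR`); relative series paths are
#'   resolved against the manifest's directory.
#' @return an `"nts_set"`.
#' @export
load_timeseries <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "timeseries_path", "TR")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  base <- dirname(manifest_path)
  subjects <- list()
  N <- NULL; labels <- NULL
  for (k in seq_len(nrow(man))) {
    f <- man$timeseries_path[k]
    if (!file.exists(f)) f <- file.path(base, man$timeseries_path[k])
    if (!file.exists(f)) stop("time-series file not found: ",
                              man$timeseries_path[k])
    raw <- utils::read.table(f, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE)
    M <- as.matrix(raw)
    num <- suppressWarnings(matrix(as.numeric(M), nrow(M), ncol(M)))
    if (anyNA(num)) {
      bad <- which(is.na(num), arr.ind = TRUE)[1, ]
      stop("non-numeric cell in ", basename(f), " at row ", bad[1],
           ", column ", bad[2])
    }
    if (is.null(N)) {
      N <- ncol(num); labels <- colnames(raw)
    } else if (ncol(num) != N) {
      stop("inconsistent node count in ", basename(f), ": ", ncol(num),
           " columns, expected ", N)
    }
    num <- apply(num, 2, function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x - mean(x)
    })
    colnames(num) <- labels
    sid <- as.character(man$subject_id[k])
    if (is.null(subjects[[sid]])) subjects[[sid]] <- list()
    subjects[[sid]][[man$session_id[k]]] <- num
  }
  structure(list(subjects = subjects, TR = man$TR[1],
                 labels = if (is.null(labels)) character(0) else labels),
            class = "nts_set")
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %-12s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the full analysis end to end
#'
#' Synthetic mode: simulate a pedigree with covariates, latent ACE coupling
#' traits and BOLD-like series, write them to disk, and continue as in real
#' mode. Real mode: load the manifest, pedigree and covariates. Then:
#' optional blind deconvolution, per-subject state-space Granger causality,
#' group aggregation, kinship-aware discovery/replication split, per-cohort
#' heritability scan with FDR, and the replication overlap. All outputs are
#' CSV/plain text under `cfg$out_dir`; a config snapshot (YAML) and a
#' structured log are written alongside. Reruns with the same configuration
#' and seed reproduce every output file byte for byte.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) list with the main in-memory results: `split`,
#'   `aggregate`, `scanA`, `scanB`, `replication`, `out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run.log")
  if (file.exists(log_path)) file.remove(log_path)
  snap <- cfg
  snap$sim <- unclass(snap$sim)
  snap$sim$edges <- if (!is.null(snap$sim$edges)) {
    apply(snap$sim$edges, 1, paste, collapse = "->")
  }
  yaml::write_yaml(unclass(snap), file.path(out, "config.yaml"))
  t0 <- Sys.time()
  stage_t <- function(stage, expr) {
    s <- Sys.time()
    r <- tryCatch(expr, error = function(e) {
      log_line(log_path, stage, paste("FAILED:", conditionMessage(e)))
      stop("stage '", stage, "' failed: ", conditionMessage(e))
    })
    log_line(log_path, stage,
             sprintf("done in %.1fs", as.numeric(Sys.time() - s, units = "secs")))
    r
  }
  if (cfg$mode == "synthetic") {
    sim <- cfg$sim
    sim$seed <- child_seed(cfg$seed, "simulate")
    class(sim) <- "sim_config"
    pc <- stage_t("simulate", {
      pc <- simulate_pedigree(sim)
      traits <- simulate_ace_traits(pc$ped, sim)
      nts <- generate_bold(pc$ped, traits, sim)
      write_pedigree(pc$ped, file.path(out, "pedigree.csv"))
      utils::write.csv(pc$cov, file.path(out, "covariates.csv"),
                       row.names = FALSE, quote = FALSE)
      write_timeseries(nts, file.path(out, "timeseries"))
      c(pc, list(nts = nts))
    })
    ped <- pc$ped; cov <- pc$cov; nts <- pc$nts
  } else {
    ped <- stage_t("load", read_pedigree(cfg$pedigree_path))
    cov <- read_covariates(cfg$covariates_path)
    nts <- stage_t("timeseries", load_timeseries(cfg$manifest_path))
    miss <- setdiff(ped$id, names(nts$subjects))
    if (length(miss)) stop("pedigree subjects missing from manifest: ",
                           paste(utils::head(miss, 5), collapse = ", "))
  }
  if (cfg$deconvolve) {
    dec <- stage_t("deconvolve", deconvolve_set(nts))
    nts <- dec$nts
    utils::write.csv(dec$hrf_table, file.path(out, "hrf_estimates.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  gcs <- stage_t("ssgc", {
    gdir <- file.path(out, "gc")
    dir.create(gdir, showWarnings = FALSE)
    gcs <- list()
    for (sid in names(nts$subjects)) {
      G <- gc_matrix(nts$subjects[[sid]], order = cfg$gc_order,
                     p_max = cfg$gc_p_max, mode = cfg$gc_mode,
                     labels = nts$labels)
      if (attr(G, "n_clipped") > 0 || attr(G, "n_failed") > 0 ||
          attr(G, "n_stabilized") > 0) {
        log_line(log_path, "ssgc",
                 sprintf("%s: %d clipped, %d failed sources, %d stabilized",
                         sid, attr(G, "n_clipped"), attr(G, "n_failed"),
                         attr(G, "n_stabilized")))
      }
      write_gc_matrix(G, file.path(gdir, paste0("gc_", sid, ".csv")))
      gcs[[sid]] <- G
    }
    gcs
  })
  agg <- stage_t("aggregate", {
    agg <- aggregate_connectome(gcs)
    utils::write.csv(as.data.frame(agg$median),
                     file.path(out, "gc_median.csv"), row.names = TRUE,
                     quote = FALSE)
    utils::write.csv(agg$upper_quartile,
                     file.path(out, "gc_upper_quartile.csv"),
                     row.names = FALSE, quote = FALSE)
    agg
  })
  sp <- stage_t("split", {
    sp <- split_cohort(ped, cov, seed = child_seed(cfg$seed, "split"),
                       max_std_diff = cfg$max_std_diff)
    writeLines(sp$A, file.path(out, "cohort_A_ids.txt"))
    writeLines(sp$B, file.path(out, "cohort_B_ids.txt"))
    utils::write.csv(balance_report(sp$A, sp$B, cov, ped),
                     file.path(out, "balance.csv"), row.names = FALSE,
                     quote = FALSE)
    sp
  })
  traits_all <- gc_trait_table(gcs)
  scans <- stage_t("heritability", {
    scans <- lapply(list(A = sp$A, B = sp$B), function(ids) {
      tr <- traits_all[intersect(rownames(traits_all), ids), , drop = FALSE]
      heritability_scan(tr, ped, cov, model = cfg$model, alpha = cfg$alpha)
    })
    utils::write.csv(scans$A, file.path(out, "heritability_discovery.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(scans$B, file.path(out, "heritability_replication.csv"),
                     row.names = FALSE, quote = FALSE)
    scans
  })
  repl <- stage_t("replicate", {
    repl <- replication_overlap(scans$A, scans$B)
    utils::write.csv(repl, file.path(out, "replication.csv"),
                     row.names = FALSE, quote = FALSE)
    repl
  })
  log_line(log_path, "run_all",
           sprintf("completed in %.1fs",
                   as.numeric(Sys.time() - t0, units = "secs")))
  invisible(list(split = sp, aggregate = agg, scanA = scans$A,
                 scanB = scans$B, replication = repl, out_dir = out))
}

#' Stack subject GC matrices into a trait table
#'
#' Rows = subjects, columns = the `N (N - 1)` directed connections keyed
#' `"src->tgt"`, i.e. each connection becomes one endophenotype trait.
#'
#' @param gcs named list of GC matrices (names = subject ids).
#' @return numeric matrix.
#' @export
gc_trait_table <- function(gcs) {
  stopifnot(length(gcs) >= 1)
  G1 <- gcs[[1]]
  N <- nrow(G1)
  labels <- rownames(G1)
  keep <- row(G1) != col(G1)
  keys <- paste0(labels[row(G1)[keep]], "->", labels[col(G1)[keep]])
  out <- t(vapply(gcs, function(G) G[keep], numeric(sum(keep))))
  colnames(out) <- keys
  rownames(out) <- names(gcs)
  out
}
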