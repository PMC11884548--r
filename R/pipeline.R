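#' Configuration for an end-to-end pipeline run
#'
#' Declarative configuration: stage toggles and the per-stage parameters,
#' each stochastic stage with an explicit seed derived from \code{seed}.
#'
#' @param spec a \code{\link{cohort_spec}} (ignored when \code{cohort_dir}
#'   is given).
#' @param cohort_dir optional directory with a serialized cohort to load
#'   instead of synthesizing one.
#' @param seed master seed.
#' @param stages character subset of
#'   \code{c("hurst", "compare", "netmap", "pmfm", "classify")}.
#' @param n_spin,n_rewired null-model iterations for the netmap stage.
#' @param k_percent,n_folds,clf_iterations classifier settings.
#' @param pmfm_iterations,pmfm_restarts,pmfm_splits,pmfm_settings
#'   mean-field fitting budget (the pmfm stage is costly; defaults are
#'   desk-scale).
#' @param out_dir optional directory; stage outputs are written as TSV/JSON.
#' @return list of class \code{run_config}.
#' @export
pipeline_config <- function(spec = cohort_spec(n_controls = 20L,
                                               n_patients = 20L,
                                               T_len = 512L),
                            cohort_dir = NULL, seed = 1L,
                            stages = c("hurst", "compare", "netmap",
                                       "classify"),
                            n_spin = 1000L, n_rewired = 200L,
                            k_percent = 10, n_folds = 4L,
                            clf_iterations = 50L,
                            pmfm_iterations = 10L, pmfm_restarts = 2L,
                            pmfm_splits = 1L,
                            pmfm_settings = sim_settings(n_tr = 200L,
                                                         window_length = 50L),
                            out_dir = NULL) {
  stages <- match.arg(stages, c("hurst", "compare", "netmap", "pmfm",
                                "classify"), several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order: cohort synthesis (or
#' loading), region-wise Hurst mapping, control-normalized ipsi/contra
#' group comparison, network spreading and epicenter mapping with nulls,
#' optional mean-field model fitting, and case-control classification.
#' Every stage seed is derived from the master seed, so a rerun with the
#' same configuration reproduces every number.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return object of class \code{run_report}: list of per-stage results
#'   and a \code{headline} vector of the key numbers.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  cohort <- if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
            else make_cohort(config$spec, seed = child_seed(seed, 1L))
  parc <- cohort$parcellation
  grp <- cohort_groups(cohort)
  report <- list(config = config, n_subjects = length(cohort$subjects))

  hurst_maps <- NULL
  if (any(c("hurst", "compare", "netmap", "classify") %in% config$stages)) {
    hurst_maps <- t(vapply(cohort$subjects, function(s) hurst_map(s$ts),
                           numeric(n_regions(parc))))
    report$hurst <- list(
      maps = hurst_maps,
      group_mean = c(control = mean(hurst_maps[grp == "control", ]),
                     patient = mean(hurst_maps[grp == "patient", ])))
  }

  comparison <- NULL
  if ("compare" %in% config$stages) {
    z <- zscore_to_controls(hurst_maps, grp == "control")
    focus <- vapply(cohort$subjects, `[[`, character(1), "focus_side")
    z_ipsi <- t(vapply(seq_len(nrow(z)), function(s)
      flip_to_ipsi(z[s, ], focus[s], parc), numeric(ncol(z))))
    cov <- cohort_covariates(cohort)[, c("age", "sex")]
    comparison <- compare_regions(z_ipsi, grp, cov)
    subj_mean <- rowMeans(hurst_maps)
    pooled <- sqrt(((sum(grp == "patient") - 1) * var(subj_mean[grp == "patient"]) +
                    (sum(grp == "control") - 1) * var(subj_mean[grp == "control"])) /
                   (length(grp) - 2))
    global_d <- (mean(subj_mean[grp == "patient"]) -
                 mean(subj_mean[grp == "control"])) / pooled
    nets <- network_means(z_ipsi, parc$community, grp)
    report$compare <- list(comparison = comparison, global_cohens_d = global_d,
                           network = nets)
  }

  if ("netmap" %in% config$stages) {
    if (is.null(comparison)) stop("netmap stage requires the compare stage")
    d_map <- comparison$cohens_d
    sc <- cohort$connectome$sc
    spin <- spin_pvalue(map_a = d_map,
                        map_b = neighbor_alteration(d_map, sc),
                        parc = parc, n = config$n_spin,
                        seed = child_seed(seed, 3L))
    rewired <- rewired_pvalue(d_map = d_map, sc = sc,
                              dist = cohort$connectome$dist,
                              n_null = config$n_rewired,
                              seed = child_seed(seed, 4L))
    epi <- epicenter_likelihood(d_map, sc)
    report$netmap <- list(spin = spin, rewired = rewired, epicenter = epi)
  }

  if ("pmfm" %in% config$stages) {
    fc_by_group <- function(which_grp, idx) {
      subs <- cohort$subjects[grp == which_grp][idx]
      list(sc = cohort$connectome$sc,
           myelin = cohort$maps$myelin, gradient = cohort$maps$gradient,
           fc_emp = group_fc(lapply(subs, function(s) static_fc(s$ts))),
           fcd_cdf_emp = group_fcd_cdf(lapply(subs, function(s)
             fcd_cdf(sliding_window_fcd(
               s$ts, config$pmfm_settings$window_length)))))
    }
    n_ctrl <- sum(grp == "control")
    splits <- lapply(seq_len(config$pmfm_splits), function(sp) {
      idx <- with_seed(child_seed(seed, 50L + sp), sample(n_ctrl))
      thirds <- split(idx, cut(seq_along(idx), 3L, labels = FALSE))
      list(train = fc_by_group("control", thirds[[1L]]),
           val = fc_by_group("control", thirds[[2L]]),
           test = fc_by_group("control", thirds[[3L]]))
    })
    report$pmfm <- pmfm_fit(splits, settings = config$pmfm_settings,
                            n_iterations = config$pmfm_iterations,
                            n_restarts = config$pmfm_restarts,
                            seed = child_seed(seed, 5L))
  }

  if ("classify" %in% config$stages) {
    report$classify <- crossval_classify(
      hurst_maps, grp, k_percent = config$k_percent,
      n_folds = config$n_folds, n_iterations = config$clf_iterations,
      seed = child_seed(seed, 6L))
  }

  headline <- c(
    if (!is.null(report$hurst))
      c(mean_H_control = unname(report$hurst$group_mean["control"]),
        mean_H_patient = unname(report$hurst$group_mean["patient"])),
    if (!is.null(report$compare))
      c(global_cohens_d = report$compare$global_cohens_d,
        n_significant = sum(report$compare$comparison$significant)),
    if (!is.null(report$netmap))
      c(spin_p = report$netmap$spin$p, rewired_p = report$netmap$rewired$p),
    if (!is.null(report$pmfm))
      c(pmfm_test_cost = mean(vapply(report$pmfm$per_split, `[[`,
                                     numeric(1), "cost"))),
    if (!is.null(report$classify))
      c(accuracy = unname(report$classify$accuracy_summary["mean"]),
        auc = unname(report$classify$auc_summary["mean"])))
  report$headline <- headline
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run report\n")
  for (nm in names(x$headline))
    cat(sprintf("  %-18s %.4f\n", nm, x$headline[nm]))
  invisible(x)
}

#' Write a pipeline report's tabular outputs
#'
#' Writes the Hurst map matrix, the region comparison table, the network
#' table, the epicenter table (TSV) and the headline numbers (JSON when
#' jsonlite is available, TSV otherwise).
#'
#' @param report a \code{run_report}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file) write.table(x, file.path(dir, file), sep = "\t",
                                      quote = FALSE, row.names = FALSE)
  if (!is.null(report$hurst)) wt(report$hurst$maps, "hurst_maps.tsv")
  if (!is.null(report$compare)) {
    wt(report$compare$comparison, "comparison.tsv")
    wt(report$compare$network, "network_means.tsv")
  }
  if (!is.null(report$netmap)) wt(report$netmap$epicenter, "epicenter.tsv")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(as.list(report$headline),
                         file.path(dir, "headline.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    wt(data.frame(metric = names(report$headline),
                  value = unname(report$headline)), "headline.tsv")
  }
  invisible(dir)
}
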