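#' Specification for a synthetic case-control cohort
#'
#' Collects the generating parameters of a synthetic cohort emulating a
#' case-control resting-state study: bilateral parcellation, distance-
#' dependent structural connectome, smooth annotation maps, and per-region
#' fractional Gaussian noise whose Hurst exponent is reduced by
#' \code{delta_h} in a designated affected-region set in patients (full
#' effect in the focus hemisphere, \code{contra_scale} of it in homotopic
#' partners). Defaults mirror a typical discovery design: 40 controls and
#' 40 patients, 695 time points per region, control ages 28-44 and patient
#' ages 18-63 years, 50/50 sex and focus-side sampling.
#'
#' @param n_controls,n_patients group sizes.
#' @param n_regions even number of regions (default 68, a desk-scale
#'   bilateral parcellation).
#' @param n_communities network labels (default 6).
#' @param T_len time points per series (default 695).
#' @param h_base baseline Hurst level (default 0.75); the regional baseline
#'   map is \code{h_base + h_range * myelin-like gradient}, so healthy H
#'   follows the cortical hierarchy.
#' @param h_range amplitude of the smooth regional variation (default 0.04).
#' @param delta_h Hurst reduction in affected regions of patients
#'   (default 0.06, a medium-to-large effect at this series length). Use 0
#'   for a null cohort.
#' @param affected integer vector of affected region indices (1-based),
#'   interpreted as the left-hemisphere ("focus = L") pattern; NULL picks
#'   one full community in the left hemisphere.
#' @param contra_scale fraction of \code{delta_h} applied to homotopic
#'   partners (default 0.5).
#' @param cog_slope,cog_noise cognitive score = \code{cog_slope} x subject
#'   mean true H + Gaussian noise with SD \code{cog_noise}.
#' @param density,decay_length,smoothness connectome and annotation-map
#'   parameters (see \code{\link{make_connectome}},
#'   \code{\link{make_annotation_maps}}).
#' @return list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_controls = 40L, n_patients = 40L, n_regions = 68L,
                        n_communities = 6L, T_len = 695L,
                        h_base = 0.75, h_range = 0.04, delta_h = 0.06,
                        affected = NULL, contra_scale = 0.5,
                        cog_slope = 20, cog_noise = 0.5,
                        density = 0.3, decay_length = 0.75, smoothness = 3) {
  check_scalar(h_base, "h_base", lower = 0.05, upper = 0.95)
  check_scalar(delta_h, "delta_h", lower = 0, upper = h_base - 0.05)
  check_scalar(contra_scale, "contra_scale", lower = 0, upper = 1)
  if (T_len < 128L) stop_bad_arg("'T_len' must be >= 128 for Hurst estimation")
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic case-control cohort
#'
#' Controls draw independent fGn per region at the baseline Hurst map;
#' patients draw fGn with H reduced by \code{delta_h} in the affected set of
#' their (randomized) focus hemisphere and by \code{contra_scale * delta_h}
#' in the homotopic partners. The generating truth (per-group H maps,
#' affected set, effect size) is recorded in the returned object.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @param seed integer seed; generation is bit-reproducible.
#' @return object of class \code{cohort}: list with \code{parcellation},
#'   \code{connectome}, \code{maps} (myelin/gradient), \code{subjects}
#'   (list of records with \code{subject_id}, \code{group},
#'   \code{focus_side}, \code{age}, \code{sex}, \code{ts},
#'   \code{cognition}), and \code{truth}.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  parc <- make_geometry(spec$n_regions, spec$n_communities,
                        seed = child_seed(seed, 1L))
  conn <- make_connectome(parc, spec$density, spec$decay_length,
                          seed = child_seed(seed, 2L))
  maps <- make_annotation_maps(parc, spec$smoothness,
                               seed = child_seed(seed, 3L))
  N <- spec$n_regions
  affected <- spec$affected
  if (is.null(affected)) {
    left <- which(parc$hemisphere == "L")
    comm <- parc$community[left][1L]
    affected <- left[parc$community[left] == comm]
  }
  affected <- as.integer(affected)
  if (any(affected < 1L | affected > N))
    stop_bad_arg(sprintf("affected regions must be in [1, %d]", N))
  h_ctrl <- spec$h_base + spec$h_range * maps$myelin
  h_ctrl <- pmin(pmax(h_ctrl, 0.1), 0.95)
  effect <- numeric(N)
  effect[affected] <- spec$delta_h
  effect[parc$pair[affected]] <- pmax(effect[parc$pair[affected]],
                                      spec$contra_scale * spec$delta_h)
  h_pat_L <- pmax(h_ctrl - effect, 0.05)     # focus-left patient H map
  mirror_map <- function(m) m[parc$pair]

  n_total <- spec$n_controls + spec$n_patients
  subjects <- vector("list", n_total)
  with_seed(seed, {
    group <- rep(c("control", "patient"), c(spec$n_controls, spec$n_patients))
    sexes <- ifelse(rbinom(n_total, 1L, 0.5) == 1L, "M", "F")
    ages <- ifelse(group == "control",
                   runif(n_total, 28, 44), runif(n_total, 18, 63))
    focus <- ifelse(group == "control", "none",
                    ifelse(rbinom(n_total, 1L, 0.5) == 1L, "L", "R"))
    for (s in seq_len(n_total)) {
      h_map <- if (group[s] == "control") h_ctrl
               else if (focus[s] == "L") h_pat_L
               else mirror_map(h_pat_L)
      ts <- vapply(seq_len(N), function(i)
        simulate_fgn(h_map[i], spec$T_len, sigma2 = 1, seed = NULL),
        numeric(spec$T_len))
      colnames(ts) <- parc$region_id
      cognition <- spec$cog_slope * mean(h_map) + rnorm(1L, sd = spec$cog_noise)
      subjects[[s]] <- list(
        subject_id = sprintf("sub-%03d", s), group = group[s],
        focus_side = focus[s], age = ages[s], sex = sexes[s],
        ts = ts, cognition = c(score = cognition))
    }
  })
  structure(list(
    parcellation = parc, connectome = conn, maps = maps, subjects = subjects,
    truth = list(h_control = h_ctrl, h_patient_focusL = h_pat_L,
                 affected = affected, delta_h = spec$delta_h,
                 contra_scale = spec$contra_scale, spec = spec, seed = seed)
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  grp <- vapply(x$subjects, `[[`, character(1), "group")
  cat(sprintf(
    "synthetic cohort: %d controls + %d patients, %d regions, T = %d\n",
    sum(grp == "control"), sum(grp == "patient"),
    length(x$parcellation$region_id), nrow(x$subjects[[1L]]$ts)))
  if (!is.null(x$truth))
    cat(sprintf("  truth: delta_h = %.3g in %d regions\n",
                x$truth$delta_h, length(x$truth$affected)))
  invisible(x)
}

cohort_groups <- function(cohort) {
  vapply(cohort$subjects, `[[`, character(1), "group")
}

cohort_covariates <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    group = cohort_groups(cohort),
    focus_side = vapply(cohort$subjects, `[[`, character(1), "focus_side"),
    age = vapply(cohort$subjects, `[[`, numeric(1), "age"),
    sex = vapply(cohort$subjects, `[[`, character(1), "sex"),
    stringsAsFactors = FALSE)
}

#' Write a cohort to a directory of tab-delimited files
#'
#' One \code{<subject_id>.tsv} per subject (T rows x N columns, header =
#' region ids), \code{subjects.tsv} (covariates and cognition),
#' \code{connectome.tsv} / \code{dist.tsv} (N x N), \code{parcellation.tsv}
#' (region_id, hemisphere, x, y, z, community), \code{maps.tsv}, and
#' \code{truth.json} when jsonlite is available.
#'
#' @param cohort a \code{cohort}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file, ...) write.table(
    x, file.path(dir, file), sep = "\t", quote = FALSE, row.names = FALSE, ...)
  parc <- cohort$parcellation
  wt(data.frame(region_id = parc$region_id, hemisphere = parc$hemisphere,
                x = parc$centroid[, 1], y = parc$centroid[, 2],
                z = parc$centroid[, 3], community = parc$community),
     "parcellation.tsv")
  wt(cohort$connectome$sc, "connectome.tsv", col.names = parc$region_id)
  wt(cohort$connectome$dist, "dist.tsv", col.names = parc$region_id)
  wt(data.frame(region_id = parc$region_id, myelin = cohort$maps$myelin,
                gradient = cohort$maps$gradient), "maps.tsv")
  cov <- cohort_covariates(cohort)
  cov$cognition <- vapply(cohort$subjects, function(s)
    unname(s$cognition["score"]), numeric(1))
  wt(cov, "subjects.tsv")
  for (s in cohort$subjects)
    wt(s$ts, paste0(s$subject_id, ".tsv"), col.names = parc$region_id)
  if (!is.null(cohort$truth) &&
      requireNamespace("jsonlite", quietly = TRUE)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(h_control = tr$h_control, h_patient_focusL = tr$h_patient_focusL,
           affected = tr$affected, delta_h = tr$delta_h,
           contra_scale = tr$contra_scale, seed = tr$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by \code{\link{write_cohort}}
#'
#' @param dir directory containing the cohort files.
#' @return a \code{cohort} (with \code{truth = NULL}; the stored truth is
#'   kept in \code{attr(, "truth_file")} if present).
#' @export
read_cohort <- function(dir) {
  need <- c("parcellation.tsv", "subjects.tsv", "connectome.tsv", "dist.tsv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop_bad_arg("cohort directory is missing: ", paste(missing, collapse = ", "))
  rd <- function(f, ...) read.delim(file.path(dir, f), sep = "\t",
                                    check.names = FALSE, ...)
  pt <- rd("parcellation.tsv")
  N <- nrow(pt)
  nh <- N %/% 2L
  parc <- structure(list(
    region_id = pt$region_id, hemisphere = pt$hemisphere,
    centroid = unname(as.matrix(pt[, c("x", "y", "z")])),
    community = pt$community,
    pair = c(seq_len(nh) + nh, seq_len(nh))), class = "parcellation")
  sc <- as.matrix(rd("connectome.tsv"))
  dimnames(sc) <- NULL
  dmat <- as.matrix(rd("dist.tsv"))
  dimnames(dmat) <- NULL
  conn <- structure(list(sc = sc, dist = dmat, fc = NULL),
                    class = "connectome")
  maps <- NULL
  if (file.exists(file.path(dir, "maps.tsv"))) {
    mt <- rd("maps.tsv")
    maps <- list(myelin = mt$myelin, gradient = mt$gradient)
  }
  cov <- rd("subjects.tsv")
  known <- c("subject_id", "group", "focus_side", "age", "sex")
  extra <- setdiff(names(cov), c(known, "cognition"))
  if (length(extra))
    warning("unknown column(s) in subjects.tsv carried through: ",
            paste(extra, collapse = ", "))
  T_ref <- NULL
  subjects <- lapply(seq_len(nrow(cov)), function(s) {
    f <- file.path(dir, paste0(cov$subject_id[s], ".tsv"))
    if (!file.exists(f)) stop_bad_arg("missing time-series file: ", f)
    ts <- as.matrix(rd(basename(f)))
    if (ncol(ts) != N)
      stop_bad_arg(sprintf("%s: expected %d columns, found %d",
                           basename(f), N, ncol(ts)))
    if (is.null(T_ref)) T_ref <<- nrow(ts)
    if (nrow(ts) != T_ref)
      stop_bad_arg(sprintf("%s: truncated at row %d (expected %d rows)",
                           basename(f), nrow(ts), T_ref))
    if (any(!is.finite(ts)))
      stop_bad_arg(sprintf("%s: non-numeric or missing entries",
                           basename(f)))
    cog <- if ("cognition" %in% names(cov)) c(score = cov$cognition[s]) else NULL
    list(subject_id = cov$subject_id[s], group = cov$group[s],
         focus_side = cov$focus_side[s], age = cov$age[s], sex = cov$sex[s],
         ts = ts, cognition = cog)
  })
  structure(list(parcellation = parc, connectome = conn, maps = maps,
                 subjects = subjects, truth = NULL), class = "cohort")
}
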