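#' Z-score regional maps relative to the control group
#'
#' Per region, z = (x - mean_ctrl) / sd_ctrl, applied to every subject
#' (controls included).
#'
#' @param maps S x N matrix of per-subject regional maps (all subjects).
#' @param control_rows indices (or logical) of control subjects; >= 3.
#' @return S x N matrix of z maps.
#' @export
zscore_to_controls <- function(maps, control_rows) {
  check_matrix(maps, "maps")
  ctrl <- maps[control_rows, , drop = FALSE]
  if (nrow(ctrl) < 3L) stop_bad_arg("need at least 3 controls")
  mu <- colMeans(ctrl)
  sdv <- apply(ctrl, 2L, sd)
  if (any(sdv == 0))
    stop_bad_arg(sprintf("zero control SD in region(s) %s",
                         paste(which(sdv == 0), collapse = ", ")))
  sweep(sweep(maps, 2L, mu), 2L, sdv, `/`)
}

#' Reorder a regional map so indices mean (ipsilateral, contralateral)
#'
#' Subjects with a right-sided focus have hemispheres swapped via the
#' parcellation's homotopic pairing; left-focus subjects and controls are
#' returned unchanged.
#'
#' @param map regional map (length N).
#' @param focus_side "L", "R", or "none".
#' @param parc a \code{parcellation} (provides \code{pair}).
#' @return reordered map.
#' @export
flip_to_ipsi <- function(map, focus_side, parc) {
  stopifnot(inherits(parc, "parcellation"))
  if (length(map) != length(parc$pair))
    stop_bad_arg("map length does not match parcellation")
  if (is.na(focus_side) || focus_side %in% c("L", "none")) return(map)
  if (focus_side != "R") stop_bad_arg("focus_side must be L, R or none")
  map[parc$pair]
}

#' Region-wise covariate-adjusted group comparison
#'
#' Per region, ordinary least squares of value ~ group + age + sex; the
#' group term's t and p (patients vs controls), Benjamini-Hochberg q-values
#' across regions, and Cohen's d computed from covariate-residualized
#' values (group means of residuals after removing age/sex, divided by the
#' pooled residual SD). Negative d means lower values in patients.
#'
#' @param maps S x N matrix of per-subject regional maps.
#' @param group character/factor of "control"/"patient" per subject.
#' @param covariates data.frame with numeric \code{age} and \code{sex}
#'   (coded or factor); may be NULL for an unadjusted comparison.
#' @param alpha FDR threshold for the significant set (default 0.05).
#' @return object of class \code{region_comparison}: data.frame with
#'   columns \code{region}, \code{t}, \code{p}, \code{q}, \code{cohens_d},
#'   \code{significant}, plus attributes \code{covariates} and
#'   \code{alpha}.
#' @export
compare_regions <- function(maps, group, covariates = NULL, alpha = 0.05) {
  check_matrix(maps, "maps")
  group <- factor(group, levels = c("control", "patient"))
  if (any(table(group) < 5L)) stop_bad_arg("both groups need >= 5 subjects")
  n <- nrow(maps)
  g <- as.numeric(group) - 1           # 0 control, 1 patient
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cv <- covariates
    if (!is.null(cv$sex) && !is.numeric(cv$sex))
      cv$sex <- as.numeric(factor(cv$sex)) - 1
    Xc <- as.matrix(data.frame(lapply(cv, as.numeric)))
    X <- cbind(X, Xc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop_bad_arg("rank-deficient design; collinear column(s): ",
                 paste(bad, collapse = ", "))
  }
  fit <- lm.fit(X, maps)
  df <- n - ncol(X)
  rss <- colSums(fit$residuals^2)
  XtXinv_gg <- chol2inv(qr.R(qrX))[2L, 2L]
  se <- sqrt(rss / df * XtXinv_gg)
  tstat <- fit$coefficients["group", ] / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  # Cohen's d on covariate-residualized values
  if (ncol(X) > 2L) {
    Xcov <- X[, -2L, drop = FALSE]
    res <- lm.fit(Xcov, maps)$residuals
  } else {
    res <- sweep(maps, 2L, colMeans(maps))
  }
  i_p <- which(g == 1)
  i_c <- which(g == 0)
  m_p <- colMeans(res[i_p, , drop = FALSE])
  m_c <- colMeans(res[i_c, , drop = FALSE])
  v_p <- apply(res[i_p, , drop = FALSE], 2L, var)
  v_c <- apply(res[i_c, , drop = FALSE], 2L, var)
  sp <- sqrt(((length(i_p) - 1) * v_p + (length(i_c) - 1) * v_c) /
               (length(i_p) + length(i_c) - 2))
  d <- ifelse(sp > 0, (m_p - m_c) / sp, 0)
  out <- data.frame(region = seq_len(ncol(maps)), t = unname(tstat),
                    p = unname(p), q = unname(q), cohens_d = unname(d),
                    significant = unname(q < alpha))
  structure(out, class = c("region_comparison", "data.frame"),
            covariates = if (is.null(covariates)) character(0)
                         else names(covariates),
            alpha = alpha, df = df)
}

#' @export
print.region_comparison <- function(x, ...) {
  cat(sprintf(
    "region-wise group comparison: %d regions, %d significant at q < %g\n",
    nrow(x), sum(x$significant), attr(x, "alpha")))
  cat(sprintf("  covariates: %s;  mean Cohen's d = %.3f\n",
              if (length(attr(x, "covariates")))
                paste(attr(x, "covariates"), collapse = ", ") else "none",
              mean(x$cohens_d)))
  invisible(x)
}

#' @export
summary.region_comparison <- function(object, ...) {
  sig <- object[object$significant, , drop = FALSE]
  cat(sprintf("%d / %d regions significant (q < %g)\n", nrow(sig),
              nrow(object), attr(object, "alpha")))
  if (nrow(sig)) {
    cat(sprintf("  significant-region Cohen's d: mean %.3f, range [%.3f, %.3f]\n",
                mean(sig$cohens_d), min(sig$cohens_d), max(sig$cohens_d)))
  }
  invisible(object)
}

#' Two-sample t statistic from summary data
#'
#' Welch form \code{t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2)}; identical to
#' the pooled-variance statistic when n1 = n2.
#'
#' @param m1,s1,n1 mean, SD, size of group 1.
#' @param m2,s2,n2 mean, SD, size of group 2.
#' @return the t statistic (signed).
#' @export
summary_ttest <- function(m1, s1, n1, m2, s2, n2) {
  if (s1 <= 0 || s2 <= 0) stop_bad_arg("SDs must be positive")
  if (n1 < 2 || n2 < 2) stop_bad_arg("group sizes must be >= 2")
  (m1 - m2) / sqrt(s1^2 / n1 + s2^2 / n2)
}

#' Pearson chi-square statistic for a 2 x 2 table
#'
#' Without continuity correction.
#'
#' @param table 2 x 2 matrix of nonnegative counts with positive margins.
#' @return the chi-square statistic.
#' @export
chisq_2x2 <- function(table) {
  check_matrix(table, "table", square = TRUE)
  if (nrow(table) != 2L || any(table < 0))
    stop_bad_arg("'table' must be 2 x 2 with nonnegative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop_bad_arg("all margins must be positive")
  n <- sum(table)
  num <- (table[1, 1] * table[2, 2] - table[1, 2] * table[2, 1])^2 * n
  num / prod(rowSums(table)) / prod(colSums(table)) * 1
}

#' Partial correlation controlling for covariates
#'
#' Correlation of the residuals of x and y after regressing each on the
#' covariates; t statistic with n - k - 2 degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates data.frame/matrix of covariates (may be NULL or
#'   zero-column for a plain Pearson correlation).
#' @param alternative "two.sided" (default), "less" or "greater".
#' @return named vector \code{c(r, t, p)}.
#' @export
partial_corr <- function(x, y, covariates = NULL,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(x)
  if (length(y) != n) stop_bad_arg("x and y lengths differ")
  k <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0L && NROW(covariates) == n) {
    Z <- as.matrix(data.frame(lapply(as.data.frame(covariates), function(v)
      if (is.numeric(v)) v else as.numeric(factor(v)))))
    k <- ncol(Z)
    X <- cbind(1, Z)
    x <- lm.fit(X, x)$residuals
    y <- lm.fit(X, y)$residuals
  } else {
    x <- x - mean(x)
    y <- y - mean(y)
  }
  if (n <= k + 2L) stop_bad_arg("need n > k + 2 observations")
  if (sd(x) == 0 || sd(y) == 0) stop_bad_arg("constant residuals")
  r <- cor(x, y)
  df <- n - k - 2L
  tt <- r * sqrt(df / max(1 - r^2, 1e-300))
  p <- switch(alternative,
              two.sided = 2 * pt(abs(tt), df, lower.tail = FALSE),
              greater = pt(tt, df, lower.tail = FALSE),
              less = pt(tt, df))
  c(r = r, t = tt, p = p)
}

#' Community-wise map means and group tests
#'
#' Per subject, the mean map value in each community; two-sample t-tests
#' between groups per community, Benjamini-Hochberg corrected across
#' communities.
#'
#' @param maps S x N matrix of per-subject maps.
#' @param community integer labels partitioning the N regions.
#' @param group "control"/"patient" per subject.
#' @return data.frame with \code{community}, \code{mean_control},
#'   \code{mean_patient}, \code{t}, \code{p}, \code{q}.
#' @export
network_means <- function(maps, community, group) {
  check_matrix(maps, "maps")
  if (length(community) != ncol(maps))
    stop_bad_arg("community labels must match the number of regions")
  comms <- sort(unique(community))
  if (any(table(factor(community, levels = comms)) == 0L))
    stop_bad_arg("empty community")
  group <- factor(group, levels = c("control", "patient"))
  subj_means <- vapply(comms, function(cm)
    rowMeans(maps[, community == cm, drop = FALSE]), numeric(nrow(maps)))
  res <- t(vapply(seq_along(comms), function(j) {
    a <- subj_means[group == "patient", j]
    b <- subj_means[group == "control", j]
    if (var(a) + var(b) < 1e-24) {
      tt <- list(statistic = 0, p.value = 1)      # identical constant means
    } else {
      tt <- t.test(a, b, var.equal = TRUE)
    }
    c(mean_control = mean(b), mean_patient = mean(a),
      t = unname(tt$statistic), p = tt$p.value)
  }, numeric(4)))
  data.frame(community = comms, res, q = p.adjust(res[, "p"], method = "BH"),
             row.names = NULL)
}

#' First-principal-component scores of a score matrix
#'
#' Columns are standardized, PCA computed, and the PC1 sign fixed so that
#' scores correlate positively with the column-mean composite.
#'
#' @param score_matrix n x k numeric matrix, n >= 3, no missing values.
#' @return list with \code{scores} (length n), \code{loadings} (length k),
#'   and \code{variance_explained} (fraction).
#' @export
pc1_scores <- function(score_matrix) {
  check_matrix(score_matrix, "score_matrix")
  if (nrow(score_matrix) < 3L) stop_bad_arg("need at least 3 subjects")
  if (any(!is.finite(score_matrix))) stop_bad_arg("missing values not allowed")
  sdv <- apply(score_matrix, 2L, sd)
  if (any(sdv == 0))
    stop_bad_arg(sprintf("zero-variance column(s): %s",
                         paste(which(sdv == 0), collapse = ", ")))
  Z <- scale(score_matrix)
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1L]
  loadings <- pc$rotation[, 1L]
  if (cor(scores, rowMeans(Z)) < 0) {
    scores <- -scores
    loadings <- -loadings
  }
  list(scores = unname(scores), loadings = unname(loadings),
       variance_explained = unname(pc$sdev[1L]^2 / sum(pc$sdev^2)))
}
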