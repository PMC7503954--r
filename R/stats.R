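#' One-sided normal critical value for activation thresholding
#'
#' The t-score threshold used for activation maps: the standard-normal
#' critical value at uncorrected significance \code{p} (0.05 gives 1.645,
#' i.e. the conventional +/-1.65 map threshold).
#'
#' @param p Uncorrected one-sided significance level.
#' @export
critical_t <- function(p = 0.05) stats::qnorm(1 - p)

#' Voxelwise GLM t-scores for a block design
#'
#' Ordinary least squares of each voxel's chromophore time course on the
#' expected response (task square wave convolved with the canonical HRF,
#' band-limited identically to the data when a filter band is given), with
#' intercept and linear-drift nuisance regressors. The flanking rest
#' minutes are excluded from the fit by default; within-task baseline
#' epochs (e.g. the SWG nonsense-symbol slides) remain as the implicit
#' baseline. Because band-pass filtering leaves far fewer independent
#' samples than time points, the effective degrees of freedom are taken as
#' \code{n * 2 * high / fs} (the number of independent samples a band of
#' width \code{high} supports), floored at 10; with unfiltered data the
#' classical residual dof is used.
#'
#' @param movie An \code{hb_movie}.
#' @param design The \code{task_design} of the recording.
#' @param hrf Optional \code{\link{canonical_hrf}} parameter overrides.
#' @param band Filter band \code{c(low, high)} the data were filtered with,
#'   or NULL for unfiltered data.
#' @param exclude_rest Drop the flanking rest minutes from the fit
#'   (default TRUE).
#' @return Object of class \code{glm_fit}: \code{beta} and \code{t_score}
#'   (voxel x chromophore matrices), \code{dof}, \code{regressor}, plus
#'   geometry fields for mapping.
#' @export
glm_tscores <- function(movie, design, hrf = list(), band = NULL,
                        exclude_rest = TRUE) {
  stopifnot(inherits(movie, "hb_movie"))
  fs <- movie$sampling_rate
  n <- ncol(movie$o2hb)
  indicator <- design_vector(design, n, fs)
  reg <- hrf_response(indicator, fs, peak = 1, hrf_params = hrf)
  if (!is.null(band)) {
    bw <- butter_bandpass_sos(4, band[1L], band[2L], fs)
    reg <- filtfilt_reflect(reg, bw, ceiling(3 * fs / band[1L]))
  }
  keep <- rep(TRUE, n)
  if (exclude_rest) {
    tt <- (seq_len(n) - 1) / fs
    ev <- design$event_table$events
    rests <- ev[ev$label == "rest", , drop = FALSE]
    for (i in seq_len(nrow(rests))) {
      keep[tt >= rests$onset[i] & tt < rests$onset[i] + rests$duration[i]] <- FALSE
    }
  }
  nk <- sum(keep)
  if (nk < 10L) stopf("fewer than 10 samples left for the GLM fit")
  x <- cbind(response = reg[keep], intercept = 1,
             drift = seq_len(nk) / nk - 0.5)
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) stopf("rank-deficient design matrix")
  xtx_inv <- chol2inv(qr.R(qrx))
  dof <- if (is.null(band)) nk - ncol(x) else max(10, nk * 2 * band[2L] / fs)

  fit_one <- function(y_mat) {
    y <- t(y_mat[, keep, drop = FALSE])          # samples x voxels
    beta <- qr.coef(qrx, y)
    resid <- y - x %*% beta
    rss <- colSums(resid^2)
    sigma2 <- rss / dof
    se <- sqrt(sigma2 * xtx_inv[1L, 1L])
    tval <- ifelse(se > 0, beta[1L, ] / se, 0)
    list(beta = beta[1L, ], t = tval, zerovar = se <= 0)
  }
  fo <- fit_one(movie$o2hb)
  fh <- fit_one(movie$hhb)
  structure(list(
    beta = cbind(o2hb = fo$beta, hhb = fh$beta),
    t_score = cbind(o2hb = fo$t, hhb = fh$t),
    zero_variance = cbind(o2hb = fo$zerovar, hhb = fh$zerovar),
    dof = dof, regressor = reg, samples_used = which(keep),
    mask = movie$mask, voxel_index = movie$voxel_index,
    grid_shape = movie$grid_shape, voxel_size = movie$voxel_size),
    class = "glm_fit")
}

#' Windowed-variability t-scores for unstructured tasks
#'
#' For tasks without a defined stimulation/rest alternation, activation is
#' inferred from the increase in hemodynamic signal variability: the
#' standard deviation of each chromophore is computed in non-overlapping
#' windows (default 10 s) of the pre-task rest minute and of the task
#' period, and the two SD populations are compared per voxel by a Welch
#' two-sample t statistic (task minus rest). The statistic is blind to the
#' response sign — exactly invariant to flipping the series sign — and is
#' interpreted one-sidedly (increased variability = activation).
#'
#' @param movie An \code{hb_movie}.
#' @param design The recording's \code{task_design}; rest windows are drawn
#'   from \code{design$baseline_window} only.
#' @param window Window length, s (default 10).
#' @return Object of class \code{variance_comparison}: \code{t_score}
#'   (voxel x chromophore), per-window SD arrays \code{rest_sds} /
#'   \code{task_sds} (window x voxel x chromophore), window counts, dof.
#' @export
variance_tscores <- function(movie, design, window = 10) {
  stopifnot(inherits(movie, "hb_movie"))
  fs <- movie$sampling_rate
  n <- ncol(movie$o2hb)
  wlen <- round(window * fs)

  windows_in <- function(start, end) {
    n_w <- floor((end - start) / window)
    if (n_w < 1L) return(NULL)
    starts <- start + window * (seq_len(n_w) - 1)
    cbind(round(starts * fs) + 1L, round(starts * fs) + wlen)
  }
  rest_w <- windows_in(design$baseline_window[1L], design$baseline_window[2L])
  task_w <- do.call(rbind, lapply(seq_len(nrow(stimulation_epochs(design))), function(i) {
    ep <- stimulation_epochs(design)[i, ]
    windows_in(ep$onset, ep$onset + ep$duration)
  }))
  if (is.null(rest_w) || nrow(rest_w) < 2L || is.null(task_w) || nrow(task_w) < 2L) {
    stopf("need at least 2 rest and 2 task windows of %g s", window)
  }
  if (max(rest_w, task_w) > n) stopf("windows extend past the movie")

  window_sds <- function(y, w) {
    t(apply(w, 1L, function(ab) {
      seg <- y[, ab[1L]:ab[2L], drop = FALSE]
      sqrt(rowSums((seg - rowMeans(seg))^2) / (ncol(seg) - 1L))
    }))  # windows x voxels
  }
  welch <- function(a, b) {  # a, b: windows x voxels; returns t (a - b) and dof
    na <- nrow(a); nb <- nrow(b)
    ma <- colMeans(a); mb <- colMeans(b)
    va <- colSums((a - rep(ma, each = na))^2) / (na - 1L)
    vb <- colSums((b - rep(mb, each = nb))^2) / (nb - 1L)
    se2 <- va / na + vb / nb
    tt <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
    dof <- ifelse(se2 > 0,
                  se2^2 / (va^2 / (na^2 * (na - 1L)) + vb^2 / (nb^2 * (nb - 1L))),
                  na + nb - 2L)
    list(t = tt, dof = dof)
  }
  res <- list()
  sds <- list()
  for (chrom in c("o2hb", "hhb")) {
    y <- movie[[chrom]]
    rsd <- window_sds(y, rest_w)
    tsd <- window_sds(y, task_w)
    res[[chrom]] <- welch(tsd, rsd)
    sds[[chrom]] <- list(rest = rsd, task = tsd)
  }
  structure(list(
    t_score = cbind(o2hb = res$o2hb$t, hhb = res$hhb$t),
    dof = cbind(o2hb = res$o2hb$dof, hhb = res$hhb$dof),
    rest_sds = lapply(sds, `[[`, "rest"), task_sds = lapply(sds, `[[`, "task"),
    n_rest = nrow(rest_w), n_task = nrow(task_w), window = window,
    mask = movie$mask, voxel_index = movie$voxel_index,
    grid_shape = movie$grid_shape, voxel_size = movie$voxel_size),
    class = "variance_comparison")
}

#' Threshold a t-score map
#'
#' Labels suprathreshold voxels at the conventional uncorrected +/-1.65
#' level: \eqn{|t| >} threshold for the (two-sided) GLM statistic, or
#' \eqn{t >} threshold for the one-sided variability statistic. No
#' multiple-comparison correction is applied.
#'
#' @param fit A \code{glm_fit} or \code{variance_comparison} (or a plain
#'   voxel x chromophore t matrix).
#' @param mask Optional \code{sensitivity_mask} restricting the map.
#' @param threshold t threshold (default 1.65).
#' @param two_sided Defaults to TRUE for GLM fits and FALSE for variance
#'   comparisons.
#' @return Object of class \code{stat_map}: \code{t_score},
#'   \code{suprathreshold} (logical, same shape), \code{threshold},
#'   \code{method}, \code{voxel_index}, geometry fields.
#' @export
threshold_map <- function(fit, mask = NULL, threshold = 1.65,
                          two_sided = NULL) {
  method <- if (inherits(fit, "glm_fit")) "GLM"
  else if (inherits(fit, "variance_comparison")) "variance"
  else "custom"
  if (is.null(two_sided)) two_sided <- method != "variance"
  tsc <- if (is.matrix(fit)) fit else fit$t_score
  vox <- if (is.matrix(fit)) seq_len(nrow(fit)) else fit$voxel_index
  if (!all(is.finite(tsc))) stopf("t-scores must be finite")
  if (!is.null(mask)) {
    keep <- vox %in% mask$voxel_index[mask$mask]
    tsc <- tsc[keep, , drop = FALSE]
    vox <- vox[keep]
  }
  supra <- if (two_sided) abs(tsc) > threshold else tsc > threshold
  structure(list(t_score = tsc, suprathreshold = supra,
                 threshold = threshold, two_sided = two_sided,
                 method = method, voxel_index = vox,
                 grid_shape = if (is.matrix(fit)) NULL else fit$grid_shape,
                 voxel_size = if (is.matrix(fit)) NULL else fit$voxel_size),
            class = "stat_map")
}

#' Spatial anticorrelation of the O2Hb and HHb maps
#'
#' Pearson correlation across masked voxels of the two chromophore t-score
#' maps; hemodynamic brain activity drives opposite O2Hb/HHb oscillations,
#' so a clearly negative value is a signature of genuine activation.
#'
#' @param t_o2hb,t_hhb Numeric t-score vectors over the same voxels (e.g.
#'   columns of a \code{glm_fit}'s \code{t_score}).
#' @return The correlation coefficient (scalar).
#' @export
anticorrelation_summary <- function(t_o2hb, t_hhb) {
  if (length(t_o2hb) != length(t_hhb) || length(t_o2hb) < 3L) {
    stopf("need at least 3 paired masked voxels")
  }
  stats::cor(t_o2hb, t_hhb)
}

#' Suprathreshold activation centroid
#'
#' t-weighted centroid of the suprathreshold voxels of one chromophore
#' column of a \code{stat_map}, in mm. Returns NULL when nothing survives
#' the threshold.
#'
#' @param map A \code{stat_map} with geometry fields.
#' @param head The \code{head_model} the map lives on.
#' @param chromophore Column name, default \code{"o2hb"}.
#' @param positive Use only positive-t suprathreshold voxels (default TRUE;
#'   activation raises O2Hb).
#' @export
stat_map_centroid <- function(map, head, chromophore = "o2hb",
                              positive = TRUE) {
  tsc <- map$t_score[, chromophore]
  sel <- map$suprathreshold[, chromophore]
  if (positive) sel <- sel & tsc > 0
  if (!any(sel)) return(NULL)
  w <- abs(tsc[sel])
  pts <- voxel_centers(head, map$voxel_index[sel])
  colSums(pts * w) / sum(w)
}
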