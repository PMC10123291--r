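# Outlier trimming, control-well normalization and composite Z scoring.

#' Quartile-fence outlier trimming
#'
#' Excludes values below Q1 - multiplier * IQR or above
#' Q3 + multiplier * IQR.  Quartiles use linear interpolation between
#' order statistics (\code{stats::quantile} type 7, the common default of
#' mainstream statistics software); the convention is recorded in the
#' result because the fences depend on it.  The default multiplier of 1.7
#' is deliberately wider than Tukey's 1.5.
#'
#' @param x numeric values (trimming is applied to raw values, before any
#'   normalization).
#' @param multiplier fence multiplier (> 0), default 1.7.
#' @param type quantile type passed to \code{stats::quantile}.
#' @return list: \code{values} (kept), \code{keep} (logical mask),
#'   \code{fences} (lower, upper), \code{multiplier},
#'   \code{quantile_type}.  With fewer than 4 values the rule is skipped
#'   with a warning and everything is kept.
#' @export
trim_outliers <- function(x, multiplier = 1.7, type = 7) {
  stopifnot(multiplier > 0)
  ok <- !is.na(x)
  if (sum(ok) < 4L) {
    warning("fewer than 4 values; outlier rule skipped", call. = FALSE)
    return(list(values = x[ok], keep = ok, fences = c(-Inf, Inf),
                multiplier = multiplier, quantile_type = type))
  }
  q <- stats::quantile(x[ok], c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - multiplier * iqr, q[2] + multiplier * iqr)
  keep <- ok & x >= fences[1] & x <= fences[2]
  list(values = x[keep], keep = keep, fences = fences,
       multiplier = multiplier, quantile_type = type)
}

#' Normalize values to their control mean
#'
#' \code{"n_fold"}: value / control mean; \code{"delta"}: value - control
#' mean.  A zero control mean under \code{"n_fold"} yields missing values
#' with a reason code.
#'
#' @param values numeric vector.
#' @param control_mean scalar control mean.
#' @param mode \code{"n_fold"} or \code{"delta"}.
#' @return numeric vector (possibly with \code{attr(, "reason")}).
#' @export
normalize_to_controls <- function(values, control_mean,
                                  mode = c("n_fold", "delta")) {
  mode <- match.arg(mode)
  stopifnot(length(control_mean) == 1L, !is.na(control_mean))
  if (mode == "delta") return(values - control_mean)
  if (control_mean == 0) {
    out <- rep(NA_real_, length(values))
    attr(out, "reason") <- "zero_control_mean"
    return(out)
  }
  values / control_mean
}

#' Z test value
#'
#' \eqn{z = (X - \mu) / \sigma}: a knockout sample value standardized
#' against the control group's mean and standard deviation.
#'
#' @param x sample value(s).
#' @param mu reference group mean.
#' @param sigma reference group standard deviation (> 0).
#' @return z value(s); NA with a reason attribute when sigma is not
#'   positive.
#' @export
z_test <- function(x, mu, sigma) {
  if (is.na(sigma) || sigma <= 0) {
    out <- rep(NA_real_, length(x))
    attr(out, "reason") <- "zero_sigma"
    return(out)
  }
  (x - mu) / sigma
}

#' Cluster Z score
#'
#' Arithmetic mean of the member Z tests, over non-missing members
#' (equal weights).
#'
#' @param z numeric vector of member Z tests.
#' @return mean z, or NA if every member is missing.
#' @export
cluster_z <- function(z) {
  if (all(is.na(z))) return(NA_real_)
  mean(z, na.rm = TRUE)
}

#' Combined pro-/anti-inflammatory Z score
#'
#' Mean of a cytokine-cluster Z score and the directionally matched shape
#' Z score (roundness for the pro-inflammatory score, aspect ratio for
#' the anti-inflammatory score).  Missing if either component is missing
#' (no silent imputation).
#'
#' @param cytokine_z cytokine-cluster Z score.
#' @param shape_z shape-descriptor Z score.
#' @return (cytokine_z + shape_z) / 2, NA if either is NA.
#' @export
combined_z <- function(cytokine_z, shape_z) {
  ifelse(is.na(cytokine_z) | is.na(shape_z), NA_real_,
         (cytokine_z + shape_z) / 2)
}

#' Per-animal composite Z-score panel
#'
#' For each treatment condition and cytokine, knockout n-fold values are
#' standardized against the mean and standard deviation of the control
#' genotype's n-fold values for the same condition and cytokine
#' (\code{\link{z_test}}); per-animal cluster scores are the equal-weight
#' means over cluster members (\code{\link{cluster_z}}); roundness and
#' aspect-ratio n-folds are standardized the same way and combined with
#' the core clusters into the ProIF and AntiIF scores
#' (\code{\link{combined_z}}).
#'
#' @param cytokine_folds data.frame with columns \code{analyte},
#'   \code{animal}, \code{genotype}, \code{treatment}, \code{n_fold}.
#' @param shape_folds data.frame with columns \code{animal},
#'   \code{genotype}, \code{treatment}, \code{roundness_fold},
#'   \code{aspect_ratio_fold}; may be NULL (combined scores then NA).
#' @param clusters list as \code{\link{default_clusters}}.
#' @param ref_genotype genotype providing mu and sigma (default "CTRL").
#' @param score_genotype genotype being scored (default "KO").
#' @return data.frame, one row per scored animal x treatment: cluster
#'   scores for the "all" and "core" cluster variants, shape z values and
#'   the combined \code{proif} / \code{antiif} scores.
#' @export
zscore_panel <- function(cytokine_folds, shape_folds = NULL,
                         clusters = default_clusters(),
                         ref_genotype = "CTRL", score_genotype = "KO") {
  cf <- cytokine_folds
  stopifnot(all(c("analyte", "animal", "genotype", "treatment", "n_fold")
                %in% names(cf)))
  treatments <- unique(cf$treatment[cf$genotype == score_genotype])
  rows <- list()
  for (tr in treatments) {
    ko <- cf[cf$genotype == score_genotype & cf$treatment == tr, ]
    ctrl <- cf[cf$genotype == ref_genotype & cf$treatment == tr, ]
    animals <- unique(ko$animal)
    # per-cytokine reference moments
    mu <- tapply(ctrl$n_fold, ctrl$analyte, mean, na.rm = TRUE)
    sg <- tapply(ctrl$n_fold, ctrl$analyte, stats::sd, na.rm = TRUE)
    for (anm in animals) {
      kk <- ko[ko$animal == anm, ]
      zs <- vapply(seq_len(nrow(kk)), function(i) {
        an <- kk$analyte[i]
        if (!an %in% names(mu)) return(NA_real_)
        z_test(kk$n_fold[i], mu[[an]], sg[[an]])[1]
      }, numeric(1))
      names(zs) <- kk$analyte
      zc <- function(members) cluster_z(zs[members[members %in% names(zs)]])
      z_round <- z_aspect <- NA_real_
      if (!is.null(shape_folds)) {
        sh_ko <- shape_folds[shape_folds$genotype == score_genotype &
                             shape_folds$treatment == tr &
                             shape_folds$animal == anm, ]
        sh_ct <- shape_folds[shape_folds$genotype == ref_genotype &
                             shape_folds$treatment == tr, ]
        if (nrow(sh_ko) == 1L && nrow(sh_ct) >= 2L) {
          z_round <- z_test(sh_ko$roundness_fold,
                            mean(sh_ct$roundness_fold, na.rm = TRUE),
                            stats::sd(sh_ct$roundness_fold, na.rm = TRUE))[1]
          z_aspect <- z_test(sh_ko$aspect_ratio_fold,
                             mean(sh_ct$aspect_ratio_fold, na.rm = TRUE),
                             stats::sd(sh_ct$aspect_ratio_fold,
                                       na.rm = TRUE))[1]
        }
      }
      pro_core <- zc(clusters$pro_core)
      anti_core <- zc(clusters$anti_core)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = anm, treatment = tr,
        z_pro_all = zc(clusters$pro_all),
        z_anti_all = zc(clusters$anti_all),
        z_pro_core = pro_core,
        z_anti_core = anti_core,
        z_roundness = z_round,
        z_aspect_ratio = z_aspect,
        proif = combined_z(pro_core, z_round),
        antiif = combined_z(anti_core, z_aspect),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
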