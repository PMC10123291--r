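# Five-parameter logistic (5PL) calibration of multiplex immunoassay
# responses, plus the correction / normalization chain: interpolate
# concentration from the standard curve, double for the 1:2 sample
# dilution, subtract the mean background (medium-only) concentration, and
# express treatment wells as n-fold of the matched control wells.
#
# Parameterization (the common immunoassay convention):
#   y = D + (A - D) / (1 + (x / C)^B)^g
# A = response at zero concentration, D = response at infinite
# concentration, C > 0 locates the transition, B is the slope factor and
# g > 0 the asymmetry (g = 1 recovers the 4PL).

#' Forward five-parameter logistic curve
#'
#' @param x concentration (>= 0).
#' @param A,D asymptotes (response units); A at x = 0, D at x = Inf.
#' @param C transition concentration (> 0).
#' @param B slope factor.
#' @param g asymmetry (> 0); g = 1 gives the 4PL.
#' @return response values.
#' @export
fivepl <- function(x, A, D, C, B, g = 1) {
  stopifnot(C > 0, g > 0)
  D + (A - D) / (1 + (x / C)^B)^g
}

#' Closed-form inverse of the 5PL
#'
#' \eqn{x = C ((( A - D) / (y - D))^{1/g} - 1)^{1/B}}.  Responses outside
#' the open interval between the asymptotes cannot be inverted and are
#' censored (NA with a flag), never extrapolated.
#'
#' @param y response values.
#' @inheritParams fivepl
#' @return data.frame with \code{concentration} and \code{censored}
#'   (\code{"ok"}, \code{"low"} or \code{"high"}).
#' @export
fivepl_inverse <- function(y, A, D, C, B, g = 1) {
  stopifnot(C > 0, g > 0)
  lo <- min(A, D); hi <- max(A, D)
  # direction: response at x=0 is A; curve runs from A to D
  below <- y <= lo; above <- y >= hi
  censored <- ifelse(!below & !above, "ok",
              ifelse((below & A == lo) | (above & A == hi), "low", "high"))
  x <- rep(NA_real_, length(y))
  okk <- censored == "ok"
  if (any(okk)) {
    x[okk] <- C * (((A - D) / (y[okk] - D))^(1 / g) - 1)^(1 / B)
  }
  data.frame(concentration = x, censored = censored,
             stringsAsFactors = FALSE)
}

#' Fit a 5PL standard curve
#'
#' Multi-start nonlinear least squares (Levenberg-Marquardt on
#' \code{(A, D, log C, B, log g)}): C starts on a log grid over the
#' standard concentrations, g starts at 0.5/1/2, A/D starts from the
#' observed response extremes.  Unweighted by default; \code{"inv_y2"}
#' applies 1/y^2 weights.
#'
#' @param concentration,response numeric vectors (duplicates allowed;
#'   >= 6 distinct positive concentrations required).
#' @param weighting \code{"none"} (default) or \code{"inv_y2"}.
#' @param fix_g optionally fix the asymmetry (e.g. \code{fix_g = 1} for a
#'   4PL fit).
#' @param analyte name used in error messages.
#' @return object of class \code{fivepl_fit}: elements \code{A}, \code{D},
#'   \code{C}, \code{B}, \code{g}, \code{sse}, \code{converged}, \code{n}.
#' @export
fit_5pl <- function(concentration, response, weighting = c("none", "inv_y2"),
                    fix_g = NULL, analyte = "analyte") {
  weighting <- match.arg(weighting)
  ok <- is.finite(concentration) & is.finite(response) & concentration > 0
  x <- concentration[ok]; y <- response[ok]
  if (length(unique(x)) < 6L) {
    stop("calibration error for ", analyte,
         ": need >= 6 distinct positive standard concentrations",
         call. = FALSE)
  }
  if (stats::sd(y) < 1e-12 * max(abs(y), 1)) {
    stop("calibration error for ", analyte,
         ": degenerate standard curve (responses all equal)", call. = FALSE)
  }
  w <- if (weighting == "inv_y2") 1 / pmax(y, 1e-12)^2 else rep(1, length(y))

  span <- max(y) - min(y)
  increasing <- stats::cor(log(x), y) > 0
  A0 <- if (increasing) min(y) - 0.05 * span else max(y) + 0.05 * span
  D0 <- if (increasing) max(y) + 0.05 * span else min(y) - 0.05 * span
  # crude slope estimate from a linearized logit on the interior points
  B0 <- 1
  gs <- if (is.null(fix_g)) c(1, 0.5, 2) else 1
  cs <- exp(seq(log(min(x)), log(max(x)), length.out = 7L))[2:6]

  model <- function(p, x) {
    g <- if (is.null(fix_g)) exp(p[5]) else fix_g
    p[2] + (p[1] - p[2]) / (1 + (x / exp(p[3]))^p[4])^g
  }
  resid_fn <- function(p) sqrt(w) * (y - model(p, x))

  best <- NULL
  for (g0 in gs) for (C0 in cs) {
    p0 <- c(A0, D0, log(C0), B0, if (is.null(fix_g)) log(g0))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(par = fit$par, sse = sse,
                   converged = fit$info %in% 1:4)
    }
    # early exit once the curve is essentially exact
    if (best$sse < 1e-16 * sum(w * y^2)) break
  }
  if (is.null(best)) {
    stop("calibration error for ", analyte,
         ": 5PL fit did not converge from any start", call. = FALSE)
  }
  p <- best$par
  out <- list(
    A = p[1], D = p[2], C = exp(p[3]), B = p[4],
    g = if (is.null(fix_g)) exp(p[5]) else fix_g,
    sse = best$sse, converged = best$converged,
    n = length(y), weighting = weighting, analyte = analyte
  )
  class(out) <- "fivepl_fit"
  out
}

#' @export
print.fivepl_fit <- function(x, ...) {
  cat(sprintf(
    "5PL fit [%s]: A=%.4g D=%.4g C=%.4g B=%.4g g=%.4g (SSE %.3g, n=%d)\n",
    x$analyte, x$A, x$D, x$C, x$B, x$g, x$sse, x$n))
  invisible(x)
}

#' Interpolate concentrations from responses
#'
#' @param fit a \code{fivepl_fit}.
#' @param response numeric responses.
#' @return data.frame from \code{\link{fivepl_inverse}}.
#' @export
concentration_from_response <- function(fit, response) {
  stopifnot(inherits(fit, "fivepl_fit"))
  fivepl_inverse(response, fit$A, fit$D, fit$C, fit$B, fit$g)
}

#' Dilution and background correction
#'
#' corrected = concentration * dilution_factor - background_mean, floored
#' at zero (concentrations are physical quantities).
#'
#' @param concentration interpolated concentrations (pg/mL).
#' @param dilution_factor sample dilution (default 2 for a 1:2 dilution).
#' @param background_mean mean concentration of the medium-only wells.
#' @return corrected concentrations.
#' @export
correct_sample <- function(concentration, dilution_factor = 2,
                           background_mean = 0) {
  stopifnot(background_mean >= 0, dilution_factor > 0)
  pmax(0, concentration * dilution_factor - background_mean)
}

#' n-fold change against control wells
#'
#' \code{value / mean(control_values)}.  A zero control mean yields a
#' missing value carrying a reason code rather than a pseudo-count.
#'
#' @param value treatment value(s).
#' @param control_values control-well values the mean is taken over.
#' @return numeric vector; entries are NA with
#'   \code{attr(, "reason") = "zero_control_mean"} when the control mean
#'   is zero.
#' @export
fold_change <- function(value, control_values) {
  if (length(control_values) == 0L || all(is.na(control_values))) {
    stop("no control wells available", call. = FALSE)
  }
  m <- mean(control_values, na.rm = TRUE)
  if (m == 0) {
    out <- rep(NA_real_, length(value))
    attr(out, "reason") <- "zero_control_mean"
    return(out)
  }
  value / m
}

#' Calibrate a whole plate and apply the correction chain
#'
#' Per analyte: fit the 5PL on the standards, interpolate every sample
#' and background well, compute the mean background concentration from
#' the medium-only wells, apply dilution doubling and background
#' subtraction to sample wells, and compute per-animal n-fold values of
#' treatment wells against the same animal's control wells.
#'
#' @param standards data.frame with columns \code{analyte},
#'   \code{concentration}, \code{response}.
#' @param samples data.frame with columns \code{analyte}, \code{well},
#'   \code{role} (\code{"treatment"}, \code{"control"} or
#'   \code{"background"}), \code{animal}, \code{genotype},
#'   \code{treatment}, \code{dilution}, \code{response}.
#' @param weighting passed to \code{\link{fit_5pl}}.
#' @return list: \code{records} (tidy per-well data.frame with
#'   interpolated, corrected and n-fold values), \code{fits} (named list
#'   of \code{fivepl_fit}).
#' @export
calibrate_plate <- function(standards, samples, weighting = "none") {
  stopifnot(all(c("analyte", "concentration", "response") %in%
                names(standards)),
            all(c("analyte", "role", "animal", "dilution", "response") %in%
                names(samples)))
  analytes <- unique(standards$analyte)
  fits <- list()
  recs <- vector("list", length(analytes))
  for (i in seq_along(analytes)) {
    an <- analytes[i]
    st <- standards[standards$analyte == an, ]
    fit <- fit_5pl(st$concentration, st$response, weighting = weighting,
                   analyte = an)
    fits[[an]] <- fit
    sa <- samples[samples$analyte == an, , drop = FALSE]
    interp <- concentration_from_response(fit, sa$response)
    # censored-low wells are treated as concentration 0 for the
    # correction chain (below quantifiable range), censored-high stay NA
    conc <- interp$concentration
    conc[interp$censored == "low"] <- 0
    bg <- conc[sa$role == "background"]
    bg_mean <- if (length(bg)) mean(bg, na.rm = TRUE) else 0
    corrected <- rep(NA_real_, nrow(sa))
    is_bg <- sa$role == "background"
    corrected[!is_bg] <- correct_sample(conc[!is_bg],
                                        dilution_factor = sa$dilution[!is_bg],
                                        background_mean = bg_mean)
    sa$concentration <- conc
    sa$censored <- interp$censored
    sa$background_mean <- bg_mean
    sa$corrected <- corrected
    recs[[i]] <- sa
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  # per-animal n-fold of treatment wells against the animal's control wells
  records$n_fold <- NA_real_
  records$n_fold_reason <- NA_character_
  is_tr <- records$role == "treatment"
  key <- paste(records$analyte, records$animal)
  for (kk in unique(key[is_tr])) {
    sel_tr <- is_tr & key == kk
    sel_ct <- records$role == "control" & key == kk
    if (!any(sel_ct)) {
      stop("no control wells for animal in group '", kk, "'", call. = FALSE)
    }
    nf <- fold_change(records$corrected[sel_tr],
                      records$corrected[sel_ct])
    records$n_fold[sel_tr] <- nf
    if (!is.null(attr(nf, "reason"))) {
      records$n_fold_reason[sel_tr] <- attr(nf, "reason")
    }
  }
  list(records = records, fits = fits)
}
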