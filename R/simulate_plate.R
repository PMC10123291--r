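# Synthetic multiplex cytokine experiments.
#
# Measurement model: each analyte has a true 5PL response curve.  An
# animal's untreated wells secrete a per-analyte base concentration times
# a per-animal lognormal biological factor; a treatment multiplies the
# secreted concentration by the analyte x genotype x treatment effect
# multiplier.  The well content is mixed 1:1 with diluent (1:2 dilution)
# on top of the growth-medium background, the forward 5PL maps the well
# concentration to a response, and multiplicative lognormal noise with
# the stated CV is applied (the standard immunoassay error model).
# Standards are a duplicated 6-point 10x serial dilution; background
# wells contain medium only.

PANEL <- c("TNFa", "IFNg", "IL1b", "IL2", "IL4", "IL6", "IL10", "IL12",
           "IL17", "IL27")
TREATMENTS <- c("BzATP", "LPS+BzATP", "JNJ-47965567", "A-804598")
STIMULATIONS <- c("BzATP", "LPS+BzATP")
ANTAGONISTS <- c("JNJ-47965567", "A-804598")

#' The ten-analyte cytokine panel
#' @return character vector of analyte names.
#' @export
cytokine_panel <- function() PANEL

#' Treatment arms
#' @return character vector: two stimulations (BzATP, LPS+BzATP) and two
#'   selective P2X7R antagonists (JNJ-47965567, A-804598).
#' @export
treatment_levels <- function() TREATMENTS

#' Cytokine cluster membership
#'
#' \code{pro_all} / \code{anti_all}: every panel member with the given
#' directionality; \code{pro_core} (IL-1b, IL-6, TNFa) and
#' \code{anti_core} (IL-4, IL-10) are the clusters entering the combined
#' pro-/anti-inflammatory scores.
#'
#' @return named list of character vectors.
#' @export
default_clusters <- function() {
  list(
    pro_all = c("TNFa", "IFNg", "IL1b", "IL2", "IL6", "IL12", "IL17",
                "IL27"),
    anti_all = c("IL4", "IL10"),
    pro_core = c("IL1b", "IL6", "TNFa"),
    anti_core = c("IL4", "IL10")
  )
}

# True per-analyte 5PL response curves (fluorescence units against
# pg/mL).  Fixed, not random: these are instrument characteristics.
default_curve_params <- function() {
  data.frame(
    analyte = PANEL,
    A = c(55, 40, 60, 45, 50, 52, 48, 42, 46, 44),
    D = c(26000, 22000, 28000, 21000, 24000, 27000, 23000, 20000,
          22500, 25000),
    C = c(120, 60, 90, 45, 70, 110, 80, 55, 40, 100),
    B = c(1.15, 1.05, 1.25, 0.95, 1.10, 1.20, 1.00, 1.05, 0.90, 1.10),
    g = c(1.00, 0.85, 1.20, 1.00, 0.90, 1.10, 1.00, 1.30, 0.95, 1.05),
    stringsAsFactors = FALSE
  )
}

# Untreated secreted concentration per analyte (pg/mL), in the
# quantifiable range of the curves above.
default_base_conc <- function() {
  stats::setNames(
    c(40, 10, 15, 8, 25, 30, 20, 12, 6, 18), PANEL)
}

#' Default effect-multiplier table
#'
#' True fold multipliers on secreted concentration per analyte x genotype
#' x treatment, encoding the qualitative directions of P2X7R biology:
#' stimulation (BzATP, and more strongly LPS+BzATP) raises
#' pro-inflammatory cytokines with a larger effect in receptor-proficient
#' (CTRL) than knockout (KO) cultures; BzATP depresses IL-4 (~9-fold in
#' CTRL, ~6-fold in KO); antagonists lower pro-inflammatory cytokines and
#' double IL-4 in CTRL only, with no effect in KO.  Magnitudes are model
#' parameters, not claims about any particular dataset.
#'
#' @return data.frame with columns analyte, genotype, treatment,
#'   multiplier.
#' @export
default_effects <- function() {
  eff <- expand.grid(analyte = PANEL, genotype = c("CTRL", "KO"),
                     treatment = TREATMENTS, stringsAsFactors = FALSE)
  eff$multiplier <- 1
  set_m <- function(eff, an, gt, tr, m) {
    i <- eff$analyte %in% an & eff$genotype == gt & eff$treatment == tr
    eff$multiplier[i] <- m
    eff
  }
  # BzATP: modest pro-inflammatory rise, CTRL > KO; IL-4 drop in both
  eff <- set_m(eff, c("TNFa", "IL6"), "CTRL", "BzATP", 2.0)
  eff <- set_m(eff, "IL1b", "CTRL", "BzATP", 2.5)
  eff <- set_m(eff, c("IFNg", "IL27"), "CTRL", "BzATP", 1.5)
  eff <- set_m(eff, c("IL2", "IL12", "IL17"), "CTRL", "BzATP", 1.2)
  eff <- set_m(eff, "IL4", "CTRL", "BzATP", 1 / 9)
  eff <- set_m(eff, "IL10", "CTRL", "BzATP", 0.7)
  eff <- set_m(eff, c("TNFa", "IL6", "IL1b"), "KO", "BzATP", 1.3)
  eff <- set_m(eff, c("IFNg", "IL27"), "KO", "BzATP", 1.2)
  eff <- set_m(eff, c("IL2", "IL12", "IL17"), "KO", "BzATP", 1.05)
  eff <- set_m(eff, "IL4", "KO", "BzATP", 1 / 6)
  eff <- set_m(eff, "IL10", "KO", "BzATP", 0.8)
  # LPS + BzATP: strong TNFa / IL-6 / IL-27 response, CTRL > KO
  eff <- set_m(eff, "TNFa", "CTRL", "LPS+BzATP", 25)
  eff <- set_m(eff, "IL6", "CTRL", "LPS+BzATP", 20)
  eff <- set_m(eff, "IL27", "CTRL", "LPS+BzATP", 8)
  eff <- set_m(eff, "IL1b", "CTRL", "LPS+BzATP", 4)
  eff <- set_m(eff, "IFNg", "CTRL", "LPS+BzATP", 2)
  eff <- set_m(eff, c("IL2", "IL12", "IL17"), "CTRL", "LPS+BzATP", 1.5)
  eff <- set_m(eff, "IL4", "CTRL", "LPS+BzATP", 0.5)
  eff <- set_m(eff, "IL10", "CTRL", "LPS+BzATP", 0.8)
  eff <- set_m(eff, "TNFa", "KO", "LPS+BzATP", 10)
  eff <- set_m(eff, "IL6", "KO", "LPS+BzATP", 5)
  eff <- set_m(eff, "IL27", "KO", "LPS+BzATP", 4)
  eff <- set_m(eff, "IL1b", "KO", "LPS+BzATP", 1.8)
  eff <- set_m(eff, "IFNg", "KO", "LPS+BzATP", 1.5)
  eff <- set_m(eff, c("IL2", "IL12", "IL17"), "KO", "LPS+BzATP", 1.2)
  eff <- set_m(eff, "IL4", "KO", "LPS+BzATP", 0.6)
  eff <- set_m(eff, "IL10", "KO", "LPS+BzATP", 0.9)
  # antagonists: anti-inflammatory shift in CTRL only
  for (tr in ANTAGONISTS) {
    eff <- set_m(eff, c("TNFa", "IFNg"), "CTRL", tr, 0.6)
    eff <- set_m(eff, c("IL6", "IL1b"), "CTRL", tr, 0.8)
    eff <- set_m(eff, "IL4", "CTRL", tr, 2.0)
    eff <- set_m(eff, "IL10", "CTRL", tr, 1.3)
  }
  eff
}

#' Describe a multiplex plate experiment
#'
#' @param n_animals animals per genotype.
#' @param analytes analyte names (default the ten-cytokine panel).
#' @param treatments treatment arms.
#' @param effects effect-multiplier table
#'   (default \code{\link{default_effects}}); multipliers must be > 0.
#' @param base_conc named per-analyte untreated secreted concentration.
#' @param curve_params per-analyte true 5PL parameters.
#' @param top_standard,n_standards,dilution_step standards: a
#'   \code{dilution_step}-fold serial dilution of \code{top_standard},
#'   \code{n_standards} points, each in duplicate.
#' @param sample_dilution sample dilution factor (default 2, i.e. 1:2).
#' @param n_background medium-only background wells (default 2).
#' @param medium_baseline per-analyte concentration already present in
#'   growth medium (pg/mL).
#' @param noise_cv lognormal CV of the response measurement (>= 0).
#' @param bio_cv lognormal CV of per-animal baseline secretion.
#' @return list of class \code{plate_design}.
#' @export
plate_design <- function(n_animals = 6, analytes = cytokine_panel(),
                         treatments = treatment_levels(),
                         effects = default_effects(),
                         base_conc = default_base_conc(),
                         curve_params = default_curve_params(),
                         top_standard = 10000, n_standards = 6,
                         dilution_step = 10, sample_dilution = 2,
                         n_background = 2, medium_baseline = 2,
                         noise_cv = 0.08, bio_cv = 0.25) {
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (bio_cv < 0) stop("bio_cv must be >= 0", call. = FALSE)
  if (any(effects$multiplier <= 0)) {
    stop("effect multipliers must be > 0", call. = FALSE)
  }
  if (dilution_step <= 1) stop("dilution_step must be > 1", call. = FALSE)
  d <- list(n_animals = n_animals, analytes = analytes,
            treatments = treatments, effects = effects,
            base_conc = base_conc, curve_params = curve_params,
            top_standard = top_standard, n_standards = n_standards,
            dilution_step = dilution_step,
            sample_dilution = sample_dilution,
            n_background = n_background,
            medium_baseline = medium_baseline,
            noise_cv = noise_cv, bio_cv = bio_cv)
  class(d) <- "plate_design"
  d
}

#' Simulate a multiplex cytokine experiment
#'
#' @param design a \code{\link{plate_design}}.
#' @param seed integer seed; the generator is a pure function of
#'   (design, seed).
#' @return list of class \code{plate_data}: \code{standards} (analyte,
#'   well, concentration, response), \code{samples} (well, role, analyte,
#'   animal, genotype, treatment, dilution, response) -- each animal has
#'   exactly two control wells -- and \code{truth} (true secreted
#'   concentration and multiplier per analyte x animal x treatment).
#' @export
generate_cytokine_experiment <- function(design, seed) {
  stopifnot(inherits(design, "plate_design"))
  d <- design
  sdlog_noise <- sqrt(log(1 + d$noise_cv^2))
  sdlog_bio <- sqrt(log(1 + d$bio_cv^2))
  cp <- d$curve_params
  rownames(cp) <- cp$analyte
  with_seed(seed, {
    noise <- function(n) {
      if (sdlog_noise == 0) rep(1, n)
      else stats::rlnorm(n, -sdlog_noise^2 / 2, sdlog_noise)
    }
    std_conc <- d$top_standard / d$dilution_step^(seq_len(d$n_standards) - 1)
    standards <- do.call(rbind, lapply(d$analytes, function(an) {
      pp <- cp[an, ]
      conc <- rep(std_conc, each = 2L)
      resp <- fivepl(conc, pp$A, pp$D, pp$C, pp$B, pp$g) * noise(length(conc))
      data.frame(analyte = an,
                 well = paste0("STD_", an, "_", seq_along(conc)),
                 concentration = conc, response = resp,
                 stringsAsFactors = FALSE)
    }))

    animals <- data.frame(
      animal = c(paste0("CTRL_", seq_len(d$n_animals)),
                 paste0("KO_", seq_len(d$n_animals))),
      genotype = rep(c("CTRL", "KO"), each = d$n_animals),
      stringsAsFactors = FALSE)
    # per animal x analyte biological factor on baseline secretion
    bio <- matrix(
      if (sdlog_bio == 0) 1 else
        stats::rlnorm(nrow(animals) * length(d$analytes),
                      -sdlog_bio^2 / 2, sdlog_bio),
      nrow(animals), length(d$analytes),
      dimnames = list(animals$animal, d$analytes))

    eff_key <- paste(d$effects$analyte, d$effects$genotype,
                     d$effects$treatment)
    eff_mult <- stats::setNames(d$effects$multiplier, eff_key)

    # sample wells: 2 control wells + one well per treatment,
    # per animal x analyte (vectorized over the whole grid)
    conds <- c("control", "control", d$treatments)
    roles <- c("control", "control", rep("treatment", length(d$treatments)))
    grid <- expand.grid(slot = seq_along(conds),
                        analyte = d$analytes,
                        ai = seq_len(nrow(animals)),
                        stringsAsFactors = FALSE)
    grid$treatment <- conds[grid$slot]
    grid$role <- roles[grid$slot]
    grid$animal <- animals$animal[grid$ai]
    grid$genotype <- animals$genotype[grid$ai]
    mult <- ifelse(grid$role == "control", 1,
                   eff_mult[paste(grid$analyte, grid$genotype,
                                  grid$treatment)])
    mult[is.na(mult)] <- 1
    base <- d$base_conc[grid$analyte] * bio[cbind(grid$ai,
                                                  match(grid$analyte,
                                                        d$analytes))]
    secreted <- base * mult
    well_conc <- (secreted + d$medium_baseline) / d$sample_dilution
    pA <- cp[grid$analyte, "A"]; pD <- cp[grid$analyte, "D"]
    pC <- cp[grid$analyte, "C"]; pB <- cp[grid$analyte, "B"]
    pg <- cp[grid$analyte, "g"]
    resp <- (pD + (pA - pD) / (1 + (well_conc / pC)^pB)^pg) *
      noise(nrow(grid))
    samples <- data.frame(
      well = sprintf("S%04d", seq_len(nrow(grid))),
      role = grid$role, analyte = grid$analyte, animal = grid$animal,
      genotype = grid$genotype, treatment = grid$treatment,
      dilution = d$sample_dilution, response = resp,
      stringsAsFactors = FALSE)
    istr <- grid$slot != 2L  # one truth row per animal x analyte x condition
    truth <- data.frame(
      analyte = grid$analyte[istr], animal = grid$animal[istr],
      genotype = grid$genotype[istr], treatment = grid$treatment[istr],
      multiplier = mult[istr], true_secreted = secreted[istr],
      stringsAsFactors = FALSE)

    # medium-only background wells, measured undiluted
    bgrid <- expand.grid(bi = seq_len(d$n_background), analyte = d$analytes,
                         stringsAsFactors = FALSE)
    bA <- cp[bgrid$analyte, "A"]; bD <- cp[bgrid$analyte, "D"]
    bC <- cp[bgrid$analyte, "C"]; bB <- cp[bgrid$analyte, "B"]
    bg <- cp[bgrid$analyte, "g"]
    bresp <- (bD + (bA - bD) / (1 + (d$medium_baseline / bC)^bB)^bg) *
      noise(nrow(bgrid))
    backgrounds <- data.frame(
      well = sprintf("BG%02d", bgrid$bi), role = "background",
      analyte = bgrid$analyte, animal = NA_character_,
      genotype = NA_character_, treatment = NA_character_,
      dilution = 1, response = bresp, stringsAsFactors = FALSE)
    samples <- rbind(samples, backgrounds)
    rownames(samples) <- rownames(truth) <- NULL
    structure(list(standards = standards, samples = samples, truth = truth),
              class = "plate_data")
  })
}
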