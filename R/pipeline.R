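# End-to-end orchestration: simulate -> measure -> count -> calibrate ->
# score -> test, as one reproducible run.

#' Default morphotype mixtures per genotype and condition
#'
#' Proportions of (round/amoeboid, polarized, ramified) cells.  Baselines
#' put most cells in the round/amoeboid class (CTRL 0.79, KO 0.83, the
#' typical picture for serum-grown primary cultures); stimulation raises
#' the round fraction (BzATP more strongly in CTRL than KO, LPS+BzATP
#' similarly in both), antagonists lower it in CTRL only.
#'
#' @return data.frame with columns genotype, treatment, round_amoeboid,
#'   polarized, ramified.
#' @export
default_mixtures <- function() {
  mk <- function(gt, tr, r, p) data.frame(
    genotype = gt, treatment = tr, round_amoeboid = r, polarized = p,
    ramified = 1 - r - p, stringsAsFactors = FALSE)
  rbind(
    mk("CTRL", "control", 0.79, 0.12),
    mk("KO", "control", 0.83, 0.10),
    mk("CTRL", "BzATP", 0.93, 0.04),
    mk("KO", "BzATP", 0.86, 0.08),
    mk("CTRL", "LPS+BzATP", 0.96, 0.025),
    mk("KO", "LPS+BzATP", 0.95, 0.03),
    mk("CTRL", "JNJ-47965567", 0.65, 0.20),
    mk("KO", "JNJ-47965567", 0.83, 0.10),
    mk("CTRL", "A-804598", 0.65, 0.20),
    mk("KO", "A-804598", 0.83, 0.10)
  )
}

#' Null effect table (no programmed genotype or treatment effect)
#'
#' @return effect table with all multipliers 1.
#' @export
null_effects <- function() {
  eff <- default_effects()
  eff$multiplier <- 1
  eff
}

#' Null mixtures (identical morphotype proportions everywhere)
#'
#' @return mixture table with the CTRL baseline in every cell.
#' @export
null_mixtures <- function() {
  mx <- default_mixtures()
  mx$round_amoeboid <- 0.79
  mx$polarized <- 0.12
  mx$ramified <- 1 - 0.79 - 0.12
  mx
}

#' Pipeline configuration
#'
#' All tunable parameters of a full run.  Defaults mirror the analysis
#' they implement: 1.7 IQR trimming on raw values, aspect-ratio threshold
#' 3 and process threshold 3 for morphotyping, 1:2 sample dilution,
#' duplicated 6-point 10x standards.  Image sizes default to a compact
#' field (ROI 400 x 400 px at 1 um/px with 10 cells per animal and
#' condition) so that replicate studies stay cheap; pass larger values
#' for production-scale fields.
#'
#' @param seed integer seed for the whole run.
#' @param n_animals animals per genotype.
#' @param treatments treatment arms.
#' @param cells_per_roi cells per simulated ROI.
#' @param roi_px ROI raster size c(rows, cols).
#' @param pixel_size_um micrometres per pixel.
#' @param mixtures morphotype mixture table (see
#'   \code{\link{default_mixtures}}).
#' @param effects cytokine effect table (see
#'   \code{\link{default_effects}}).
#' @param noise_cv,bio_cv plate measurement / biological lognormal CVs.
#' @param trim_multiplier IQR fence multiplier.
#' @param clusters cytokine cluster membership.
#' @param process_k process-length threshold (fraction of soma radius).
#' @param ar_threshold,min_processes morphotype decision thresholds.
#' @param normalization \code{"n_fold"} or \code{"delta"} for shape
#'   descriptors.
#' @param count_nuclei run the nuclei-counting stage.
#' @param out_dir optional output directory for tables and manifest.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(seed = 1, n_animals = 8,
                            treatments = treatment_levels(),
                            cells_per_roi = 10,
                            roi_px = c(400L, 400L), pixel_size_um = 1,
                            mixtures = default_mixtures(),
                            effects = default_effects(),
                            noise_cv = 0.08, bio_cv = 0.25,
                            trim_multiplier = 1.7,
                            clusters = default_clusters(),
                            process_k = 0.5, ar_threshold = 3,
                            min_processes = 3,
                            normalization = c("n_fold", "delta"),
                            count_nuclei = TRUE, out_dir = NULL) {
  cfg <- list(seed = seed, n_animals = n_animals, treatments = treatments,
              cells_per_roi = cells_per_roi, roi_px = roi_px,
              pixel_size_um = pixel_size_um, mixtures = mixtures,
              effects = effects, noise_cv = noise_cv, bio_cv = bio_cv,
              trim_multiplier = trim_multiplier, clusters = clusters,
              process_k = process_k, ar_threshold = ar_threshold,
              min_processes = min_processes,
              normalization = match.arg(normalization),
              count_nuclei = count_nuclei, out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

# Fingerprint of a config for the run manifest.
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                        auto_unbox = TRUE, digits = 10)
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}

.descriptor_cols <- c("area_um2", "perimeter_um", "circularity",
                      "roundness", "aspect_ratio", "solidity",
                      "complexity_index")

#' Run the full pipeline
#'
#' Stages: (morphology) simulate one ROI per animal x condition and
#' measure every cell; (counting) count nuclei per ROI and flag
#' multinucleation; (cytokines) simulate the multiplex plate and run the
#' 5PL calibration chain; (scoring) trim raw descriptor values per
#' genotype x treatment group, form per-animal descriptor n-folds against
#' the animal's untreated condition, and build the composite Z panel;
#' (stats) chi-square on morphotype proportions per treatment vs
#' baseline, Welch t per analyte x treatment between genotypes, Kruskal-
#' Wallis + Dunn across treatments per descriptor and genotype, ANOVA +
#' Tukey across treatments for the combined scores.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param stages subset of c("morphology", "counting", "cytokines",
#'   "scoring", "stats") to run; later stages silently skip when their
#'   inputs are missing.
#' @return list of class \code{pipeline_run} with elements \code{cells},
#'   \code{counts}, \code{morphotype_props}, \code{shape_folds},
#'   \code{cytokines} (tidy records), \code{zpanel}, \code{tests},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config,
                         stages = c("morphology", "counting", "cytokines",
                                    "scoring", "stats")) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  stages <- match.arg(stages, several.ok = TRUE)
  conds <- c("control", cfg$treatments)
  genos <- c("CTRL", "KO")
  run <- list(manifest = list(
    seed = cfg$seed, config_hash = .config_hash(cfg),
    r_version = as.character(getRversion()),
    stages = stages,
    parameters = list(trim_multiplier = cfg$trim_multiplier,
                      ar_threshold = cfg$ar_threshold,
                      min_processes = cfg$min_processes,
                      process_k = cfg$process_k,
                      noise_cv = cfg$noise_cv, bio_cv = cfg$bio_cv,
                      normalization = cfg$normalization)))
  class(run) <- "pipeline_run"

  if ("morphology" %in% stages) {
    mx <- cfg$mixtures
    cells <- list(); counts <- list(); idx <- 0L
    for (gt in genos) for (a in seq_len(cfg$n_animals)) for (tr in conds) {
      idx <- idx + 1L
      anm <- paste0(gt, "_", a)
      row <- mx[mx$genotype == gt & mx$treatment == tr, ]
      if (nrow(row) != 1L) {
        stop("morphology stage: no mixture for ", gt, " / ", tr,
             call. = FALSE)
      }
      roi <- generate_roi(
        c(row$round_amoeboid, row$polarized, row$ramified),
        n_cells = cfg$cells_per_roi,
        seed = child_seed(cfg$seed, idx),
        pixel_size_um = cfg$pixel_size_um, roi_px = cfg$roi_px)
      cm <- measure_roi(roi, process_k = cfg$process_k,
                        ar_threshold = cfg$ar_threshold,
                        min_processes = cfg$min_processes)
      if (nrow(cm) > 0L) {
        cm$animal <- anm; cm$genotype <- gt; cm$treatment <- tr
        cells[[idx]] <- cm
      }
      if ("counting" %in% stages && cfg$count_nuclei) {
        cn <- count_nuclei(roi$nuclei, cfg$pixel_size_um)
        npc <- nuclei_per_cell(roi$labels, cn, cfg$pixel_size_um)
        counts[[idx]] <- data.frame(
          animal = anm, genotype = gt, treatment = tr,
          n_cells_truth = nrow(roi$truth), n_nuclei = cn$n_cells,
          density_per_mm2 = cn$density_per_mm2,
          multinucleated = npc$multinucleated,
          stringsAsFactors = FALSE)
      }
    }
    run$cells <- if (length(cells)) do.call(rbind, cells) else NULL
    if (!is.null(run$cells)) rownames(run$cells) <- NULL
    run$counts <- if (length(counts)) do.call(rbind, counts) else NULL

    if (!is.null(run$cells) && nrow(run$cells) > 0L) {
      cc <- run$cells
      agg <- stats::aggregate(
        list(n = rep(1L, nrow(cc))),
        by = list(genotype = cc$genotype, treatment = cc$treatment,
                  morphotype = cc$morphotype), FUN = sum)
      tot <- stats::aggregate(list(total = agg$n),
                              by = list(genotype = agg$genotype,
                                        treatment = agg$treatment),
                              FUN = sum)
      agg <- merge(agg, tot)
      agg$proportion <- agg$n / agg$total
      run$morphotype_props <- agg[order(agg$genotype, agg$treatment,
                                        agg$morphotype), ]
      rownames(run$morphotype_props) <- NULL
    }
  }

  if ("cytokines" %in% stages) {
    des <- plate_design(n_animals = cfg$n_animals,
                        treatments = cfg$treatments,
                        effects = cfg$effects, noise_cv = cfg$noise_cv,
                        bio_cv = cfg$bio_cv)
    plate <- generate_cytokine_experiment(des,
                                          seed = child_seed(cfg$seed, 9e5))
    cal <- calibrate_plate(plate$standards, plate$samples)
    run$cytokines <- cal$records
    run$calibration <- cal$fits
    run$plate_truth <- plate$truth
  }

  if ("scoring" %in% stages && !is.null(run$cells)) {
    run$shape_folds <- shape_fold_table(run$cells,
                                        trim_multiplier = cfg$trim_multiplier,
                                        mode = cfg$normalization)
    if (!is.null(run$cytokines)) {
      cyto <- run$cytokines[run$cytokines$role == "treatment", ]
      run$zpanel <- zscore_panel(cyto, run$shape_folds,
                                 clusters = cfg$clusters)
    }
  }

  if ("stats" %in% stages) {
    run$tests <- pipeline_tests(run)
  }

  if (!is.null(cfg$out_dir)) write_run(run, cfg$out_dir)
  run
}

#' Per-animal shape-descriptor n-folds
#'
#' Raw per-cell descriptor values are trimmed per genotype x treatment x
#' descriptor group (quartile fences on raw values), averaged per animal
#' and condition, then expressed relative to the same animal's untreated
#' condition (ratio or difference per \code{mode}).
#'
#' @param cells per-cell table from \code{\link{measure_roi}} with
#'   \code{animal}, \code{genotype}, \code{treatment} columns.
#' @param trim_multiplier IQR fence multiplier.
#' @param mode \code{"n_fold"} or \code{"delta"}.
#' @return data.frame: animal, genotype, treatment, and
#'   \code{<descriptor>_fold} columns.
#' @export
shape_fold_table <- function(cells, trim_multiplier = 1.7,
                             mode = "n_fold") {
  stopifnot(all(c("animal", "genotype", "treatment") %in% names(cells)))
  desc <- intersect(.descriptor_cols, names(cells))
  grp <- paste(cells$genotype, cells$treatment)
  keep_any <- rep(TRUE, nrow(cells))
  per_animal <- NULL
  for (dcol in desc) {
    keep <- rep(TRUE, nrow(cells))
    for (g in unique(grp)) {
      sel <- grp == g
      if (sum(sel) >= 4L) {
        tr <- trim_outliers(cells[[dcol]][sel], multiplier = trim_multiplier)
        keep[sel] <- tr$keep
      }
    }
    v <- ifelse(keep, cells[[dcol]], NA_real_)
    ag <- stats::aggregate(list(value = v),
                           by = list(animal = cells$animal,
                                     genotype = cells$genotype,
                                     treatment = cells$treatment),
                           FUN = mean, na.rm = TRUE)
    names(ag)[names(ag) == "value"] <- dcol
    per_animal <- if (is.null(per_animal)) ag else merge(per_animal, ag)
  }
  # relative to the same animal's untreated condition
  base <- per_animal[per_animal$treatment == "control", ]
  out <- per_animal[per_animal$treatment != "control", ]
  for (dcol in desc) {
    b <- base[[dcol]][match(out$animal, base$animal)]
    out[[paste0(dcol, "_fold")]] <- if (mode == "n_fold") {
      ifelse(is.na(b) | b == 0, NA_real_, out[[dcol]] / b)
    } else {
      out[[dcol]] - b
    }
  }
  out
}

#' Group statistics for a completed run
#'
#' @param run a \code{pipeline_run}.
#' @return data.frame of test results (comparison, test, statistic, p,
#'   p_adj, stars), or NULL if no stage output is available.
#' @export
pipeline_tests <- function(run) {
  res <- list()
  # chi-square: [round/amoeboid] vs [polarized + ramified], treatment vs
  # within-genotype baseline
  if (!is.null(run$cells)) {
    cc <- run$cells
    for (gt in unique(cc$genotype)) {
      base <- cc[cc$genotype == gt & cc$treatment == "control", ]
      b_counts <- c(sum(base$morphotype == "round_amoeboid"),
                    sum(base$morphotype != "round_amoeboid"))
      for (tr in setdiff(unique(cc$treatment), "control")) {
        tt <- cc[cc$genotype == gt & cc$treatment == tr, ]
        t_counts <- c(sum(tt$morphotype == "round_amoeboid"),
                      sum(tt$morphotype != "round_amoeboid"))
        if (all(b_counts + t_counts > 0) && sum(t_counts) > 0 &&
            all(colSums(rbind(b_counts, t_counts)) > 0)) {
          r <- chi2_morphotype(b_counts, t_counts,
                               comparison = paste0(gt, ": control vs ", tr,
                                                   " (morphotype)"))
          res[[length(res) + 1L]] <- r
        }
      }
    }
  }
  # Welch t: cytokine n-folds CTRL vs KO per treatment x analyte
  if (!is.null(run$cytokines)) {
    cy <- run$cytokines[run$cytokines$role == "treatment", ]
    for (tr in unique(cy$treatment)) for (an in unique(cy$analyte)) {
      a <- cy$n_fold[cy$treatment == tr & cy$analyte == an &
                     cy$genotype == "CTRL"]
      b <- cy$n_fold[cy$treatment == tr & cy$analyte == an &
                     cy$genotype == "KO"]
      if (sum(!is.na(a)) >= 2 && sum(!is.na(b)) >= 2) {
        res[[length(res) + 1L]] <-
          welch_t(a, b, comparison = paste0(an, " ", tr,
                                            ": CTRL vs KO (n-fold)"))
      }
    }
  }
  # KW + Dunn: descriptor n-folds across treatments, per genotype
  if (!is.null(run$shape_folds)) {
    sf <- run$shape_folds
    fold_cols <- grep("_fold$", names(sf), value = TRUE)
    for (gt in unique(sf$genotype)) for (fc in fold_cols) {
      sel <- sf$genotype == gt & !is.na(sf[[fc]])
      if (length(unique(sf$treatment[sel])) >= 3) {
        kw <- kw_dunn(sf[[fc]][sel], sf$treatment[sel])
        om <- kw$omnibus
        om$comparison <- paste0(gt, " ", fc, ": across treatments")
        res[[length(res) + 1L]] <- om
      }
    }
  }
  # ANOVA + Tukey: combined Z scores across treatments
  if (!is.null(run$zpanel)) {
    zp <- run$zpanel
    for (sc in c("proif", "antiif")) {
      sel <- !is.na(zp[[sc]])
      if (length(unique(zp$treatment[sel])) >= 2 &&
          all(table(zp$treatment[sel]) >= 2)) {
        at <- anova_tukey(zp[[sc]][sel], zp$treatment[sel])
        om <- at$omnibus
        om$comparison <- paste0(toupper(sc), ": across treatments")
        res[[length(res) + 1L]] <- om
        res[[length(res) + 1L]] <- at$pairwise
      }
    }
  }
  if (!length(res)) return(NULL)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write run tables and manifest to a directory
#'
#' @param run a \code{pipeline_run}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
    }
  }
  wr(run$cells, "cells")
  wr(run$counts, "counts")
  wr(run$morphotype_props, "morphotype_props")
  wr(run$shape_folds, "shape_folds")
  wr(run$cytokines, "cytokine_records")
  wr(run$zpanel, "zscore_panel")
  wr(run$tests, "tests")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Human-readable markdown summary of a run
#'
#' Emits the panel families of a completed analysis: cell counts,
#' morphotype proportions, descriptor n-folds, cytokine n-folds, Z-score
#' panels and the statistics table.  Missing stages produce a partial
#' report with a warning line instead of an error.
#'
#' @param run a \code{pipeline_run}.
#' @param path file to write (default \code{report.md} in the working
#'   directory); use NULL to return the lines invisibly without writing.
#' @return invisibly, the markdown lines.
#' @export
write_report <- function(run, path = "report.md") {
  stopifnot(inherits(run, "pipeline_run"))
  fmt_table <- function(df, digits = 3) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, digits))
    header <- paste0("| ", paste(names(df), collapse = " | "), " |")
    sepr <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
    body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                            " |"))
    c(header, sepr, body, "")
  }
  L <- c("# Pipeline run report", "",
         paste0("- seed: ", run$manifest$seed),
         paste0("- config hash: ", run$manifest$config_hash), "")
  add_sec <- function(L, title, df, summarize = NULL) {
    L <- c(L, paste0("## ", title), "")
    if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L)) {
      return(c(L, "_stage output missing or empty_", ""))
    }
    if (!is.null(summarize)) df <- summarize(df)
    c(L, fmt_table(df))
  }
  L <- add_sec(L, "Cell counts (nuclei channel)", run$counts,
               function(df) stats::aggregate(
                 cbind(n_nuclei, density_per_mm2) ~ genotype + treatment,
                 data = df, FUN = mean))
  L <- add_sec(L, "Morphotype proportions", run$morphotype_props)
  L <- add_sec(L, "Shape descriptor n-folds (per-animal means)",
               run$shape_folds,
               function(df) {
                 fc <- grep("_fold$", names(df), value = TRUE)
                 stats::aggregate(df[fc],
                                  by = list(genotype = df$genotype,
                                            treatment = df$treatment),
                                  FUN = mean, na.rm = TRUE)
               })
  L <- add_sec(L, "Cytokine n-folds", run$cytokines,
               function(df) {
                 df <- df[df$role == "treatment" & !is.na(df$n_fold), ]
                 stats::aggregate(list(n_fold = df$n_fold),
                                  by = list(analyte = df$analyte,
                                            genotype = df$genotype,
                                            treatment = df$treatment),
                                  FUN = mean)
               })
  L <- add_sec(L, "Composite Z scores", run$zpanel,
               function(df) stats::aggregate(
                 df[c("z_pro_all", "z_anti_all", "proif", "antiif")],
                 by = list(treatment = df$treatment),
                 FUN = mean, na.rm = TRUE))
  L <- add_sec(L, "Group statistics", run$tests)
  if (!is.null(path)) writeLines(L, path)
  invisible(L)
}
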