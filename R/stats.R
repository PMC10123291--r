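# Inferential tests with the pairing of test to comparison used in the
# analysis: Welch t for two-group cytokine n-folds, Pearson chi-square
# (no continuity correction) for morphotype proportions, Kruskal-Wallis +
# Dunn for multi-group shape/count panels, one-way ANOVA + Tukey HSD for
# Z-score panels.

#' Significance tiers
#'
#' ns, *, **, ***, **** at p < 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p p values in [0, 1].
#' @return character vector of tiers.
#' @export
stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  ifelse(is.na(p), NA_character_,
  ifelse(p < 1e-4, "****",
  ifelse(p < 1e-3, "***",
  ifelse(p < 1e-2, "**",
  ifelse(p < 0.05, "*", "ns")))))
}

.result_row <- function(comparison, test, statistic, df, p,
                        p_adj = NA_real_, n = NA_integer_) {
  data.frame(comparison = comparison, test = test, statistic = statistic,
             df = df, p = p, p_adj = p_adj, n = n,
             stars = stars(if (is.na(p_adj)) p else p_adj),
             stringsAsFactors = FALSE)
}

#' Welch two-sample t test
#'
#' Two-tailed t test with Welch's correction (Satterthwaite degrees of
#' freedom).
#'
#' @param a,b numeric samples (each n >= 2).
#' @param comparison label carried into the result.
#' @return one-row results data.frame (comparison, test, statistic, df,
#'   p, p_adj, n, stars).
#' @export
welch_t <- function(a, b, comparison = "a vs b") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("welch_t requires n >= 2 per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical spreads of zero; no evidence either way
    return(.result_row(comparison, "welch_t",
                       statistic = 0, df = length(a) + length(b) - 2,
                       p = if (mean(a) == mean(b)) 1 else 0,
                       n = length(a) + length(b)))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  .result_row(comparison, "welch_t", unname(tt$statistic),
              unname(tt$parameter), tt$p.value, n = length(a) + length(b))
}

#' Chi-square test on morphotype proportions
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2 x 2 table
#' of [round/amoeboid] vs [polarized + ramified] counts in control vs
#' treated cells.
#'
#' @param control_counts,treated_counts length-2 integer vectors:
#'   c(round_amoeboid, polarized_plus_ramified).
#' @param comparison label.
#' @return one-row results data.frame.
#' @export
chi2_morphotype <- function(control_counts, treated_counts,
                            comparison = "control vs treated") {
  stopifnot(length(control_counts) == 2L, length(treated_counts) == 2L)
  tab <- rbind(control = control_counts, treated = treated_counts)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square requires all table margins > 0", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .result_row(comparison, "chi2", unname(ct$statistic),
              unname(ct$parameter), ct$p.value, n = sum(tab))
}

#' Kruskal-Wallis omnibus test with Dunn's post hoc comparisons
#'
#' Kruskal-Wallis H with midrank tie correction (via
#' \code{stats::kruskal.test}) followed by Dunn's z tests for all group
#' pairs.  Dunn's z uses the pooled-rank variance with tie correction,
#' \eqn{z = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T/(12(N-1)))
#' (1/n_i + 1/n_j)}} with \eqn{T = \sum (t^3 - t)} over tie groups;
#' pairwise p values are Bonferroni-adjusted over the tested pairs (the
#' adjustment method is recorded in the output).
#'
#' @param values numeric vector.
#' @param groups grouping factor/vector (>= 3 groups for the omnibus).
#' @return list: \code{omnibus} (one-row results data.frame),
#'   \code{pairwise} (one row per pair), \code{p_adjust_method}.
#' @export
kw_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  lv <- levels(groups)
  if (any(table(groups) == 0) || length(lv) < 2L) {
    stop("kw_dunn requires >= 2 non-empty groups", call. = FALSE)
  }
  if (length(lv) < 3L) {
    warning("fewer than 3 groups: omnibus reduces to a two-group rank test",
            call. = FALSE)
  }
  if (stats::var(values) == 0) {
    omni <- .result_row("omnibus", "kruskal_wallis", 0,
                        length(lv) - 1, 1, n = length(values))
  } else {
    kt <- stats::kruskal.test(values, groups)
    omni <- .result_row("omnibus", "kruskal_wallis", unname(kt$statistic),
                        unname(kt$parameter), kt$p.value,
                        n = length(values))
  }

  r <- rank(values)
  N <- length(values)
  tie <- table(values)
  Tcorr <- sum(tie^3 - tie)
  s2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2L)
  m <- ncol(pairs)
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(s2 * (1 / ns[[g1]] + 1 / ns[[g2]]))
    z <- if (se == 0) 0 else (rbar[[g1]] - rbar[[g2]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    rows[[i]] <- .result_row(paste(g1, "vs", g2), "dunn", z, NA_real_, p,
                             p_adj = min(1, p * m),
                             n = ns[[g1]] + ns[[g2]])
  }
  pairwise <- do.call(rbind, rows)
  rownames(pairwise) <- NULL
  list(omnibus = omni, pairwise = pairwise, p_adjust_method = "bonferroni")
}

#' One-way ANOVA with Tukey's HSD
#'
#' @param values numeric vector.
#' @param groups grouping factor (>= 2 groups, each n >= 2).
#' @return list: \code{omnibus} (F test) and \code{pairwise} (Tukey HSD
#'   adjusted p per pair).
#' @export
anova_tukey <- function(values, groups) {
  groups <- as.factor(groups)
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (length(levels(groups)) < 2L || any(table(groups) < 2L)) {
    stop("anova_tukey requires >= 2 groups with n >= 2 each", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    lv <- levels(groups)
    pairs <- utils::combn(lv, 2L)
    pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      .result_row(paste(pairs[2, i], "vs", pairs[1, i]), "tukey_hsd",
                  0, NA_real_, 1, p_adj = 1)
    }))
    return(list(omnibus = .result_row("omnibus", "anova_f", 0,
                                      length(lv) - 1, 1,
                                      n = length(values)),
                pairwise = pw))
  }
  fit <- stats::aov(values ~ groups)
  sm <- summary(fit)[[1]]
  Fv <- sm[1, "F value"]; p <- sm[1, "Pr(>F)"]
  omni <- .result_row("omnibus", "anova_f", Fv, sm[1, "Df"], p,
                      n = length(values))
  tk <- stats::TukeyHSD(fit)$groups
  pw <- do.call(rbind, lapply(rownames(tk), function(nm) {
    .result_row(sub("-", " vs ", nm, fixed = TRUE), "tukey_hsd",
                tk[nm, "diff"], NA_real_, tk[nm, "p adj"],
                p_adj = tk[nm, "p adj"])
  }))
  rownames(pw) <- NULL
  list(omnibus = omni, pairwise = pw)
}
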