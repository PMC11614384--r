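# Group-comparison machinery mirroring the study's statistics policy:
# normality screening (Shapiro-Wilk for n <= 50, Kolmogorov-Smirnov above),
# Levene's test for homogeneity of variance, then dispatch to two-way
# ANOVA + Tukey, one-way Welch ANOVA + Games-Howell, or Kruskal-Wallis +
# Dunn; Hedge's g effect sizes for all pairwise contrasts; and mean +/- SEM
# summary tables. Games-Howell and Dunn's tests are computed here from their
# standard formulas (studentized-range and rank-based z statistics).

#' Hedge's g effect size
#'
#' Bias-corrected standardized mean difference `g = J * (mean_a - mean_b) /
#' s_pooled`, with the exact small-sample correction
#' `J = gamma(df/2) / (sqrt(df/2) * gamma((df-1)/2))`, `df = n_a + n_b - 2`.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return Hedge's g (signed; swapping the groups flips the sign).
#' @export
hedges_g <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("each group needs at least 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) stop("Hedge's g undefined: zero pooled variance")
  df <- na + nb - 2
  j <- exp(lgamma(df / 2) - log(sqrt(df / 2)) - lgamma((df - 1) / 2))
  j * (mean(a) - mean(b)) / sqrt(sp2)
}

#' Grouped measurements
#'
#' @param values Numeric vector.
#' @param genotype,zone,cell_type Label vectors, recycled to
#'   `length(values)`; missing labels are not allowed.
#' @param measure,units Measure name and units.
#' @return An object of class `grouped_measure`.
#' @export
grouped_measure <- function(values, genotype, zone = "LES",
                            cell_type = "type_I", measure = "measure",
                            units = "") {
  n <- length(values)
  genotype <- rep_len(as.character(genotype), n)
  zone <- rep_len(as.character(zone), n)
  cell_type <- rep_len(as.character(cell_type), n)
  if (anyNA(genotype) || anyNA(zone) || anyNA(cell_type))
    stop("labels must not be missing")
  structure(list(values = as.numeric(values), genotype = genotype,
                 zone = zone, cell_type = cell_type, measure = measure,
                 units = units),
            class = "grouped_measure")
}

# Games-Howell post hoc test for unequal variances.
games_howell <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  m <- tapply(values, groups, mean)
  v <- tapply(values, groups, stats::var)
  n <- tapply(values, groups, length)
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    t_stat <- (m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) +
                   (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    out <- rbind(out, data.frame(
      group_a = lev[i], group_b = lev[j], diff = unname(m[i] - m[j]),
      statistic = unname(t_stat), df = unname(df), p = unname(p)))
  }
  out
}

# Dunn's rank-based post hoc test (tie-corrected), Holm-adjusted p-values.
dunn_test <- function(values, groups) {
  groups <- factor(groups)
  lev <- levels(groups)
  k <- length(lev)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(values, groups, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  out <- NULL
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
    out <- rbind(out, data.frame(
      group_a = lev[i], group_b = lev[j], statistic = unname(z),
      p = unname(p)))
  }
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Compare groups with the study's dispatch policy
#'
#' Normality is screened per group (Shapiro-Wilk for n <= 50,
#' Kolmogorov-Smirnov for larger groups) and variance homogeneity with
#' Levene's test. Dispatch: normal and homogeneous data go to ANOVA (two-way
#' for genotype x zone when both factors vary, else one-way) with Tukey's
#' post hoc test; normal but heteroscedastic data to one-way Welch ANOVA
#' with Games-Howell; non-normal data to Kruskal-Wallis with Dunn's test.
#' Hedge's g is reported for every pairwise contrast. Groups are the
#' genotype x zone cells (collapsed to whichever factors vary).
#'
#' @param measure A [grouped_measure()].
#' @param alpha Significance level used in the screening tests.
#' @param force_path Optionally bypass the dispatch (`"anova"`, `"welch"`,
#'   `"kruskal"`), e.g. for calibration simulations.
#' @param posthoc Compute pairwise post hoc tests and effect sizes (default
#'   `TRUE`; disable for large null simulations where only the omnibus
#'   p-value is needed).
#' @return An object of class `group_comparison`: `path`, `normality`
#'   (per-group p-values), `levene_p`, `omnibus` (named p-value(s)),
#'   `posthoc` (data frame with pairwise p-values and Hedge's g),
#'   `group_sizes`.
#' @export
compare_groups <- function(measure, alpha = 0.05, force_path = NULL,
                           posthoc = TRUE) {
  stopifnot(inherits(measure, "grouped_measure"))
  x <- measure$values
  geno <- factor(measure$genotype)
  zone <- factor(measure$zone)
  two_way <- nlevels(geno) > 1 && nlevels(zone) > 1
  group <- if (two_way) interaction(geno, zone, drop = TRUE)
           else if (nlevels(geno) > 1) geno else zone
  n_by <- table(group)
  if (nlevels(group) < 2 || any(n_by < 3))
    return(structure(list(path = "skipped",
                          reason = "need >= 2 groups with n >= 3 each",
                          group_sizes = n_by),
                     class = "group_comparison"))
  if (is.null(force_path)) {
    norm_p <- vapply(levels(group), function(g) {
      xi <- x[group == g]
      if (stats::sd(xi) == 0) return(0)
      if (length(xi) <= 50) stats::shapiro.test(xi)$p.value
      else suppressWarnings(stats::ks.test(scale(xi), "pnorm")$p.value)
    }, 0)
    normal <- all(norm_p > alpha)
    lev_p <- car::leveneTest(x ~ group)[1, "Pr(>F)"]
    homo <- lev_p > alpha
    path <- if (!normal) "kruskal" else if (homo) "anova" else "welch"
  } else {
    norm_p <- NULL; lev_p <- NA_real_
    path <- match.arg(force_path, c("anova", "welch", "kruskal"))
  }
  ph <- NULL
  if (path == "anova") {
    if (two_way) {
      fit <- stats::aov(x ~ geno * zone)
      tab <- summary(fit)[[1]]
      omnibus <- stats::setNames(tab[["Pr(>F)"]][seq_len(nrow(tab) - 1)],
                                 trimws(rownames(tab)[seq_len(nrow(tab) - 1)]))
    } else {
      fit <- stats::aov(x ~ group)
      omnibus <- c(group = summary(fit)[[1]][["Pr(>F)"]][1])
    }
    if (posthoc) {
      tk <- stats::TukeyHSD(if (two_way) stats::aov(x ~ group) else
        fit)$group
      pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
      ph <- data.frame(
        group_a = vapply(pairs, `[`, "", 1),
        group_b = vapply(pairs, `[`, "", 2),
        diff = tk[, "diff"], p = tk[, "p adj"], row.names = NULL)
    }
  } else if (path == "welch") {
    w <- stats::oneway.test(x ~ group, var.equal = FALSE)
    omnibus <- c(welch = w$p.value)
    if (posthoc) ph <- games_howell(x, group)
  } else {
    kw <- stats::kruskal.test(x, group)
    omnibus <- c(kruskal = kw$p.value)
    if (posthoc) ph <- dunn_test(x, group)
  }
  if (!is.null(ph)) {
    ph$hedges_g <- mapply(function(a, b) {
      tryCatch(hedges_g(x[group == a], x[group == b]),
               error = function(e) NA_real_)
    }, ph$group_a, ph$group_b)
  }
  structure(list(path = path, normality = norm_p, levene_p = lev_p,
                 omnibus = omnibus, posthoc = ph, group_sizes = n_by,
                 measure = measure$measure, units = measure$units),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$path == "skipped") {
    cat("Group comparison skipped:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Group comparison of %s [%s]: %s path\n",
              x$measure, x$units, x$path))
  cat("  omnibus p:",
      paste(sprintf("%s = %.3g", names(x$omnibus), x$omnibus),
            collapse = ", "), "\n")
  ph <- x$posthoc
  if (is.null(ph)) return(invisible(x))
  for (i in seq_len(nrow(ph)))
    cat(sprintf("  %s vs %s: p = %.3g%s, g = %.2f %s\n",
                ph$group_a[i], ph$group_b[i], ph$p[i],
                if (!is.null(ph$p_adj)) sprintf(" (adj %.3g)", ph$p_adj[i])
                else "",
                ph$hedges_g[i], p_stars(ph$p[i])))
  invisible(x)
}

# Asterisk bands: * <0.05, ** <0.01, *** <0.001, **** <0.0001.
p_stars <- function(p) {
  if (is.na(p)) "" else if (p < 1e-4) "****" else if (p < 1e-3) "***"
  else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' Table-style summary per genotype x zone cell
#'
#' The default style is `"mean_sem"` (mean +/- SEM with the cell count),
#' the convention for physiological measures; `"median_range"` (median,
#' min-max) is the convention for age columns.
#'
#' @param measure A [grouped_measure()].
#' @param style `"mean_sem"` or `"median_range"`.
#' @param digits Significant digits for the formatted column.
#' @return Data frame with one row per genotype x zone combination:
#'   `mean`/`sem` or `median`/`min`/`max`, `n`, and a `formatted` column.
#' @export
summarize_table <- function(measure, style = c("mean_sem", "median_range"),
                            digits = 3) {
  stopifnot(inherits(measure, "grouped_measure"))
  style <- match.arg(style)
  key <- interaction(measure$genotype, measure$zone, drop = TRUE, sep = " ")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    xi <- measure$values[key == k]
    n <- length(xi)
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    if (style == "mean_sem") {
      sem <- if (n > 1) stats::sd(xi) / sqrt(n) else NA_real_
      data.frame(genotype = parts[1], zone = parts[2], mean = mean(xi),
                 sem = sem, n = n)
    } else {
      data.frame(genotype = parts[1], zone = parts[2],
                 median = stats::median(xi), min = min(xi), max = max(xi),
                 n = n)
    }
  }))
  out$formatted <- if (style == "mean_sem") {
    ifelse(is.na(out$sem),
           sprintf("%s (1)", signif(out$mean, digits)),
           sprintf("%s ± %s (%d)", signif(out$mean, digits),
                   signif(out$sem, 2), out$n))
  } else {
    sprintf("%s, %s–%s (%d)", signif(out$median, digits),
            signif(out$min, digits), signif(out$max, digits), out$n)
  }
  attr(out, "measure") <- measure$measure
  attr(out, "units") <- measure$units
  out
}

#' Age dependence as a partial correlation
#'
#' Pearson correlation between a measure and age after removing the linear
#' contribution of dummy-coded genotype and zone from both, i.e. the
#' correlation of the residuals. The p-value uses the t distribution with
#' `n - 2 - k` degrees of freedom, `k` the number of covariate columns.
#'
#' @param measure A [grouped_measure()].
#' @param age Ages (days), one per value.
#' @return List with `r` (partial correlation), `p`, `df`.
#' @export
age_partial_cor <- function(measure, age) {
  stopifnot(inherits(measure, "grouped_measure"),
            length(age) == length(measure$values))
  covs <- Filter(function(f) nlevels(f) > 1,
                 list(genotype = factor(measure$genotype),
                      zone = factor(measure$zone)))
  mm <- if (length(covs) == 0)
    matrix(1, length(measure$values), 1)
  else stats::model.matrix(stats::reformulate(names(covs)),
                           as.data.frame(covs))
  rx <- stats::lm.fit(mm, measure$values)$residuals
  ry <- stats::lm.fit(mm, age)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("partial correlation undefined: a residual vector is constant")
  r <- stats::cor(rx, ry)
  df <- length(rx) - 2 - (ncol(mm) - 1)
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE), df = df)
}
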