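#' The 17 per-well MEA parameters
#'
#' Activity: MFR (mean firing rate, spikes/s), PRS (percentage of random
#' spikes).  Single-channel bursting: BR (bursts/min), BD (mean burst
#' duration, s), BSR (burst spike rate, spikes/s), IBI (inter-burst
#' interval, s).  Network bursting: NBR (network bursts/min), NBD (s), NIBI
#' (s), CV_NIBI (regularity), RT and DT (rise/decay time of the mean
#' network-burst shape, s), shape_fwhm (full width at half maximum of the
#' mean shape, s -- the shape summary).  Connectivity: C0 (mean zero-lag
#' correlation), C_peak (mean peak correlation), link_weight, n_connections.
#'
#' @return Character vector of the 17 parameter column names.
#' @export
mea_parameters <- function() {
  c("MFR", "PRS", "BR", "BD", "BSR", "IBI", "NBR", "NBD", "NIBI", "CV_NIBI",
    "RT", "DT", "shape_fwhm", "C0", "C_peak", "link_weight", "n_connections")
}

#' Per-parameter coefficient of variation across wells, by line
#'
#' For each parameter, the coefficient of variation (CV% = 100 * SD / mean)
#' is computed within each line across its wells, then summarised as
#' mean +/- SD across lines.  Parameters whose mean CV exceeds `cv_cutoff`
#' (default 50%) are flagged as unstable.
#'
#' @param table Parameter table (rows = wells).
#' @param group_by Grouping column, default `"line_id"`.
#' @param params Parameter columns to evaluate.
#' @param cv_cutoff Stability cutoff in CV%.
#' @return Data frame `parameter, mean_cv, sd_cv, n_lines, stable`.
#' @export
parameter_cv <- function(table, group_by = "line_id",
                         params = intersect(mea_parameters(), names(table)),
                         cv_cutoff = 50) {
  groups <- unique(table[[group_by]])
  out <- data.frame(parameter = params, mean_cv = NA_real_, sd_cv = NA_real_,
                    n_lines = NA_integer_, stable = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(params)) {
    cvs <- vapply(groups, function(g) {
      x <- table[[params[i]]][table[[group_by]] == g]
      x <- x[!is.na(x)]
      if (length(x) < 2 || mean(x) == 0) return(NA_real_)
      100 * stats::sd(x) / mean(x)
    }, numeric(1))
    cvs <- cvs[!is.na(cvs)]
    out$mean_cv[i] <- if (length(cvs)) mean(cvs) else NA_real_
    out$sd_cv[i] <- if (length(cvs) >= 2) stats::sd(cvs) else NA_real_
    out$n_lines[i] <- length(cvs)
    out$stable[i] <- if (length(cvs)) mean(cvs) <= cv_cutoff else NA
  }
  out
}

#' PCA embedding of a parameter table
#'
#' Columns are Z-score standardised, then decomposed with [stats::prcomp()].
#' The sign convention is fixed so that each component's largest-magnitude
#' loading is positive, making embeddings reproducible.  Columns with zero
#' variance (or NA values) are dropped with a warning.
#'
#' @param table Parameter table.
#' @param params Parameter columns to embed.
#' @return List with `scores` (wells x PCs), `loadings` (params x PCs),
#'   `variance_explained` (percent, sums to 100) and `params_used`.
#' @export
pca_embed <- function(table,
                      params = intersect(mea_parameters(), names(table))) {
  if (nrow(table) < 2 || length(params) < 2) {
    stop("PCA needs at least 2 wells and 2 parameters")
  }
  x <- as.matrix(table[, params, drop = FALSE])
  bad <- apply(x, 2, function(col) anyNA(col) || stats::sd(col) == 0)
  if (any(bad)) {
    warning("dropping constant or incomplete parameter(s): ",
            paste(params[bad], collapse = ", "))
    x <- x[, !bad, drop = FALSE]
    params <- params[!bad]
  }
  if (ncol(x) < 2) stop("fewer than 2 usable parameters for PCA")
  z <- scale(x)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  for (k in seq_len(ncol(pc$rotation))) {
    if (pc$rotation[which.max(abs(pc$rotation[, k])), k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       variance_explained = 100 * pc$sdev^2 / sum(pc$sdev^2),
       params_used = params)
}

#' Variance explained by a batch factor
#'
#' For each parameter a separate one-way linear model with the batch factor
#' as categorical predictor is fitted; the variance explained is
#' `R^2 = SS_between / SS_total`, with per-parameter significance from the
#' model F test, Benjamini-Hochberg adjusted across parameters.  The
#' combined percentage is the `R^2` of the same factor on the stacked
#' Z-scored parameter values.
#'
#' @param table Parameter table with the factor column.
#' @param factor Batch column: `"astro_batch"` or `"mea_batch"` (any
#'   categorical column is accepted).
#' @param params Parameter columns.
#' @return List with `per_parameter` (data frame `parameter, r_squared, p,
#'   p_adj`) and `combined_pct` (percent of variance on all parameters
#'   combined).
#' @export
variance_explained_by_batch <- function(table, factor = "mea_batch",
                                        params = intersect(mea_parameters(),
                                                           names(table))) {
  f <- base::factor(table[[factor]])
  degenerate <- nlevels(f) < 2
  if (degenerate) {
    warning("factor '", factor, "' has a single level; design is degenerate ",
            "and all variance shares are 0")
  }
  per <- data.frame(parameter = params, r_squared = 0, p = NA_real_,
                    p_adj = NA_real_, stringsAsFactors = FALSE)
  z_all <- numeric(0)
  f_all <- character(0)
  for (i in seq_along(params)) {
    y <- table[[params[i]]]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) next
    if (!degenerate) {
      fit <- stats::lm(y[ok] ~ f[ok])
      s <- summary(fit)
      per$r_squared[i] <- s$r.squared
      fstat <- s$fstatistic
      per$p[i] <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
    }
    z_all <- c(z_all, as.numeric(scale(y[ok])))
    f_all <- c(f_all, as.character(f[ok]))
  }
  per$p_adj <- stats::p.adjust(per$p, method = "BH")
  combined <- 0
  if (!degenerate && length(z_all)) {
    combined <- 100 * summary(stats::lm(z_all ~ base::factor(f_all)))$r.squared
  }
  list(per_parameter = per, combined_pct = combined)
}

# Dunn's rank-based post hoc test after Kruskal-Wallis, with tie correction.
.dunn_pairwise <- function(values, groups) {
  g <- base::factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[[a]] + 1 / ni[[b]]))
    z[k] <- (rbar[[a]] - rbar[[b]]) / se
    p[k] <- 2 * stats::pnorm(-abs(z[k]))
  }
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, "bonferroni"),
             stringsAsFactors = FALSE)
}

#' Group comparison across parameters
#'
#' Two-group designs use the Mann-Whitney U test with Bonferroni correction
#' across parameters.  Multi-group designs gate on normality (Lilliefors /
#' Kolmogorov-Smirnov test on the pooled residuals when `nortest` is
#' available, otherwise Shapiro-Wilk): normal data get one-way ANOVA with
#' Tukey post hoc, non-normal data get Kruskal-Wallis with Dunn's post hoc.
#' Significance level is 0.05 on the adjusted p values.
#'
#' @param table Parameter table.
#' @param grouping Grouping column name.
#' @param params Parameter columns to test.
#' @param design `"auto"` (from the number of groups), `"two_group"` or
#'   `"multi_group"`.
#' @param correction Correction across parameters: `"bonferroni"` (default),
#'   `"BH"`, `"holm"` or `"none"`.
#' @param posthoc Also compute pairwise post hoc tables (multi-group).
#' @return Data frame `parameter, test, statistic, p, p_adj, significant`;
#'   when `posthoc` is `TRUE`, a `posthoc` attribute holds one pairwise
#'   table per parameter.
#' @export
group_compare <- function(table, grouping, params = intersect(mea_parameters(),
                                                              names(table)),
                          design = c("auto", "two_group", "multi_group"),
                          correction = c("bonferroni", "BH", "holm", "none"),
                          posthoc = FALSE) {
  design <- match.arg(design)
  correction <- match.arg(correction)
  g_all <- base::factor(table[[grouping]])
  if (nlevels(g_all) < 2) stop("grouping must have at least 2 levels")
  if (design == "auto") {
    design <- if (nlevels(g_all) == 2) "two_group" else "multi_group"
  }
  out <- data.frame(parameter = params, test = NA_character_,
                    statistic = NA_real_, p = NA_real_, p_adj = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  ph <- list()
  for (i in seq_along(params)) {
    y <- table[[params[i]]]
    ok <- !is.na(y)
    y <- y[ok]; g <- droplevels(g_all[ok])
    if (nlevels(g) < 2 || length(y) < 4) next
    if (design == "two_group") {
      wt <- suppressWarnings(stats::wilcox.test(y ~ g))
      out$test[i] <- "mann_whitney"
      out$statistic[i] <- unname(wt$statistic)
      out$p[i] <- wt$p.value
    } else {
      resid <- y - stats::ave(y, g)
      norm_p <- if (stats::sd(resid) == 0) 0 else
        .normality_p(resid)
      if (norm_p > 0.05) {
        fit <- stats::aov(y ~ g)
        s <- summary(fit)[[1]]
        out$test[i] <- "anova"
        out$statistic[i] <- s[["F value"]][1]
        out$p[i] <- s[["Pr(>F)"]][1]
        if (posthoc) {
          tk <- stats::TukeyHSD(fit)$g
          ph[[params[i]]] <- data.frame(
            comparison = rownames(tk), diff = tk[, "diff"],
            p_adj = tk[, "p adj"], row.names = NULL)
        }
      } else {
        kw <- stats::kruskal.test(y ~ g)
        out$test[i] <- "kruskal_wallis"
        out$statistic[i] <- unname(kw$statistic)
        out$p[i] <- kw$p.value
        if (posthoc) ph[[params[i]]] <- .dunn_pairwise(y, g)
      }
    }
  }
  out$p_adj <- if (correction == "none") out$p else
    stats::p.adjust(out$p, method = tolower(correction))
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  if (posthoc) attr(out, "posthoc") <- ph
  out
}

.normality_p <- function(x) {
  if (requireNamespace("nortest", quietly = TRUE) && length(x) >= 5) {
    nortest::lillie.test(x)$p.value
  } else {
    stats::shapiro.test(x[seq_len(min(length(x), 5000))])$p.value
  }
}

#' Holm-Sidak step-down adjustment
#'
#' @param p Vector of raw p values.
#' @return Adjusted p values (monotone step-down Sidak).
#' @export
holm_sidak <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Stack aligned network-burst shapes into a wells-by-bins matrix
#'
#' @param shapes List of [network_burst_shape()] results with identical bin
#'   grids.
#' @return Matrix (wells x bins) with the bin centres as an attribute `t`.
#' @export
shape_matrix <- function(shapes) {
  bw <- unique(vapply(shapes, `[[`, numeric(1), "bin_width"))
  win <- unique(vapply(shapes, `[[`, numeric(1), "window"))
  if (length(bw) != 1 || length(win) != 1) {
    stop("shapes have mismatched bin grids; re-bin before comparing")
  }
  m <- do.call(rbind, lapply(shapes, `[[`, "profile"))
  attr(m, "t") <- shapes[[1]]$t
  m
}

#' Per-bin comparison of network-burst shapes between two groups
#'
#' Two-sample t tests on each profile bin across wells, with Holm-Sidak
#' family correction across bins.
#'
#' @param shapes_a,shapes_b Wells-by-bins matrices ([shape_matrix()]) on the
#'   same bin grid.
#' @return Data frame `bin, t_s, statistic, p, p_adj, significant`.
#' @export
burst_shape_compare <- function(shapes_a, shapes_b) {
  if (ncol(shapes_a) != ncol(shapes_b)) {
    stop("shape matrices have different bin grids; re-bin before comparing")
  }
  ta <- attr(shapes_a, "t"); tb <- attr(shapes_b, "t")
  if (!is.null(ta) && !is.null(tb) && !isTRUE(all.equal(ta, tb))) {
    stop("shape matrices have different bin grids; re-bin before comparing")
  }
  n_bins <- ncol(shapes_a)
  stat <- p <- rep(NA_real_, n_bins)
  for (k in seq_len(n_bins)) {
    xa <- shapes_a[, k]; xb <- shapes_b[, k]
    if (stats::sd(c(xa, xb)) == 0) { p[k] <- 1; stat[k] <- 0; next }
    tt <- stats::t.test(xa, xb, var.equal = TRUE)
    stat[k] <- unname(tt$statistic)
    p[k] <- tt$p.value
  }
  p_adj <- holm_sidak(p)
  data.frame(bin = seq_len(n_bins),
             t_s = if (is.null(ta)) (seq_len(n_bins) - 0.5) else ta,
             statistic = stat, p = p, p_adj = p_adj,
             significant = p_adj < 0.05)
}

#' Wells required per group for a target power
#'
#' Smallest per-group n for which a two-sided two-sample t test at level
#' `alpha` detects a standardised effect `d` with at least the target power
#' (noncentral-t formula).  The floor is n = 2, the smallest meaningful
#' group.
#'
#' @param effect Cohen's d.
#' @param alpha Significance level.
#' @param power Target power.
#' @param n_max Search cap.
#' @return Integer n per group.
#' @export
wells_required <- function(effect, alpha = 0.05, power = 0.8, n_max = 10000) {
  d <- abs(effect)
  if (!is.finite(d) || d <= 0) stop("effect size must be positive")
  for (n in 2:n_max) {
    if (.t_power(n, n, d, alpha) >= power) return(n)
  }
  stop("no n <= ", n_max, " reaches the target power")
}

.t_power <- function(n1, n2, d, alpha) {
  df <- n1 + n2 - 2
  ncp <- d / sqrt(1 / n1 + 1 / n2)
  crit <- stats::qt(1 - alpha / 2, df)
  1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
}

#' Post hoc power of an observed two-group comparison
#'
#' Power of a two-sided two-sample t test given the observed group means,
#' pooled SD and group sizes.
#'
#' @param table Parameter table.
#' @param grouping Grouping column (must have exactly 2 levels).
#' @param parameter Parameter column.
#' @param alpha Significance level.
#' @return List with `d` (observed Cohen's d), `n` (group sizes), `power`.
#' @export
post_hoc_power <- function(table, grouping, parameter, alpha = 0.05) {
  g <- base::factor(table[[grouping]])
  if (nlevels(g) != 2) stop("post hoc power needs exactly 2 groups")
  y <- table[[parameter]]
  ok <- !is.na(y)
  y <- y[ok]; g <- droplevels(g[ok])
  ya <- y[g == levels(g)[1]]; yb <- y[g == levels(g)[2]]
  n1 <- length(ya); n2 <- length(yb)
  sp <- sqrt(((n1 - 1) * stats::var(ya) + (n2 - 1) * stats::var(yb)) /
               (n1 + n2 - 2))
  d <- if (sp == 0) 0 else abs(mean(ya) - mean(yb)) / sp
  list(d = d, n = c(n1, n2),
       power = .t_power(n1, n2, d, alpha))
}
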