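#' PCA of spectral curve metrics
#'
#' Principal component analysis of the four curve metrics (peak
#' wavelength, FWHM, AUC, average reflectance) across specimen x region
#' observations, used to assess how reflectance strategies group.
#' Variables are centered and scaled to unit variance (a correlation
#' PCA). Component signs follow a fixed convention: the
#' largest-magnitude loading of each component is made positive, so
#' score plots are reproducible.
#'
#' @param table data frame containing the metric columns and optionally
#'   a grouping column.
#' @param metric_cols names of the metric columns.
#' @param group optional name of a grouping column (or a vector of
#'   labels) used to compute per-group convex hulls of the first two
#'   score dimensions.
#' @return An object of class `"pca_metrics"`: list with `variance_pct`
#'   (sums to 100), `scores`, `loadings`, `sdev`, and `hulls` (per-group
#'   row indices of the PC1/PC2 convex hull, when `group` is given).
#' @export
pca_metrics <- function(table,
                        metric_cols = c("peak_nm", "fwhm_nm",
                                        "auc_pct_nm", "avg_pct"),
                        group = NULL) {
  if (!all(metric_cols %in% names(table)))
    stop("missing metric columns: ",
         paste(setdiff(metric_cols, names(table)), collapse = ", "),
         call. = FALSE)
  x <- as.matrix(table[, metric_cols, drop = FALSE])
  if (nrow(x) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (anyNA(x)) stop("metric table contains missing cells", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance variable: ", metric_cols[which(v == 0)[1]],
         call. = FALSE)
  p <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  # sign convention: dominant loading positive per component
  for (j in seq_len(ncol(p$rotation))) {
    k <- which.max(abs(p$rotation[, j]))
    if (p$rotation[k, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  var_pct <- 100 * p$sdev^2 / sum(p$sdev^2)
  hulls <- NULL
  if (!is.null(group)) {
    labels <- if (length(group) == 1L && is.character(group) &&
                  group %in% names(table)) table[[group]] else group
    hulls <- lapply(split(seq_len(nrow(x)), labels), function(idx) {
      if (length(idx) < 3L) return(idx)
      idx[grDevices::chull(p$x[idx, 1], p$x[idx, 2])]
    })
  }
  structure(list(variance_pct = var_pct, scores = p$x,
                 loadings = p$rotation, sdev = p$sdev, hulls = hulls),
            class = "pca_metrics")
}

#' @export
print.pca_metrics <- function(x, ...) {
  cat("PCA of curve metrics\n")
  cat(sprintf("  PC%d: %5.1f%% of variance\n",
              seq_along(x$variance_pct), x$variance_pct), sep = "")
  invisible(x)
}

#' @export
plot.pca_metrics <- function(x, ...) {
  graphics::plot(x$scores[, 1], x$scores[, 2],
                 xlab = sprintf("PC1 (%.1f%%)", x$variance_pct[1]),
                 ylab = sprintf("PC2 (%.1f%%)", x$variance_pct[2]), ...)
  if (!is.null(x$hulls))
    for (h in x$hulls)
      if (length(h) >= 3L)
        graphics::polygon(x$scores[h, 1], x$scores[h, 2], border = "grey40")
  invisible(x)
}

#' One-way ANOVA with Tukey HSD and compact-letter display
#'
#' Classical between/within decomposition for a single grouping factor
#' (e.g. scaled body reflectance across species), followed by all
#' pairwise Tukey honest-significant-difference comparisons and a
#' compact-letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels.
#' @param alpha significance level for the letter display.
#' @return Object of class `"anova_result"`: list with `table` (term,
#'   df, sum_sq, mean_sq, F, p), `pairwise` (contrast, estimate, raw p,
#'   adjusted p, method), `letters`, `undefined_f` flag.
#' @export
one_way_anova <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) != length(groups))
    stop("'values' and 'groups' lengths differ", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  tab <- data.frame(term = c("group", "Residuals"),
                    df = an$Df, sum_sq = an$`Sum Sq`,
                    mean_sq = an$`Mean Sq`, F = an$`F value`, p = an$`Pr(>F)`)
  all_const <- all(tapply(values, groups, function(v) max(v) == min(v)))
  undefined_f <- !is.finite(tab$mean_sq[2]) || all_const
  pairwise <- NULL; letters <- NULL
  if (!undefined_f) {
    tk <- stats::TukeyHSD(fit)$groups
    cn <- rownames(tk)
    # raw p from the same pooled-MSE t statistic the Tukey q is built on
    mse <- tab$mean_sq[2]; dfe <- tab$df[2]
    ns <- table(groups)
    parts <- strsplit(cn, "-", fixed = TRUE)
    raw_p <- vapply(seq_along(cn), function(i) {
      a <- parts[[i]][1]; b <- parts[[i]][2]
      se <- sqrt(mse * (1 / ns[[a]] + 1 / ns[[b]]))
      2 * stats::pt(abs(tk[i, "diff"]) / se, dfe, lower.tail = FALSE)
    }, numeric(1))
    pairwise <- data.frame(contrast = cn, estimate = tk[, "diff"],
                           p_raw = raw_p,
                           p_adjusted = pmin(pmax(tk[, "p adj"], raw_p), 1),
                           method = "tukey")
    rownames(pairwise) <- NULL
    letters <- compact_letters(pairwise$contrast, pairwise$p_adjusted,
                               levels(groups), alpha = alpha)
  }
  structure(list(table = tab, pairwise = pairwise, letters = letters,
                 undefined_f = undefined_f, alpha = alpha),
            class = "anova_result")
}

# Compact-letter display: connected sets are the maximal cliques of the
# "not significantly different" graph; letters assigned in alphabetical
# group order, ties broken alphabetically.
compact_letters <- function(contrasts, p_adj, group_levels, alpha = 0.05) {
  k <- length(group_levels)
  adj <- matrix(TRUE, k, k, dimnames = list(group_levels, group_levels))
  parts <- strsplit(contrasts, "-", fixed = TRUE)
  for (i in seq_along(contrasts)) {
    if (p_adj[i] < alpha) {
      a <- parts[[i]][1]; b <- parts[[i]][2]
      adj[a, b] <- adj[b, a] <- FALSE
    }
  }
  cliques <- max_cliques(adj)
  # order cliques by their alphabetically first member
  first <- vapply(cliques, function(cl) min(group_levels[cl]), character(1))
  cliques <- cliques[order(first)]
  out <- stats::setNames(rep("", k), group_levels)
  for (ci in seq_along(cliques))
    for (g in cliques[[ci]])
      out[g] <- paste0(out[g], letters[ci])
  out
}

# maximal cliques by simple Bron-Kerbosch (group counts here are tiny)
max_cliques <- function(adj) {
  n <- nrow(adj)
  res <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      res[[length(res) + 1L]] <<- sort(r)
      return(invisible())
    }
    for (v in p) {
      nb <- which(adj[v, ] & seq_len(n) != v)
      bk(c(r, v), intersect(p, nb), intersect(x, nb))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat("ANOVA\n")
  print(x$table, row.names = FALSE, digits = 5)
  if (isTRUE(x$undefined_f))
    cat("F undefined: zero within-group variance everywhere\n")
  if (!is.null(x$letters)) {
    cat("compact letters (alpha = ", x$alpha, "): ", sep = "")
    cat(paste(names(x$letters), x$letters, sep = ":", collapse = "  "), "\n")
  }
  if (!is.null(x$pairwise)) {
    cat("pairwise (", x$pairwise$method[1], "):\n", sep = "")
    print(x$pairwise, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Two-way factorial ANOVA with Bonferroni-corrected contrasts
#'
#' Factorial decomposition of a response (retinal threshold) over two
#' crossed factors — typically stimulus wavelength and a grouping
#' factor (species, strategy, morph, sex) — including their
#' interaction. Type II sums of squares are used so unbalanced designs
#' are handled; on balanced data they coincide with sequential sums of
#' squares. Levels of `factor_a` not observed in every level of
#' `factor_b` are dropped with a warning (some stimulus wavelengths are
#' only tested in a subset of groups). Pairwise contrasts of the
#' grouping factor use unweighted marginal means with the model MSE;
#' when the interaction is significant at `alpha`, within-level simple
#' effects of `factor_b` are added. All contrasts are
#' Bonferroni-adjusted together.
#'
#' @param response numeric response.
#' @param factor_a first factor (e.g. wavelength).
#' @param factor_b second, grouping factor (e.g. morph).
#' @param alpha significance level driving the simple-effects rule.
#' @return Object of class `"anova_result"` with elements `table`,
#'   `pairwise`, `dropped_levels`, `alpha`.
#' @export
two_way_anova <- function(response, factor_a, factor_b, alpha = 0.05) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stop("both factors need at least 2 levels", call. = FALSE)
  tab <- table(fa, fb)
  incomplete <- rownames(tab)[apply(tab == 0, 1, any)]
  if (length(incomplete)) {
    warning("dropping level(s) of the first factor absent from some cells: ",
            paste(incomplete, collapse = ", "))
    keep <- !(fa %in% incomplete)
    response <- response[keep]; fa <- droplevels(fa[keep]); fb <- droplevels(fb[keep])
    if (nlevels(fa) < 2L)
      stop("fewer than 2 complete levels remain", call. = FALSE)
  }
  d <- data.frame(y = response, A = fa, B = fb)
  fit <- stats::lm(y ~ A * B, data = d)
  a2 <- tryCatch(car::Anova(fit, type = 2), error = function(e) NULL)
  if (!is.null(a2)) {
    an <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                     df = a2$Df, sum_sq = a2$`Sum Sq`)
    an$mean_sq <- an$sum_sq / an$df
    an$F <- c(a2$`F value`[1:3], NA)
    an$p <- c(a2$`Pr(>F)`[1:3], NA)
  } else {
    # degenerate (zero-residual) designs: Type II SS by explicit model
    # comparison; F is undefined when the residual mean square vanishes
    rss <- function(fm) sum(stats::resid(stats::lm(fm, data = d))^2)
    r_add <- rss(y ~ A + B); r_full <- rss(y ~ A * B)
    ss <- c(A = rss(y ~ B) - r_add, B = rss(y ~ A) - r_add,
            `A:B` = r_add - r_full, Residuals = r_full)
    dfs <- c(nlevels(fa) - 1L, nlevels(fb) - 1L,
             (nlevels(fa) - 1L) * (nlevels(fb) - 1L),
             stats::df.residual(fit))
    an <- data.frame(term = c("A", "B", "A:B", "Residuals"),
                     df = dfs, sum_sq = pmax(ss, 0))
    an$mean_sq <- an$sum_sq / an$df
    an$F <- NA_real_
    an$p <- NA_real_
  }

  mse <- an$mean_sq[an$term == "Residuals"]
  dfe <- an$df[an$term == "Residuals"]
  cell_mean <- tapply(d$y, list(d$A, d$B), mean)
  cell_n <- table(d$A, d$B)
  la <- levels(fa); lb <- levels(fb)

  contrasts <- list()
  # marginal contrasts of the grouping factor (unweighted cell means)
  for (i in seq_along(lb)) for (j in seq_along(lb)) if (i < j) {
    est <- mean(cell_mean[, i]) - mean(cell_mean[, j])
    se <- sqrt(mse * sum(1 / cell_n[, i] + 1 / cell_n[, j]) / length(la)^2)
    contrasts[[length(contrasts) + 1L]] <- data.frame(
      contrast = paste0(lb[i], "-", lb[j]), level = "marginal",
      estimate = est, se = se)
  }
  interaction_p <- an$p[an$term == "A:B"]
  if (is.finite(interaction_p) && interaction_p < alpha) {
    for (a in la) for (i in seq_along(lb)) for (j in seq_along(lb)) if (i < j) {
      est <- cell_mean[a, i] - cell_mean[a, j]
      se <- sqrt(mse * (1 / cell_n[a, i] + 1 / cell_n[a, j]))
      contrasts[[length(contrasts) + 1L]] <- data.frame(
        contrast = paste0(lb[i], "-", lb[j], " @ ", a), level = a,
        estimate = est, se = se)
    }
  }
  pw <- do.call(rbind, contrasts)
  pw$t <- pw$estimate / pw$se
  pw$p_raw <- 2 * stats::pt(abs(pw$t), dfe, lower.tail = FALSE)
  pw$p_adjusted <- stats::p.adjust(pw$p_raw, method = "bonferroni")
  pw$method <- "bonferroni"
  rownames(pw) <- NULL

  structure(list(table = an, pairwise = pw,
                 dropped_levels = incomplete, alpha = alpha,
                 interaction_p = interaction_p),
            class = "anova_result")
}

#' Variance-homogeneity and normality checks
#'
#' The assumption screen run before parametric comparisons: Levene's
#' test on absolute deviations from group means for homogeneity of
#' variance, and a per-group normality test — by default the
#' Lilliefors-corrected Kolmogorov-Smirnov test (the appropriate null
#' when the normal's moments are estimated from the sample); a naive KS
#' against the sample moments is available for comparison.
#'
#' @param values numeric response.
#' @param groups group labels.
#' @param normality `"lilliefors"` (default) or `"ks_naive"`.
#' @return List with `levene` (`statistic`, `p`, `df`), `normality`
#'   (per-group data frame with `group`, `n`, `statistic`, `p`,
#'   `degenerate`), and `method`.
#' @export
assumption_checks <- function(values, groups,
                              normality = c("lilliefors", "ks_naive")) {
  normality <- match.arg(normality)
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop("Levene's test needs at least 2 groups", call. = FALSE)
  dev_by_group <- tapply(values, groups, function(v) any(v != v[1]))
  if (!all(dev_by_group)) {
    lev <- list(statistic = NA_real_, p = NA_real_, df = c(NA, NA),
                degenerate = TRUE)
  } else {
    lv <- car::leveneTest(values ~ groups, center = mean)
    lev <- list(statistic = lv$`F value`[1], p = lv$`Pr(>F)`[1],
                df = lv$Df, degenerate = FALSE)
  }
  nt <- do.call(rbind, lapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(v) < 4L || stats::sd(v) == 0)
      return(data.frame(group = g, n = length(v), statistic = NA_real_,
                        p = NA_real_, degenerate = TRUE))
    r <- if (normality == "lilliefors") nortest::lillie.test(v)
         else suppressWarnings(stats::ks.test(v, "pnorm", mean(v), stats::sd(v)))
    data.frame(group = g, n = length(v),
               statistic = unname(r$statistic), p = r$p.value,
               degenerate = FALSE)
  }))
  rownames(nt) <- NULL
  list(levene = lev, normality = nt, method = normality)
}

#' Matched-filter comparison of tuning curve and dorsal reflectance
#'
#' Under the matched-filter hypothesis a receiver's spectral
#' sensitivity tracks the spectrum of the signal it must detect. For
#' each group this report juxtaposes the stimulus wavelength of minimum
#' mean threshold (maximum retinal sensitivity, among the tested
#' stimuli) with the wavelength of peak mean dorsal reflectance
#' (continuous, from the summary curve), and their absolute mismatch in
#' nm. No significance claim is attached.
#'
#' @param tuning a [build_tuning_curve()] data frame (>= 3 wavelengths
#'   per group).
#' @param dorsal_summary a [summarize_group()] data frame of dorsal
#'   reflectance (`group`, `wavelength_nm`, `mean_pct`); its wavelength
#'   range must cover the tuning wavelengths.
#' @return Data frame `group`, `sensitivity_peak_nm`,
#'   `reflectance_peak_nm`, `mismatch_nm`.
#' @export
matched_filter_report <- function(tuning, dorsal_summary) {
  shared <- intersect(unique(tuning$group), unique(dorsal_summary$group))
  if (!length(shared))
    stop("no group appears in both inputs", call. = FALSE)
  out <- do.call(rbind, lapply(shared, function(g) {
    tn <- tuning[tuning$group == g, ]
    rf <- dorsal_summary[dorsal_summary$group == g, ]
    if (nrow(tn) < 3L)
      stop("tuning curve for group ", g, " has fewer than 3 wavelengths",
           call. = FALSE)
    if (min(tn$wavelength_nm) < min(rf$wavelength_nm) ||
        max(tn$wavelength_nm) > max(rf$wavelength_nm))
      stop("reflectance curve for group ", g,
           " does not cover the tuning wavelengths", call. = FALSE)
    sens <- tn$wavelength_nm[which.min(tn$mean_threshold)]
    refl <- rf$wavelength_nm[which.max(rf$mean_pct)]
    data.frame(group = g, sensitivity_peak_nm = sens,
               reflectance_peak_nm = refl,
               mismatch_nm = abs(refl - sens))
  }))
  rownames(out) <- NULL
  out
}
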