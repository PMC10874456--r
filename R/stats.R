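#' Spearman rank correlation
#'
#' Midrank-based Spearman correlation with a two-sided p-value
#' (exact/AS 89 for small samples without ties, t approximation
#' otherwise, as in [stats::cor.test()]). Pairs with missing values are
#' dropped. A variable with zero rank variance yields `rho = 0` flagged
#' as degenerate.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with `rho`, `p_value`, `n`, `degenerate`.
#' @export
spearman_cor <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("spearman_cor(): need >= 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = 0, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n,
       degenerate = FALSE)
}

# Dunn's post-hoc test after Kruskal-Wallis: pairwise z statistics on
# pooled midranks with tie correction, Bonferroni-adjusted.
dunn_posthoc <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  lv <- levels(groups)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  rbar <- tapply(r, groups, mean)
  ni <- tapply(r, groups, length)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_)
  for (k in seq_len(m)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ni[[a]] + 1 / ni[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    out$z[k] <- z
    out$p_raw[k] <- 2 * pnorm(-abs(z))
  }
  out$p_adj <- pmin(out$p_raw * m, 1)
  out
}

#' Compare a measure across groups
#'
#' Routes between the parametric and non-parametric family by normality:
#' if every group passes the Shapiro-Wilk test at `normality_alpha`, a
#' one-way ANOVA with Tukey's HSD is used; otherwise a Kruskal-Wallis test
#' with Dunn's post-hoc comparisons (Bonferroni-adjusted). Groups with
#' fewer than 3 observations are excluded with a warning; a constant group
#' routes to the non-parametric branch. The method actually used is always
#' recorded.
#'
#' @param values Numeric vector.
#' @param group_labels Group labels, same length.
#' @param normality_alpha Shapiro-Wilk alpha (default 0.05).
#' @return List with `method` (`"anova_tukey"` or `"kruskal_dunn"`),
#'   `omnibus` (test name, statistic, p-value) and `pairwise`
#'   (`data.frame` with one row per group pair and adjusted p-values).
#' @export
compare_groups <- function(values, group_labels, normality_alpha = 0.05) {
  keep <- is.finite(values) & !is.na(group_labels)
  values <- values[keep]
  groups <- factor(group_labels[keep])
  sizes <- table(groups)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning(sprintf("compare_groups(): excluding group(s) with n < 3: %s",
                    paste(small, collapse = ", ")))
    keep2 <- !(as.character(groups) %in% small)
    values <- values[keep2]
    groups <- droplevels(groups[keep2])
  }
  if (nlevels(groups) < 2) {
    stop("compare_groups(): fewer than 2 groups with n >= 3", call. = FALSE)
  }
  normal <- vapply(levels(groups), function(g) {
    v <- values[groups == g]
    if (length(unique(v)) < 2 || length(v) > 5000) return(FALSE)
    shapiro.test(v)$p.value > normality_alpha
  }, logical(1))
  if (all(normal)) {
    fit <- aov(values ~ groups)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$groups
    pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    list(method = "anova_tukey",
         omnibus = list(test = "one-way ANOVA", statistic = an[1, "F value"],
                        p_value = an[1, "Pr(>F)"]),
         pairwise = data.frame(group_a = pairs[, 2], group_b = pairs[, 1],
                               p_adj = unname(tk[, "p adj"])))
  } else {
    kw <- kruskal.test(values, groups)
    dn <- dunn_posthoc(values, groups)
    list(method = "kruskal_dunn",
         omnibus = list(test = "Kruskal-Wallis",
                        statistic = unname(kw$statistic),
                        p_value = kw$p.value),
         pairwise = dn[, c("group_a", "group_b", "p_adj")])
  }
}

#' Margin-versus-focus comparison of one measure
#'
#' Compares a measure between resection-margin and fibrotic-focus records
#' of a cohort: an unpaired t-test when both samples pass Shapiro-Wilk,
#' otherwise a Mann-Whitney U test. Also returns the per-patient
#' difference `delta = focus - margin` for every fully paired patient;
#' incompletely paired patients are counted in a warning.
#'
#' @param tbl Cohort `data.frame` (see [validate_cohort()]).
#' @param measure Column name to compare.
#' @return List with `method`, `p_value`, `statistic`, `mean_margin`,
#'   `mean_focus`, and `deltas` (`data.frame` with `patient_id`, `measure`,
#'   `delta`).
#' @export
compare_two_paired_locations <- function(tbl, measure) {
  tbl <- validate_cohort(tbl)
  if (!measure %in% names(tbl)) {
    stop(sprintf("measure '%s' not present in the cohort table", measure),
         call. = FALSE)
  }
  vm <- tbl[[measure]][tbl$location == "margin"]
  vf <- tbl[[measure]][tbl$location == "focus"]
  vm <- vm[is.finite(vm)]; vf <- vf[is.finite(vf)]
  if (length(vm) < 3 || length(vf) < 3) {
    stop("compare_two_paired_locations(): need >= 3 values per location",
         call. = FALSE)
  }
  normal_ok <- function(v) length(unique(v)) >= 2 && length(v) <= 5000 &&
    shapiro.test(v)$p.value > 0.05
  if (normal_ok(vm) && normal_ok(vf)) {
    tst <- t.test(vf, vm)
    method <- "t_test"
  } else {
    tst <- suppressWarnings(wilcox.test(vf, vm))
    method <- "mann_whitney"
  }
  pid <- paired_patients(tbl)
  all_pid <- unique(tbl$patient_id)
  unpaired <- setdiff(all_pid, pid)
  deltas <- data.frame(patient_id = character(0), measure = character(0),
                       delta = numeric(0))
  for (id in pid) {
    m <- tbl[[measure]][tbl$patient_id == id & tbl$location == "margin"]
    f <- tbl[[measure]][tbl$patient_id == id & tbl$location == "focus"]
    if (length(m) == 1 && length(f) == 1 && is.finite(m) && is.finite(f)) {
      deltas <- rbind(deltas, data.frame(patient_id = id, measure = measure,
                                         delta = f - m))
    } else {
      unpaired <- c(unpaired, id)
    }
  }
  if (length(unpaired)) {
    warning(sprintf(
      "compare_two_paired_locations(): %d patient(s) without a complete %s",
      length(unique(unpaired)), "margin/focus pair excluded from deltas"))
  }
  list(method = method, p_value = tst$p.value,
       statistic = unname(tst$statistic),
       mean_margin = mean(vm), mean_focus = mean(vf), deltas = deltas)
}

#' Per-patient discrimination check
#'
#' A measure "discriminates" the fibrotic focus from the resection margin
#' when its per-patient difference `delta = focus - margin` is strictly
#' positive for every patient; ties count as violations.
#'
#' @param deltas `data.frame` with a `delta` column (as produced by
#'   [compare_two_paired_locations()]), or a numeric vector of deltas.
#' @return List with `discriminates` (logical) and `violations` (count of
#'   non-positive deltas).
#' @export
discrimination_check <- function(deltas) {
  d <- if (is.data.frame(deltas)) deltas$delta else deltas
  if (!length(d)) stop("discrimination_check(): no paired patients",
                       call. = FALSE)
  violations <- sum(d <= 0)
  list(discriminates = violations == 0L, violations = violations)
}

#' qPCR relative expression
#'
#' `2^-(ct_target - ct_reference)` — the standard delta-CT relative
#' expression of a target gene normalized to a reference gene.
#'
#' @param ct_target,ct_reference Cycle thresholds.
#' @return Relative expression, `> 0`.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference))) {
    stop("relative_expression(): non-finite CT value", call. = FALSE)
  }
  2^(-(ct_target - ct_reference))
}

#' Collagen I / collagen III expression ratio
#'
#' @param col1a1,col3a1 Relative expression values (`2^-dCT`).
#' @return `col1a1 / col3a1`.
#' @export
collagen_ratio <- function(col1a1, col3a1) {
  if (any(!is.finite(col3a1)) || any(col3a1 == 0)) {
    stop("collagen_ratio(): col3a1 expression must be finite and non-zero",
         call. = FALSE)
  }
  col1a1 / col3a1
}

#' Full cohort statistics report
#'
#' Runs the complete validation analysis on a cohort table: all pairwise
#' Spearman correlations among the available measures, group comparisons
#' of each measure across fibrosis grades, and margin/focus comparisons
#' with the per-patient delta discrimination check. The result serializes
#' directly to JSON.
#'
#' @param tbl Cohort `data.frame`.
#' @param measures Measure columns to analyze; defaults to every standard
#'   measurement column present in the table.
#' @return List with elements `correlations`, `group_comparisons`,
#'   `location_comparisons`, `n_patients`, `n_records`.
#' @export
stats_report <- function(tbl,
                         measures = intersect(
                           c("fibrosis_score", "fractal_dimension",
                             "lacunarity", "ecm_fraction",
                             "alignment_score", "color_score",
                             "col1a1_expr", "col3a1_expr"),
                           names(tbl))) {
  tbl <- validate_cohort(tbl)
  cors <- list()
  if (length(measures) >= 2) {
    cmb <- utils::combn(measures, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      res <- tryCatch(spearman_cor(tbl[[a]], tbl[[b]]),
                      error = function(e) NULL)
      if (!is.null(res)) cors[[paste(a, b, sep = "_vs_")]] <- res
    }
  }
  grp <- list()
  for (m in setdiff(measures, "fibrosis_score")) {
    grp[[m]] <- tryCatch(
      suppressWarnings(compare_groups(tbl[[m]], tbl$fibrosis_score)),
      error = function(e) list(error = conditionMessage(e)))
  }
  loc <- list()
  for (m in setdiff(measures, character(0))) {
    res <- tryCatch(
      suppressWarnings(compare_two_paired_locations(tbl, m)),
      error = function(e) NULL)
    if (is.null(res)) next
    disc <- tryCatch(discrimination_check(res$deltas),
                     error = function(e) NULL)
    loc[[m]] <- list(method = res$method, p_value = res$p_value,
                     mean_margin = res$mean_margin,
                     mean_focus = res$mean_focus,
                     deltas = res$deltas$delta,
                     discriminates = disc$discriminates,
                     violations = disc$violations)
  }
  list(n_patients = length(unique(tbl$patient_id)),
       n_records = nrow(tbl),
       correlations = cors,
       group_comparisons = grp,
       location_comparisons = loc)
}
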