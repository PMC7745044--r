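# Statistical comparison layer: mixed-design ANOVAs with partial eta
# squared, paired / independent t tests with Cohen's d, Benjamini-Hochberg
# FDR adjustment, and Pearson correlation of per-subject state-change
# scores.
#
# The study table is long format: one row per
# (subject, group, state[, region], index) with a numeric `value`.

validate_study_table <- function(table, regions = FALSE) {
  need <- c("subject", "group", "state", "index", "value")
  if (regions) need <- c(need, "region")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("study table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(table$value)) stop("value column must be numeric")
  invisible(table)
}

#' Mixed-design ANOVA
#'
#' Two-way (group between-subjects, state within-subjects) or three-way
#' (adding region, within-subjects) mixed ANOVA on one index of a long
#' study table, via `aov()` with the appropriate error strata. Effect
#' sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error_of_stratum)`. Requires a complete
#' balanced design (every subject observed in every within-subject cell).
#'
#' @param table Long data frame with columns `subject`, `group`, `state`,
#'   optionally `region`, `index`, `value`.
#' @param index Which index to analyze (default: the only one present).
#' @param factors 2 (group x state) or 3 (group x state x region).
#' @return Data frame: one row per effect with `effect`, `df1`, `df2`,
#'   `F`, `p`, `pes` (partial eta squared).
#' @export
mixed_anova <- function(table, index = NULL, factors = 2) {
  validate_study_table(table, regions = factors == 3)
  if (is.null(index)) {
    index <- unique(table$index)
    if (length(index) != 1)
      stop("several indices present; pick one via `index`")
  }
  d <- table[table$index == index, , drop = FALSE]
  if (!nrow(d)) stop("no rows for index ", index)
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$state <- factor(d$state)
  within <- "state"
  if (factors == 3) {
    d$region <- factor(d$region)
    within <- c("state", "region")
  }
  cell_factor <- interaction(lapply(within, function(v) d[[v]]), drop = FALSE)
  cells <- table(d$subject, cell_factor)
  if (any(cells != 1)) {
    bad <- which(cells != 1, arr.ind = TRUE)[1, ]
    stop("design incomplete or duplicated: subject ",
         levels(d$subject)[bad[1]], " does not have exactly one value per cell")
  }
  fml <- if (factors == 2)
    value ~ group * state + Error(subject / state)
  else
    value ~ group * state * region + Error(subject / (state * region))
  fit <- stats::aov(fml, data = d)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    rn <- trimws(rownames(tab))
    resid_row <- which(rn == "Residuals")
    ss_err <- tab[resid_row, "Sum Sq"]
    df_err <- tab[resid_row, "Df"]
    for (r in setdiff(seq_len(nrow(tab)), resid_row)) {
      out[[length(out) + 1L]] <- data.frame(
        effect = gsub(":", " x ", rn[r]),
        df1 = tab[r, "Df"], df2 = df_err,
        F = tab[r, "F value"], p = tab[r, "Pr(>F)"],
        pes = tab[r, "Sum Sq"] / (tab[r, "Sum Sq"] + ss_err),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simple-effects follow-up
#'
#' Splits the table on one factor and reruns the mixed (or one-way
#' repeated-measures) ANOVA within each level, the usual follow-up to a
#' significant interaction.
#'
#' @param table Long study table (see [mixed_anova()]).
#' @param split_by Factor column to split on (e.g. `"group"`).
#' @param index Index to analyze.
#' @param factors Factors of the ANOVA run within each level: 2 requires
#'   both `group` and `state` to remain; use `factors = 1` for a one-way
#'   repeated-measures ANOVA on `state`.
#' @return Named list of result data frames, one per level.
#' @export
simple_effects <- function(table, split_by, index = NULL, factors = 1) {
  validate_study_table(table)
  lv <- unique(table[[split_by]])
  out <- list()
  for (l in lv) {
    d <- table[table[[split_by]] == l, , drop = FALSE]
    if (factors >= 2) {
      out[[as.character(l)]] <- mixed_anova(d, index = index,
                                            factors = factors)
    } else {
      if (is.null(index)) index <- unique(d$index)[1]
      di <- d[d$index == index, , drop = FALSE]
      di$subject <- factor(di$subject); di$state <- factor(di$state)
      fit <- stats::aov(value ~ state + Error(subject / state), data = di)
      s <- summary(fit)
      tab <- s[[length(s)]][[1]]
      rr <- which(trimws(rownames(tab)) == "Residuals")
      er <- which(trimws(rownames(tab)) == "state")
      out[[as.character(l)]] <- data.frame(
        effect = "state", df1 = tab[er, "Df"], df2 = tab[rr, "Df"],
        F = tab[er, "F value"], p = tab[er, "Pr(>F)"],
        pes = tab[er, "Sum Sq"] / (tab[er, "Sum Sq"] + tab[rr, "Sum Sq"]),
        stringsAsFactors = FALSE)
    }
  }
  out
}

#' Paired t test with Cohen's d
#'
#' @param x,y Paired numeric vectors (same subjects, two conditions).
#' @return Data frame with `t`, `df`, `p`, `d` (Cohen's d =
#'   `mean(diff) / sd(diff)`), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  dd <- x - y
  if (stats::sd(dd) == 0)
    stop("zero variance of paired differences; t test undefined")
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = mean(dd) / stats::sd(dd),
             mean_diff = mean(dd))
}

#' Independent-samples t test with Cohen's d (pooled SD)
#'
#' @param x,y Numeric vectors from two disjoint groups.
#' @return Data frame with `t`, `df`, `p`, `d`, `mean_diff`.
#' @export
independent_t <- function(x, y) {
  if (stats::sd(c(x, y)) == 0) stop("zero variance; t test undefined")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, d = (mean(x) - mean(y)) / sp,
             mean_diff = mean(x) - mean(y))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values with monotonicity enforcement; input order
#' preserved.
#'
#' @param pvals Numeric vector of raw p values in `[0, 1]`.
#' @return Numeric vector of adjusted p values, same order.
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Correlation of per-subject state-change scores
#'
#' For each subject, computes the change `value(state_a) - value(state_b)`
#' of two indices, then the Pearson correlation of those changes across
#' subjects (groups pooled).
#'
#' @param table Long study table with both indices in both states per
#'   subject (use the `region == "global"` slice for regional tables).
#' @param index_x,index_y Index names, e.g. `"RMSSD"` and `"SMP"`.
#' @param states Length-2 character, change = first minus second
#'   (default `c("affective", "neutral")`).
#' @return Data frame with `r`, `t`, `df`, `p`, `n`.
#' @export
delta_correlation <- function(table, index_x, index_y,
                              states = c("affective", "neutral")) {
  validate_study_table(table)
  delta_of <- function(idx) {
    d <- table[table$index == idx, , drop = FALSE]
    if (!nrow(d)) stop("no rows for index ", idx)
    a <- d[d$state == states[1], ]; b <- d[d$state == states[2], ]
    if (!nrow(a) || !nrow(b))
      stop("missing state level for index ", idx)
    m <- merge(a[, c("subject", "value")], b[, c("subject", "value")],
               by = "subject", suffixes = c("_a", "_b"))
    stats::setNames(m$value_a - m$value_b, m$subject)
  }
  dx <- delta_of(index_x); dy <- delta_of(index_y)
  common <- intersect(names(dx), names(dy))
  if (length(common) < 3) stop("fewer than 3 subjects with both indices")
  dx <- dx[common]; dy <- dy[common]
  if (stats::sd(dx) == 0 || stats::sd(dy) == 0)
    stop("zero-variance change score; correlation undefined")
  ct <- stats::cor.test(dx, dy, method = "pearson")
  data.frame(r = unname(ct$estimate), t = unname(ct$statistic),
             df = unname(ct$parameter), p = ct$p.value,
             n = length(common))
}

#' Pairwise-comparison table with FDR adjustment
#'
#' Runs the within-group paired (state) contrasts and between-group
#' independent contrasts for one index and adjusts the resulting p values
#' as one family.
#'
#' @param table Long study table.
#' @param index Index to compare.
#' @param states Length-2 character of state levels.
#' @return Data frame: one row per contrast with `contrast`, `t`, `df`,
#'   `p`, `p_fdr`, `d`.
#' @export
pairwise_comparisons <- function(table, index,
                                 states = c("affective", "neutral")) {
  validate_study_table(table)
  d <- table[table$index == index, , drop = FALSE]
  groups <- unique(d$group)
  rows <- list()
  for (g in groups) {
    dg <- d[d$group == g, ]
    m <- merge(dg[dg$state == states[1], c("subject", "value")],
               dg[dg$state == states[2], c("subject", "value")],
               by = "subject")
    r <- paired_t(m$value.x, m$value.y)
    r$contrast <- sprintf("%s: %s vs %s", g, states[1], states[2])
    rows[[length(rows) + 1L]] <- r
  }
  if (length(groups) == 2) {
    for (s in states) {
      ds <- d[d$state == s, ]
      r <- independent_t(ds$value[ds$group == groups[1]],
                         ds$value[ds$group == groups[2]])
      r$contrast <- sprintf("%s: %s vs %s", s, groups[1], groups[2])
      rows[[length(rows) + 1L]] <- r
    }
  }
  res <- do.call(rbind, rows)
  res$p_fdr <- bh_fdr(res$p)
  res[, c("contrast", "t", "df", "p", "p_fdr", "d")]
}
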