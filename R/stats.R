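#' Significance stars
#'
#' The figure-legend convention: "ns" for p > 0.05, then "*", "**", "***",
#' "****" for p below 0.05, 0.01, 0.001 and 0.0001 respectively. Boundary
#' values (exactly 0.05, 0.01, ...) take the less significant label, since
#' the convention's strict inequalities leave them unassigned.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Character vector of labels.
#' @examples
#' starAnnotation(c(0.5, 0.03, 0.002, 5e-5))
#' @export
starAnnotation <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  # left-closed intervals put each boundary value in the less significant bin
  as.character(cut(p, breaks = c(-Inf, 0.0001, 0.001, 0.01, 0.05, Inf),
                   labels = c("****", "***", "**", "*", "ns"),
                   right = FALSE))
}

#' Unpaired two-sample t test on per-fish totals
#'
#' Student's pooled-variance t test (the Prism default for "unpaired t
#' test"), two-sided, used for total cell numbers between control and
#' ablated groups. Welch's correction is available via \code{varEqual =
#' FALSE}. Groups with zero pooled variance and equal means report t = 0,
#' p = 1; zero variance with unequal means is an error.
#'
#' @param x,y numeric vectors of per-fish totals for the two groups
#'   (each n >= 2).
#' @param varEqual pool the variances (default TRUE).
#' @return data.frame (one row): test, statistic, df, p_value, stars, plus
#'   the group means and the estimated percent reduction of \code{y}
#'   relative to \code{x}.
#' @examples
#' unpairedTTest(c(10, 12, 14), c(4, 6, 8))
#' @export
unpairedTTest <- function(x, y, varEqual = TRUE) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      t <- 0; df <- length(x) + length(y) - 2L; p <- 1
    } else {
      stopf("zero variance in both groups with unequal means")
    }
  } else {
    fit <- stats::t.test(x, y, var.equal = varEqual)
    t <- unname(fit$statistic); df <- unname(fit$parameter)
    p <- fit$p.value
  }
  data.frame(
    test = if (varEqual) "unpaired t (pooled)" else "unpaired t (Welch)",
    statistic = t, df = df, p_value = p, stars = starAnnotation(p),
    mean_x = mean(x), mean_y = mean(y),
    reduction_pct = 100 * (1 - mean(y) / mean(x))
  )
}

#' Two-way ANOVA on regional counts
#'
#' Fits count ~ group * quarter by least squares and reports sums of
#' squares, F and p for the group main effect, the quarter main effect and
#' their interaction, as used for the regional ablation comparisons. For
#' balanced tables the decomposition is exact (SS_total = SS_group +
#' SS_quarter + SS_interaction + SS_error); unbalanced tables use Type-II
#' sums of squares by default (Type III available). A table with no
#' variance at all reports F = 0, p = 1 by convention.
#'
#' @param table long-format count table for one subtype: columns
#'   \code{group}, \code{quarter}, \code{count}.
#' @param type \code{"II"} (default) or \code{"III"} sums of squares for
#'   unbalanced data.
#' @return data.frame with rows group, quarter, group:quarter, Residuals;
#'   columns effect, df, sum_sq, mean_sq, statistic, p_value, stars.
#' @export
twoWayANOVA <- function(table, type = c("II", "III")) {
  type <- match.arg(type)
  table$group <- factor(table$group)
  table$quarter <- factor(table$quarter)
  if (nlevels(table$group) < 2L || nlevels(table$quarter) < 2L)
    stopf("both factors need at least 2 levels")
  cells <- base::table(table$group, table$quarter)
  if (any(cells == 0L)) {
    bad <- which(cells == 0L, arr.ind = TRUE)[1L, ]
    stopf("empty design cell: group %s, quarter %s",
          rownames(cells)[bad[1L]], colnames(cells)[bad[2L]])
  }
  if (stats::var(table$count) == 0) {
    out <- data.frame(
      effect = c("group", "quarter", "group:quarter", "Residuals"),
      df = c(nlevels(table$group) - 1L, nlevels(table$quarter) - 1L,
             (nlevels(table$group) - 1L) * (nlevels(table$quarter) - 1L),
             nrow(table) - nlevels(table$group) * nlevels(table$quarter)),
      sum_sq = 0, mean_sq = 0, statistic = c(0, 0, 0, NA),
      p_value = c(1, 1, 1, NA)
    )
    out$stars <- c(starAnnotation(out$p_value[1:3]), NA)
    return(out)
  }
  fit <- stats::lm(count ~ group * quarter, data = table,
                   contrasts = list(group = "contr.sum",
                                    quarter = "contr.sum"))
  rss <- sum(stats::residuals(fit)^2)
  if (rss < 1e-10 * sum((table$count - mean(table$count))^2)) {
    # a saturated fit (cells internally constant): SS still decompose, but
    # F is degenerate; report Inf/0 or 0/1 per effect by convention
    a1 <- suppressWarnings(stats::anova(fit))
    ss <- a1$`Sum Sq`
    out <- data.frame(
      effect = c("group", "quarter", "group:quarter", "Residuals"),
      df = a1$Df, sum_sq = ss, mean_sq = ss / a1$Df,
      statistic = c(ifelse(ss[1:3] > 1e-12, Inf, 0), NA),
      p_value = c(ifelse(ss[1:3] > 1e-12, 0, 1), NA)
    )
    out$stars <- c(starAnnotation(out$p_value[1:3]), NA)
    return(out)
  }
  an <- car::Anova(fit, type = type)
  an <- as.data.frame(an)
  effects <- rownames(an)
  out <- data.frame(
    effect = sub("group:quarter", "group:quarter", effects),
    df = an$Df, sum_sq = an$`Sum Sq`,
    mean_sq = an$`Sum Sq` / an$Df,
    statistic = an$`F value`, p_value = an$`Pr(>F)`
  )
  if (type == "III") out <- out[out$effect != "(Intercept)", ]
  resid <- out$effect == "Residuals"
  out$stars <- NA_character_
  out$stars[!resid] <- starAnnotation(out$p_value[!resid])
  rownames(out) <- NULL
  out
}

#' Tukey's multiple comparisons after ANOVA
#'
#' All pairwise mean differences for one factor of the two-way design, with
#' adjusted p-values from the studentized range distribution using the
#' ANOVA's mean-square error and residual degrees of freedom. With two
#' levels the adjusted p equals the F-test p for that effect (q^2 = F).
#'
#' @param table long-format count table (columns group, quarter, count).
#' @param effect which factor to compare: \code{"group"},
#'   \code{"quarter"}, or \code{"group:quarter"} for all cell-wise pairs.
#' @return data.frame: comparison, diff, lwr, upr, p_adj, stars.
#' @export
tukeyHSD <- function(table, effect = c("group", "quarter",
                                       "group:quarter")) {
  effect <- match.arg(effect)
  table$group <- factor(table$group)
  table$quarter <- factor(table$quarter)
  fit <- stats::aov(count ~ group * quarter, data = table)
  tk <- stats::TukeyHSD(fit, which = effect)[[effect]]
  out <- data.frame(
    comparison = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
    upr = tk[, "upr"], p_adj = tk[, "p adj"]
  )
  out$stars <- starAnnotation(pmin(1, pmax(0, out$p_adj)))
  rownames(out) <- NULL
  out
}

#' Per-fish totals from a long count table
#'
#' Sums counts over quarters (optionally after [excludeRegion()]) to give
#' one total per fish for the t test.
#'
#' @param table long count table (fish_id, group, subtype, quarter, count).
#' @param subtype optional subtype to restrict to.
#' @return data.frame: fish_id, group, total.
#' @export
fishTotals <- function(table, subtype = NULL) {
  if (!is.null(subtype)) table <- table[table$subtype == subtype, ]
  agg <- stats::aggregate(count ~ fish_id + group, data = table, FUN = sum)
  names(agg)[names(agg) == "count"] <- "total"
  agg[order(agg$group, agg$fish_id), ]
}
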