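# Group-level statistics: per-speaker aggregation, normality gate, dyadic
# correlation, mixed-design contrasts with permutation inference, and
# false-discovery-rate adjustment.
#
# Primary inference on group contrasts is permutation-based (group labels
# shuffled across units with each unit's within-factor profile kept
# intact), with a Greenhouse-Geisser-corrected repeated-measures ANOVA
# reported alongside for comparability with conventional mixed ANOVA
# output. Alpha is 0.05 throughout; one-tailed tests only where the
# scientific hypothesis is directional (the dyad correlation).

stat_result <- function(test_name, statistic, p_value, effect_size = NA_real_,
                        tails = "two", adjusted_p = NA_real_, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic,
                   p_value = p_value, effect_size = effect_size,
                   tails = tails, adjusted_p = adjusted_p), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<%s: stat %.4g, p %.4g%s%s>\n", x$test_name, x$statistic,
              x$p_value,
              if (!is.na(x$adjusted_p)) sprintf(", adj p %.4g", x$adjusted_p) else "",
              if (!is.na(x$effect_size)) sprintf(", effect %.3g", x$effect_size) else ""))
  invisible(x)
}

#' Average features per speaker
#'
#' Collapses a per-sample feature table to one row per
#' `speaker_id x direction_label`, averaging every numeric feature column.
#'
#' @param table data frame with `speaker_id`, `direction_label` and numeric
#'   feature columns.
#' @return aggregated data frame.
#' @export
speaker_average <- function(table) {
  stopifnot(all(c("speaker_id", "direction_label") %in% names(table)))
  num <- names(table)[vapply(table, is.numeric, logical(1))]
  stats::aggregate(table[num],
                   by = list(speaker_id = table$speaker_id,
                             direction_label = table$direction_label),
                   FUN = mean)
}

#' Shapiro-Wilk normality gate
#'
#' @param values numeric vector, n >= 3, non-constant.
#' @return a `stat_result` with W and p; downstream correlation methods
#'   should go rank-based when `p_value < 0.05`.
#' @export
normality_gate <- function(values) {
  if (length(values) < 3) stop("Shapiro-Wilk requires n >= 3")
  if (sd_pop(values) == 0) stop("constant input: normality test undefined")
  sw <- stats::shapiro.test(values)
  stat_result("shapiro_wilk", unname(sw$statistic), sw$p.value)
}

#' One-tailed dyadic correlation between questioner and respondent
#'
#' Tests for a positive association between per-dyad questioner and
#' respondent feature values. With `method = "auto"` the margins are gated
#' through Shapiro-Wilk: if either departs from normality (p < 0.05) the
#' rank-based Spearman test is used, else Pearson. For n <= 10 the Spearman
#' p comes from the exact permutation distribution of the rank statistic;
#' larger n use the asymptotic approximation.
#'
#' @param questioner_values,respondent_values paired per-dyad values
#'   (n >= 4).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return a `stat_result` with the correlation as both statistic and
#'   effect size, and a `method` field.
#' @export
dyad_correlation <- function(questioner_values, respondent_values,
                             method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(questioner_values) == length(respondent_values))
  n <- length(questioner_values)
  if (n < 4) stop("dyad correlation requires at least 4 pairs")
  if (method == "auto") {
    p1 <- stats::shapiro.test(questioner_values)$p.value
    p2 <- stats::shapiro.test(respondent_values)$p.value
    method <- if (min(p1, p2) < 0.05) "spearman" else "pearson"
  }
  ties <- anyDuplicated(questioner_values) || anyDuplicated(respondent_values)
  if (method == "spearman" && ties) {
    warning("ties present: Spearman falls back to average ranks")
  }
  ct <- suppressWarnings(stats::cor.test(
    respondent_values, questioner_values,
    alternative = "greater", method = method,
    exact = (method == "spearman" && n <= 10 && !ties)))
  stat_result(paste0("dyad_correlation_", method), unname(ct$estimate),
              ct$p.value, effect_size = unname(ct$estimate), tails = "one",
              extra = list(method = method, n = n))
}

# Interaction and per-level statistics for a two-group design with a
# within-unit factor, computed on a units x levels matrix. Standard
# mixed-design sums of squares; returns the interaction F and per-level
# group mean differences.
mixed_stats <- function(Y, g) {
  glev <- unique(g)
  k <- ncol(Y)
  grand <- mean(Y)
  unit_mean <- rowMeans(Y)
  lvl_mean <- colMeans(Y)
  ss_int <- 0
  cell <- matrix(0, length(glev), k)
  for (gi in seq_along(glev)) {
    sel <- g == glev[gi]
    cell[gi, ] <- colMeans(Y[sel, , drop = FALSE])
    gm <- mean(Y[sel, ])
    ss_int <- ss_int + sum(sel) * sum((cell[gi, ] - gm - lvl_mean + grand)^2)
  }
  resid <- Y
  for (gi in seq_along(glev)) {
    sel <- g == glev[gi]
    gmean <- mean(Y[sel, ])
    resid[sel, ] <- Y[sel, , drop = FALSE] - unit_mean[sel] -
      rep(cell[gi, ], each = sum(sel)) + gmean
  }
  ss_err <- sum(resid^2)
  df_int <- (length(glev) - 1) * (k - 1)
  df_err <- (nrow(Y) - length(glev)) * (k - 1)
  f_int <- (ss_int / df_int) / (ss_err / df_err)
  list(f_int = f_int, df_int = df_int, df_err = df_err,
       ss_int = ss_int, ss_err = ss_err,
       level_diff = cell[1, ] - cell[2, ], cell = cell, resid = resid)
}

# Greenhouse-Geisser epsilon from the within-unit residual covariance.
gg_epsilon <- function(Y, g) {
  k <- ncol(Y)
  res <- Y
  for (gl in unique(g)) {
    sel <- g == gl
    res[sel, ] <- sweep(Y[sel, , drop = FALSE], 2, colMeans(Y[sel, , drop = FALSE]))
  }
  S <- stats::cov(res)
  C <- diag(k) - 1 / k
  SC <- C %*% S %*% C
  ev <- Re(eigen(SC, symmetric = TRUE, only.values = TRUE)$values)
  sum(ev)^2 / ((k - 1) * sum(ev^2))
}

#' Group contrast with a within-unit factor
#'
#' Permutation test of the group x factor interaction (group labels
#' permuted across units, each unit's profile kept intact), per-level
#' permutation contrasts with Benjamini-Hochberg adjustment, and a
#' Greenhouse-Geisser-corrected mixed-design repeated-measures ANOVA as a
#' parametric reference.
#'
#' @param table long data frame with columns `unit`, `group`, `level`,
#'   `value`; exactly two groups, at least two levels, one value per
#'   unit x level (units replicated across all levels).
#' @param n_permutations number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list with `interaction` (a `stat_result`: permutation p, F as
#'   statistic, partial eta squared as effect size), `levels` (data frame
#'   of per-level mean differences, permutation p and BH-adjusted p) and
#'   `parametric` (GG-corrected F test).
#' @export
group_contrast <- function(table, n_permutations = 999, seed = 0) {
  stopifnot(all(c("unit", "group", "level", "value") %in% names(table)))
  wide <- stats::reshape(table[c("unit", "group", "level", "value")],
                         idvar = c("unit", "group"), timevar = "level",
                         direction = "wide")
  g <- as.character(wide$group)
  glev <- unique(g)
  if (length(glev) != 2) stop("exactly two groups required")
  if (any(tabulate(factor(g, glev)) < 2)) stop("each group needs at least 2 units")
  Y <- as.matrix(wide[, -(1:2), drop = FALSE])
  if (anyNA(Y)) stop("missing unit x level cells")
  levels_ <- sub("^value\\.", "", colnames(Y))
  k <- ncol(Y)

  obs <- mixed_stats(Y, g)
  eta_p <- obs$ss_int / (obs$ss_int + obs$ss_err)

  set.seed(seed)
  n <- nrow(Y)
  count_int <- 0L
  count_lvl <- integer(k)
  for (b in seq_len(n_permutations)) {
    gp <- g[sample.int(n)]
    perm <- mixed_stats(Y, gp)
    if (perm$f_int >= obs$f_int - 1e-12) count_int <- count_int + 1L
    count_lvl <- count_lvl +
      (abs(perm$level_diff) >= abs(obs$level_diff) - 1e-12)
  }
  p_int <- (count_int + 1) / (n_permutations + 1)
  p_lvl <- (count_lvl + 1) / (n_permutations + 1)

  eps <- gg_epsilon(Y, g)
  df1 <- obs$df_int * eps
  df2 <- obs$df_err * eps
  p_para <- stats::pf(obs$f_int, df1, df2, lower.tail = FALSE)

  list(
    interaction = stat_result("interaction_permutation", obs$f_int, p_int,
                              effect_size = eta_p,
                              extra = list(df = c(obs$df_int, obs$df_err),
                                           n_permutations = n_permutations)),
    levels = data.frame(level = levels_,
                        mean_diff = obs$level_diff,
                        groups = paste(glev[1], "-", glev[2]),
                        p_value = p_lvl,
                        adjusted_p = fdr_adjust(p_lvl),
                        stringsAsFactors = FALSE),
    parametric = stat_result("rm_anova_gg", obs$f_int, p_para,
                             effect_size = eta_p,
                             extra = list(df = c(df1, df2), gg_epsilon = eps))
  )
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values: monotone, idempotent, capped at 1.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  stats::p.adjust(p_values, method = "BH")
}
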