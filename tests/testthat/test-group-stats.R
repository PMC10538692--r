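# Group statistics: aggregation, normality gate, dyadic correlation,
# permutation contrasts, FDR adjustment.

test_that("speaker averaging collapses to one row per speaker x label", {
  tab <- data.frame(sample_id = c("a", "b", "c"),
                    speaker_id = c("sp1", "sp1", "sp2"),
                    direction_label = c("NT_speech", "NT_speech", "NT_speech"),
                    prosody_power = c(2, 4, 5))
  avg <- speaker_average(tab)
  expect_equal(nrow(avg), 2)
  expect_equal(avg$prosody_power[avg$speaker_id == "sp1"], 3)
  expect_equal(avg$prosody_power[avg$speaker_id == "sp2"], 5)
  # identity when each speaker has one row
  one <- speaker_average(tab[c(1, 3), ])
  expect_equal(sort(one$prosody_power), c(2, 5))
})

test_that("Shapiro-Wilk gate is calibrated under normality and powered against t(1)", {
  set.seed(1)
  rej_norm <- mean(vapply(1:500, function(i) {
    normality_gate(rnorm(50))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej_norm, 0.03)
  expect_lt(rej_norm, 0.07)
  rej_t1 <- mean(vapply(1:200, function(i) {
    normality_gate(rt(50, df = 1))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej_t1, 0.5)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
  expect_error(normality_gate(rep(1, 10)), "constant")
})

test_that("perfect concordance gives rho 1 with exact permutation p = 1/n!", {
  q <- c(1, 2, 3, 4, 5); r <- c(10, 20, 30, 40, 50)
  res <- dyad_correlation(q, r, method = "spearman")
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / factorial(5), tolerance = 1e-9)
  expect_equal(res$tails, "one")
  # antitonic pairs: rho -1, one-tailed p near 1
  res2 <- dyad_correlation(rev(q), r, method = "spearman")
  expect_equal(res2$statistic, -1)
  expect_gt(res2$p_value, 0.99)
})

test_that("dyad correlation auto method gates through Shapiro-Wilk", {
  set.seed(2)
  qn <- rnorm(20); rn <- qn + rnorm(20, sd = 0.5)
  expect_equal(dyad_correlation(qn, rn, "auto")$method, "pearson")
  qh <- rt(20, df = 1); rh <- qh + rnorm(20)
  expect_equal(dyad_correlation(qh, rh, "auto")$method, "spearman")
  expect_error(dyad_correlation(1:3, 1:3), "at least 4")
})

test_that("Spearman dyad correlation is invariant to monotone marginal transforms", {
  set.seed(3)
  q <- rnorm(12); r <- q + rnorm(12, sd = 0.7)
  a <- dyad_correlation(q, r, "spearman")
  b <- dyad_correlation(exp(q), r^3 + 5 * r, "spearman")
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("BH adjustment matches hand computation, is monotone and idempotent", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  set.seed(4)
  p <- runif(20)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # monotone: adjusted order follows raw order
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  # idempotent on an already-flat configuration
  expect_equal(fdr_adjust(fdr_adjust(rep(0.5, 3))), fdr_adjust(rep(0.5, 3)))
})

make_long <- function(Y, g) {
  data.frame(unit = rep(seq_len(nrow(Y)), ncol(Y)),
             group = rep(g, ncol(Y)),
             level = rep(colnames(Y), each = nrow(Y)),
             value = as.vector(Y))
}

test_that("group contrast detects an interaction planted in one level", {
  set.seed(5)
  n <- 15
  Y <- matrix(rnorm(2 * n * 3), ncol = 3,
              dimnames = list(NULL, c("prosody", "syllable", "phoneme")))
  g <- rep(c("A", "B"), each = n)
  Y[g == "A", "prosody"] <- Y[g == "A", "prosody"] - 2
  res <- group_contrast(make_long(Y, g), n_permutations = 499, seed = 1)
  expect_lt(res$interaction$p_value, 0.01)
  lv <- res$levels
  expect_lt(lv$adjusted_p[lv$level == "prosody"], 0.05)
  expect_gt(lv$adjusted_p[lv$level == "syllable"], 0.05)
  expect_gt(lv$adjusted_p[lv$level == "phoneme"], 0.05)
  expect_lt(lv$mean_diff[lv$level == "prosody"], 0)
  # parametric reference agrees on direction
  expect_lt(res$parametric$p_value, 0.01)
  expect_true(res$parametric$gg_epsilon <= 1 + 1e-9)
})

test_that("group contrast is calibrated under the null", {
  set.seed(6)
  rej <- mean(vapply(1:200, function(i) {
    Y <- matrix(rnorm(20 * 3), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
    g <- rep(c("A", "B"), each = 10)
    group_contrast(make_long(Y, g), n_permutations = 99,
                   seed = i)$interaction$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("degenerate designs are handled", {
  Y <- matrix(rnorm(8 * 2), ncol = 2, dimnames = list(NULL, c("a", "b")))
  g <- rep(c("A", "B"), each = 4)
  # one permutation: p bounded away from 0
  res <- group_contrast(make_long(Y, g), n_permutations = 1, seed = 1)
  expect_true(res$interaction$p_value %in% c(0.5, 1))
  expect_error(group_contrast(make_long(Y, rep("A", 8))), "two groups")
  expect_error(group_contrast(make_long(Y, c("A", rep("B", 7)))), "at least 2")
})
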