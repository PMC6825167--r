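# independent longhand sums-of-squares decomposition for a 2x2
# within-subject design, written directly from the definitional formulas
longhand_anova <- function(tab) {
  y <- alphasupp:::effect_cell_matrix(tab)
  n <- nrow(y)
  grand <- mean(y)
  cmap <- c(1, 1, 2, 2)
  emap <- c(1, 2, 1, 2)
  ybar_s <- rowMeans(y)
  ybar_c <- c(mean(y[, 1:2]), mean(y[, 3:4]))
  ybar_e <- c(mean(y[, c(1, 3)]), mean(y[, c(2, 4)]))
  ybar_cell <- colMeans(y)
  ybar_cs <- cbind(rowMeans(y[, 1:2]), rowMeans(y[, 3:4]))
  ybar_es <- cbind(rowMeans(y[, c(1, 3)]), rowMeans(y[, c(2, 4)]))

  ss <- list(C = 0, E = 0, CE = 0, CS = 0, ES = 0, CES = 0)
  for (s in 1:n) for (cell in 1:4) {
    ci <- cmap[cell]; ei <- emap[cell]
    ss$C <- ss$C + (ybar_c[ci] - grand)^2
    ss$E <- ss$E + (ybar_e[ei] - grand)^2
    ss$CE <- ss$CE + (ybar_cell[cell] - ybar_c[ci] - ybar_e[ei] + grand)^2
    ss$CS <- ss$CS + (ybar_cs[s, ci] - ybar_c[ci] - ybar_s[s] + grand)^2
    ss$ES <- ss$ES + (ybar_es[s, ei] - ybar_e[ei] - ybar_s[s] + grand)^2
    ss$CES <- ss$CES + (y[s, cell] -
                          ybar_cs[s, ci] - ybar_es[s, ei] - ybar_cell[cell] +
                          ybar_c[ci] + ybar_e[ei] + ybar_s[s] - grand)^2
  }
  f <- function(eff, err) (ss[[eff]] / 1) / (ss[[err]] / (n - 1))
  c(Contingency = f("C", "CS"), Extinction = f("E", "ES"),
    `Contingency:Extinction` = f("CE", "CES"))
}

test_that("identical cells per subject give F = 0 for every effect", {
  tab <- make_effect_table(6, sd_noise = 0)
  res <- rm_anova_2x2(tab)
  expect_equal(res$statistic, rep(0, 3), tolerance = 1e-20)
})

test_that("F values equal the longhand SS decomposition on random tables", {
  for (seed in 1:25) {
    tab <- make_effect_table(5, c_eff = runif(1, -8, 8),
                             e_eff = runif(1, -4, 4),
                             x_eff = runif(1, -4, 4), seed = seed)
    res <- rm_anova_2x2(tab)
    oracle <- longhand_anova(tab)  # ordered Contingency, Extinction, CxE
    expect_lt(max(abs(res$statistic - unname(oracle))), 1e-8)
  }
})

test_that("results agree with stats::aov on the same model", {
  tab <- make_effect_table(9, c_eff = -5, x_eff = 2, seed = 42)
  res <- rm_anova_2x2(tab)
  d <- tab
  d$S <- factor(d$subject_id)
  d$C <- factor(d$contingency)
  d$E <- factor(d$extinction)
  a <- summary(stats::aov(alpha_pct ~ C * E + Error(S / (C * E)), data = d))
  f_aov <- c(a[["Error: S:C"]][[1]]["C", "F value"],
             a[["Error: S:E"]][[1]]["E", "F value"],
             a[["Error: S:C:E"]][[1]]["C:E", "F value"])
  expect_equal(res$statistic, f_aov, tolerance = 1e-10)
})

test_that("partial eta squared satisfies F / (F + df_error)", {
  tab <- make_effect_table(12, c_eff = -6, seed = 3)
  res <- rm_anova_2x2(tab)
  expect_equal(res$eta_p_sq,
               res$statistic / (res$statistic + res$df2), tolerance = 1e-12)
  # the identity applied at the published scale: F(1, 86) = 9.85
  expect_equal(9.85 / (9.85 + 86), 0.103, tolerance = 0.005)
})

test_that("type-I error of each 2x2 effect is nominal under the null", {
  n_rep <- 1000
  rej <- matrix(FALSE, n_rep, 3)
  for (r in seq_len(n_rep)) {
    tab <- make_effect_table(12, seed = 5000 + r)
    rej[r, ] <- rm_anova_2x2(tab)$p_value < 0.05
  }
  rates <- colMeans(rej)
  tol <- 1.96 * sqrt(0.05 * 0.95 / n_rep)
  expect_true(all(abs(rates - 0.05) <= tol))
})

test_that("incomplete designs fail naming the subjects", {
  tab <- make_effect_table(5)[-2, ]
  expect_error(rm_anova_2x2(tab), "s01")
  expect_error(rm_anova_2x2(make_effect_table(2)), "3 subjects")
})

test_that("moment estimates match their sampling targets and e1071", {
  withr::with_seed(10, {
    z <- rnorm(1e5)
    ex <- rexp(1e5)
  })
  expect_lt(abs(alphasupp:::sample_skewness(z)), 0.05)
  expect_lt(abs(alphasupp:::sample_kurtosis(z)), 0.05)
  expect_equal(alphasupp:::sample_skewness(ex), 2, tolerance = 0.1)
  expect_equal(alphasupp:::sample_skewness(ex),
               e1071::skewness(ex, type = 1), tolerance = 1e-12)
  expect_equal(alphasupp:::sample_kurtosis(ex),
               e1071::kurtosis(ex, type = 1), tolerance = 1e-12)
})

test_that("distribution check flags pass/fail and survives degenerate cells", {
  tab <- make_effect_table(20, seed = 8)
  chk <- distribution_check(tab)
  expect_equal(nrow(chk), 4)
  expect_true(all(chk$pass))
  # constant cell: undefined moments flagged, no crash
  const <- tab
  const$alpha_pct[const$contingency == "CS+" & const$extinction == "E"] <- 1
  chk2 <- distribution_check(const)
  bad <- chk2[chk2$contingency == "CS+" & chk2$extinction == "E", ]
  expect_true(is.nan(bad$skewness))
  expect_true(is.na(bad$pass))
})

test_that("within-subject SEM is zero for parallel subjects and matches longhand", {
  # every subject has identical offsets from its own mean -> SEM 0
  base <- tibble::tibble(contingency = c("CS+", "CS+", "CS-", "CS-"),
                         extinction = c("E", "N", "E", "N"),
                         offset = c(1, -2, 4, -3))
  tab <- purrr::map_dfr(1:5, function(s) {
    dplyr::mutate(base, subject_id = sprintf("s%02d", s),
                  alpha_pct = offset + s * 10)
  })[, c("subject_id", "contingency", "extinction", "alpha_pct")]
  sem <- within_subject_sem(tab)
  expect_equal(sem$sem, rep(0, 4), tolerance = 1e-12)

  tab2 <- make_effect_table(3, seed = 77)
  sem2 <- within_subject_sem(tab2)
  y <- alphasupp:::effect_cell_matrix(tab2)
  centred <- y - rowMeans(y) + mean(y)
  oracle <- apply(centred, 2, stats::sd) * sqrt(4 / 3) / sqrt(3)
  expect_equal(sem2$sem,
               unname(oracle[paste0(sem2$contingency, sem2$extinction)]),
               tolerance = 1e-12)

  # adding a per-subject constant changes nothing
  tab3 <- dplyr::mutate(tab2, alpha_pct = alpha_pct +
                          as.integer(factor(subject_id)) * 100)
  expect_equal(within_subject_sem(tab3)$sem, sem2$sem, tolerance = 1e-10)
})

test_that("block partition is sequential with remainders to the earliest blocks", {
  expect_equal(alphasupp:::block_partition(8, 4), rep(1:4, each = 2))
  p10 <- alphasupp:::block_partition(10, 4)
  expect_equal(as.vector(table(p10)), c(3, 3, 2, 2))
  expect_true(all(diff(p10) >= 0))
  expect_equal(max(table(p10)) - min(table(p10)), 1)
})

test_that("Greenhouse-Geisser epsilon is exactly 1 for two levels and near 1 under compound symmetry", {
  withr::with_seed(31, {
    n <- 40
    subj <- rnorm(n, 0, 6)
    blocked <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:n),
                                  contingency = c("CS+", "CS-"),
                                  block = 1:4)
    blocked$alpha_pct <- subj[as.integer(factor(blocked$subject_id))] +
      rnorm(nrow(blocked), 0, 2)  # compound-symmetric covariance
  })
  res <- block_anova(blocked)
  eps <- res$anova$gg_epsilon
  expect_equal(eps[res$anova$effect == "Contingency"], 1, tolerance = 1e-12)
  expect_gt(eps[res$anova$effect == "Block"], 0.85)
  expect_gt(eps[res$anova$effect == "Block:Contingency"], 0.85)
})

test_that("block ANOVA F values agree with stats::aov and t-tests with stats::t.test", {
  blocked <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:8),
                                contingency = c("CS+", "CS-"), block = 1:4)
  withr::with_seed(9, {
    blocked$alpha_pct <- rnorm(nrow(blocked)) -
      3 * (blocked$contingency == "CS+") + 0.5 * blocked$block
  })
  res <- block_anova(blocked)
  d <- blocked
  d$S <- factor(d$subject_id); d$C <- factor(d$contingency)
  d$B <- factor(d$block)
  a <- summary(stats::aov(alpha_pct ~ C * B + Error(S / (C * B)), data = d))
  expect_equal(res$anova$statistic[res$anova$effect == "Contingency"],
               a[["Error: S:C"]][[1]]["C", "F value"], tolerance = 1e-10)
  expect_equal(res$anova$statistic[res$anova$effect == "Block"],
               a[["Error: S:B"]][[1]]["B", "F value"], tolerance = 1e-10)
  expect_equal(res$anova$statistic[res$anova$effect == "Block:Contingency"],
               a[["Error: S:C:B"]][[1]]["C:B", "F value"], tolerance = 1e-10)

  b2 <- d[d$block == 2, ]
  tt <- stats::t.test(b2$alpha_pct[b2$contingency == "CS+"],
                      b2$alpha_pct[b2$contingency == "CS-"], paired = TRUE)
  row <- res$t_tests[res$t_tests$block == 2, ]
  expect_equal(row$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("missing block cells fail naming the subjects", {
  blocked <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:4),
                                contingency = c("CS+", "CS-"), block = 1:4)
  blocked$alpha_pct <- rnorm(nrow(blocked))
  expect_error(block_anova(blocked[-5, ]), "s01")
})
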