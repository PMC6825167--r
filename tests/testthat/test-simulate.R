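small_params <- function(...) {
  sim_params(trials_retained = c(4L, 6L), ...)
}

test_that("simulation is bit-identical under a fixed seed", {
  sch <- generate_schedule("recall", 3)
  p <- small_params()
  a <- simulate_subject(sch, p, full_montage, seed = 11)
  b <- simulate_subject(sch, p, full_montage, seed = 11)
  expect_identical(a$data, b$data)
  expect_identical(a$trial_labels, b$trial_labels)
  c <- simulate_subject(sch, p, full_montage, seed = 12)
  expect_false(identical(a$data, c$data))
})

test_that("simulated epochs honour the paradigm geometry and retained-trial bounds", {
  sch <- generate_schedule("recall", 5)
  p <- small_params()
  ep <- simulate_subject(sch, p, full_montage, seed = 2)
  expect_equal(dim(ep$data)[1:2], c(64, 1300))
  counts <- table(ep$trial_labels)
  expect_true(all(counts >= 4 & counts <= 6))
  expect_setequal(names(counts), c("CS+E", "CS+N", "CS-E", "CS-N"))
})

test_that("suppression depths outside [0, 1] are rejected", {
  expect_error(sim_params(suppression_depth = c("CS+E" = 1.2, "CS+N" = 0.5,
                                                "CS-E" = 0.2, "CS-N" = 0.2)),
               "\\[0, 1\\]")
  sch <- generate_schedule("recall", 1)
  p <- small_params()
  p$suppression_depth["CS+E"] <- -0.1
  expect_error(simulate_subject(sch, p, full_montage, seed = 1), "\\[0, 1\\]")
})

test_that("non-recall schedules are rejected by the subject simulator", {
  sch <- generate_schedule("acquisition", 1)
  expect_error(simulate_subject(sch, small_params(), full_montage, seed = 1),
               "recall")
})

test_that("cohorts have distinct subjects, are reproducible, and derive per-subject seeds", {
  p <- small_params(n_subjects = 4)
  co1 <- simulate_cohort(p, full_montage, seed = 21)
  co2 <- simulate_cohort(p, full_montage, seed = 21)
  expect_equal(length(co1), 4)
  expect_setequal(names(co1), sprintf("sub%02d", 1:4))
  expect_identical(co1$sub03$data, co2$sub03$data)
  # subject 2 alone can be regenerated from master seed + index
  sch <- generate_schedule("recall", 21 + 2)
  solo <- simulate_subject(sch, p, full_montage, seed = 21 + 2,
                           subject_id = "sub02")
  expect_identical(solo$data, co1$sub02$data)
  expect_error(simulate_cohort(small_params(n_subjects = 1), full_montage),
               ">= 2")
})

test_that("equal suppression depths leave the CS+/CS- contrast centred on zero", {
  # symmetric construction: with one shared depth the two contingency levels
  # are exchangeable, so subject-level contrasts straddle zero
  p <- small_params(
    suppression_depth = c("CS+E" = 0.3, "CS+N" = 0.3,
                          "CS-E" = 0.3, "CS-N" = 0.3))
  cfg <- pipeline_config(
    sim = p, wavelet = list(f_min = 9.12, f_max = 11.4, f_step = 0.38),
    n_perm = 10, iterations = 10)
  basis <- csd_basis(full_montage, cfg$csd)
  contrasts <- vapply(1:8, function(i) {
    sch <- generate_schedule("recall", 300 + i)
    ep <- simulate_subject(sch, p, full_montage, seed = 300 + i)
    rows <- analyze_subject(ep, cfg, basis = basis)$effect_rows
    mean(rows$alpha_pct[rows$contingency == "CS+"]) -
      mean(rows$alpha_pct[rows$contingency == "CS-"])
  }, numeric(1))
  expect_gt(sum(contrasts > 0), 0)
  expect_gt(sum(contrasts < 0), 0)
})

test_that("default suppression contrast drives the subject-level summary negative", {
  # CS+ depth 0.5 vs CS- 0.2: the single-subject pipeline summary should be
  # more negative for CS+ in nearly every simulated subject
  p <- small_params()
  cfg <- pipeline_config(
    sim = p, wavelet = list(f_min = 9.12, f_max = 11.4, f_step = 0.38))
  basis <- csd_basis(full_montage, cfg$csd)
  n_sub <- 25
  contrasts <- vapply(seq_len(n_sub), function(i) {
    sch <- generate_schedule("recall", 400 + i)
    ep <- simulate_subject(sch, p, full_montage, seed = 400 + i)
    rows <- analyze_subject(ep, cfg, basis = basis)$effect_rows
    mean(rows$alpha_pct[rows$contingency == "CS+"]) -
      mean(rows$alpha_pct[rows$contingency == "CS-"])
  }, numeric(1))
  expect_gte(mean(contrasts < 0), 0.95)
})

test_that("timecourse cohorts are deterministic and exchangeable under the null", {
  a <- simulate_timecourse_cohort(6, 400, seed = 5)
  b <- simulate_timecourse_cohort(6, 400, seed = 5)
  expect_identical(a$cs_plus, b$cs_plus)
  expect_identical(a$cs_minus, b$cs_minus)
  expect_equal(dim(a$cs_plus), c(6, 400))
  # null: difference mean over many subjects/samples is near zero
  big <- simulate_timecourse_cohort(40, 1300, seed = 6)
  d <- big$cs_plus - big$cs_minus
  expect_lt(abs(mean(d)) / stats::sd(d), 0.1)
  # injected effect appears inside its window only
  eff <- simulate_timecourse_cohort(40, 1300, effect = -30, seed = 7)
  de <- colMeans(eff$cs_plus - eff$cs_minus)
  inside <- eff$times >= 600 & eff$times <= 1100
  before <- eff$times < 350
  expect_lt(mean(de[inside]), -20)
  expect_lt(abs(mean(de[before])), 6)
})
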