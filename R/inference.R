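#' Two-by-two repeated-measures ANOVA on the alpha effect table
#'
#' Within-subject ANOVA with factors Contingency (CS+ vs. CS-) and
#' Extinction (E vs. N). Each effect is tested against its own
#' effect-by-subject interaction: `F = MS_effect / MS_(effect x subject)`
#' with df (1, n - 1); partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param table An effect table: tibble with columns `subject_id`,
#'   `contingency`, `extinction`, `alpha_pct`; exactly one row per subject
#'   and design cell, at least 3 subjects.
#' @return A tibble of class `"anova_2x2"` with columns `effect`, `df1`,
#'   `df2`, `statistic` (F), `p_value`, `eta_p_sq`.
#' @examples
#' tab <- tidyr::expand_grid(subject_id = sprintf("s%02d", 1:10),
#'                           contingency = c("CS+", "CS-"),
#'                           extinction = c("E", "N"))
#' tab$alpha_pct <- stats::rnorm(nrow(tab)) - 5 * (tab$contingency == "CS+")
#' rm_anova_2x2(tab)
#' @export
rm_anova_2x2 <- function(table) {
  tab <- validate_effect_table(table)
  n <- length(unique(tab$subject_id))
  if (n < 3L) stop("Need at least 3 subjects", call. = FALSE)

  # cell matrix: subjects x 4 (C x E), fixed cell order
  y <- effect_cell_matrix(tab)
  grand <- mean(y)
  subj <- rowMeans(y)
  c_lvl <- cbind(rowMeans(y[, 1:2]), rowMeans(y[, 3:4]))  # CS+, CS-
  e_lvl <- cbind(rowMeans(y[, c(1, 3)]), rowMeans(y[, c(2, 4)]))  # E, N

  mean_c <- colMeans(c_lvl)
  mean_e <- colMeans(e_lvl)
  cell_means <- colMeans(y)

  ss_c <- 2 * n * sum((mean_c - grand)^2)
  ss_e <- 2 * n * sum((mean_e - grand)^2)
  # interaction on cell means
  cmap <- c(1, 1, 2, 2)  # contingency level per cell
  emap <- c(1, 2, 1, 2)
  ss_ce <- n * sum((cell_means - mean_c[cmap] - mean_e[emap] + grand)^2)

  ss_cs <- 2 * sum((c_lvl - outer(subj, c(1, 1)) -
                      outer(rep(1, n), mean_c) + grand)^2)
  ss_es <- 2 * sum((e_lvl - outer(subj, c(1, 1)) -
                      outer(rep(1, n), mean_e) + grand)^2)
  # residual for the interaction error term: full decomposition
  fit <- outer(rep(1, n), cell_means) + outer(subj - grand, rep(1, 4)) +
    (c_lvl[, cmap] - outer(rep(1, n), mean_c[cmap]) -
       outer(subj - grand, rep(1, 4))) +
    (e_lvl[, emap] - outer(rep(1, n), mean_e[emap]) -
       outer(subj - grand, rep(1, 4)))
  ss_ces <- sum((y - fit)^2)

  df_err <- n - 1L
  res <- tibble::tibble(
    effect = c("Contingency", "Extinction", "Contingency:Extinction"),
    ss_effect = c(ss_c, ss_e, ss_ce),
    ss_error = c(ss_cs, ss_es, ss_ces),
    df1 = 1L, df2 = df_err
  )
  res$statistic <- ifelse(res$ss_effect == 0, 0,
                          (res$ss_effect / res$df1) / (res$ss_error / res$df2))
  res$p_value <- stats::pf(res$statistic, res$df1, res$df2, lower.tail = FALSE)
  res$eta_p_sq <- ifelse(res$ss_effect == 0, 0,
                         res$ss_effect / (res$ss_effect + res$ss_error))
  out <- res[, c("effect", "df1", "df2", "statistic", "p_value", "eta_p_sq")]
  class(out) <- c("anova_2x2", class(out))
  out
}

# canonical cell order: CS+E, CS+N, CS-E, CS-N
effect_cell_matrix <- function(tab) {
  tab$cell <- paste0(tab$contingency, tab$extinction)
  cells <- c("CS+E", "CS+N", "CS-E", "CS-N")
  subjects <- unique(tab$subject_id)
  y <- matrix(NA_real_, length(subjects), 4,
              dimnames = list(subjects, cells))
  idx <- cbind(match(tab$subject_id, subjects), match(tab$cell, cells))
  y[idx] <- tab$alpha_pct
  y
}

validate_effect_table <- function(table) {
  stopifnot(is.data.frame(table),
            all(c("subject_id", "contingency", "extinction", "alpha_pct")
                %in% names(table)))
  if (!all(table$contingency %in% c("CS+", "CS-")) ||
      !all(table$extinction %in% c("E", "N"))) {
    stop("contingency must be CS+/CS- and extinction E/N", call. = FALSE)
  }
  if (any(!is.finite(table$alpha_pct))) {
    stop("Non-finite alpha_pct values in effect table", call. = FALSE)
  }
  counts <- base::table(table$subject_id,
                        paste0(table$contingency, table$extinction))
  bad <- rownames(counts)[apply(counts, 1, function(r)
    !all(r == 1) || length(r) != 4)]
  if (ncol(counts) != 4L || length(bad) > 0L) {
    stop("Incomplete or duplicated 2x2 cells for subject(s): ",
         paste(if (length(bad)) bad else rownames(counts), collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(table)
}

#' Skewness / excess kurtosis check per design cell
#'
#' Sample skewness (`m3 / m2^1.5`) and excess kurtosis (`m4 / m2^2 - 3`) of
#' the subject values in each of the four cells, with normality screening
#' flags at |skewness| <= 2 and |excess kurtosis| <= 7 (conventional cutoffs
#' for treating a cell as near-normal).
#'
#' @param table An effect table (>= 8 subjects recommended).
#' @param skew_limit,kurt_limit Screening thresholds.
#' @return A tibble with columns `contingency`, `extinction`, `skewness`,
#'   `kurtosis`, `pass` (NA when the cell is degenerate).
#' @export
distribution_check <- function(table, skew_limit = 2, kurt_limit = 7) {
  tab <- validate_effect_table(table)
  dplyr::summarise(
    dplyr::group_by(tab, .data$contingency, .data$extinction),
    skewness = sample_skewness(.data$alpha_pct),
    kurtosis = sample_kurtosis(.data$alpha_pct),
    .groups = "drop"
  ) |>
    dplyr::mutate(pass = ifelse(
      is.finite(.data$skewness) & is.finite(.data$kurtosis),
      abs(.data$skewness) <= skew_limit & abs(.data$kurtosis) <= kurt_limit,
      NA))
}

sample_skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NaN)
  mean((x - mean(x))^3) / m2^1.5
}

sample_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(NaN)
  mean((x - mean(x))^4) / m2^2 - 3
}

#' Within-subject standard errors of the cell means
#'
#' Subject-centred (Cousineau) values with the Morey bias correction
#' `sqrt(k / (k - 1))`, k = 4 cells: each subject's cell values are shifted
#' by the grand mean minus the subject mean, the per-cell SD of the centred
#' values is corrected, and the SEM is `SD / sqrt(n)`. Adding any
#' per-subject constant leaves the result unchanged.
#'
#' @param table An effect table.
#' @return A tibble with columns `contingency`, `extinction`, `mean`, `sem`,
#'   `n`.
#' @export
within_subject_sem <- function(table) {
  tab <- validate_effect_table(table)
  y <- effect_cell_matrix(tab)
  n <- nrow(y)
  k <- ncol(y)
  centred <- y - rowMeans(y) + mean(y)
  sds <- unname(apply(centred, 2, stats::sd)) * sqrt(k / (k - 1))
  tibble::tibble(
    contingency = c("CS+", "CS+", "CS-", "CS-"),
    extinction = c("E", "N", "E", "N"),
    mean = colMeans(y),
    sem = sds / sqrt(n),
    n = n
  )
}

# sequential partition of trial indices into k blocks; earlier blocks take
# the remainder, so all blocks are within one trial of each other
block_partition <- function(n, k = 4L) {
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  rep(seq_len(k), times = sizes)
}

#' Block-by-contingency repeated-measures ANOVA
#'
#' Tests the stability of the contingency effect across the recall test:
#' a Block (1..4) x Contingency (CS+ vs. CS-) within-subject ANOVA with
#' Greenhouse-Geisser sphericity correction (Box epsilon from the covariance
#' of orthonormalized repeated-measure contrasts) applied to Block-containing
#' effects, plus uncorrected two-sided paired t-tests per block. The design
#' is balanced, so type III and type I sums of squares coincide.
#'
#' @param blocked A tibble with columns `subject_id`, `contingency`
#'   (`"CS+"`/`"CS-"`), `block` (1..4), `alpha_pct`; one row per subject x
#'   contingency x block.
#' @param n_blocks Number of blocks (default 4).
#' @return A list of class `"block_anova"` with elements `anova` (tibble:
#'   `effect`, `df1`, `df2`, `statistic`, `p_value`, `eta_p_sq`,
#'   `gg_epsilon`, `p_gg`) and `t_tests` (tibble: `block`, `statistic`,
#'   `df`, `p_value`, `mean_diff`).
#' @export
block_anova <- function(blocked, n_blocks = 4L) {
  stopifnot(is.data.frame(blocked),
            all(c("subject_id", "contingency", "block", "alpha_pct")
                %in% names(blocked)))
  subjects <- unique(blocked$subject_id)
  n <- length(subjects)
  if (n < 3L) stop("Need at least 3 subjects", call. = FALSE)
  blocks <- sort(unique(blocked$block))
  if (!identical(as.integer(blocks), seq_len(n_blocks))) {
    stop("block must take values 1..", n_blocks, call. = FALSE)
  }
  cg <- c("CS+", "CS-")
  # cells ordered contingency-major: (CS+, b1..b4, CS-, b1..b4)
  cells <- expand.grid(block = seq_len(n_blocks), contingency = cg,
                       stringsAsFactors = FALSE)[, c(2, 1)]
  y <- matrix(NA_real_, n, nrow(cells))
  idx <- cbind(match(blocked$subject_id, subjects),
               match(paste(blocked$contingency, blocked$block),
                     paste(cells$contingency, cells$block)))
  y[idx] <- blocked$alpha_pct
  if (anyNA(y)) {
    bad <- subjects[apply(y, 1, anyNA)]
    stop("Missing block cells for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # orthonormal within-subject contrasts
  ortho <- function(k) {
    m <- stats::contr.helmert(k)
    sweep(m, 2, sqrt(colSums(m^2)), `/`)
  }
  unit <- function(k) matrix(1 / sqrt(k), k, 1)
  c_cg <- ortho(2)           # contingency (1 df)
  c_bl <- ortho(n_blocks)    # block (3 df)
  contrasts <- list(
    Contingency = kronecker(c_cg, unit(n_blocks)),
    Block = kronecker(unit(2), c_bl),
    `Block:Contingency` = kronecker(c_cg, c_bl)
  )

  one_effect <- function(M) {
    z <- y %*% M
    df1 <- ncol(M)
    zbar <- colMeans(z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(z, 2, zbar)^2)
    df2 <- df1 * (n - 1L)
    f <- (ss_eff / df1) / (ss_err / df2)
    # Box / Greenhouse-Geisser epsilon from the contrast covariance
    s <- stats::cov(z)
    eps <- sum(diag(s))^2 / (df1 * sum(s^2))
    tibble::tibble(df1 = df1, df2 = df2, statistic = f,
                   p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
                   eta_p_sq = ss_eff / (ss_eff + ss_err),
                   gg_epsilon = eps,
                   p_gg = stats::pf(f, df1 * eps, df2 * eps,
                                    lower.tail = FALSE))
  }
  anova_tab <- dplyr::bind_rows(lapply(contrasts, one_effect))
  anova_tab <- dplyr::bind_cols(tibble::tibble(effect = names(contrasts)),
                                anova_tab)

  # per-block paired t-tests (uncorrected, two-sided)
  t_tests <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    d <- y[, b] - y[, n_blocks + b]  # CS+ minus CS- in block b
    tt <- stats::t.test(d)
    tibble::tibble(block = b, statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   mean_diff = mean(d))
  })

  structure(list(anova = anova_tab, t_tests = t_tests, n = n),
            class = "block_anova")
}

#' @export
print.block_anova <- function(x, ...) {
  cat("Block x Contingency repeated-measures ANOVA (n =", x$n, ")\n")
  print(x$anova)
  cat("\nPer-block paired t-tests (uncorrected, two-sided):\n")
  print(x$t_tests)
  invisible(x)
}
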