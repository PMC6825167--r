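#' Bayesian model comparison for the 2x2 within-subject design
#'
#' Compares four fixed-effect structures — Contingency only (`C`),
#' Extinction only (`E`), both main effects (`C+E`) and the complete model
#' with the interaction (`C+E+CxE`) — against a subject-only null model,
#' under a Bayesian mixed linear model with scaled g-priors: standardized
#' fixed effects receive Cauchy scale `r_fixed = 0.5` and the subject random
#' effect scale `r_subject = 1` (the defaults of the standard Bayesian ANOVA
#' software), a flat prior on the grand mean and Jeffreys prior on the error
#' variance.
#'
#' For this balanced complete design the subject and effect subspaces are
#' mutually orthogonal, so the marginal likelihood conditional on the g
#' parameters has a closed form; only the g's are integrated, by seeded
#' Monte Carlo over their inverse-gamma(1/2, r^2/2) priors with common
#' random numbers across models. The Monte-Carlo standard error of each
#' log Bayes factor is reported.
#'
#' @param table An effect table (see [rm_anova_2x2()]).
#' @param iterations Monte-Carlo iterations (default 100000).
#' @param seed Seed for the g draws.
#' @param r_fixed,r_subject Prior scales.
#' @return A list of class `"bayes_2x2"`: `models` (tibble with `model`,
#'   `bf10`, `log_bf10`, `mc_error` — the SE of `log_bf10`), `incl` (tibble
#'   from [inclusion_bf()]), `iterations`, `seed`.
#' @export
bayes_model_comparison <- function(table, iterations = 100000, seed = 1L,
                                   r_fixed = 0.5, r_subject = 1) {
  tab <- validate_effect_table(table)
  y <- effect_cell_matrix(tab)
  s <- nrow(y)
  if (s < 3L) stop("Need at least 3 subjects", call. = FALSE)
  n_obs <- length(y)

  grand <- mean(y)
  ss_t <- sum((y - grand)^2)
  ss_s <- 4 * sum((rowMeans(y) - grand)^2)
  # effect codes on the canonical cell order CS+E, CS+N, CS-E, CS-N
  x_c <- c(1, 1, -1, -1)
  x_e <- c(1, -1, 1, -1)
  x_ce <- x_c * x_e
  proj_ss <- function(x) {
    w <- as.vector(y %*% x)        # per-subject projections
    sum(w)^2 / (s * sum(x^2))
  }
  ss_c <- proj_ss(x_c)
  ss_e <- proj_ss(x_e)
  ss_ce <- proj_ss(x_ce)
  ss_resid <- ss_t - ss_s - ss_c - ss_e - ss_ce
  if (ss_resid <= 1e-12 * max(ss_t, 1)) {
    stop("Zero residual variance in the effect table (degenerate input, ",
         "e.g. duplicated rows): Bayes factors are undefined", call. = FALSE)
  }

  # effective prior-precision multipliers k_b: squared column norm of the
  # orthonormalized (per-observation standardized) effect codes
  k_c <- 2 * s   # 2-level factor: codes +-1/sqrt(2), 4s observations
  k_e <- 2 * s
  k_ce <- s      # interaction codes +-1/2
  k_s <- 4       # subject indicators, 4 observations each

  effects <- list(
    C = list(ss = ss_c, k = k_c, g = "gc"),
    E = list(ss = ss_e, k = k_e, g = "ge"),
    CxE = list(ss = ss_ce, k = k_ce, g = "gx")
  )
  models <- list(
    "C" = "C",
    "E" = "E",
    "C+E" = c("C", "E"),
    "C+E+CxE" = c("C", "E", "CxE")
  )

  local_rng(seed)
  draw_g <- function(r) 1 / stats::rgamma(iterations, shape = 0.5,
                                          rate = r^2 / 2)
  g <- list(gs = draw_g(r_subject), gc = draw_g(r_fixed),
            ge = draw_g(r_fixed), gx = draw_g(r_fixed))

  # log marginal (up to a constant common to all models) given g draws
  log_marg <- function(included) {
    logdet <- (s - 1) * log1p(k_s * g$gs)
    q <- ss_resid + ss_s / (1 + k_s * g$gs)
    for (nm in names(effects)) {
      ef <- effects[[nm]]
      if (nm %in% included) {
        gb <- g[[ef$g]]
        logdet <- logdet + log1p(ef$k * gb)
        q <- q + ef$ss / (1 + ef$k * gb)
      } else {
        q <- q + ef$ss
      }
    }
    -0.5 * logdet - (n_obs - 1) / 2 * log(q)
  }

  log_mean_exp <- function(lx) {
    m <- max(lx)
    w <- exp(lx - m)
    list(log_mean = m + log(mean(w)),
         se_log = stats::sd(w) / (mean(w) * sqrt(length(w))))
  }

  null_lm <- log_mean_exp(log_marg(character(0)))
  rows <- purrr::map_dfr(names(models), function(nm) {
    mm <- log_mean_exp(log_marg(models[[nm]]))
    tibble::tibble(model = nm,
                   log_bf10 = mm$log_mean - null_lm$log_mean,
                   mc_error = sqrt(mm$se_log^2 + null_lm$se_log^2))
  })
  rows$bf10 <- exp(rows$log_bf10)
  rows <- rows[, c("model", "bf10", "log_bf10", "mc_error")]

  out <- structure(list(models = rows, iterations = iterations, seed = seed,
                        r_fixed = r_fixed, r_subject = r_subject),
                   class = "bayes_2x2")
  out$incl <- inclusion_bf(out)
  out
}

#' Inclusion Bayes factors from matched models
#'
#' For each effect, models containing the effect (but no higher-order
#' interaction involving it) are compared with the matched models stripped
#' of it, under equal prior model probabilities: for Contingency,
#' `(P(C) + P(C+E)) / (P(null) + P(E))`; analogously for Extinction; for the
#' interaction, `P(C+E+CxE) / P(C+E)`. The arithmetic is exact given the
#' model Bayes factors.
#'
#' @param result A `"bayes_2x2"` object, or a named numeric of BF10 values
#'   with names `C`, `E`, `C+E`, `C+E+CxE` (the null has BF10 = 1).
#' @return A tibble with columns `effect`, `bf_incl`, `label` (the
#'   reciprocal `"1 / x"` form when `bf_incl < 1`).
#' @export
inclusion_bf <- function(result) {
  bf <- if (inherits(result, "bayes_2x2")) {
    stats::setNames(result$models$bf10, result$models$model)
  } else {
    result
  }
  needed <- c("C", "E", "C+E", "C+E+CxE")
  if (!all(needed %in% names(bf))) {
    stop("Missing model BF10 for: ",
         paste(setdiff(needed, names(bf)), collapse = ", "), call. = FALSE)
  }
  if (any(bf <= 0) || any(!is.finite(bf))) {
    stop("Model Bayes factors must be positive and finite", call. = FALSE)
  }
  vals <- c(
    Contingency = unname((bf["C"] + bf["C+E"]) / (1 + bf["E"])),
    Extinction = unname((bf["E"] + bf["C+E"]) / (1 + bf["C"])),
    `Contingency:Extinction` = unname(bf["C+E+CxE"] / bf["C+E"])
  )
  tibble::tibble(effect = names(vals), bf_incl = unname(vals),
                 label = format_bf(unname(vals)))
}

#' Format a Bayes factor in reporting style
#'
#' Values below 1 are reported as their reciprocal, e.g. `"1 / 8.1"`.
#' @param x Numeric vector of Bayes factors.
#' @param digits Significant digits.
#' @return Character vector.
#' @export
format_bf <- function(x, digits = 3) {
  ifelse(x < 1,
         paste0("1 / ", signif(1 / x, digits)),
         as.character(signif(x, digits)))
}

#' @export
print.bayes_2x2 <- function(x, ...) {
  cat("Bayesian 2x2 model comparison (", x$iterations, " MC iterations)\n",
      sep = "")
  df <- x$models
  df$bf10 <- signif(df$bf10, 4)
  print(df)
  cat("\nInclusion Bayes factors (matched models):\n")
  print(x$incl)
  invisible(x)
}
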