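#' Trial schedules for the two-day differential conditioning paradigm
#'
#' The paradigm uses four conditioned stimuli crossing Contingency
#' (CS+ reinforced during acquisition vs. CS- never reinforced) with
#' Extinction status (E = presented during Day-1 extinction, N = not
#' presented). Phases and per-CS trial counts:
#'
#' * habituation: 5 presentations per CS, none reinforced
#' * acquisition: 45 per CS; each CS+ reinforced on exactly 21 trials (46.6%)
#' * extinction: 40 presentations of CS+E and CS-E only, none reinforced
#' * recall (Day 2): 60 per CS, no reinforcement
#'
#' @name schedule
NULL

cs_types <- function() c("CS+E", "CS+N", "CS-E", "CS-N")

phase_design <- function(phase) {
  switch(phase,
    habituation = list(cs = cs_types(), n_per_cs = 5L, n_reinforced = 0L),
    acquisition = list(cs = cs_types(), n_per_cs = 45L, n_reinforced = 21L),
    extinction  = list(cs = c("CS+E", "CS-E"), n_per_cs = 40L,
                       n_reinforced = 0L),
    recall      = list(cs = cs_types(), n_per_cs = 60L, n_reinforced = 0L),
    stop("Unknown phase '", phase, "'; must be one of habituation, ",
         "acquisition, extinction, recall", call. = FALSE)
  )
}

#' Generate a trial schedule for one paradigm phase
#'
#' Trial order is a seeded random interleaving of the CS types presented in
#' the phase. During acquisition each CS+ is reinforced (paired with the
#' aversive US) on exactly 21 of its 45 trials, chosen uniformly at random;
#' CS- trials and all trials of the other phases are never reinforced.
#'
#' @param phase One of `"habituation"`, `"acquisition"`, `"extinction"`,
#'   `"recall"`.
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @return A tibble with columns `phase`, `cs_type`, `reinforced` (logical),
#'   `index` (1-based presentation order).
#' @examples
#' sched <- generate_schedule("acquisition", seed = 1)
#' table(sched$cs_type, sched$reinforced)
#' @export
generate_schedule <- function(phase, seed = 1L) {
  design <- phase_design(phase)
  local_rng(seed)

  trials <- purrr::map(design$cs, function(cs) {
    reinforced <- rep(FALSE, design$n_per_cs)
    if (design$n_reinforced > 0L && startsWith(cs, "CS+")) {
      reinforced[sample.int(design$n_per_cs, design$n_reinforced)] <- TRUE
    }
    tibble::tibble(cs_type = cs, reinforced = reinforced)
  })
  sched <- dplyr::bind_rows(trials)
  sched <- sched[sample.int(nrow(sched)), , drop = FALSE]
  sched$phase <- phase
  sched$index <- seq_len(nrow(sched))
  sched <- sched[, c("phase", "cs_type", "reinforced", "index")]
  validate_schedule(sched)
  sched
}

validate_schedule <- function(sched) {
  stopifnot(is.data.frame(sched),
            all(c("phase", "cs_type", "reinforced", "index") %in% names(sched)))
  phase <- unique(sched$phase)
  stopifnot(length(phase) == 1L)
  design <- phase_design(phase)
  counts <- table(factor(sched$cs_type, levels = design$cs))
  if (!all(counts == design$n_per_cs)) {
    stop("Schedule counts do not match the ", phase, " design", call. = FALSE)
  }
  if (any(sched$reinforced & !startsWith(sched$cs_type, "CS+"))) {
    stop("Reinforcement on a CS- trial", call. = FALSE)
  }
  if (phase != "acquisition" && any(sched$reinforced)) {
    stop("Reinforcement outside acquisition", call. = FALSE)
  }
  invisible(sched)
}

#' Write / read a schedule as CSV
#'
#' @param sched A schedule tibble from [generate_schedule()].
#' @param path File path.
#' @return `write_schedule()` returns `path` invisibly; `read_schedule()`
#'   returns the schedule tibble.
#' @export
write_schedule <- function(sched, path) {
  validate_schedule(sched)
  utils::write.csv(as.data.frame(sched), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  raw$reinforced <- as.logical(raw$reinforced)
  sched <- tibble::as_tibble(raw)
  validate_schedule(sched)
  sched
}
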