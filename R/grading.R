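# Modified Sunnybrook scale, expert-consensus modes, assessor accuracy.

#' Parameters of the modified Sunnybrook grading scale
#'
#' Three resting-symmetry parameters (eye 1-2, cheek 1-3, mouth 1-2) and five
#' voluntary-movement parameters graded 1 (no movement) to 5 (normal), one
#' per expression. Only the voluntary parameters are regression targets; the
#' resting parameters are carried in the data model.
#'
#' @return A data frame with columns `parameter`, `category`, `min_grade`,
#'   `max_grade`, `expression` (`NA` for resting parameters).
#' @export
sunnybrook_parameters <- function() {
  data.frame(
    parameter = c("resting_eye", "resting_cheek", "resting_mouth",
                  "forehead_wrinkling", "gentle_eye_closure",
                  "open_mouth_smiling", "cheek_puffing", "lip_puckering"),
    category = c(rep("resting", 3), rep("voluntary", 5)),
    min_grade = c(1L, 1L, 1L, rep(1L, 5)),
    max_grade = c(2L, 3L, 2L, rep(5L, 5)),
    expression = c(NA, NA, NA, expression_types()),
    stringsAsFactors = FALSE)
}

#' Expert-consensus grade of one panel cell
#'
#' The consensus of a 7-assessor x 2-session panel is the mode of its 14
#' observations; its occurrence count divided by the panel size is the
#' accuracy of the subjective parameter. When several grades tie for the
#' mode, the smaller grade wins (recorded in the output).
#'
#' @param grades Integer vector of panel observations (14 for the default
#'   panel shape; any positive length is accepted).
#' @param range Allowed grade range `c(min, max)`.
#' @return A list of class `consensus_grade` with `mode`, `occurrences`,
#'   `accuracy`, `n`, `tie` (whether a tie was broken) and `tie_rule`.
#' @export
consensus_mode <- function(grades, range = c(1L, 5L)) {
  if (length(grades) == 0L) stop("empty grade panel", call. = FALSE)
  if (anyNA(grades)) stop("grade panel contains missing values", call. = FALSE)
  grades <- as.integer(grades)
  if (any(grades < range[1] | grades > range[2])) {
    stop(sprintf("grade outside allowed range [%d, %d]", range[1], range[2]),
         call. = FALSE)
  }
  tab <- table(grades)
  top <- max(tab)
  modes <- as.integer(names(tab)[tab == top])
  structure(list(mode = min(modes),
                 occurrences = as.integer(top),
                 accuracy = as.numeric(top) / length(grades),
                 n = length(grades),
                 tie = length(modes) > 1L,
                 tie_rule = "smallest grade"),
            class = "consensus_grade")
}

#' @export
print.consensus_grade <- function(x, ...) {
  cat(sprintf("<consensus: mode %d (%d/%d, accuracy %.4f)%s>\n",
              x$mode, x$occurrences, x$n, x$accuracy,
              if (x$tie) ", tie broken to smallest" else ""))
  invisible(x)
}

#' Simulate one multi-rater panel cell
#'
#' Each of the `n_assessors * n_sessions` observations is drawn from a
#' discretized-Gaussian ordinal confusion model centred on the true grade:
#' `P(obs = k) \propto exp(-(k - true)^2 / (2 noise^2))` over the allowed
#' grades. With `noise = 0` every observation equals the true grade; as
#' `noise` grows, observations approach a uniform draw over the scale.
#'
#' @param true_grade Integer true grade.
#' @param n_assessors,n_sessions Panel shape (default 7 x 2).
#' @param noise Confusion noise (standard deviation of the discretized
#'   Gaussian).
#' @param range Allowed grade range.
#' @param seed Optional seed.
#' @return Integer vector of `n_assessors * n_sessions` observations.
#' @export
simulate_rater_panel <- function(true_grade, n_assessors = 7, n_sessions = 2,
                                 noise = 0.3, range = c(1L, 5L), seed = NULL) {
  true_grade <- as.integer(true_grade)
  if (true_grade < range[1] || true_grade > range[2]) {
    stop("true grade outside the allowed range", call. = FALSE)
  }
  n <- n_assessors * n_sessions
  if (noise <= 0) return(rep(true_grade, n))
  k <- seq.int(range[1], range[2])
  p <- exp(-(k - true_grade)^2 / (2 * noise^2))
  with_seed(seed, sample(k, n, replace = TRUE, prob = p / sum(p)))
}

#' Per-parameter accuracy of the assessor panel
#'
#' For every (subject, parameter) cell, computes the consensus mode and the
#' fraction of observations equal to it; then averages this fraction over
#' subjects, per parameter. This is the accuracy of the subjective parameter:
#' how often an individual expert observation agrees with the expert
#' consensus.
#'
#' @param panels Long-format data frame with columns `subject_id`,
#'   `parameter`, `assessor`, `session`, `grade` (see
#'   [simulate_cohort_panels]).
#' @param expected_n Expected observations per cell (default
#'   `7 * 2 = 14`); incomplete cells are an error, no imputation is done.
#' @return A list with `per_parameter` (data frame `parameter`, `accuracy`,
#'   `n_subjects`) and `consensus` (data frame of per-cell modes,
#'   occurrences and accuracies, including the tie flag).
#' @export
assessor_accuracy <- function(panels, expected_n = 14L) {
  needed <- c("subject_id", "parameter", "assessor", "session", "grade")
  if (!all(needed %in% names(panels))) {
    stop(sprintf("panels must have columns %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(panels$grade)) stop("missing grades in panel", call. = FALSE)
  params <- sunnybrook_parameters()
  cells <- split(panels,
                 list(panels$subject_id, panels$parameter), drop = TRUE)
  cons <- lapply(cells, function(cell) {
    if (nrow(cell) != expected_n) {
      stop(sprintf(
        "incomplete panel for subject %s, parameter %s: %d of %d observations",
        cell$subject_id[1], cell$parameter[1], nrow(cell), expected_n),
        call. = FALSE)
    }
    pr <- params[params$parameter == cell$parameter[1], ]
    range <- if (nrow(pr) == 1L) c(pr$min_grade, pr$max_grade) else c(1L, 5L)
    cm <- consensus_mode(cell$grade, range = range)
    data.frame(subject_id = cell$subject_id[1],
               parameter = cell$parameter[1],
               mode = cm$mode, occurrences = cm$occurrences,
               accuracy = cm$accuracy, tie = cm$tie,
               stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, cons)
  rownames(cons) <- NULL
  acc <- stats::aggregate(accuracy ~ parameter, cons, mean)
  nsub <- stats::aggregate(subject_id ~ parameter, cons,
                    function(s) length(unique(s)))
  names(nsub)[2] <- "n_subjects"
  list(per_parameter = merge(acc, nsub, by = "parameter"),
       consensus = cons)
}

#' Simulate grade panels for a synthetic cohort
#'
#' For every capture, simulates a 7 x 2 panel of the matching voluntary
#' parameter around the true severity; resting parameters are panelled once
#' per subject from a deterministic mapping of the subject's mean severity
#' (droop and narrowed eye aperture appear below grade 3).
#'
#' @param cohort A [synthesize_cohort] result.
#' @param noise Rater confusion noise; defaults to the cohort spec's value.
#' @param seed Seed; defaults to the cohort spec's master seed.
#' @return Long-format data frame `subject_id`, `parameter`, `assessor`,
#'   `session`, `grade`.
#' @export
simulate_cohort_panels <- function(cohort, noise = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(noise)) noise <- cohort$spec$rater_noise
  if (is.null(seed)) seed <- cohort$spec$seed + 1L
  params <- sunnybrook_parameters()
  vol <- params[params$category == "voluntary", ]
  truth <- cohort$truth
  n_cells <- nrow(truth) + 3L * nrow(cohort$subjects)
  seeds <- derive_seeds(seed, n_cells)
  out <- vector("list", n_cells)
  grid <- expand.grid(assessor = seq_len(7), session = seq_len(2))
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    k <- k + 1L
    par <- vol$parameter[match(truth$expression[i], vol$expression)]
    g <- simulate_rater_panel(truth$true_grade[i], noise = noise,
                              seed = seeds[k])
    out[[k]] <- data.frame(subject_id = truth$subject_id[i], parameter = par,
                           assessor = grid$assessor, session = grid$session,
                           grade = g, stringsAsFactors = FALSE)
  }
  rest_par <- params[params$category == "resting", ]
  mean_sev <- stats::aggregate(true_grade ~ subject_id, truth, mean)
  for (i in seq_len(nrow(mean_sev))) {
    s <- mean_sev$true_grade[i]
    true_rest <- c(resting_eye = if (s < 3) 1L else 2L,
                   resting_cheek = if (s < 2) 1L else if (s < 4) 2L else 3L,
                   resting_mouth = if (s < 3) 1L else 2L)
    for (j in seq_len(nrow(rest_par))) {
      k <- k + 1L
      rng <- c(rest_par$min_grade[j], rest_par$max_grade[j])
      g <- simulate_rater_panel(true_rest[[rest_par$parameter[j]]],
                                noise = noise, range = rng, seed = seeds[k])
      out[[k]] <- data.frame(subject_id = mean_sev$subject_id[i],
                             parameter = rest_par$parameter[j],
                             assessor = grid$assessor, session = grid$session,
                             grade = g, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Consensus voluntary grades per capture
#'
#' Joins the per-capture consensus modes of the voluntary parameters back to
#' capture identifiers, producing the regression targets for training.
#'
#' @param panels Long-format panel data frame.
#' @return Data frame `subject_id`, `expression`, `grade` (consensus mode),
#'   `occurrences`, `accuracy`.
#' @export
consensus_grades <- function(panels) {
  aa <- assessor_accuracy(panels)
  params <- sunnybrook_parameters()
  vol <- params[params$category == "voluntary", ]
  cons <- aa$consensus[aa$consensus$parameter %in% vol$parameter, ]
  cons$expression <- vol$expression[match(cons$parameter, vol$parameter)]
  data.frame(subject_id = cons$subject_id, expression = cons$expression,
             grade = cons$mode, occurrences = cons$occurrences,
             accuracy = cons$accuracy, stringsAsFactors = FALSE)
}

#' Read / write grade panels as CSV
#'
#' @param panels Long-format panel data frame.
#' @param path File path.
#' @return `read_grade_panels` returns the panel data frame.
#' @export
write_grade_panels <- function(panels, path) {
  utils::write.csv(panels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grade_panels
#' @export
read_grade_panels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
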