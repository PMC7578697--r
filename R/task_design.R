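# Symbolic contour identification task (CIT) design: stimulus space,
# trial blocks, behavioural scoring and correlation reports.

#' Melodic contour directions
#'
#' The three admissible pitch-contour directions used by the contour
#' identification tasks.
#'
#' @return Character vector `c("ascending", "stationary", "descending")`.
#' @export
contour_directions <- function() c("ascending", "stationary", "descending")

#' Default musical parameters of the CIT item pool
#'
#' Five major keys spanning the chromatic range G-sharp to C, and three
#' instrument timbres chosen for their distinct spectral envelopes.
#'
#' @name cit_defaults
#' @export
default_keys <- function() c("G#", "A", "A#", "B", "C")

#' @rdname cit_defaults
#' @export
default_timbres <- function() c("piano", "flute", "string")

# environmental-sound distractor labels used in CIT1
env_sound_labels <- function() {
  c("traffic", "raining", "twittering", "ticktack", "bustling",
    "laughing", "gabbling", "applause", "crying", "jeering")
}

#' Enumerate ordered pairs of distinct contour directions
#'
#' Each test item presents two consecutive contours of different direction;
#' this enumerates all such ordered pairs in canonical order (first element
#' cycling through ascending, stationary, descending; second element in the
#' same order, skipping repeats).
#'
#' @return A tibble with columns `dir1`, `dir2`; 6 rows.
#' @export
enumerate_contour_pairs <- function() {
  dirs <- contour_directions()
  grid <- tidyr::expand_grid(dir1 = dirs, dir2 = dirs)
  # expand_grid preserves the given order; drop same-direction pairs
  dplyr::filter(grid, .data$dir1 != .data$dir2)
}

#' Build the full CIT test-item pool
#'
#' The cartesian product of contour-direction pairs, keys and timbres.
#' With the defaults (6 pairs x 5 keys x 3 timbres) this yields 90 items,
#' each lasting `2 * contour_ms + gap_ms` = 5250 ms.
#'
#' @param keys Character vector of distinct key labels.
#' @param timbres Character vector of distinct timbre labels.
#' @param contour_ms Duration of a single contour in ms (default 2250).
#' @param gap_ms Inter-contour interval in ms (default 750).
#' @return A tibble with columns `item_id`, `dir1`, `dir2`, `key`, `timbre`,
#'   `duration_ms`.
#' @export
build_item_pool <- function(keys = default_keys(),
                            timbres = default_timbres(),
                            contour_ms = 2250, gap_ms = 750) {
  if (length(keys) == 0 || length(timbres) == 0) {
    stop("`keys` and `timbres` must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(keys)) stop("duplicate entries in `keys`", call. = FALSE)
  if (anyDuplicated(timbres)) {
    stop("duplicate entries in `timbres`", call. = FALSE)
  }
  pool <- tidyr::expand_grid(enumerate_contour_pairs(),
                             key = keys, timbre = timbres)
  pool$duration_ms <- 2 * contour_ms + gap_ms
  pool$item_id <- seq_len(nrow(pool))
  dplyr::relocate(pool, "item_id")
}

#' Build one CIT trial block
#'
#' Draws `n_items` items from the pool without replacement under a seeded
#' generator and attaches the distractor structure of the requested task:
#' CIT1 trials carry environmental-sound distractors, CIT2/CIT3 trials carry
#' a target-like contour in a different timbre, and CIT3 trials additionally
#' carry an attention-shift cue giving the position (upper/lower line) of
#' the first target contour.
#'
#' @param cit_id One of `"CIT1"`, `"CIT2"`, `"CIT3"`.
#' @param pool Item pool from [build_item_pool()].
#' @param n_items Number of trials per block (default 18).
#' @param seed Integer seed; identical `(seed, inputs)` give identical
#'   blocks.
#' @return An object of class `cit_block`: a list with `cit_id`, `n_items`
#'   and a `trials` tibble.
#' @export
build_cit_block <- function(cit_id, pool, n_items = 18, seed) {
  cit_id <- match.arg(cit_id, c("CIT1", "CIT2", "CIT3"))
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_items > nrow(pool)) {
    stop("`n_items` exceeds the pool size", call. = FALSE)
  }
  trials <- withr::with_seed(as.integer(seed), {
    tr <- pool[sample.int(nrow(pool), n_items), , drop = FALSE]
    tr$trial <- seq_len(n_items)
    if (cit_id == "CIT1") {
      tr$distractor_type <- "environmental"
      tr$distractor_label <- sample(env_sound_labels(), n_items,
                                    replace = TRUE)
      tr$cue <- NA_character_
    } else {
      # target-like distractor: another contour pair in a different timbre
      pairs <- enumerate_contour_pairs()
      dp <- pairs[sample.int(nrow(pairs), n_items, replace = TRUE), ]
      dt <- vapply(tr$timbre, function(tb) {
        sample(setdiff(default_timbres(), tb), 1)
      }, character(1))
      tr$distractor_type <- "target_like"
      tr$distractor_label <- paste0(substr(dp$dir1, 1, 4), "-",
                                    substr(dp$dir2, 1, 4), "/", dt)
      tr$cue <- if (cit_id == "CIT3") {
        paste0("shift:", sample(c("upper", "lower"), n_items,
                                replace = TRUE), "-first")
      } else {
        paste0("timbre:", tr$timbre)
      }
    }
    tr
  })
  structure(list(cit_id = cit_id, n_items = n_items,
                 trials = tibble::as_tibble(trials)),
            class = "cit_block")
}

#' @export
print.cit_block <- function(x, ...) {
  cat("<cit_block>", x$cit_id, "-", x$n_items, "trials\n")
  print(x$trials, n = 5)
  invisible(x)
}

#' Score trial-level responses into a behaviour table
#'
#' Accuracy is the fraction of correct responses per subject and CIT; mean
#' reaction time is averaged over answered trials. Subject x CIT cells with
#' no responses are flagged as missing (`NA`), never scored as zero.
#'
#' @param responses Data frame with columns `subject_id`, `group`, `cit_id`,
#'   `correct` (logical) and `rt_ms` (positive).
#' @param expected Optional data frame of `subject_id`, `group`, `cit_id`
#'   combinations that must appear; missing cells are emitted with `NA`
#'   scores and a warning.
#' @return A tibble with columns `subject_id`, `group`, `cit_id`,
#'   `accuracy`, `mean_rt_ms`.
#' @export
score_behavior <- function(responses, expected = NULL) {
  stopifnot(all(c("subject_id", "group", "cit_id", "correct", "rt_ms")
                %in% names(responses)))
  if (any(responses$rt_ms <= 0)) {
    stop("reaction times must be positive", call. = FALSE)
  }
  if (!is.logical(responses$correct)) {
    stop("`correct` must be logical", call. = FALSE)
  }
  out <- responses |>
    dplyr::group_by(.data$subject_id, .data$group, .data$cit_id) |>
    dplyr::summarise(accuracy = mean(.data$correct),
                     mean_rt_ms = mean(.data$rt_ms), .groups = "drop")
  if (!is.null(expected)) {
    out <- dplyr::left_join(tibble::as_tibble(expected), out,
                            by = c("subject_id", "group", "cit_id"))
    n_missing <- sum(is.na(out$accuracy))
    if (n_missing > 0) {
      warning(n_missing, " subject x CIT cell(s) had no responses; ",
              "flagged as missing", call. = FALSE)
    }
  }
  out
}

#' Correlate CIT performance with neurocognitive test scores
#'
#' Pearson correlations (with two-sided p-values) between the CIT measures
#' (accuracy, mean reaction time) and the neurocognitive screening scores
#' (number connection tests NCT-A/NCT-B in seconds, digit span forward /
#' backward), computed per group and per CIT plus a per-subject CIT-total
#' row (scores averaged over CITs).
#'
#' @param behavior Behaviour table with columns `subject_id`, `group`,
#'   `cit_id`, `accuracy`, `mean_rt_ms`, `nct_a_s`, `nct_b_s`,
#'   `dst_forward`, `dst_backward`.
#' @return A tibble with one row per (group, cit, measure, test) cell:
#'   columns `group`, `cit`, `measure`, `test`, `r`, `p`, `n`. Zero-variance
#'   cells yield `NA` with a warning.
#' @export
correlate_behavior <- function(behavior) {
  tests <- c("nct_a_s", "nct_b_s", "dst_forward", "dst_backward")
  stopifnot(all(c("subject_id", "group", "cit_id", "accuracy",
                  "mean_rt_ms", tests) %in% names(behavior)))
  counts <- table(behavior$group)
  if (length(counts) < 2 || any(counts < 3)) {
    stop("need at least 3 complete rows in each of two groups",
         call. = FALSE)
  }

  totals <- behavior |>
    dplyr::group_by(.data$subject_id, .data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("accuracy", "mean_rt_ms",
                                                   tests)), mean),
                     .groups = "drop") |>
    dplyr::mutate(cit_id = "Total")
  full <- dplyr::bind_rows(tibble::as_tibble(behavior), totals)

  cells <- tidyr::expand_grid(
    group = sort(unique(behavior$group)),
    cit = c(sort(unique(behavior$cit_id)), "Total"),
    measure = c("accuracy", "mean_rt_ms"),
    test = tests
  )
  res <- purrr::pmap_dfr(cells, function(group, cit, measure, test) {
    sub <- full[full$group == group & full$cit_id == cit, ]
    x <- sub[[measure]]
    y <- sub[[test]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
      warning("correlation undefined for ", group, "/", cit, " ",
              measure, " vs ", test, call. = FALSE)
      return(tibble::tibble(group = group, cit = cit, measure = measure,
                            test = test, r = NA_real_, p = NA_real_,
                            n = length(x)))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble::tibble(group = group, cit = cit, measure = measure,
                   test = test, r = unname(ct$estimate), p = ct$p.value,
                   n = length(x))
  })
  res
}
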