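#' Event tables
#'
#' An event table is a tibble with one row per sound event and columns
#' `onset_s` (seconds, sorted ascending), `category` (label), `condition`
#' (`"narrow"`, `"wide"` or `NA`) and `duration_s` (seconds). It is the
#' ground-truth annotation of a soundscape: sound-identity (SI) markers,
#' condition splits and simulated EEG all derive from it.
#'
#' @param onset_s,category,condition,duration_s Column vectors, recycled to a
#'   common length.
#'
#' @return A tibble of class `event_table`.
#' @export
event_table <- function(onset_s = numeric(), category = character(),
                        condition = NA_character_, duration_s = 0.2) {
  tb <- tibble::tibble(
    onset_s = as.numeric(onset_s),
    category = as.character(category),
    condition = as.character(condition),
    duration_s = as.numeric(duration_s)
  )
  validate_event_table(tb)
  class(tb) <- c("event_table", class(tb))
  tb
}

validate_event_table <- function(events) {
  stopifnot(all(c("onset_s", "category", "condition", "duration_s") %in%
                  names(events)))
  if (nrow(events) == 0) return(invisible(events))
  if (any(!is.finite(events$onset_s)) || any(events$onset_s < 0)) {
    abort("event onsets must be finite and >= 0")
  }
  if (is.unsorted(events$onset_s)) {
    abort("event onsets must be sorted ascending")
  }
  if (any(events$duration_s <= 0)) abort("event durations must be > 0")
  bad <- !is.na(events$condition) &
    !events$condition %in% c("narrow", "wide")
  if (any(bad)) abort("condition labels must be 'narrow', 'wide' or NA")
  invisible(events)
}

#' Generate a random event train with a minimum inter-onset gap
#'
#' Places `n_events` onsets uniformly at random in `[0, duration_s)` subject
#' to all pairwise gaps being at least `min_gap_s` (the classical
#' spacing-by-translation construction: sorted uniforms plus a deterministic
#' gap ramp). Categories are assigned in exact proportions (largest-remainder
#' rounding) and then randomly permuted; conditions likewise when
#' `condition_split` is given.
#'
#' @param duration_s Soundscape duration in seconds.
#' @param n_events Number of events.
#' @param min_gap_s Minimum inter-onset interval in seconds.
#' @param categories Character vector of category labels to draw from.
#' @param category_probs Proportions per category (recycled uniform when
#'   `NULL`).
#' @param condition_split Named proportions over `c("narrow", "wide")`, or
#'   `NULL` for no condition labels.
#' @param tone_duration_s Duration recorded per event (seconds).
#' @param seed Integer seed; the result is a pure function of it.
#'
#' @return An [event_table()].
#' @export
generate_event_train <- function(duration_s, n_events, min_gap_s = 0.6,
                                 categories = c("beep", "irrelevant", "alarm"),
                                 category_probs = NULL,
                                 condition_split = NULL,
                                 tone_duration_s = 0.2,
                                 seed) {
  stopifnot(duration_s > 0, n_events >= 0, min_gap_s >= 0)
  if (missing(seed)) abort("`seed` is required: event trains are stochastic")
  if (n_events == 0) return(event_table())
  if (n_events * min_gap_s >= duration_s) {
    abort(sprintf(
      "cannot place %d events with min gap %.3g s in %.3g s of audio",
      n_events, min_gap_s, duration_s
    ))
  }
  slack <- duration_s - n_events * min_gap_s
  onsets <- withr::with_seed(as.integer(seed), {
    u <- sort(runif(n_events, 0, slack))
    on <- u + (seq_len(n_events) - 1L) * min_gap_s
    cat <- assign_proportional(categories, category_probs, n_events)
    cond <- if (is.null(condition_split)) {
      rep(NA_character_, n_events)
    } else {
      assign_proportional(names(condition_split),
                          unname(condition_split), n_events)
    }
    list(on = on, cat = cat, cond = cond)
  })
  event_table(onset_s = onsets$on, category = onsets$cat,
              condition = onsets$cond, duration_s = tone_duration_s)
}

# Exact-count assignment of labels by proportion (largest remainder),
# randomly permuted. Must be called inside a seeded RNG context.
assign_proportional <- function(labels, probs, n) {
  k <- length(labels)
  probs <- probs %||% rep(1 / k, k)
  stopifnot(length(probs) == k, all(probs >= 0), sum(probs) > 0)
  probs <- probs / sum(probs)
  counts <- floor(probs * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(probs * n - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  sample(rep(labels, times = counts))
}
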