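#' The hierarchical natural-sound taxonomy
#'
#' Builds the three-tier taxonomy of the 36 natural sound exemplars used in
#' the experiment: 2 superordinate categories (animate, inanimate), each
#' containing 2 intermediate categories (humans, animals, vehicles, objects),
#' each of which contains 3 subordinate categories with 3 exemplars apiece.
#'
#' @return A tibble with 36 rows and columns `exemplar`, `subordinate`,
#'   `intermediate`, `superordinate` (all character). Every exemplar carries
#'   exactly one label per tier.
#' @examples
#' tree <- build_taxonomy()
#' dplyr::count(tree, superordinate, intermediate)
#' @export
build_taxonomy <- function() {
  tree <- tibble::tribble(
    ~superordinate, ~intermediate, ~subordinate, ~exemplar,
    "animate",   "humans",   "mouth sounds", "baby",
    "animate",   "humans",   "mouth sounds", "cough",
    "animate",   "humans",   "mouth sounds", "talking",
    "animate",   "humans",   "feet sounds",  "walking with heels",
    "animate",   "humans",   "feet sounds",  "walking on gravel",
    "animate",   "humans",   "feet sounds",  "marching",
    "animate",   "humans",   "hand sounds",  "person clapping",
    "animate",   "humans",   "hand sounds",  "audience applause",
    "animate",   "humans",   "hand sounds",  "snapping fingers",
    "animate",   "animals",  "mammals",      "dog",
    "animate",   "animals",  "mammals",      "sheep",
    "animate",   "animals",  "mammals",      "horse",
    "animate",   "animals",  "birds",        "chicken",
    "animate",   "animals",  "birds",        "duck",
    "animate",   "animals",  "birds",        "seagull",
    "animate",   "animals",  "insects",      "bee",
    "animate",   "animals",  "insects",      "cricket",
    "animate",   "animals",  "insects",      "mosquito",
    "inanimate", "vehicles", "by road",      "bike",
    "inanimate", "vehicles", "by road",      "car",
    "inanimate", "vehicles", "by road",      "motorbike",
    "inanimate", "vehicles", "by air",       "helicopter",
    "inanimate", "vehicles", "by air",       "plane",
    "inanimate", "vehicles", "by air",       "jet",
    "inanimate", "vehicles", "by sea",       "ferry",
    "inanimate", "vehicles", "by sea",       "tugboat",
    "inanimate", "vehicles", "by sea",       "jetski",
    "inanimate", "objects",  "tools",        "drill",
    "inanimate", "objects",  "tools",        "hammer",
    "inanimate", "objects",  "tools",        "handsaw",
    "inanimate", "objects",  "kitchen",      "microwave",
    "inanimate", "objects",  "kitchen",      "teaspoon",
    "inanimate", "objects",  "kitchen",      "soda can",
    "inanimate", "objects",  "office",       "phone",
    "inanimate", "objects",  "office",       "scissors",
    "inanimate", "objects",  "office",       "typewriter"
  )
  tree[, c("exemplar", "subordinate", "intermediate", "superordinate")]
}

tier_levels <- c("superordinate", "intermediate", "subordinate", "exemplar")

validate_taxonomy <- function(tree) {
  stopifnot(is.data.frame(tree),
            all(c("exemplar", tier_levels[1:3]) %in% names(tree)))
  if (anyDuplicated(tree$exemplar) > 0)
    stop("taxonomy exemplars must be unique")
  invisible(tree)
}

# Reshuffle `labels` until no two adjacent entries are equal; falls back to a
# deterministic swap repair if rejection sampling stalls.
shuffle_no_repeat <- function(labels, max_tries = 200L) {
  n <- length(labels)
  if (n < 2L) return(sample(labels, n))
  for (i in seq_len(max_tries)) {
    cand <- sample(labels, n)
    if (!any(cand[-1] == cand[-n])) return(cand)
  }
  cand <- sample(labels, n)
  repeat {
    bad <- which(cand[-1] == cand[-n])
    if (length(bad) == 0L) return(cand)
    i <- bad[1] + 1L
    ok <- which(cand != cand[i - 1L] &
                  seq_len(n) != i &
                  c(cand[-1], NA) != cand[i] &
                  c(NA, cand[-n]) != cand[i])
    ok <- ok[!is.na(ok)]
    if (length(ok) == 0L) { cand <- sample(labels, n); next }
    j <- ok[sample.int(length(ok), 1L)]
    tmp <- cand[i]; cand[i] <- cand[j]; cand[j] <- tmp
  }
}

#' Generate a pseudo-randomized trial schedule
#'
#' Lays out the event sequence of the listening experiment: every exemplar is
#' presented `reps_per_sound` times, spread evenly over `n_runs` runs and
#' pseudo-randomized so that the same exemplar never occurs twice in a row. A
#' fraction of sound trials carry a target beep (half high-pitched at 800 Hz,
#' half low-pitched at 400 Hz) and additional silent null events let activity
#' return to baseline. Inter-stimulus intervals are jittered uniformly in
#' steps of `isi_jitter_s` around `isi_mean_s`.
#'
#' @param tree Taxonomy tibble from [build_taxonomy()].
#' @param n_runs Number of functional runs (default 4).
#' @param reps_per_sound Presentations per exemplar (default 12); must be
#'   divisible by `n_runs` so sound trials split evenly across runs.
#' @param beep_frac Fraction of sound trials carrying a target beep
#'   (default 0.10).
#' @param null_frac Number of null events as a fraction of the sound trials
#'   (default 0.10), distributed as evenly as possible across runs.
#' @param isi_mean_s,isi_jitter_s Mean inter-stimulus interval and jitter
#'   step, seconds. The realized ISI is drawn uniformly from
#'   `isi_mean_s + {-1, 0, +1} * isi_jitter_s`.
#' @param seed Integer seed; the same seed reproduces the same schedule.
#' @return A tibble with one row per event and columns `run`, `trial`,
#'   `onset_s`, `kind` (`"sound"` or `"null"`), `exemplar`, `beep`
#'   (`"none"`, `"high_800Hz"`, `"low_400Hz"`), `duration_s`, `isi_s`.
#'   Onsets increase strictly within each run.
#' @examples
#' sched <- generate_schedule(build_taxonomy(), seed = 1)
#' table(sched$kind)
#' @export
generate_schedule <- function(tree, n_runs = 4, reps_per_sound = 12,
                              beep_frac = 0.10, null_frac = 0.10,
                              isi_mean_s = 4.0, isi_jitter_s = 0.5,
                              seed = 1L) {
  validate_taxonomy(tree)
  n_ex <- nrow(tree)
  if ((n_ex * reps_per_sound) %% n_runs != 0)
    stop("total sound trials (", n_ex * reps_per_sound,
         ") not divisible by n_runs (", n_runs, ")")
  if (reps_per_sound %% n_runs != 0)
    stop("reps_per_sound (", reps_per_sound,
         ") must be divisible by n_runs (", n_runs,
         ") so each exemplar appears equally often in every run")
  n_sound <- n_ex * reps_per_sound
  per_run_reps <- reps_per_sound %/% n_runs
  n_beep <- round(beep_frac * n_sound)
  n_null <- round(null_frac * n_sound)

  with_seed(seed, {
    # fixed per-exemplar sound durations, uniform on [2, 3] s
    dur <- stats::setNames(runif(n_ex, 2, 3), tree$exemplar)

    runs <- purrr::map(seq_len(n_runs), function(r) {
      seq_ex <- shuffle_no_repeat(rep(tree$exemplar, per_run_reps))
      tibble::tibble(run = r, kind = "sound", exemplar = seq_ex)
    })
    events <- dplyr::bind_rows(runs)

    # null events: as even a split across runs as possible, random positions
    null_per_run <- rep(n_null %/% n_runs, n_runs)
    extra <- n_null %% n_runs
    if (extra > 0) null_per_run[seq_len(extra)] <- null_per_run[seq_len(extra)] + 1L
    events <- dplyr::bind_rows(purrr::map(seq_len(n_runs), function(r) {
      ev <- events[events$run == r, ]
      nn <- null_per_run[r]
      if (nn > 0) {
        pos <- sort(sample.int(nrow(ev) + nn, nn))
        out <- tibble::tibble(run = r, kind = rep("sound", nrow(ev) + nn),
                              exemplar = NA_character_)
        out$kind[pos] <- "null"
        out$exemplar[out$kind == "sound"] <- ev$exemplar
        out
      } else ev
    }))

    # beeps: uniformly at random over sound trials, half high / half low
    is_sound <- which(events$kind == "sound")
    beep_ix <- sample(is_sound, n_beep)
    events$beep <- "none"
    hi <- ceiling(n_beep / 2)
    events$beep[beep_ix[seq_len(hi)]] <- "high_800Hz"
    if (n_beep > hi) events$beep[beep_ix[(hi + 1):n_beep]] <- "low_400Hz"

    events$duration_s <- ifelse(events$kind == "sound",
                                unname(dur[events$exemplar]), 2.5)
    jit <- if (isi_jitter_s > 0) {
      sample(c(-1, 0, 1), nrow(events), replace = TRUE) * isi_jitter_s
    } else rep(0, nrow(events))
    events$isi_s <- isi_mean_s + jit

    events <- events |>
      dplyr::group_by(.data$run) |>
      dplyr::mutate(
        trial = dplyr::row_number(),
        onset_s = cumsum(dplyr::lag(.data$duration_s + .data$isi_s,
                                    default = 0))
      ) |>
      dplyr::ungroup()
    events[, c("run", "trial", "onset_s", "kind", "exemplar", "beep",
               "duration_s", "isi_s")]
  })
}

#' Category labels of the sound trials at a given tier
#'
#' Maps every sound trial of a schedule to its category label at the
#' requested tier of the taxonomy. Null trials carry no label and are
#' excluded.
#'
#' @param schedule Schedule tibble from [generate_schedule()].
#' @param tree Taxonomy tibble from [build_taxonomy()].
#' @param level One of `"superordinate"`, `"intermediate"`, `"subordinate"`,
#'   `"exemplar"`.
#' @return Character vector with one label per sound trial, in schedule
#'   order.
#' @export
labels_for_level <- function(schedule, tree,
                             level = c("superordinate", "intermediate",
                                       "subordinate", "exemplar")) {
  level <- match.arg(level)
  validate_taxonomy(tree)
  snd <- schedule[schedule$kind == "sound", , drop = FALSE]
  if (nrow(snd) == 0L) return(character(0))
  unknown <- setdiff(unique(snd$exemplar), tree$exemplar)
  if (length(unknown) > 0)
    stop("schedule contains exemplars absent from the taxonomy: ",
         paste(unknown, collapse = ", "))
  if (level == "exemplar") return(snd$exemplar)
  lut <- stats::setNames(tree[[level]], tree$exemplar)
  unname(lut[snd$exemplar])
}

#' Write or read a trial schedule as CSV
#'
#' @param schedule Schedule tibble.
#' @param path File path.
#' @return `write_schedule_csv()` returns `path` invisibly;
#'   `read_schedule_csv()` returns the schedule tibble.
#' @export
write_schedule_csv <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write or read the taxonomy as CSV
#'
#' Mirrors the exemplar table: one row per exemplar with its three tier
#' labels.
#'
#' @param tree Taxonomy tibble from [build_taxonomy()].
#' @param path File path.
#' @return `write_taxonomy_csv()` returns `path` invisibly;
#'   `read_taxonomy_csv()` returns the validated taxonomy tibble.
#' @export
write_taxonomy_csv <- function(tree, path) {
  validate_taxonomy(tree)
  utils::write.csv(tree, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy_csv
#' @export
read_taxonomy_csv <- function(path) {
  tree <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  validate_taxonomy(tree)
  tree
}
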