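#' Trial sequences for the repetition-detection task
#'
#' A trial sequence is a data frame with one row per trial and columns
#' `index`, `category` (`"RefTC-1"`, `"RefTC-2"`, `"RefTC-3"`, `"RTC"`,
#' `"NTC"`), `exemplar_id` (RefTC only, otherwise `NA`), `onset_s`,
#' `duration_s` and `repetition_present` (ground truth: `TRUE` unless the
#' trial is an NTC). Onsets are spaced at `stimulus_s + isi_s` with no
#' jitter. Attributes `phase`, `isi_s` and `stimulus_s` record the design.
#'
#' @name trial_sequence
NULL

trial_categories <- c("RefTC-1", "RefTC-2", "RefTC-3", "RTC", "NTC")

as_trial_sequence <- function(categories, phase, isi_s = 3, stimulus_s = 1.5) {
  n <- length(categories)
  ex <- rep(NA_integer_, n)
  is_ref <- grepl("^RefTC-", categories)
  ex[is_ref] <- as.integer(sub("^RefTC-", "", categories[is_ref]))
  out <- data.frame(
    index = seq_len(n),
    category = categories,
    exemplar_id = ex,
    onset_s = (seq_len(n) - 1) * (stimulus_s + isi_s),
    duration_s = rep(stimulus_s, n),
    repetition_present = categories != "NTC",
    stringsAsFactors = FALSE
  )
  structure(out, phase = phase, isi_s = isi_s, stimulus_s = stimulus_s,
            class = c("trial_sequence", "data.frame"))
}

#' Generate one training block
#'
#' A training block presents one RefTC exemplar together with RTC and NTC
#' trials, `n_per_class` of each, in pseudorandom order constrained so that
#' no two RefTC trials are adjacent. The order is sampled uniformly over
#' valid arrangements by shuffling the non-RefTC trials and inserting the
#' RefTC trials into distinct gaps between them.
#'
#' @param n_per_class Trials per category (training default 20).
#' @param ref_exemplar_id Which RefTC exemplar (1-3) this block trains.
#' @param isi_s,stimulus_s Inter-stimulus interval and stimulus duration (s).
#' @return A [trial_sequence] of `3 * n_per_class` trials.
#' @export
generate_training_block <- function(n_per_class = 20, ref_exemplar_id = 1L,
                                    isi_s = 3, stimulus_s = 1.5) {
  if (n_per_class < 1) stop("design infeasible: n_per_class >= 1", call. = FALSE)
  ref <- paste0("RefTC-", as.integer(ref_exemplar_id))
  others <- sample(rep(c("RTC", "NTC"), each = n_per_class))
  n_gaps <- length(others) + 1          # before, between and after the others
  if (n_per_class > n_gaps)
    stop("design infeasible: too many RefTC trials to keep non-adjacent",
         call. = FALSE)
  gaps <- sort(sample.int(n_gaps, n_per_class))
  ord <- character(0)
  for (g in seq_len(n_gaps)) {
    if (g %in% gaps) ord <- c(ord, ref)
    if (g <= length(others)) ord <- c(ord, others[g])
  }
  as_trial_sequence(ord, phase = "training-block",
                    isi_s = isi_s, stimulus_s = stimulus_s)
}

#' Generate the test session
#'
#' The scanned test session mixes the three trained RefTC exemplars with
#' fresh RTC and NTC trials in fully random order (the default counts give
#' the standard 20/20/20 + 60 + 120 = 240-trial session).
#'
#' @param n_ref_per_exemplar Trials per RefTC exemplar.
#' @param n_rtc,n_ntc RTC and NTC trial counts.
#' @param isi_s,stimulus_s Inter-stimulus interval and stimulus duration (s).
#' @return A [trial_sequence].
#' @export
generate_test_session <- function(n_ref_per_exemplar = 20, n_rtc = 60, n_ntc = 120,
                                  isi_s = 3, stimulus_s = 1.5) {
  stopifnot(n_ref_per_exemplar >= 0, n_rtc >= 0, n_ntc >= 0)
  cats <- c(rep(c("RefTC-1", "RefTC-2", "RefTC-3"), each = n_ref_per_exemplar),
            rep("RTC", n_rtc), rep("NTC", n_ntc))
  if (length(cats) > 1) cats <- sample(cats)
  as_trial_sequence(cats, phase = "test-session",
                    isi_s = isi_s, stimulus_s = stimulus_s)
}

#' Observer model parameters
#'
#' A simple stand-in for a human listener doing within-trial repetition
#' detection. Repeated stimuli (RTC and RefTC before any exposure) are
#' reported "yes" with probability `base_yes_rate_repeated`; NTC trials
#' draw false alarms at `false_alarm_rate`. Each prior exposure to a given
#' RefTC exemplar adds `learning_increment` to its yes-probability
#' (capped at 1), emulating incidental template learning; lapses flip the
#' intended response with probability `lapse_rate`.
#'
#' @param base_yes_rate_repeated Hit probability for an unlearnt repeated
#'   stimulus.
#' @param false_alarm_rate Yes-probability on NTC trials.
#' @param learning_increment Per-exposure increase in RefTC hit probability.
#' @param lapse_rate Probability of flipping the response.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(base_yes_rate_repeated = 0.6, false_alarm_rate = 0.25,
                            learning_increment = 0.02, lapse_rate = 0.02) {
  p <- c(base_yes_rate_repeated, false_alarm_rate, learning_increment, lapse_rate)
  if (any(p < 0) || any(p[c(1, 2, 4)] > 1))
    stop("observer probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(base_yes_rate_repeated = base_yes_rate_repeated,
                 false_alarm_rate = false_alarm_rate,
                 learning_increment = learning_increment,
                 lapse_rate = lapse_rate),
            class = "observer_params")
}

#' Simulate an observer's responses
#'
#' @param sequence A [trial_sequence].
#' @param params An [observer_params()].
#' @return The sequence with a logical `response` column added.
#' @export
simulate_observer <- function(sequence, params = observer_params()) {
  stopifnot(inherits(sequence, "trial_sequence"), inherits(params, "observer_params"))
  n <- nrow(sequence)
  exposure <- integer(4)  # prior exposures per RefTC exemplar id (1..3)
  p_yes <- numeric(n)
  for (i in seq_len(n)) {
    cat_i <- sequence$category[i]
    if (grepl("^RefTC-", cat_i)) {
      id <- sequence$exemplar_id[i]
      p_yes[i] <- min(1, params$base_yes_rate_repeated +
                        params$learning_increment * exposure[id])
      exposure[id] <- exposure[id] + 1L
    } else if (cat_i == "RTC") {
      p_yes[i] <- params$base_yes_rate_repeated
    } else {
      p_yes[i] <- params$false_alarm_rate
    }
  }
  resp <- runif(n) < p_yes
  lapse <- runif(n) < params$lapse_rate
  sequence$response <- ifelse(lapse, !resp, resp)
  sequence
}

#' Sensitivity index d-prime
#'
#' `d' = z(H) - z(FA)` with `z` the standard-normal quantile. Extreme rates
#' are corrected before the quantile: with the default `"halfN"` rule a
#' rate of 0 becomes `1/(2N)` and a rate of 1 becomes `1 - 1/(2N)`; the
#' `"loglinear"` rule instead adds 0.5 to the counts and 1 to the totals.
#'
#' @param hits,n_signal Hit count and number of signal (repeated) trials.
#' @param fas,n_noise False-alarm count and number of noise (NTC) trials.
#' @param correction Extreme-rate correction rule.
#' @return The d-prime value (finite scalar).
#' @export
compute_dprime <- function(hits, n_signal, fas, n_noise,
                           correction = c("halfN", "loglinear")) {
  correction <- match.arg(correction)
  if (n_signal < 1 || n_noise < 1)
    stop("invalid input: trial counts must be >= 1", call. = FALSE)
  if (hits < 0 || hits > n_signal || fas < 0 || fas > n_noise)
    stop("invalid input: counts exceed totals", call. = FALSE)
  if (correction == "loglinear") {
    h <- (hits + 0.5) / (n_signal + 1)
    f <- (fas + 0.5) / (n_noise + 1)
  } else {
    h <- hits / n_signal
    f <- fas / n_noise
    h <- min(max(h, 1 / (2 * n_signal)), 1 - 1 / (2 * n_signal))
    f <- min(max(f, 1 / (2 * n_noise)), 1 - 1 / (2 * n_noise))
  }
  qnorm(h) - qnorm(f)
}

#' Behavioural summary of a responded sequence
#'
#' Computes per-class hit rates and d-prime for each RefTC exemplar and for
#' RTC, each against the session-wide NTC false-alarm rate.
#'
#' @param sequence A [trial_sequence] with a `response` column.
#' @param correction Extreme-rate correction passed to [compute_dprime()].
#' @return A data frame with one row per class (`RefTC-1..3`, `RTC`) and
#'   columns `class`, `n`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
behavioural_summary <- function(sequence, correction = c("halfN", "loglinear")) {
  correction <- match.arg(correction)
  stopifnot(!is.null(sequence$response))
  noise <- sequence$category == "NTC"
  n_noise <- sum(noise)
  fas <- sum(sequence$response[noise])
  classes <- intersect(trial_categories[1:4], unique(sequence$category))
  rows <- lapply(classes, function(cl) {
    sel <- sequence$category == cl
    n <- sum(sel)
    hits <- sum(sequence$response[sel])
    data.frame(class = cl, n = n, hit_rate = hits / n, fa_rate = fas / n_noise,
               dprime = compute_dprime(hits, n, fas, n_noise, correction),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write or read a trial sequence as a BIDS-style events table
#'
#' Tab-separated with columns `onset`, `duration`, `category`,
#' `exemplar_id`, `repetition_present` and `response`; missing values are
#' written as `n/a`.
#'
#' @param sequence A [trial_sequence].
#' @param path Output TSV path.
#' @return `path` invisibly (`write_events`); a [trial_sequence]
#'   (`read_events`).
#' @export
write_events <- function(sequence, path) {
  out <- data.frame(onset = sequence$onset_s, duration = sequence$duration_s,
                    category = sequence$category,
                    exemplar_id = sequence$exemplar_id,
                    repetition_present = sequence$repetition_present,
                    response = if (is.null(sequence$response)) NA else sequence$response)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "n/a")
  invisible(path)
}

#' @rdname write_events
#' @param phase,isi_s,stimulus_s Design attributes to attach on read.
#' @export
read_events <- function(path, phase = "test-session", isi_s = 3, stimulus_s = 1.5) {
  tab <- read.delim(path, na.strings = "n/a", stringsAsFactors = FALSE)
  seq <- as_trial_sequence(tab$category, phase = phase,
                           isi_s = isi_s, stimulus_s = stimulus_s)
  seq$onset_s <- tab$onset
  seq$duration_s <- tab$duration
  if (!all(is.na(tab$response))) seq$response <- as.logical(tab$response)
  seq
}
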