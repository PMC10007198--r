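#' Conveyor belt configuration
#'
#' Kinematics of the sorting conveyor: kernels are spaced `spacing_mm`
#' apart on the belt and dropped every `interval_s` seconds into one of
#' `n_channels` parallel sorting channels.
#'
#' @param spacing_mm Kernel spacing on the belt in millimetres
#'   (default 30).
#' @param interval_s Seconds between kernel drops per channel.
#' @param n_channels Number of parallel sorting channels (default 3).
#' @return A list of class `"belt_config"`.
#' @export
belt_config <- function(spacing_mm = 30, interval_s = 0.5, n_channels = 3L) {
  if (spacing_mm <= 0 || interval_s <= 0 || n_channels < 1)
    stop("belt_config fields must be positive")
  structure(list(spacing_mm = spacing_mm, interval_s = interval_s,
                 n_channels = as.integer(n_channels)),
            class = "belt_config")
}

#' Belt speed implied by spacing and drop interval
#'
#' For the belt to keep kernels `spacing_mm` apart at one drop every
#' `interval_s` seconds, it must run at
#' `spacing_mm / 1000 / interval_s` metres per second: 30 mm at 0.5 s
#' gives 0.060 m/s, at 0.45 s 0.067 m/s, at 0.4 s 0.075 m/s.
#'
#' @param cfg A [belt_config()].
#' @return Belt speed in m/s.
#' @export
belt_speed <- function(cfg) {
  stopifnot(inherits(cfg, "belt_config"))
  cfg$spacing_mm / 1000 / cfg$interval_s
}

#' @rdname belt_speed
#' @return `drop_rate`: total kernels dropped per minute across all
#'   channels (`n_channels * 60 / interval_s`).
#' @export
drop_rate <- function(cfg) {
  stopifnot(inherits(cfg, "belt_config"))
  cfg$n_channels * 60 / cfg$interval_s
}

#' Default double-drop probability curve
#'
#' Probability that the seed-drop device releases two kernels at once,
#' as a function of the drop interval: faster dropping (shorter
#' interval) raises the failure rate. The curve is a non-increasing
#' linear interpolation through calibration points chosen once so that
#' simulated accuracies at a 0.96-accurate classifier bracket the
#' 94.4% to 92.1% span observed across 0.5/0.45/0.4 s intervals; it is
#' illustrative, not a mechanistic claim.
#'
#' @param interval_s Drop interval in seconds.
#' @return Probability in `[0, 1]`.
#' @export
default_p_double <- function(interval_s) {
  pts_t <- c(0.30, 0.40, 0.45, 0.50, 0.70)
  pts_p <- c(0.200, 0.093, 0.057, 0.036, 0.010)
  clip01(approx(pts_t, pts_p, xout = pmin(pmax(interval_s, 0.30), 0.70))$y)
}

#' Sorting-run specification
#'
#' @param n_fluor,n_non Numbers of fluorescent and non-fluorescent
#'   kernels in the mixed sample (defaults 500 + 500).
#' @param p_correct Per-kernel classifier accuracy in `[0, 1]`.
#' @param p_double A function of the drop interval giving the
#'   double-drop probability (default [default_p_double()]), or a fixed
#'   number.
#' @param seed Integer RNG seed.
#' @return A list of class `"sort_run"`.
#' @export
sort_run <- function(n_fluor = 500L, n_non = 500L, p_correct = 0.96,
                     p_double = default_p_double, seed = 1L) {
  if (n_fluor < 0 || n_non < 0) stop("sample sizes must be non-negative")
  if (p_correct < 0 || p_correct > 1) stop("p_correct must be in [0, 1]")
  if (is.numeric(p_double)) {
    pd <- p_double
    if (pd < 0 || pd > 1) stop("p_double must be in [0, 1]")
    p_double <- function(interval_s) pd
  }
  structure(list(n_fluor = as.integer(n_fluor), n_non = as.integer(n_non),
                 p_correct = p_correct, p_double = p_double,
                 seed = as.integer(seed)),
            class = "sort_run")
}

#' Simulate one conveyor sorting run
#'
#' The mixed sample is shuffled into a drop order. Each drop is a
#' double drop with probability `p_double(interval_s)`; a double-dropped
#' pair shares a single classification decision (the second kernel is
#' routed wherever the first was sent). Single kernels are classified
#' correctly with probability `p_correct`. Counts are accumulated into
#' per-kernel confusion counts (fluorescent = positive), so
#' `tp + tn + fp + fn = n_fluor + n_non` on every run. The result also
#' reports how many kernels were misrouted mechanically (double-drop
#' tails sent to the wrong channel) versus misclassified by the model.
#'
#' @param run A [sort_run()].
#' @param cfg A [belt_config()]; only `interval_s` enters the failure
#'   model.
#' @return A [confusion_counts()] with attributes `"n_double_misroute"`
#'   and `"n_model_error"`.
#' @export
simulate_sorting <- function(run, cfg = belt_config()) {
  stopifnot(inherits(run, "sort_run"), inherits(cfg, "belt_config"))
  pd <- run$p_double(cfg$interval_s)
  with_seed(run$seed, {
    is_fluor <- sample(rep(c(TRUE, FALSE), c(run$n_fluor, run$n_non)))
    n <- length(is_fluor)
    routed_fluor <- logical(n)   # channel each kernel ends up in
    mech <- 0L; model_err <- 0L
    i <- 1L
    while (i <= n) {
      double <- i < n && runif(1) < pd
      correct <- runif(1) < run$p_correct
      decision <- if (correct) is_fluor[i] else !is_fluor[i]
      if (!correct) model_err <- model_err + 1L
      routed_fluor[i] <- decision
      if (double) {
        routed_fluor[i + 1L] <- decision   # pair shares one decision
        if (decision != is_fluor[i + 1L]) mech <- mech + 1L
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    cc <- confusion_counts(
      tp = sum(is_fluor & routed_fluor),
      tn = sum(!is_fluor & !routed_fluor),
      fp = sum(!is_fluor & routed_fluor),
      fn = sum(is_fluor & !routed_fluor))
    attr(cc, "n_double_misroute") <- mech
    attr(cc, "n_model_error") <- model_err
    cc
  })
}

#' Accuracy-versus-speed sorting experiment
#'
#' Repeats [simulate_sorting()] over a grid of drop intervals,
#' reporting mean metrics across seeded replicates: the protocol of a
#' mixed 500+500 sample sorted at progressively shorter drop intervals.
#'
#' @param intervals_s Drop intervals to test (default 0.5, 0.45, 0.4).
#' @param run Template [sort_run()]; each replicate `r` at interval `i`
#'   uses a seed derived from `run$seed`, `i` and `r`.
#' @param reps Replicates per interval.
#' @param spacing_mm,n_channels Passed to [belt_config()].
#' @return A data frame with one row per interval: belt speed, drop
#'   rate, mean TP/TN/FP/FN and mean precision/recall/accuracy.
#' @export
sorting_experiment <- function(intervals_s = c(0.5, 0.45, 0.4),
                               run = sort_run(), reps = 20L,
                               spacing_mm = 30, n_channels = 3L) {
  rows <- lapply(seq_along(intervals_s), function(ii) {
    cfg <- belt_config(spacing_mm, intervals_s[ii], n_channels)
    ccs <- lapply(seq_len(reps), function(r) {
      rr <- run
      rr$seed <- as.integer(mix_seed(run$seed, ii * 1000 + r))
      simulate_sorting(rr, cfg)
    })
    m <- function(f) mean(vapply(ccs, f, 0))
    data.frame(interval_s = intervals_s[ii],
               belt_speed_mps = belt_speed(cfg),
               drop_rate_npm = drop_rate(cfg),
               tp = m(function(c) c$tp), tn = m(function(c) c$tn),
               fp = m(function(c) c$fp), fn = m(function(c) c$fn),
               precision = m(precision), recall = m(recall),
               accuracy = m(accuracy))
  })
  do.call(rbind, rows)
}
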