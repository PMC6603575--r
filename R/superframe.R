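# Superframe communications scheme: beacon + channel-request registration
# (CRR) + requested communications (RC) + periodic communications (PC),
# with a truncated-Poisson analytic delay model and a matching
# discrete-event Monte-Carlo simulator.

#' Superframe protocol configuration
#'
#' Timing and capacity parameters of the TDMA superframe. Each superframe of
#' duration `T_frame` carries `m_slots` timeslots of duration `t_slot`;
#' `p_slots` of them form the periodic-communication (PC) section served
#' round-robin across the `n_devices` affiliated devices, the remaining
#' `m_slots - p_slots` form the requested-communication (RC) section used by
#' devices whose sensor reading changed by more than `delta_th` since their
#' last transmission. Each timeslot splits into a communication window of
#' `(1 - delta) * t_slot` and an acknowledgement window of `delta * t_slot`.
#' Beacon and CRR durations are absorbed into the `T_frame - m_slots * t_slot`
#' idle remainder and are not separately parameterised.
#'
#' The number of PC slots per frame is not pinned down by the protocol
#' definition; the default splits the frame evenly (`p_slots = m_slots / 2`).
#'
#' @param T_frame Superframe duration in seconds (default 5 ms).
#' @param n_devices Maximum number of devices affiliated to the data sink.
#' @param m_slots Total timeslots per superframe.
#' @param p_slots Periodic-communication slots per superframe
#'   (`1 <= p_slots <= m_slots`).
#' @param t_slot Timeslot duration in seconds (default 300 microseconds).
#' @param delta Acknowledgement fraction of a timeslot (default 1/6, i.e. a
#'   50 microsecond acknowledgement window).
#' @param omega Number of parallel processing streams at the data sink.
#' @param delta_th Sensor-change request threshold, in signal-magnitude units
#'   (g for accelerometer streams).
#'
#' @return An object of class `superframe_config` (a validated list).
#' @examples
#' cfg <- superframe_config()
#' periodic_interval(cfg)
#' @export
superframe_config <- function(T_frame = 5e-3, n_devices = 50, m_slots = 10,
                              p_slots = m_slots / 2, t_slot = 300e-6,
                              delta = 1 / 6, omega = 4, delta_th = 0.05) {
  check_number(T_frame, "T_frame", min = 0, strict_min = TRUE)
  check_number(n_devices, "n_devices", min = 1)
  check_number(m_slots, "m_slots", min = 1)
  check_number(p_slots, "p_slots", min = 1, max = m_slots, strict_min = FALSE)
  if (p_slots <= 0) abort_bad_input("`p_slots` must be positive")
  check_number(t_slot, "t_slot", min = 0, strict_min = TRUE)
  check_number(delta, "delta", min = 0, max = 1)
  if (delta <= 0 || delta >= 1) abort_bad_input("`delta` must be in (0, 1)")
  check_number(omega, "omega", min = 1)
  check_number(delta_th, "delta_th", min = 0, strict_min = TRUE)
  if (m_slots * t_slot > T_frame + 1e-12) {
    abort_bad_input("timeslots do not fit in the superframe: m_slots * t_slot > T_frame")
  }
  structure(
    list(T_frame = T_frame, n_devices = as.integer(n_devices),
         m_slots = as.integer(m_slots), p_slots = as.integer(p_slots),
         t_slot = t_slot, delta = delta, omega = as.integer(omega),
         delta_th = delta_th),
    class = "superframe_config"
  )
}

#' @export
print.superframe_config <- function(x, ...) {
  cat("<superframe_config>\n")
  cat(sprintf("  T = %g ms, %d slots x %g us (%d periodic + %d requested)\n",
              x$T_frame * 1e3, x$m_slots, x$t_slot * 1e6, x$p_slots,
              x$m_slots - x$p_slots))
  cat(sprintf("  n = %d devices, TR = %g ms, delta = %.3f, omega = %d\n",
              x$n_devices, periodic_interval(x) * 1e3, x$delta, x$omega))
  invisible(x)
}

#' Delay-model parameters
#'
#' Parameters of the end-to-end delay decomposition: `alpha`, the average
#' number of channel requests per superframe; `sigma`, the machine processing
#' delay (feature extraction plus class identification) at the data sink; and
#' `dc`, the control-channel feedback delay. With `omega` parallel processing
#' streams `dc` ranges from one timeslot `t` to `omega * t`; the default takes
#' the conservative upper end of that range.
#'
#' @param alpha Average channel requests per frame (non-negative).
#' @param sigma Processing delay in seconds (non-negative).
#' @param dc Feedback delay in seconds; defaults to `omega * t_slot` of
#'   `config`.
#' @param config A [superframe_config()] used to derive the default `dc`.
#'
#' @return An object of class `delay_params`.
#' @export
delay_params <- function(alpha = 5, sigma = 0, dc = NULL,
                         config = superframe_config()) {
  check_number(alpha, "alpha", min = 0)
  check_number(sigma, "sigma", min = 0)
  if (is.null(dc)) dc <- config$omega * config$t_slot
  check_number(dc, "dc", min = 0)
  structure(list(alpha = alpha, sigma = sigma, dc = dc),
            class = "delay_params")
}

#' Truncated Poisson probability mass function
#'
#' PMF of the number of channel requests per superframe: a Poisson
#' distribution with mean `alpha`, truncated (renormalised) to the support
#' `0:n_max`, `n_max` being the number of affiliated devices.
#'
#' @param alpha Mean request rate per frame (non-negative).
#' @param n_max Upper support bound (positive integer).
#'
#' @return Numeric probability vector of length `n_max + 1`; element `i + 1`
#'   is the probability of `i` requests. Sums to one; for `alpha = 0` it is
#'   the point mass at zero.
#' @examples
#' truncated_poisson_pmf(1, 1) # c(0.5, 0.5)
#' @export
truncated_poisson_pmf <- function(alpha, n_max) {
  check_number(alpha, "alpha", min = 0)
  check_number(n_max, "n_max", min = 1)
  if (n_max != floor(n_max)) abort_bad_input("`n_max` must be an integer")
  if (alpha == 0) return(c(1, rep(0, n_max)))
  p <- dpois(0:n_max, alpha)
  p / sum(p)
}

#' Periodic service interval
#'
#' Time between successive guaranteed (periodic-communication) transmissions
#' of one device under the round-robin schedule: `ceil(n / p) * T`, with `n`
#' affiliated devices and `p` periodic slots per superframe of duration `T`.
#'
#' @param config A [superframe_config()].
#' @return Interval in seconds.
#' @examples
#' periodic_interval(superframe_config(p_slots = 10)) # 25 ms
#' @export
periodic_interval <- function(config) {
  stopifnot(inherits(config, "superframe_config"))
  if (config$p_slots <= 0) abort_bad_input("p_slots must be positive")
  ceiling(config$n_devices / config$p_slots) * config$T_frame
}

# Per-request service delay within a registration cohort.
#
# The r-th request of a cohort (requests registered at the same CRR, served
# FIFO in ascending device id) is scheduled into RC slot ((r-1) mod K) + 1 of
# the frame floor((r-1) / K) frames after registration, K = m - p being the
# RC slots per frame. Its delay, CRR registration to the end of its
# communication window, is floor((r-1)/K) * T + (slot - delta) * t.
cohort_request_delays <- function(config, n_requests) {
  if (n_requests == 0L) return(numeric(0))
  K <- config$m_slots - config$p_slots
  r <- seq_len(n_requests) - 1L
  (r %/% K) * config$T_frame +
    ((r %% K) + 1 - config$delta) * config$t_slot
}

#' Analytic average requested-communication delay
#'
#' Exact expectation of the per-request sensed-data communication delay under
#' the superframe request scheme. Per frame, the number of requesting devices
#' follows the truncated Poisson law of [truncated_poisson_pmf()] capped at
#' `n`; a cohort of `i` requests is served FIFO over the `m - p` RC slots of
#' the registration frame, overflowing into subsequent frames in whole-frame
#' deferrals of `floor((r-1)/(m-p)) * T` for the r-th request. The averaged
#' sensed-data delay `ds` is the size-biased (per-request) expectation
#' `E[sum of cohort delays] / E[cohort size]`; the end-to-end total adds the
#' processing delay `sigma` and the feedback delay `dc`.
#'
#' @param config A [superframe_config()]; requires `m_slots > p_slots`.
#' @param params A [delay_params()].
#'
#' @return A `delay_report` object with fields `ds`, `sigma`, `dc`,
#'   `total = ds + sigma + dc`, `alpha` and `p_slots` used. Use [tidy()] for
#'   a tibble view.
#' @seealso [simulate_superframes()] for the Monte-Carlo counterpart.
#' @export
analytic_average_delay <- function(config, params) {
  stopifnot(inherits(config, "superframe_config"),
            inherits(params, "delay_params"))
  if (config$m_slots <= config$p_slots) {
    abort_bad_input("no requested-communication slots: m_slots must exceed p_slots")
  }
  n <- config$n_devices
  pmf <- truncated_poisson_pmf(params$alpha, n)
  d <- cohort_request_delays(config, n)
  cohort_sum <- c(0, cumsum(d)) # indexed by cohort size 0..n
  e_size <- sum((0:n) * pmf)
  ds <- if (e_size == 0) 0 else sum(pmf * cohort_sum) / e_size
  new_delay_report(ds = ds, sigma = params$sigma, dc = params$dc,
                   alpha = params$alpha, config = config,
                   method = "analytic")
}

new_delay_report <- function(ds, sigma, dc, alpha, config, method,
                             samples = NULL, se = NA_real_,
                             n_frames = NA_integer_, n_requests = NA_integer_) {
  structure(
    list(ds = ds, sigma = sigma, dc = dc, total = ds + sigma + dc,
         alpha = alpha, p_slots = config$p_slots, method = method,
         samples = samples, se = se, n_frames = n_frames,
         n_requests = n_requests),
    class = "delay_report"
  )
}

#' @export
print.delay_report <- function(x, ...) {
  cat(sprintf("<delay_report [%s]> alpha = %g, p = %d\n",
              x$method, x$alpha, x$p_slots))
  cat(sprintf("  ds = %.4g ms, sigma = %.4g ms, dc = %.4g ms, total = %.4g ms\n",
              x$ds * 1e3, x$sigma * 1e3, x$dc * 1e3, x$total * 1e3))
  if (!is.na(x$se)) {
    cat(sprintf("  Monte-Carlo se(ds) = %.3g ms over %d frames, %d requests\n",
                x$se * 1e3, x$n_frames, x$n_requests))
  }
  invisible(x)
}

#' @rdname analytic_average_delay
#' @param x A `delay_report`.
#' @param ... Unused.
#' @method tidy delay_report
#' @export
tidy.delay_report <- function(x, ...) {
  tibble::tibble(method = x$method, alpha = x$alpha, p_slots = x$p_slots,
                 ds = x$ds, sigma = x$sigma, dc = x$dc, total = x$total,
                 se = x$se)
}

#' Discrete-event simulation of the superframe scheme
#'
#' Monte-Carlo counterpart of [analytic_average_delay()]. Per frame, the
#' number of requesting devices is drawn from the truncated Poisson law
#' capped at `n`; the frame's cohort is served FIFO (ascending device id)
#' over the RC slots, overflow requests deferring by whole frames. Cohorts
#' are scheduled independently of each other; every request is served exactly
#' once and no two requests of a cohort share a slot. The reported `ds` is
#' the mean delay over all simulated requests, with a delta-method
#' Monte-Carlo standard error.
#'
#' @param config A [superframe_config()].
#' @param alpha Average requests per frame.
#' @param n_frames Number of superframes to simulate.
#' @param seed Integer RNG seed; runs are reproducible for a fixed seed.
#' @param sigma,dc Optional processing and feedback delays added to the
#'   report totals (defaults 0 and `omega * t_slot`).
#' @param keep_samples If `TRUE`, attach the per-request delay vector to the
#'   report (`samples`).
#'
#' @return A `delay_report` with Monte-Carlo fields `se`, `n_frames`,
#'   `n_requests` filled in.
#' @export
simulate_superframes <- function(config, alpha, n_frames, seed,
                                 sigma = 0, dc = NULL, keep_samples = FALSE) {
  stopifnot(inherits(config, "superframe_config"))
  check_number(alpha, "alpha", min = 0)
  check_number(n_frames, "n_frames", min = 1)
  if (config$m_slots <= config$p_slots) {
    abort_bad_input("no requested-communication slots: m_slots must exceed p_slots")
  }
  if (is.null(dc)) dc <- config$omega * config$t_slot
  n <- config$n_devices
  pmf <- truncated_poisson_pmf(alpha, n)
  set.seed(as.integer(seed))
  counts <- sample.int(n + 1L, size = n_frames, replace = TRUE, prob = pmf) - 1L

  d <- cohort_request_delays(config, n)
  cohort_sum <- c(0, cumsum(d))
  cohort_sq <- c(0, cumsum(d^2))

  tot_requests <- sum(counts)
  if (tot_requests == 0) {
    rep <- new_delay_report(ds = 0, sigma = sigma, dc = dc, alpha = alpha,
                            config = config, method = "simulation",
                            samples = if (keep_samples) numeric(0) else NULL,
                            se = 0, n_frames = as.integer(n_frames),
                            n_requests = 0L)
    return(rep)
  }
  s <- cohort_sum[counts + 1L]
  ds <- sum(s) / tot_requests
  # delta-method se of the ratio estimator sum(S_f) / sum(I_f)
  mi <- mean(counts)
  cv <- stats::cov(cbind(s, counts))
  var_ratio <- (cv[1, 1] - 2 * ds * cv[1, 2] + ds^2 * cv[2, 2]) /
    (n_frames * mi^2)
  samples <- NULL
  if (keep_samples) {
    samples <- unlist(lapply(counts[counts > 0L], function(i) d[seq_len(i)]),
                      use.names = FALSE)
  }
  new_delay_report(ds = ds, sigma = sigma, dc = dc, alpha = alpha,
                   config = config, method = "simulation",
                   samples = samples, se = sqrt(max(var_ratio, 0)),
                   n_frames = as.integer(n_frames),
                   n_requests = as.integer(tot_requests))
}

#' Round-robin periodic communication schedule
#'
#' Slot assignment of the periodic-communication section: devices are served
#' in ascending id, `p_slots` per frame, wrapping after all `n_devices` have
#' been served, so each device transmits once per [periodic_interval()].
#'
#' @param config A [superframe_config()].
#' @param n_frames Number of frames to lay out.
#' @return A tibble with columns `frame` (0-based), `slot` (1-based within
#'   the PC section), `device` (1-based id) and `time` (slot start, seconds).
#' @export
periodic_schedule <- function(config, n_frames) {
  stopifnot(inherits(config, "superframe_config"))
  p <- config$p_slots
  total <- n_frames * p
  k <- seq_len(total) - 1L
  frame <- k %/% p
  slot <- k %% p + 1L
  cycle_len <- ceiling(config$n_devices / p) * p
  device <- (k %% cycle_len) + 1L
  keep <- device <= config$n_devices
  tibble::tibble(
    frame = frame[keep], slot = slot[keep], device = as.integer(device[keep]),
    time = frame[keep] * config$T_frame +
      (config$m_slots - p + slot[keep] - 1L) * config$t_slot
  )
}

#' Periodic-only baseline delay
#'
#' Delay of an idealised periodic-only schedule with no request channel
#' (the regular-interval baseline the request scheme is compared against):
#' a sensor change arising uniformly in time waits for the device's next
#' periodic slot, so the worst case equals the periodic interval `TR` and
#' the mean is `TR / 2`.
#'
#' @param config A [superframe_config()].
#' @return A tibble with columns `mean` and `worst` (seconds).
#' @examples
#' baseline_periodic_delay(superframe_config(p_slots = 10)) # 12.5 / 25 ms
#' @export
baseline_periodic_delay <- function(config) {
  tr <- periodic_interval(config)
  tibble::tibble(mean = tr / 2, worst = tr)
}

#' Sweep the delay model over request rates
#'
#' Evaluates the analytic delay model and the discrete-event simulator over a
#' grid of average request rates, alongside the periodic-only baseline.
#'
#' @param config A [superframe_config()].
#' @param alphas Numeric vector of request rates.
#' @param n_frames Frames per simulation.
#' @param seed Integer seed; one independent substream per rate.
#' @param sigma,dc Delay components passed through to the reports.
#' @return A tibble of class `delay_sweep` with one row per rate:
#'   `alpha`, `ds_analytic`, `ds_sim`, `ci95` (half-width), `total_analytic`,
#'   `baseline_mean`, `baseline_worst`.
#' @export
delay_sweep <- function(config, alphas, n_frames = 1e4, seed = 1,
                        sigma = 0, dc = NULL) {
  # periodic-only baseline: every slot of the frame serves the round-robin
  # schedule, so TR = ceil(n / m) * T (25 ms at the defaults)
  base_cfg <- config
  base_cfg$p_slots <- config$m_slots
  base <- baseline_periodic_delay(base_cfg)
  rows <- purrr::imap(alphas, function(a, i) {
    an <- analytic_average_delay(config, delay_params(a, sigma,
                                                      dc %||% NULL, config))
    si <- simulate_superframes(config, a, n_frames, seed + i, sigma, dc)
    tibble::tibble(alpha = a, ds_analytic = an$ds, ds_sim = si$ds,
                   ci95 = 1.96 * si$se, total_analytic = an$total,
                   baseline_mean = base$mean, baseline_worst = base$worst)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("delay_sweep", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
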