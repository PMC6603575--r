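# Phenomenological synthetic sensor streams for both modalities.
#
# The generator emulates the second-order structure the pipeline relies on,
# not biomechanics: a gravity vector pointing along a posture-specific
# orientation, label-specific dynamics on top (near-static lying, a slow
# orientation slew plus low-amplitude movement for on-bed, a gait
# oscillation for off-bed), additive Gaussian noise, and for the RFID
# modality motion-dependent Bernoulli sample dropout with a label-dependent
# RSSI channel.

#' Activity protocol
#'
#' An ordered sequence of activity segments, each a class label with a
#' duration in seconds, describing what a monitored subject does over a
#' recording.
#'
#' @param segments A data frame (or tibble) with columns `label`
#'   (`on_bed` / `off_bed` / `lying`) and `duration_s` (> 0).
#' @param modality `"smartphone"` or `"rfid"`.
#' @return An `activity_protocol` (tibble with a modality attribute).
#' @export
activity_protocol <- function(segments, modality = c("smartphone", "rfid")) {
  modality <- match.arg(modality)
  segments <- tibble::as_tibble(segments)
  if (nrow(segments) == 0L) abort_bad_input("protocol must have segments")
  if (!all(c("label", "duration_s") %in% names(segments))) {
    abort_bad_input("segments need `label` and `duration_s` columns")
  }
  if (!all(segments$label %in% activity_levels())) {
    abort_bad_input("labels must be on_bed / off_bed / lying")
  }
  if (any(segments$duration_s <= 0)) abort_bad_input("durations must be > 0")
  structure(segments, modality = modality,
            class = c("activity_protocol", class(segments)))
}

#' Default activity protocols
#'
#' Protocols whose class time shares mirror the two study populations the
#' pipeline is designed around. The smartphone protocol is dominated by
#' ambulation: about 77% of the duration is off-bed (more than three
#' quarters), the remainder split between on-bed and lying. The RFID
#' protocol reflects an elderly-care ward biased towards bed rest: lying is
#' the modal class (about 74% of duration), on-bed about 24%, and only a
#' small off-bed share, which together with motion-dependent dropout yields
#' the strong class imbalance typical of that modality.
#'
#' @param modality `"smartphone"` or `"rfid"`.
#' @return An [activity_protocol()].
#' @export
default_protocol <- function(modality = c("smartphone", "rfid")) {
  modality <- match.arg(modality)
  segs <- if (modality == "smartphone") {
    tibble::tribble(
      ~label,    ~duration_s,
      "lying",   15,
      "on_bed",  10,
      "off_bed", 95,
      "on_bed",  15,
      "off_bed", 90,
      "lying",   15
    )
  } else {
    tibble::tribble(
      ~label,    ~duration_s,
      "lying",   260,
      "on_bed",  120,
      "off_bed", 12,
      "lying",   270,
      "on_bed",  106,
      "off_bed", 12,
      "lying",   180
    )
  }
  activity_protocol(segs, modality)
}

#' Synthetic-stream generator parameters
#'
#' Tunable parameters of the stream generator. Units: sampling rate in Hz,
#' accelerations in g, durations in seconds, RSSI in dBm. Defaults describe
#' a trunk/pocket-worn sensor: 1 g gravity baseline, a 2 Hz gait oscillation
#' of 0.4 g while ambulating, 0.02 g sensor noise, a 1.5 s lying-to-upright
#' slew for the on-bed transition, and for the RFID modality a 30% baseline
#' sample loss growing by a further 40% during ambulation (backscatter links
#' degrade with motion and distance), with RSSI centred per posture.
#'
#' @param fs Nominal sampling rate (Hz).
#' @param gravity Baseline gravity magnitude (g).
#' @param posture_orientations Named list of unit 3-vectors giving the
#'   gravity direction in sensor axes per label.
#' @param walk_freq,walk_amp Gait oscillation frequency (Hz) and amplitude
#'   (g) for off-bed segments.
#' @param move_amp Low-amplitude movement (g) on on-bed segments.
#' @param noise_sd Additive Gaussian noise (g).
#' @param transition_s Duration of the smooth lying-to-upright orientation
#'   slew at the start of an on-bed segment.
#' @param rfid_base_drop Baseline Bernoulli sample-loss probability.
#' @param rfid_motion_drop Additional loss probability during off-bed.
#' @param rssi_by_label Named mean RSSI per label (dBm).
#' @param rssi_sd RSSI jitter standard deviation (dB).
#' @param seed Integer RNG seed.
#' @return A `generator_params` object.
#' @export
generator_params <- function(fs = 50, gravity = 1.0,
                             posture_orientations = NULL,
                             walk_freq = 2.0, walk_amp = 0.4,
                             move_amp = 0.08, noise_sd = 0.02,
                             transition_s = 1.5,
                             rfid_base_drop = 0.3, rfid_motion_drop = 0.4,
                             rssi_by_label = c(on_bed = -55, off_bed = -70,
                                               lying = -50),
                             rssi_sd = 3, seed = 1L) {
  check_number(fs, "fs", min = 0, strict_min = TRUE)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(walk_amp, "walk_amp", min = 0)
  check_number(move_amp, "move_amp", min = 0)
  check_number(rfid_base_drop, "rfid_base_drop", min = 0, max = 1)
  check_number(rfid_motion_drop, "rfid_motion_drop", min = 0, max = 1)
  if (rfid_base_drop >= 1 || rfid_base_drop + rfid_motion_drop >= 1) {
    abort_bad_input("dropout probabilities must leave a positive retention rate")
  }
  unit <- function(v) v / sqrt(sum(v^2))
  if (is.null(posture_orientations)) {
    posture_orientations <- list(
      lying = unit(c(0.95, 0.15, 0.10)),  # gravity along the body axis
      on_bed = unit(c(0.45, 0.10, 0.90)), # sitting up, part-way to upright
      off_bed = unit(c(0.08, 0.05, 0.99)) # upright, gravity on z
    )
  }
  structure(list(fs = fs, gravity = gravity,
                 posture_orientations = posture_orientations,
                 walk_freq = walk_freq, walk_amp = walk_amp,
                 move_amp = move_amp, noise_sd = noise_sd,
                 transition_s = transition_s,
                 rfid_base_drop = rfid_base_drop,
                 rfid_motion_drop = rfid_motion_drop,
                 rssi_by_label = rssi_by_label, rssi_sd = rssi_sd,
                 seed = as.integer(seed)),
            class = "generator_params")
}

#' Generate a labelled synthetic sensor stream
#'
#' Simulates a 3-axis accelerometer stream following an
#' [activity_protocol()]. Per segment the gravity vector points along the
#' label's posture orientation; on-bed segments slew smoothly from the lying
#' orientation towards the sitting orientation over `transition_s` and carry
#' low-amplitude movement; off-bed segments add a sinusoidal gait
#' oscillation (`walk_amp` at `walk_freq`, phase-shifted per axis); Gaussian
#' noise is added throughout. Smartphone streams are uniformly sampled at
#' `fs` with no loss. RFID streams drop each sample independently with
#' probability `rfid_base_drop` (plus `rfid_motion_drop` during off-bed) and
#' carry an `rssi` column drawn around the label's mean RSSI.
#'
#' @param protocol An [activity_protocol()].
#' @param params A [generator_params()].
#' @return A tibble with columns `t`, `ax`, `ay`, `az`, (`rssi`,) `label` —
#'   one row per (received) sample, reproducible for a fixed
#'   `params$seed`.
#' @export
generate_stream <- function(protocol, params = generator_params()) {
  stopifnot(inherits(protocol, "activity_protocol"),
            inherits(params, "generator_params"))
  modality <- attr(protocol, "modality")
  set.seed(params$seed)
  fs <- params$fs
  po <- params$posture_orientations
  pieces <- vector("list", nrow(protocol))
  t0 <- 0
  for (i in seq_len(nrow(protocol))) {
    lab <- protocol$label[i]
    dur <- protocol$duration_s[i]
    n <- round(dur * fs)
    tt <- t0 + (seq_len(n) - 1) / fs
    tl <- tt - t0 # time since segment start
    ori <- matrix(rep(po[[lab]], each = n), ncol = 3)
    if (lab == "on_bed" && params$transition_s > 0) {
      # smooth slew from the lying orientation into the sitting one
      w <- pmin(tl / params$transition_s, 1)
      ori <- (1 - w) %o% po[["lying"]] + w %o% po[["on_bed"]]
      ori <- ori / sqrt(rowSums(ori^2))
    }
    acc <- ori * params$gravity
    if (lab == "off_bed" && params$walk_amp > 0) {
      phase <- c(0, 2 * pi / 3, 4 * pi / 3)
      osc <- sapply(1:3, function(ax) {
        params$walk_amp * sin(2 * pi * params$walk_freq * tt + phase[ax])
      })
      acc <- acc + osc
    }
    if (lab == "on_bed" && params$move_amp > 0) {
      osc <- sapply(1:3, function(ax) {
        params$move_amp * sin(2 * pi * 0.5 * tt + ax)
      })
      acc <- acc + osc
    }
    acc <- acc + matrix(rnorm(3 * n, sd = params$noise_sd), ncol = 3)
    piece <- tibble::tibble(t = tt, ax = acc[, 1], ay = acc[, 2],
                            az = acc[, 3], label = lab)
    if (modality == "rfid") {
      drop_p <- params$rfid_base_drop +
        if (lab == "off_bed") params$rfid_motion_drop else 0
      keep <- runif(n) >= drop_p
      piece <- piece[keep, , drop = FALSE]
      piece$rssi <- rnorm(nrow(piece),
                          mean = params$rssi_by_label[[lab]],
                          sd = params$rssi_sd)
      piece <- piece[, c("t", "ax", "ay", "az", "rssi", "label")]
    }
    pieces[[i]] <- piece
    t0 <- t0 + dur
  }
  out <- dplyr::bind_rows(pieces)
  attr(out, "modality") <- modality
  out
}

#' Write / read a stream CSV
#'
#' Streams are exchanged as plain CSV with header
#' `t,ax,ay,az[,rssi],label`, one row per sample.
#'
#' @param stream A stream tibble.
#' @param path File path.
#' @return `read_stream_csv` returns the stream tibble; `write_stream_csv`
#'   returns `path` invisibly.
#' @export
write_stream_csv <- function(stream, path) {
  write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stream_csv
#' @export
read_stream_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("t", "ax", "ay", "az", "label")
  if (!all(need %in% names(df))) {
    abort_bad_input("stream CSV needs columns t, ax, ay, az, label")
  }
  df
}
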