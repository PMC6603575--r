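# Windowing and feature extraction for the two sensing modalities.
#
# Smartphone streams are uniformly sampled at 50 Hz and windowed into 151
# samples (3.02 s); per window, 11 statistical descriptors and 11 wavelet
# band-energy features are computed on each of the four signals (x, y, z,
# SMV), plus 3 axis correlations: 4 * 22 + 3 = 91 features. RFID streams
# are sparse and non-uniform, so windows are 50 received samples and the
# frequency-domain (wavelet) block is omitted: 4 * 11 stats + 3
# correlations + 6 RSSI descriptors = 53 features, or 52 when the
# degenerate SMV zero-crossing feature is dropped to match the conventional
# count.

#' Signal magnitude vector
#'
#' Euclidean norm of the three acceleration axes, an orientation-invariant
#' movement-intensity measure: `sqrt(ax^2 + ay^2 + az^2)`.
#'
#' @param ax,ay,az Accelerations along x, y, z (vectorised).
#' @return Non-negative numeric vector.
#' @examples
#' smv(3, 4, 0) # 5
#' @export
smv <- function(ax, ay, az) {
  sqrt(ax^2 + ay^2 + az^2)
}

#' Statistical descriptors of a windowed signal
#'
#' The eleven per-signal descriptors: mean, standard deviation (population,
#' divisor N), root-mean-square, minimum, maximum, range, zero-crossing
#' count, 25th and 75th percentiles (linear interpolation), and the
#' quarter-energy descriptors (sum of squared elements at or below the 25th
#' / 75th percentile). Zero crossings are counted as sign changes of the
#' mean-removed signal by default, since raw accelerometer axes carry a
#' gravity offset that makes raw-sign crossings uninformative.
#'
#' @param values Non-empty numeric vector.
#' @param zero_cross Either `"mean_removed"` (default) or `"raw"`.
#' @return Named numeric vector of length 11: `mean`, `std`, `rms`, `min`,
#'   `max`, `range`, `zcr`, `p25`, `p75`, `ep25`, `ep75`.
#' @export
stat_descriptors <- function(values, zero_cross = c("mean_removed", "raw")) {
  if (length(values) == 0L || !is.numeric(values)) {
    abort_bad_input("`values` must be a non-empty numeric vector")
  }
  if (any(!is.finite(values))) abort_bad_input("`values` must be finite")
  zero_cross <- match.arg(zero_cross)
  n <- length(values)
  mu <- mean(values)
  centred <- if (zero_cross == "mean_removed") values - mu else values
  s <- sign(centred)
  s <- s[s != 0]
  zcr <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  p <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  c(mean = mu,
    std = sqrt(mean((values - mu)^2)),
    rms = sqrt(mean(values^2)),
    min = min(values),
    max = max(values),
    range = max(values) - min(values),
    zcr = as.numeric(zcr),
    p25 = p[1],
    p75 = p[2],
    ep25 = sum(values[values <= p[1]]^2),
    ep75 = sum(values[values <= p[2]]^2))
}

#' Pairwise axis correlations
#'
#' Pearson correlations of the three accelerometer axis pairs (x,y), (x,z),
#' (y,z). When either member of a pair is constant the correlation is
#' undefined and reported as 0.
#'
#' @param x,y,z Equal-length numeric vectors (length >= 2).
#' @return Named numeric vector `corr_xy`, `corr_xz`, `corr_yz`, each in
#'   \[-1, 1\].
#' @export
axis_correlations <- function(x, y, z) {
  if (length(x) != length(y) || length(x) != length(z)) {
    abort_bad_input("axis sequences must have equal length")
  }
  if (length(x) < 2L) abort_bad_input("need at least 2 samples")
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }
  c(corr_xy = safe_cor(x, y), corr_xz = safe_cor(x, z),
    corr_yz = safe_cor(y, z))
}

#' RSSI descriptors
#'
#' The six statistical descriptors retained for the received-signal-strength
#' channel of the RFID modality: mean, standard deviation (population), RMS,
#' minimum, maximum and range.
#'
#' @param values Non-empty numeric vector of RSSI readings (dBm).
#' @return Named numeric vector `mean`, `std`, `rms`, `min`, `max`, `range`.
#' @export
rssi_descriptors <- function(values) {
  stat_descriptors(values)[c("mean", "std", "rms", "min", "max", "range")]
}

window_length <- function(modality) {
  switch(modality, smartphone = 151L, rfid = 50L,
         abort_bad_input("modality must be 'smartphone' or 'rfid'"))
}

#' Segment a sensor stream into fixed-length windows
#'
#' Cuts a time-ordered stream into fixed-length windows: 151 samples
#' (3.02 s at 50 Hz) for the smartphone modality, 50 received samples for
#' RFID (index-based; sparse non-uniform spacing is expected and not
#' resampled). Consecutive windows step by `length * (1 - overlap_fraction)`
#' samples (rounded down, minimum 1); a trailing partial window is
#' discarded. Each window is labelled by the majority ground-truth label of
#' its samples (ties broken in the fixed class order on-bed, off-bed,
#' lying).
#'
#' @param stream A data frame with columns `t`, `ax`, `ay`, `az`, `label`
#'   (and `rssi` for RFID), sorted by `t`.
#' @param modality `"smartphone"` or `"rfid"`.
#' @param overlap_fraction Window overlap in \[0, 1).
#' @return A tibble with one row per window: `window_id`, `t_start`, `t_end`,
#'   `label`, `modality` and a `samples` list-column of per-window tibbles.
#' @export
segment_windows <- function(stream, modality = c("smartphone", "rfid"),
                            overlap_fraction = 0) {
  modality <- match.arg(modality)
  check_number(overlap_fraction, "overlap_fraction", min = 0, max = 1)
  if (overlap_fraction >= 1) abort_bad_input("`overlap_fraction` must be < 1")
  stream <- tibble::as_tibble(stream)
  empty <- tibble::tibble(window_id = integer(), t_start = numeric(),
                          t_end = numeric(), label = character(),
                          modality = character(), samples = list())
  if (nrow(stream) == 0L) return(empty)
  if (is.unsorted(stream$t)) abort_bad_input("`stream` must be sorted by t")
  len <- window_length(modality)
  if (nrow(stream) < len) return(empty)
  step <- max(1L, as.integer(floor(len * (1 - overlap_fraction))))
  starts <- seq.int(1L, nrow(stream) - len + 1L, by = step)
  rows <- purrr::imap(starts, function(s0, i) {
    w <- stream[s0:(s0 + len - 1L), , drop = FALSE]
    tab <- table(factor(w$label, levels = activity_levels()))
    tibble::tibble(window_id = i, t_start = w$t[1], t_end = w$t[len],
                   label = names(tab)[which.max(tab)], modality = modality,
                   samples = list(w))
  })
  dplyr::bind_rows(rows)
}

# ordered descriptor block for one signal
signal_block <- function(values, prefix, wavelet = FALSE, drop_zcr = FALSE) {
  st <- stat_descriptors(values)
  if (drop_zcr) st <- st[names(st) != "zcr"]
  out <- st
  if (wavelet) {
    w <- wavelet_energy_features(values)
    wav <- c(stats::setNames(w$e_abs, paste0("eabs_", names(w$e_abs))),
             stats::setNames(w$e_rel, paste0("erel_", names(w$e_rel))),
             etotal = w$e_total)
    out <- c(out, wav)
  }
  stats::setNames(out, paste0(prefix, "_", names(out)))
}

#' Build the feature vector of one window
#'
#' Assembles the fixed-order feature vector of a window: for each of the
#' four signals (x, y, z, SMV) the 11 statistical descriptors and, for the
#' smartphone modality, the 11 wavelet band-energy features; then the 3 axis
#' correlations; then, for RFID, the 6 RSSI descriptors. Smartphone vectors
#' have 91 features. The full RFID count is 53; because SMV is non-negative
#' its zero-crossing count is degenerate, and `match_printed_total = TRUE`
#' (the default) drops it to emit the conventional 52.
#'
#' @param window One row of [segment_windows()] output (or any list with
#'   `samples` and `modality`), or a plain data frame of samples if
#'   `modality` is given.
#' @param modality Optional override when `window` is a plain data frame.
#' @param match_printed_total Drop the degenerate SMV zero-crossing feature
#'   from RFID vectors (52 instead of 53 features).
#' @return Named numeric feature vector.
#' @export
build_feature_vector <- function(window, modality = NULL,
                                 match_printed_total = TRUE) {
  if (is.data.frame(window) && all(c("ax", "ay", "az") %in% names(window))) {
    samples <- window
    if (is.null(modality)) abort_bad_input("supply `modality` with a raw sample frame")
  } else {
    samples <- window$samples[[1]] %||% window$samples
    modality <- modality %||% window$modality
  }
  if (!is.data.frame(samples) || !all(c("ax", "ay", "az") %in% names(samples))) {
    abort_bad_input("window samples must contain ax, ay, az columns")
  }
  len <- window_length(modality)
  if (nrow(samples) != len) {
    abort_bad_input(sprintf("%s windows must contain exactly %d samples",
                            modality, len))
  }
  v_smv <- smv(samples$ax, samples$ay, samples$az)
  wavelet <- modality == "smartphone"
  out <- c(
    signal_block(samples$ax, "x", wavelet),
    signal_block(samples$ay, "y", wavelet),
    signal_block(samples$az, "z", wavelet),
    signal_block(v_smv, "smv", wavelet,
                 drop_zcr = modality == "rfid" && match_printed_total),
    axis_correlations(samples$ax, samples$ay, samples$az)
  )
  if (modality == "rfid") {
    if (!"rssi" %in% names(samples)) {
      abort_bad_input("rfid windows must contain an rssi column")
    }
    out <- c(out, stats::setNames(rssi_descriptors(samples$rssi),
                                  paste0("rssi_", c("mean", "std", "rms",
                                                    "min", "max", "range"))))
  }
  out
}

#' Extract a feature table from a sensor stream
#'
#' Windows a stream with [segment_windows()] and computes the feature vector
#' of every window, returning a wide tibble ready for
#' [cross_validate()] / [train_classifier()].
#'
#' @inheritParams segment_windows
#' @inheritParams build_feature_vector
#' @return A tibble with one row per window: the feature columns in fixed
#'   order, then `label` and `modality`.
#' @examples
#' stream <- generate_stream(default_protocol("smartphone"),
#'                           generator_params(seed = 1))
#' feats <- extract_features(stream, "smartphone")
#' dim(feats)
#' @export
extract_features <- function(stream, modality = c("smartphone", "rfid"),
                             overlap_fraction = 0, match_printed_total = TRUE) {
  modality <- match.arg(modality)
  win <- segment_windows(stream, modality, overlap_fraction)
  if (nrow(win) == 0L) {
    abort_bad_input("stream is shorter than one window; nothing to extract")
  }
  mat <- purrr::map(win$samples, function(s) {
    build_feature_vector(s, modality = modality,
                         match_printed_total = match_printed_total)
  })
  feats <- tibble::as_tibble(do.call(rbind, mat))
  feats$label <- win$label
  feats$modality <- modality
  feats
}

#' Split a feature table into matrix and labels
#'
#' Helper used by the classifiers: everything except `label` / `modality`
#' becomes the numeric feature matrix.
#'
#' @param data Feature tibble from [extract_features()].
#' @return List with `x` (numeric matrix) and `label` (factor with the
#'   canonical class levels).
#' @keywords internal
feature_matrix <- function(data) {
  keep <- setdiff(names(data), c("label", "modality"))
  x <- as.matrix(data[keep])
  storage.mode(x) <- "double"
  list(x = x, label = factor(data$label, levels = activity_levels()))
}
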