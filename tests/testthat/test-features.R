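# Windowing, statistical descriptors and feature-vector assembly.

test_that("SMV is the Euclidean norm, axis-order and sign invariant", {
  expect_equal(smv(3, 4, 0), 5)
  expect_equal(smv(0, 0, 0), 0)
  expect_equal(smv(1, 1, 1), sqrt(3))
  expect_equal(smv(1, -2, 3), smv(3, 1, 2))
  expect_equal(smv(-1, 2, -3), smv(1, 2, 3))
})

test_that("statistical descriptors match their definitions", {
  cst <- stat_descriptors(rep(2.5, 40))
  expect_equal(cst[["mean"]], 2.5)
  expect_equal(cst[["std"]], 0)
  expect_equal(cst[["range"]], 0)
  expect_equal(cst[["zcr"]], 0)

  expect_equal(stat_descriptors(c(1, -1, 1, -1))[["zcr"]], 3)
  # raw-sign variant: a positive-offset oscillation has no raw crossings
  expect_equal(stat_descriptors(10 + c(1, -1, 1, -1), "raw")[["zcr"]], 0)
  expect_equal(stat_descriptors(10 + c(1, -1, 1, -1))[["zcr"]], 3)

  # brute-force oracles on an arbitrary window
  v <- det_window(51)
  st <- stat_descriptors(v)
  expect_equal(st[["std"]], sqrt(sum((v - mean(v))^2) / length(v)))
  expect_equal(st[["rms"]], sqrt(mean(v^2)))
  # sort-and-interpolate percentile oracle (linear interpolation)
  s <- sort(v)
  interp <- function(q) {
    h <- (length(s) - 1) * q
    s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2 - (h == floor(h))] -
                                          s[floor(h) + 1])
  }
  expect_equal(st[["p25"]], interp(0.25), tolerance = 1e-9)
  expect_equal(st[["p75"]], interp(0.75), tolerance = 1e-9)
  expect_equal(st[["ep25"]], sum(v[v <= st[["p25"]]]^2))
  expect_equal(st[["ep75"]], sum(v[v <= st[["p75"]]]^2))

  expect_error(stat_descriptors(numeric(0)), "non-empty")
})

test_that("axis correlations match the direct formula and handle ties", {
  x <- det_window(60, 1); y <- det_window(60, 2); z <- det_window(60, 3)
  cc <- axis_correlations(x, y, z)
  direct <- function(a, b) {
    mean((a - mean(a)) * (b - mean(b))) /
      (sqrt(mean((a - mean(a))^2)) * sqrt(mean((b - mean(b))^2)))
  }
  expect_equal(cc[["corr_xy"]], direct(x, y), tolerance = 1e-9)
  expect_equal(cc[["corr_xz"]], direct(x, z), tolerance = 1e-9)
  expect_equal(cc[["corr_yz"]], direct(y, z), tolerance = 1e-9)
  expect_true(all(abs(cc) <= 1))

  expect_equal(axis_correlations(x, x, z)[["corr_xy"]], 1)
  expect_equal(axis_correlations(x, -x, z)[["corr_xy"]], -1)
  expect_equal(axis_correlations(x, rep(1, 60), z)[["corr_xy"]], 0)
  expect_error(axis_correlations(x, y[-1], z), "equal length")
})

test_that("RSSI descriptors are the six-statistic subset", {
  cst <- rssi_descriptors(rep(-60, 50))
  expect_equal(cst[["mean"]], -60)
  expect_equal(cst[["std"]], 0)
  expect_equal(cst[["range"]], 0)
  expect_equal(rssi_descriptors(c(-50, -70))[["range"]], 20)

  v <- det_window(50)
  expect_equal(rssi_descriptors(v),
               stat_descriptors(v)[c("mean", "std", "rms", "min", "max",
                                     "range")])
})

test_that("window segmentation follows length, step and majority-label rules", {
  mk_stream <- function(n, lab = "lying") {
    tibble::tibble(t = (seq_len(n) - 1) / 50, ax = 0, ay = 0, az = 1,
                   label = lab)
  }
  expect_equal(nrow(segment_windows(mk_stream(302), "smartphone")), 2)
  expect_equal(nrow(segment_windows(mk_stream(150), "smartphone")), 0)
  expect_equal(nrow(segment_windows(mk_stream(0)[0, ], "smartphone")), 0)

  w <- segment_windows(mk_stream(151), "smartphone")
  expect_equal(nrow(w$samples[[1]]), 151)
  # 151 samples at 50 Hz span 3.02 s of signal
  expect_equal(w$t_end - w$t_start + 1 / 50, 3.02)

  # 50% overlap halves the step
  expect_equal(nrow(segment_windows(mk_stream(302), "smartphone", 0.5)), 3)

  # majority labelling
  lab <- c(rep("lying", 80), rep("off_bed", 71))
  w2 <- segment_windows(mk_stream(151, lab), "smartphone")
  expect_equal(w2$label, "lying")

  expect_equal(nrow(segment_windows(mk_stream(100), "rfid")), 2)
})

test_that("feature vectors have the documented lengths and fixed order", {
  sp <- segment_windows(mixed_smartphone_stream(), "smartphone")
  v <- build_feature_vector(sp[1, ])
  expect_length(v, 91)
  expect_true(all(is.finite(v)))
  # fixed block order: x, y, z, SMV, correlations
  expect_equal(names(v)[1], "x_mean")
  expect_match(names(v)[23], "^y_")
  expect_equal(names(v)[89:91], c("corr_xy", "corr_xz", "corr_yz"))

  rf <- segment_windows(mixed_rfid_stream(), "rfid")
  expect_length(build_feature_vector(rf[1, ]), 52)
  v53 <- build_feature_vector(rf[1, ], match_printed_total = FALSE)
  expect_length(v53, 53)
  expect_true("smv_zcr" %in% names(v53))
  expect_false("smv_zcr" %in% names(build_feature_vector(rf[1, ])))
  expect_true(all(grepl("^rssi_", names(v53)[48:53])))

  # purity: identical window, identical vector
  expect_identical(build_feature_vector(sp[1, ]), build_feature_vector(sp[1, ]))
})

test_that("feature extraction is deterministic and order-stable", {
  st <- mixed_smartphone_stream()
  f1 <- extract_features(st, "smartphone")
  f2 <- extract_features(st, "smartphone")
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 91 + 2) # features + label + modality
  expect_equal(names(f1)[92:93], c("label", "modality"))
})

test_that("off-bed windows carry more SMV variability than lying windows", {
  f <- extract_features(mixed_smartphone_stream(), "smartphone")
  agg <- f |>
    dplyr::group_by(label) |>
    dplyr::summarise(std = mean(smv_std), .groups = "drop")
  expect_gt(agg$std[agg$label == "off_bed"], agg$std[agg$label == "lying"])
})
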