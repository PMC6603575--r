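# Synthetic stream generator: sampling, determinism, class structure,
# dropout model and default protocols.

test_that("smartphone streams are uniform, complete and fully labelled", {
  proto <- activity_protocol(data.frame(label = "lying", duration_s = 10),
                             "smartphone")
  st <- generate_stream(proto, generator_params(seed = 1))
  expect_equal(nrow(st), 500) # 50 Hz x 10 s
  expect_true(all(st$label == "lying"))
  expect_equal(diff(st$t), rep(1 / 50, 499), tolerance = 1e-12)
  expect_false("rssi" %in% names(st))
})

test_that("generation is reproducible under a fixed seed", {
  p <- generator_params(seed = 33)
  s1 <- generate_stream(default_protocol("rfid"), p)
  s2 <- generate_stream(default_protocol("rfid"), p)
  expect_identical(s1, s2)
  s3 <- generate_stream(default_protocol("rfid"), generator_params(seed = 34))
  expect_false(identical(s1, s3))
})

test_that("off-bed dynamics exceed lying dynamics; RFID retention drops with motion", {
  st <- mixed_smartphone_stream()
  v <- smv(st$ax, st$ay, st$az)
  sd_by <- tapply(v, st$label, sd)
  expect_gt(sd_by[["off_bed"]], sd_by[["lying"]])

  # retention per label within 3 binomial standard errors of the
  # configured Bernoulli rates
  proto <- default_protocol("rfid")
  par <- generator_params(seed = 77)
  st_r <- generate_stream(proto, par)
  raw <- tapply(proto$duration_s, proto$label, sum) * par$fs
  got <- table(st_r$label)
  for (lab in names(raw)) {
    keep_p <- 1 - par$rfid_base_drop -
      if (lab == "off_bed") par$rfid_motion_drop else 0
    se <- sqrt(keep_p * (1 - keep_p) / raw[[lab]])
    expect_lt(abs(got[[lab]] / raw[[lab]] - keep_p), 3 * se)
  }
  # off-bed retention below lying retention
  expect_lt(got[["off_bed"]] / raw[["off_bed"]],
            got[["lying"]] / raw[["lying"]])
})

test_that("RSSI is label-dependent", {
  st <- mixed_rfid_stream()
  mu <- tapply(st$rssi, st$label, mean)
  expect_lt(mu[["off_bed"]], mu[["lying"]])
})

test_that("default protocols reproduce the modality class balances", {
  sp <- default_protocol("smartphone")
  shares <- tapply(sp$duration_s, sp$label, sum) / sum(sp$duration_s)
  expect_gte(shares[["off_bed"]], 0.75)
  expect_lte(shares[["off_bed"]], 0.80)
  expect_equal(sum(shares), 1)

  rf <- default_protocol("rfid")
  shares_r <- tapply(rf$duration_s, rf$label, sum) / sum(rf$duration_s)
  expect_equal(names(which.max(shares_r)), "lying")
  expect_gt(shares_r[["lying"]], 0.7)
  expect_equal(sum(shares_r), 1)
})

test_that("generator output flows through the feature pipeline", {
  fs <- extract_features(generate_stream(default_protocol("smartphone"),
                                         generator_params(seed = 2)),
                         "smartphone")
  expect_equal(ncol(fs), 93)
  expect_true(all(activity_levels() %in% fs$label))

  fr <- extract_features(generate_stream(default_protocol("rfid"),
                                         generator_params(seed = 2)),
                         "rfid")
  expect_equal(ncol(fr), 54)
  expect_true(all(activity_levels() %in% fr$label))
})

test_that("protocol validation rejects bad segments", {
  expect_error(activity_protocol(data.frame(label = character(),
                                            duration_s = numeric())),
               "segments")
  expect_error(activity_protocol(data.frame(label = "napping",
                                            duration_s = 5)),
               "labels")
  expect_error(activity_protocol(data.frame(label = "lying",
                                            duration_s = 0)),
               "> 0")
})

test_that("stream CSV round-trips", {
  st <- generate_stream(
    activity_protocol(data.frame(label = "on_bed", duration_s = 4), "rfid"),
    generator_params(seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_stream_csv(st, path)
  back <- read_stream_csv(path)
  expect_equal(back$ax, st$ax, tolerance = 1e-12)
  expect_equal(back$label, st$label)
})
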