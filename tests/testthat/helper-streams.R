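# Shared fixtures, generated in code.

default_cfg <- function(...) superframe_config(...)

# a short mixed-activity smartphone stream (deterministic seed)
mixed_smartphone_stream <- function(seed = 11) {
  proto <- activity_protocol(
    data.frame(label = c("lying", "on_bed", "off_bed", "lying"),
               duration_s = c(12, 8, 20, 10)),
    modality = "smartphone")
  generate_stream(proto, generator_params(seed = seed))
}

mixed_rfid_stream <- function(seed = 12) {
  proto <- activity_protocol(
    data.frame(label = c("lying", "on_bed", "off_bed", "lying"),
               duration_s = c(60, 40, 30, 50)),
    modality = "rfid")
  generate_stream(proto, generator_params(seed = seed))
}

# deterministic pseudo-random window, no RNG state touched
det_window <- function(n = 151, k = 1) {
  i <- seq_len(n)
  sin(i * 0.37 * k) + 0.25 * cos(i * 2.1) + 0.1 * k
}

# linearly separable 3-class toy feature set
toy_features <- function(n_per = c(on_bed = 20, off_bed = 20, lying = 20),
                         sd = 0.2, seed = 5) {
  set.seed(seed)
  centers <- list(on_bed = c(0, 3), off_bed = c(3, 0), lying = c(-3, -1))
  rows <- lapply(names(n_per), function(cl) {
    n <- n_per[[cl]]
    tibble::tibble(f1 = rnorm(n, centers[[cl]][1], sd),
                   f2 = rnorm(n, centers[[cl]][2], sd), label = cl)
  })
  dplyr::bind_rows(rows)
}
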