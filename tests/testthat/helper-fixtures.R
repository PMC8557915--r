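# Small in-code fixtures shared across test files.

# One hand-sized vial: 8 twice-weekly intervals starting at day 10.
makeIntervalTable <- function(pupae = c(5, 30, 45, 40, 25, 12, 5, 2),
                              deaths = c(1, 1, 2, 1, 1, 2, 1, 0),
                              censored = c(0, 1, 0, 0, 1, 0, 0, 0),
                              females0 = 30L) {
  len <- rep_len(c(3, 4), length(pupae))
  start <- 10 + cumsum(c(0, len[-length(len)]))
  females <- females0 - cumsum(c(0, (deaths + censored)[-length(pupae)]))
  data.frame(start_day = start, class_length_days = len,
             laying_window_hours = 18, pupae_count = pupae,
             females_at_start = females, female_deaths = deaths,
             females_censored = censored)
}

makeVial <- function(id = "v1", treatment = "trtA", experiment = 1L,
                     replicate = 1L, ...) {
  VialRecord(id, treatment, experiment, replicate, makeIntervalTable(...))
}

# random valid vital schedule for property tests
randomSchedule <- function(k = sample(2:12, 1)) {
  VitalSchedule(f = runif(k, 0, 10), s = runif(k - 1))
}

# brute-force Euler-Lotka left-hand side, written independently of the
# package's solver
elLHS <- function(f, s, lam) {
  l <- c(1, cumprod(s))
  sum(l * f * lam^(-seq_along(f)))
}
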