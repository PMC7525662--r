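# Shared fixture builders. Everything is constructed in code; no data files.

f18 <- decay_constants(109.77)

# frames of uniform width dt spanning [0, total] minutes
uniform_frames <- function(total = 240, dt = 1) {
  starts <- seq(0, total - dt, by = dt)
  data.frame(t_start = starts, t_end = starts + dt)
}

# scan whose whole body decays purely physically and each organ is a fixed
# fraction of the whole-body activity
make_decay_scan <- function(fractions = c(kidneys = 0.3, liver = 0.1),
                            total = 240, dt = 1, decay = f18,
                            reconstruction = "FBP") {
  fr <- uniform_frames(total, dt)
  mids <- frame_midpoints(fr)
  wb_act <- 100 * exp(-decay$lambda * mids)
  tacs <- lapply(names(fractions), function(org) {
    tac(org, data.frame(fr, activity = fractions[[org]] * wb_act))
  })
  names(tacs) <- names(fractions)
  subject_scan("T1", "test", 332.67, tacs,
               tac("whole_body", data.frame(fr, activity = wb_act)),
               reconstruction = reconstruction)
}

# analytic residence time (hours) of A(t) = A0 * exp(-lambda t) integrated
# from 0 to infinity, A0 in %ID
analytic_decay_tau <- function(A0 = 100, decay = f18) {
  (A0 / 100) / decay$lambda / 60
}

# simple 3-organ scan on the 13-frame template for I/O tests
make_small_scan <- function(decay_corrected = FALSE) {
  fr <- default_frame_schedule(57)   # exactly the 13-frame template
  mids <- frame_midpoints(fr)
  mk <- function(org, a0, k) {
    tac(org, data.frame(fr, activity = a0 * exp(-k * mids)),
        decay_corrected = decay_corrected)
  }
  subject_scan("S1", "tracer-x", 400,
               list(brain = mk("brain", 2, 0.01),
                    heart = mk("heart", 3, 0.02)),
               mk("whole_body", 95, 0.005),
               reconstruction = "FBP")
}
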