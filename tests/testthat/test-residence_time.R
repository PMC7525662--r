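test_that("decay constants satisfy lambda * half_life = ln 2", {
  dc <- decay_constants(109.77)
  expect_equal(dc$lambda * dc$half_life, log(2))
  expect_error(decay_constants(-1), "positive")
})

test_that("uncorrect_decay reinstates physical decay at frame midpoints", {
  one_frame <- function(t_mid, act) {
    tac("brain", data.frame(t_start = t_mid - 0.5, t_end = t_mid + 0.5,
                            activity = act), decay_corrected = TRUE)
  }
  # one half-life: 100 -> 50
  expect_equal(uncorrect_decay(one_frame(109.77, 100), f18)$frames$activity,
               50)
  # two half-lives: 100 -> 25
  expect_equal(uncorrect_decay(one_frame(219.54, 100), f18)$frames$activity,
               25)
  # t = 0 midpoint is the identity
  z <- tac("brain", data.frame(t_start = -0.5, t_end = 0.5, activity = 80),
           decay_corrected = TRUE)
  expect_equal(uncorrect_decay(z, f18)$frames$activity, 80)
  # already-uncorrected input: warning, unchanged
  u <- tac("brain", data.frame(t_start = 0, t_end = 1, activity = 10))
  expect_warning(out <- uncorrect_decay(u, f18), "no-op")
  expect_identical(out$frames$activity, u$frames$activity)
})

test_that("trapezoid area matches hand arithmetic", {
  # (100 + 50)/2 %ID over 1 h = 0.75 fraction.h
  expect_equal(trapezoid_auc(c(0, 60), c(100, 50)), 0.75)
  # constant 100 %ID over 4 h
  expect_equal(trapezoid_auc(c(0, 240), c(100, 100)), 4)
  expect_error(trapezoid_auc(0, 100), "at least 2 time points")
  expect_error(trapezoid_auc(c(0, 60), c(100, -1)), "negative activity")
})

test_that("trapezoid matches the analytic integral of pure decay", {
  # closed-form oracle: int_0^T 100 e^(-lambda t) dt / 100 / 60 hours
  t_min <- seq(0, 240, by = 1)
  act <- 100 * exp(-f18$lambda * t_min)
  oracle <- (1 - exp(-f18$lambda * 240)) / f18$lambda / 60
  expect_equal(trapezoid_auc(t_min, act), oracle, tolerance = 1e-4)
})

test_that("tail residence is A_end / (100 lambda) in hours", {
  expect_equal(tail_residence(0, f18), 0)
  # 100 %ID: 1/lambda = 109.77/ln2 min = 2.6394 h
  expect_equal(tail_residence(100, f18), 109.77 / log(2) / 60,
               tolerance = 1e-12)
  expect_equal(tail_residence(100, f18), 2.6394, tolerance = 1e-4)
  # linearity
  expect_equal(tail_residence(10, f18), tail_residence(100, f18) / 10)
  expect_error(tail_residence(-5, f18), "negative activity")
})

test_that("residence times of a pure-decay scan match the closed form", {
  scan <- make_decay_scan(c(kidneys = 0.3, liver = 0.1), dt = 1)
  rts <- residence_times(scan)
  # whole body integrates to 1/lambda within trapezoid error
  expect_equal(rts$whole_body, analytic_decay_tau(100),
               tolerance = 1e-3)
  # organs are fixed fractions of the whole body, up to the t = 0 anchor
  # (organs anchor at 0 %ID, the whole body at 100 %ID, so the first
  # half-frame contributes slightly differently)
  expect_equal(unname(rts$tau["kidneys"]), 0.3 * rts$whole_body,
               tolerance = 5e-3)
  expect_equal(rts$remainder, rts$whole_body - sum(rts$tau))
})

test_that("an organ identical to the whole body leaves zero remainder", {
  fr <- uniform_frames(240, 1)
  mids <- frame_midpoints(fr)
  wb_act <- 100 * exp(-f18$lambda * mids)
  wb <- tac("whole_body", data.frame(fr, activity = wb_act))
  organ <- tac("liver", data.frame(fr, activity = wb_act))
  scan <- subject_scan("S", "t", 300, list(liver = organ), wb)
  # without anchoring the two integrals coincide exactly
  rts <- residence_times(scan, anchor = FALSE)
  expect_equal(rts$remainder, 0, tolerance = 1e-12)
  # with the bolus anchors the residual is only the first half-frame wedge
  rts_a <- residence_times(scan)
  expect_lt(rts_a$remainder / rts_a$whole_body, 2e-3)
})

test_that("residence times are linear in activity", {
  base <- make_decay_scan(c(kidneys = 0.2, liver = 0.1))
  for (c_scale in c(0.5, 2)) {
    scaled <- base
    for (org in names(scaled$tacs))
      scaled$tacs[[org]]$frames$activity <-
        c_scale * scaled$tacs[[org]]$frames$activity
    # note: whole body kept; only organ taus tested for linearity
    rts0 <- residence_times(base)
    rts1 <- suppressWarnings(residence_times(scaled))
    expect_equal(rts1$tau, c_scale * rts0$tau, tolerance = 1e-12)
  }
})

test_that("iterative activities 1.6x FBP give tau ratio 1.6 organ-wise", {
  fbp <- make_decay_scan(c(kidneys = 0.3, liver = 0.1))
  iter <- fbp
  iter$reconstruction <- "iterative"
  for (org in names(iter$tacs))
    iter$tacs[[org]]$frames$activity <-
      1.6 * iter$tacs[[org]]$frames$activity
  r_f <- residence_times(fbp)
  r_i <- residence_times(iter)
  expect_equal(r_i$tau / r_f$tau, c(kidneys = 1.6, liver = 1.6),
               tolerance = 1e-12)
})

test_that("sum-of-exponentials taus agree with the analytic integral", {
  # oracle: integral of 100 f (e^(-a t) - e^(-b t)) e^(-lambda t) dt
  #       = 100 f (1/(a+lambda) - 1/(b+lambda)), minutes -> hours
  f <- 0.2; a <- 0.004; b <- 0.08
  fr <- uniform_frames(240, 0.1)
  mids <- frame_midpoints(fr)
  act <- 100 * f * (exp(-a * mids) - exp(-b * mids)) *
    exp(-f18$lambda * mids)
  organ <- tac("kidneys", data.frame(fr, activity = act))
  tau <- trapezoid_auc(organ, anchor = c(0, 0)) +
    tail_residence(act[length(act)], f18)
  # beyond-scan tail uses decay only, so compare on [0, T] + physical tail
  la <- f18$lambda
  oracle_scan <- (f) * ((1 - exp(-(a + la) * 240)) / (a + la) -
                          (1 - exp(-(b + la) * 240)) / (b + la)) / 60
  oracle_tail <- tail_residence(act[length(act)], f18)
  expect_equal(tau, oracle_scan + oracle_tail, tolerance = 5e-4)
})

test_that("whole-body tau can never exceed the physical-decay bound", {
  fr <- uniform_frames(240, 1)
  mids <- frame_midpoints(fr)
  # flat 100 %ID is physically impossible for a decaying nuclide
  wb <- tac("whole_body", data.frame(fr, activity = rep(100, nrow(fr))))
  organ <- tac("liver", data.frame(fr, activity = rep(1, nrow(fr))))
  scan <- subject_scan("S", "t", 300, list(liver = organ), wb)
  expect_error(residence_times(scan), "physical-decay bound")
})

test_that("negative remainder is clamped below tolerance, fatal above", {
  fr <- uniform_frames(240, 1)
  mids <- frame_midpoints(fr)
  wb_act <- 100 * exp(-f18$lambda * mids)
  wb <- tac("whole_body", data.frame(fr, activity = wb_act))
  mk_scan <- function(scale) {
    organ <- tac("kidneys", data.frame(fr, activity = scale * wb_act))
    subject_scan("S", "t", 300, list(kidneys = organ), wb)
  }
  # 1% overcount: clamped with warning
  expect_warning(rts <- residence_times(mk_scan(1.01)), "clamped")
  expect_equal(rts$remainder, 0)
  # 10% overcount: hard error
  expect_error(suppressWarnings(residence_times(mk_scan(1.10))),
               "negative remainder")
})

test_that("decay-corrected scans are uncorrected automatically", {
  fr <- uniform_frames(240, 1)
  mids <- frame_midpoints(fr)
  # decay-corrected constant = physically decaying exponential
  wb_c <- tac("whole_body", data.frame(fr, activity = rep(100, nrow(fr))),
              decay_corrected = TRUE)
  org_c <- tac("kidneys", data.frame(fr, activity = rep(30, nrow(fr))),
               decay_corrected = TRUE)
  scan <- subject_scan("S", "t", 300, list(kidneys = org_c), wb_c)
  expect_message(rts <- residence_times(scan), "uncorrecting")
  expect_equal(rts$whole_body, analytic_decay_tau(100), tolerance = 1e-3)
  expect_equal(unname(rts$tau["kidneys"]), 0.3 * rts$whole_body,
               tolerance = 5e-3)
})

test_that("residence-time CSV round-trips", {
  rts <- residence_times(make_decay_scan())
  path <- withr::local_tempfile(fileext = ".csv")
  write_residence_times(rts, path)
  back <- read_residence_times(path)
  expect_equal(back$tau, rts$tau)
  expect_equal(back$whole_body, rts$whole_body)
  expect_identical(back$reconstruction, rts$reconstruction)
  expect_identical(back$normalised, rts$normalised)
})
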