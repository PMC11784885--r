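# PERCLOS scoring, the per-cycle decision rule, and the windowed sequence
# classifier, cross-checked against a brute-force oracle.

test_that("perclos_score sums clipped overlaps over f0", {
  eps <- data.frame(kind = "eye_closure", start = c(10L, 50L),
                    end = c(16L, 67L), duration = c(6L, 17L))
  expect_equal(perclos_score(eps, c(0, 150), 150), 23 / 150)
  expect_identical(perclos_score(eps[0, ], c(0, 150), 150), 0)
  full <- data.frame(kind = "eye_closure", start = 0L, end = 150L,
                     duration = 150L)
  expect_identical(perclos_score(full, c(0, 150), 150), 1)
  # straddling episodes contribute only their in-window part
  straddle <- data.frame(kind = "eye_closure", start = 140L, end = 170L,
                         duration = 30L)
  expect_equal(perclos_score(straddle, c(0, 150), 150), 10 / 150)
  expect_error(perclos_score(eps, c(0, 150), 100),
               class = "perclos_config_error")
  expect_error(perclos_score(eps, c(0, 0), 0),
               class = "perclos_config_error")
})

test_that("classify_summary applies the inclusive disjunctive rule", {
  cfg <- cycle_config()
  expect_identical(classify_summary(0, 0, 0, 0, cfg)$verdict, "normal")
  expect_identical(classify_summary(0, 0, 0, 0, cfg)$triggered, character(0))
  # 19 closed frames in 150: 19/150 < 0.15 and 19 < 20 -> normal
  expect_identical(classify_summary(19 / 150, 0, 19, 0, cfg)$verdict,
                   "normal")
  # inclusive boundaries fire exactly at the threshold
  expect_identical(classify_summary(0, 0, 20, 0, cfg)$triggered, "fe")
  expect_identical(classify_summary(0, 0, 0, 30, cfg)$triggered, "fm")
  expect_identical(classify_summary(0.15, 0, 0, 0, cfg)$triggered,
                   "perclos_eyes")
  expect_identical(classify_summary(0, 0.15, 0, 0, cfg)$triggered,
                   "perclos_mouth")
  # multiple criteria are all listed
  trig <- classify_summary(0.2, 0.2, 25, 35, cfg)$triggered
  expect_setequal(trig, c("perclos_eyes", "perclos_mouth", "fe", "fm"))
  # disabled criteria never fire
  only_fm <- cycle_config(criteria = "fm")
  expect_identical(classify_summary(1, 1, 150, 0, only_fm)$verdict, "normal")
  expect_error(classify_summary(-0.1, 0, 0, 0, cfg),
               class = "perclos_input_error")
})

test_that("cycle_config validates its fields", {
  expect_error(cycle_config(f0 = 0), class = "perclos_config_error")
  expect_error(cycle_config(perclos_threshold = 1.2),
               class = "perclos_config_error")
  expect_error(cycle_config(stride = 0), class = "perclos_config_error")
  expect_error(thresholds(ear_closed = 0), class = "perclos_config_error")
})

test_that("classify_sequence handles the canonical 150-frame scenarios", {
  neutral <- simulate_face(simulation_config(150))
  r <- classify_sequence(neutral$frames)
  expect_identical(nrow(r$cycles), 1L)
  expect_identical(r$overall, "normal")
  expect_false(r$cycles$partial)

  # one 25-frame closure: fe = 25 >= 20 fires (PERCLOS 25/150 also >= 0.15)
  one <- simulate_face(simulation_config(
    150, events = list(event_spec("closure", 60, 25))))
  r1 <- classify_sequence(one$frames)
  expect_identical(r1$overall, "fatigued")
  expect_identical(r1$cycles$fe, 25L)
  expect_true(grepl("fe", r1$cycles$triggered))

  # five separated 5-frame closures: PERCLOS = 25/150 >= 0.15 fires, fe = 5
  five <- simulate_face(simulation_config(
    150, events = lapply(c(5L, 35L, 65L, 95L, 125L),
                         function(o) event_spec("closure", o, 5))))
  r5 <- classify_sequence(five$frames)
  expect_identical(r5$overall, "fatigued")
  expect_identical(r5$cycles$fe, 5L)
  expect_equal(r5$cycles$p_eyes, 25 / 150)
  expect_identical(r5$cycles$triggered, "perclos_eyes")

  expect_error(classify_sequence(list()), class = "perclos_input_error")
})

test_that("windowing: stride, partial trailing cycles, straddling episodes", {
  # 300 frames, closure straddling the window border at frame 150
  s <- states_from_flags(c(rep(FALSE, 140), rep(TRUE, 25), rep(FALSE, 135)))
  r <- classify_sequence(s)
  expect_identical(nrow(r$cycles), 2L)
  # clipped PERCLOS: 10 frames in window 1, 15 in window 2
  expect_equal(r$cycles$p_eyes, c(10 / 150, 15 / 150))
  # but the full 25-frame run is the Fe of both windows it overlaps
  expect_identical(r$cycles$fe, c(25L, 25L))
  expect_identical(r$cycles$verdict, c("fatigued", "fatigued"))

  # trailing partial window is evaluated with f0 as divisor and flagged
  s2 <- states_from_flags(rep(FALSE, 200))
  r2 <- classify_sequence(s2)
  expect_identical(r2$cycles$partial, c(FALSE, TRUE))
  expect_identical(r2$overall, "normal")

  # input shorter than one cycle: partial cycle decides
  s3 <- states_from_flags(c(rep(TRUE, 30), rep(FALSE, 30)))
  r3 <- classify_sequence(s3)
  expect_true(r3$cycles$partial[1])
  expect_identical(r3$overall, "fatigued")

  # sliding stride produces overlapping windows
  r4 <- classify_sequence(s, config = cycle_config(stride = 75L))
  expect_identical(r4$cycles$f_start, c(0L, 75L, 150L, 225L))
})

test_that("verdicts match a brute-force run enumeration oracle", {
  oracle_verdict <- function(closed, yawn, f0 = 150, p_thr = 0.15,
                             fe_thr = 20, fm_thr = 30) {
    n <- length(closed)
    runs <- function(flags) {
      out <- list(); s <- NA
      for (i in seq_len(n + 1)) {
        on <- i <= n && flags[i]
        if (on && is.na(s)) s <- i
        if (!on && !is.na(s)) { out[[length(out) + 1]] <- c(s, i - 1); s <- NA }
      }
      out
    }
    re <- runs(closed); rm_ <- runs(yawn)
    starts <- seq(1, n, by = f0)
    fat <- logical(length(starts)); complete <- logical(length(starts))
    for (k in seq_along(starts)) {
      a <- starts[k]; b <- a + f0 - 1
      complete[k] <- b <= n
      ov <- function(rr) sum(vapply(rr, function(r)
        max(0, min(r[2], b) - max(r[1], a) + 1), numeric(1)))
      fdur <- function(rr) {
        d <- vapply(rr, function(r)
          if (r[2] >= a && r[1] <= b) r[2] - r[1] + 1 else 0, numeric(1))
        if (length(d)) max(d) else 0
      }
      fat[k] <- ov(re) / f0 >= p_thr || ov(rm_) / f0 >= p_thr ||
        fdur(re) >= fe_thr || fdur(rm_) >= fm_thr
    }
    if (any(complete)) any(fat[complete]) else any(fat)
  }
  set.seed(99)
  for (k in 1:20) {
    n <- sample(50:300, 1)
    closed <- stats::runif(n) < 0.12
    yawn <- stats::runif(n) < 0.10
    got <- classify_sequence(states_from_flags(closed, yawn))$overall
    expect_identical(got == "fatigued", oracle_verdict(closed, yawn),
                     info = sprintf("case %d (n = %d)", k, n))
  }
})

test_that("adding closed frames never flips fatigued to normal", {
  set.seed(7)
  for (k in 1:10) {
    closed <- stats::runif(150) < 0.1
    v1 <- classify_sequence(states_from_flags(closed))$overall
    more <- closed
    more[sample(which(!closed), 10)] <- TRUE
    v2 <- classify_sequence(states_from_flags(more))$overall
    expect_false(v1 == "fatigued" && v2 == "normal")
  }
})

test_that("fatigue_report methods expose the cycle table", {
  sim <- simulate_face(simulation_config(
    150, events = list(event_spec("closure", 60, 25))))
  r <- classify_sequence(sim$frames)
  expect_s3_class(r, "fatigue_report")
  expect_identical(as.data.frame(r), r$cycles)
  expect_output(print(r), "FATIGUED")
  expect_output(summary(r), "OVERALL")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); on.exit(unlink(tf))
  expect_invisible(plot(r))
  grDevices::dev.off()
})
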