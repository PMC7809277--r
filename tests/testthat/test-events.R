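test_that("event process parameters are validated", {
  expect_error(event_process(1.5, 10, 0.5), "frequency")
  expect_error(event_process(0.1, -1, 0.5), "duration")
  expect_error(event_process(0.1, 10, 0.1), "strength")
  expect_error(event_process(0.1, 10, 0.9), "strength")
  expect_s3_class(event_process(0.1, 10, 0.5), "siem_event_process")
})

test_that("spawning respects the frequency bounds", {
  set.seed(13)
  never <- event_process(0, 10, 0.5)
  expect_true(all(vapply(1:1000, function(t) length(spawn_events(never, t)),
                         integer(1)) == 0L))
  always <- event_process(1, 10, 0.5)
  expect_true(all(vapply(1:1000, function(t) length(spawn_events(always, t)),
                         integer(1)) == 1L))
})

test_that("event strengths and durations follow their stated distributions", {
  set.seed(14)
  params <- event_process(1, 10, 0.5)
  evs <- lapply(1:10000, function(t) spawn_events(params, t)[[1]])
  strengths <- vapply(evs, `[[`, numeric(1), "strength")
  expect_true(all(strengths >= 0.3 & strengths <= 0.7))
  expect_lt(abs(mean(strengths) - 0.5), 0.01)

  durations <- vapply(evs, `[[`, integer(1), "duration")
  expect_true(all(durations >= 1L & durations <= 20L))
  # mean duration ~ E_d; uniform on [0, 2 E_d] has SD E_d/sqrt(3)
  se <- (10 / sqrt(3)) / sqrt(10000)
  expect_lt(abs(mean(durations) - 10), 3 * se + 0.02)  # 0.02 rounding bias

  # signs are two-sided under the default mode
  opinions <- vapply(evs, `[[`, numeric(1), "opinion")
  expect_gt(mean(opinions > 0), 0.45)
  expect_lt(mean(opinions > 0), 0.55)
  expect_equal(abs(opinions), strengths)

  # degenerate duration parameter still yields at least one active step
  set.seed(15)
  short <- event_process(1, 0, 0.5)
  expect_true(all(vapply(1:100, function(t) spawn_events(short, t)[[1]]$duration,
                         integer(1)) == 1L))
})

test_that("event influence respects certainty and confidence eligibility", {
  ev <- structure(list(start = 1L, duration = 5L, strength = 0.5,
                       opinion = 0.5), class = "siem_event")
  # too certain: untouched
  pop <- manual_population(c(0.4, 0.4), c(0.9, 0.1))
  set.seed(16)
  out <- apply_event(pop, ev, epsilon = 0.3)
  expect_identical(out$opinions[1], 0.4)
  expect_false(out$opinions[2] == 0.4)

  # outside the confidence threshold: untouched
  pop2 <- manual_population(c(-0.8), c(0.1))
  out2 <- apply_event(pop2, ev, epsilon = 0.2)
  expect_identical(out2$opinions, -0.8)
})

test_that("event moves are convex: toward the event, never past it", {
  set.seed(17)
  for (rep in 1:50) {
    n <- 20
    O <- runif(n, -1, 1)
    C <- runif(n)
    W <- runif(n)
    opinion <- runif(1, -1, 1)
    strength <- abs(opinion)
    out <- siem:::apply_event_core(O, C, opinion, strength, 0.8, W)
    moved <- out != O
    expect_true(all(abs(out[moved] - opinion) <= abs(O[moved] - opinion)))
    expect_true(all(sign(out[moved] - O[moved]) ==
                    sign(opinion - O[moved])))
    slow <- brute_event(O, C, opinion, strength, 0.8, W)
    expect_equal(out, slow, tolerance = 0)
  }
})

test_that("every eligible individual is exposed in the same timestep", {
  set.seed(18)
  n <- 200
  pop <- manual_population(runif(n, 0.3, 0.7), rep(0, n))
  ev <- structure(list(start = 1L, duration = 1L, strength = 0.6,
                       opinion = 0.6), class = "siem_event")
  out <- apply_event(pop, ev, epsilon = 0.5)
  expect_true(all(out$opinions != pop$opinions |
                  pop$opinions == 0.6))
})

test_that("realized durations track the mean over the stochastic process", {
  set.seed(19)
  params <- event_process(1, 3, 0.4)
  durs <- vapply(1:10000, function(t) spawn_events(params, t)[[1]]$duration,
                 integer(1))
  expect_true(all(durs >= 1L & durs <= 6L))
  se <- (3 / sqrt(3)) / sqrt(10000)
  expect_lt(abs(mean(durs) - 3), 3 * se + 0.1)
})
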