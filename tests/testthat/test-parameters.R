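# Per-trial parameter battery against closed forms and brute-force oracles.

test_that("mean hand speed matches closed forms and the trapezoid oracle", {
  still <- make_trial(make_objects(1, "missed"), make_samples(5),
                      n_targets = 1)
  expect_equal(mean_hand_speed(still, "left"), 0)

  pyth <- make_trial(make_objects(1, "missed"),
                     make_samples(5, rvx = function(t) 3 + 0 * t,
                                  rvy = function(t) 4 + 0 * t),
                     n_targets = 1)
  expect_equal(mean_hand_speed(pyth, "right"), 5)

  tr <- simulate_trial(oh_task(), default_participant(21))
  oracle <- trapz_mean_speed_oracle(tr$samples$t, tr$samples$left_vx,
                                    tr$samples$left_vy)
  expect_equal(mean_hand_speed(tr, "left"), oracle, tolerance = 1e-9)
})

test_that("bilateral bias endpoints, symmetry and undefined case", {
  expect_equal(bilateral_bias(3, 3), 0)
  expect_equal(bilateral_bias(0, 5), 1)
  expect_equal(bilateral_bias(5, 0), -1)
  expect_equal(bilateral_bias(2, 1), -1 / 3)
  expect_warning(out <- bilateral_bias(0, 0), "both sides are zero")
  expect_true(is.na(out))
})

test_that("movement area: square, degenerate, and hull oracle", {
  sq <- data.frame(t = seq(0, 1, length.out = 5),
                   left_x = c(0, 10, 10, 0, 0), left_y = c(0, 0, 10, 10, 0),
                   left_vx = 0, left_vy = 0, right_x = 0, right_y = 0,
                   right_vx = 0, right_vy = 0)
  tr <- make_trial(make_objects(1, "missed"), sq, n_targets = 1)
  expect_equal(movement_area(tr, "left"), 100)

  line <- sq
  line$left_y <- line$left_x   # collinear path
  expect_equal(movement_area(make_trial(make_objects(1, "missed"), line,
                                        n_targets = 1), "left"), 0)

  set.seed(41)
  x <- rnorm(1000); y <- rnorm(1000)
  got <- rapidmotor:::convex_hull_area(x, y)
  expect_equal(got, hull_area_oracle(x, y), tolerance = 1e-9)
})

test_that("hand bias of hits covers the endpoint semantics", {
  all_left <- make_objects(rep(1:5, 2), "hit", hand = "left")
  expect_equal(hand_bias_of_hits(make_trial(all_left, n_targets = 10)), -1)

  even <- make_objects(rep(1:5, 4), "hit",
                       hand = rep(c("left", "right"), 10))
  expect_equal(hand_bias_of_hits(make_trial(even, n_targets = 20)), 0)

  skew <- make_objects(rep(1:5, 4), "hit",
                       hand = rep(c("left", "right"), c(5, 15)))
  expect_equal(hand_bias_of_hits(make_trial(skew, n_targets = 20)), 0.5)
})

test_that("hand selection overlap counts per-bin alternations", {
  mono <- make_objects(rep(1:10, each = 3), "hit",
                       hand = rep(c("left", "right"), each = 15))
  expect_equal(hand_selection_overlap(make_trial(mono, n_targets = 300)), 0)

  lrlr <- make_objects(rep(1, 4), "hit", hand = c("left", "right",
                                                  "left", "right"),
                       t_created = 1:4)
  expect_equal(hand_selection_overlap(make_trial(lrlr, n_targets = 300)),
               3 / 300 * 100)

  set.seed(5)
  bins <- sample(1:10, 120, replace = TRUE)
  hands <- sample(c("left", "right"), 120, replace = TRUE)
  tt <- runif(120, 0, 100)
  rnd <- make_objects(bins, "hit", hand = hands, t_created = tt - 1,
                      t_outcome = tt)
  expect_equal(hand_selection_overlap(make_trial(rnd, n_targets = 300)),
               overlap_oracle(bins, hands, tt, 300))
})

test_that("miss bias averages signed miss positions", {
  sym <- make_objects(c(3, 8), "missed", x_outcome = c(-12, 12))
  expect_equal(miss_bias(make_trial(sym, n_targets = 2)), 0)
  single <- make_objects(2, "missed", x_outcome = -12)
  expect_equal(miss_bias(make_trial(single, n_targets = 1)), -12)
  set.seed(6)
  xs <- runif(40, -30, 30)
  rnd <- make_objects(sample(1:10, 40, TRUE), "missed", x_outcome = xs)
  expect_equal(miss_bias(make_trial(rnd, n_targets = 40)), mean(xs))
  none <- make_objects(1:3, "hit", hand = "left")
  expect_warning(out <- miss_bias(make_trial(none, n_targets = 3)), "no missed")
  expect_true(is.na(out))
})

test_that("hand transition locates the preference switch point", {
  # perfectly lateralised at the midline: bins 1-5 left, 6-10 right
  split0 <- make_objects(rep(1:10, each = 4), "hit",
                         hand = rep(c("left", "right"), each = 20))
  expect_equal(hand_transition(make_trial(split0, n_targets = 40)), 0)

  # split between bins 6 and 7: boundary at x = +8
  split8 <- make_objects(rep(1:10, each = 4), "hit",
                         hand = rep(c("left", "right"), c(24, 16)))
  expect_equal(hand_transition(make_trial(split8, n_targets = 40)), 8)

  # noisy assignment from a logistic with midpoint +3 cm is recovered
  set.seed(8)
  bins <- sample(1:10, 400, replace = TRUE)
  centres <- -40 + 8 * (bins - 0.5)
  hands <- ifelse(runif(400) < plogis((centres - 3) / 2), "right", "left")
  noisy <- make_objects(bins, "hit", hand = hands)
  # recovery is limited by the 8 cm bin-centre interpolation grid
  expect_lt(abs(hand_transition(make_trial(noisy, n_targets = 400)) - 3), 1.5)

  one_handed <- make_objects(1:5, "hit", hand = "left")
  expect_warning(out <- hand_transition(make_trial(one_handed, n_targets = 5)),
                 "fewer than two hands")
  expect_true(is.na(out))
})

test_that("median error tracks the creation-order position of misses", {
  # misses confined to the last 30 of 300 targets
  outcomes <- rep("hit", 300); outcomes[271:300] <- "missed"
  hands <- ifelse(outcomes == "hit", "left", "none")
  late <- make_objects(rep(1:10, 30), outcomes, hand = hands,
                       t_created = 1:300)
  expect_gte(median_error(make_trial(late, n_targets = 300)), 90)

  # exactly two misses at creation indices 30 and 270: half reached at 30
  outcomes2 <- rep("hit", 300); outcomes2[c(30, 270)] <- "missed"
  hands2 <- ifelse(outcomes2 == "hit", "right", "none")
  two <- make_objects(rep(1:10, 30), outcomes2, hand = hands2,
                      t_created = 1:300)
  expect_equal(median_error(make_trial(two, n_targets = 300)), 10)

  # uniform misses centre near 50%
  set.seed(9)
  meds <- vapply(1:40, function(i) {
    oc <- rep("hit", 300)
    oc[sample(300, 50)] <- "missed"
    hd <- ifelse(oc == "hit", "left", "none")
    tr <- make_trial(make_objects(rep(1:10, 30), oc, hand = hd,
                                  t_created = 1:300), n_targets = 300)
    median_error(tr)
  }, numeric(1))
  expect_lt(abs(mean(meds) - 50), 5)
})

test_that("distractor proportion is an exact event-count ratio", {
  mixed <- make_objects(rep(1:10, 10),
                        outcome = rep(c("hit", "hit"), c(90, 10)),
                        hand = "left",
                        role = rep(c("target", "distractor"), c(90, 10)))
  tr <- make_trial(mixed, task_name = "OHA", n_targets = 200,
                   n_distractors = 100)
  expect_equal(distractor_proportion(tr), 10)

  clean <- make_objects(1:10, "hit", hand = "right")
  expect_equal(distractor_proportion(make_trial(clean, n_targets = 10)), 0)

  sim <- simulate_trial(oha_task(),
                        participant_spec("d", 60, distractor_error_prob = 0.2,
                                         rng_seed = 14),
                        include_samples = FALSE)
  obj <- sim$objects
  expect_equal(distractor_proportion(sim),
               100 * sum(obj$role == "distractor" & obj$outcome == "hit") /
                 sum(obj$outcome == "hit"))
})

test_that("object processing rate counts hits and cleared distractors at t80", {
  sim <- simulate_trial(oha_task(), default_participant(15),
                        include_samples = FALSE)
  obj <- sim$objects[order(sim$objects$t_created), ]
  t80 <- obj$t_created[ceiling(0.8 * nrow(obj))]
  expect_equal(t80, sort(obj$t_created)[240])
  correct <- sum(obj$role == "target" & obj$outcome == "hit" &
                   obj$t_outcome <= t80) +
    sum(obj$role == "distractor" & obj$outcome == "avoided" &
          obj$t_outcome <= t80)
  expect_equal(object_processing_rate(sim), correct / t80)

  # a participant who hits nothing is credited only with exited distractors
  oc <- rep(c("missed", "avoided"), c(6, 4))
  role <- rep(c("target", "distractor"), c(6, 4))
  passive <- make_objects(rep(1:10), oc, role = role, t_created = 1:10,
                          t_outcome = 1:10 + 1.5)
  tr <- make_trial(passive, task_name = "OHA", n_targets = 6,
                   n_distractors = 4)
  t80p <- 8
  expect_equal(object_processing_rate(tr),
               sum(role == "distractor" & (1:10 + 1.5) <= t80p) / t80p)
})

test_that("kinematic summaries match closed forms", {
  const <- make_trial(make_objects(1, "missed"),
                      make_samples(4, lvx = function(t) 2 + 0 * t),
                      n_targets = 1)
  ks <- hand_kinematic_summaries(const)
  left <- ks[ks$hand == "left", ]
  expect_equal(left$max_acceleration, 0)
  expect_equal(left$median_speed, 2)

  A <- 15; f <- 1.2
  sine <- make_trial(make_objects(1, "missed"),
                     make_samples(6, rvx = function(t) A * sin(2 * pi * f * t)),
                     n_targets = 1)
  ks2 <- hand_kinematic_summaries(sine)
  right <- ks2[ks2$hand == "right", ]
  expect_equal(right$max_acceleration, 2 * pi * f * A, tolerance = 1e-3)
  expect_equal(right$max_speed, A, tolerance = 1e-4)
})

test_that("parameter extraction is pure and respects ranges", {
  tr <- simulate_trial(oha_task(), default_participant(30))
  a <- extract_parameters(tr)
  b <- extract_parameters(tr)
  expect_identical(a, b)
  for (col in c("mean_hand_speed_bias", "movement_area_bias",
                "hand_bias_of_hits")) {
    expect_true(is.na(a[[col]]) || abs(a[[col]]) <= 1)
  }
  expect_true(a$hand_selection_overlap >= 0 && a$hand_selection_overlap <= 100)
  expect_true(is.na(a$median_error) ||
                (a$median_error > 0 && a$median_error <= 100))
  expect_lte(a$targets_hit, 200)
  expect_gte(a$steady_state_rate, 0)
})

test_that("steady-state rate and targets hit correlate across a cohort", {
  spec <- cohort_spec(200, age_slopes = c(capacity_lambda = -0.0099),
                      global_seed = 77)
  sim <- simulate_cohort(spec, oh_task(), include_samples = FALSE)
  pars <- extract_all_parameters(sim$trials, sim$manifest)
  r <- cor(pars$steady_state_rate, pars$targets_hit)
  expect_gt(r, 0.8)
})
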