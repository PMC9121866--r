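test_that("road intersection adjusts breeding-female survival by class", {
  expect_identical(road_adjusted_annual_survival(has_primary = TRUE,
                                                 mechanism_on = TRUE), 0.297)
  expect_identical(road_adjusted_annual_survival(has_secondary = TRUE,
                                                 mechanism_on = TRUE), 0.81)
  expect_identical(road_adjusted_annual_survival(has_primary = TRUE,
                                                 has_secondary = TRUE,
                                                 mechanism_on = TRUE), 0.297)
  expect_identical(road_adjusted_annual_survival(has_primary = TRUE,
                                                 mechanism_on = FALSE), 0.9)
  expect_identical(road_adjusted_annual_survival(mechanism_on = TRUE), 0.9)

  # through a real territory / road layer
  cl <- matrix(0L, 10, 10); cl[4, 6] <- 2L; cl[8, 2] <- 1L
  rl <- road_layer(cl)
  terr_pri <- c(which(cl == 2L), 1L)
  terr_sec <- c(which(cl == 1L), 1L)
  expect_identical(road_adjusted_annual_survival(terr_pri, rl), 0.297)
  expect_identical(road_adjusted_annual_survival(terr_sec, rl), 0.81)
  expect_identical(road_adjusted_annual_survival(1L, rl), 0.9)
})

test_that("monthly survival is the twelfth root of annual survival", {
  expect_identical(monthly_survival(1), 1)
  expect_equal(monthly_survival(0.9), 0.9^(1 / 12))
  expect_equal(monthly_survival(0.297), 0.297^(1 / 12))
  expect_equal(monthly_survival(0.9)^12, 0.9)
  expect_identical(monthly_survival(0), 0) # lethal limit used in stress tests
  expect_error(monthly_survival(-0.1), "negative")
})

test_that("challenge strength is a prime-age curve giving symmetric even-age odds", {
  expect_equal(challenge_weight(36), 1)
  expect_equal(challenge_weight(60), 2)
  expect_equal(challenge_weight(108), 2)
  expect_equal(challenge_weight(144), 1)
  expect_equal(challenge_weight(48), 1.5)
  set.seed(8)
  wins <- replicate(4000, resolve_challenge(84, 84)$challenger_wins)
  expect_lt(abs(mean(wins) - 0.5), 0.025)
})

test_that("challenge outcomes only kill in the prescribed branches", {
  set.seed(3)
  for (i in 1:200) {
    out <- resolve_challenge(60, 60, n_cubs = 2, n_juveniles = 1)
    if (out$challenger_wins) {
      expect_false(out$challenger_dies)
    } else {
      expect_false(out$incumbent_dies)
      expect_false(any(out$cub_killed))
      expect_false(any(out$juvenile_killed))
    }
  }
})

test_that("a female starves after three consecutive months below the minimum", {
  # a 12x12 grid of 0.5 kg/month cells: even the full grid yields utilized
  # prey 0.1 * 144 * 0.5 = 7.2 << 76, so starvation is certain
  land <- tiny_landscape(12, 12, prey = 0.5)
  cfg <- scenario_config(burn_in = 0, experiment = 24, landscape = land,
                         init_pop = data.frame(sex = "F", age = 60,
                                               origin_row = 6, origin_col = 6),
                         params = tiger_params(survival = c(
                           breeding_male = 1, breeding_female = 1,
                           dispersing_male = 1, transient_male = 1,
                           transient_female = 1, juvenile = 1, cub = 1)))
  set.seed(1)
  st <- init_state(cfg, land)
  for (s in 1:24) {
    sim_step(st)
    if (!length(st$id)) break
  }
  d <- data.frame(st$deaths)
  starv <- d[d$cause == "starvation", ]
  expect_identical(nrow(starv), 1L)
  # grace of 6 months after settling, then 3 consecutive shortfall months
  expect_identical(starv$step, 9L)

  # ample prey: the same female never starves
  rich <- tiny_landscape(12, 12, prey = 100)
  cfg2 <- scenario_config(burn_in = 0, experiment = 24, landscape = rich,
                          init_pop = data.frame(sex = "F", age = 60,
                                                origin_row = 6, origin_col = 6),
                          params = tiger_params(survival = c(
                            breeding_male = 1, breeding_female = 1,
                            dispersing_male = 1, transient_male = 1,
                            transient_female = 1, juvenile = 1, cub = 1)))
  set.seed(1)
  st2 <- init_state(cfg2, rich)
  for (s in 1:24) sim_step(st2)
  expect_identical(nrow(data.frame(st2$deaths)), 0L)
})

test_that("the starvation counter resets after a month above the minimum", {
  # low-production grid: the female owns the whole 12x12 grid within three
  # months and expansion can no longer change her prey sum, which the test
  # then sets directly to alternate lean and good months
  land <- tiny_landscape(12, 12, prey = 0.5)
  cfg <- scenario_config(burn_in = 0, experiment = 40, landscape = land,
                         init_pop = data.frame(sex = "F", age = 60,
                                               origin_row = 6, origin_col = 6),
                         params = tiger_params(survival = c(
                           breeding_male = 1, breeding_female = 1,
                           dispersing_male = 1, transient_male = 1,
                           transient_female = 1, juvenile = 1, cub = 1)))
  set.seed(1)
  st <- init_state(cfg, land)
  for (s in 1:8) { st$prey_sum[1] <- 1000; sim_step(st) }
  # two lean months, one good month, repeatedly: never three in a row
  for (cycle in 1:4) {
    st$prey_sum[1] <- 10; sim_step(st)
    st$prey_sum[1] <- 10; sim_step(st)
    st$prey_sum[1] <- 1000; sim_step(st)
  }
  expect_identical(length(st$id), 1L)
  # three consecutive lean months kill
  for (s in 1:3) { st$prey_sum[1] <- 10; sim_step(st) }
  expect_identical(length(st$id), 0L)
  d <- data.frame(st$deaths)
  expect_identical(d$cause, "starvation")
})

test_that("dependent offspring die with their mother, in the same month", {
  land <- tiny_landscape(12, 12, prey = 100)
  p <- tiger_params(survival = c(breeding_male = 1, breeding_female = 0,
                                 dispersing_male = 1, transient_male = 1,
                                 transient_female = 1, juvenile = 1, cub = 1))
  cfg <- scenario_config(burn_in = 0, experiment = 2, landscape = land,
                         init_pop = data.frame(sex = "F", age = 60,
                                               origin_row = 6, origin_col = 6),
                         params = p)
  set.seed(1)
  st <- init_state(cfg, land)
  # hand the female three cubs, then step: she dies (survival 0), cubs orphan
  .id <- st$id[1]
  tigersim:::.add_tigers(st, 3L, c("F", "M", "F"), age = 3L, mother = .id,
                         natal = st$origin[1])
  sim_step(st)
  d <- data.frame(st$deaths)
  expect_identical(nrow(d), 4L)
  expect_identical(sum(d$cause == "orphaned"), 3L)
  expect_identical(d$stage[d$cause == "orphaned"], rep("cub", 3))
  expect_identical(d$step, rep(1L, 4))
  expect_identical(length(st$id), 0L)
})

test_that("zero survival empties the population in a single step", {
  land <- tiny_landscape(15, 15, prey = 100)
  p <- tiger_params(survival = c(breeding_male = 0, breeding_female = 0,
                                 dispersing_male = 0, transient_male = 0,
                                 transient_female = 0, juvenile = 0, cub = 0))
  cfg <- scenario_config(burn_in = 0, experiment = 2, landscape = land,
                         n_females = 4, n_males = 2, params = p)
  set.seed(4)
  st <- init_state(cfg, land)
  n0 <- length(st$id)
  expect_gt(n0, 0)
  sim_step(st)
  expect_identical(length(st$id), 0L)
  expect_identical(nrow(data.frame(st$deaths)), n0)
})
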