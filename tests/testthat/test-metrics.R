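# A tiny hand-built decision log: player 7 has 4 request opportunities
# (acts on 3) and 2 accept opportunities (acts on 0); player 8 acts on its
# single request opportunity.
toy_log <- function() {
  opp <- data.frame(
    opportunity = 1:7,
    game = "g1", round = 0:6,
    actor = c(7L, 7L, 7L, 7L, 7L, 7L, 8L),
    actor_controller = c(rep("human", 6), "agent"),
    action_type = c("request", "request", "request", "request",
                    "accept", "accept", "request"),
    s_i = c(2L, 2L, 5L, 5L, 3L, 3L, 1L),
    n_options = 1L,
    chosen_option = c(1L, 1L, 1L, NA, NA, NA, 1L)
  )
  opt <- data.frame(
    opportunity = 1:7, option = 1L, target = c(2L, 2L, 3L, 3L, 4L, 4L, 9L),
    target_colour = 2L,
    target_controller = c("agent", "agent", "human", "human",
                          "agent", "agent", "human"),
    s_j = c(2L, 4L, 2L, 2L, 1L, 1L, 3L),
    s_avg_inc = c(3, 3, 2, 2, 1, 1, 3),
    s_avg_exc = c(4, 2, 2, 2, 1, 1, 3),
    chosen = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  )
  list(opportunities = opp, options = opt)
}

test_that("activity is the acted fraction of opportunities, missing when none", {
  log <- toy_log()
  expect_equal(activity(log, 7, "request"), 0.75)
  expect_equal(activity(log, 7, "accept"), 0)
  expect_equal(activity(log, 8, "request"), 1)
  expect_true(is.na(activity(log, 8, "accept")))
  expect_true(is.na(activity(log, 99, "request")))
  tab <- activity_table(log)
  expect_true(all(tab$activity >= 0 & tab$activity <= 1))
  expect_equal(tab$n_acted[tab$actor == 7 & tab$action_type == "request"], 3)
})

test_that("risk-averseness conditions activity on own cluster size", {
  log <- toy_log()
  expect_equal(risk_averseness(log, 7, 2, "request"), 1)
  expect_equal(risk_averseness(log, 7, 5, "request"), 0.5)
  expect_true(is.na(risk_averseness(log, 7, 8, "request")))
  # partition property: size-conditioned counts sum to the totals
  rt <- risk_table(log, by = "player")
  for (a in unique(rt$actor)) {
    for (ty in unique(rt$action_type[rt$actor == a])) {
      sub <- rt[rt$actor == a & rt$action_type == ty, ]
      opp <- log$opportunities
      sel <- opp$actor == a & opp$action_type == ty
      expect_equal(sum(sub$n_opportunities), sum(sel))
      expect_equal(sum(sub$n_acted), sum(sel & !is.na(opp$chosen_option)))
    }
  }
})

test_that("risk-averseness estimates a size-dependent act rate from simulation", {
  set.seed(41)
  n <- 4000
  s_i <- sample(1:10, n, replace = TRUE)
  act <- stats::rbinom(n, 1, ifelse(s_i <= 5, 0.8, 0.2))
  log <- list(
    opportunities = data.frame(
      opportunity = 1:n, game = "sim", round = 0L, actor = 1L,
      actor_controller = "sim", action_type = "request", s_i = s_i,
      n_options = 1L, chosen_option = ifelse(act == 1, 1L, NA_integer_)
    ),
    options = data.frame(
      opportunity = 1:n, option = 1L, target = 2L, target_colour = 2L,
      target_controller = "sim", s_j = 1L, s_avg_inc = 1, s_avg_exc = 1,
      chosen = act == 1
    )
  )
  lo <- vapply(1:5, function(s) risk_averseness(log, 1, s), 0)
  hi <- vapply(6:10, function(s) risk_averseness(log, 1, s), 0)
  expect_true(all(abs(lo - 0.8) < 0.1))
  expect_true(all(abs(hi - 0.2) < 0.1))
})

test_that("strategy value is the inclusive mean minus the chosen size", {
  # single same-colour neighbour: U = 0
  expect_equal(strategy_value(2, 2), 0)
  # neighbour sizes {2, 4}, chosen 2: U = 1
  expect_equal(strategy_value(mean(c(2, 4)), 2), 1)
  expect_equal(strategy_value(3, 2, l = 10, normalised = TRUE), 0.1)
  st <- strategy_table(toy_log())
  expect_equal(nrow(st), 4)  # one row per acted decision
  expect_equal(st$U[st$opportunity == 1], 1)   # 3 - 2
  expect_equal(st$U[st$opportunity == 2], -1)  # 3 - 4
})

test_that("uniform choice gives mean strategy value statistically zero", {
  rec <- gen_decision_records(agent_params(), 10000, chooser = "uniform",
                              seed = 77)
  st <- strategy_table(rec)
  se <- stats::sd(st$U) / sqrt(nrow(st))
  expect_lt(abs(mean(st$U)), 3 * se)
})

test_that("interaction matrix counts initiated requests by controller type", {
  log <- toy_log()
  im <- interaction_matrix(log)
  expect_equal(sum(im), 4)  # total acted requests
  expect_equal(im["human", "agent"], 2)
  expect_equal(im["human", "human"], 1)
  expect_equal(im["agent", "human"], 1)
  # all-agent game: all mass on agent->agent
  cfg <- game_config(seed = 6)
  rec <- run_game(cfg, list(agent = agent_policy()))
  im2 <- interaction_matrix(rec)
  expect_equal(dimnames(im2), list("agent", "agent"))
  expect_equal(sum(im2), sum(rec$requests$round >= 0))
})

test_that("mixed compositions produce human-agent interactions both ways", {
  spec <- build_setup("B", n_realizations = 2, base_seed = 11)
  batch <- run_batch(spec)
  im <- batch$summary$interaction_matrix
  expect_gt(im["human", "agent"], 0)
  expect_gt(im["agent", "human"], 0)
  expect_equal(sum(im), sum(vapply(batch$records,
                                   function(r) nrow(r$requests), 0)))
})

test_that("points trajectories pad terminated games and average across games", {
  cfg <- game_config(seed = 2)
  done <- run_game(cfg, list(agent = agent_policy()),
                   board = board_with_largest(c(10, 10, 10)))
  tr1 <- points_trajectory(done)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$mean_points, 20)
  expect_equal(tr1$se, 0)
  # two games, one finished at round 0: padded at 20 for later rounds
  running <- run_game(game_config(seed = 14), list(agent = agent_policy()))
  tr <- points_trajectory(list(done, running))
  expect_equal(nrow(tr), running$rounds_played + 1)
  expect_true(all(tr$n_games == 2))
  run_mean <- points_trajectory(running)$mean_points
  expect_equal(tr$mean_points, (run_mean + 20) / 2)
  # truncation mode drops the finished game from later rounds
  trt <- points_trajectory(list(done, running), pad = FALSE)
  expect_equal(trt$n_games[1], 2)
  expect_true(all(trt$n_games[-1] == 1))
})

test_that("metrics survive a serialisation round-trip unchanged", {
  cfg <- game_config(seed = 8)
  rec <- run_game(cfg, list(agent = agent_policy()))
  f <- tempfile(fileext = ".jsonl")
  write_game_record(rec, f)
  rec2 <- read_game_record(f)
  expect_equal(activity_table(rec2), activity_table(rec))
  expect_equal(interaction_matrix(rec2), interaction_matrix(rec))
  expect_equal(strategy_table(rec2), strategy_table(rec))
  expect_equal(points_trajectory(rec2), points_trajectory(rec))
})

test_that("request/accept action counts reconcile with the event log", {
  cfg <- game_config(seed = 19)
  rec <- run_game(cfg, list(agent = agent_policy()))
  opp <- rec$decisions$opportunities
  n_req_acted <- sum(opp$action_type == "request" & !is.na(opp$chosen_option))
  expect_equal(n_req_acted, nrow(rec$requests))
  n_acc_acted <- sum(opp$action_type == "accept" & !is.na(opp$chosen_option))
  expect_equal(n_acc_acted, sum(rec$requests$accepted))
})
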