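test_that("requesting colour cycles so each colour gets r/m turns", {
  expect_equal(requesting_colour(0, 3), 1)
  expect_equal(requesting_colour(4, 3), 2)
  turns <- table(vapply(0:14, requesting_colour, 1L, m = 3))
  expect_true(all(turns == 5))
  expect_error(requesting_colour(-1, 3), ">= 0")
})

test_that("fully enclosed players are not eligible to request", {
  b <- board_with_largest(c(10, 10, 10))
  cfg <- game_config(seed = 1)
  st <- new_game(cfg, board = b)
  el <- eligible_requesters(st)
  interior <- setdiff(which(b$colour == 1), el)
  for (v in interior) {
    expect_true(all(b$colour[b$adj[[v]]] == 1))
  }
  for (v in el) {
    expect_true(any(b$colour[b$adj[[v]]] != 1))
  }
  # proper colouring: every node of the turn colour has foreign neighbours
  bp <- assign_colours(generate_board(5, 6, 0, seed = 2), 3, mode = "proper")
  stp <- new_game(cfg, board = bp)
  expect_length(eligible_requesters(stp), 10)
})

test_that("a round without requests leaves the board unchanged", {
  cfg <- game_config(seed = 3)
  st <- new_game(cfg)
  before <- st$board$colour
  passive <- uniform_policy(act_prob = 0)
  st2 <- step_round(st, list(agent = passive), cfg)
  expect_identical(st2$board$colour, before)
  expect_equal(st2$round, 1)
})

test_that("an accepted request swaps exactly the two endpoint colours", {
  fx <- gen_fixture_log("single_swap")
  rec <- fx$record
  expect_equal(nrow(rec$requests), 1)
  expect_true(rec$requests$accepted)
  i <- rec$requests$requester; j <- rec$requests$receiver
  expect_identical(rec$final_colours[i], rec$initial_colours[j])
  expect_identical(rec$final_colours[j], rec$initial_colours[i])
  others <- setdiff(1:30, c(i, j))
  expect_identical(rec$final_colours[others], rec$initial_colours[others])
})

test_that("a receiver facing several requests accepts at most one", {
  found_multi <- FALSE
  for (s in 1:6) {
    cfg <- game_config(seed = 100 + s)
    rec <- run_game(cfg, list(agent = agent_policy()))
    req <- rec$requests
    if (nrow(req) == 0) next
    per_recv <- split(req, list(req$round, req$receiver), drop = TRUE)
    for (grp in per_recv) {
      expect_lte(sum(grp$accepted), 1)
      if (nrow(grp) > 1) found_multi <- TRUE
    }
    # requesters send at most one request per round
    expect_false(any(duplicated(req[, c("round", "requester")])))
  }
  expect_true(found_multi)
})

test_that("swaps conserve colour counts and the edge set never changes", {
  cfg <- game_config(seed = 9)
  st <- new_game(cfg)
  edges_before <- rbind(st$board$mesh_edges, st$board$extra_edges)
  rec <- run_game(cfg, list(agent = agent_policy()))
  expect_equal(as.vector(table(rec$final_colours)), c(10, 10, 10))
  st2 <- new_game(cfg)
  expect_identical(rbind(st2$board$mesh_edges, st2$board$extra_edges),
                   edges_before)
})

test_that("per-player opportunity counts respect r/m and 2r/m bounds", {
  cfg <- game_config(seed = 21)
  rec <- run_game(cfg, list(agent = agent_policy()))
  opp <- rec$decisions$opportunities
  sends <- table(opp$actor[opp$action_type == "request"])
  recvs <- table(opp$actor[opp$action_type == "accept"])
  expect_true(all(sends <= 5))
  expect_true(all(recvs <= 10))
})

test_that("games replay bit-identically under the same seed and policies", {
  cfg <- game_config(seed = 33)
  r1 <- run_game(cfg, list(agent = agent_policy()))
  r2 <- run_game(cfg, list(agent = agent_policy()))
  expect_identical(r1$requests, r2$requests)
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$decisions, r2$decisions)
  r3 <- run_game(game_config(seed = 34), list(agent = agent_policy()))
  expect_false(identical(r1$requests, r3$requests))
})

test_that("termination: immediate at objective, at round cap otherwise", {
  cfg <- game_config(seed = 2)
  rec <- run_game(cfg, list(agent = agent_policy()),
                  board = board_with_largest(c(10, 10, 10)))
  expect_equal(rec$rounds_played, 0)
  expect_equal(rec$reason, "objective")
  expect_true(all(rec$snapshots$points == 20))
  rec2 <- run_game(cfg, list(agent = uniform_policy(act_prob = 0)))
  expect_equal(rec2$rounds_played, 15)
  expect_equal(rec2$reason, "round_cap")
  # collective scheme ends exactly at ACP = 1
  cfgc <- game_config(payoff_scheme = "collective", seed = 2)
  recc <- run_game(cfgc, list(agent = agent_policy()),
                   board = board_with_largest(c(10, 10, 10)))
  expect_equal(recc$reason, "objective")
  expect_equal(recc$snapshots$acp[1], 1)
  recc2 <- run_game(cfgc, list(agent = agent_policy()),
                    board = board_with_largest(c(10, 10, 9)))
  expect_gt(recc2$rounds_played, 0)
})

test_that("snapshot count equals rounds played plus one", {
  for (s in c(5, 6)) {
    cfg <- game_config(seed = s)
    rec <- run_game(cfg, list(agent = agent_policy()))
    expect_equal(length(unique(rec$snapshots$round)), rec$rounds_played + 1)
  }
})

test_that("illegal policy targets are rejected at the protocol level", {
  cfg <- game_config(seed = 4)
  rogue <- list(
    request = function(view, l) {
      # deliberately request a same-colour neighbour
      own <- view$neighbours$node[view$neighbours$colour == view$colour]
      if (length(own)) own[1] else NA_integer_
    },
    accept = function(view, incoming, l) NA_integer_
  )
  expect_error(run_game(cfg, list(agent = rogue)), "illegal target")
})

test_that("game records round-trip through JSONL", {
  cfg <- game_config(seed = 12)
  rec <- run_game(cfg, list(agent = agent_policy()))
  f <- tempfile(fileext = ".jsonl")
  write_game_record(rec, f)
  rec2 <- read_game_record(f)
  expect_equal(rec2$initial_colours, rec$initial_colours)
  expect_equal(rec2$rounds_played, rec$rounds_played)
  expect_equal(nrow(rec2$requests), nrow(rec$requests))
  expect_equal(rec2$decisions$opportunities$chosen_option,
               rec$decisions$opportunities$chosen_option)
})
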