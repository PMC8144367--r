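test_that("utility ratio has the logistic-exponential closed form", {
  p0 <- agent_params(lambda = 0, alpha = 0, beta = 0, delta = 0)
  expect_equal(utility_ratio(p0, 3, 5, 2), 1)
  p1 <- agent_params(lambda = 1, alpha = 0, beta = 0, delta = 0)
  expect_equal(utility_ratio(p1, 1, 1, 1), exp(1))
  p2 <- agent_params(lambda = 0, alpha = -0.2, beta = 0.1, delta = -0.1)
  expect_equal(utility_ratio(p2, 2, 3, 4), exp(-0.5))
  expect_error(utility_ratio(agent_params(lambda = 1e309), 1, 1, 1), "non-finite")
})

test_that("choice probabilities match probability matching and sum to one", {
  expect_equal(choice_probabilities(numeric(0)), 1)  # opt-out only
  expect_equal(choice_probabilities(1), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(1, 3)), c(0.2, 0.6, 0.2))
  set.seed(1)
  for (k in 1:200) {
    ratios <- exp(stats::runif(sample(1:6, 1), -4, 4))
    expect_equal(sum(choice_probabilities(ratios)), 1, tolerance = 1e-12)
  }
})

test_that("raising one option's ratio raises its probability and lowers the rest", {
  ratios <- c(0.5, 1, 2)
  p <- choice_probabilities(ratios)
  ratios2 <- ratios; ratios2[2] <- ratios[2] * 1.5
  p2 <- choice_probabilities(ratios2)
  expect_gt(p2[2], p[2])
  expect_lt(p2[1], p[1])
  expect_lt(p2[3], p[3])
  expect_lt(p2[4], p[4])  # opt-out shrinks too
})

make_view <- function(s_i, nb) {
  list(focal = 99L, colour = 1L, s_i = s_i, neighbours = nb,
       group_points = 0, global_largest = c(1, 1, 1))
}

test_that("stability rule removes request options between two large clusters", {
  nb <- data.frame(node = c(2L, 3L), colour = c(2L, 3L), s = c(7L, 3L))
  view <- make_view(7L, nb)
  p <- agent_params()
  set.seed(1)
  d <- decide_request(view, p, l = 10)
  # s_i = 7 > 6 and s_j = 7 > 6: excluded; s_j = 3 retained
  expect_equal(d$options$target, 3L)
  # threshold is strict: size exactly 6 does not trigger
  nb6 <- data.frame(node = 2L, colour = 2L, s = 6L)
  d6 <- decide_request(make_view(7L, nb6), p, l = 10)
  expect_equal(d6$options$target, 2L)
  # all options removed => certain opt-out
  nb77 <- data.frame(node = c(2L, 3L), colour = c(2L, 2L), s = c(7L, 8L))
  d77 <- decide_request(make_view(9L, nb77), p, l = 10)
  expect_true(is.na(d77$choice))
  expect_equal(d77$p_opt_out, 1)
})

test_that("players with no foreign neighbours always opt out", {
  nb <- data.frame(node = c(2L, 3L), colour = c(1L, 1L), s = c(2L, 2L))
  d <- decide_request(make_view(2L, nb), agent_params(), l = 10)
  expect_true(is.na(d$choice))
  expect_equal(d$p_opt_out, 1)
})

test_that("accept decisions follow the same choice model over incoming requests", {
  nb <- data.frame(node = c(2L, 3L, 4L), colour = c(2L, 2L, 3L), s = c(3L, 5L, 2L))
  view <- make_view(4L, nb)
  p <- agent_params(role = "accept")
  d0 <- decide_accept(view, integer(0), p, l = 10)
  expect_true(is.na(d0$choice))
  d <- decide_accept(view, c(2L, 4L), p, l = 10)
  expect_setequal(d$options$target, c(2L, 4L))
  expect_error(decide_accept(view, 17L, p, l = 10), "not adjacent")
  # neutral parameters, one incoming: accept probability exactly 1/2
  pn <- agent_params(lambda = 0, alpha = 0, beta = 0, delta = 0, role = "accept")
  dn <- decide_accept(view, 2L, pn, l = 10)
  expect_equal(dn$probs, c(0.5, 0.5))
})

test_that("exclusive neighbourhood mean falls back to s_j when alone", {
  nb <- data.frame(node = c(2L, 3L, 4L), colour = c(2L, 2L, 3L), s = c(2L, 4L, 6L))
  view <- make_view(1L, nb)
  opts <- groupswap:::option_covariates(view, c(2L, 4L))
  # target 2 shares colour 2 with node 3: exclusive mean is 4, inclusive 3
  expect_equal(opts$s_avg_exc[opts$target == 2], 4)
  expect_equal(opts$s_avg_inc[opts$target == 2], 3)
  # target 4 is alone in colour 3: exclusive falls back to own size
  expect_equal(opts$s_avg_exc[opts$target == 4], 6)
  expect_equal(opts$s_avg_inc[opts$target == 4], 6)
})

test_that("single-option fit recovers the closed-form logit intercept", {
  p <- agent_params(lambda = 0.4, alpha = 0, beta = 0, delta = 0)
  rec <- gen_decision_records(p, 3000, n_options_range = 1, seed = 5)
  rate <- mean(!is.na(rec$opportunities$chosen_option))
  fit <- fit_params(rec, "request")
  # the empirical logit of the act rate is the saturated-intercept solution;
  # covariate terms should stay near zero
  glm_fit <- stats::glm(
    chosen ~ s_i + s_j + s_avg,
    family = stats::binomial(),
    data = data.frame(
      chosen = !is.na(rec$opportunities$chosen_option),
      s_i = rec$opportunities$s_i,
      s_j = rec$options$s_j,
      s_avg = rec$options$s_avg_exc
    )
  )
  expect_equal(unname(fit$estimates), unname(stats::coef(glm_fit)),
               tolerance = 1e-4)
  expect_equal(plogis(sum(fit$estimates * c(1, mean(rec$opportunities$s_i),
                                            mean(rec$options$s_j),
                                            mean(rec$options$s_avg_exc)))),
               rate, tolerance = 0.05)
})

test_that("fitting rejects non-identifiable records", {
  p <- agent_params()
  rec <- gen_decision_records(p, 50, s_range = 4, n_options_range = 1, seed = 2)
  expect_error(fit_params(rec, "request"), "identifiable")
})

test_that("parameters are recovered from model-generated records", {
  truth <- c(lambda = -1, alpha = -0.3, beta = 0.2, delta = -0.2)
  p <- do.call(agent_params, as.list(truth))
  rec <- gen_decision_records(p, 4000, seed = 99)
  fit <- fit_params(rec, "request")
  z <- abs(fit$estimates - truth) / fit$se
  expect_true(all(z < 3))
})

test_that("agent parameters round-trip through JSON", {
  p <- agent_params(lambda = -0.5, alpha = 0.1, beta = -0.2, delta = 0.3,
                    stability_fraction = 0.7, role = "accept")
  f <- tempfile(fileext = ".json")
  write_agent_params(p, f)
  p2 <- read_agent_params(f)
  expect_equal(p2, p)
  expect_error(agent_params(stability_fraction = 0), "stability_fraction")
})
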