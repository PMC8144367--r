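# Synthetic inputs with the statistical structure the analysis assumes:
# decision records drawn from the probability-matching choice model (for
# fitting and metric tests), heterogeneous behavioural profiles standing in
# for human players, and small fixture logs with known ground truth.

#' Generate synthetic decision records from the choice model
#'
#' Each opportunity draws a focal cluster size and 1-4 options. Every
#' option gets a small set of same-colour neighbour sizes, from which the
#' option's own size (first element), the inclusive mean and the exclusive
#' mean are derived, so the two neighbourhood-mean conventions stay
#' mutually consistent. The action is sampled from the probability-matching
#' model (or uniformly among options for the null chooser).
#'
#' @param params an \code{\link{agent_params}} generating the choices.
#' @param n_opportunities number of decision opportunities.
#' @param s_range integer range cluster sizes are drawn from (within 1..l).
#' @param n_options_range range of options per opportunity.
#' @param chooser \code{"model"} (probability matching with opt-out) or
#'   \code{"uniform"} (always act, uniform among options).
#' @param seed optional integer seed.
#' @return a decision log: list with \code{opportunities} and
#'   \code{options} data frames in the engine's schema.
#' @export
gen_decision_records <- function(params, n_opportunities,
                                 s_range = 1:10, n_options_range = 1:4,
                                 chooser = c("model", "uniform"),
                                 seed = NULL) {
  chooser <- match.arg(chooser)
  if (n_opportunities < 1) stop("n_opportunities must be >= 1")
  if (length(s_range) == 0 || length(n_options_range) == 0) {
    stop("empty covariate range")
  }
  s_range <- as.integer(s_range)
  n_options_range <- as.integer(n_options_range)
  if (!is.null(seed)) set.seed(seed)
  # safe against R's scalar-x sample() surprise
  resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
  opps <- vector("list", n_opportunities)
  opts <- vector("list", n_opportunities)
  for (i in seq_len(n_opportunities)) {
    s_i <- resample(s_range, 1L)
    k <- resample(n_options_range, 1L)
    sets <- lapply(seq_len(k), function(j) {
      resample(s_range, sample.int(3L, 1L))
    })
    s_j <- vapply(sets, `[`, 0L, 1L)
    s_inc <- vapply(sets, mean, 0)
    s_exc <- vapply(sets, function(x) if (length(x) > 1) mean(x[-1]) else x[1], 0)
    if (chooser == "model") {
      ratios <- utility_ratio(params, s_i, s_j, s_exc)
      choice <- sample_choice(choice_probabilities(ratios))
    } else {
      choice <- sample.int(k, 1L)
    }
    opps[[i]] <- data.frame(
      opportunity = i, game = "synthetic", round = i - 1L, actor = 0L,
      actor_controller = "synthetic", action_type = params$role, s_i = s_i,
      n_options = k, chosen_option = if (choice == 0L) NA_integer_ else choice
    )
    opts[[i]] <- data.frame(
      opportunity = i, option = seq_len(k), target = seq_len(k),
      target_colour = 1L, target_controller = "synthetic",
      s_j = s_j, s_avg_inc = s_inc, s_avg_exc = s_exc,
      chosen = seq_len(k) == choice
    )
  }
  list(opportunities = do.call(rbind, opps), options = do.call(rbind, opts))
}

#' A behavioural profile: parameter sets plus optional point-awareness
#'
#' Profiles are the simulator's stand-in for human players; the
#' point-aware flag adds an accept-leniency bonus to the intercept once the
#' player's group has banked the small-cluster points, mirroring the
#' observed relaxation of accepting after a threshold is reached. This is a
#' modelling choice of the package, not a fitted human model.
#'
#' @param id profile identifier.
#' @param request_params,accept_params \code{\link{agent_params}} per role.
#' @param point_aware enable the accept-leniency bonus.
#' @param accept_bonus intercept bonus when active.
#' @return a list of class \code{behaviour_profile}.
#' @export
behaviour_profile <- function(id,
                              request_params = agent_params(role = "request"),
                              accept_params = agent_params(role = "accept"),
                              point_aware = FALSE, accept_bonus = 0.5) {
  structure(list(id = id, request_params = request_params,
                 accept_params = accept_params, point_aware = point_aware,
                 accept_bonus = accept_bonus), class = "behaviour_profile")
}

#' The two stock profiles
#'
#' \code{cooperative_profile}: the plain cooperative agent model (stability
#' rule, no point awareness) used for autonomous agents.
#' \code{point_seeking_profile}: the human stand-in, identical utilities
#' but point-aware accepting.
#' @return a \code{\link{behaviour_profile}}.
#' @export
cooperative_profile <- function() behaviour_profile("agent")

#' @rdname cooperative_profile
#' @export
point_seeking_profile <- function() {
  behaviour_profile("human", point_aware = TRUE)
}

profile_policy <- function(profile) {
  agent_policy(request_params = profile$request_params,
               accept_params = profile$accept_params,
               point_aware = profile$point_aware,
               accept_bonus = profile$accept_bonus)
}

#' Generate a heterogeneous player population from profiles
#'
#' Draws per-player parameters as profile means plus Gaussian jitter
#' (truncated to keep utilities finite) and returns per-player policies
#' with unique controller ids, ready for \code{\link{game_config}}.
#'
#' @param profiles list of \code{list(profile = behaviour_profile, count = k)}.
#' @param jitter standard deviation added to each of lambda, alpha, beta,
#'   delta (both roles); 0 gives identical players within a profile.
#' @param seed optional integer seed.
#' @return list with \code{controllers} (character vector, one id per
#'   player slot) and \code{policies} (named list keyed by those ids).
#' @export
gen_population <- function(profiles, jitter = 0, seed = NULL) {
  if (jitter < 0) stop("jitter must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  controllers <- character(0)
  policies <- list()
  for (entry in profiles) {
    prof <- entry$profile; count <- entry$count
    for (k in seq_len(count)) {
      id <- sprintf("%s_%02d", prof$id, length(controllers) + 1L)
      p <- prof
      if (jitter > 0) {
        for (role in c("request_params", "accept_params")) {
          for (f in c("lambda", "alpha", "beta", "delta")) {
            p[[role]][[f]] <- max(-10, min(10, p[[role]][[f]] + stats::rnorm(1, 0, jitter)))
          }
        }
      }
      policies[[id]] <- profile_policy(p)
      controllers <- c(controllers, id)
    }
  }
  list(controllers = controllers, policies = policies)
}

# Board whose three colour groups occupy contiguous 2-column bands of the
# 5x6 torus: every group is a single cluster of 10, so the points objective
# is already met.
complete_board <- function() {
  b <- generate_board(5, 6, n_extra_links = 0, seed = 1)
  cols_of <- ((seq_len(30) - 1L) %% 6L) %/% 2L + 1L
  b$colour <- as.integer(cols_of)
  b$m <- 3L; b$l <- 10L
  b
}

#' Generate a fixture game log with known ground truth
#'
#' Three scenarios: \code{"empty"} (game already complete at round 0: no
#' opportunities, activities undefined), \code{"single_swap"} (exactly one
#' request, one accept, one swap), and \code{"full_game"} (an all-agent
#' game whose metrics at generation time are stored as ground truth).
#'
#' @param scenario one of \code{"empty"}, \code{"single_swap"},
#'   \code{"full_game"}.
#' @param seed integer seed.
#' @return list with \code{record} (a \code{game_record}) and \code{truth}
#'   (named list of expected metric values).
#' @export
gen_fixture_log <- function(scenario = c("empty", "single_swap", "full_game"),
                            seed = 1) {
  scenario <- match.arg(scenario)
  if (scenario == "empty") {
    cfg <- game_config(seed = seed, game_id = "fixture_empty")
    rec <- run_game(cfg, list(agent = agent_policy()), board = complete_board())
    return(list(record = rec,
                truth = list(n_requests = 0L, rounds_played = 0L,
                             reason = "objective")))
  }
  if (scenario == "single_swap") {
    # one round; only node 1 ever requests (it borders colour 2 after a
    # two-node recolouring) and every receiver deterministically accepts,
    # so the log holds exactly one request, one accept, one swap
    b <- complete_board()
    # displace two cross-band pairs so no group holds the scheme maximum
    # (otherwise the game ends at round 0); node 1 keeps a colour-2
    # neighbour (node 2) to request
    b$colour[2] <- 2L; b$colour[3] <- 1L
    b$colour[14] <- 2L; b$colour[15] <- 1L
    controllers <- rep("acceptor", 30)
    controllers[1] <- "requester"
    cfg <- game_config(r = 1, seed = seed, controllers = controllers,
                       game_id = "fixture_single")
    policies <- list(
      requester = list(
        request = function(view, l) {
          view$neighbours$node[view$neighbours$colour != view$colour][1]
        },
        accept = function(view, incoming, l) NA_integer_),
      acceptor = list(
        request = function(view, l) NA_integer_,
        accept = function(view, incoming, l) incoming[1])
    )
    rec <- run_game(cfg, policies, board = b)
    return(list(record = rec,
                truth = list(n_requests = 1L,
                             all_accepted = all(rec$requests$accepted),
                             requester_activity = 1.0)))
  }
  cfg <- game_config(seed = seed, game_id = "fixture_full")
  rec <- run_game(cfg, list(agent = agent_policy()))
  truth <- list(
    activity = activity_table(rec),
    interaction_total = sum(interaction_matrix(rec)),
    n_requests = nrow(rec$requests),
    trajectory = points_trajectory(rec)
  )
  list(record = rec, truth = truth)
}
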