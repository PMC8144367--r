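# Round-based engine. Rounds are 0-based; in round t the colour
# (t mod m) + 1 sends requests. Each eligible requester is asked for at
# most one request, each receiver with incoming requests accepts at most
# one, and accepted swaps (vertex-disjoint by construction) execute in a
# uniformly shuffled order. Decisions within a round are made on the
# round-start cluster sizes; the board updates as swaps execute.
#
# Players are distinct from nodes (seats): a player keeps their colour and
# controller for the whole game and moves to the other seat when a swap
# executes. state$occupant maps node -> player id (players are numbered by
# their starting node), so a player's request opportunities are capped at
# r/m and receive opportunities at 2r/m, as the turn schedule implies.

SCHEMA_VERSION <- 1L

#' Game configuration
#'
#' @param m number of colour groups (default 3).
#' @param l players per group (default 10).
#' @param r maximum number of rounds (default 15, giving each colour
#'   r/m = 5 request turns and at most 2r/m = 10 receive turns).
#' @param rows,cols torus dimensions; \code{rows * cols} must equal
#'   \code{m * l}.
#' @param n_extra_links small-world links added to the mesh.
#' @param max_degree total degree cap.
#' @param payoff_scheme \code{"points"} (terminate once every group holds
#'   the scheme maximum) or \code{"collective"} (terminate at ACP = 1).
#' @param scheme a \code{\link{point_scheme}}.
#' @param seed integer seed controlling the board, colour assignment and
#'   every in-game random draw.
#' @param controllers character vector of length n mapping each player
#'   (identified by their starting node) to a policy id (default all
#'   \code{"agent"}); the controller travels with the player through swaps.
#' @param game_id identifier stamped on logs.
#' @return a list of class \code{game_config}.
#' @export
game_config <- function(m = 3, l = 10, r = 15, rows = 5, cols = 6,
                        n_extra_links = 10, max_degree = 5,
                        payoff_scheme = c("points", "collective"),
                        scheme = point_scheme(), seed = 1,
                        controllers = NULL, game_id = paste0("game", seed)) {
  payoff_scheme <- match.arg(payoff_scheme)
  n <- m * l
  if (rows * cols != n) stop("rows * cols must equal m * l")
  if (r < 1) stop("r must be >= 1")
  if (is.null(controllers)) controllers <- rep("agent", n)
  if (length(controllers) != n) stop("controllers must have one entry per node")
  structure(list(m = m, l = l, n = n, r = r, rows = rows, cols = cols,
                 n_extra_links = n_extra_links, max_degree = max_degree,
                 payoff_scheme = payoff_scheme, scheme = scheme, seed = seed,
                 controllers = controllers, game_id = game_id),
            class = "game_config")
}

# Refresh the derived fields (cluster sizes, largest clusters, points).
refresh_state <- function(state) {
  state$cluster_sizes <- all_cluster_sizes(state$board)
  state$global_largest <- largest_clusters(state$board)
  state$points <- if (state$payoff_scheme == "points") {
    all_group_points(state$board, state$scheme)
  } else {
    rep(NA_real_, state$board$m)
  }
  state
}

#' Initialise a game state
#'
#' Builds the board (unless one is supplied), assigns start colours under
#' the experimental constraint that no group holds more than 6 points, and
#' computes the initial derived quantities.
#'
#' @param config a \code{\link{game_config}}.
#' @param board optional pre-built, coloured \code{swap_board}.
#' @return a list of class \code{game_state}.
#' @export
new_game <- function(config, board = NULL) {
  set.seed(config$seed)
  if (is.null(board)) {
    board <- generate_board(config$rows, config$cols,
                            n_extra_links = config$n_extra_links,
                            max_degree = config$max_degree)
    board <- assign_colours(board, config$m, mode = "random_constrained")
  }
  state <- structure(list(
    board = board, round = 0L,
    occupant = seq_len(board$n),
    payoff_scheme = config$payoff_scheme, scheme = config$scheme,
    terminated = FALSE, reason = NA_character_
  ), class = "game_state")
  refresh_state(state)
}

#' Requesting colour for a round
#'
#' Rounds are 0-based and the requesting colour cycles so that with r = 15
#' and m = 3 every colour gets exactly five request turns.
#'
#' @param round 0-based round index.
#' @param m number of colours.
#' @return colour index in 1..m.
#' @export
requesting_colour <- function(round, m) {
  if (round < 0) stop("round must be >= 0")
  as.integer(round %% m) + 1L
}

#' Nodes eligible to send a request this round
#'
#' Nodes of the current requesting colour having at least one differently
#' coloured neighbour; fully enclosed players can neither send nor receive.
#'
#' @param state a \code{game_state}.
#' @return integer vector of node ids.
#' @export
eligible_requesters <- function(state) {
  if (state$terminated) stop("game already terminated")
  board <- state$board
  col <- requesting_colour(state$round, board$m)
  nodes <- which(board$colour == col)
  nodes[vapply(nodes, function(v) {
    any(board$colour[board$adj[[v]]] != col)
  }, TRUE)]
}

check_objective <- function(state, max_pts) {
  if (state$payoff_scheme == "points") {
    all(state$points >= max_pts)
  } else {
    isTRUE(all.equal(acp(state$board), 1))
  }
}

# Mutable per-game log accumulator.
new_log <- function() {
  env <- new.env(parent = emptyenv())
  env$opportunities <- list(); env$options <- list()
  env$requests <- list(); env$n_opp <- 0L
  env
}

log_opportunity <- function(log, game_id, round, actor, controller, type,
                            s_i, opts, choice, target_controllers) {
  log$n_opp <- log$n_opp + 1L
  oid <- log$n_opp
  chosen_idx <- NA_integer_
  if (!is.na(choice) && !is.null(opts)) chosen_idx <- match(choice, opts$target)
  log$opportunities[[oid]] <- data.frame(
    opportunity = oid, game = game_id, round = round, actor = actor,
    actor_controller = controller, action_type = type, s_i = s_i,
    n_options = if (is.null(opts)) 0L else nrow(opts),
    chosen_option = chosen_idx
  )
  if (!is.null(opts) && nrow(opts) > 0) {
    log$options[[length(log$options) + 1L]] <- data.frame(
      opportunity = oid, option = seq_len(nrow(opts)),
      target = opts$target, target_colour = opts$colour,
      target_controller = target_controllers,
      s_j = opts$s_j, s_avg_inc = opts$s_avg_inc, s_avg_exc = opts$s_avg_exc,
      chosen = seq_len(nrow(opts)) == ifelse(is.na(chosen_idx), -1L, chosen_idx)
    )
  }
  oid
}

#' Advance a game by one round
#'
#' Collects one request decision from every eligible requester, one accept
#' decision from every receiver with incoming requests, executes the
#' accepted swaps, recomputes points and checks termination.
#'
#' @param state a \code{game_state}.
#' @param policies named list of policies (see \code{\link{agent_policy}}),
#'   one per controller id used in \code{config$controllers}.
#' @param config the game's \code{\link{game_config}}.
#' @param log internal log accumulator (created by \code{\link{run_game}}).
#' @return the updated \code{game_state}.
#' @export
step_round <- function(state, policies, config, log = new_log()) {
  if (state$terminated) stop("game already terminated")
  board <- state$board
  col <- requesting_colour(state$round, board$m)
  controllers <- config$controllers
  requesters <- eligible_requesters(state)

  occ <- state$occupant
  requests <- data.frame(requester = integer(0), receiver = integer(0))
  for (node in requesters) {
    player <- occ[node]
    view <- local_view(state, node)
    cands <- view$neighbours$node[view$neighbours$colour != col]
    opts <- option_covariates(view, cands)
    pol <- policies[[controllers[player]]]
    if (is.null(pol)) stop("no policy registered for controller '", controllers[player], "'")
    target <- pol$request(view, config$l)
    if (!is.na(target)) {
      if (!(target %in% cands)) {
        stop("policy for node ", node, " requested an illegal target ", target)
      }
      requests <- rbind(requests, data.frame(requester = node, receiver = target))
    }
    log_opportunity(log, config$game_id, state$round, player, controllers[player],
                    "request", view$s_i, opts, target,
                    if (is.null(opts)) NULL else controllers[occ[opts$target]])
  }

  accepted <- data.frame(requester = integer(0), receiver = integer(0))
  for (recv in sort(unique(requests$receiver))) {
    player <- occ[recv]
    inc <- requests$requester[requests$receiver == recv]
    view <- local_view(state, recv)
    opts <- option_covariates(view, inc)
    pol <- policies[[controllers[player]]]
    choice <- pol$accept(view, inc, config$l)
    if (!is.na(choice) && !(choice %in% inc)) {
      stop("policy for node ", recv, " accepted a non-incoming request")
    }
    log_opportunity(log, config$game_id, state$round, player, controllers[player],
                    "accept", view$s_i, opts, choice,
                    if (is.null(opts)) NULL else controllers[occ[opts$target]])
    if (!is.na(choice)) {
      accepted <- rbind(accepted, data.frame(requester = choice, receiver = recv))
    }
  }

  if (nrow(requests) > 0) {
    requests$accepted <- paste(requests$requester, requests$receiver) %in%
      paste(accepted$requester, accepted$receiver)
    requests$round <- state$round
    log$requests[[length(log$requests) + 1L]] <- requests
  }

  if (nrow(accepted) > 0) {
    for (k in sample.int(nrow(accepted))) {
      a <- accepted$requester[k]; b <- accepted$receiver[k]
      state$board$colour[c(a, b)] <- state$board$colour[c(b, a)]
      state$occupant[c(a, b)] <- state$occupant[c(b, a)]
    }
  }

  state$round <- state$round + 1L
  refresh_state(state)
}

#' Run a complete game
#'
#' Loops \code{\link{step_round}} until the objective is met (every group
#' at the scheme maximum for the points scheme; ACP = 1 for the collective
#' scheme) or the round cap r is reached, logging every request, accept
#' decision and board snapshot.
#'
#' @param config a \code{\link{game_config}}.
#' @param policies named list of policies keyed by controller id.
#' @param board optional pre-built coloured board (skips board generation;
#'   the seed then only drives in-game randomness).
#' @return a \code{game_record}: list with \code{config}, \code{snapshots}
#'   (long data.frame: round, group, largest, points, acp), \code{requests}
#'   (round, requester, receiver, accepted), \code{decisions}
#'   (opportunities + options tables), \code{initial_colours},
#'   \code{final_colours}, \code{rounds_played}, \code{reason}.
#' @export
run_game <- function(config, policies = list(agent = agent_policy()),
                     board = NULL) {
  state <- new_game(config, board)
  initial <- state$board$colour
  max_pts <- if (config$payoff_scheme == "points") {
    max_scheme_points(config$scheme, config$m, config$l)
  } else NA
  log <- new_log()
  snap <- list(snapshot_row(state, config))
  reason <- "round_cap"
  if (check_objective(state, max_pts)) {
    reason <- "objective"
  } else {
    while (state$round < config$r) {
      state <- step_round(state, policies, config, log)
      snap[[length(snap) + 1L]] <- snapshot_row(state, config)
      if (check_objective(state, max_pts)) { reason <- "objective"; break }
    }
  }
  state$terminated <- TRUE
  state$reason <- reason
  requests <- if (length(log$requests)) {
    do.call(rbind, log$requests)[, c("round", "requester", "receiver", "accepted")]
  } else {
    data.frame(round = integer(0), requester = integer(0),
               receiver = integer(0), accepted = logical(0))
  }
  structure(list(
    schema_version = SCHEMA_VERSION,
    config = config,
    initial_colours = initial,
    final_colours = state$board$colour,
    snapshots = do.call(rbind, snap),
    requests = requests,
    decisions = list(
      opportunities = rbind_or_empty(log$opportunities, empty_opportunities()),
      options = rbind_or_empty(log$options, empty_options())
    ),
    rounds_played = state$round,
    reason = reason,
    final_state = state
  ), class = "game_record")
}

snapshot_row <- function(state, config) {
  data.frame(
    game = config$game_id, round = state$round,
    group = seq_len(config$m),
    largest = state$global_largest,
    points = if (config$payoff_scheme == "points") state$points else NA_real_,
    acp = acp(state$board)
  )
}

rbind_or_empty <- function(lst, empty) if (length(lst)) do.call(rbind, lst) else empty

empty_opportunities <- function() data.frame(
  opportunity = integer(0), game = character(0), round = integer(0),
  actor = integer(0), actor_controller = character(0),
  action_type = character(0), s_i = integer(0), n_options = integer(0),
  chosen_option = integer(0)
)

empty_options <- function() data.frame(
  opportunity = integer(0), option = integer(0), target = integer(0),
  target_colour = integer(0), target_controller = character(0),
  s_j = integer(0), s_avg_inc = numeric(0), s_avg_exc = numeric(0),
  chosen = logical(0)
)

#' @export
print.game_record <- function(x, ...) {
  cat("game_record", x$config$game_id, "-", x$rounds_played, "rounds,",
      "terminated by", x$reason, "\n")
  last <- x$snapshots[x$snapshots$round == x$rounds_played, ]
  cat("final largest clusters:", paste(last$largest, collapse = " "),
      "| points:", paste(last$points, collapse = " "), "\n")
  invisible(x)
}

# ---- agent and baseline policies -------------------------------------------

#' Build a policy from agent parameters
#'
#' A policy is a pair of decision functions, \code{request(view, l)} and
#' \code{accept(view, incoming, l)}, each returning a node id or \code{NA}
#' (opt-out / reject-all). The point-aware variant adds a leniency bonus to
#' the accept intercept once the player's group has banked the small-cluster
#' points, mimicking the observed relaxation of accepting after the
#' threshold is reached.
#'
#' @param request_params,accept_params \code{\link{agent_params}} per role
#'   (defaults identical).
#' @param apply_stability_request,apply_stability_accept whether the
#'   stability rule constrains each role.
#' @param point_aware enable the accept-leniency bonus.
#' @param accept_bonus added to the accept intercept when active.
#' @param points_trigger group points at which the bonus activates
#'   (default 5, the small-cluster award).
#' @return a policy list.
#' @export
agent_policy <- function(request_params = agent_params(role = "request"),
                         accept_params = agent_params(role = "accept"),
                         apply_stability_request = TRUE,
                         apply_stability_accept = TRUE,
                         point_aware = FALSE, accept_bonus = 0.5,
                         points_trigger = 5) {
  list(
    request = function(view, l) {
      decide_request(view, request_params, l, apply_stability_request)$choice
    },
    accept = function(view, incoming, l) {
      p <- accept_params
      if (point_aware && !is.na(view$group_points) &&
          view$group_points >= points_trigger) {
        p$lambda <- p$lambda + accept_bonus
      }
      decide_accept(view, incoming, p, l, apply_stability_accept)$choice
    },
    params = list(request = request_params, accept = accept_params,
                  point_aware = point_aware)
  )
}

#' Uniform-random baseline policy
#'
#' Acts with probability \code{act_prob} and, when acting, picks uniformly
#' among the available options. Useful as the null model for the strategy
#' metric (its expected strategy value is 0).
#'
#' @param act_prob probability of acting at each opportunity.
#' @return a policy list.
#' @export
uniform_policy <- function(act_prob = 1) {
  pick <- function(targets) {
    if (length(targets) == 0 || stats::runif(1) > act_prob) return(NA_integer_)
    targets[sample.int(length(targets), 1L)]
  }
  list(
    request = function(view, l) {
      pick(view$neighbours$node[view$neighbours$colour != view$colour])
    },
    accept = function(view, incoming, l) pick(incoming)
  )
}

# ---- JSONL serialisation ---------------------------------------------------

#' Write a game record as JSON-lines
#'
#' One JSON object per line: a header (schema version, config, initial
#' colours), then one line per snapshot row, request, and decision
#' opportunity (options nested).
#'
#' @param record a \code{game_record}.
#' @param path output file.
#' @export
write_game_record <- function(record, path) {
  cfg <- record$config
  cfg$scheme <- unclass(cfg$scheme)
  lines <- c(
    jsonlite::toJSON(list(type = "header", schema_version = record$schema_version,
                          config = unclass(cfg),
                          initial_colours = record$initial_colours,
                          final_colours = record$final_colours,
                          rounds_played = record$rounds_played,
                          reason = record$reason),
                     auto_unbox = TRUE, digits = NA),
    vapply(seq_len(nrow(record$snapshots)), function(i) {
      jsonlite::toJSON(c(list(type = "snapshot"), as.list(record$snapshots[i, ])),
                       auto_unbox = TRUE, digits = NA)
    }, ""),
    if (nrow(record$requests)) vapply(seq_len(nrow(record$requests)), function(i) {
      jsonlite::toJSON(c(list(type = "request"), as.list(record$requests[i, ])),
                       auto_unbox = TRUE, digits = NA)
    }, "") else character(0),
    {
      opp <- record$decisions$opportunities
      opt <- record$decisions$options
      vapply(seq_len(nrow(opp)), function(i) {
        o <- opt[opt$opportunity == opp$opportunity[i], -1, drop = FALSE]
        jsonlite::toJSON(c(list(type = "opportunity"), as.list(opp[i, ]),
                           list(options = o)),
                         auto_unbox = TRUE, digits = NA, na = "null")
      }, "")
    }
  )
  writeLines(lines, path)
}

#' Read a game record written by \code{\link{write_game_record}}
#' @param path a JSONL file.
#' @return a \code{game_record} (without the live \code{final_state}).
#' @export
read_game_record <- function(path) {
  lines <- lapply(readLines(path), jsonlite::fromJSON, simplifyVector = TRUE)
  types <- vapply(lines, `[[`, "", "type")
  hdr <- lines[[which(types == "header")[1]]]
  if (hdr$schema_version != SCHEMA_VERSION) {
    stop("unsupported log schema version: ", hdr$schema_version)
  }
  row_df <- function(x, drop = "type") {
    x <- x[setdiff(names(x), drop)]
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  snapshots <- do.call(rbind, lapply(lines[types == "snapshot"], row_df))
  req_lines <- lines[types == "request"]
  requests <- if (length(req_lines)) {
    do.call(rbind, lapply(req_lines, row_df))
  } else {
    data.frame(round = integer(0), requester = integer(0),
               receiver = integer(0), accepted = logical(0))
  }
  opp_lines <- lines[types == "opportunity"]
  opportunities <- if (length(opp_lines)) {
    do.call(rbind, lapply(opp_lines, function(x) {
      x$chosen_option <- if (is.null(x$chosen_option)) NA_integer_ else x$chosen_option
      row_df(x, drop = c("type", "options"))
    }))
  } else empty_opportunities()
  options <- if (length(opp_lines)) {
    tabs <- lapply(opp_lines, function(x) {
      if (length(x$options) == 0 || NROW(x$options) == 0) return(NULL)
      cbind(opportunity = x$opportunity, as.data.frame(x$options))
    })
    rbind_or_empty(Filter(Negate(is.null), tabs), empty_options())
  } else empty_options()
  cfg <- hdr$config
  cfg$scheme <- do.call(point_scheme, as.list(cfg$scheme))
  cfg$controllers <- as.character(cfg$controllers)
  class(cfg) <- "game_config"
  structure(list(
    schema_version = hdr$schema_version, config = cfg,
    initial_colours = as.integer(hdr$initial_colours),
    final_colours = as.integer(hdr$final_colours),
    snapshots = snapshots, requests = requests,
    decisions = list(opportunities = opportunities, options = options),
    rounds_played = hdr$rounds_played, reason = hdr$reason
  ), class = "game_record")
}
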