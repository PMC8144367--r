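# Batch runners for the four team compositions: A (all human), B (every
# group half human, half agent), C (one human group, one mixed, one agent),
# D (all agent). "Human" slots in simulation are filled by behavioural
# profiles (point-aware agents by default) since no generative human model
# exists for the point-based payoff; summaries from A-C are therefore
# profile-dependent.

#' Build a named setup specification
#'
#' @param name one of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"}.
#' @param n_realizations number of games; defaults per setup reproduce the
#'   study design (A 4, B 5, C 4 games played; D 100 simulated
#'   realizations).
#' @param base_seed seed of the first game; game k uses
#'   \code{base_seed + k - 1}.
#' @param r round cap.
#' @param payoff_scheme \code{"points"} or \code{"collective"}.
#' @return a list of class \code{setup_spec} with the per-group controller
#'   composition.
#' @export
build_setup <- function(name = c("A", "B", "C", "D"), n_realizations = NULL,
                        base_seed = 1, r = 15,
                        payoff_scheme = "points") {
  name <- match.arg(name)
  comp <- switch(name,
    A = rep(list(c(human = 10L)), 3),
    B = rep(list(c(human = 5L, agent = 5L)), 3),
    C = list(c(human = 10L), c(human = 5L, agent = 5L), c(agent = 10L)),
    D = rep(list(c(agent = 10L)), 3)
  )
  if (is.null(n_realizations)) {
    n_realizations <- switch(name, A = 4L, B = 5L, C = 4L, D = 100L)
  }
  spec <- structure(list(
    name = name, composition = comp, n_realizations = n_realizations,
    base_seed = base_seed, r = r, payoff_scheme = payoff_scheme,
    m = 3L, l = 10L, rows = 5L, cols = 6L, n_extra_links = 10L,
    max_degree = 5L
  ), class = "setup_spec")
  validate_setup(spec)
  spec
}

#' Validate a setup specification against its composition invariants
#' @param spec a \code{setup_spec}.
#' @return the spec, invisibly; errors if invalid.
#' @export
validate_setup <- function(spec) {
  if (length(spec$composition) != spec$m) {
    stop("composition must list one entry per group")
  }
  sums <- vapply(spec$composition, sum, 0L)
  if (!all(sums == spec$l)) {
    stop("each group's composition must sum to l = ", spec$l)
  }
  if (sum(sums) != spec$m * spec$l) stop("total players must be n = m*l")
  invisible(spec)
}

# Assign controller labels to nodes so each colour group gets its
# composition (labels shuffled within the group).
compose_controllers <- function(board, spec) {
  controllers <- character(board$n)
  for (g in seq_len(spec$m)) {
    nodes <- which(board$colour == g)
    labels <- rep(names(spec$composition[[g]]), spec$composition[[g]])
    controllers[nodes] <- sample(labels)
  }
  controllers
}

default_policies <- function() {
  list(agent = profile_policy(cooperative_profile()),
       human = profile_policy(point_seeking_profile()))
}

#' Run a batch of games for a setup
#'
#' Each realization builds a fresh board, assigns start colours under the
#' 6-point constraint, distributes controllers per the composition, runs
#' the game, and the batch is summarised (point trajectory, interaction
#' matrix, activity and risk tables).
#'
#' @param spec a \code{\link{setup_spec}}.
#' @param policies named list of policies covering every controller id in
#'   the composition (defaults: cooperative agents, point-seeking human
#'   stand-ins).
#' @return list of class \code{batch_result}: \code{spec}, \code{records},
#'   \code{summary} (trajectory, interaction matrices, activity, risk) —
#'   empty but well-formed when \code{n_realizations} is 0.
#' @export
run_batch <- function(spec, policies = default_policies()) {
  validate_setup(spec)
  needed <- unique(unlist(lapply(spec$composition, names)))
  missing <- setdiff(needed, names(policies))
  if (length(missing)) {
    stop("no policy registered for controller(s): ", paste(missing, collapse = ", "))
  }
  records <- vector("list", spec$n_realizations)
  for (k in seq_len(spec$n_realizations)) {
    seed <- spec$base_seed + k - 1L
    set.seed(seed)
    board <- generate_board(spec$rows, spec$cols,
                            n_extra_links = spec$n_extra_links,
                            max_degree = spec$max_degree)
    board <- assign_colours(board, spec$m, mode = "random_constrained")
    controllers <- compose_controllers(board, spec)
    cfg <- game_config(m = spec$m, l = spec$l, r = spec$r,
                       rows = spec$rows, cols = spec$cols,
                       n_extra_links = spec$n_extra_links,
                       max_degree = spec$max_degree,
                       payoff_scheme = spec$payoff_scheme,
                       seed = seed, controllers = controllers,
                       game_id = sprintf("%s_%03d", spec$name, k))
    records[[k]] <- run_game(cfg, policies, board = board)
  }
  structure(list(spec = spec, records = records,
                 summary = summarise_batch(records, spec)), class = "batch_result")
}

summarise_batch <- function(records, spec) {
  if (length(records) == 0) {
    return(list(trajectory = points_trajectory(list()),
                interaction_matrix = matrix(0, 0, 0),
                interaction_mean = matrix(0, 0, 0),
                activity = activity_table(list(opportunities = empty_opportunities(),
                                               options = empty_options())),
                n_games = 0L))
  }
  d <- pool_decisions(records)
  list(
    trajectory = points_trajectory(records),
    interaction_matrix = interaction_matrix(d),
    interaction_mean = interaction_matrix(d, average = TRUE),
    activity = activity_table(d),
    risk_by_size = if (nrow(d$opportunities)) risk_table(d, by = "size") else NULL,
    n_games = length(records)
  )
}

#' @export
print.batch_result <- function(x, ...) {
  cat("batch_result: setup", x$spec$name, "-", length(x$records), "games\n")
  if (length(x$records)) {
    tr <- x$summary$trajectory
    cat("mean points at final round:",
        round(tr$mean_points[nrow(tr)], 2), "\n")
    cat("mean requests per game:",
        round(sum(x$summary$interaction_matrix) / length(x$records), 1), "\n")
  }
  invisible(x)
}

#' Play a 3-game session for a setup
#'
#' Runs up to three games and applies the session reward logic: the third
#' game is skipped if the first two already reach the reward threshold.
#' Game totals are the focal group's points at termination.
#'
#' @param spec a \code{setup_spec} (its \code{n_realizations} is ignored).
#' @param group focal colour group whose points count toward the reward.
#' @param policies as in \code{\link{run_batch}}.
#' @param reward_threshold session points needed for the reward.
#' @return list: \code{game_totals}, \code{outcome}
#'   (\code{\link{session_outcome}}), \code{records}.
#' @export
run_session <- function(spec, group = 1, policies = default_policies(),
                        reward_threshold = 27) {
  totals <- numeric(0)
  records <- list()
  for (k in 1:3) {
    if (k == 3) {
      if (!session_outcome(totals, reward_threshold)$play_third_game) break
    }
    spec_k <- spec
    spec_k$n_realizations <- 1L
    spec_k$base_seed <- spec$base_seed + k - 1L
    batch <- run_batch(spec_k, policies)
    rec <- batch$records[[1]]
    final <- rec$snapshots[rec$snapshots$round == rec$rounds_played &
                             rec$snapshots$group == group, ]
    totals <- c(totals, final$points)
    records[[k]] <- rec
  }
  list(game_totals = totals,
       outcome = session_outcome(totals, reward_threshold),
       records = records)
}
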