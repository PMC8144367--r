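# Behavioural statistics computed from decision logs. Activity a_i is the
# fraction of a player's opportunities (request or accept, counted once per
# round per player) on which the player acted; risk-averseness a_i(s) is
# the same fraction restricted to opportunities where the player's cluster
# size was s; the strategy value U_j = <s(c_j)> - s_j compares the chosen
# neighbour's cluster size against the mean cluster size of the focal
# player's neighbours of that colour (inclusive of the chosen one, so a
# uniformly random chooser has expectation exactly 0).

#' Pool the decision logs of several game records
#'
#' Opportunity ids are namespaced by game id so the pooled tables stay
#' relational.
#'
#' @param records a \code{game_record} or list of them.
#' @return list with \code{opportunities} and \code{options} data frames.
#' @export
pool_decisions <- function(records) {
  if (inherits(records, "game_record")) records <- list(records)
  opps <- list(); opts <- list()
  for (rec in records) {
    d <- rec$decisions
    if (nrow(d$opportunities) == 0) next
    o <- d$opportunities
    key <- paste0(o$game, ":", o$opportunity)
    o2 <- d$options
    o2$opportunity <- key[match(o2$opportunity, o$opportunity)]
    o$opportunity <- key
    opps[[length(opps) + 1L]] <- o
    opts[[length(opts) + 1L]] <- o2
  }
  list(opportunities = rbind_or_empty(opps, empty_opportunities()),
       options = rbind_or_empty(opts, empty_options()))
}

as_decisions <- function(records) {
  if (is.list(records) && !is.null(records$opportunities)) return(records)
  pool_decisions(records)
}

#' Activity of a player
#'
#' Fraction of opportunities of the given type on which the player acted.
#' A player with no opportunities has no defined activity and \code{NA} is
#' returned (never 0).
#'
#' @param records a decision log (or game record(s)).
#' @param player node id.
#' @param action_type \code{"request"} or \code{"accept"}.
#' @return fraction in \code{[0, 1]}, or \code{NA} if no opportunities.
#' @export
activity <- function(records, player, action_type = c("request", "accept")) {
  action_type <- match.arg(action_type)
  opp <- as_decisions(records)$opportunities
  opp <- opp[opp$actor == player & opp$action_type == action_type, , drop = FALSE]
  if (nrow(opp) == 0) return(NA_real_)
  mean(!is.na(opp$chosen_option))
}

#' Risk-averseness: activity conditioned on own cluster size
#'
#' @inheritParams activity
#' @param s the player's cluster size at the opportunity.
#' @return fraction, or \code{NA} if the player never had an opportunity at
#'   that cluster size (gaps are reported as missing, never imputed as 0).
#' @export
risk_averseness <- function(records, player, s,
                            action_type = c("request", "accept")) {
  action_type <- match.arg(action_type)
  opp <- as_decisions(records)$opportunities
  opp <- opp[opp$actor == player & opp$action_type == action_type &
               opp$s_i == s, , drop = FALSE]
  if (nrow(opp) == 0) return(NA_real_)
  mean(!is.na(opp$chosen_option))
}

#' Per-player activity table
#'
#' One row per (player, action type) with the opportunity count, action
#' count and activity.
#'
#' @param records a decision log (or game record(s)).
#' @return data.frame: actor, actor_controller, action_type, n_opportunities,
#'   n_acted, activity.
#' @export
activity_table <- function(records) {
  opp <- as_decisions(records)$opportunities
  if (nrow(opp) == 0) {
    return(data.frame(actor = integer(0), actor_controller = character(0),
                      action_type = character(0), n_opportunities = integer(0),
                      n_acted = integer(0), activity = numeric(0)))
  }
  agg <- stats::aggregate(
    cbind(n_opportunities = rep(1L, nrow(opp)),
          n_acted = as.integer(!is.na(opp$chosen_option))) ~
      actor + actor_controller + action_type,
    data = opp, FUN = sum)
  agg$activity <- agg$n_acted / agg$n_opportunities
  agg[order(agg$action_type, agg$actor), ]
}

#' Activity by cluster size (risk-averseness table)
#'
#' @param records a decision log (or game record(s)).
#' @param by \code{"player"} for per-(player, size) rows or \code{"size"}
#'   for event-level pooling across players within each size.
#' @return data.frame with n_opportunities, n_acted and activity per cell;
#'   cluster sizes with no opportunities simply do not appear.
#' @export
risk_table <- function(records, by = c("player", "size")) {
  by <- match.arg(by)
  opp <- as_decisions(records)$opportunities
  if (nrow(opp) == 0) stop("no opportunities in the records")
  form <- if (by == "player") {
    cbind(n_opportunities = rep(1L, nrow(opp)),
          n_acted = as.integer(!is.na(opp$chosen_option))) ~
      actor + actor_controller + s_i + action_type
  } else {
    cbind(n_opportunities = rep(1L, nrow(opp)),
          n_acted = as.integer(!is.na(opp$chosen_option))) ~
      s_i + action_type + actor_controller
  }
  agg <- stats::aggregate(form, data = opp, FUN = sum)
  agg$activity <- agg$n_acted / agg$n_opportunities
  agg[order(agg$action_type, agg$s_i), ]
}

#' Strategy value of a chosen option
#'
#' \code{U = <s(c_j)> - s_j} with the inclusive neighbourhood mean; positive
#' values indicate cooperative targeting of below-average (small) clusters.
#' When \code{normalised}, both terms are divided by l first.
#'
#' @param s_avg_inclusive mean cluster size of the focal player's
#'   neighbours sharing the chosen option's colour, including the option.
#' @param s_j cluster size of the chosen option.
#' @param l group size (for normalisation).
#' @param normalised divide both terms by l.
#' @return numeric (vectorised).
#' @export
strategy_value <- function(s_avg_inclusive, s_j, l = 10, normalised = FALSE) {
  if (normalised) s_avg_inclusive / l - s_j / l else s_avg_inclusive - s_j
}

#' Strategy values of all acted decisions in a log
#'
#' One row per chosen option with its U value (inclusive mean by default;
#' the exclusive-mean variant is also returned for comparison).
#'
#' @param records a decision log (or game record(s)).
#' @param l group size.
#' @param normalised normalise by l.
#' @return data.frame: opportunity, actor, actor_controller, action_type,
#'   s_i, s_j, U (inclusive), U_exclusive.
#' @export
strategy_table <- function(records, l = 10, normalised = FALSE) {
  d <- as_decisions(records)
  opt <- d$options[d$options$chosen, , drop = FALSE]
  opp <- d$opportunities
  i <- match(opt$opportunity, opp$opportunity)
  data.frame(
    opportunity = opt$opportunity,
    actor = opp$actor[i], actor_controller = opp$actor_controller[i],
    action_type = opp$action_type[i], s_i = opp$s_i[i], s_j = opt$s_j,
    U = strategy_value(opt$s_avg_inc, opt$s_j, l, normalised),
    U_exclusive = strategy_value(opt$s_avg_exc, opt$s_j, l, normalised)
  )
}

#' Interaction-count matrix by controller type
#'
#' Counts initiated interactions (requests sent) from the initiator's
#' controller type to the receiver's, summed over the supplied logs and
#' optionally averaged per game.
#'
#' @param records a decision log (or game record(s)).
#' @param average divide counts by the number of distinct games.
#' @return a numeric matrix, rows = initiator type, cols = receiver type.
#' @export
interaction_matrix <- function(records, average = FALSE) {
  d <- as_decisions(records)
  opp <- d$opportunities
  req <- opp[opp$action_type == "request" & !is.na(opp$chosen_option), , drop = FALSE]
  types <- sort(unique(opp$actor_controller))
  mat <- matrix(0, length(types), length(types), dimnames = list(types, types))
  if (nrow(req) > 0) {
    key <- paste(d$options$opportunity, d$options$option)
    tgt <- d$options$target_controller[match(paste(req$opportunity, req$chosen_option), key)]
    tab <- table(factor(req$actor_controller, types), factor(tgt, types))
    mat <- mat + unclass(tab)
  }
  if (average) {
    n_games <- length(unique(opp$game))
    if (n_games > 0) mat <- mat / n_games
  }
  mat
}

#' Per-round mean group points across games
#'
#' Games that terminate early are padded at their final value so every game
#' contributes to every round index (set \code{pad = FALSE} to truncate
#' instead). The mean at each round is over games (group points averaged
#' within a game first); the standard error is over games.
#'
#' @param records a list of \code{game_record}s (or one).
#' @param pad pad terminated games at their final points.
#' @return data.frame: round, mean_points, se, n_games.
#' @export
points_trajectory <- function(records, pad = TRUE) {
  if (inherits(records, "game_record")) records <- list(records)
  if (length(records) == 0) {
    return(data.frame(round = integer(0), mean_points = numeric(0),
                      se = numeric(0), n_games = integer(0)))
  }
  per_game <- lapply(records, function(rec) {
    s <- rec$snapshots
    agg <- stats::aggregate(points ~ round, data = s, FUN = mean)
    agg[order(agg$round), ]
  })
  max_round <- max(vapply(per_game, function(g) max(g$round), 0))
  mat <- vapply(per_game, function(g) {
    v <- rep(NA_real_, max_round + 1)
    v[g$round + 1] <- g$points
    if (pad) {
      last <- g$points[nrow(g)]
      v[seq_len(max_round + 1) > max(g$round) + 1] <- last
    }
    v
  }, numeric(max_round + 1))
  mat <- matrix(mat, nrow = max_round + 1)
  n <- rowSums(!is.na(mat))
  mean_pts <- rowMeans(mat, na.rm = TRUE)
  se <- apply(mat, 1, function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) 0 else stats::sd(x) / sqrt(length(x))
  })
  data.frame(round = 0:max_round, mean_points = mean_pts, se = se, n_games = n)
}

#' Write the standard metric tables for a batch of games as CSV
#'
#' Emits activity, risk-averseness (player- and size-level), strategy,
#' interaction-matrix and trajectory tables into a directory.
#'
#' @param records list of \code{game_record}s.
#' @param dir output directory (created if needed).
#' @param l group size used for strategy normalisation.
#' @return invisibly, the list of tables.
#' @export
write_metric_tables <- function(records, dir, l = 10) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- pool_decisions(records)
  tabs <- list(
    activity = activity_table(d),
    risk_by_player = risk_table(d, by = "player"),
    risk_by_size = risk_table(d, by = "size"),
    strategy = strategy_table(d, l = l, normalised = TRUE),
    trajectory = points_trajectory(records)
  )
  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  im <- interaction_matrix(d, average = TRUE)
  utils::write.csv(as.data.frame(im), file.path(dir, "interaction_matrix.csv"))
  invisible(c(tabs, list(interaction_matrix = im)))
}
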