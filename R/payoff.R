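# Two payoff schemes: the point scheme (rewards per cluster-size threshold,
# own group and other groups) and the collective ACP (mean normalised
# largest cluster over colours) used by the earlier purely cooperative game.

#' Default point scheme
#'
#' Points attach to groups: 5 once the group's largest cluster reaches the
#' small threshold (6), a further 7 at the large threshold (9), and 4 for
#' every other group whose largest cluster reaches the large threshold.
#' Points are a pure function of the current board, so they are lost again
#' if a requirement stops being satisfied. With three groups the maximum a
#' group can hold is 5 + 7 + 4 + 4 = 20.
#'
#' @param own_small_threshold,own_small_points own-group small requirement.
#' @param own_large_threshold,own_large_points own-group large requirement
#'   (cumulative with the small one).
#' @param other_large_threshold,other_large_points awarded once per other
#'   group at the large threshold.
#' @return a list of class \code{point_scheme}.
#' @export
point_scheme <- function(own_small_threshold = 6, own_small_points = 5,
                         own_large_threshold = 9, own_large_points = 7,
                         other_large_threshold = 9, other_large_points = 4) {
  structure(list(
    own_small_threshold = own_small_threshold,
    own_small_points = own_small_points,
    own_large_threshold = own_large_threshold,
    own_large_points = own_large_points,
    other_large_threshold = other_large_threshold,
    other_large_points = other_large_points
  ), class = "point_scheme")
}

#' Read a point scheme from a YAML file
#'
#' Accepts the field names of \code{\link{point_scheme}}; missing fields
#' keep their defaults.
#' @param file path to a YAML file.
#' @return a \code{point_scheme}.
#' @export
read_point_scheme <- function(file) {
  vals <- yaml::read_yaml(file)
  known <- names(formals(point_scheme))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown point scheme fields: ", paste(unknown, collapse = ", "))
  do.call(point_scheme, vals)
}

# Score one group given the vector of largest clusters per colour.
score_from_largest <- function(largest, group, scheme) {
  own <- largest[group]
  others <- largest[-group]
  scheme$own_small_points * (own >= scheme$own_small_threshold) +
    scheme$own_large_points * (own >= scheme$own_large_threshold) +
    scheme$other_large_points * sum(others >= scheme$other_large_threshold)
}

#' Points currently held by a group
#'
#' @param board a coloured \code{swap_board}.
#' @param group colour index in 1..m.
#' @param scheme a \code{\link{point_scheme}}.
#' @return integer points.
#' @export
group_points <- function(board, group, scheme = point_scheme()) {
  score_from_largest(largest_clusters(board), group, scheme)
}

#' Points of every group
#' @inheritParams group_points
#' @return integer vector of length m.
#' @export
all_group_points <- function(board, scheme = point_scheme()) {
  lg <- largest_clusters(board)
  vapply(seq_along(lg), function(g) score_from_largest(lg, g, scheme), 0)
}

#' Maximum points one group can hold under a scheme
#'
#' Brute-force enumeration over all largest-cluster combinations in
#' \code{{1..l}^m}, taking the maximum group score. With the default scheme
#' and m = 3 this is 20.
#'
#' @param scheme a \code{\link{point_scheme}}.
#' @param m number of groups.
#' @param l group size (cluster sizes range over 1..l).
#' @return the maximum score.
#' @export
max_scheme_points <- function(scheme = point_scheme(), m = 3, l = 10) {
  if (m < 2) stop("need m >= 2")
  grids <- rep(list(seq_len(l)), m)
  combos <- as.matrix(expand.grid(grids))
  best <- 0
  for (k in seq_len(nrow(combos))) {
    for (g in seq_len(m)) {
      best <- max(best, score_from_largest(combos[k, ], g, scheme))
    }
  }
  best
}

#' Average collective progress (ACP)
#'
#' Mean over colours of the largest cluster size divided by the group size
#' l: 1/l on a properly coloured mesh (all clusters singletons), 1.0 when
#' every group has formed its full cluster.
#'
#' @param board a coloured \code{swap_board}.
#' @return fraction in \code{[1/l, 1]}.
#' @export
acp <- function(board) {
  mean(largest_clusters(board)) / board$l
}

#' Session outcome for a series of up to three games
#'
#' A session consists of at most \code{games_per_session} games; the reward
#' is granted once the summed group points reach \code{reward_threshold}
#' (27 by default). If the first two games already reach the threshold the
#' third game is skipped.
#'
#' @param game_totals numeric vector of per-game points (length 1..3).
#' @param reward_threshold points needed for the reward.
#' @param games_per_session maximum games in a session.
#' @return list with \code{rewarded} and \code{play_third_game}.
#' @export
session_outcome <- function(game_totals, reward_threshold = 27,
                            games_per_session = 3) {
  if (length(game_totals) < 1 || length(game_totals) > games_per_session) {
    stop("a session has between 1 and ", games_per_session, " games")
  }
  rewarded <- sum(game_totals) >= reward_threshold
  play_third <- !(length(game_totals) >= 2 &&
                    sum(game_totals[1:2]) >= reward_threshold)
  list(rewarded = rewarded, play_third_game = play_third)
}
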