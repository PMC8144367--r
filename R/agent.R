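# Probability-matching decision model. Each available swap option (a
# differently coloured neighbour, or an incoming requester) carries a
# utility ratio relative to doing nothing,
#   P_w / P_0 = exp(lambda + alpha*s_i + beta*s_j + delta*<s(c_j)>),
# where s_i is the focal player's cluster size, s_j the option's, and
# <s(c_j)> the average cluster size of the focal player's OTHER neighbours
# sharing the option's colour (exclusive mean; equal to s_j when the option
# is the only neighbour of its colour). Choice follows probability
# matching: p_w = ratio_w / (1 + sum(ratios)), opt-out = 1 / (1 + sum).

#' Agent decision-model parameters
#'
#' The default values are configurable placeholders with qualitatively
#' cooperative signs (reluctant to move a large own cluster, inclined to
#' help small clusters); the originating experiments did not publish fitted
#' values, so any quantitative agent-behaviour output depends on these.
#'
#' @param lambda intercept (baseline propensity to act).
#' @param alpha weight on the focal player's cluster size s_i.
#' @param beta weight on the option's cluster size s_j.
#' @param delta weight on the mean cluster size of the other same-coloured
#'   neighbours of the focal player.
#' @param stability_fraction fraction of l above which the stability rule
#'   suppresses requests between two large clusters (default 0.6, strict
#'   comparison: sizes strictly greater than 0.6*l trigger it).
#' @param role \code{"request"} or \code{"accept"}; separate parameter sets
#'   per role are allowed.
#' @return a list of class \code{agent_params}.
#' @export
agent_params <- function(lambda = -1, alpha = -0.3, beta = 0.2, delta = -0.2,
                         stability_fraction = 0.6,
                         role = c("request", "accept")) {
  role <- match.arg(role)
  if (stability_fraction <= 0 || stability_fraction > 1) {
    stop("stability_fraction must be in (0, 1]")
  }
  structure(list(lambda = lambda, alpha = alpha, beta = beta, delta = delta,
                 stability_fraction = stability_fraction, role = role),
            class = "agent_params")
}

#' Utility ratio of one option relative to inaction
#' @param params an \code{\link{agent_params}}.
#' @param s_i focal player's cluster size.
#' @param s_j option's cluster size.
#' @param s_avg mean cluster size of the focal player's other neighbours of
#'   the option's colour.
#' @return positive real \code{exp(lambda + alpha*s_i + beta*s_j + delta*s_avg)}.
#' @export
utility_ratio <- function(params, s_i, s_j, s_avg) {
  r <- exp(params$lambda + params$alpha * s_i + params$beta * s_j +
             params$delta * s_avg)
  if (any(!is.finite(r))) stop("non-finite utility ratio")
  r
}

#' Probability-matching choice probabilities with opt-out
#'
#' @param ratios numeric vector of utility ratios, one per option (may be
#'   empty).
#' @return numeric vector of length \code{length(ratios) + 1}: option
#'   probabilities followed by the opt-out probability; sums to 1.
#' @export
choice_probabilities <- function(ratios) {
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("utility ratios must be finite and positive")
  }
  denom <- 1 + sum(ratios)
  c(ratios / denom, 1 / denom)
}

# Inverse-CDF sample over (options..., opt-out); returns index into the
# option vector, or 0L for opt-out. Uses the session RNG for replayability.
sample_choice <- function(probs) {
  u <- stats::runif(1)
  idx <- findInterval(u, cumsum(probs)) + 1L
  if (idx >= length(probs)) 0L else idx
}

# Covariates for candidate targets seen from a local view. For each target,
# the inclusive mean averages over ALL of the focal player's neighbours of
# the target's colour (used by the strategy metric); the exclusive mean
# omits the target itself and falls back to s_j when the target is alone.
option_covariates <- function(view, targets) {
  if (length(targets) == 0) return(NULL)
  nb <- view$neighbours
  rows <- lapply(targets, function(t) {
    i <- match(t, nb$node)
    if (is.na(i)) stop("target ", t, " is not adjacent to node ", view$focal)
    same <- nb$s[nb$colour == nb$colour[i]]
    excl <- nb$s[nb$colour == nb$colour[i] & nb$node != t]
    data.frame(
      target = t, colour = nb$colour[i], s_j = nb$s[i],
      s_avg_inc = mean(same),
      s_avg_exc = if (length(excl)) mean(excl) else nb$s[i]
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Shared core of the two decisions: build options, apply the stability
# rule, compute probabilities, sample. Returns the full audit trail.
decide_among <- function(view, targets, params, l, apply_stability = TRUE) {
  opts <- option_covariates(view, targets)
  if (!is.null(opts) && nrow(opts) > 0 && apply_stability) {
    thr <- params$stability_fraction * l
    keep <- !(view$s_i > thr & opts$s_j > thr)
    opts <- opts[keep, , drop = FALSE]
  }
  if (is.null(opts) || nrow(opts) == 0) {
    return(list(choice = NA_integer_, options = opts,
                probs = 1, p_opt_out = 1))
  }
  ratios <- utility_ratio(params, view$s_i, opts$s_j, opts$s_avg_exc)
  probs <- choice_probabilities(ratios)
  k <- sample_choice(probs)
  list(choice = if (k == 0L) NA_integer_ else opts$target[k],
       options = opts, probs = probs, p_opt_out = probs[length(probs)])
}

#' Decide whether (and to whom) to send a swap request
#'
#' Candidates are the focal player's differently coloured neighbours. The
#' stability rule removes candidates where both the focal player's and the
#' candidate's cluster sizes exceed \code{stability_fraction * l}; the
#' remaining options are sampled by probability matching, with opt-out.
#'
#' @param view a local view from \code{\link{local_view}}.
#' @param params an \code{\link{agent_params}} (request role).
#' @param l group size.
#' @param apply_stability whether to apply the stability rule.
#' @return list with \code{choice} (target node id, or \code{NA} for
#'   opt-out), the filtered \code{options} table and the choice
#'   probabilities.
#' @export
decide_request <- function(view, params, l, apply_stability = TRUE) {
  targets <- view$neighbours$node[view$neighbours$colour != view$colour]
  decide_among(view, targets, params, l, apply_stability)
}

#' Decide which (if any) incoming request to accept
#'
#' Each incoming requester becomes an option with covariates taken from the
#' receiver's own view; at most one request is accepted (the receiving
#' player can only vacate one position). The stability rule applies as for
#' requests unless disabled.
#'
#' @param view the receiver's local view.
#' @param incoming integer vector of requester node ids (must be adjacent).
#' @param params an \code{\link{agent_params}} (accept role).
#' @param l group size.
#' @param apply_stability whether to apply the stability rule.
#' @return as \code{\link{decide_request}}; \code{choice} is the accepted
#'   requester or \code{NA} for reject-all.
#' @export
decide_accept <- function(view, incoming, params, l, apply_stability = TRUE) {
  if (length(incoming) == 0) {
    return(list(choice = NA_integer_, options = NULL, probs = 1, p_opt_out = 1))
  }
  if (!all(incoming %in% view$neighbours$node)) {
    stop("incoming requester is not adjacent to the receiver")
  }
  decide_among(view, incoming, params, l, apply_stability)
}

#' Fit the choice model to a decision log by maximum likelihood
#'
#' Maximises the probability-matching likelihood: for every recorded
#' opportunity, the probability of the chosen option (or of opting out)
#' under \code{p_w = ratio_w / (1 + sum(ratios))}. With a single option per
#' opportunity this reduces to binary logistic regression on
#' (s_i, s_j, s_avg). Standard errors come from the inverse observed
#' information at the optimum.
#'
#' @param records a decision log as produced by \code{\link{run_game}} or
#'   \code{\link{gen_decision_records}} (list with \code{opportunities} and
#'   \code{options} data frames).
#' @param role fit request or accept decisions.
#' @param covariate which neighbourhood mean enters the model:
#'   \code{"exclusive"} (the decision model's definition) or
#'   \code{"inclusive"}.
#' @return object of class \code{agent_fit}: \code{estimates}, \code{se},
#'   \code{loglik}, \code{n_opportunities}, \code{role}.
#' @export
fit_params <- function(records, role = c("request", "accept"),
                       covariate = c("exclusive", "inclusive")) {
  role <- match.arg(role)
  covariate <- match.arg(covariate)
  opp <- records$opportunities
  opt <- records$options
  opp <- opp[opp$action_type == role, , drop = FALSE]
  opt <- opt[opt$opportunity %in% opp$opportunity, , drop = FALSE]
  if (nrow(opp) == 0) stop("no opportunities of type '", role, "' in the records")
  s_avg <- if (covariate == "exclusive") opt$s_avg_exc else opt$s_avg_inc
  s_i <- opp$s_i[match(opt$opportunity, opp$opportunity)]
  X <- cbind(1, s_i, opt$s_j, s_avg)
  if (qr(X)$rank < 4) {
    stop("covariates are not identifiable (constant or collinear); ",
         "need variation in s_i, s_j and the neighbourhood mean")
  }
  chosen <- !is.na(opp$chosen_option)
  if (!any(chosen) || all(chosen)) {
    stop("records must contain both acted and not-acted opportunities")
  }
  # flag the chosen option rows
  key <- paste(opt$opportunity, opt$option)
  chosen_key <- paste(opp$opportunity[chosen], opp$chosen_option[chosen])
  is_chosen <- key %in% chosen_key
  grp <- match(opt$opportunity, opp$opportunity)
  nll <- function(theta) {
    eta <- drop(X %*% theta)
    if (any(eta > 700)) return(1e10)
    denom <- 1 + rowsum(exp(eta), grp, reorder = TRUE)[, 1]
    -(sum(eta[is_chosen]) - sum(log(denom)))
  }
  fit <- stats::optim(c(0, 0, 0, 0), nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-12))
  if (fit$convergence != 0) stop("likelihood optimisation did not converge")
  vcov <- tryCatch(solve(fit$hessian), error = function(e) {
    stop("singular information matrix: model not identifiable ",
         "(possible separation); diagnostic: ", conditionMessage(e))
  })
  se <- sqrt(pmax(diag(vcov), 0))
  est <- stats::setNames(fit$par, c("lambda", "alpha", "beta", "delta"))
  structure(list(
    estimates = est, se = stats::setNames(se, names(est)),
    loglik = -fit$value, n_opportunities = nrow(opp),
    role = role, covariate = covariate
  ), class = "agent_fit")
}

#' @export
print.agent_fit <- function(x, ...) {
  cat("Choice-model fit (", x$role, ", ", x$n_opportunities,
      " opportunities)\n", sep = "")
  tab <- cbind(estimate = x$estimates, se = x$se)
  print(round(tab, 4))
  cat("log-likelihood:", round(x$loglik, 2), "\n")
  invisible(x)
}

#' Write / read agent parameters as JSON
#' @param params an \code{\link{agent_params}}.
#' @param file path.
#' @export
write_agent_params <- function(params, file) {
  jsonlite::write_json(unclass(params), file, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_agent_params
#' @export
read_agent_params <- function(file) {
  do.call(agent_params, jsonlite::read_json(file, simplifyVector = TRUE))
}

#' Write a fit report (estimates, standard errors, log-likelihood) as JSON
#' @param fit an \code{agent_fit}.
#' @param file path.
#' @export
write_fit_report <- function(fit, file) {
  jsonlite::write_json(list(
    role = fit$role, covariate = fit$covariate,
    estimates = as.list(fit$estimates), se = as.list(fit$se),
    loglik = fit$loglik, n_opportunities = fit$n_opportunities
  ), file, auto_unbox = TRUE, digits = NA)
}
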