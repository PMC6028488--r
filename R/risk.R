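#' Construct a risk curve
#'
#' A risk curve maps the cumulative group contribution \eqn{C} to the
#' probability that a loss event strikes in the current round. All families
#' are normalized so that only the invested fraction \eqn{C / W_0} of the
#' total initial group wealth \eqn{W_0} matters, and all are monotone
#' non-increasing in \eqn{C}:
#'
#' * `"linear"`: \eqn{p(C) = 1 - \lambda_1 C / W_0}, clamped to \[0, 1\].
#'   `lambda` controls how fast the risk declines; for \eqn{\lambda_1 > 1}
#'   the risk hits zero before the whole endowment is in the pot.
#' * `"power"`: \eqn{p(C) = 1 - (C / W_0)^{\lambda_2}}, clamped to \[0, 1\].
#'   `lambda` sets the convexity (concave for \eqn{\lambda_2 < 1}, convex
#'   for \eqn{\lambda_2 > 1}).
#' * `"sigmoid"`: \eqn{p(C) = 1 / (e^{\lambda_3 (C/W_0 - 1/2)} + 1)}, a
#'   step-like curve with its inflection point at \eqn{C = W_0 / 2} where the
#'   probability is exactly 1/2; `lambda` sets the steepness of the
#'   threshold.
#'
#' @param family One of `"linear"`, `"power"`, `"sigmoid"`.
#' @param lambda Positive shape parameter of the chosen family.
#' @param normalizer Total initial group wealth \eqn{W_0} (wealth units).
#'   May be left `NULL` and filled in later by [game_config()], which sets it
#'   to the summed initial wealth of the players in the game.
#' @return An object of class `crd_risk_curve`.
#' @seealso [risk_probability()], [hetero_linear_risk()], [loss_timing()]
#' @examples
#' curve <- risk_curve("sigmoid", lambda = 10, normalizer = 2)
#' risk_probability(curve, c(0, 1, 2))
#' @export
risk_curve <- function(family = c("linear", "power", "sigmoid"), lambda,
                       normalizer = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            lambda > 0)
  if (!is.null(normalizer)) {
    stopifnot(is.numeric(normalizer), length(normalizer) == 1L)
    if (!is.finite(normalizer) || normalizer <= 0) {
      stop("`normalizer` (total initial wealth W_0) must be positive",
           call. = FALSE)
    }
  }
  structure(
    list(family = family, lambda = as.numeric(lambda),
         normalizer = if (is.null(normalizer)) NULL else as.numeric(normalizer)),
    class = "crd_risk_curve"
  )
}

#' @export
print.crd_risk_curve <- function(x, ...) {
  cat(sprintf("<risk curve: %s, lambda = %g, W0 = %s>\n", x$family, x$lambda,
              if (is.null(x$normalizer)) "unset" else format(x$normalizer)))
  invisible(x)
}

#' Evaluate the loss probability of a risk curve
#'
#' @param curve A [risk_curve()] with its normalizer set.
#' @param contribution Cumulative contribution \eqn{C \ge 0} (wealth units);
#'   vectorized.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @examples
#' risk_probability(risk_curve("linear", 1, normalizer = 2), c(0, 1, 2))
#' @export
risk_probability <- function(curve, contribution) {
  stopifnot(inherits(curve, "crd_risk_curve"))
  if (is.null(curve$normalizer)) {
    stop("risk curve has no normalizer W_0; supply one or use it via game_config()",
         call. = FALSE)
  }
  if (any(!is.finite(contribution)) || any(contribution < 0)) {
    stop("`contribution` must be finite and >= 0", call. = FALSE)
  }
  frac <- contribution / curve$normalizer
  p <- switch(curve$family,
    linear  = 1 - curve$lambda * frac,
    power   = 1 - frac^curve$lambda,
    sigmoid = 1 / (exp(curve$lambda * (frac - 0.5)) + 1)
  )
  pmin(1, pmax(0, p))
}

#' Heterogeneous linear risk for a rich and a poor player
#'
#' In the one-round analysis of wealth and risk inequality the poor player
#' faces the plain linear risk \eqn{p_P(C) = 1 - C/W} (zero only when the
#' whole combined endowment \eqn{W = W_R + W_P} is contributed), while the
#' rich player's risk declines faster: \eqn{p_R(C) = 1 - \lambda_R C / W}
#' for \eqn{C < W/\lambda_R} and 0 beyond, with \eqn{\lambda_R \ge 1}. The
#' rich player's risk therefore never exceeds the poor player's.
#'
#' @param lambda_rich Slope multiplier \eqn{\lambda_R \ge 1} for the rich
#'   player's risk decline.
#' @param normalizer Combined endowment \eqn{W = W_R + W_P} (wealth units).
#' @return An object of class `crd_hetero_risk`.
#' @examples
#' h <- hetero_linear_risk(lambda_rich = 2, normalizer = 5)
#' heterogeneous_risk(h, contribution = 2.5, who = "rich")
#' @export
hetero_linear_risk <- function(lambda_rich, normalizer) {
  stopifnot(is.numeric(lambda_rich), length(lambda_rich) == 1L,
            is.numeric(normalizer), length(normalizer) == 1L, normalizer > 0)
  if (!is.finite(lambda_rich) || lambda_rich < 1) {
    stop("`lambda_rich` must be >= 1 (the rich face weakly lower risk)",
         call. = FALSE)
  }
  structure(
    list(lambda_rich = as.numeric(lambda_rich), lambda_poor = 1,
         normalizer = as.numeric(normalizer)),
    class = "crd_hetero_risk"
  )
}

#' Evaluate the heterogeneous linear risk
#'
#' @param risk A [hetero_linear_risk()].
#' @param contribution Cumulative contribution \eqn{C \ge 0}; vectorized.
#' @param who `"rich"` or `"poor"`.
#' @return Loss probabilities in \[0, 1\].
#' @export
heterogeneous_risk <- function(risk, contribution, who = c("rich", "poor")) {
  stopifnot(inherits(risk, "crd_hetero_risk"))
  who <- match.arg(who)
  lam <- if (who == "rich") risk$lambda_rich else risk$lambda_poor
  risk_probability(risk_curve("linear", lam, risk$normalizer), contribution)
}

#' Loss-timing scenario
#'
#' Which rounds of an \eqn{\Omega}-round game can carry a loss event:
#' a potential loss in every round (recurrent events), only in the first
#' round, only in the last round, or in one round drawn uniformly at random
#' per game (an unpredictable event).
#'
#' @param scenario One of `"every_round"`, `"first_round"`, `"last_round"`,
#'   `"random_round"`.
#' @param rounds Number of rounds \eqn{\Omega \ge 1}.
#' @return An object of class `crd_loss_timing`.
#' @export
loss_timing <- function(scenario = c("every_round", "first_round",
                                     "last_round", "random_round"),
                        rounds) {
  scenario <- match.arg(scenario)
  stopifnot(is.numeric(rounds), length(rounds) == 1L, rounds >= 1,
            rounds == round(rounds))
  structure(list(scenario = scenario, rounds = as.integer(rounds)),
            class = "crd_loss_timing")
}

#' Draw the loss-capable rounds of one game
#'
#' Deterministic for the fixed scenarios; for `"random_round"` a single round
#' is drawn uniformly from \eqn{\{1, \ldots, \Omega\}}, independently per
#' game, using the current R random number stream.
#'
#' @param timing A [loss_timing()].
#' @return Integer vector of loss-capable rounds (non-empty).
#' @export
draw_loss_rounds <- function(timing) {
  stopifnot(inherits(timing, "crd_loss_timing"))
  switch(timing$scenario,
    every_round  = seq_len(timing$rounds),
    first_round  = 1L,
    last_round   = timing$rounds,
    random_round = sample.int(timing$rounds, 1L)
  )
}

#' @rdname risk_curve
#' @param object,... For `autoplot()`: a risk curve and ignored arguments.
#' @export
autoplot.crd_risk_curve <- function(object, ...) {
  w0 <- if (is.null(object$normalizer)) 1 else object$normalizer
  curve <- if (is.null(object$normalizer)) {
    risk_curve(object$family, object$lambda, normalizer = 1)
  } else {
    object
  }
  df <- tibble::tibble(
    contribution = seq(0, w0, length.out = 201),
    probability = risk_probability(curve, seq(0, w0, length.out = 201))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$contribution, .data$probability)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cumulative contribution C",
      y = "loss probability p[C]",
      title = sprintf("%s risk curve (lambda = %g)", object$family,
                      object$lambda)
    ) +
    ggplot2::ylim(0, 1)
}
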