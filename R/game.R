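#' Configure a collective-risk game
#'
#' Static parameters of one game: group size \eqn{m}, number of rounds
#' \eqn{\Omega}, per-player initial wealth \eqn{W_{i,0}}, per-player loss
#' fractions \eqn{\alpha_i}, the risk curve(s) mapping the cumulative pot to
#' the per-round loss probability, and the loss-timing scenario. Within each
#' round all players contribute simultaneously (observing only the pot of
#' previous rounds); the loss probability is evaluated at the pot including
#' the current round's contributions; in a loss event a player first commits
#' the contribution and then loses the fraction \eqn{\alpha_i} of what
#' remains: \eqn{W_{i,r} = (1 - \alpha_i)(W_{i,r-1} - c_{i,r})}.
#'
#' @param m Group size (>= 2).
#' @param rounds Number of rounds \eqn{\Omega} (>= 1).
#' @param wealth Initial wealth per player; a scalar is recycled to all `m`
#'   players.
#' @param alpha Loss fraction per player in \[0, 1\]; recycled like `wealth`.
#' @param risk A [risk_curve()] shared by all players, a list of `m` curves
#'   (one per player), or a [hetero_linear_risk()] (then `m` must be 2 and
#'   player 1 is the rich player). Curves without a normalizer get
#'   \eqn{W_0 = \sum_i W_{i,0}}.
#' @param timing A [loss_timing()] or one of its scenario names.
#' @return An object of class `crd_game_config`.
#' @examples
#' cfg <- game_config(m = 2, rounds = 2, wealth = 1, alpha = 1,
#'                    risk = risk_curve("sigmoid", 10))
#' @export
game_config <- function(m, rounds, wealth, alpha = 1,
                        risk = risk_curve("linear", 1),
                        timing = "every_round") {
  stopifnot(m >= 2, m == round(m), rounds >= 1, rounds == round(rounds))
  m <- as.integer(m)
  rounds <- as.integer(rounds)
  wealth <- rep_len(as.numeric(wealth), m)
  alpha <- rep_len(as.numeric(alpha), m)
  if (any(wealth <= 0)) stop("all initial wealths must be > 0", call. = FALSE)
  if (any(alpha < 0 | alpha > 1)) {
    stop("all loss fractions `alpha` must be in [0, 1]", call. = FALSE)
  }
  w0 <- sum(wealth)

  if (inherits(risk, "crd_hetero_risk")) {
    if (m != 2L) stop("hetero_linear_risk requires m = 2", call. = FALSE)
    curves <- list(risk_curve("linear", risk$lambda_rich, risk$normalizer),
                   risk_curve("linear", risk$lambda_poor, risk$normalizer))
  } else if (inherits(risk, "crd_risk_curve")) {
    curves <- rep(list(risk), m)
  } else if (is.list(risk) && length(risk) == m &&
             all(vapply(risk, inherits, logical(1), "crd_risk_curve"))) {
    curves <- risk
  } else {
    stop("`risk` must be a risk_curve, a list of m risk_curves, or a hetero_linear_risk",
         call. = FALSE)
  }
  curves <- lapply(curves, function(cv) {
    if (is.null(cv$normalizer)) risk_curve(cv$family, cv$lambda, w0) else cv
  })

  if (is.character(timing)) timing <- loss_timing(timing, rounds)
  stopifnot(inherits(timing, "crd_loss_timing"))
  if (timing$rounds != rounds) {
    stop("`timing` rounds disagree with the game's `rounds`", call. = FALSE)
  }

  structure(
    list(m = m, rounds = rounds, wealth = wealth, alpha = alpha,
         risk = curves, timing = timing, w0 = w0),
    class = "crd_game_config"
  )
}

#' @export
print.crd_game_config <- function(x, ...) {
  cat(sprintf("<collective-risk game: m = %d, rounds = %d, W0 = %g, timing = %s>\n",
              x$m, x$rounds, x$w0, x$timing$scenario))
  invisible(x)
}

check_strategies <- function(strategies, config) {
  if (!is.list(strategies) || length(strategies) != config$m ||
      !all(vapply(strategies, inherits, logical(1), "crd_strategy"))) {
    stop(sprintf("`strategies` must be a list of %d crd_strategy objects",
                 config$m), call. = FALSE)
  }
  lens <- vapply(strategies, n_rounds, integer(1))
  if (any(lens != config$rounds)) {
    stop(sprintf("strategy length %s does not match rounds = %d",
                 paste(unique(lens), collapse = "/"), config$rounds),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Play one Monte-Carlo realization of a game
#'
#' Runs the game round by round with stochastic loss events and returns the
#' realized payoffs together with a tidy per-round trace.
#'
#' @param strategies List of `m` [strategy()] objects (player order matches
#'   `config$wealth`).
#' @param config A [game_config()].
#' @return A list of class `crd_game_result` with elements `payoffs` (final
#'   wealth per player), `loss_rounds` (the loss-capable rounds of this
#'   game), and `trace`, a tibble with one row per player and round
#'   (`round`, `player`, `contribution`, `pot`, `risk`, `loss`, `wealth`).
#' @examples
#' s1 <- strategy(c(0.0, 0.2), c(0.1, 0.1), c(0.0, 0.5))
#' s2 <- strategy(c(0.1, 0.7), c(0.5, 0.2), c(0.1, 0.5))
#' cfg <- game_config(2, 2, wealth = 1, alpha = 0,
#'                    risk = risk_curve("linear", 1))
#' play_game(list(s1, s2), cfg)$payoffs
#' @export
play_game <- function(strategies, config) {
  check_strategies(strategies, config)
  m <- config$m
  active <- draw_loss_rounds(config$timing)
  wealth <- config$wealth
  pot <- 0
  trace <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    contrib <- vapply(seq_len(m), function(i) {
      decide_contribution(strategies[[i]], r, pot, wealth[i])
    }, numeric(1))
    pot <- pot + sum(contrib)
    wealth <- wealth - contrib
    p <- vapply(seq_len(m), function(i) {
      risk_probability(config$risk[[i]], pot)
    }, numeric(1))
    loss <- rep(FALSE, m)
    if (r %in% active) {
      loss <- stats::runif(m) < p
      wealth <- ifelse(loss, wealth * (1 - config$alpha), wealth)
    }
    trace[[r]] <- tibble::tibble(round = r, player = seq_len(m),
                                 contribution = contrib, pot = pot,
                                 risk = p, loss = loss, wealth = wealth)
  }
  structure(
    list(payoffs = wealth, loss_rounds = active,
         trace = dplyr::bind_rows(trace)),
    class = "crd_game_result"
  )
}

#' @export
print.crd_game_result <- function(x, ...) {
  cat("<game result>\npayoffs:", format(x$payoffs, digits = 4), "\n")
  print(x$trace)
  invisible(x)
}

#' Monte-Carlo payoff replicates of a game
#'
#' Plays `n` independent realizations of the same game, vectorized over
#' replicates, and returns the payoffs in tidy form. This is the sampling
#' counterpart to the exact [expected_payoffs()].
#'
#' @inheritParams play_game
#' @param n Number of replicate games.
#' @return A tibble with columns `game`, `player`, `payoff`.
#' @export
play_games <- function(strategies, config, n) {
  check_strategies(strategies, config)
  stopifnot(n >= 1)
  m <- config$m
  omega <- config$rounds
  W <- matrix(rep(config$wealth, each = n), nrow = n)
  pot <- numeric(n)
  scen <- config$timing$scenario
  rand_round <- if (scen == "random_round") {
    sample.int(omega, n, replace = TRUE)
  }
  for (r in seq_len(omega)) {
    cmat <- matrix(0, n, m)
    for (i in seq_len(m)) {
      s <- strategies[[i]]
      level <- ifelse(pot <= s$tau[r], s$a[r], s$b[r])
      cmat[, i] <- pmin(level, W[, i])
    }
    pot <- pot + rowSums(cmat)
    W <- W - cmat
    capable <- switch(scen,
      every_round  = rep(TRUE, n),
      first_round  = rep(r == 1L, n),
      last_round   = rep(r == omega, n),
      random_round = rand_round == r
    )
    if (any(capable)) {
      for (i in seq_len(m)) {
        p <- risk_probability(config$risk[[i]], pot)
        loss <- capable & (stats::runif(n) < p)
        W[loss, i] <- W[loss, i] * (1 - config$alpha[i])
      }
    }
  }
  tibble::tibble(
    game = rep(seq_len(n), times = m),
    player = rep(seq_len(m), each = n),
    payoff = as.numeric(W)
  )
}

#' Exact expected payoffs by enumeration
#'
#' Enumerates every joint outcome of the independent per-player Bernoulli
#' loss events along the game tree (wealth caps applied on every path) and
#' returns the probability-weighted expected final wealth of each player.
#' For the `"random_round"` scenario the expectation averages the
#' fixed-round expectations with weight \eqn{1/\Omega}. For a two-round game
#' in which caps never bind this reduces to the closed form
#' \eqn{\pi_i = (1 - \alpha_i p_i[C_2])\,((1 - \alpha_i p_i[C_1])(W_{i,0} -
#' c_{i,1}) - c_{i,2})}.
#'
#' @inheritParams play_game
#' @param max_slots Guard on the enumeration size: the number of
#'   loss-capable player-round slots (branching is \eqn{2^{slots}}).
#' @return Numeric vector of expected payoffs, one per player.
#' @export
expected_payoffs <- function(strategies, config, max_slots = 20L) {
  check_strategies(strategies, config)
  if (config$timing$scenario == "random_round") {
    out <- numeric(config$m)
    for (r in seq_len(config$rounds)) {
      out <- out + expected_payoffs_fixed(strategies, config, r, max_slots)
    }
    return(out / config$rounds)
  }
  active <- switch(config$timing$scenario,
    every_round = seq_len(config$rounds),
    first_round = 1L,
    last_round  = config$rounds
  )
  expected_payoffs_active(strategies, config, active, max_slots)
}

expected_payoffs_fixed <- function(strategies, config, r, max_slots) {
  expected_payoffs_active(strategies, config, r, max_slots)
}

expected_payoffs_active <- function(strategies, config, active, max_slots) {
  m <- config$m
  slots <- m * length(active)
  if (slots > max_slots) {
    stop(sprintf(
      "enumeration over %d loss-capable player-round slots (2^%d paths) exceeds max_slots = %d",
      slots, slots, max_slots), call. = FALSE)
  }
  # all 2^m loss patterns of one round, rows = patterns
  patterns <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  dimnames(patterns) <- NULL

  recurse <- function(wealth, pot, r) {
    if (r > config$rounds) return(wealth)
    contrib <- vapply(seq_len(m), function(i) {
      decide_contribution(strategies[[i]], r, pot, wealth[i])
    }, numeric(1))
    pot2 <- pot + sum(contrib)
    w2 <- wealth - contrib
    if (!(r %in% active)) return(recurse(w2, pot2, r + 1L))
    p <- vapply(seq_len(m), function(i) {
      risk_probability(config$risk[[i]], pot2)
    }, numeric(1))
    out <- numeric(m)
    for (k in seq_len(nrow(patterns))) {
      hit <- patterns[k, ]
      prob <- prod(ifelse(hit, p, 1 - p))
      if (prob == 0) next
      w3 <- ifelse(hit, w2 * (1 - config$alpha), w2)
      out <- out + prob * recurse(w3, pot2, r + 1L)
    }
    out
  }
  recurse(config$wealth, 0, 1L)
}
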