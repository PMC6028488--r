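# Shared fixtures: the two printed strategies of the two-player, two-round
# worked example, and random game generators used by the oracle-equivalence
# suites.

worked_example_strategies <- function() {
  list(
    strategy(tau = c(0.0, 0.2), a = c(0.1, 0.1), b = c(0.0, 0.5)),
    strategy(tau = c(0.1, 0.7), a = c(0.5, 0.2), b = c(0.1, 0.5))
  )
}

worked_example_config <- function() {
  # no risk: the loss multiplier never fires because alpha = 0
  game_config(m = 2, rounds = 2, wealth = 1, alpha = 0,
              risk = risk_curve("linear", 1), timing = "every_round")
}

random_game <- function(m = 2, rounds = sample(1:4, 1),
                        timing = sample(c("every_round", "first_round",
                                          "last_round", "random_round"), 1)) {
  fam <- sample(c("linear", "power", "sigmoid"), 1)
  lambda <- switch(fam, linear = runif(1, 0.5, 2), power = runif(1, 0.5, 3),
                   sigmoid = runif(1, 2, 15))
  game_config(m = m, rounds = rounds,
              wealth = runif(m, 0.5, 2),
              alpha = runif(m),
              risk = risk_curve(fam, lambda),
              timing = timing)
}

random_strategies <- function(config) {
  lapply(seq_len(config$m), function(i) {
    random_strategy(config$rounds, config$wealth[i], tau_max = config$w0)
  })
}

# brute-force one-round best response on a fine grid, independent of the
# package's zoomed grid search
brute_best_response <- function(who, c_other, game, n = 10000L) {
  upper <- if (who == "rich") game$w_rich else game$w_poor
  xs <- seq(0, upper, length.out = n + 1L)
  pays <- payoff_one_round(xs, c_other, who, game)
  xs[which.max(pays)]
}
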