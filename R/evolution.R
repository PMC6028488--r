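#' Payoff-to-fitness mapping
#'
#' Payoffs (final wealth, averaged over the games an individual played in a
#' generation) translate into reproductive fitness exponentially:
#' \eqn{f_i = \exp(\pi_i)}.
#'
#' @param pi Numeric payoff(s).
#' @return `exp(pi)`.
#' @export
fitness <- function(pi) {
  stopifnot(is.numeric(pi), all(is.finite(pi)))
  exp(pi)
}

#' Configure an evolutionary run
#'
#' Parameters of the Wright-Fisher dynamics layered on top of a
#' [game_config()]: population size, per-trait mutation probability and
#' threshold noise scale, how many games are played per generation, how many
#' generations to run, and how many initial generations to discard before
#' averaging (burn-in, by default 10% of the generations, discarding the
#' influence of the random initial population).
#'
#' @param game A [game_config()].
#' @param n_pop Population size \eqn{N \ge 2}.
#' @param mu Mutation probability per trait, in \[0, 1\].
#' @param sigma Standard deviation of Gaussian threshold mutations.
#' @param games_per_generation Number of games sampled per generation.
#' @param generations Number of generations to simulate.
#' @param burn_in Generations discarded before averaging
#'   (`< generations`); default `generations %/% 10`.
#' @param seed Optional integer seed; if supplied, [run_evolution()] calls
#'   `set.seed()` so runs are exactly reproducible.
#' @param selection If `FALSE`, fitness is held constant (neutral drift);
#'   a diagnostic mode for checking the mutation kernel's stationary
#'   distribution.
#' @return An object of class `crd_evolution_config`.
#' @export
evolution_config <- function(game, n_pop = 100, mu = 0.03, sigma = 0.15,
                             games_per_generation = 1000,
                             generations = 20000, burn_in = NULL,
                             seed = NULL, selection = TRUE) {
  stopifnot(inherits(game, "crd_game_config"),
            n_pop >= 2, n_pop == round(n_pop),
            mu >= 0, mu <= 1, sigma > 0,
            games_per_generation >= 1, generations >= 1)
  if (is.null(burn_in)) burn_in <- generations %/% 10L
  if (burn_in >= generations) {
    stop("`burn_in` must be smaller than `generations`", call. = FALSE)
  }
  structure(
    list(game = game, n_pop = as.integer(n_pop), mu = mu, sigma = sigma,
         games_per_generation = as.integer(games_per_generation),
         generations = as.integer(generations),
         burn_in = as.integer(burn_in),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         selection = isTRUE(selection)),
    class = "crd_evolution_config"
  )
}

timing_code <- function(timing) {
  match(timing$scenario,
        c("every_round", "first_round", "last_round", "random_round")) - 1L
}

family_code <- function(curve) {
  match(curve$family, c("linear", "power", "sigmoid")) - 1L
}

#' Random initial population
#'
#' An `n` by `3 * rounds` matrix of strategy traits in engine layout
#' (`tau_1, a_1, b_1, tau_2, ...`): thresholds uniform on \[0, `tau_max`\],
#' contribution levels uniform on \[0, `w`\].
#'
#' @param n Population size.
#' @param rounds Rounds per game.
#' @param w Individual initial wealth (contribution bound).
#' @param tau_max Threshold bound, usually the total group wealth.
#' @return A numeric matrix of class `crd_population`.
#' @export
random_population <- function(n, rounds, w, tau_max = w) {
  stopifnot(n >= 1, rounds >= 1, w > 0, tau_max > 0)
  mat <- matrix(0, n, 3L * rounds)
  for (r in seq_len(rounds)) {
    mat[, 3L * r - 2L] <- stats::runif(n, 0, tau_max)
    mat[, 3L * r - 1L] <- stats::runif(n, 0, w)
    mat[, 3L * r] <- stats::runif(n, 0, w)
  }
  class(mat) <- c("crd_population", class(mat))
  mat
}

engine_args_single <- function(cfg) {
  game <- cfg$game
  if (length(unique(game$wealth)) != 1L || length(unique(game$alpha)) != 1L) {
    stop("single-population evolution requires homogeneous wealth and alpha; use run_two_populations() for rich/poor games",
         call. = FALSE)
  }
  fams <- vapply(game$risk, function(cv) cv$family, character(1))
  lams <- vapply(game$risk, function(cv) cv$lambda, numeric(1))
  if (length(unique(fams)) != 1L || length(unique(lams)) != 1L) {
    stop("single-population evolution requires a shared risk curve",
         call. = FALSE)
  }
  list(w0 = game$wealth[1], alpha = game$alpha[1],
       family = family_code(game$risk[[1]]), lambda = lams[1],
       norm = game$risk[[1]]$normalizer)
}

summarize_engine <- function(res, labels, generations, rounds) {
  purrr::imap_dfr(labels, function(lab, p) {
    contrib <- res$contrib[[p]]
    risk <- res$risk[[p]]
    payoff <- res$payoff[[p]]
    tibble::tibble(
      generation = rep(seq_len(generations), times = rounds),
      population = lab,
      round = rep(seq_len(rounds), each = generations),
      mean_contribution = as.numeric(contrib),
      mean_risk = as.numeric(risk),
      mean_payoff = rep(payoff, times = rounds)
    )
  }) |>
    dplyr::arrange(.data$generation, .data$population, .data$round)
}

new_crd_evolution <- function(summary, config, labels, wealth, populations,
                              pi) {
  structure(
    list(summary = summary, config = config, labels = labels,
         wealth = wealth, populations = populations, pi = pi),
    class = "crd_evolution"
  )
}

#' Run the Wright-Fisher evolutionary dynamics
#'
#' Iterates generations of game play, exponential-fitness Wright-Fisher
#' selection and mutation over a single population playing a homogeneous
#' game, and returns per-generation summaries. Fully reproducible from
#' `config$seed`.
#'
#' @param config An [evolution_config()] whose game has identical wealth,
#'   loss fraction and risk curve for all players.
#' @return An object of class `crd_evolution`; see [tidy.crd_evolution()]
#'   and [glance.crd_evolution()] for post-burn-in summaries, and
#'   `$summary` for the per-generation tibble (`generation`, `population`,
#'   `round`, `mean_contribution`, `mean_risk`, `mean_payoff`).
#' @examples
#' \donttest{
#' cfg <- evolution_config(
#'   game_config(2, 1, wealth = 1, alpha = 1, risk = risk_curve("linear", 1)),
#'   generations = 200, games_per_generation = 200, seed = 1
#' )
#' fit <- run_evolution(cfg)
#' glance(fit)
#' }
#' @export
run_evolution <- function(config) {
  stopifnot(inherits(config, "crd_evolution_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  game <- config$game
  ea <- engine_args_single(config)
  pop <- random_population(config$n_pop, game$rounds, ea$w0,
                           tau_max = ea$norm)
  res <- wf_engine_cpp(list(unclass(pop)), ea$w0, ea$alpha, ea$family,
                       ea$lambda, ea$norm, game$m, game$rounds,
                       timing_code(game$timing), config$generations,
                       config$games_per_generation, config$mu, config$sigma,
                       FALSE, config$selection)
  summary <- summarize_engine(res, "all", config$generations, game$rounds)
  new_crd_evolution(summary, config, labels = "all", wealth = ea$w0,
                    populations = res$pops, pi = res$pi)
}

#' Coevolve rich and poor populations
#'
#' Two separate populations of equal size evolve over a shared two-player
#' game: every game pairs one randomly drawn rich individual with one
#' randomly drawn poor individual (player 1 of the game configuration is
#' the rich slot). Selection and mutation act within each population
#' independently, so poor players only ever inherit behavior from other
#' poor players (and vice versa); mutated contribution levels are resampled
#' on each population's own endowment scale.
#'
#' @param cfg_rich,cfg_poor [evolution_config()]s for the two populations.
#'   They must share the same game, population size, mutation parameters,
#'   and generation counts; the game must have `m = 2`, with `wealth[1]`
#'   the rich endowment. Only `cfg_rich$seed` is used.
#' @return A `crd_evolution` with populations labelled `"rich"` and
#'   `"poor"`.
#' @export
run_two_populations <- function(cfg_rich, cfg_poor = cfg_rich) {
  stopifnot(inherits(cfg_rich, "crd_evolution_config"),
            inherits(cfg_poor, "crd_evolution_config"))
  same <- c("n_pop", "mu", "sigma", "games_per_generation", "generations",
            "burn_in")
  for (f in same) {
    if (!identical(cfg_rich[[f]], cfg_poor[[f]])) {
      stop(sprintf("rich and poor configs must agree on `%s`", f),
           call. = FALSE)
    }
  }
  game <- cfg_rich$game
  if (game$m != 2L) {
    stop("two-population games are pairwise: m must be 2", call. = FALSE)
  }
  if (!is.null(cfg_rich$seed)) set.seed(cfg_rich$seed)
  norm <- game$risk[[1]]$normalizer
  pops <- list(
    unclass(random_population(cfg_rich$n_pop, game$rounds, game$wealth[1],
                              tau_max = norm)),
    unclass(random_population(cfg_poor$n_pop, game$rounds, game$wealth[2],
                              tau_max = norm))
  )
  res <- wf_engine_cpp(
    pops, game$wealth, game$alpha,
    vapply(game$risk, family_code, integer(1)),
    vapply(game$risk, function(cv) cv$lambda, numeric(1)),
    norm, game$m, game$rounds, timing_code(game$timing),
    cfg_rich$generations, cfg_rich$games_per_generation,
    cfg_rich$mu, cfg_rich$sigma, TRUE, cfg_rich$selection
  )
  summary <- summarize_engine(res, c("rich", "poor"), cfg_rich$generations,
                              game$rounds)
  new_crd_evolution(summary, cfg_rich, labels = c("rich", "poor"),
                    wealth = game$wealth, populations = res$pops,
                    pi = res$pi)
}

#' One Wright-Fisher generation
#'
#' Plays one generation of games for an explicit population, then applies
#' selection and mutation once. Mainly useful for diagnostics of the
#' selection step itself.
#'
#' @param population A [random_population()]-style matrix
#'   (`n_pop` x `3 * rounds`).
#' @param config An [evolution_config()] (its `n_pop` must match the matrix;
#'   the seed field is ignored here -- seed the session RNG instead).
#' @return A list with `population` (the offspring matrix), `pi` (the mean
#'   payoffs earned by the parent generation), and `parents` (1-based index
#'   of each offspring's parent).
#' @export
generation_step <- function(population, config) {
  stopifnot(inherits(config, "crd_evolution_config"), is.matrix(population))
  game <- config$game
  if (nrow(population) != config$n_pop) {
    stop("population size does not match config$n_pop", call. = FALSE)
  }
  if (game$m > config$n_pop) {
    stop("group size m cannot exceed the population size", call. = FALSE)
  }
  ea <- engine_args_single(config)
  res <- wf_engine_cpp(list(unclass(population)), ea$w0, ea$alpha, ea$family,
                       ea$lambda, ea$norm, game$m, game$rounds,
                       timing_code(game$timing), 1L,
                       config$games_per_generation, config$mu, config$sigma,
                       FALSE, config$selection)
  list(population = res$pops[[1]], pi = res$pi[[1]],
       parents = res$parents[[1]] + 1L)
}

#' @export
print.crd_evolution <- function(x, ...) {
  cat(sprintf("<evolutionary run: %d generation(s), %s population(s)>\n",
              x$config$generations, paste(x$labels, collapse = "/")))
  print(glance(x))
  invisible(x)
}

post_burn_in <- function(x) {
  dplyr::filter(x$summary, .data$generation > x$config$burn_in)
}

#' Tidy post-burn-in summaries of an evolutionary run
#'
#' @param x A `crd_evolution` from [run_evolution()] or
#'   [run_two_populations()].
#' @param ... Unused.
#' @return A tibble with one row per population and round: the long-run
#'   mean contribution (wealth units and as a fraction of the population's
#'   own initial wealth) and the mean loss probability, averaged over
#'   post-burn-in generations.
#' @export
tidy.crd_evolution <- function(x, ...) {
  w <- stats::setNames(x$wealth[seq_along(x$labels)], x$labels)
  post_burn_in(x) |>
    dplyr::group_by(.data$population, .data$round) |>
    dplyr::summarise(
      mean_contribution = mean(.data$mean_contribution),
      mean_risk = mean(.data$mean_risk),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      contribution_fraction = .data$mean_contribution / w[.data$population]
    )
}

#' One-row-per-population overview of an evolutionary run
#'
#' @inheritParams tidy.crd_evolution
#' @return A tibble with, per population, the post-burn-in mean total
#'   contribution (wealth units and fraction of own endowment), mean
#'   payoff, and the run dimensions.
#' @export
glance.crd_evolution <- function(x, ...) {
  w <- stats::setNames(x$wealth[seq_along(x$labels)], x$labels)
  post <- post_burn_in(x)
  per_gen <- post |>
    dplyr::group_by(.data$population, .data$generation) |>
    dplyr::summarise(total = sum(.data$mean_contribution),
                     payoff = .data$mean_payoff[1], .groups = "drop")
  per_gen |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean_total_contribution = mean(.data$total),
                     mean_payoff = mean(.data$payoff), .groups = "drop") |>
    dplyr::mutate(
      total_fraction = .data$mean_total_contribution / w[.data$population],
      generations = x$config$generations,
      burn_in = x$config$burn_in,
      n_pop = x$config$n_pop
    )
}

#' @rdname tidy.crd_evolution
#' @param object A `crd_evolution`.
#' @param window Generations per averaging bin of the plotted trajectories.
#' @export
autoplot.crd_evolution <- function(object, window = NULL, ...) {
  df <- object$summary
  if (is.null(window)) {
    window <- max(1L, object$config$generations %/% 200L)
  }
  df <- df |>
    dplyr::mutate(bin = (.data$generation - 1L) %/% window) |>
    dplyr::group_by(.data$population, .data$round, .data$bin) |>
    dplyr::summarise(generation = mean(.data$generation),
                     mean_contribution = mean(.data$mean_contribution),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation,
                                   .data$mean_contribution,
                                   colour = factor(.data$round))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~population) +
    ggplot2::labs(x = "generation", y = "mean contribution per game",
                  colour = "round")
}
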