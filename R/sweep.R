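#' Specify a parameter sweep of evolutionary runs
#'
#' Describes a grid of evolutionary experiments: a base set of game and
#' evolution arguments, the parameters to sweep (cartesian product), and
#' the replicate seeds. Sweepable parameters are any of the base argument
#' names (`alpha`, `lambda`, `family`, `timing`, `rounds`, `m`, `mu`,
#' `sigma`, ...).
#'
#' @param base Named list of arguments: game parameters (`m`, `rounds`,
#'   `wealth`, `alpha`, `family`, `lambda`, `timing`) and evolution
#'   parameters (`n_pop`, `mu`, `sigma`, `games_per_generation`,
#'   `generations`, `burn_in`).
#' @param sweep Named list mapping parameter names to the vectors of values
#'   to sweep.
#' @param seeds Integer vector of replicate seeds.
#' @param two_populations If `TRUE`, each run coevolves rich and poor
#'   populations (requires `wealth` of length 2, rich first).
#' @return An object of class `crd_sweep_spec`. Its print method reports
#'   the grid size before anything is run.
#' @export
sweep_spec <- function(base, sweep = list(), seeds = 1L,
                       two_populations = FALSE) {
  stopifnot(is.list(base), is.list(sweep), length(seeds) >= 1)
  bad <- setdiff(names(sweep), c(names(base), "alpha_rich", "alpha_poor"))
  if (length(bad)) {
    stop(sprintf("unknown sweep parameter(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  structure(
    list(base = base, sweep = sweep, seeds = as.integer(seeds),
         two_populations = isTRUE(two_populations)),
    class = "crd_sweep_spec"
  )
}

#' @export
print.crd_sweep_spec <- function(x, ...) {
  ncoord <- prod(vapply(x$sweep, length, integer(1)))
  if (length(x$sweep) == 0L) ncoord <- 1L
  cat(sprintf(
    "<sweep: %d coordinate(s) x %d seed(s) = %d run(s); swept: %s>\n",
    ncoord, length(x$seeds), ncoord * length(x$seeds),
    if (length(x$sweep)) paste(names(x$sweep), collapse = ", ") else "none"))
  invisible(x)
}

build_run_config <- function(args, seed = NULL) {
  grab <- function(name, default) {
    if (!is.null(args[[name]])) args[[name]] else default
  }
  risk <- risk_curve(grab("family", "linear"), grab("lambda", 1))
  alpha <- grab("alpha", 1)
  if (!is.null(args$alpha_rich) || !is.null(args$alpha_poor)) {
    alpha <- rep_len(alpha, 2L)
    if (!is.null(args$alpha_rich)) alpha[1] <- args$alpha_rich
    if (!is.null(args$alpha_poor)) alpha[2] <- args$alpha_poor
  }
  game <- game_config(
    m = grab("m", 2), rounds = grab("rounds", 1),
    wealth = grab("wealth", 1), alpha = alpha, risk = risk,
    timing = grab("timing", "every_round")
  )
  evolution_config(
    game, n_pop = grab("n_pop", 100), mu = grab("mu", 0.03),
    sigma = grab("sigma", 0.15),
    games_per_generation = grab("games_per_generation", 1000),
    generations = grab("generations", 20000),
    burn_in = grab("burn_in", NULL), seed = seed
  )
}

sweep_grid <- function(spec) {
  if (length(spec$sweep) == 0L) {
    grid <- tibble::tibble(.coord = 1L)
  } else {
    grid <- tidyr::expand_grid(!!!spec$sweep)
    grid$.coord <- seq_len(nrow(grid))
  }
  grid
}

run_one_coordinate <- function(spec, coord_args, seed) {
  args <- utils::modifyList(spec$base, coord_args)
  cfg <- build_run_config(args, seed = seed)
  fit <- if (spec$two_populations) {
    run_two_populations(cfg)
  } else {
    run_evolution(cfg)
  }
  dplyr::left_join(
    tidy(fit),
    dplyr::select(glance(fit), "population", "mean_total_contribution",
                  "total_fraction", "mean_payoff"),
    by = "population"
  )
}

#' Run a parameter sweep
#'
#' Executes every (coordinate, seed) combination of a [sweep_spec()] and
#' returns one tidy row per population and round of each run. When
#' `out_dir` is given, each coordinate's rows are also written to
#' `coord_<k>.csv` there and coordinates whose file already exists are
#' skipped, so an interrupted sweep resumes where it stopped.
#'
#' @param spec A [sweep_spec()].
#' @param out_dir Optional directory for per-coordinate CSV output.
#' @param quiet Suppress per-coordinate progress messages.
#' @return A tibble: sweep coordinates, `seed`, then the per-round
#'   summaries of [tidy.crd_evolution()] plus the run totals of
#'   [glance.crd_evolution()].
#' @export
run_sweep <- function(spec, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(spec, "crd_sweep_spec"))
  grid <- sweep_grid(spec)
  coord_cols <- setdiff(names(grid), ".coord")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  out <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    file_k <- if (!is.null(out_dir)) {
      file.path(out_dir, sprintf("coord_%03d.csv", grid$.coord[k]))
    }
    if (!is.null(file_k) && file.exists(file_k)) {
      out[[k]] <- readr::read_csv(file_k, show_col_types = FALSE)
      next
    }
    coord_args <- as.list(grid[k, coord_cols, drop = FALSE])
    rows <- purrr::map_dfr(spec$seeds, function(s) {
      dplyr::bind_cols(
        tibble::as_tibble(coord_args[lengths(coord_args) > 0]),
        tibble::tibble(seed = s),
        run_one_coordinate(spec, coord_args, s)
      )
    })
    if (!is.null(file_k)) readr::write_csv(rows, file_k)
    if (!quiet) {
      message(sprintf("sweep coordinate %d/%d done", k, nrow(grid)))
    }
    out[[k]] <- rows
  }
  dplyr::bind_rows(out)
}

#' Aggregate sweep results across seeds
#'
#' @param results Output of [run_sweep()].
#' @return Means and standard errors of the per-round contribution and the
#'   run totals per coordinate, population and round, taken across seeds.
#'   Order of the input rows does not affect the result.
#' @export
summarize_sweep <- function(results) {
  coord_cols <- setdiff(
    names(results),
    c("seed", "population", "round", "mean_contribution", "mean_risk",
      "contribution_fraction", "mean_total_contribution", "total_fraction",
      "mean_payoff")
  )
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(coord_cols, "population", "round")))) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      se_contribution = stats::sd(.data$mean_contribution) /
        sqrt(dplyr::n()),
      mean_contribution = mean(.data$mean_contribution),
      mean_risk = mean(.data$mean_risk),
      se_total = stats::sd(.data$mean_total_contribution) / sqrt(dplyr::n()),
      mean_total_contribution = mean(.data$mean_total_contribution),
      total_fraction = mean(.data$total_fraction),
      mean_payoff = mean(.data$mean_payoff),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(
      c(coord_cols, "population", "round"))))
}
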