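#' One-round heterogeneous linear-risk game
#'
#' The analytically tractable special case: one round, two players with
#' endowments \eqn{W_R \ge W_P}, loss fraction 1, and linear risk curves
#' normalized by the combined endowment \eqn{W = W_R + W_P}. The poor
#' player's risk is \eqn{p_P = 1 - C/W}; the rich player's risk declines
#' faster, \eqn{p_R = 1 - \lambda_R C/W} for \eqn{C < W/\lambda_R} and zero
#' beyond, with \eqn{\lambda_R \ge 1}.
#'
#' @param w_rich,w_poor Endowments with `w_rich >= w_poor > 0`.
#' @param lambda_rich Risk-decline multiplier \eqn{\lambda_R \ge 1} for the
#'   rich player.
#' @return An object of class `crd_hetlin_game`.
#' @examples
#' g <- het_linear_game(w_rich = 4, w_poor = 1, lambda_rich = 2)
#' analytical_ess(g)
#' @export
het_linear_game <- function(w_rich, w_poor, lambda_rich = 1) {
  stopifnot(is.numeric(w_rich), is.numeric(w_poor),
            is.numeric(lambda_rich), length(lambda_rich) == 1L)
  if (w_poor <= 0 || w_rich < w_poor) {
    stop("endowments must satisfy w_rich >= w_poor > 0", call. = FALSE)
  }
  if (lambda_rich < 1) {
    stop("`lambda_rich` must be >= 1", call. = FALSE)
  }
  structure(
    list(w_rich = as.numeric(w_rich), w_poor = as.numeric(w_poor),
         w = as.numeric(w_rich + w_poor),
         lambda_rich = as.numeric(lambda_rich)),
    class = "crd_hetlin_game"
  )
}

#' @export
print.crd_hetlin_game <- function(x, ...) {
  cat(sprintf("<one-round linear game: W_R = %g, W_P = %g, lambda_R = %g>\n",
              x$w_rich, x$w_poor, x$lambda_rich))
  invisible(x)
}

#' One-round payoff under heterogeneous linear risk
#'
#' \eqn{\pi_f = (W_f - c_f)(1 - p_f(C))} with \eqn{C = c_f + c_{other}};
#' the full endowment is at stake (\eqn{\alpha = 1}).
#'
#' @param c_self Focal player's contribution (vectorized), within
#'   \[0, own endowment\].
#' @param c_other Co-player's contribution.
#' @param who `"rich"` or `"poor"`: the focal player's role.
#' @param game A [het_linear_game()].
#' @return Expected payoff(s).
#' @export
payoff_one_round <- function(c_self, c_other, who = c("rich", "poor"), game) {
  stopifnot(inherits(game, "crd_hetlin_game"))
  who <- match.arg(who)
  w_f <- if (who == "rich") game$w_rich else game$w_poor
  if (any(c_self < 0) || any(c_self > w_f + 1e-12)) {
    stop("contribution must lie in [0, own endowment]", call. = FALSE)
  }
  stopifnot(all(c_other >= 0))
  risk <- hetero_linear_risk(game$lambda_rich, game$w)
  p <- heterogeneous_risk(risk, c_self + c_other, who)
  (w_f - c_self) * (1 - p)
}

#' Closed-form best response
#'
#' In the region where the focal player's risk is positive the payoff is a
#' concave quadratic with interior optimum \eqn{c_R = (W_R - c_P)/2} (and
#' symmetrically for the poor). When the rich player's interior optimum
#' falls into the zero-risk region, the cheapest contribution that keeps
#' the risk exactly at zero, \eqn{\max(0, W/\lambda_R - c_P)}, is optimal
#' (any more is wasted). Results are clipped to \[0, own endowment\]; at
#' payoff ties the smaller contribution is returned.
#'
#' @inheritParams payoff_one_round
#' @param c_other Co-player's contribution (scalar).
#' @return The payoff-maximizing contribution.
#' @export
best_response <- function(who = c("rich", "poor"), c_other, game) {
  stopifnot(inherits(game, "crd_hetlin_game"),
            length(c_other) == 1L, c_other >= 0)
  who <- match.arg(who)
  if (who == "poor") {
    # p_P > 0 until C = W, which needs both full endowments: the quadratic
    # branch always applies.
    return(min(max((game$w_poor - c_other) / 2, 0), game$w_poor))
  }
  # payoff in c_R is a concave quadratic up to the zero-risk edge
  # C = W / lambda_R, then linearly decreasing: the maximum is either at the
  # (clipped) quadratic vertex or at the cheapest zero-risk contribution.
  clip <- function(x) min(max(x, 0), game$w_rich)
  cand <- sort(unique(c(clip((game$w_rich - c_other) / 2),
                        clip(game$w / game$lambda_rich - c_other))))
  pays <- payoff_one_round(cand, c_other, "rich", game)
  # smallest contribution among (near-)ties
  cand[which(pays >= max(pays) - 1e-12)][1]
}

new_equilibrium <- function(c_rich, c_poor, case_label, converged = TRUE,
                            iterations = NA_integer_) {
  structure(
    list(c_rich = c_rich, c_poor = c_poor, case_label = case_label,
         converged = converged, iterations = iterations),
    class = "crd_equilibrium"
  )
}

#' @export
print.crd_equilibrium <- function(x, ...) {
  cat(sprintf("<equilibrium [%s]: c_R* = %.6g, c_P* = %.6g%s>\n",
              x$case_label, x$c_rich, x$c_poor,
              if (isTRUE(x$converged)) "" else ", NOT CONVERGED"))
  invisible(x)
}

#' @export
tidy.crd_equilibrium <- function(x, ...) {
  tibble::tibble(c_rich = x$c_rich, c_poor = x$c_poor,
                 total = x$c_rich + x$c_poor,
                 case_label = x$case_label, converged = x$converged)
}

#' Piecewise closed-form evolutionarily stable state
#'
#' Dispatches on the endowment ratio (below or above \eqn{W_R = 2 W_P}) and
#' on the \eqn{\lambda_R} regime to the matching closed-form
#' \eqn{(c_R^*, c_P^*)} pair; adjacent regimes agree at their boundaries,
#' so the equilibrium is continuous in \eqn{\lambda_R}. In the interior
#' regime (\eqn{W_R \le 2 W_P}, \eqn{\lambda_R \le 3}) the total
#' contribution is \eqn{C^* = W/3}. At the overlap \eqn{W_R = 2 W_P} both
#' branches give identical results and the first is used.
#'
#' @param game A [het_linear_game()].
#' @return A `crd_equilibrium` with the contributions and the regime label.
#' @export
analytical_ess <- function(game) {
  stopifnot(inherits(game, "crd_hetlin_game"))
  wr <- game$w_rich
  wp <- game$w_poor
  w <- game$w
  lam <- game$lambda_rich
  if (wr <= 2 * wp) {
    if (lam <= 3) {
      new_equilibrium((2 * wr - wp) / 3, (2 * wp - wr) / 3,
                      "case1_interior")
    } else if (lam <= 2 * w / wp) {
      new_equilibrium(2 * w / lam - wp, wp - w / lam,
                      "case1_zero_risk_mixed")
    } else {
      new_equilibrium(0, wp / 2, "case1_poor_only")
    }
  } else {
    if (lam <= 2 * w / wr) {
      new_equilibrium(wr / 2, 0, "case2_rich_interior")
    } else if (lam <= w / wp) {
      new_equilibrium(w / lam, 0, "case2_rich_zero_risk")
    } else if (lam <= 2 * w / wp) {
      new_equilibrium(2 * w / lam - wp, wp - w / lam,
                      "case2_zero_risk_mixed")
    } else {
      new_equilibrium(0, wp / 2, "case2_poor_only")
    }
  }
}

# zoomed grid search: unimodal payoffs, ties resolved to the smallest
# contribution; resolution upper * (2/(n-1))^refine
grid_argmax <- function(payoff, upper, n = 1001L, refine = 3L) {
  lo <- 0
  hi <- upper
  best <- 0
  for (k in seq_len(refine)) {
    xs <- seq(lo, hi, length.out = n)
    vals <- payoff(xs)
    i <- which.max(vals)
    best <- xs[i]
    step <- (hi - lo) / (n - 1)
    lo <- max(0, best - step)
    hi <- min(upper, best + step)
  }
  best
}

#' Numerical equilibrium by iterated best response
#'
#' Alternates numerically computed best responses (zoomed grid search over
#' each player's contribution range) until the contribution pair moves less
#' than `tol`. Works for any continuous one-round payoff functions, so it
#' serves as an independent check on [analytical_ess()] and extends the
#' equilibrium analysis to arbitrary risk curves.
#'
#' @param game A [het_linear_game()], or `NULL` when explicit payoff
#'   functions are supplied.
#' @param payoff_rich,payoff_poor Functions `(c_self, c_other) -> payoff`,
#'   vectorized in `c_self`. Defaults are built from `game`.
#' @param endowments Length-2 vector `c(rich, poor)` of contribution upper
#'   bounds; taken from `game` when given.
#' @param start Starting pair `c(c_rich, c_poor)`; defaults to half the
#'   endowments.
#' @param tol Convergence tolerance on the max coordinate move.
#' @param max_iter Iteration cap; exceeding it flags non-convergence in the
#'   result rather than raising an error.
#' @return A `crd_equilibrium` (case label `"numerical"`, with `converged`
#'   and `iterations` filled in).
#' @export
iterated_best_response <- function(game = NULL, payoff_rich = NULL,
                                   payoff_poor = NULL, endowments = NULL,
                                   start = NULL, tol = 1e-9,
                                   max_iter = 200L) {
  if (!is.null(game)) {
    stopifnot(inherits(game, "crd_hetlin_game"))
    endowments <- c(game$w_rich, game$w_poor)
    if (is.null(payoff_rich)) {
      payoff_rich <- function(c_self, c_other) {
        payoff_one_round(c_self, c_other, "rich", game)
      }
    }
    if (is.null(payoff_poor)) {
      payoff_poor <- function(c_self, c_other) {
        payoff_one_round(c_self, c_other, "poor", game)
      }
    }
  }
  if (is.null(payoff_rich) || is.null(payoff_poor) || is.null(endowments)) {
    stop("supply either `game` or both payoff functions plus `endowments`",
         call. = FALSE)
  }
  stopifnot(length(endowments) == 2L, all(endowments > 0))
  if (is.null(start)) start <- endowments / 2
  cr <- start[1]
  cp <- start[2]
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    cr_new <- grid_argmax(function(x) payoff_rich(x, cp), endowments[1])
    cp_new <- grid_argmax(function(x) payoff_poor(x, cr_new), endowments[2])
    delta <- max(abs(cr_new - cr), abs(cp_new - cp))
    cr <- cr_new
    cp <- cp_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  new_equilibrium(cr, cp, "numerical", converged = converged,
                  iterations = it)
}

#' Equilibrium table over a parameter sweep
#'
#' Evaluates [analytical_ess()] on the cartesian grid of the supplied
#' endowments and \eqn{\lambda_R} values.
#'
#' @param w_rich,w_poor,lambda_rich Numeric vectors of parameter values.
#' @return A tibble with columns `w_rich`, `w_poor`, `lambda_rich`,
#'   `c_rich`, `c_poor`, `total`, `case_label`.
#' @export
ess_table <- function(w_rich, w_poor, lambda_rich) {
  grid <- tidyr::expand_grid(w_rich = w_rich, w_poor = w_poor,
                             lambda_rich = lambda_rich)
  purrr::pmap_dfr(grid, function(w_rich, w_poor, lambda_rich) {
    eq <- analytical_ess(het_linear_game(w_rich, w_poor, lambda_rich))
    tibble::tibble(w_rich = w_rich, w_poor = w_poor,
                   lambda_rich = lambda_rich,
                   c_rich = eq$c_rich, c_poor = eq$c_poor,
                   total = eq$c_rich + eq$c_poor,
                   case_label = eq$case_label)
  })
}
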