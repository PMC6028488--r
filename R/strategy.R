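#' Threshold contribution strategy
#'
#' A hard-coded strategy for an \eqn{\Omega}-round collective-risk game. In
#' round \eqn{r} the player observes the pot accumulated over the previous
#' rounds, \eqn{C}, and contributes `a[r]` if \eqn{C \le \tau_r} and `b[r]`
#' otherwise (ties play `a[r]`). Contributions are capped by the remaining
#' wealth: players cannot spend more than they have.
#'
#' @param tau Numeric vector of non-negative per-round pot thresholds
#'   (wealth units).
#' @param a Contribution played when the observed pot is at most the
#'   threshold.
#' @param b Contribution played when the pot exceeds the threshold.
#' @return A tibble of class `crd_strategy` with columns `round`, `tau`,
#'   `a`, `b`.
#' @examples
#' # the two-player, two-round strategies of the worked example
#' s1 <- strategy(tau = c(0.0, 0.2), a = c(0.1, 0.1), b = c(0.0, 0.5))
#' decide_contribution(s1, round = 1, pot = 0, wealth = 1)
#' @export
strategy <- function(tau, a, b) {
  stopifnot(is.numeric(tau), is.numeric(a), is.numeric(b),
            length(tau) == length(a), length(a) == length(b),
            length(tau) >= 1L)
  if (any(tau < 0) || any(a < 0) || any(b < 0)) {
    stop("thresholds and contribution levels must be non-negative",
         call. = FALSE)
  }
  out <- tibble::tibble(round = seq_along(tau), tau = as.numeric(tau),
                        a = as.numeric(a), b = as.numeric(b))
  class(out) <- c("crd_strategy", class(out))
  out
}

n_rounds <- function(s) nrow(s)

#' Draw a random strategy
#'
#' Used to seed the evolutionary dynamics: thresholds are uniform on
#' \[0, `tau_max`\] (the scale of the largest attainable pot) and both
#' contribution levels uniform on \[0, `w`\] (the player's own endowment).
#'
#' @param rounds Number of rounds \eqn{\Omega}.
#' @param w The player's initial wealth (upper bound for contributions).
#' @param tau_max Upper bound for thresholds; defaults to `w` and is usually
#'   set to the total initial group wealth.
#' @return A `crd_strategy`.
#' @export
random_strategy <- function(rounds, w, tau_max = w) {
  stopifnot(rounds >= 1, w > 0, tau_max > 0)
  strategy(tau = stats::runif(rounds, 0, tau_max),
           a = stats::runif(rounds, 0, w),
           b = stats::runif(rounds, 0, w))
}

#' Contribution prescribed by a strategy
#'
#' @param s A [strategy()].
#' @param round Round index in `1:rounds`.
#' @param pot Pot accumulated over the rounds played so far (the current
#'   round's simultaneous contributions are not yet visible).
#' @param wealth Remaining wealth of the player; the returned contribution
#'   never exceeds it.
#' @return A single non-negative contribution (wealth units).
#' @export
decide_contribution <- function(s, round, pot, wealth) {
  stopifnot(inherits(s, "crd_strategy"), length(round) == 1L)
  if (round < 1 || round > n_rounds(s)) {
    stop(sprintf("round %s out of range 1..%d", round, n_rounds(s)),
         call. = FALSE)
  }
  stopifnot(pot >= 0, wealth >= 0)
  level <- if (pot <= s$tau[round]) s$a[round] else s$b[round]
  min(level, wealth)
}

#' Mutate a strategy
#'
#' Reproduction errors of the Wright-Fisher dynamics: each of the
#' \eqn{3\Omega} traits mutates independently with probability `mu`. A
#' mutated threshold gets additive Gaussian noise with standard deviation
#' `sigma` (clamped at 0); a mutated contribution level is resampled
#' uniformly on \[0, `w`\].
#'
#' @param s A [strategy()].
#' @param mu Per-trait mutation probability in \[0, 1\].
#' @param sigma Standard deviation of threshold noise (> 0).
#' @param w Upper bound of the uniform contribution resampling (the
#'   individual's initial wealth).
#' @return A new `crd_strategy`; the input is never modified.
#' @export
mutate_strategy <- function(s, mu, sigma, w) {
  stopifnot(inherits(s, "crd_strategy"), mu >= 0, mu <= 1, sigma > 0, w > 0)
  k <- n_rounds(s)
  tau <- s$tau
  a <- s$a
  b <- s$b
  hit <- matrix(stats::runif(3L * k) < mu, nrow = k)
  if (any(hit[, 1L])) {
    i <- which(hit[, 1L])
    tau[i] <- pmax(0, tau[i] + stats::rnorm(length(i), 0, sigma))
  }
  if (any(hit[, 2L])) {
    i <- which(hit[, 2L])
    a[i] <- stats::runif(length(i), 0, w)
  }
  if (any(hit[, 3L])) {
    i <- which(hit[, 3L])
    b[i] <- stats::runif(length(i), 0, w)
  }
  strategy(tau, a, b)
}

# flatten to the engine layout: tau_1, a_1, b_1, tau_2, ...
strategy_to_row <- function(s) {
  as.numeric(t(as.matrix(s[, c("tau", "a", "b")])))
}

row_to_strategy <- function(x) {
  m <- matrix(x, ncol = 3L, byrow = TRUE)
  strategy(m[, 1L], m[, 2L], m[, 3L])
}
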