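test_that("one-round payoffs match the piecewise closed form and the game engine", {
  g <- het_linear_game(4, 1, lambda_rich = 2)
  # no contributions: risk is certain, payoff zero
  expect_equal(payoff_one_round(0, 0, "rich", g), 0)
  expect_equal(payoff_one_round(0, 0, "poor", g), 0)
  # beyond the zero-risk boundary the rich keep everything uninvested
  expect_equal(payoff_one_round(2.5, 0.4, "rich", g), 4 - 2.5)
  # cross-module check: the same game expressed as a one-round GameConfig
  set.seed(43)
  cfg <- game_config(2, 1, wealth = c(4, 1), alpha = 1,
                     risk = hetero_linear_risk(2, normalizer = 5))
  for (k in 1:25) {
    cr <- runif(1, 0, 4)
    cp <- runif(1, 0, 1)
    ss <- list(strategy(0, cr, cr), strategy(0, cp, cp))
    expect_equal(
      expected_payoffs(ss, cfg),
      c(payoff_one_round(cr, cp, "rich", g),
        payoff_one_round(cp, cr, "poor", g)),
      tolerance = 1e-12
    )
  }
})

test_that("closed-form best responses attain the brute-force grid maximum", {
  # the interior formula at lambda_R = 1
  g1 <- het_linear_game(2, 1, 1)
  expect_equal(best_response("rich", 0, g1), g1$w_rich / 2)
  expect_equal(best_response("poor", c_other = 1, g1), 0)
  set.seed(47)
  for (k in 1:40) {
    g <- het_linear_game(w_rich = runif(1, 1, 4), w_poor = 1,
                         lambda_rich = runif(1, 1, 8))
    who <- sample(c("rich", "poor"), 1)
    other_w <- if (who == "rich") g$w_poor else g$w_rich
    c_other <- runif(1, 0, other_w)
    br <- best_response(who, c_other, g)
    brute <- brute_best_response(who, c_other, g)
    # the returned point must do at least as well as the brute-force argmax
    expect_gte(payoff_one_round(br, c_other, who, g) + 1e-10,
               payoff_one_round(brute, c_other, who, g))
    expect_lt(abs(br - brute), 2e-4 * g$w)
  }
})

table1_representatives <- function() {
  # one (w_rich, w_poor, lambda_rich) point per Table-style regime
  list(
    list(g = het_linear_game(1.5, 1, 2), label = "case1_interior"),
    list(g = het_linear_game(1.5, 1, 4), label = "case1_zero_risk_mixed"),
    list(g = het_linear_game(1.5, 1, 10), label = "case1_poor_only"),
    list(g = het_linear_game(4, 1, 2), label = "case2_rich_interior"),
    list(g = het_linear_game(4, 1, 4), label = "case2_rich_zero_risk"),
    list(g = het_linear_game(4, 1, 7), label = "case2_zero_risk_mixed"),
    list(g = het_linear_game(4, 1, 12), label = "case2_poor_only")
  )
}

test_that("analytical regimes match the numerical oracle on every branch", {
  for (rep in table1_representatives()) {
    eq <- analytical_ess(rep$g)
    expect_equal(eq$case_label, rep$label)
    num <- iterated_best_response(rep$g)
    expect_true(num$converged)
    expect_lt(abs(eq$c_rich - num$c_rich), 1e-6 * max(1, rep$g$w_rich))
    expect_lt(abs(eq$c_poor - num$c_poor), 1e-6 * max(1, rep$g$w_poor))
    # equilibrium check: no unilateral improvement on a fine grid
    for (who in c("rich", "poor")) {
      own <- if (who == "rich") eq$c_rich else eq$c_poor
      oth <- if (who == "rich") eq$c_poor else eq$c_rich
      expect_gte(payoff_one_round(own, oth, who, rep$g) + 1e-6,
                 payoff_one_round(brute_best_response(who, oth, rep$g),
                                  oth, who, rep$g))
    }
  }
})

test_that("equal endowments at lambda_R = 1 give the one-third equilibrium", {
  eq <- analytical_ess(het_linear_game(1, 1, 1))
  expect_equal(eq$c_rich, 1 / 3)
  expect_equal(eq$c_poor, 1 / 3)
  num <- iterated_best_response(het_linear_game(1, 1, 1))
  expect_equal(num$c_rich, 1 / 3, tolerance = 1e-6)
  expect_equal(num$c_poor, 1 / 3, tolerance = 1e-6)
})

test_that("worked regime anchors match their closed forms", {
  # rich dominate: c_R* = W_R / 2, c_P* = 0
  eq2 <- analytical_ess(het_linear_game(4, 1, 2))
  expect_equal(eq2$c_rich, 2)
  expect_equal(eq2$c_poor, 0)
  # very fast risk decline for the rich: the poor carry the burden alone
  eq3 <- analytical_ess(het_linear_game(1.5, 1, 10))
  expect_equal(eq3$c_rich, 0)
  expect_equal(eq3$c_poor, 0.5)
  # interior case keeps the total at W / 3
  for (wr in c(1, 1.3, 1.8)) {
    eq <- analytical_ess(het_linear_game(wr, 1, 2))
    expect_equal(eq$c_rich + eq$c_poor, (wr + 1) / 3)
  }
})

test_that("the equilibrium is continuous in lambda_R at every regime boundary", {
  eps <- 1e-9
  for (wr in c(1.2, 1.8, 2, 3, 5)) {
    g <- function(lam) het_linear_game(wr, 1, lam)
    w <- wr + 1
    bounds <- unique(c(3, 2 * w / wr, w / 1, 2 * w / 1))
    bounds <- bounds[bounds >= 1]
    for (b in bounds) {
      lo <- analytical_ess(g(max(1, b - eps)))
      hi <- analytical_ess(g(b + eps))
      expect_lt(abs(lo$c_rich - hi$c_rich), 1e-6)
      expect_lt(abs(lo$c_poor - hi$c_poor), 1e-6)
    }
    # at W_R = 2 W_P both dispatch branches coincide
    if (wr == 2) {
      for (lam in c(1.5, 3, 4.5, 6, 8)) {
        eq <- analytical_ess(g(lam))
        expect_true(startsWith(eq$case_label, "case1"))
      }
    }
  }
})

test_that("rich contributions fall and poor contributions rise in lambda_R", {
  for (wr in c(1.5, 3)) {
    w <- wr + 1
    lams <- seq(1, 2 * w / 1, length.out = 25)
    tab <- ess_table(wr, 1, lams)
    expect_true(all(diff(tab$c_rich) <= 1e-9))
    expect_true(all(diff(tab$c_poor) >= -1e-9))
  }
})

test_that("the numerical solver handles arbitrary risk curves", {
  # sigmoid risk, unequal endowments: fixed point is unilaterally
  # unimprovable on a fine grid
  w <- c(4, 1)
  curve <- risk_curve("sigmoid", 10, normalizer = sum(w))
  pay <- function(c_self, c_other, wf) {
    (wf - c_self) * (1 - risk_probability(curve, c_self + c_other))
  }
  eq <- iterated_best_response(
    payoff_rich = function(cs, co) pay(cs, co, w[1]),
    payoff_poor = function(cs, co) pay(cs, co, w[2]),
    endowments = w
  )
  expect_true(eq$converged)
  for (i in 1:2) {
    own <- c(eq$c_rich, eq$c_poor)[i]
    oth <- c(eq$c_poor, eq$c_rich)[i]
    grid <- seq(0, w[i], length.out = 1001)
    expect_gte(pay(own, oth, w[i]) + 1e-6, max(pay(grid, oth, w[i])))
  }
})

test_that("non-convergence is reported, not raised", {
  # matching-pennies payoffs: one player matches, the other mismatches,
  # so alternating best responses cycle forever
  eq <- iterated_best_response(
    payoff_rich = function(cs, co) -abs(cs - co),
    payoff_poor = function(cs, co) abs(cs - co),
    endowments = c(1, 1), max_iter = 10
  )
  expect_false(eq$converged)
  expect_equal(eq$iterations, 10L)
})
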