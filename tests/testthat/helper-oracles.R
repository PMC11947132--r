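# Independent oracles used to cross-check the implementation. None of these
# call the package's solvers.

# Root of the 1-d tilting gradient g(b) = sum(x * exp(b * x)) by bisection.
bisect_tilting_1d <- function(x_centered, lower = -50, upper = 50,
                              tol = 1e-12) {
  g <- function(b) sum(x_centered * exp(b * x_centered))
  stats::uniroot(g, c(lower, upper), tol = tol)$root
}

# 2-d minimizer of Q(b) = sum(exp(X b)) by iterated dense grid refinement.
grid_tilting_2d <- function(X, half_width = 5, rounds = 8, pts = 41) {
  center <- c(0, 0)
  for (r in seq_len(rounds)) {
    b1 <- seq(center[1] - half_width, center[1] + half_width, length.out = pts)
    b2 <- seq(center[2] - half_width, center[2] + half_width, length.out = pts)
    grid <- expand.grid(b1 = b1, b2 = b2)
    q <- apply(grid, 1L, function(b) sum(exp(X %*% b)))
    center <- as.numeric(grid[which.min(q), ])
    half_width <- half_width * 2 / (pts - 1) * 2  # keep a margin around best
  }
  center
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration: sum P(table) over all tables with the observed margins whose
# probability is at most the observed table's (with a tiny tolerance for
# floating ties, as the classical rule requires).
fisher_2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Simulate a two-trial joint dataset and return both the per-trial contrasts
# and the direct active-vs-active contrast from a joint fixed-effect model
# (trial main effect plus a per-trial treatment dummy).
joint_model_contrast <- function(y, trial, treat) {
  d <- data.frame(y = y, trial = factor(trial),
                  t1 = as.integer(trial == levels(factor(trial))[1] & treat == 1),
                  t2 = as.integer(trial == levels(factor(trial))[2] & treat == 1))
  fit <- stats::lm(y ~ trial + t1 + t2, data = d)
  unname(stats::coef(fit)["t1"] - stats::coef(fit)["t2"])
}

# small fast scenario for property tests
tiny_scenario <- function(...) {
  args <- utils::modifyList(list(n_active = 60L, n_anchor = 60L,
                                 n_centers = 3L), list(...))
  do.call(trial_scenario, args)
}
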