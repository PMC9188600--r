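# Group statistics: normality screening, Mann-Whitney with enumeration
# oracle, effect sizes, and summary-level t / ANOVA reconstruction.

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
mw_enum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("Anderson-Darling screening is calibrated and detects skew", {
  set.seed(101)
  rej_norm <- mean(replicate(200, {
    anderson_darling_normal(rnorm(200))$reject_5pct
  }))
  expect_lte(rej_norm, 0.10)
  rej_exp <- mean(replicate(50, {
    anderson_darling_normal(rexp(200))$reject_5pct
  }))
  expect_gte(rej_exp, 0.99)
  # location-scale invariance of the statistic
  set.seed(5)
  x <- rnorm(60)
  expect_equal(anderson_darling_normal(x)$a2,
               anderson_darling_normal(5 - 3 * x)$a2, tolerance = 1e-12)
  expect_error(anderson_darling_normal(rep(1, 20)),
               class = "phonemark_degenerate_sample")
  expect_error(anderson_darling_normal(rnorm(5)),
               class = "phonemark_invalid_argument")
})

test_that("Mann-Whitney exact branch equals full enumeration", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$u, 0)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p_value, 0.100)
  set.seed(202)
  for (i in 1:60) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- rnorm(nx); y <- rnorm(ny, sample(c(0, 1), 1))
    res <- mann_whitney_u(x, y)
    expect_equal(res$p_value, mw_enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("tied and large samples take a sane approximation branch", {
  x <- c(1.5, 2.5, 3.5)
  expect_equal(mann_whitney_u(x, x)$p_value, 1)
  set.seed(9)
  a <- rnorm(30); b <- rnorm(30, 2)
  expect_lt(mann_whitney_u(a, b)$p_value, 1e-4)
  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "phonemark_invalid_argument")
})

test_that("Glass's delta uses the control SD and its sign convention", {
  expect_equal(glass_delta_from_summary(1, 2, 1), 0)
  expect_equal(glass_delta_from_summary(0, 1.5, 3), -2)
  set.seed(3)
  co <- rnorm(40, 10, 2); pd <- rnorm(40, 13, 4)
  d <- glass_delta(co, pd)
  expect_equal(d, (mean(co) - mean(pd)) / sd(co))
  expect_lt(d, 0)  # impaired group higher => negative
  expect_error(glass_delta_from_summary(1, 0, 2),
               class = "phonemark_invalid_argument")
})

test_that("summary-level t-test matches a raw-data pooled t-test", {
  set.seed(44)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), 2); y <- rnorm(sample(5:40, 1), 2.4, 1.6)
    ours <- ttest_from_summary(mean(x), sd(x), length(x),
                               mean(y), sd(y), length(y))
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
  same <- ttest_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0); expect_equal(same$p_value, 1)
  expect_error(ttest_from_summary(1, 0, 10, 1, 0, 10),
               class = "phonemark_invalid_argument")
})

test_that("summary-level ANOVA reduces to t-test for two groups", {
  a <- anova_from_summary(list(c(1, 2, 12), c(3, 2.5, 14)))
  t <- ttest_from_summary(1, 2, 12, 3, 2.5, 14)
  expect_equal(a$f, t$t^2, tolerance = 1e-12)
  expect_equal(a$p_value, t$p_value, tolerance = 1e-12)

  eq <- anova_from_summary(list(c(2, 1, 8), c(2, 1.5, 9), c(2, 2, 10)))
  expect_equal(eq$f, 0); expect_equal(eq$p_value, 1)
})

test_that("summary-level ANOVA matches aov on reconstructed raw data", {
  # construct raw groups with exactly the stated moments
  mk <- function(m, s, n) { z <- scale(rnorm(n)); as.numeric(m + s * z) }
  set.seed(77)
  gs <- list(c(0, 1, 10), c(0.5, 1, 10), c(1, 1, 10))
  raw <- lapply(gs, function(g) mk(g[1], g[2], g[3]))
  dat <- data.frame(y = unlist(raw),
                    g = factor(rep(seq_along(raw), times = vapply(raw, length,
                                                                  1L))))
  ref <- summary(aov(y ~ g, dat))[[1]]
  ours <- anova_from_summary(gs)
  expect_equal(ours$f, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(ours$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
  expect_equal(ours$f, 2.5, tolerance = 1e-12)
})

test_that("the per-feature group table reports directions and decisions", {
  set.seed(12)
  n <- 20
  tab <- data.frame(subject_id = sprintf("s%02d", 1:(2 * n)),
                    group = rep(c("CO", "PD"), each = n),
                    phoneme = "a", repetition = 1L,
                    jit = c(rnorm(n, 0.005, 0.001), rnorm(n, 0.009, 0.002)),
                    flat = rnorm(2 * n))
  out <- group_stats_table(tab)
  jit_row <- out[out$feature == "jit", ]
  expect_lt(jit_row$p_value, 0.01)
  expect_lt(jit_row$effect_size, -1)
  flat_row <- out[out$feature == "flat", ]
  expect_gt(flat_row$p_value, 0.05)
  out2 <- group_stats_table(tab, p_adjust = "holm")
  expect_true("p_adjusted" %in% names(out2))
  expect_gte(out2$p_adjusted[1], out2$p_value[1])
})
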