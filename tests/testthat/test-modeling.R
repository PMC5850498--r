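test_that("perfect linear fits behave as expected", {
  d <- data.frame(y = c(1, 2, 3), x = c(1, 2, 3))
  m <- suppressWarnings(fit_ols(d, "y", "x"))  # perfect-fit F warning
  expect_equal(m$r_squared, 1)
  expect_equal(m$anova$df_resid, 1L)
  expect_equal(unname(m$coefficients["x"]), 1)
})

test_that("fit_ols agrees with a pseudoinverse of the normal equations", {
  set.seed(77)
  for (i in 1:5) {
    n <- 40
    d <- data.frame(y = rnorm(n), a = rnorm(n), b = rnorm(n),
                    f = factor(sample(letters[1:4], n, replace = TRUE)))
    m <- fit_ols(d, "y", c("a", "b", "f"))
    X <- model.matrix(~ a + b + f, d)
    beta <- solve(crossprod(X), crossprod(X, d$y))
    expect_equal(unname(m$coefficients), unname(drop(beta)),
                 tolerance = 1e-8)
    rss <- sum((d$y - X %*% beta)^2)
    tss <- sum((d$y - mean(d$y))^2)
    expect_equal(m$r_squared, 1 - rss / tss, tolerance = 1e-8)
    # sequential SS are non-negative and sum (with residual) to total SS
    an <- anova(m$fit)
    expect_true(all(an$`Sum Sq` >= -1e-10))
    expect_equal(sum(an$`Sum Sq`), tss, tolerance = 1e-8)
  }
})

test_that("observation order does not change any output", {
  set.seed(78)
  d <- data.frame(y = rpois(30, 3), a = rnorm(30),
                  f = factor(sample(c("u", "v", "w"), 30, replace = TRUE)))
  m1 <- fit_ols(d, "y", c("a", "f"))
  m2 <- fit_ols(d[sample(30), ], "y", c("a", "f"))
  expect_equal(m1$anova, m2$anova, tolerance = 1e-10)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 1e-10)
})

test_that("single-factor F equals squared slope t, and leads a sequence", {
  set.seed(79)
  y <- rnorm(25); x <- rnorm(25)
  s <- single_factor_test(y, x)
  sm <- summary(lm(y ~ x))
  expect_equal(s$F, sm$coefficients["x", "t value"]^2, tolerance = 1e-10)
  expect_equal(s$p, sm$coefficients["x", "Pr(>|t|)"], tolerance = 1e-10)
  expect_equal(s$df_resid, 23L)
  expect_error(single_factor_test(y, rep(1, 25)), "constant")

  # with an orthogonal second predictor, the first term's sequential sum
  # of squares equals its sum of squares when fitted alone
  x2 <- residuals(lm(rnorm(25) ~ x))  # orthogonal to x by construction
  m <- fit_ols(data.frame(y = y, x = x, x2 = x2), "y", c("x", "x2"))
  ss_alone <- anova(lm(y ~ x))["x", "Sum Sq"]
  expect_equal(anova(m$fit)["x", "Sum Sq"], ss_alone, tolerance = 1e-8)
  # and sequential ANOVA of the single-term model reproduces the test
  m1 <- fit_ols(data.frame(y = y, x = x), "y", "x")
  expect_equal(m1$anova$F, s$F, tolerance = 1e-10)
  expect_equal(m1$anova$p, s$p, tolerance = 1e-10)
})

test_that("rank-deficient designs raise an error naming aliased terms", {
  d <- data.frame(y = rnorm(10), a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(d, "y", c("a", "b")), "alias")
})

test_that("degrees of freedom match the published bookkeeping", {
  # 58 lineages in 14 families sized as the study's gene families
  lin <- c4coopt:::sim_lineages(sim_config())
  set.seed(80)
  d <- data.frame(n_cooptions = rpois(58, 2),
                  ala = rlnorm(58, 3, 1), leaf_root = rlnorm(58, 0, 1),
                  family = factor(lin$family_id))
  s <- single_factor_test(d$n_cooptions, d$ala)
  expect_equal(s$df_resid, 56L)
  m <- fit_ols(d, "n_cooptions", c("ala", "leaf_root", "family"))
  expect_equal(m$anova$df_term, c(1L, 1L, 13L))
  expect_equal(unique(m$anova$df_resid), 42L)
})

test_that("threshold sweep produces one block per usable threshold", {
  sim <- simulate_dataset(sim_config(), seed = 25)
  expr <- build_expression_matrix(sim$counts, sim$lineages,
                                  sim$libraries, sim$totals)
  meta <- species_metadata(sim$libraries)
  sw <- threshold_sensitivity(expr, meta, sim$lineages, sim$tree)
  expect_setequal(unique(sw$table$threshold), c(300, 500, 1000, 1500))
  for (T in c(300, 500, 1000, 1500)) {
    blk <- sw$table[sw$table$threshold == T, ]
    expect_equal(blk$term, c("ala", "leaf_root", "family"))
  }
  # an absurd threshold yields a degenerate block, not a fit
  sw9 <- threshold_sensitivity(expr, meta, sim$lineages, sim$tree,
                               thresholds = c(500, 1e9))
  expect_true(1e9 %in% sw9$degenerate)
  expect_false("1e+09" %in% names(sw9$fits))
})

test_that("the Poisson option fits a log-link count model", {
  set.seed(81)
  d <- data.frame(y = rpois(40, 3), x = rnorm(40))
  m <- fit_ols(d, "y", "x", family = "poisson")
  expect_s3_class(m$fit, "glm")
  expect_equal(m$anova$term, "x")
  expect_true(is.na(m$r_squared))
})
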