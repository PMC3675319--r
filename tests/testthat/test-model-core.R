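# Independent per-equation oracle: each governing equation transcribed
# term by term, kept deliberately separate from the package right-hand
# side so the two can disagree.
oracle_rhs <- function(y, p, tim2 = TRUE, media_ref = 0,
                       ferritin_media = FALSE) {
  x1 <- y[["x1"]]; x2 <- y[["x2"]]; x3 <- y[["x3"]]; x4 <- y[["x4"]]
  x5 <- y[["x5"]]; x6 <- y[["x6"]]; x7 <- y[["x7"]]; x8 <- y[["x8"]]
  x9 <- y[["x9"]]; M <- y[["media_unbound"]]
  frac <- if (ferritin_media && media_ref > 0) min(1, M / media_ref) else 0
  bind <- if (tim2) p$alpha7_Ftex * x6 * frac else 0
  f <- p$gamma7 * x7 * p$K47 / (p$K47 + (x4 + x9))
  d <- c(
    x1 = p$alpha1_Feex_x2 * M + p$gamma4 * x4 -
      p$alpha6_x3_eff * x1 -
      p$alpha4_storage * x1 * p$k54 / (p$k54 + x5) +
      p$alpha10 * f + p$alpha11 * p$gamma9 * x9,
    x2 = if (p$frozen_core) 0 else
      p$alpha2 * x5 / (p$k52 + x5) - p$gamma2 * x2,
    x3 = if (p$frozen_core) 0 else
      p$alpha3 * p$k53 / (p$k53 + x5) - (p$gamma3 + p$gammah_Hep) * x3,
    x4 = p$alpha4_storage * x1 * p$k54 / (p$k54 + x5) - p$gamma4 * x4,
    x5 = if (p$frozen_core) 0 else
      p$alpha5 * p$k15 / (p$k15 + x1) - p$gamma5 * x5,
    x6 = if (tim2) p$gamma6 * x8 - bind else 0,
    x7 = if (tim2) bind - f else 0,
    x8 = if (tim2) f - p$gamma6 * x8 else 0,
    x9 = p$alpha9 * f - p$gamma9 * x9,
    media_unbound = -bind - p$alpha1_Feex_x2 * M,
    media_exported = p$alpha6_x3_eff * x1
  )
  d
}

test_that("Hill promotion and inhibition obey their limits and half-rates", {
  expect_equal(hill_promote(1, 0.5, 1), 0.25)            # alpha/2 at x = k
  expect_equal(hill_promote(3.7, 0.9, 3.7), 0.45)
  expect_equal(hill_inhibit(0, 0.5, 1), 0.5)             # unsuppressed limit
  # endocytosis rate halved at the saturation threshold
  expect_equal(hill_inhibit(0.11, 0.118, 0.11), 0.059)
  for (i in 1:25) {
    set.seed(i)
    x <- runif(1, 0, 10); a <- runif(1, 0, 2); k <- runif(1, 0.01, 5)
    expect_gte(hill_promote(x, a, k), 0)
    expect_lte(hill_promote(x, a, k), a)
    expect_gte(hill_inhibit(x, a, k), 0)
    expect_lte(hill_inhibit(x, a, k), a)
    # the two forms partition the maximum rate
    expect_equal(hill_promote(x, a, k) + hill_inhibit(x, a, k), a)
  }
  expect_error(hill_inhibit(1, 0.5, 0), "threshold")
  expect_error(hill_promote(1, -0.5, 1), "alpha")
  expect_error(hill_promote(-1, 0.5, 1), "x must be")
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(model_parameters(gamma7 = -1), "non-negative")
  expect_error(model_parameters(K47 = 0), "> 0")
  expect_error(model_parameters(alpha9 = 1.2), "\\[0, 1\\]")
  expect_error(model_parameters(alpha10 = -0.1), "\\[0, 1\\]")
  p <- model_parameters(alpha9 = 0.3)
  expect_equal(p$alpha10, 0.7)    # conservation default
  expect_equal(p$alpha11, 1)
})

test_that("right-hand side matches the per-equation oracle", {
  for (i in 1:10) {
    set.seed(100 + i)
    y <- random_state()
    p <- model_parameters(frozen_core = i %% 2 == 0)
    tim2 <- i %% 3 != 0
    ferr <- i %% 2 == 1
    got <- iron_rhs(0, y, p, tim2_present = tim2, media_ref = 50,
                    ferritin_media = ferr)[[1]]
    want <- oracle_rhs(y, p, tim2 = tim2, media_ref = 50,
                       ferritin_media = ferr)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("surviving exogenous HFt decays at gamma9 and feeds the LIP", {
  p <- table1_parameters()
  y <- state_vector(x9 = 1)
  d <- iron_rhs(0, y, p)[[1]]
  expect_equal(d[["x9"]], -0.00031)
  expect_equal(d[["x1"]], 0.00031 * p$alpha11)
})

test_that("with no free receptor the binding term vanishes", {
  p <- table1_parameters()
  y <- state_vector(x8 = 2, media_unbound = 50)
  d <- iron_rhs(0, y, p, media_ref = 50, ferritin_media = TRUE)[[1]]
  expect_equal(d[["x6"]], p$gamma6 * 2)
  expect_equal(d[["x7"]], 0)
})

test_that("state domain errors are caught", {
  p <- table1_parameters()
  y <- state_vector(); y[["x1"]] <- -1
  expect_error(iron_rhs(0, y, p), "negative pool")
  expect_error(state_vector(x1 = -2), "negative pool")
})

test_that("zero-label equilibrium has empty labelled pools and zero residual", {
  for (frozen in c(TRUE, FALSE)) {
    p <- model_parameters(frozen_core = frozen)
    y <- equilibrate(p)
    expect_equal(unname(y[c("x1", "x4", "x7", "x9", "media_unbound",
                            "media_exported")]), rep(0, 6))
    expect_equal(y[["x6"]], p$x6_total)
    resid <- iron_rhs(0, y, p)[[1]]
    expect_lt(max(abs(resid)), 1e-9)
  }
  yv <- equilibrate(table1_parameters(), cell_line = "vector")
  expect_equal(yv[["x6"]], 0)
})

test_that("a cell preload splits 80/20 between ferritin and LIP", {
  # storage/release balance alpha4_eff : gamma4 is 4:1 in the packaged set
  y <- equilibrate(table1_parameters(), preload_cell = 10.8)
  expect_equal(y[["x4"]], 0.8 * 10.8, tolerance = 1e-12)
  expect_equal(y[["x1"]], 0.2 * 10.8, tolerance = 1e-12)
  expect_equal(y[["x4"]] + y[["x1"]], 10.8)
})

test_that("compiled and reference integrations agree", {
  p <- table1_parameters()
  pr <- build_protocol("storage", "tim2")
  a <- simulate_protocol(pr, p, compiled = TRUE)
  b <- simulate_protocol(pr, p, compiled = FALSE)
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-6)
})
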