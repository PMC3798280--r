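test_that("PET emission is uniform on the covering set", {
  expect_equal(pet_log_emission(100, 149, 120), log(1 / 50))
  expect_equal(pet_log_emission(100, 149, 149), log(1 / 50))  # boundary
  expect_equal(pet_log_emission(100, 149, 150), -Inf)
  # vectorized over fragments
  expect_equal(pet_log_emission(c(100, 200), c(149, 249), 210),
               c(-Inf, log(1 / 50)))
})

test_that("background emission is flat and strand-halved for SET", {
  region <- test_region(0L, 400L)
  expect_equal(background_log_emission(region, "pet"), log(1 / 400))
  expect_equal(background_log_emission(region, "set"),
               log(1 / 400) + log(0.5))
  expect_error(background_log_emission(test_region(10L, 10L), "pet"),
               "width")
})

test_that("SET emission has mirror symmetry and Normal scaling", {
  mu <- 5000; delta <- 75; sigma <- 30
  peak <- set_log_emission(mu - delta, "+", mu, delta, sigma, q = 0.5)
  expect_equal(peak, log(0.5) + log(1 / (sigma * sqrt(2 * pi))))
  for (k in c(-40, -5, 0, 12, 33)) {
    expect_equal(set_log_emission(mu - delta + k, "+", mu, delta, sigma),
                 set_log_emission(mu + delta - k, "-", mu, delta, sigma))
  }
  expect_equal(set_log_emission(mu - delta, "+", mu, delta, 30) -
                 set_log_emission(mu - delta, "+", mu, delta, 60),
               log(2))
  expect_error(set_log_emission(0, "+", 0, 75, -1), "sigma")
})

test_that("bic matches its closed form", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-100, 3, 1), 200)
  expect_equal(bic(-100, 2, exp(2)), 204)
})

test_that("initialization is deterministic and finds modes", {
  region <- test_region(500L, 2500L)
  set.seed(1)
  left <- c(sample(900:1000, 40, replace = TRUE),
            sample(1900:2000, 40, replace = TRUE))
  frag <- data.frame(chrom = "chrT", left = left, right = left + 99L,
                     length = 100L)
  # quantile strategy: G=1 -> median of midpoints
  i1 <- init_params(frag, region, 1, "pet", strategy = "quantile")
  expect_equal(i1$mu, median((frag$left + frag$right) / 2))
  # balanced bimodal midpoints -> one start near each mode
  i2 <- init_params(frag, region, 2, "pet", strategy = "quantile")
  expect_lt(abs(i2$mu[1] - 1000), 60)
  expect_lt(abs(i2$mu[2] - 2000), 60)
  i2c <- init_params(frag, region, 2, "pet", strategy = "coverage")
  expect_lt(abs(i2c$mu[1] - 1000), 60)
  expect_lt(abs(i2c$mu[2] - 2000), 60)
  # determinism
  expect_identical(init_params(frag, region, 2, "pet"),
                   init_params(frag, region, 2, "pet"))
  expect_equal(i2$weights, c(0.4, 0.4, 0.2))
  expect_error(init_params(frag[1:2, ], region, 2, "pet"), "insufficient")
})

test_that("a lone PET event lands at the centre of the covering tie run", {
  region <- test_region(50L, 250L, id = "toy")
  fit <- em_fit(toy_fragments(), region, G = 1, mode = "pet")
  expect_equal(fit$params$mu, 135)   # all mu in [120,150] tie; centre wins
  expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-10))
})

test_that("EM log-likelihood is monotone and responsibilities normalized", {
  region <- test_region()
  for (s in 1:5) {
    spec <- simulation_spec(region, c(9900, 10050), 150, n_background = 15)
    ds <- derive_set(simulate_pet(spec, seed = s), seed = s)
    for (mode in c("pet", "set")) {
      obs <- if (mode == "pet") ds$fragments else ds$tags
      for (G in 1:3) {
        fit <- em_fit(obs, region, G, mode)
        expect_true(all(diff(fit$loglik_trace) >= -1e-9),
                    label = paste("monotone trace", mode, "G", G, "seed", s))
        expect_true(all(abs(rowSums(fit$responsibilities) - 1) < 1e-10))
        expect_equal(fit$bic,
                     -2 * fit$loglik +
                       (if (mode == "pet") 2 * G else 2 * G + 3) *
                       log(fit$n_obs))
      }
    }
  }
})

test_that("EM beats a fixed-weight exhaustive grid search", {
  region <- test_region(9900L, 10100L)
  for (s in 1:3) {
    spec <- simulation_spec(region, c(9960, 10040), 12, n_background = 4,
                            length_dist = default_length_dist(100, 15, 60, 150))
    ds <- derive_set(simulate_pet(spec, seed = s), seed = s)
    for (G in 1:2) {
      pet <- em_fit(ds$fragments, region, G, "pet")
      oracle <- grid_search_loglik(ds$fragments, region,
                                   pet$params$weights, "pet")
      expect_gte(pet$loglik, oracle - 1e-6)
      p <- em_fit(ds$tags, region, G, "set")
      oracle_s <- grid_search_loglik(ds$tags, region, p$params$weights,
                                     "set", delta = p$params$delta,
                                     sigma = p$params$sigma, q = p$params$q)
      expect_gte(p$loglik, oracle_s - 1e-6)
    }
  }
})

test_that("fits are equivariant under coordinate translation", {
  region <- test_region()
  spec <- simulation_spec(region, c(9900, 10050), 120, n_background = 12)
  ds <- derive_set(simulate_pet(spec, seed = 11), seed = 11)
  shift <- 12345L
  region2 <- test_region(region$start + shift, region$end + shift)
  fr2 <- ds$fragments
  fr2$left <- fr2$left + shift; fr2$right <- fr2$right + shift
  tg2 <- ds$tags
  tg2$pos5 <- tg2$pos5 + shift
  a <- em_fit(ds$fragments, region, 2, "pet")
  b <- em_fit(fr2, region2, 2, "pet")
  expect_equal(b$params$mu, a$params$mu + shift)
  expect_equal(b$params$weights, a$params$weights, tolerance = 1e-8)
  expect_equal(b$loglik, a$loglik, tolerance = 1e-8)
  as <- em_fit(ds$tags, region, 2, "set")
  bs <- em_fit(tg2, region2, 2, "set")
  expect_equal(bs$params$mu, as$params$mu + shift, tolerance = 1e-6)
  expect_equal(bs$params$delta, as$params$delta, tolerance = 1e-8)
  expect_equal(bs$params$sigma, as$params$sigma, tolerance = 1e-8)
  expect_equal(bs$loglik, as$loglik, tolerance = 1e-7)
})

test_that("SET fit recovers position, shift and spread", {
  hits <- 0L
  for (s in 1:100) {
    tags <- sim_set_tags(200, mu = 5000, delta = 75, sigma = 30, seed = s)
    fit <- em_fit(tags, test_region(4600L, 5400L), 1, "set")
    if (abs(fit$params$mu - 5000) <= 5 && abs(fit$params$delta - 75) <= 5) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 95L)
})

test_that("PET position error shrinks with depth", {
  region <- test_region()
  rmse <- vapply(c(25, 100, 300), function(n) {
    err <- vapply(1:30, function(s) {
      spec <- simulation_spec(region, 10000, n, n_background = round(n / 10))
      ds <- simulate_pet(spec, seed = s + n)
      em_fit(ds$fragments, region, 1, "pet")$params$mu - 10000
    }, 0)
    sqrt(mean(err^2))
  }, 0)
  expect_true(rmse[1] > rmse[2] && rmse[2] >= rmse[3])
})

test_that("model selection honours G_max, degeneracy and ordering", {
  region <- test_region()
  spec <- simulation_spec(region, c(9900, 10050), 300, n_background = 30)
  ds <- simulate_pet(spec, seed = 5)
  sel <- select_model(ds$fragments, region, "pet", G_max = 1)
  expect_equal(sel$params$G, 1L)    # only candidate
  sel5 <- select_model(ds$fragments, region, "pet", G_max = 5)
  expect_equal(sel5$params$G, 2L)
  expect_equal(sel5$params$mu, sort(sel5$params$mu))
  expect_error(em_fit(ds$fragments[1:2, ], region, G = 5, mode = "pet"),
               "insufficient reads")

  # pure background: event components collapse, background dominates
  set.seed(9)
  left <- region$start + floor(runif(200) * (region$end - region$start))
  bg <- data.frame(chrom = "chrT", left = left, right = left + 149L,
                   length = 150L)
  fitbg <- suppressWarnings(select_model(bg, region, "pet", G_max = 1))
  expect_gt(fitbg$params$weights[2], 0.8)
})

test_that("event tables carry strength = weight x reads", {
  region <- test_region()
  spec <- simulation_spec(region, c(9900, 10050), 100, n_background = 10)
  ds <- simulate_pet(spec, seed = 2)
  sel <- select_model(ds$fragments, region, "pet", G_max = 3)
  ev <- events_from_fit(sel, region)
  expect_equal(nrow(ev), sel$params$G)
  expect_equal(ev$strength,
               sel$params$weights[seq_len(sel$params$G)] * sel$n_obs)
  expect_equal(ev$region_id, rep(region$region_id, nrow(ev)))
})
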