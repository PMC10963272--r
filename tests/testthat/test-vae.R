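tiny_cfg <- function(...) {
  vae_config(input_shape = 12L, latent_dim = 3L, hidden = c(6L),
             batch_size = 4L, ...)
}

test_that("the loss has its closed forms", {
  x <- runif(10)
  post0 <- structure(list(mu = rep(0, 3), logvar = rep(0, 3)),
                     class = "latent_posterior")
  l <- vae_loss(x, x, post0)
  expect_equal(l$total, 0)
  expect_equal(l$recon, 0)
  expect_equal(l$kl, 0)

  post1 <- structure(list(mu = 1, logvar = 0), class = "latent_posterior")
  expect_equal(vae_loss(x, x, post1)$kl, 0.5)

  # mu = 0, variance 4 at L = 1: -0.5 * (1 + log 4 - 4)
  post2 <- structure(list(mu = 0, logvar = log(4)), class = "latent_posterior")
  expect_equal(vae_loss(x, x, post2)$kl, 1.5 - 0.5 * log(4))
  expect_equal(vae_loss(x, x, post2)$kl, 0.8068528, tolerance = 1e-6)
})

test_that("the KL term is non-negative for arbitrary posteriors", {
  set.seed(3)
  for (i in 1:50) {
    post <- structure(list(mu = rnorm(5, sd = 3), logvar = rnorm(5, sd = 3)),
                      class = "latent_posterior")
    expect_gte(vae_loss(runif(4), runif(4), post)$kl, 0)
  }
})

test_that("encoding is deterministic and shape-checked; decoding stays in range", {
  v <- vae_new(tiny_cfg(), seed = 4)
  x <- runif(12)
  p1 <- vae_encode(v, x)
  expect_identical(p1, vae_encode(v, x))
  expect_true(all(is.finite(c(p1$mu, p1$logvar))))
  expect_error(vae_encode(v, runif(5)), "length")

  set.seed(100)
  z <- rnorm(3)
  y <- vae_decode(v, z)
  expect_true(all(y >= 0 & y <= 1))
  expect_identical(y, vae_decode(v, z))
  expect_error(vae_decode(v, rnorm(5)), "latent")
})

test_that("latent sampling follows the reparameterization", {
  post <- structure(list(mu = c(1, -2), logvar = c(-20, -20)),
                    class = "latent_posterior")
  expect_equal(vae_sample_latent(post, seed = 5), c(1, -2), tolerance = 1e-3)

  post2 <- structure(list(mu = 2, logvar = log(4)), class = "latent_posterior")
  set.seed(6)
  draws <- replicate(10000, vae_sample_latent(post2))
  # CLT: sample mean within 4 sigma / sqrt(n) of mu
  expect_lt(abs(mean(draws) - 2), 4 * 2 / sqrt(10000))
  expect_identical(vae_sample_latent(post2, seed = 7),
                   vae_sample_latent(post2, seed = 7))
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- tiny_cfg()
  v <- vae_new(cfg, seed = 8)
  set.seed(9)
  X <- matrix(runif(4 * 12), 4)
  eps <- matrix(rnorm(4 * 3), 4)
  objective <- function(vae) {
    fe <- genmem:::forward_encoder(vae, X)
    Z <- fe$mu + exp(fe$lv / 2) * eps
    Y <- genmem:::forward_decoder(vae, Z)$Y
    recon <- mean(abs(X - Y))
    kl <- mean(-0.5 * rowSums(1 + fe$lv - fe$mu^2 - exp(fe$lv)))
    recon + cfg$kl_weight * kl / cfg$input_dim
  }
  bw <- genmem:::vae_backward(v, X, X, eps)
  h <- 1e-6
  for (nm in c("We1", "Wmu", "Wlv", "Wd1", "Wo", "bo", "bmu")) {
    g <- bw$grads[[nm]]
    for (idx in sample(length(g), 3)) {
      vp <- v; vp$params[[nm]][idx] <- vp$params[[nm]][idx] + h
      vm <- v; vm$params[[nm]][idx] <- vm$params[[nm]][idx] - h
      num <- (objective(vp) - objective(vm)) / (2 * h)
      expect_equal(g[idx], num, tolerance = 1e-3)
    }
  }
})

test_that("training reduces reconstruction error reproducibly", {
  set.seed(10)
  # structured toy data: two latent factors drive 12 outputs
  f <- matrix(runif(200 * 2), 200)
  X <- cbind(f, 1 - f, f * 0.5 + 0.2, f[, 2:1], f^2, 0.3 + 0.4 * f)
  cfg <- tiny_cfg(max_epochs = 30L)
  fit1 <- vae_train(vae_new(cfg, seed = 11), X, seed = 12)
  expect_lt(fit1$log$recon[nrow(fit1$log)], fit1$log$recon[1])
  fit2 <- vae_train(vae_new(cfg, seed = 11), X, seed = 12)
  expect_identical(fit1$log, fit2$log)
  expect_error(vae_train(vae_new(cfg), X[0, , drop = FALSE]), "empty")
})

test_that("latent interpolation hits its endpoints and count", {
  s <- small_scene_vae()
  a <- render_scene(sample_factors(seed = 13))
  b <- render_scene(sample_factors(seed = 14))
  imgs <- latent_interpolate(s$vae, a, b, steps = 5L)
  expect_length(imgs, 5L)
  expect_equal(imgs[[1]], vae_decode(s$vae, vae_encode(s$vae, a)$mu))
  expect_equal(imgs[[5]], vae_decode(s$vae, vae_encode(s$vae, b)$mu))
  mid <- vae_decode(s$vae, 0.5 * vae_encode(s$vae, a)$mu +
                      0.5 * vae_encode(s$vae, b)$mu)
  expect_equal(imgs[[3]], mid)
})

test_that("latent arithmetic cancels and differs from pixel mixing", {
  s <- small_scene_vae()
  a <- render_scene(sample_factors(seed = 15))
  b <- render_scene(sample_factors(seed = 16))
  out <- latent_arithmetic(s$vae, a, b, b)
  expect_equal(out, vae_decode(s$vae, vae_encode(s$vae, a)$mu),
               tolerance = 1e-10)

  # generativity: decoding a latent mixture is not pixel-space mixing
  mix_latent <- latent_interpolate(s$vae, a, b, steps = 3L)[[2]]
  mix_pixel <- (recall_basic(s$vae, a) + recall_basic(s$vae, b)) / 2
  expect_gt(mean(abs(mix_latent - mix_pixel)), 1e-4)
})

test_that("imagination samples every shape category within budget", {
  sys <- std_run()
  stats <- latent_distribution(sys$run$vae, sys$probes$x[1:500, ])
  for (shape in c("cube", "cylinder", "sphere", "capsule")) {
    r <- sample_from_category(sys$run$vae, sys$run$readout, shape,
                              budget = 1000L, seed = 42,
                              latent_stats = stats)
    expect_true(r$found)
    expect_identical(as.character(predict(sys$run$readout,
                                          matrix(r$z, nrow = 1))), shape)
    expect_true(all(r$image >= 0 & r$image <= 1))
  }
  # empty acceptance region: fails explicitly without error cascade
  set.seed(9)
  toy <- fit_readout(rbind(matrix(5, 10, 20), matrix(-5, 10, 20)) +
                       matrix(rnorm(400, sd = 0.1), 20),
                     rep(c("far_a", "far_b"), each = 10))
  at_origin <- as.character(predict(toy, matrix(0, 1, 20)))
  unreachable <- setdiff(c("far_a", "far_b"), at_origin)
  miss <- sample_from_category(sys$run$vae, toy, unreachable, budget = 3L,
                               seed = 1,
                               latent_stats = list(mean = rep(0, 20),
                                                   sd = rep(1e-6, 20)))
  expect_false(miss$found)
  expect_null(miss$image)
})

test_that("recall stays in range and degrades gracefully with corruption", {
  s <- small_scene_vae()
  img <- unflatten_image(s$probes$x[1, ], c(64L, 64L, 3L))
  rec_clean <- recall_basic(s$vae, img)
  expect_true(all(rec_clean >= 0 & rec_clean <= 1))
  rec_cor <- recall_basic(s$vae, corrupt_partial(img, 0.1, seed = 17))
  expect_lte(mean(abs(rec_clean - img)), mean(abs(rec_cor - img)) + 0.02)

  noise <- array(runif(prod(dim(img))), dim(img))
  expect_lt(mean(abs(rec_cor - img)),
            mean(abs(recall_basic(s$vae, noise) - img)))
})
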