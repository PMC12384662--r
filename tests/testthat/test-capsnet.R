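# The capsule network core: squash, routing, margin loss, shapes, gradients.

test_that("squash obeys its analytic laws", {
  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(sqrt(sum(squash(c(1, 0))^2)), 0.5)        # ||s|| = 1 -> 1/2
  expect_equal(squash(c(3, 0)), c(0.9, 0))               # 9/10 along (1,0)
  set.seed(1)
  prev <- -1
  for (n in c(0.01, 0.1, 0.5, 1, 2, 5, 50)) {
    s <- rnorm(4); s <- s / sqrt(sum(s^2)) * n
    out <- squash(s)
    len <- sqrt(sum(out^2))
    expect_lt(len, 1)
    expect_gt(len, prev)                                  # increasing in ||s||
    cosim <- sum(s * out) / (sqrt(sum(s^2)) * sqrt(sum(out^2)))
    expect_equal(cosim, 1, tolerance = 1e-9)              # direction kept
    prev <- len
  }
  expect_error(squash(c(1, NA)), "finite")
  expect_error(squash(c(1, Inf)), "finite")
})

test_that("feature extraction reproduces the expected spatial shrinkage", {
  for (hw in list(c(19, 18, 13, 12), c(15, 12, 9, 6), c(7, 7, 1, 1))) {
    cfg <- capsnet_config(hw[1:2], 2)
    m <- init_capsnet(cfg, 1)
    x <- array(rnorm(2 * hw[1] * hw[2]), c(2, hw[1], hw[2]))
    f <- feature_extract(m, x)
    expect_equal(dim(f), c(2, hw[3], hw[4], 8))
  }
  expect_error(capsnet_config(c(6, 6), 2), "receptive field")
})

test_that("primary capsules are a reshape + squash of the feature map", {
  f <- array(rnorm(2 * 13 * 12 * 8), c(2, 13, 12, 8))
  u <- to_primary_capsules(f, 4)
  expect_equal(dim(u), c(2, 312, 4))
  expect_true(all(sqrt(rowSums(matrix(u, 2 * 312, 4)^2)) < 1))
  u0 <- to_primary_capsules(array(0, c(1, 1, 1, 8)), 4)
  expect_equal(dim(u0), c(1, 2, 4))
  expect_true(all(u0 == 0))                               # squash(0) = 0
  expect_error(to_primary_capsules(array(0, c(1, 1, 1, 6)), 4), "divisible")
})

test_that("prediction vectors equal a per-pair loop over the weight array", {
  cfg <- capsnet_config(c(7, 7), 3, label_dim = 5)
  m <- init_capsnet(cfg, 2)
  B <- 2; I <- cfg$n_primary; P <- cfg$primary_dim; D <- cfg$label_dim
  u <- array(rnorm(B * I * P), c(B, I, P))
  u_hat <- capseeg:::predict_uhat(m, u)
  for (b in 1:B) for (i in 1:I) for (j in 1:cfg$n_classes) {
    Wij <- m$W[, (j - 1) * D + 1:D, i]
    expect_equal(u_hat[b, i, (j - 1) * D + 1:D],
                 as.vector(u[b, i, ] %*% Wij), tolerance = 1e-12)
  }
})

test_that("dynamic routing matches a straight-loop oracle on random small tensors", {
  set.seed(42)
  for (trial in 1:40) {
    I <- sample(1:5, 1); K <- sample(2:3, 1); D <- sample(2:4, 1)
    r <- sample(1:4, 1)
    uh <- array(rnorm(I * K * D), c(I, K, D))
    got <- dynamic_routing(uh, r)
    want <- oracle_routing(uh, r)
    expect_equal(got$v, want$v, tolerance = 1e-6)
    expect_equal(got$c, want$c, tolerance = 1e-6)
    expect_equal(rowSums(got$c), rep(1, I), tolerance = 1e-6)
  }
  expect_error(dynamic_routing(array(0, c(2, 2, 2)), 0), "r >= 1")
})

test_that("one routing iteration couples uniformly; identical predictions pass through", {
  # with zero logits the softmax over the K label capsules gives c = 1/K
  # for every (i, j), so s_j = (1/K) * sum_i u_hat[i, j, ]
  set.seed(17)
  uh <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  rs <- dynamic_routing(uh, 1)
  expect_true(all(abs(rs$c - 0.5) < 1e-12))
  for (j in 1:2)
    expect_equal(rs$v[j, ], squash(0.5 * colSums(uh[, j, ])), tolerance = 1e-12)
  # identical u_hat across i: every s_j is a positive multiple of the
  # common prediction (at r = 1 exactly (I/K) of it), so the label capsule
  # keeps its direction at every r; with I = K the combination has unit
  # total coefficient and v_j = squash(u_hat[1, j, ]) exactly
  base <- matrix(rnorm(2 * 3), 2, 3)
  uh2 <- array(0, c(5, 2, 3))
  for (i in 1:5) uh2[i, , ] <- base
  expect_equal(dynamic_routing(uh2, 1)$v[1, ],
               squash(5 / 2 * base[1, ]), tolerance = 1e-12)
  for (r in 1:4) {
    v <- dynamic_routing(uh2, r)$v
    for (j in 1:2) {
      cosim <- sum(v[j, ] * base[j, ]) /
        sqrt(sum(v[j, ]^2) * sum(base[j, ]^2))
      expect_equal(cosim, 1, tolerance = 1e-9)
    }
  }
  uh_eq <- array(0, c(2, 2, 3))          # I = K: unit total coefficient
  for (i in 1:2) uh_eq[i, , ] <- base
  for (j in 1:2)
    expect_equal(dynamic_routing(uh_eq, 1)$v[j, ], squash(base[j, ]),
                 tolerance = 1e-12)
})

test_that("class probabilities are capsule lengths; argmax with low-index ties", {
  v <- rbind(c(0.9, rep(0, 15)), c(0.1, rep(0, 15)))
  expect_equal(class_probabilities(v), c(0.9, 0.1))
  expect_equal(predict_classes(matrix(c(0.9, 0.1), 1)), 0L)
  expect_equal(predict_classes(matrix(c(0, 0), 1)), 0L)   # tie -> lowest index
  expect_equal(predict_classes(matrix(c(0.2, 0.2, 0.7), 1)), 2L)
  vb <- array(rnorm(3 * 2 * 16), c(3, 2, 16))
  expect_equal(dim(class_probabilities(vb)), c(3, 2))
})

test_that("margin loss matches hand-computed values and its zero set", {
  expect_equal(margin_loss(c(0.9, 0.1), 0)$batch, 0)
  expect_equal(margin_loss(c(1.0, 0.0), 0)$batch, 0)
  expect_equal(margin_loss(c(0.5, 0.5), 0)$batch, 0.24)   # 0.16 + 0.5*0.16
  expect_error(margin_loss(c(1.2, 0), 0), "0, 1")
  set.seed(8)
  for (trial in 1:50) {
    K <- sample(2:3, 1)
    len <- runif(K)
    y <- sample(0:(K - 1), 1)
    l <- margin_loss(len, y)$batch
    expect_gte(l, 0)
    zero_expected <- len[y + 1] >= 0.9 && all(len[-(y + 1)] <= 0.1)
    expect_equal(l == 0, zero_expected)
  }
  # batch loss is the mean of per-sample losses
  L <- matrix(runif(6), 3, 2)
  ml <- margin_loss(L, c(0, 1, 0))
  expect_equal(ml$batch, mean(ml$per_sample))
})

test_that("the full forward pass reproduces every canonical layer shape", {
  cfg <- capsnet_config(c(19, 18), 2)
  m <- init_capsnet(cfg, 1)
  x <- array(rnorm(19 * 18), c(1, 19, 18))
  f <- feature_extract(m, x)
  expect_equal(dim(f), c(1, 13, 12, 8))
  u <- to_primary_capsules(f, 4)
  expect_equal(dim(u), c(1, 312, 4))
  fw <- capsnet_forward(m, x)
  expect_equal(dim(fw$v), c(1, 2, 16))
  expect_equal(dim(fw$probs), c(1, 2))
  expect_true(all(fw$probs >= 0 & fw$probs < 1))
  # ternary configuration: (3, 16) label capsules, 3 probabilities
  cfg3 <- capsnet_config(c(19, 18), 3)
  fw3 <- capsnet_forward(init_capsnet(cfg3, 1), x)
  expect_equal(dim(fw3$v), c(1, 3, 16))
  expect_equal(ncol(fw3$probs), 3)
})

test_that("the forward pass is deterministic and coupling rows sum to one", {
  cfg <- capsnet_config(c(10, 9), 2)
  m <- init_capsnet(cfg, 4)
  x <- array(rnorm(3 * 10 * 9), c(3, 10, 9))
  a <- capsnet_forward(m, x, labels = c(0, 1, 0))
  b <- capsnet_forward(m, x, labels = c(0, 1, 0))
  expect_identical(a$probs, b$probs)
  expect_identical(a$loss, b$loss)
  sums <- apply(a$routing, c(1, 2), sum)
  expect_equal(max(abs(sums - 1)), 0, tolerance = 1e-6)
})

test_that("trainable parameter count equals the layer-by-layer arithmetic", {
  # independent hand count for the 342-point binary preset:
  # Con-1 kernels 4*4*1*8 + 8 biases; two Con-2 convolutions 4*4*8*8 + 8
  # each; routing weights 312 * 2 * 4 * 16; no other parameters exist.
  hand <- (4 * 4 * 1 * 8 + 8) + 2 * (4 * 4 * 8 * 8 + 8) + 312 * 2 * 4 * 16
  m <- init_capsnet(capsnet_config(c(19, 18), 2), 1)
  expect_equal(count_params(m), hand)
  expect_equal(hand, 42136)
})

test_that("analytic gradients match finite differences where routing is single-pass", {
  cfg <- capsnet_config(c(8, 8), 2, routing_iters = 1)
  m <- init_capsnet(cfg, 3)
  set.seed(5)
  x <- array(rnorm(3 * 8 * 8), c(3, 8, 8)); y <- c(0, 1, 0)
  fw <- capsnet_forward(m, x, labels = y, keep_cache = TRUE)
  gr <- capseeg:::capsnet_backward(m, fw)
  eps <- 1e-5
  for (nm in c("km1", "b1", "km2a", "b2a", "km2b", "b2b", "W")) {
    for (rep in 1:4) {
      i <- sample(length(m[[nm]]), 1)
      mp <- m; mp[[nm]][i] <- mp[[nm]][i] + eps
      mm <- m; mm[[nm]][i] <- mm[[nm]][i] - eps
      num <- (capsnet_forward(mp, x, labels = y)$loss -
                capsnet_forward(mm, x, labels = y)$loss) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("weight %s[%d]", nm, i))
    }
  }
})

test_that("one Adam step at the default learning rate decreases the loss", {
  cfg <- capsnet_config(c(8, 8), 2)   # r = 3, the production setting
  m <- init_capsnet(cfg, 7)
  set.seed(6)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8)); y <- rep(0:1, 4)
  fw <- capsnet_forward(m, x, labels = y, keep_cache = TRUE)
  gr <- capseeg:::capsnet_backward(m, fw)
  st <- capseeg:::adam_init(m)
  m2 <- capseeg:::adam_step(m, gr, st, 5e-4)$model
  expect_lt(capsnet_forward(m2, x, labels = y)$loss, fw$loss)
})

test_that("checkpoints round-trip weights and reject mismatched shapes", {
  cfg <- capsnet_config(c(9, 8), 2)
  m <- init_capsnet(cfg, 9)
  f <- withr::local_tempfile(fileext = ".caps.json")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  x <- array(rnorm(2 * 9 * 8), c(2, 9, 8))
  expect_equal(capsnet_forward(m2, x)$probs, capsnet_forward(m, x)$probs,
               tolerance = 1e-12)
  # corrupt a shape in the stored config
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  js$cfg$input_hw <- c(12, 11)
  jsonlite::write_json(js, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_checkpoint(f), "shape")
})
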