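test_that("prototype sets are deterministic, unit-norm and well separated", {
  p1 <- make_prototypes(4, 64, sigma_noise = 0.05, seed = 1)
  p2 <- make_prototypes(4, 64, sigma_noise = 0.05, seed = 1)
  expect_equal(p1, p2)
  p3 <- make_prototypes(4, 64, sigma_noise = 0.05, seed = 2)
  expect_false(isTRUE(all.equal(p1[[1]]$mu, p3[[1]]$mu)))
  mus <- sapply(p1, `[[`, "mu")
  expect_true(all(mus >= 0))
  expect_equal(colSums(mus^2), rep(1, 4), tolerance = 1e-12)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sqrt(sum((mus[, i] - mus[, j])^2))
    expect_gt(d, 0.2)
    expect_gt(d, 4 * 0.05)
  }
  expect_error(make_prototypes(10, 4), "infeasible")
  expect_error(make_prototypes(2, 16, sigma_noise = 0.4), "infeasible")
})

test_that("observe returns exact prototypes when noise-free, clipped noise otherwise", {
  protos <- make_prototypes(3, 12, sigma_noise = 0, seed = 5)
  expect_identical(observe(protos[[1]]), protos[[1]]$mu)
  expect_identical(observe(NULL, ell = 12, sigma_noise = 0), numeric(12))
  noisy <- make_prototypes(3, 12, sigma_noise = 0.1, seed = 5)
  set.seed(99)
  for (k in 1:200) {
    expect_true(all(observe(noisy[[2]]) >= 0))
    expect_true(all(observe(NULL, ell = 12, sigma_noise = 0.1) >= 0))
  }
})

test_that("recognition is binary and silent for an untrained layer", {
  protos <- clean_protos()
  for (rule in c("oja", "bcm")) {
    layer <- hebbian_layer(4, 64, rule = rule, theta_H = 0.5)
    out <- recognize(layer, protos[[1]]$mu)
    expect_equal(out, rep(0, 4))
    expect_true(all(out %in% c(0, 1)))
  }
  layer <- hebbian_layer(4, 64, "oja", theta_H = 0.5)
  expect_error(recognize(layer, numeric(3)), "ell")
})

test_that("one supervised Oja step imprints the frame as the class weight row", {
  protos <- clean_protos()
  layer <- hebbian_layer(4, 64, rule = "oja")
  layer <- learn_label(layer, protos[[1]]$mu, 1, dt = 1)
  expect_equal(layer$H[1, ], protos[[1]]$mu)
  expect_equal(layer$H[2:4, ], matrix(0, 3, 64))
  # trained response is the squared norm = 1; recognized for any theta_H < 1
  layer$theta_H <- 0.5
  expect_equal(recognize(layer, protos[[1]]$mu), c(1, 0, 0, 0))
  # orthogonal prototype evokes exactly zero response
  expect_equal(sum(layer$H[1, ] * protos[[2]]$mu), 0)
  expect_equal(recognize(layer, protos[[2]]$mu), c(0, 0, 0, 0))
})

test_that("BCM supervision is stable at its threshold fixed point", {
  protos <- clean_protos()
  layer <- hebbian_layer(4, 64, rule = "bcm")
  layer <- learn_label(layer, protos[[1]]$mu, 1)
  expect_equal(layer$H[1, ], protos[[1]]$mu)
  expect_equal(layer$theta[1], 1)
  # theta = v = 1 is a fixed point: further steps change nothing
  layer2 <- learn_label(layer, protos[[1]]$mu, 1)
  expect_equal(layer2$H, layer$H)
  expect_equal(layer2$theta, layer$theta)
  expect_error(learn_label(layer, protos[[1]]$mu, 9), "registered")
})

test_that("the BCM margin survives repeated naming steps", {
  protos <- make_prototypes(4, 64, sigma_noise = 0.05, seed = 1)
  layer <- hebbian_layer(4, 64, rule = "bcm")
  set.seed(21)
  for (step in 1:5) {
    layer <- learn_label(layer, observe(protos[[1]]), 1)
    raw_present <- sum(layer$H[1, ] * protos[[1]]$mu)
    raw_absent <- sum(layer$H[1, ] * observe(NULL, ell = 64, sigma_noise = 0.05))
    expect_gt(raw_present - raw_absent, 0)
    # and the binary readout separates presence from absence at every step
    expect_equal(recognize(layer, protos[[1]]$mu)[1], 1)
    expect_equal(recognize(layer, observe(NULL, ell = 64, sigma_noise = 0.05))[1], 0)
  }
})

test_that("theta_H calibration halves the weakest trained response", {
  protos <- clean_protos()
  layer <- hebbian_layer(4, 64, rule = "oja")
  for (s in 1:4) layer <- learn_label(layer, protos[[s]]$mu, s)
  layer <- calibrate_theta_H(layer, protos)
  expect_equal(layer$theta_H, 0.5)
  for (s in 1:4) {
    expect_equal(recognize(layer, protos[[s]]$mu), as.numeric(seq_len(4) == s))
  }
  # calibration on an untrained layer disables the readout instead of
  # letting it fire on silence
  blank <- calibrate_theta_H(hebbian_layer(4, 64, "oja"), protos)
  expect_identical(blank$theta_H, Inf)
  expect_equal(recognize(blank, protos[[1]]$mu), rep(0, 4))
})

test_that("vocabulary registration is idempotent and capacity-bounded", {
  v <- vocabulary(4)
  r <- register_pattern(v, "coin")
  expect_equal(r$index, 1)
  r2 <- register_pattern(r$vocab, "coin")
  expect_equal(r2$index, 1)
  expect_equal(length(r2$vocab$names), 1)
  for (nm in c("tablet", "lemon", "notebook")) {
    r2 <- register_pattern(r2$vocab, nm)
  }
  expect_equal(r2$index, 4)
  expect_error(register_pattern(r2$vocab, "fifth"), "capacity")
})

test_that("prototype sets round-trip through JSON", {
  protos <- make_prototypes(3, 16, sigma_noise = 0.02, seed = 9)
  v <- register_pattern(vocabulary(3), "coin")$vocab
  json <- prototypes_to_json(protos, v)
  back <- prototypes_from_json(json)
  expect_equal(length(back$prototypes), 3)
  expect_equal(back$prototypes[[2]]$mu, protos[[2]]$mu)
  expect_equal(back$vocabulary$names, "coin")
  tmp <- tempfile(fileext = ".json")
  prototypes_to_json(protos, v, path = tmp)
  expect_equal(prototypes_from_json(tmp)$prototypes[[1]]$mu, protos[[1]]$mu)
})
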