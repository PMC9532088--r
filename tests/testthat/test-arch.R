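test_that("channel trace matches the hand-computed lite arithmetic", {
  # no fusion: stem 16 -> blocks +2*8 -> transitions halve
  tr <- channel_trace(arch_lite(8, fusion_enabled = FALSE))
  out <- setNames(tr$out_channels, tr$stage)
  expect_equal(unname(out[c("stem", "block1", "transition1", "block2",
                            "transition2", "block3", "transition3",
                            "block4")]),
               c(16, 32, 16, 32, 16, 32, 16, 32))
  expect_equal(tr$spatial[tr$stage == "stem"], 32) # 2x stem downsampling
  expect_equal(tr$spatial[tr$stage == "block4"], 4)
  # with fusion: +10 orientation maps after every transition
  trf <- channel_trace(arch_lite(8, fusion_enabled = TRUE))
  outf <- setNames(trf$out_channels, trf$stage)
  expect_equal(unname(outf[c("fuse1", "block2", "fuse2", "block3", "fuse3",
                             "block4")]),
               c(26, 42, 31, 47, 33, 49))
  expect_equal(trf$out_channels[trf$stage == "head"], 8)
})

test_that("dense concatenation arithmetic: block output = input + L * growth", {
  for (i in 1:5) {
    L <- sample(1:6, 1)
    g <- sample(1:16, 1)
    cfg <- arch_config(block_sizes = L, growth_rate = g, stem_channels = 8,
                       input_size = 16, num_classes = 2)
    tr <- channel_trace(cfg)
    expect_equal(tr$out_channels[tr$type == "dense_block"], 8 + L * g)
  }
  # doubling growth doubles every block's added channels
  t1 <- channel_trace(arch_lite(8, fusion_enabled = FALSE, growth_rate = 8))
  t2 <- channel_trace(arch_lite(8, fusion_enabled = FALSE, growth_rate = 16))
  a1 <- t1$out_channels[t1$type == "dense_block"] -
    t1$in_channels[t1$type == "dense_block"]
  a2 <- t2$out_channels[t2$type == "dense_block"] -
    t2$in_channels[t2$type == "dense_block"]
  expect_equal(a2, 2 * a1)
})

test_that("the DenseNet201-shaped trace pools 1920 features", {
  tr <- channel_trace(arch_densenet201())
  expect_equal(tr$out_channels[tr$type == "gap"], 1920)
})

test_that("invalid configurations are rejected", {
  expect_error(arch_config(growth_rate = 0), "growth_rate")
  expect_error(arch_config(input_size = 60), "divisible")
  expect_error(arch_config(num_classes = 1), "num_classes")
  expect_error(arch_config(compression = 0), "compression")
})

test_that("fusion adds exactly the pooled map count at every transition", {
  set.seed(99)
  for (i in 1:20) {
    nb <- sample(2:4, 1)
    cfg_args <- list(
      block_sizes = sample(1:3, nb, replace = TRUE),
      growth_rate = sample(2:8, 1),
      stem_channels = sample(4:12, 1),
      input_size = 16 * 2^(nb - 2), num_classes = sample(2:5, 1),
      gabor = log_gabor_params(n_scales = 2,
                               n_orientations = sample(2:4, 1),
                               min_wavelength = 3)
    )
    toff <- channel_trace(do.call(arch_config,
                                  c(cfg_args, fusion_enabled = FALSE)))
    ton <- channel_trace(do.call(arch_config,
                                 c(cfg_args, fusion_enabled = TRUE)))
    k <- cfg_args$gabor$n_orientations
    off_tr <- toff$out_channels[toff$type == "transition"]
    on_tr <- ton$out_channels[ton$type == "transition"]
    on_fuse <- ton$out_channels[ton$type == "fusion"]
    # each fusion stage concatenates exactly k maps onto its transition
    expect_equal(on_fuse, on_tr + k)
    # and strictly exceeds the fusion-off width by at least k (compression
    # compounds the extra channels through later transitions)
    expect_true(all(on_fuse - off_tr >= k))
  }
})

test_that("instantiated parameter shapes agree with the channel trace", {
  set.seed(7)
  for (i in 1:20) {
    nb <- sample(2:3, 1)
    cfg <- arch_config(
      block_sizes = sample(1:3, nb, replace = TRUE),
      growth_rate = sample(2:6, 1), stem_channels = sample(4:10, 1),
      input_size = 8 * 2^(nb - 1), num_classes = sample(2:4, 1),
      fusion_enabled = sample(c(TRUE, FALSE), 1),
      gabor = log_gabor_params(n_scales = 2, n_orientations = 2,
                               min_wavelength = 3)
    )
    spec <- build_backbone(cfg)
    net <- init_network(spec, seed = i)
    plan <- gaborleaf:::nn_plan(cfg)
    # dense-layer convs consume the running concatenation width
    for (b in seq_along(cfg$block_sizes)) {
      cin <- plan$block_in[b]
      for (l in seq_len(cfg$block_sizes[b])) {
        w <- net$params[[sprintf("b%d.l%d.conv.w", b, l)]]
        expect_equal(dim(w), c(9 * cin, cfg$growth_rate))
        cin <- cin + cfg$growth_rate
      }
    }
    tr <- channel_trace(cfg)
    expect_equal(nrow(net$params$head.w), cfg$num_classes)
    expect_equal(ncol(net$params$head.w), tr$in_channels[tr$type == "gap"])
    # forward shape contract on a small batch
    n <- 2
    x <- array(runif(cfg$input_size^2 * n), c(cfg$input_size, cfg$input_size, 1, n))
    gm <- NULL
    if (cfg$fusion_enabled) {
      sizes <- tr$spatial[tr$type == "fusion"]
      gm <- lapply(sizes, function(s) array(rnorm(s * s * 2 * n), c(s, s, 2, n)))
    }
    fwd <- network_forward(net$params, net$bn_state, spec, x, gm)
    expect_equal(dim(fwd$probs), c(cfg$num_classes, n))
    expect_equal(colSums(fwd$probs), rep(1, n), tolerance = 1e-6)
    expect_true(all(fwd$probs >= 0))
  }
})

test_that("fuse_gabor_at_transitions is the identity when fusion is off", {
  cfg <- arch_lite(8, fusion_enabled = FALSE)
  spec <- build_backbone(cfg)
  expect_identical(fuse_gabor_at_transitions(spec), spec)
})

test_that("forward passes are deterministic and weights round-trip", {
  ds <- toy_two_class(4, seed = 2)
  fit <- fit_otamnet(ds, tiny_arch(2, fusion_enabled = TRUE),
                     train_config(max_epochs = 2, seed = 5))
  imgs <- ds$data$image[1:4]
  p1 <- predict(fit, imgs, type = "prob")
  p2 <- predict(fit, imgs, type = "prob")
  expect_identical(p1, p2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  reloaded <- load_model(path)
  expect_identical(predict(reloaded, imgs, type = "prob"), p1)
})

test_that("constant input yields standardized-zero injected maps", {
  # with zero-variance training maps the standardizer floors the sd and the
  # injected channels are exactly zero, so fusion-on output equals a network
  # whose extra channels see zeros
  p <- log_gabor_params(n_scales = 2, n_orientations = 2, min_wavelength = 4)
  cfg <- arch_config(block_sizes = c(1, 1), growth_rate = 2,
                     stem_channels = 4, input_size = 16, num_classes = 2,
                     fusion_enabled = TRUE, gabor = p)
  imgs <- replicate(4, matrix(0.5, 16, 16), simplify = FALSE)
  pyr <- gaborleaf:::gabor_pyramid(imgs, cfg)
  st <- gaborleaf:::gabor_standardizer(pyr, 1:4)
  std <- gaborleaf:::standardize_pyramid(pyr, st)
  expect_true(all(vapply(std$sites, function(a) max(abs(a)), 1) < 1e-6))
})
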