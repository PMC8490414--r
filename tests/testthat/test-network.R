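# Tiny configuration used across the network tests: 4 backbone layers with
# pools after 2 and 4, two pyramid bins, two stages.
tiny_cfg <- function(stages = 2L)
  network_config(channels = c(4, 4, 4, 4), pool_after = c(2, 4),
                 ppm_bins = c(1, 2), stages = stages, head_channels = 3L,
                 bottleneck_channels = 4L)

tiny_scene <- function(seed = 8, size = 48L, n = 2L)
  generate_scene(scene_spec(size, size, n_trees = n,
                            crown_radius_range = c(4, 6),
                            min_center_separation = 12, clutter_level = 0.2,
                            seed = seed))

test_that("backbone parameter count matches the closed-form sum", {
  cfg <- network_config()  # 64,64 | pool | 128,128 | pool | 256 x4
  p <- build_network(cfg, seed = 1)
  cins <- c(3, cfg$channels)
  expected <- sum(3 * 3 * cins[-length(cins)] * cfg$channels + cfg$channels)
  expect_equal(n_parameters(p["backbone"]), expected)
})

test_that("the full-size network maps 256x256 RGB to T sigmoid maps at 1/4 scale", {
  cfg <- network_config(stages = 4L)
  p <- build_network(cfg, seed = 2)
  x <- array(runif(256 * 256 * 3), dim = c(256, 256, 3))
  fw <- net_forward(p, x, cfg)
  expect_length(fw$preds, 4)
  for (m in fw$preds) {
    expect_equal(dim(m), c(64L, 64L))
    expect_true(all(m > 0 & m < 1))
  }
})

test_that("degenerate and invalid shapes are handled", {
  cfg <- tiny_cfg(stages = 1L)
  p <- build_network(cfg, seed = 3)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  fw <- net_forward(p, x, cfg)
  expect_length(fw$preds, 1)  # MSM reduces to its first-stage head
  expect_error(net_forward(p, array(0, dim = c(18, 16, 3)), cfg),
               "divisible")
  big_bins <- network_config(channels = c(4, 4, 4, 4), pool_after = c(2, 4),
                             ppm_bins = c(1, 8), stages = 1L,
                             head_channels = 3L, bottleneck_channels = 4L)
  expect_error(net_forward(build_network(big_bins, 1), x, big_bins),
               "pyramid")
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  p <- build_network(cfg, seed = 3)
  # jitter biases away from 0 so no pre-activation sits exactly on a ReLU
  # kink (where the subgradient is not unique and finite differences are
  # uninformative)
  set.seed(21)
  jig <- function(l) { l$b <- l$b + rnorm(length(l$b), sd = 0.05); l }
  p$backbone <- lapply(p$backbone, jig)
  p$ppm <- lapply(p$ppm, jig)
  p$stages <- lapply(p$stages, function(s) lapply(s, jig))
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  tg <- lapply(1:2, function(t) matrix(runif(16), 4, 4))
  lossfn <- function(p) total_loss(net_forward(p, x, cfg)$preds, tg)
  fw <- net_forward(p, x, cfg, keep_cache = TRUE)
  g <- buriti:::net_backward(p, cfg, fw$cache,
                             buriti:::loss_grads(fw$preds, tg))
  eps <- 1e-5
  get_at <- function(obj, path) { for (k in path) obj <- obj[[k]]; obj }
  set_at <- function(obj, path, slot, idx, val) {
    if (length(path) == 1L) obj[[path[[1]]]][[slot]][idx] <- val
    else obj[[path[[1]]]] <- set_at(obj[[path[[1]]]], path[-1], slot, idx,
                                    val)
    obj
  }
  probes <- list(
    list(list("backbone", 1L), "W"), list(list("backbone", 3L), "W"),
    list(list("ppm", 2L), "W"), list(list("stages", 1L, 1L), "W"),
    list(list("stages", 1L, 4L), "b"), list(list("stages", 2L, 3L), "W"),
    list(list("stages", 2L, 5L), "W"), list(list("stages", 2L, 5L), "b"))
  for (pr in probes) {
    path <- pr[[1]]; slot <- pr[[2]]
    v <- get_at(p, path)[[slot]]
    for (idx in sample(length(v), min(3, length(v)))) {
      f1 <- lossfn(set_at(p, path, slot, idx, v[idx] + eps))
      f2 <- lossfn(set_at(p, path, slot, idx, v[idx] - eps))
      num <- (f1 - f2) / (2 * eps)
      ana <- get_at(g, path)[[slot]][idx]
      expect_lt(abs(num - ana), 1e-4 * max(1, abs(num)))
    }
  }
})

test_that("stage loss is the summed squared difference", {
  a <- matrix(c(1, 0, 0, 0.5), 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(stage_loss(a, a), 0)
  expect_equal(stage_loss(z, a), 1.25)
  expect_equal(stage_loss(a, z), stage_loss(z, a))  # symmetric
  expect_error(stage_loss(z, matrix(0, 3, 2)), "shape")
})

test_that("total loss adds per-stage losses with intermediate supervision", {
  a <- matrix(c(1, 0, 0, 0.5), 2, 2)
  b <- matrix(c(0.5, 0.5, 0.5, 0.5), 2, 2)
  z <- matrix(0, 2, 2)
  expect_equal(total_loss(list(a, b), list(a, b)), 0)
  per_stage <- c(stage_loss(z, a), stage_loss(z, b))
  expect_equal(per_stage, c(1.25, 1))  # sanity on the fixture itself
  expect_equal(total_loss(list(z, z), list(a, b)), sum(per_stage),
               tolerance = 1e-6)
  expect_gte(total_loss(list(z, z), list(a, b)), max(per_stage))
  expect_error(total_loss(list(a), list(a, b)), "stage count")
})

test_that("zero epochs leave the initial weights untouched", {
  sc <- tiny_scene()
  cfg <- tiny_cfg()
  ctl <- train_control(epochs = 0, seed = 5,
                       schedule = make_sigma_schedule(1, 2, 2))
  fit <- palm_detector(list(sc), net = cfg, control = ctl)
  expect_equal(nrow(fit$history), 0)
  expect_identical(fit$params, build_network(cfg, seed = 5))
})

test_that("training is reproducible and its loss decreases on one scene", {
  sc <- tiny_scene()
  cfg <- tiny_cfg()
  ctl <- train_control(learning_rate = 3e-5, epochs = 6, seed = 5,
                       schedule = make_sigma_schedule(1, 2, 2))
  f1 <- palm_detector(list(sc), net = cfg, control = ctl)
  f2 <- palm_detector(list(sc), net = cfg, control = ctl)
  expect_identical(f1$history, f2$history)
  expect_lt(f1$history$train_loss[6], f1$history$train_loss[1])
  expect_error(palm_detector(list(), net = cfg, control = ctl), "empty")
})

test_that("a reduced model overfits a single scene", {
  sc <- generate_scene(easy_scene_spec(64, 3, seed = 1))
  cfg <- reduced_network_config(stages = 2)
  ctl <- train_control(learning_rate = 3e-5, epochs = 200, seed = 3,
                       schedule = make_sigma_schedule(1.5, 4, 2))
  fit <- palm_detector(list(sc), net = cfg, control = ctl)
  h <- fit$history$train_loss
  expect_lt(h[length(h)], 0.1 * h[1])
  # shifting the input by 4k pixels shifts a tree's confidence peak by ~k
  # cells: track the peak near the most central tree (the global argmax may
  # legitimately jump between trees when the circular shift clips a crown)
  img <- sc$image
  sh <- 8L
  img2 <- img[c((sh + 1):64, 1:sh), , , drop = FALSE]  # circular row shift
  m1 <- predict(fit, img, type = "confidence")[[2]]$grid
  m2 <- predict(fit, img2, type = "confidence")[[2]]$grid
  ann <- sc$annotations
  mid <- which.min((ann$x - 32)^2 + (ann$y - 32)^2)
  cr <- round(ann$y[mid] / 4) + 1L; cc <- round(ann$x[mid] / 4) + 1L
  local_argmax <- function(m, r, c) {
    win <- m[max(1, r - 2):min(nrow(m), r + 2),
             max(1, c - 2):min(ncol(m), c + 2)]
    idx <- which(m == max(win), arr.ind = TRUE)[1, ]
    idx
  }
  a1 <- local_argmax(m1, cr, cc)
  a2 <- local_argmax(m2, cr - sh %/% 4L, cc)
  expect_lte(abs((a1["row"] - a2["row"]) - sh / 4), 1)
  expect_lte(abs(a1["col"] - a2["col"]), 1)
})

test_that("detectors round-trip through the JSON checkpoint", {
  sc <- tiny_scene()
  cfg <- tiny_cfg()
  ctl <- train_control(learning_rate = 3e-5, epochs = 2, seed = 5,
                       schedule = make_sigma_schedule(1, 2, 2))
  fit <- palm_detector(list(sc), net = cfg, control = ctl)
  path <- tempfile(fileext = ".json")
  save_detector(fit, path)
  fit2 <- load_detector(path)
  m1 <- predict(fit, sc, type = "confidence")[[2]]$grid
  m2 <- predict(fit2, sc, type = "confidence")[[2]]$grid
  expect_equal(m1, m2, tolerance = 1e-12)
  unlink(path)
})
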