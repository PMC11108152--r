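# Network construction, subject-level splitting, training dynamics,
# prediction and the capture interface.

test_that("the full-scale trunk has 13 conv layers and the stated head", {
  spec <- network_spec(preset = "paper_faithful", head = "fc")
  expect_equal(n_conv_layers(spec), 13)
  expect_equal(length(spec$blocks), 5)
  expect_equal(vapply(spec$blocks, `[`, 1, 1), c(2, 2, 3, 3, 3))
  expect_equal(spec$fc_units, c(2048L, 1024L))
  expect_equal(spec$dropout, 0.5)
  expect_equal(spec$n_classes, 2L)
})

test_that("GAP head adds exactly channels x classes (+bias) parameters and fewer than FC", {
  sg <- network_spec(input_shape = c(16, 16, 16), in_channels = 2,
                     blocks = list(c(1, 4), c(1, 6)), head = "gap")
  sf <- network_spec(input_shape = c(16, 16, 16), in_channels = 2,
                     blocks = list(c(1, 4), c(1, 6)), head = "fc",
                     fc_units = c(64, 32))
  mg <- build_network(sg, seed = 1); mf <- build_network(sf, seed = 1)
  head_layer <- mg$layers[[length(mg$layers)]]
  expect_equal(length(head_layer$W) + length(head_layer$b), 6 * 2 + 2)
  expect_lt(n_params(mg), n_params(mf))
})

test_that("width scaling shrinks channels and the forward pass is a softmax", {
  spec <- network_spec(input_shape = c(24, 28, 24), in_channels = 4,
                       blocks = list(c(1, 16), c(1, 32)), width_scale = 0.25)
  expect_equal(vapply(spec$blocks, `[`, 1, 2), c(4, 8))
  model <- build_network(spec, seed = 2)
  set.seed(1)
  x <- array(rnorm(24 * 28 * 24 * 4), c(24, 28, 24, 4))
  p <- predict_stack(model, x)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, predict_stack(model, x))   # eval-mode determinism
  expect_error(predict_stack(model, array(0, c(8, 8, 8, 4))), "shape")
  expect_error(predict_stack(model, array(0, c(24, 28, 24, 2))), "channels")
})

test_that("too-small inputs are rejected with the minimum shape", {
  expect_error(network_spec(input_shape = c(8, 8, 8),
                            blocks = list(c(1, 4), c(1, 4), c(1, 4), c(1, 4)),
                            head = "fc"),
               "at least 16")
})

test_that("subject splits are leak-free, stratified and seeded", {
  man <- data.frame(subject_id = rep(sprintf("S%02d", 1:20), each = 2),
                    scan_id = sprintf("scan%02d", 1:40),
                    label = rep(c("AD", "NC"), each = 20))
  for (seed in 1:50) {
    pl <- subject_split(man, 0.8, seed)
    expect_length(intersect(pl$train_subjects, pl$test_subjects), 0)
    expect_length(intersect(man$subject_id[man$scan_id %in% pl$train_scans],
                            man$subject_id[man$scan_id %in% pl$test_scans]), 0)
    expect_setequal(c(pl$train_subjects, pl$test_subjects),
                    unique(man$subject_id))
  }
  # 10 subjects per class at 0.8 -> ceiling gives 8 train / 2 test per class
  pl <- subject_split(man, 0.8, 3)
  for (cl in c("AD", "NC")) {
    subj <- unique(man$subject_id[man$label == cl])
    expect_length(intersect(pl$train_subjects, subj), 8)
    expect_length(intersect(pl$test_subjects, subj), 2)
  }
  expect_identical(subject_split(man, 0.8, 7), subject_split(man, 0.8, 7))
  expect_false(identical(subject_split(man, 0.8, 7)$train_subjects,
                         subject_split(man, 0.8, 8)$train_subjects))
  one <- data.frame(subject_id = c("a", "b", "c"), scan_id = c("1", "2", "3"),
                    label = c("AD", "NC", "NC"))
  expect_error(subject_split(one, 0.8, 1), "fewer than 2 subjects")
})

test_that("capture gradients match finite differences of the class score", {
  for (head in c("gap", "fc")) {
    spec <- network_spec(input_shape = c(8, 8, 8), in_channels = 2,
                         blocks = list(c(1, 3), c(1, 4)), head = head,
                         fc_units = c(16, 8))
    model <- build_network(spec, seed = 5)
    set.seed(head == "gap")
    x <- array(rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
    cap <- capture(model, x, class_index = 1)
    expect_identical(dim(cap$gradients), dim(cap$activations))
    A <- cap$activations
    eps <- 1e-5
    # probe clearly active coordinates: at exact ReLU zeros tied inside a
    # max-pool window the central difference straddles the kink
    active <- which(A > 0.05)
    for (i in 1:10) {
      idx <- sample(active, 1)
      Ap <- A; Ap[idx] <- Ap[idx] + eps
      Am <- A; Am[idx] <- Am[idx] - eps
      fd <- (score_from_capture(model, Ap)[1] -
               score_from_capture(model, Am)[1]) / (2 * eps)
      expect_equal(cap$gradients[idx], fd, tolerance = 1e-3)
    }
  }
})

test_that("training separates a strong synthetic contrast and is deterministic", {
  fx <- tiny_experiment_data()
  spec <- network_spec(input_shape = c(24, 28, 24), in_channels = 4,
                       preset = "desk")
  cfg <- train_config(lr = 1e-3, weight_decay = 5e-4, batch_size = 4,
                      n_epochs = 12, seed = 3)
  m1 <- train_model(build_network(spec, seed = 1), fx$stacks,
                    fx$cohort$manifest$label, cfg)
  expect_equal(tail(m1$training_log$accuracy, 1), 1)
  # smoothed loss decreases over the run
  lo <- m1$training_log$loss
  expect_lt(mean(tail(lo, 3)), mean(head(lo, 3)))
  m2 <- train_model(build_network(spec, seed = 1), fx$stacks,
                    fx$cohort$manifest$label, cfg)
  expect_identical(m1$training_log$loss, m2$training_log$loss)
  expect_equal(m1$layers[[1]]$W, m2$layers[[1]]$W, tolerance = 1e-12)
})

test_that("training protocol defaults match the stated hyperparameters", {
  cfg <- train_config()
  expect_equal(cfg$lr, 5e-5)
  expect_equal(cfg$weight_decay, 5e-4)
  expect_equal(cfg$batch_size, 4L)
})
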