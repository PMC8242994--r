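# a tiny linearly separable dataset: class decided by the first chemical
# feature, both modalities present
make_separable <- function(n = 20, p1 = 4, p2 = 6, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x1 <- matrix(rnorm(n * p1, sd = 0.1), n, p1)
  x1[, 1] <- x1[, 1] + ifelse(y == 1, 2, -2)
  x2 <- matrix(rnorm(n * p2, sd = 0.1), n, p2)
  x2[, 1] <- x2[, 1] + ifelse(y == 1, 1, -1)
  bimodal_dataset(x1, x2, y)
}

test_that("OPCNN structure matches the stated architecture", {
  cfg <- opcnn_config()
  expect_equal(cfg$embed_dim, 50L)
  model <- build_opcnn(cfg)
  audit <- model_audit(model)
  expect_equal(audit$n_fc, 5L)
  expect_equal(audit$n_conv, 9L)
  expect_equal(audit$n_proj, 1L) # 1x1 projection where channels go 1 -> 32
  # the map entering the first residual block is 51 x 51, one channel
  g1 <- model$geoms[[1]]$convs[[1]]
  expect_equal(c(g1$H, g1$W, g1$Cin), c(51, 51, 1))
  expect_equal(model$geoms[[2]]$convs[[1]]$Cin, 32)
  expect_null(model$params$blocks[[2]]$proj)
})

test_that("configs reject invalid settings", {
  expect_error(opcnn_config(stride = 2), class = "config_error")
  expect_error(opcnn_config(head = c(100, 50)), class = "config_error")
  expect_error(dmnn_config("late", "addition"), class = "config_error")
  expect_error(dmnn_config("late", "tfl"), class = "config_error")
  expect_error(dmnn_config("late", "mcf"), class = "config_error")
})

test_that("builds are deterministic given the seed", {
  a <- build_opcnn(opcnn_config(embed_dim = 6, kernels = 4, p1 = 4, p2 = 6,
                                seed = 11))
  b <- build_opcnn(opcnn_config(embed_dim = 6, kernels = 4, p1 = 4, p2 = 6,
                                seed = 11))
  expect_identical(a$params, b$params)
  c2 <- build_opcnn(opcnn_config(embed_dim = 6, kernels = 4, p1 = 4, p2 = 6,
                                 seed = 12))
  expect_false(identical(a$params, c2$params))
})

test_that("DMNN fused widths follow the fusion operator", {
  w_of <- function(level, mode, ...) {
    m <- build_dmnn(dmnn_config(level, mode, p1 = 4, p2 = 6, ...))
    nrow(m$params$head[[1]]$W)
  }
  expect_equal(w_of("early", "concat"), 100)
  expect_equal(w_of("early", "addition"), 50)
  expect_equal(w_of("early", "product"), 50)
  expect_equal(w_of("early", "tfl"), 51 * 51)
  expect_equal(w_of("early", "mcf", mcf_k = 20), 20)
  expect_equal(w_of("intermediate", "tfl"), 51 * 51)
  expect_equal(w_of("late", "concat"), 100)
  # tfl/mcf intermediate branches use the shortened FC(100)-FC(50) stack
  m <- build_dmnn(dmnn_config("intermediate", "tfl", p1 = 4, p2 = 6))
  expect_length(m$params$branch1, 2)
  m2 <- build_dmnn(dmnn_config("intermediate", "concat", p1 = 4, p2 = 6))
  expect_length(m2$params$branch1, 3)
})

test_that("forward pass yields probabilities and honours batching", {
  ds <- make_separable(8)
  model <- build_opcnn(opcnn_config(embed_dim = 5, kernels = 3, p1 = 4,
                                    p2 = 6, seed = 2))
  p <- predict_proba(model, ds)
  expect_length(p, 8)
  expect_true(all(p > 0 & p < 1))
  # batch prediction equals per-row prediction
  single <- vapply(1:8, function(i) {
    predict_proba(model, subset_rows(ds, i))
  }, numeric(1))
  expect_equal(p, single, tolerance = 1e-12)
  # duplicated row -> duplicated score
  dup <- subset_rows(ds, c(3, 3))
  expect_equal(predict_proba(model, dup)[1], predict_proba(model, dup)[2])
  expect_error(predict_proba(model, make_separable(4, p1 = 7)),
               class = "dimension_error")
})

test_that("weighted BCE reduces to hand-computed values", {
  logit <- c(0.3, -1.2)
  y <- c(1, 0)
  w <- c(2, 5)
  lo <- opcnn:::wbce_loss(logit, y, w)
  hand <- (2 * -log(plogis(0.3)) + 5 * -log(1 - plogis(-1.2))) / 2
  expect_equal(lo$loss, hand, tolerance = 1e-12)
  # unit weights equal plain BCE
  lo1 <- opcnn:::wbce_loss(logit, y, c(1, 1))
  plain <- mean(-c(log(plogis(0.3)), log(1 - plogis(-1.2))))
  expect_equal(lo1$loss, plain, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences on tiny networks", {
  ds <- make_separable(5)
  sm <- split_modalities(ds)
  w <- ifelse(sm$y == 1, 0.8, 1.7)
  check <- function(model, n_checks = 6) {
    fw <- opcnn:::nn_forward(model, sm$x1, sm$x2)
    lo <- opcnn:::wbce_loss(as.numeric(fw$logit), sm$y, w)
    gr <- opcnn:::nn_backward(model, fw$cache,
                              matrix(lo$dlogit, length(sm$y), 1))
    loss_of <- function(params) {
      m <- model
      m$params <- params
      f <- opcnn:::nn_forward(m, sm$x1, sm$x2)
      opcnn:::wbce_loss(as.numeric(f$logit), sm$y, w)$loss
    }
    # jitter so no ReLU pre-activation sits exactly at 0
    jitter <- function(p) {
      if (is.null(p)) return(NULL)
      if (is.list(p)) return(lapply(p, jitter))
      p + stats::rnorm(length(p), sd = 0.05)
    }
    model$params <- jitter(model$params)
    fw <- opcnn:::nn_forward(model, sm$x1, sm$x2)
    lo <- opcnn:::wbce_loss(as.numeric(fw$logit), sm$y, w)
    gr <- opcnn:::nn_backward(model, fw$cache,
                              matrix(lo$dlogit, length(sm$y), 1))
    # probe the first weight matrix of each top-level parameter group
    for (grp in names(model$params)) {
      leaf_path <- list()
      node <- model$params[[grp]]
      gnode <- gr[[grp]]
      while (is.list(node)) {
        node_names <- names(node) %||% seq_along(node)
        node <- node[[node_names[[1]]]]
        gnode <- gnode[[node_names[[1]]]]
        leaf_path <- c(leaf_path, list(node_names[[1]]))
      }
      for (i in sample(length(node), min(3, length(node)))) {
        h <- 1e-5
        bump <- function(delta) {
          pp <- model$params
          # walk down and modify entry i of the first leaf
          assign_leaf <- function(x, path, delta) {
            if (length(path) == 0) {
              x[i] <- x[i] + delta
              return(x)
            }
            x[[path[[1]]]] <- assign_leaf(x[[path[[1]]]], path[-1], delta)
            x
          }
          pp[[grp]] <- assign_leaf(pp[[grp]], leaf_path, delta)
          loss_of(pp)
        }
        num <- (bump(h) - bump(-h)) / (2 * h)
        expect_equal(gnode[i], num, tolerance = 1e-4)
      }
    }
  }
  check(build_opcnn(opcnn_config(embed_dim = 3, kernels = 4, head = c(6, 1),
                                 p1 = 4, p2 = 6, seed = 9)))
  check(build_dmnn(dmnn_config("intermediate", "mcf", branch_widths = c(5, 3),
                               head_widths = c(4, 1), mcf_d = 3, mcf_k = 4,
                               p1 = 4, p2 = 6, seed = 4)))
  check(build_dmnn(dmnn_config("early", "tfl", branch_widths = 3,
                               head_widths = c(4, 1), p1 = 4, p2 = 6,
                               seed = 4)))
})

test_that("fit drives training accuracy to 1 on separable data", {
  ds <- make_separable(20)
  model <- build_dmnn(dmnn_config("early", "concat", embed_dim = 8,
                                  head_widths = c(16, 1), p1 = 4, p2 = 6,
                                  seed = 3))
  trained <- fit(model, ds, train_config(learning_rate = 5e-3, epochs = 150,
                                         batch_size = 10, patience = 150,
                                         seed = 4))
  p <- predict_proba(trained, ds)
  expect_equal(as.numeric(p >= 0.5), as.numeric(ds$y))
  expect_true(trained$trained)
  expect_gt(length(trained$history), 10)
})

test_that("unit class weights reproduce unweighted training exactly", {
  ds <- make_separable(16)
  tc1 <- train_config("bce", learning_rate = 1e-3, epochs = 3,
                      batch_size = 8, seed = 6)
  tc2 <- train_config("weighted_bce", class_weights = c(1, 1),
                      learning_rate = 1e-3, epochs = 3, batch_size = 8,
                      seed = 6)
  m <- build_unimodal(unimodal_config("chemical", widths = c(8, 4),
                                      p1 = 4, p2 = 6, seed = 7))
  a <- fit(m, ds, tc1)
  b <- fit(m, ds, tc2)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("training loss is non-increasing for small full-batch steps", {
  ds <- make_separable(12)
  m <- build_unimodal(unimodal_config("chemical", widths = c(8, 4),
                                      p1 = 4, p2 = 6, seed = 8))
  trained <- fit(m, ds, train_config(learning_rate = 1e-4, epochs = 40,
                                     batch_size = 12, patience = 40,
                                     seed = 9))
  expect_true(all(diff(trained$history) < 1e-5))
})

test_that("fit validates inputs", {
  ds <- make_separable(10)
  one_class <- subset_rows(ds, which(ds$y == 1))
  m <- build_unimodal(unimodal_config("chemical", widths = c(4),
                                      p1 = 4, p2 = 6, seed = 1))
  expect_error(fit(m, one_class, train_config(epochs = 1)),
               class = "data_error")
  wrong <- make_separable(10, p1 = 5)
  expect_error(fit(m, wrong, train_config(epochs = 1)),
               class = "dimension_error")
})

test_that("baselines expose seeded, score-producing fits", {
  ds <- make_separable(40)
  rf <- fit_baseline("rf_100", ds, seed = 2)
  p_rf <- predict_proba(rf, ds)
  expect_equal(as.numeric(p_rf >= 0.5), as.numeric(ds$y))
  rf2 <- fit_baseline("rf_100", ds, seed = 2)
  expect_identical(predict_proba(rf2, ds), p_rf)

  sv <- fit_baseline("svm_poly3_C10", ds, seed = 2)
  p_sv <- predict_proba(sv, ds)
  expect_true(all(p_sv > 0 & p_sv < 1))
  expect_gt(roc_auc(p_sv, ds$y), 0.9)

  mj <- fit_baseline("majority", ds, seed = 2)
  expect_equal(predict_proba(mj, ds), rep(mean(ds$y), 40))
  expect_error(fit_baseline("adaboost", ds), regexp = "arg")
})

test_that("model printing and checkpoints round-trip", {
  m <- build_opcnn(opcnn_config(embed_dim = 5, kernels = 3, p1 = 4, p2 = 6,
                                seed = 2))
  expect_output(print(m), "5 fully connected, 9 convolutional")
  ds <- make_separable(6)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(predict_proba(back, ds), predict_proba(m, ds))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_model(bad), class = "data_error")
})
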