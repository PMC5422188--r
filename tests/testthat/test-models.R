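# SVM decision function, training/extraction, model files, trees, rules.

identity_scaler <- function(d) list(mean = rep(0, d), sd = rep(1, d))

test_that("decision function limits: zero distance and infinite distance", {
  m <- svm_model(matrix(c(1, 2), 1, 2), alpha = 1, y = 1, sigma = 1, b = 0,
                 feature_names = c("f1", "f2"), scaler = identity_scaler(2))
  r <- svm_decision(m, c(f1 = 1, f2 = 2))
  expect_equal(r$margin, 1)   # kernel at zero distance = 1
  expect_equal(r$label, 1)

  m2 <- svm_model(matrix(c(1, 2), 1, 2), alpha = 1, y = 1, sigma = 1,
                  b = -0.5, feature_names = c("f1", "f2"),
                  scaler = identity_scaler(2))
  far <- svm_decision(m2, c(f1 = 1e4, f2 = 1e4))
  expect_equal(far$margin, -0.5, tolerance = 1e-12)  # kernel -> 0, margin -> b
  expect_equal(far$label, -1)
})

test_that("an exact zero margin flags no symptom (sign(0) := -1)", {
  m <- svm_model(matrix(0, 1, 1), alpha = 1, y = 1, sigma = 1, b = -1,
                 feature_names = "f", scaler = identity_scaler(1))
  r <- svm_decision(m, c(f = 0))  # kernel 1, margin exactly 0
  expect_equal(r$margin, 0)
  expect_equal(r$label, -1)
})

test_that("missing features raise an input error", {
  m <- svm_model(matrix(0, 1, 2), alpha = 1, y = 1, sigma = 1, b = 0,
                 feature_names = c("f1", "f2"), scaler = identity_scaler(2))
  expect_error(svm_decision(m, c(f1 = 0)), "f2")
})

test_that("decision values match a brute-force double loop and the reference
           trainer on random evaluations", {
  withr::local_seed(10)
  n <- 80; d <- 5
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, paste0("f", 1:d)))
  lab <- X[, 1] + 0.6 * X[, 2] + rnorm(n, sd = 0.4) > 0
  m <- fit_svm(X, lab, C = 2, seed = 1)

  brute <- function(model, x) {
    z <- (x[model$feature_names] - model$scaler$mean) / model$scaler$sd
    acc <- 0
    for (i in seq_len(nrow(model$support_vectors))) {
      d2 <- 0
      for (j in seq_along(z)) d2 <- d2 + (model$support_vectors[i, j] - z[j])^2
      acc <- acc + model$alpha[i] * model$y[i] * exp(-d2 / (2 * model$sigma^2))
    }
    acc + model$b
  }
  Xt <- matrix(rnorm(200 * d), 200, d, dimnames = list(NULL, paste0("f", 1:d)))
  fast <- svm_decision_many(m, Xt)$margin
  for (i in 1:200) {
    x <- setNames(Xt[i, ], colnames(Xt))
    expect_equal(svm_decision(m, x)$margin, unname(brute(m, x)),
                 tolerance = 1e-10)
    expect_equal(fast[i], svm_decision(m, x)$margin, tolerance = 1e-10)
  }

  # label agreement with the reference implementation on the same model
  Z <- sweep(sweep(Xt, 2, m$scaler$mean), 2, m$scaler$sd, "/")
  ours <- svm_decision_many(m, Xt)$label
  refp <- predict(e1071::svm(
    sweep(sweep(X, 2, m$scaler$mean), 2, m$scaler$sd, "/"),
    factor(ifelse(lab, "pos", "neg"), levels = c("pos", "neg")),
    kernel = "radial", gamma = 1 / (2 * m$sigma^2), cost = 2, scale = FALSE),
    Z)
  expect_equal(ours == 1, unname(refp == "pos"))
})

test_that("training is deterministic and reproduces its own predictions", {
  withr::local_seed(11)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  lab <- X[, 1] > 0
  m1 <- fit_svm(X, lab, seed = 5)
  m2 <- fit_svm(X, lab, seed = 5)
  expect_identical(nrow(m1$support_vectors), nrow(m2$support_vectors))
  expect_identical(m1$b, m2$b)
  # linearly separable toy set -> perfect training accuracy
  Xs <- rbind(matrix(rnorm(40, -3), 20, 2), matrix(rnorm(40, 3), 20, 2))
  colnames(Xs) <- c("u", "v")
  ls <- rep(c(FALSE, TRUE), each = 20)
  ms <- fit_svm(Xs, ls, seed = 1)
  expect_equal(svm_decision_many(ms, Xs)$label == 1, ls)
  expect_error(fit_svm(Xs, rep(TRUE, 40)), "both classes")
})

test_that("model files round-trip functionally and reject tampering", {
  withr::local_seed(12)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- fit_svm(X, X[, 1] > 0, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$support_vectors, m$support_vectors)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$scaler$mean, m$scaler$mean)
  Xt <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(svm_decision_many(m2, Xt)$margin,
               svm_decision_many(m, Xt)$margin, tolerance = 1e-12)

  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sigma <- -1
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "sigma")
  obj$sigma <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "missing|version")
})

test_that("margins are continuous in the input", {
  withr::local_seed(13)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  m <- fit_svm(X, X[, 1] > 0, seed = 3)
  x0 <- setNames(rnorm(4), paste0("f", 1:4))
  base <- svm_decision(m, x0)$margin
  for (eps in c(1e-4, 1e-6)) {
    pert <- svm_decision(m, x0 + eps * rnorm(4))$margin
    expect_lt(abs(pert - base), 1e2 * eps * sum(m$alpha) + 1e-12)
  }
})

test_that("decision trees traverse deterministically with ties going left", {
  expect_identical(tree_eval(tree_leaf("on"), c(a = 5)), "on")
  t1 <- tree_node("a", 2, tree_leaf("L"), tree_leaf("R"))
  expect_identical(tree_eval(t1, c(a = 2)), "L")  # tie -> left
  expect_identical(tree_eval(t1, c(a = 2.001)), "R")
  expect_error(tree_eval(t1, c(b = 1)), "'a'")

  # random trees vs an independent recursive evaluator
  ref_eval <- function(tr, x) {
    if (inherits(tr, "tree_leaf")) return(tr$label)
    if (x[[tr$feature]] <= tr$threshold) Recall(tr$left, x)
    else Recall(tr$right, x)
  }
  withr::local_seed(14)
  rand_tree <- function(depth) {
    if (depth == 0 || runif(1) < 0.3) return(tree_leaf(sample(letters, 1)))
    tree_node(sample(c("a", "b", "c"), 1), rnorm(1),
              rand_tree(depth - 1), rand_tree(depth - 1))
  }
  for (i in 1:30) {
    tr <- rand_tree(4)
    x <- c(a = rnorm(1), b = rnorm(1), c = rnorm(1))
    expect_identical(tree_eval(tr, x), ref_eval(tr, x))
  }
})

test_that("threshold rules fire in their stated direction only", {
  r <- threshold_rule("fl", 0.5, "below")
  expect_true(rule_eval(r, c(fl = 0.3)))
  expect_false(rule_eval(r, c(fl = 0.5)))
  expect_false(rule_eval(r, c(fl = 0.7)))
  expect_true(rule_eval(threshold_rule("fl", 0.5, "above"), c(fl = 0.7)))
  expect_error(rule_eval(r, c(other = 1)), "fl")
})

test_that("model memory accessor feeds the budget arithmetic", {
  m <- svm_model(matrix(0, 7, 3), alpha = rep(1, 7), y = rep(1, 7),
                 sigma = 1, b = 0, feature_names = c("a", "b", "c"),
                 scaler = identity_scaler(3))
  expect_identical(model_memory_bytes(m), 7L * 3L * 4L)
})
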