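# independent oracle for the per-task subproblem: generic numerical
# minimizer of the penalized least-squares objective in w with the prior
# held fixed
numeric_ws <- function(F_s, y_s, mu, sigma, lam) {
  obj <- function(w) {
    r <- F_s %*% w - y_s
    sum(r^2) / (2 * lam) +
      0.5 * t(w - mu) %*% solve(sigma) %*% (w - mu)
  }
  stats::optim(rep(0, ncol(F_s)), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))$par
}

test_that("closed-form weight update equals a numerical minimizer (d <= 5)", {
  set.seed(42)
  for (rep in 1:6) {
    d <- sample(2:5, 1)
    n <- sample(6:20, 1)
    F_s <- matrix(rnorm(n * d), n)
    y_s <- sample(c(-1, 1), n, replace = TRUE)
    mu <- rnorm(d)
    sigma <- rand_spd(d, seed = rep)
    lam <- exp(runif(1, -1, 1))
    w_closed <- update_ws(F_s, y_s, mu, sigma, lam)
    w_num <- numeric_ws(F_s, y_s, mu, sigma, lam)
    expect_equal(w_closed, w_num, tolerance = 1e-5)
  }
})

test_that("weight update limits: ridge, prior pull, empty design, least squares", {
  set.seed(7)
  F_s <- matrix(rnorm(30), 10, 3)
  y_s <- rep(c(1, -1), 5)
  # Sigma = I, mu = 0: ridge regression solution
  w <- update_ws(F_s, y_s, rep(0, 3), diag(3), lam = 2)
  ridge <- solve(crossprod(F_s) / 2 + diag(3), crossprod(F_s, y_s) / 2)
  expect_equal(w, as.numeric(ridge), tolerance = 1e-10)
  # lambda -> infinity pulls to the prior mean
  mu <- c(0.3, -0.2, 1)
  expect_equal(update_ws(F_s, y_s, mu, diag(3), lam = 1e12), mu,
               tolerance = 1e-6)
  # zero features return mu exactly
  expect_equal(update_ws(matrix(0, 5, 3), rep(1, 5), mu, diag(3), 1), mu)
  # lambda -> 0 with square full-rank design: least-squares solution
  Fsq <- matrix(rnorm(9), 3) + 2 * diag(3)
  ysq <- c(1, -1, 1)
  expect_equal(update_ws(Fsq, ysq, rep(0, 3), diag(3), lam = 1e-8),
               as.numeric(solve(Fsq, ysq)), tolerance = 1e-5)
  expect_error(update_ws(F_s, y_s, rep(0, 2), diag(2), 1), "shape")
})

test_that("prior update is the mean and divisor-S covariance plus ridge", {
  # hand case: w1 = (1,0), w2 = (-1,0) -> mu = 0, Sigma ~ diag(1, 0) + ridge
  pr <- update_prior(list(c(1, 0), c(-1, 0)))
  expect_equal(pr$mu, c(0, 0))
  expect_equal(pr$sigma[1, 1], 1, tolerance = 1e-5)
  expect_lt(pr$sigma[2, 2], 1e-5)
  expect_gt(pr$sigma[2, 2], 0)
  # identical tasks: scaled-identity ridge only
  pr2 <- update_prior(list(c(1, 2), c(1, 2)))
  expect_equal(pr2$mu, c(1, 2))
  expect_equal(pr2$sigma, diag(2) * pr2$sigma[1, 1], tolerance = 1e-12)
  expect_gt(pr2$sigma[1, 1], 0)
  # permutation symmetry
  ws <- list(c(1, 2), c(0, -1), c(3, 0.5))
  pr3 <- update_prior(ws)
  pr4 <- update_prior(ws[c(3, 1, 2)])
  expect_equal(pr3$mu, pr4$mu)
  expect_equal(pr3$sigma, pr4$sigma)
  # single task: identity prior covariance
  expect_equal(update_prior(list(c(2, 2)))$sigma, diag(2))
})

make_tasks <- function(S = 4, n = 30, d = 3, sep = 2, seed = 1) {
  set.seed(seed)
  w_true <- rnorm(d)
  lapply(seq_len(S), function(s) {
    F_s <- matrix(rnorm(n * d), n)
    y <- ifelse(F_s %*% (w_true + rnorm(d, sd = 0.1)) + rnorm(n, sd = 1 / sep)
                >= 0, 1, -1)
    list(F = F_s, y = as.numeric(y))
  })
}

test_that("objective bookkeeping: empty list, plug-in values, lambda scaling", {
  expect_equal(mtl_objective(list(weights = list(), mu = 0, sigma = diag(1),
                                  lam = 1), list()), 0)
  tasks <- make_tasks(S = 2)
  mu <- c(0.5, -0.5, 0.1)
  model <- list(weights = list(mu, mu), mu = mu, sigma = diag(3), lam = 1)
  # all weights at the prior mean with Sigma = I: only the data term remains
  datafit <- sum(vapply(tasks, function(t)
    sum((t$F %*% mu - t$y)^2), numeric(1)))
  expect_equal(mtl_objective(model, tasks), datafit / 2, tolerance = 1e-12)
  model2 <- model
  model2$lam <- 2
  expect_equal(mtl_objective(model2, tasks), datafit / 4, tolerance = 1e-12)
})

test_that("alternating fit decreases the objective monotonically", {
  for (seed in 1:4) {
    tasks <- make_tasks(S = 5, n = 40, seed = seed)
    fit <- mtl_fit(tasks, lam = 1)
    expect_true(all(diff(fit$history) <= 1e-8 * (abs(fit$history[-length(fit$history)]) + 1)))
  }
})

test_that("identical tasks converge to weights at the shared mean", {
  set.seed(3)
  F_s <- matrix(rnorm(40 * 3), 40)
  y <- rep(c(1, -1), 20)
  tasks <- lapply(1:4, function(s) list(F = F_s, y = y))
  fit <- mtl_fit(tasks, lam = 1)
  for (w in fit$weights)
    expect_equal(w, fit$mu, tolerance = 1e-6)
})

test_that("separable tasks reach high training accuracy", {
  tasks <- make_tasks(S = 5, n = 60, sep = 20, seed = 11)
  fit <- mtl_fit(tasks, lam = 0.1)
  for (s in seq_along(tasks)) {
    pred <- ifelse(tasks[[s]]$F %*% fit$weights[[s]] >= 0, 1, -1)
    expect_gte(mean(pred == tasks[[s]]$y), 0.95)
  }
})

test_that("prediction uses the prior mean with the +1 tie rule", {
  model <- structure(list(weights = list(), mu = c(1, 0), sigma = diag(2),
                          lam = 1), class = "mtl_model")
  F_t <- rbind(c(0.7, 5), c(-0.2, 3))
  expect_equal(mtl_predict(F_t, model), c(1L, -1L))
  expect_equal(mtl_predict(matrix(0, 3, 2), model), rep(1L, 3))
  expect_error(mtl_predict(matrix(0, 2, 3), model), "shape")
})

test_that("model round-trips through the JSON container", {
  tasks <- make_tasks(S = 3)
  fit <- mtl_fit(tasks, lam = 1)
  path <- tempfile(fileext = ".json")
  write_mtl_model(fit, path)
  back <- read_mtl_model(path)
  expect_equal(back$mu, fit$mu)
  expect_equal(back$sigma, fit$sigma)
  expect_equal(back$weights, fit$weights)
  expect_equal(back$lam, fit$lam)
})
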