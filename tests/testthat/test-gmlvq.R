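test_that("angular dissimilarity matches a naive loop computation", {
  # independent oracle: plain three-loop cosine on transformed vectors
  naive <- function(x, w, omega) {
    tx <- numeric(nrow(omega)); tw <- numeric(nrow(omega))
    for (i in seq_len(nrow(omega))) {
      for (j in seq_along(x)) {
        tx[i] <- tx[i] + omega[i, j] * x[j]
        tw[i] <- tw[i] + omega[i, j] * w[j]
      }
    }
    dot <- 0; nx2 <- 0; nw2 <- 0
    for (i in seq_along(tx)) {
      dot <- dot + tx[i] * tw[i]
      nx2 <- nx2 + tx[i]^2
      nw2 <- nw2 + tw[i]^2
    }
    (1 - dot / sqrt(nx2 * nw2)) / 2
  }
  set.seed(101)
  for (rep in 1:200) {
    x <- rnorm(8); w <- rnorm(8); omega <- matrix(rnorm(64), 8, 8)
    expect_equal(angular_dissimilarity(x, w, omega), naive(x, w, omega),
                 tolerance = 1e-12)
  }
})

test_that("angular dissimilarity honors its geometric contracts", {
  set.seed(5)
  x <- rnorm(20); omega <- matrix(rnorm(400), 20, 20)
  expect_equal(angular_dissimilarity(x, x, omega), 0)
  expect_equal(angular_dissimilarity(x, -x, omega), 1)
  expect_equal(angular_dissimilarity(c(1, 0), c(0, 1)), 0.5)
  # scale invariance for positive scalings
  w <- rnorm(20)
  expect_equal(angular_dissimilarity(3.7 * x, 0.2 * w, omega),
               angular_dissimilarity(x, w, omega), tolerance = 1e-12)
  expect_error(angular_dissimilarity(rep(0, 20), x), "degenerate")
  omega0 <- matrix(0, 20, 20)
  expect_error(angular_dissimilarity(x, w, omega0), "degenerate")
})

test_that("compiled cost/gradient core agrees with the R reference", {
  set.seed(77)
  X <- matrix(rnorm(60 * 6), 60, 6)
  y_idx <- rep(1:2, 30)
  W <- rbind(colMeans(X[y_idx == 1, ]) + 0.1,
             colMeans(X[y_idx == 2, ]) - 0.1)
  omega <- matrix(rnorm(36), 6, 6) / 6
  a <- cdlvq:::gmlvq_cost_grad(W, omega, X, y_idx, c(1L, 2L))
  b <- cdlvq:::gmlvq_cost_grad_cpp(W, omega, X, y_idx, c(1L, 2L), TRUE)
  expect_equal(a$cost, b$cost, tolerance = 1e-12)
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  expect_equal(a$gradW, b$gradW, tolerance = 1e-10)
  expect_equal(a$gradOmega, b$gradOmega, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(88)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y_idx <- rep(1:2, 15)
  W <- matrix(rnorm(8, sd = 0.5), 2, 4)
  omega <- matrix(rnorm(16), 4, 4) / 4
  eg <- cdlvq:::gmlvq_cost_grad(W, omega, X, y_idx, c(1L, 2L))
  h <- 1e-6
  numW <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wp[i] <- Wp[i] + h
    Wm <- W; Wm[i] <- Wm[i] - h
    numW[i] <- (cdlvq:::gmlvq_cost_grad(Wp, omega, X, y_idx, c(1L, 2L),
                                        gradients = FALSE)$cost -
                cdlvq:::gmlvq_cost_grad(Wm, omega, X, y_idx, c(1L, 2L),
                                        gradients = FALSE)$cost) / (2 * h)
  }
  expect_equal(eg$gradW, numW, tolerance = 1e-5)
  numO <- omega * 0
  for (i in seq_along(omega)) {
    Op <- omega; Op[i] <- Op[i] + h
    Om <- omega; Om[i] <- Om[i] - h
    numO[i] <- (cdlvq:::gmlvq_cost_grad(W, Op, X, y_idx, c(1L, 2L),
                                        gradients = FALSE)$cost -
                cdlvq:::gmlvq_cost_grad(W, Om, X, y_idx, c(1L, 2L),
                                        gradients = FALSE)$cost) / (2 * h)
  }
  expect_equal(eg$gradOmega, numO, tolerance = 1e-5)
})

test_that("separable antipodal clusters are fit perfectly with mu < 0", {
  dat <- antipodal_clusters(seed = 3)
  fit <- angle_gmlvq(dat, control = quick_control())
  expect_equal(fit$in_sample_wacc, 1.0)
  am <- as.matrix(dat[fit$features])
  eg <- cdlvq:::gmlvq_cost_grad(
    fit$prototypes, fit$omega, am,
    match(dat$group, fit$classes),
    match(fit$prototype_class, fit$classes))
  expect_true(all(eg$mu < 0))
  expect_true(all(eg$mu >= -1 & eg$mu <= 1))
  # held-out data from the same process is also perfectly classified
  new <- antipodal_clusters(seed = 4)
  expect_equal(mean(predict(fit, new) == new$group), 1.0)
})

test_that("training history is non-increasing and relevances normalized", {
  co <- simulate_cohort(small_config(), seed = 41)
  adj <- adjust_features(co, "female")
  fit <- angle_gmlvq(adj, control = quick_control(max_iter = 120))
  expect_true(all(diff(fit$training_history) <= 1e-9))
  rel <- relevance_scores(fit)
  expect_equal(sum(rel), 1, tolerance = 1e-9)
  expect_true(all(rel >= 0))
  expect_named(rel, feature_schema()$feature_id)
  # mu in [-1, 1] always
  am <- as.matrix(adj[fit$features])
  eg <- cdlvq:::gmlvq_cost_grad(fit$prototypes, fit$omega, am,
                                match(adj$group, fit$classes),
                                match(fit$prototype_class, fit$classes))
  expect_true(all(eg$mu >= -1 & eg$mu <= 1))
  # classification correct iff mu < 0
  pred <- predict(fit, am)
  expect_equal(unname(pred == adj$group), unname(eg$mu < 0))
})

test_that("relevance scores follow the diagonal of the relevance matrix", {
  co <- simulate_cohort(small_config(), seed = 42)
  adj <- adjust_features(co, "male")
  fit <- angle_gmlvq(adj, control = quick_control())
  lam <- crossprod(fit$omega)
  expect_equal(unname(relevance_scores(fit)),
               unname(diag(lam) / sum(diag(lam))))
  # uniform transform -> uniform scores; single-column -> degenerate scores
  m <- fit
  m$omega <- diag(20) / sqrt(20)
  expect_equal(unname(diag(crossprod(m$omega)) / 1), rep(0.05, 20))
  o1 <- matrix(0, 20, 20); o1[, 7] <- 1
  l1 <- crossprod(o1)
  s1 <- diag(l1) / sum(diag(l1))
  expect_equal(unname(s1[7]), 1)
  expect_equal(sum(s1[-7]), 0)
})

test_that("label swap yields the same accuracy and relevances", {
  co <- simulate_cohort(small_config(), seed = 43)
  adj <- adjust_features(co, "female")
  swapped <- adj
  swapped$group <- ifelse(adj$group == "CD", "control", "CD")
  f1 <- angle_gmlvq(adj, control = quick_control(max_iter = 80))
  f2 <- angle_gmlvq(swapped, control = quick_control(max_iter = 80))
  expect_equal(f1$in_sample_wacc, f2$in_sample_wacc, tolerance = 1e-6)
  expect_equal(f1$relevance_scores, f2$relevance_scores, tolerance = 1e-6)
})

test_that("prediction is scale invariant and fixes the prototypes", {
  dat <- antipodal_clusters(seed = 6)
  fit <- angle_gmlvq(dat, control = quick_control())
  # prototypes classify as their own class
  expect_equal(unname(predict(fit, fit$prototypes)), fit$prototype_class)
  X <- as.matrix(dat[fit$features])
  expect_equal(predict(fit, X * 10), predict(fit, X))
  row_scaled <- X
  row_scaled[3, ] <- 10 * row_scaled[3, ]
  expect_equal(predict(fit, row_scaled)[3], predict(fit, X)[3])
})

test_that("degenerate prediction rows fall back to the unweighted angle", {
  dat <- antipodal_clusters(seed = 7)
  fit <- angle_gmlvq(dat, control = quick_control())
  # a direction annihilated by omega would be needed; force it by zeroing
  # omega's action on a synthetic row via an exactly-zero feature vector
  X <- as.matrix(dat[fit$features])[1:3, ]
  X[2, ] <- 0
  expect_warning(p <- predict(fit, X), "zero norm")
  expect_equal(attr(p, "degenerate_rows"), 2L)
  expect_equal(p[1], "CD")
})

test_that("planted single-feature signal earns the top relevance score", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 120
    ids <- feature_schema()$feature_id
    X <- matrix(rnorm(n * 20), n, 20)
    grp <- rep(c("CD", "control"), each = n / 2)
    # direction difference on feature 1 only
    X[grp == "CD", 1] <- X[grp == "CD", 1] + 1.5
    X[grp == "control", 1] <- X[grp == "control", 1] - 1.5
    colnames(X) <- ids
    dat <- tibble::as_tibble(X)
    dat$group <- grp
    fit <- angle_gmlvq(dat, control = quick_control(seed = s, max_iter = 150))
    if (which.max(fit$relevance_scores) == 1) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("degenerate training inputs raise named errors", {
  dat <- antipodal_clusters(seed = 8)
  one_class <- dat[dat$group == "CD", ]
  expect_error(angle_gmlvq(one_class, control = quick_control()),
               "two classes")
  tiny <- dat[c(1, 31, 32), ]
  expect_error(angle_gmlvq(tiny, control = quick_control()), ">= 2 samples")
  bad <- dat
  bad$hex_happy[1] <- NA
  expect_error(angle_gmlvq(bad, control = quick_control()), "non-finite")
})

test_that("models serialize to JSON and reload intact", {
  dat <- antipodal_clusters(seed = 9)
  fit <- angle_gmlvq(dat, control = quick_control())
  path <- withr::local_tempfile(fileext = ".json")
  write_gmlvq(fit, path)
  back <- read_gmlvq(path)
  expect_equal(back$prototypes, fit$prototypes, ignore_attr = TRUE)
  expect_equal(back$omega, fit$omega, ignore_attr = TRUE)
  expect_equal(back$relevance_scores, fit$relevance_scores)
  expect_equal(predict(back, as.matrix(dat[fit$features])),
               predict(fit, as.matrix(dat[fit$features])))
})
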