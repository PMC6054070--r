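test_that("response transforms match their closed forms", {
  expect_equal(transform_response(15000, "logit_capped", cap = 30000), 0)
  expect_equal(transform_response(0, "logit_offset"),
               log(0.001 / 0.999), tolerance = 1e-12)
  expect_equal(round(transform_response(0, "logit_offset"), 4), -6.9068)
  expect_equal(transform_response(1, "log"), 0)
  expect_error(transform_response(0, "log"), "x > 0")
  expect_error(transform_response(30000, "logit_capped"), "cap")
  expect_error(transform_response(1.5, "logit_offset"), "logit_offset")
})

test_that("backward elimination keeps real effects and drops noise", {
  set.seed(101)
  n <- 150L
  pool <- factor(rep(1:5, n / 5))
  x <- rnorm(n)
  z <- rnorm(n)
  y <- 2 * x + rnorm(5L)[pool] + rnorm(n)
  d <- data.frame(y, x, z, pool)
  fit <- fit_mixed(y ~ x + z + (1 | pool), d)
  expect_identical(fit$trail$dropped, "z")
  expect_true("x" %in% names(coef(fit)))
  expect_false("z" %in% names(coef(fit)))
  expect_lt(abs(coef(fit)[["x"]] - 2), 0.2)
  # alpha = 1 keeps the full model
  fit_full <- fit_mixed(y ~ x + z + (1 | pool), d, alpha = 1)
  expect_identical(nrow(fit_full$trail), 0L)
  expect_true(all(c("x", "z") %in% names(coef(fit_full))))
})

test_that("interactions are eliminated before their main effects", {
  set.seed(7)
  n <- 120L
  g <- factor(rep(1:4, n / 4))
  x <- rnorm(n)
  w <- rnorm(n)
  y <- 1.5 * x + rnorm(4L)[g] + rnorm(n)
  d <- data.frame(y, x, w, g)
  fit <- fit_mixed(y ~ x * w + (1 | g), d)
  if (nrow(fit$trail) >= 2L)
    expect_identical(fit$trail$dropped[1L], "x:w")
  expect_true("x" %in% names(coef(fit)))
})

test_that("without random effects the fit reduces to least squares", {
  set.seed(3)
  d <- data.frame(x = rnorm(30), z = rnorm(30))
  d$y <- 1 + 3 * d$x + rnorm(30, 0, 0.5)
  fit <- fit_mixed(y ~ x + z, d, alpha = 1)
  X <- cbind(1, d$x, d$z)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-10)
})

test_that("mdmr statistics equal an explicit brute-force computation", {
  set.seed(42)
  n <- 6L
  y <- matrix(rnorm(n * 2L), n)
  m <- as.matrix(dist(y))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  pred <- data.frame(x1 = rnorm(n), x2 = factor(rep(c("u", "v"), 3L)),
                     row.names = rownames(m))
  fit <- mdmr(m, pred, n_permutations = 49L, seed = 1L)

  # independent oracle: element-wise Gower centering and explicit traces
  A <- m^2
  G <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    G[i, j] <- -0.5 * (A[i, j] - mean(A[i, ]) - mean(A[, j]) + mean(A))
  X <- model.matrix(~ x1 + x2, pred)
  Hf <- X %*% solve(t(X) %*% X) %*% t(X)
  tr <- function(M) sum(diag(M))
  omnibus <- tr(Hf %*% G %*% Hf) / tr(G)
  drop_one <- function(cols) {
    Xr <- X[, setdiff(colnames(X), cols), drop = FALSE]
    Hr <- Xr %*% solve(t(Xr) %*% Xr) %*% t(Xr)
    (tr(Hf %*% G %*% Hf) - tr(Hr %*% G %*% Hr)) / tr(G)
  }
  expect_equal(fit$effects$pseudo_r2[1L], omnibus, tolerance = 1e-10)
  expect_equal(fit$effects$pseudo_r2[2L], drop_one("x1"), tolerance = 1e-10)
  expect_equal(fit$effects$pseudo_r2[3L], drop_one("x2v"), tolerance = 1e-10)
})

test_that("mdmr agrees with an independent permutational MANOVA on R2", {
  set.seed(5)
  n <- 12L
  y <- matrix(rnorm(n * 3L), n)
  m <- as.matrix(dist(y))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  pred <- data.frame(x = rnorm(n), g = factor(rep(1:3, 4L)),
                     row.names = rownames(m))
  fit <- mdmr(m, pred, n_permutations = 49L, seed = 2L)
  ado <- vegan::adonis2(as.dist(m) ~ x + g, data = pred, by = NULL,
                        permutations = 19L)
  expect_equal(fit$effects$pseudo_r2[1L], ado$R2[1L], tolerance = 1e-8)
})

test_that("mdmr recovers a perfect predictor and validates its inputs", {
  set.seed(9)
  x <- rnorm(8L)
  m <- as.matrix(dist(x))
  dimnames(m) <- list(paste0("s", 1:8), paste0("s", 1:8))
  fit <- mdmr(m, data.frame(x = x, row.names = rownames(m)),
              n_permutations = 99L, seed = 3L)
  expect_equal(fit$effects$pseudo_r2[1L], 1, tolerance = 1e-10)
  expect_lte(fit$effects$p[1L], 0.05)
  # rank-deficient design errors and names the aliased column
  expect_error(
    mdmr(m, data.frame(x = x, x2 = 2 * x, row.names = rownames(m))),
    "aliased.*x2")
  # p-value granularity and reproducibility under a fixed seed
  fit2 <- mdmr(m, data.frame(x = x, row.names = rownames(m)),
               n_permutations = 99L, seed = 3L)
  expect_identical(fit$effects, fit2$effects)
  expect_gte(min(fit$effects$p), 1 / 100)
})

test_that("mdmr is invariant to joint relabeling of the input rows", {
  set.seed(10)
  n <- 10L
  m <- as.matrix(dist(rnorm(n)))
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  pred <- data.frame(g = factor(rep(c("a", "b"), 5L)), x = rnorm(n),
                     row.names = rownames(m))
  fit <- mdmr(m, pred, n_permutations = 0L)
  perm <- sample.int(n)
  m2 <- m[perm, perm]
  fit2 <- mdmr(m2, pred[perm, , drop = FALSE], n_permutations = 0L)
  expect_equal(fit$effects$pseudo_r2, fit2$effects$pseudo_r2,
               tolerance = 1e-10)
  # relabeling categorical levels leaves pseudo-R2 unchanged
  pred3 <- pred
  levels(pred3$g) <- c("zzz", "aaa")
  fit3 <- mdmr(m, pred3, n_permutations = 0L)
  expect_equal(fit$effects$pseudo_r2, fit3$effects$pseudo_r2,
               tolerance = 1e-10)
})
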