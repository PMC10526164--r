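test_that("the logistic squash matches its closed form", {
  expect_equal(squash(0), 0.5)
  expect_lt(squash(-50), 1e-20)
  expect_equal(squash(2), 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_error(squash(c(1, NA)), "finite")
})

test_that("Bernoulli response sampling is calibrated and validated", {
  expect_identical(sample_responses(rep(0, 20)), rep(0L, 20))
  expect_identical(sample_responses(rep(1, 20)), rep(1L, 20))
  draws <- sample_responses(rep(0.3, 10000), seed = 1)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(mean(draws) - 0.3), 3 * se)
  expect_error(sample_responses(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(sample_responses(c(-0.1)), "\\[0, 1\\]")
})

test_that("hit and false-alarm rates count per class", {
  out <- detection_outcome(probs = rep(0.5, 4), labels = c(1, 1, -1, -1),
                           predictions = c(1, 1, 0, 0))
  r <- hit_false_rates(out)
  expect_equal(r$hit_rate, 1.0)
  expect_equal(r$false_rate, 0.0)

  out2 <- detection_outcome(probs = rep(0.5, 4), labels = c(1, 1, -1, -1),
                            predictions = rep(1, 4))
  expect_equal(unlist(hit_false_rates(out2)), c(hit_rate = 1, false_rate = 1))

  out3 <- detection_outcome(probs = rep(0.5, 6),
                            labels = c(1, 1, 1, -1, -1, -1),
                            predictions = c(1, 0, 1, 0, 1, 0))
  r3 <- hit_false_rates(out3)
  expect_equal(r3$hit_rate, 2 / 3)
  expect_equal(r3$false_rate, 1 / 3)

  out4 <- detection_outcome(probs = rep(0.5, 2), labels = c(1, 1),
                            predictions = c(1, 0))
  expect_error(hit_false_rates(out4), "Catch")
})

test_that("d-prime follows the block-rate arithmetic", {
  # three blocks engineered to give rates (.9,.1), (.8,.2), (1,0):
  # numerator 0.8, sigma = sd(c(.8,.6,1)) = 0.2, d' = 4 (hand-checked)
  mk_block <- function(n_hit, n_fa, block) {
    list(labels = c(rep(1, 10), rep(-1, 10)),
         preds = c(rep(1, n_hit), rep(0, 10 - n_hit),
                   rep(1, n_fa), rep(0, 10 - n_fa)),
         blocks = rep(block, 20))
  }
  parts <- list(mk_block(9, 1, 1), mk_block(8, 2, 2), mk_block(10, 0, 3))
  out <- detection_outcome(
    probs = rep(0.5, 60),
    labels = unlist(lapply(parts, `[[`, "labels")),
    predictions = unlist(lapply(parts, `[[`, "preds")),
    block_ids = unlist(lapply(parts, `[[`, "blocks")))
  dp <- dprime(out)
  expect_equal(dp$hit_rate, 0.9, tolerance = 1e-12)
  expect_equal(dp$false_rate, 0.1, tolerance = 1e-12)
  expect_equal(dp$sigma, 0.2, tolerance = 1e-12)
  expect_equal(dp$dprime, 4, tolerance = 1e-12)
  expect_equal(dp$n_go, 30)
  expect_equal(dp$n_catch, 30)

  # identical hit and false rates in every block -> 0
  out0 <- detection_outcome(probs = rep(0.5, 40),
                            labels = rep(c(1, -1), 20),
                            predictions = rep(c(1, 1, 0, 0), 10),
                            block_ids = rep(1:2, each = 20))
  expect_equal(dprime(out0)$dprime, 0)

  # invariant to relabeling of blocks
  perm <- c(3, 1, 2)
  out_p <- out
  out_p$block_ids <- perm[out$block_ids]
  expect_equal(dprime(out_p)$dprime, dp$dprime, tolerance = 1e-12)

  # doubling the numerator at fixed sigma doubles the index
  expect_equal(dprime(out, fixed_sigma = 0.2)$dprime, 4, tolerance = 1e-12)
  expect_equal(dprime(out0, fixed_sigma = 0.2)$dprime, 0)

  # single block rejected unless sigma is supplied
  out1 <- detection_outcome(probs = rep(0.5, 20), labels = rep(c(1, -1), 10),
                            predictions = rep(0:1, 10),
                            block_ids = rep(1, 20))
  expect_error(dprime(out1), "two blocks")
  expect_silent(dprime(out1, fixed_sigma = 1))
})

test_that("a random responder scores d-prime near zero", {
  set.seed(10)
  n <- 4000
  labels <- rep(c(1, -1), n / 2)
  out <- detection_outcome(probs = rep(0.5, n), labels = labels,
                           predictions = sample_responses(rep(0.5, n)),
                           block_ids = block_assignment(labels, 20))
  expect_lt(abs(dprime(out)$dprime), 0.75)
})

test_that("block assignment spreads both classes over blocks", {
  labels <- rep(c(1, -1), each = 10)
  ids <- block_assignment(labels, 4)
  for (b in 1:4) {
    expect_true(any(labels[ids == b] == 1) && any(labels[ids == b] == -1))
  }
  expect_error(block_assignment(labels, 11), "fewer trials")
})

test_that("response matrices tabulate transitions faithfully", {
  set.seed(2)
  n <- 10000
  pre <- sample.int(8, n, replace = TRUE)
  go <- runif(n) < 0.5
  post <- ifelse(go, ((pre + sample.int(7, n, replace = TRUE) - 1L) %% 8L) + 1L,
                 pre)
  labels <- ifelse(post != pre, 1L, -1L)
  # fixed stochastic responder: p = .8 on change, .2 on repeat
  p_true <- ifelse(labels == 1L, 0.8, 0.2)
  out <- detection_outcome(probs = p_true, labels = labels,
                           predictions = sample_responses(p_true),
                           pre_images = pre, post_images = post)
  rm_ <- response_matrix(out, 8)
  expect_equal(dim(rm_$probs), c(8L, 8L))
  expect_equal(sum(rm_$counts), n)
  off <- rm_$probs[row(rm_$probs) != col(rm_$probs)]
  # cells converge to the responder's true rates (3 binomial SEs at the
  # smallest cell count)
  min_n <- min(rm_$counts[rm_$counts > 0])
  tol <- 3 * sqrt(0.8 * 0.2 / min_n)
  expect_true(all(abs(off - 0.8) < tol, na.rm = TRUE))
  expect_true(all(abs(diag(rm_$probs) - 0.2) < tol))

  # perfect detector: respond iff the image changed
  out_p <- detection_outcome(probs = pmin(pmax(as.numeric(labels == 1L),
                                               0.01), 0.99),
                             labels = labels,
                             predictions = as.numeric(labels == 1L),
                             pre_images = pre, post_images = post)
  rm_p <- response_matrix(out_p, 8)
  expect_true(all(rm_p$probs[row(rm_p$probs) != col(rm_p$probs)] == 1,
                  na.rm = TRUE))
  expect_true(all(diag(rm_p$probs) == 0))

  # never-responder
  out_0 <- detection_outcome(probs = rep(0.01, n), labels = labels,
                             predictions = rep(0, n),
                             pre_images = pre, post_images = post)
  expect_true(all(response_matrix(out_0, 8)$probs == 0, na.rm = TRUE))
})

test_that("symmetric/antisymmetric decomposition is exact", {
  set.seed(3)
  for (i in 1:10) {
    m <- matrix(rnorm(25), 5, 5)
    parts <- sym_antisym(m)
    expect_identical(parts$m_sym, t(parts$m_sym))
    expect_equal(parts$m_antisym, -t(parts$m_antisym))
    expect_equal(parts$m_sym + parts$m_antisym, m)
  }
  expect_error(sym_antisym(matrix(1, 2, 3)), "square")
})

test_that("the asymmetry index matches brute-force norms and its bounds", {
  # purely antisymmetric -> +1
  a <- matrix(c(0, 1, -2, -1, 0, 3, 2, -3, 0), 3, 3)
  expect_equal(asymmetry_index(a)$q, 1)
  # symmetric after centring -> -1
  s <- matrix(c(2, 1, 1, 2), 2, 2)
  expect_equal(asymmetry_index(s)$q, -1)
  # random matrices: oracle arithmetic, bounds, transpose invariance
  set.seed(4)
  for (i in 1:10) {
    m <- matrix(rnorm(9), 3, 3)
    res <- asymmetry_index(m)
    cm <- m - mean(m)
    ns <- sqrt(sum(((cm + t(cm)) / 2)^2))
    na_ <- sqrt(sum(((cm - t(cm)) / 2)^2))
    expect_equal(res$q, (na_ - ns) / (ns + na_), tolerance = 1e-12)
    expect_true(res$q >= -1 && res$q <= 1)
    expect_identical(asymmetry_index(t(m))$q, res$q)
    expect_equal(res$m_sym + res$m_antisym, cm)
  }
  # zero matrix flagged degenerate
  z <- asymmetry_index(matrix(0, 4, 4))
  expect_true(z$degenerate)
  expect_true(is.na(z$q))
  # conventions recorded
  expect_identical(asymmetry_index(a, "norm-diff")$convention, "norm-diff")
  expect_gt(asymmetry_index(a + 5, "classic")$q, 0)
})

test_that("the classical variant behaves sanely and is clearly separate", {
  out <- detection_outcome(probs = rep(0.5, 40), labels = rep(c(1, -1), 20),
                           predictions = rep(c(1, 0), 20))
  expect_gt(dprime_classical(out), 0)
  out_null <- detection_outcome(probs = rep(0.5, 40),
                                labels = rep(c(1, -1), 20),
                                predictions = rep(c(1, 1, 0, 0), 10))
  expect_equal(dprime_classical(out_null), 0)
})
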