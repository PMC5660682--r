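test_that("quantile normalization leaves identical columns unchanged", {
  m <- matrix(c(3, 1, 2, 3, 1, 2), ncol = 2)
  expect_equal(quantile_normalize(m), m)
})

test_that("quantile normalization matches the sort-average oracle on a 3x2 matrix", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), ncol = 2)
  ## oracle: reference = row means of the two sorted columns
  ref <- rowMeans(cbind(sort(m[, 1]), sort(m[, 2])))
  got <- quantile_normalize(m)
  expect_equal(got[, 1], ref[rank(m[, 1])])
  expect_equal(got[, 2], ref[rank(m[, 2])])
})

test_that("normalized columns share identical value multisets", {
  set.seed(41)  # test-local randomness, not package state
  m <- matrix(rnorm(200), 40, 5)
  q <- quantile_normalize(m)
  for (j in 2:5) expect_equal(sort(q[, 1]), sort(q[, j]))
  ## ties: tied inputs receive the mean of the tied target values
  m2 <- matrix(c(1, 1, 5, 2, 3, 4), ncol = 2)
  q2 <- quantile_normalize(m2)
  expect_equal(q2[1, 1], q2[2, 1])
  expect_equal(q2[1, 1], mean(sort(q2[, 2])[1:2]))
})

test_that("quantile normalization agrees with limma on complete tie-free input", {
  skip_if_not_installed("limma")
  set.seed(8)
  m <- matrix(rnorm(600), 60, 10)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-12)
})

test_that("monotone per-column transforms only move the target distribution, not ranks", {
  set.seed(9)
  m <- matrix(rnorm(150), 30, 5)
  m2 <- m
  m2[, 1] <- exp(m2[, 1])
  m2[, 3] <- m2[, 3]^3
  q1 <- quantile_normalize(m)
  q2 <- quantile_normalize(m2)
  ## within-column ordering is untouched by the transform (the reference
  ## vector itself depends on all columns, so values shift together)
  for (j in 1:5) expect_equal(rank(q1[, j]), rank(q2[, j]))
  ## untransformed columns map to the same ranks of the shared reference
  expect_equal(order(q1[, 2]), order(q2[, 2]))
})

test_that("missing cells stay missing and all-missing columns are named in errors", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  m[c(1, 5), 2] <- NA
  q <- quantile_normalize(m)
  expect_true(all(is.na(q[c(1, 5), 2])))
  expect_false(anyNA(q[-c(1, 5), 2]))
  m[, 3] <- NA
  expect_error(quantile_normalize(m), "s3")
})

test_that("remove_pcs with n_pc = 0 centers and does nothing else", {
  m <- matrix(rnorm(60), 6, 10)
  out <- remove_pcs(m, 0)
  expect_equal(out$matrix, m - rowMeans(m))
  expect_equal(out$report$n_pc, 0L)
})

test_that("a rank-1 matrix is annihilated by removing one component", {
  set.seed(2)
  m <- outer(rnorm(30), rnorm(12))
  out <- remove_pcs(m, 1)
  expect_lt(max(abs(out$matrix)), 1e-8)
})

test_that("remove_pcs matches the truncated-reconstruction oracle", {
  set.seed(3)
  m <- matrix(rnorm(1000), 50, 20)
  out <- remove_pcs(m, 3)
  ## oracle: subtract the rank-3 SVD reconstruction of the centered matrix
  mc <- m - rowMeans(m)
  sv <- svd(mc)
  recon <- sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% t(sv$v[, 1:3])
  expect_lt(max(abs(out$matrix - (mc - recon))), 1e-8)
  expect_true(all(diff(out$report$var_explained) <= 1e-12))
  expect_true(all(out$report$var_explained >= 0 &
                    out$report$var_explained <= 1))
  ## residuals orthogonal to the removed components
  expect_lt(max(abs(out$matrix %*% sv$v[, 1:3])), 1e-8)
})

test_that("re-projecting out the same components is idempotent", {
  set.seed(4)
  m <- matrix(rnorm(600), 30, 20)
  out <- remove_pcs(m, 3)
  V <- out$report$basis
  ## projecting the residuals onto the removed subspace again changes
  ## nothing: they are already orthogonal to it
  reproj <- out$matrix - out$matrix %*% V %*% solve(crossprod(V), t(V))
  expect_lt(max(abs(out$matrix - reproj)), 1e-8)
})

test_that("n_pc >= sample count is rejected and NAs are restored", {
  m <- matrix(rnorm(50), 10, 5)
  expect_error(remove_pcs(m, 5), "smaller than")
  m[2, 3] <- NA
  out <- remove_pcs(m, 1)
  expect_true(is.na(out$matrix[2, 3]))
  expect_false(anyNA(out$matrix[-2, ]))
})

test_that("protecting the environment keeps the treated/control contrast", {
  set.seed(6)
  E <- rep(c(0, 1), each = 10)
  ## phenotypes whose leading structure IS the environment effect
  m <- outer(rnorm(40, sd = 2), E - 0.5) + matrix(rnorm(800, sd = 0.2),
                                                  40, 20)
  plain <- remove_pcs(m, 1)$matrix
  prot <- remove_pcs(m, 1, protect = E)$matrix
  contrast <- function(x) mean(abs(rowMeans(x[, E == 1]) -
                                     rowMeans(x[, E == 0])))
  expect_lt(contrast(plain), 0.1 * contrast(m - rowMeans(m)))
  expect_gt(contrast(prot), 0.9 * contrast(m - rowMeans(m)))
})
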