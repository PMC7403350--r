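test_that("selectivity d' follows the standardized mean difference", {
  expect_equal(selectivity_dprime(c(1, 2, 3), c(1, 2, 3)), 0)
  # mu_x = 2, mu_y = 1, sd_x = sd_y = 1 -> 1
  x <- c(1, 2, 3); y <- c(0, 1, 2)
  expect_equal(selectivity_dprime(x, y), 1)
  expect_equal(selectivity_dprime(y, x), -1)   # sign flips under swap
  # invariant to adding a constant to all rates
  expect_equal(selectivity_dprime(x + 7, y + 7), 1)
  expect_error(selectivity_dprime(c(1, 1), c(1, 1)), "variance")
})

test_that("bootstrap selectivity test detects planted effects and rejects
           degenerate inputs", {
  set.seed(4)
  rates <- c(rnorm(120, 0.4), rnorm(120, 0))
  labels <- rep(c(TRUE, FALSE), each = 120)
  r <- bootstrap_selectivity_test(rates, labels, n_boot = 200, seed = 2)
  expect_true(r$significant)
  expect_gt(r$dprime, 0.2)
  expect_error(bootstrap_selectivity_test(rates, labels, n_boot = 1), "n_boot")
  expect_error(bootstrap_selectivity_test(rates[1:3], labels[1:3]), "classes")
})

test_that("bootstrap selectivity test calibrates under its own null", {
  set.seed(9)
  labels <- rep(c(TRUE, FALSE), each = 60)
  resp <- matrix(rnorm(200 * 120), 200)
  tab <- site_selectivity_table(resp, labels, n_boot = 100, seed = 31)
  # 95% binomial band around alpha = 0.05 at n = 200, plus MC slack
  expect_lt(abs(mean(tab$significant) - 0.05), 0.045)
})

test_that("binomial tests for selective fractions and hemispheric bias", {
  expect_equal(selective_fraction_test(0, 100), 1)
  expect_equal(selective_fraction_test(10, 10, p0 = 0.5), 2^-10)
  expect_lt(selective_fraction_test(51, 510, p0 = 0.05), 1e-5)
  # cross-check against the closed-form tail
  expect_equal(selective_fraction_test(51, 510, p0 = 0.05),
               sum(stats::dbinom(51:510, 510, 0.05)), tolerance = 1e-12)

  expect_gt(hemisphere_bias_test(rep(c("left", "right"), 10), 0.5), 0.99)
  p_all <- hemisphere_bias_test(rep("left", 20), 0.5)
  expect_equal(p_all, 2 * 2^-20, tolerance = 1e-10)
  expect_error(hemisphere_bias_test(character(0)), "missing")
})

test_that("sparsity index hits its analytic endpoints and scale invariance", {
  expect_equal(sparsity_index(rep(3, 26)), 0)
  expect_equal(sparsity_index(c(5, rep(0, 25))), 1)
  expect_equal(sparsity_index(c(3, 1)), 0.4)   # A = 0.8, N = 2
  x <- c(4, 1, 0.5, 2)
  expect_equal(sparsity_index(x), sparsity_index(10 * x))
  expect_error(sparsity_index(c(0, 0, 0)), "all-zero")
  expect_error(sparsity_index(5), "length")
})

test_that("sparsity nulls recover the uniform and one-hot extremes", {
  # noise-free uniform site
  resp_u <- matrix(5, 26, 6)
  # add microscopic jitter so the empirical vector is not degenerate
  set.seed(2); resp_u <- resp_u + matrix(rnorm(26 * 6, 0, 1e-6), 26)
  sn_u <- sparsity_nulls(resp_u, n_perm = 50, seed = 3)
  expect_lt(mean(sn_u$null_uniform), 0.01)
  expect_lt(abs(sn_u$SI - mean(sn_u$null_uniform)), 0.01)

  # noise-free one-hot site
  resp_o <- matrix(0, 26, 6); resp_o[7, ] <- 8
  sn_o <- sparsity_nulls(resp_o, n_perm = 50, seed = 4)
  expect_gt(mean(sn_o$null_onehot), 0.99)
  expect_equal(sn_o$SI, 1)

  # broad-tuned noisy population: empirical median SI sits above the uniform
  # null and below the one-hot null
  tens <- fx_tensor()
  sites <- 1:15
  sr <- lapply(sites, function(s)
    sparsity_nulls(site_category_responses(tens, s, "letters"),
                   n_perm = 40, seed = s))
  si <- vapply(sr, `[[`, 0, "SI")
  nu <- do.call(rbind, lapply(sr, `[[`, "null_uniform"))
  no <- do.call(rbind, lapply(sr, `[[`, "null_onehot"))
  t_u <- sparsity_median_test(si, nu, "greater")
  t_o <- sparsity_median_test(si, no, "less")
  expect_lt(t_u$p, 0.05)
  expect_lt(t_o$p, 0.05)
})

test_that("Moran's I matches brute force, known fields and the analytic null", {
  # 10x10 checkerboard, rook adjacency, row-standardized: every neighbour has
  # the opposite value, so I = -1 exactly
  gr <- rep(0:9, each = 10); gc <- rep(0:9, 10)
  cb <- ifelse((gr + gc) %% 2 == 0, 1, -1)
  m <- morans_I(cb, gr, gc, n_perm = 100, seed = 5)
  expect_equal(m$I, -1, tolerance = 1e-12)

  # brute-force evaluation of the formula on a random field
  set.seed(6)
  v <- rnorm(100)
  mi <- morans_I(v, gr, gc, seed = 2)
  w <- outer(seq_along(v), seq_along(v), function(i, j)
    (abs(gr[i] - gr[j]) + abs(gc[i] - gc[j])) == 1) * 1
  w <- w / rowSums(w)
  z <- v - mean(v)
  i_brute <- (length(v) / sum(w)) * sum(w * outer(z, z)) / sum(z^2)
  expect_equal(mi$I, i_brute, tolerance = 1e-12)

  # independent oracle: ape's implementation with the same weights
  if (requireNamespace("ape", quietly = TRUE)) {
    expect_equal(mi$I, ape::Moran.I(v, w)$observed, tolerance = 1e-10)
    expect_equal(m$I, ape::Moran.I(cb, {
      wcb <- outer(1:100, 1:100, function(i, j)
        (abs(gr[i] - gr[j]) + abs(gc[i] - gc[j])) == 1) * 1
      wcb / rowSums(wcb)
    })$observed, tolerance = 1e-10)
  }

  # iid values: permutation null centres on -1/(n-1)
  expect_lt(abs(mean(mi$perm) + 1 / 99), 0.02)

  # two-block field: strong positive autocorrelation, small p
  tb <- ifelse(gc < 5, 1, 0) + rnorm(100, 0, 0.1)
  mb <- morans_I(tb, gr, gc, seed = 3)
  expect_gt(mb$I, 0.5)
  expect_lt(mb$p, 0.02)

  expect_error(morans_I(rep(1, 100), gr, gc), "constant")
})

test_that("array-averaged Moran's I handles multiple partial grids", {
  meta <- data.frame(array_id = rep(1:2, each = 50),
                     grid_row = rep(rep(0:9, each = 5), 2),
                     grid_col = rep(rep(0:4, 10), 2))
  set.seed(8)
  v <- rnorm(100)
  out <- morans_I_arrays(v, meta, n_perm = 100, seed = 2)
  expect_length(out$per_array, 2)
  expect_equal(out$I, mean(out$per_array))
  expect_true(out$p > 0 && out$p <= 1)
})
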