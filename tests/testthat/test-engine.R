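test_that("normalize_rows centers, unit-scales and flags constant rows", {
  ts <- ts_matrix(rbind(c(1, 2, 3), c(5, 5, 5), c(3, 2, 1)))
  nm <- normalize_rows(ts)
  expect_equal(nm$values[1, ], c(-1, 0, 1) / sqrt(2), tolerance = 1e-15)
  expect_identical(nm$degenerate_mask, c(FALSE, TRUE, FALSE))
  expect_identical(nm$values[2, ], c(0, 0, 0))
  expect_equal(sum(nm$values[1, ] * nm$values[3, ]), -1, tolerance = 1e-14)

  # non-degenerate rows: mean 0, unit L2 norm
  ts2 <- random_ts(10, 8, seed = 11)
  nm2 <- normalize_rows(ts2)
  expect_true(all(abs(rowMeans(nm2$values)) < 1e-6))
  expect_true(all(abs(sqrt(rowSums(nm2$values^2)) - 1) < 1e-12))

  # dot products of normalized rows equal the definitional correlation
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    expect_equal(sum(nm2$values[pair[1], ] * nm2$values[pair[2], ]),
                 pcc_direct(ts2$values[pair[1], ], ts2$values[pair[2], ]),
                 tolerance = 1e-12)
  }

  bad <- matrix(c(1, 2, NA, 4), 2, 2)
  expect_error(ts_matrix(bad), class = "blockcor_data_error")
})

test_that("f32 normalization demotes values but keeps the contract", {
  nm <- normalize_rows(random_ts(6, 10, seed = 3), precision = "f32")
  expect_identical(nm$precision_tag, "f32")
  # idempotent demotion means values are exactly f32-representable
  expect_identical(nm$values, demote_single(nm$values))
  expect_true(all(abs(sqrt(rowSums(nm$values^2)) - 1) < 1e-5))
})

test_that("the two correlation formulas agree and handle edge cases", {
  expect_equal(pcc_direct(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc_direct(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pcc_direct(c(1, 0, 0, 1), c(0, 1, 1, 0)), -1)
  expect_equal(pcc_single_pass(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pcc_single_pass(c(0, 1), c(0, 1)), 1)
  expect_true(is.nan(pcc_direct(c(2, 2, 2), c(1, 2, 3))))
  expect_true(is.nan(pcc_single_pass(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pcc_direct(1:3, 1:4), class = "blockcor_invalid_argument")
  expect_error(pcc_single_pass(1:3, 1:4), class = "blockcor_invalid_argument")

  # cross-oracle agreement on random well-conditioned pairs
  set.seed(21)
  devs <- replicate(100, {
    x <- rnorm(32); y <- rnorm(32)
    abs(pcc_direct(x, y) - pcc_single_pass(x, y))
  })
  expect_lt(max(devs), 1e-10)
})

test_that("plan_blocks reproduces the budgeted round recurrence", {
  # hand-traced example: first B = floor(20/10) = 2, then N' = 3 and
  # B = floor(20/6) = 3 clamped to 3
  plan <- plan_blocks(5, 10, 20)
  expect_false(plan$single_round)
  expect_equal(plan$rounds$start, c(0, 2))
  expect_equal(plan$rounds$block_size, c(2, 3))
  expect_equal(plan$rounds$remaining, c(5, 3))
  expect_equal(plan$rounds$out_length, c(7, 3))
  expect_equal(plan$rounds$out_offset, c(0, 7))
  expect_equal(sum(plan$rounds$out_length), triangle_size(5))

  # generous budget: first candidate B = 100 > 5, one round
  plan2 <- plan_blocks(5, 10, 1000)
  expect_true(plan2$single_round)
  expect_equal(nrow(plan2$rounds), 1)
  expect_equal(plan2$rounds$out_length, triangle_size(5))

  expect_error(plan_blocks(100, 10, 199), class = "blockcor_budget_error")
  expect_match(tryCatch(plan_blocks(100, 10, 199), error = conditionMessage),
               "200")
})

test_that("every feasible plan partitions all pairs exactly once", {
  n <- 100
  for (x in c(200, 350, 1000, 4950, 1e6)) {
    plan <- plan_blocks(n, 10, x)
    r <- plan$rounds
    # blocks partition 0..n-1
    expect_equal(r$start[1], 0)
    expect_equal(r$start + r$block_size,
                 c(r$start[-1], n))
    expect_equal(r$remaining, n - r$start)
    # condensed slices tile the array
    expect_equal(r$out_length,
                 r$remaining * r$block_size -
                   r$block_size * (r$block_size + 1) / 2)
    expect_equal(r$out_offset, cumsum(c(0, r$out_length[-nrow(r)])))
    expect_equal(sum(r$out_length), 4950)
    # recurrence: every pair (i, j) falls in exactly the round owning row i
    pairs <- enumerate_pairs(n)
    owner <- findInterval(pairs$i, r$start)
    local_i <- pairs$i - r$start[owner]
    local_j <- pairs$j - r$start[owner]
    np <- r$remaining[owner]
    k <- r$out_offset[owner] + local_i * np - local_i * (local_i + 1) / 2 +
      local_j - local_i - 1
    expect_identical(sort(k), as.numeric(0:4949))
  }
})

test_that("block products are correlation sub-blocks on both backends", {
  ts <- ts_matrix(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)))
  nm <- normalize_rows(ts)
  plan <- plan_blocks(3, 3, 1e4)
  s <- block_products(nm, plan$rounds[1, ])
  expect_equal(s, rbind(c(1, -1, 1), c(-1, 1, -1), c(1, -1, 1)),
               tolerance = 1e-14)

  ts2 <- random_ts(20, 16, seed = 5)
  nm2 <- normalize_rows(ts2)
  plan2 <- plan_blocks(20, 16, 250)   # several rounds
  expect_gt(nrow(plan2$rounds), 1)
  for (r in seq_len(nrow(plan2$rounds))) {
    round <- plan2$rounds[r, ]
    s_blas <- block_products(nm2, round, backend = "blas")
    s_naive <- block_products(nm2, round, backend = "naive")
    expect_equal(s_blas, s_naive, tolerance = 1e-13)
    # diagonal of the local frame is the self-correlation, 1
    for (a in seq_len(round$block_size)) {
      expect_equal(s_blas[a, a], 1, tolerance = 1e-13)
    }
    # entries match the definitional correlation on raw rows
    gi <- round$start + 2   # an arbitrary in-block row (global, 1-based)
    gj <- round$start + round$remaining   # last unfinished column
    if (round$block_size >= 2) {
      expect_equal(s_blas[2, round$remaining],
                   pcc_direct(ts2$values[gi, ], ts2$values[gj, ]),
                   tolerance = 1e-12)
    }
  }
})

test_that("extract_upper_block emits a < b entries in row-major order", {
  # B = 2, N' = 5: pairs (0,1)..(0,4) then (1,2)..(1,4), 7 values
  s <- matrix(seq_len(10), nrow = 2, byrow = TRUE)  # s[a, b] = 5(a-1) + b
  round <- data.frame(start = 0, block_size = 2, remaining = 5,
                      out_offset = 0, out_length = 7)
  expect_equal(extract_upper_block(s, round), c(2, 3, 4, 5, 8, 9, 10))

  # full-triangle round reduces to the whole condensed array
  set.seed(8)
  m <- matrix(rnorm(16), 4, 4)
  round4 <- data.frame(start = 0, block_size = 4, remaining = 4,
                       out_offset = 0, out_length = 6)
  got <- extract_upper_block(m, round4)
  expect_length(got, triangle_size(4))
  pairs <- enumerate_pairs(4)
  expect_equal(got, m[cbind(pairs$i + 1, pairs$j + 1)])

  expect_error(extract_upper_block(m, round),
               class = "blockcor_invalid_argument")
})

test_that("compute_condensed matches the all-pairs oracle at any budget", {
  ts <- ts_matrix(rbind(c(1, 2, 3), c(3, 2, 1), c(1, 2, 3)))
  expect_equal(compute_condensed(ts, 100)$values, c(-1, 1, -1),
               tolerance = 1e-14)

  ts2 <- random_ts(50, 20, seed = 13)
  want <- oracle_condensed(ts2$values)
  got <- compute_condensed(ts2, 500)$values
  expect_lt(max(abs(got - want)), 1e-12)

  # budget invariance: minimal, medium and effectively unbounded budgets
  runs <- lapply(c(2 * 50 + 1, 500, 1e6),
                 function(x) compute_condensed(ts2, x)$values)
  expect_lt(max(abs(runs[[1]] - runs[[2]])), 1e-12)
  expect_lt(max(abs(runs[[2]] - runs[[3]])), 1e-12)
})

test_that("correlations are invariant to positive affine rescaling", {
  ts <- random_ts(12, 25, seed = 17)
  base <- compute_condensed(ts, 1e5)$values
  v2 <- ts$values
  v2[4, ] <- 3.5 * v2[4, ] + 11        # a > 0: unchanged
  expect_lt(max(abs(compute_condensed(ts_matrix(v2), 1e5)$values - base)),
            1e-12)
  v3 <- ts$values
  v3[4, ] <- -2 * v3[4, ] + 1          # a < 0: sign flip on voxel 4's pairs
  flipped <- compute_condensed(ts_matrix(v3), 1e5)$values
  k4 <- pairs_touching(3, 12)
  expect_lt(max(abs(flipped[k4] + base[k4])), 1e-12)
  expect_lt(max(abs(flipped[-k4] - base[-k4])), 1e-12)
})

test_that("identical rows give 1 and outputs stay inside the unit range", {
  ts <- random_ts(15, 30, seed = 23)
  v <- ts$values
  v[9, ] <- v[2, ]
  got <- compute_condensed(ts_matrix(v), 1e5)$values
  expect_equal(got[pair_to_linear(1, 8, 15) + 1], 1, tolerance = 8e-15 * 30)
  eps <- .Machine$double.eps
  expect_true(all(got >= -1 - 4 * eps * 30 & got <= 1 + 4 * eps * 30))
})

test_that("degenerate voxels follow the configured policy", {
  v <- rbind(c(1, 2, 3, 4), c(7, 7, 7, 7), c(4, 3, 2, 1))
  ts <- ts_matrix(v)

  out_nan <- compute_condensed(ts, 1e4, degenerate_policy = "nan")
  expect_identical(out_nan$degenerate_voxels, 1L)
  expect_true(is.nan(out_nan$values[pair_to_linear(0, 1, 3) + 1]))
  expect_true(is.nan(out_nan$values[pair_to_linear(1, 2, 3) + 1]))
  expect_equal(out_nan$values[pair_to_linear(0, 2, 3) + 1], -1,
               tolerance = 1e-14)

  out_zero <- compute_condensed(ts, 1e4, degenerate_policy = "zero")
  expect_identical(out_zero$values[pair_to_linear(0, 1, 3) + 1], 0)

  expect_error(compute_condensed(ts, 1e4, degenerate_policy = "error"),
               class = "blockcor_data_error")
})

test_that("f32 pipeline stays within single-precision tolerance", {
  ts <- random_ts(40, 64, seed = 29)
  want <- oracle_condensed(ts$values)
  for (budget in c(2 * 40 + 5, 1e6)) {
    got <- compute_condensed(ts, budget, precision = "f32")$values
    expect_lt(max(abs(got - want)), 1e-6)
  }
})
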