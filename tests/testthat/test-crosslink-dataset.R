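make_measurements <- function(yields_by_pair, control_yields, total = 100) {
  pair_rows <- do.call(rbind, lapply(names(yields_by_pair), function(id) {
    y <- yields_by_pair[[id]]
    data.frame(pair_id = id, replicate = seq_along(y), band = y * total,
               total = total, condition = "pair", stringsAsFactors = FALSE)
  }))
  ctrl <- data.frame(pair_id = "ctrl", replicate = seq_along(control_yields),
                     band = control_yields * total, total = total,
                     condition = "control", stringsAsFactors = FALSE)
  rbind(pair_rows, ctrl)
}

test_that("crosslinking efficiency is the band/total ratio with clipping", {
  expect_equal(crosslink_efficiency(0, 100), 0)
  expect_equal(crosslink_efficiency(25, 100), 0.25)
  expect_warning(y <- crosslink_efficiency(110, 100), "clipped")
  expect_equal(y, 1)
  expect_error(crosslink_efficiency(10, 0), "total")
  expect_error(crosslink_efficiency(-1, 10), "band")
})

test_that("two-test filter flags a strong pair and matches closed-form p-values", {
  set.seed(11)
  pair_y <- rnorm(3, 0.30, 0.05)
  ctrl_y <- pmax(rnorm(20, 0.02, 0.01), 0)
  m <- make_measurements(list(p1 = pair_y), ctrl_y)
  res <- validate_pairs(m)
  expect_equal(res$verdict, "significant")
  expect_equal(res$n, 3)
  expect_equal(res$yield, mean(pair_y))

  # independent oracle: closed-form pooled and Welch t statistics
  n1 <- 3; n2 <- 20
  sp2 <- ((n1 - 1) * var(pair_y) + (n2 - 1) * var(ctrl_y)) / (n1 + n2 - 2)
  t_pool <- (mean(pair_y) - mean(ctrl_y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_pool <- pt(t_pool, n1 + n2 - 2, lower.tail = FALSE)
  se_w <- sqrt(var(pair_y) / n1 + var(ctrl_y) / n2)
  t_w <- (mean(pair_y) - mean(ctrl_y)) / se_w
  df_w <- se_w^4 / ((var(pair_y) / n1)^2 / (n1 - 1) +
                    (var(ctrl_y) / n2)^2 / (n2 - 1))
  p_w <- pt(t_w, df_w, lower.tail = FALSE)
  expect_equal(res$p_t, p_pool, tolerance = 1e-12)
  expect_equal(res$p_welch, p_w, tolerance = 1e-12)
})

test_that("pairs with fewer than min_n replicates stay untested", {
  m <- make_measurements(list(p1 = c(0.9, 0.95)), rep(0.02, 10))
  res <- validate_pairs(m)
  expect_equal(res$verdict, "untested")
  expect_true(is.na(res$p_t))
})

test_that("verdicts are invariant to replicate ordering", {
  set.seed(4)
  y <- rnorm(5, 0.2, 0.05)
  ctrl <- pmax(rnorm(15, 0.02, 0.01), 0)
  m1 <- make_measurements(list(p1 = y), ctrl)
  m2 <- make_measurements(list(p1 = rev(y)), ctrl)
  m2$replicate[m2$condition == "pair"] <- 5:1
  r1 <- validate_pairs(m1); r2 <- validate_pairs(m2)
  expect_equal(r1$p_t, r2$p_t)
  expect_equal(r1$verdict, r2$verdict)
})

test_that("significance is monotone in effect size", {
  set.seed(8)
  y <- rnorm(3, 0.15, 0.03)
  ctrl <- pmax(rnorm(20, 0.02, 0.01), 0)
  base <- validate_pairs(make_measurements(list(p1 = y), ctrl))
  expect_equal(base$verdict, "significant")
  up <- validate_pairs(make_measurements(list(p1 = y + 0.2), ctrl))
  expect_equal(up$verdict, "significant")
  expect_lte(up$p_t, base$p_t)
})

test_that("degenerate zero-variance samples fall back to comparing means", {
  m_hi <- make_measurements(list(p1 = rep(0.4, 3)), rep(0.02, 10))
  expect_equal(validate_pairs(m_hi)$verdict, "significant")
  m_eq <- make_measurements(list(p1 = rep(0.02, 3)), rep(0.02, 10))
  expect_equal(validate_pairs(m_eq)$verdict, "not-significant")
})

test_that("duplicate replicate indices are rejected", {
  m <- make_measurements(list(p1 = c(0.2, 0.25, 0.3)), rep(0.02, 10))
  m$replicate[m$condition == "pair"] <- c(1, 1, 2)
  expect_error(validate_pairs(m), "duplicate replicate")
})

test_that("summary counts tested, detectable and significant pairs", {
  expect_equal(dataset_summary(NULL),
               c(tested = 0L, detectable = 0L, significant = 0L))
  set.seed(12)
  ctrl <- pmax(rnorm(20, 0.02, 0.01), 0)
  yl <- c(lapply(1:5, function(i) rnorm(3, 0.4, 0.03)),
          lapply(1:3, function(i) pmax(rnorm(3, 0.02, 0.01), 0)))
  names(yl) <- paste0("p", 1:8)
  res <- validate_pairs(make_measurements(yl, ctrl))
  s <- dataset_summary(res)
  expect_equal(unname(s["significant"]), 5L)
  expect_equal(unname(s["tested"]), 8L)
  expect_gte(s["detectable"], s["significant"])
})

test_that("type-I error of the combined filter stays below the stricter threshold", {
  # 2,000 null pairs in batches with fresh controls; the full 10,000-pair
  # calibration runs in the acceptance suite
  set.seed(100)
  n_false <- 0L
  n_pairs <- 0L
  for (batch in 1:100) {
    ctrl <- pmax(rnorm(20, 0.02, 0.01), 0)
    yl <- lapply(1:20, function(i) pmax(rnorm(3, 0.02, 0.01), 0))
    names(yl) <- paste0("p", 1:20)
    res <- validate_pairs(make_measurements(yl, ctrl))
    n_false <- n_false + sum(res$verdict == "significant")
    n_pairs <- n_pairs + nrow(res)
  }
  phat <- n_false / n_pairs
  expect_lte(phat, 0.02 + 3 * sqrt(0.02 * 0.98 / n_pairs))
})

test_that("blot tables round trip through files", {
  sim <- simulate_blot_table(c(a = 0.3, b = 0.02), seed = 6)
  f <- tempfile(fileext = ".tsv")
  write.table(sim$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_blot_table(f)
  expect_equal(nrow(tab), nrow(sim$table))
  res <- validate_pairs(tab)
  expect_equal(nrow(res), 2)
  f2 <- tempfile(fileext = ".tsv")
  write_pairs(res, f2)
  expect_true(file.exists(f2))
})
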