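test_that("COMFORT totals span 6-30 and sum the items", {
  expect_equal(validate_and_total(rep(1L, 6))$total, 6)
  expect_equal(validate_and_total(rep(5L, 6))$total, 30)
  expect_equal(validate_and_total(c(1, 2, 3, 4, 5, 5))$total, 20)
})

test_that("out-of-range or malformed items are rejected with diagnostics", {
  expect_error(validate_and_total(c(0, 2, 3, 4, 5, 5)), "alertness=0")
  expect_error(validate_and_total(c(1, 2, 3, 4, 5, 6)), "out of the 1-5")
  expect_error(validate_and_total(c(1, 2, 3, 4, 5)), "six")
  expect_error(validate_and_total(c(1.5, 2, 3, 4, 5, 5)), "integers")
})

test_that("the total is strictly increasing in any single item", {
  base <- c(2L, 3L, 2L, 4L, 1L, 3L)
  t0 <- validate_and_total(base)$total
  for (i in 1:6) {
    up <- base; up[i] <- up[i] + 1L
    expect_gt(validate_and_total(up)$total, t0)
  }
})

test_that("comfort_table builds one validated row per episode", {
  tab <- comfort_table(list(rep(2L, 6), rep(4L, 6)), c("cry", "distress"))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$total, c(12, 24))
  expect_named(tab, c("episode", "condition", cs_default("comfort_items"), "total"),
               ignore.order = TRUE)
})
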