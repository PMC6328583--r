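test_that("log2 ratios behave like paired log fold changes", {
  expect_equal(log2_ratio(100, 100), 0)
  expect_equal(log2_ratio(200, 100), 1)
  expect_equal(log2_ratio(100, 800), -3)
  # pseudocount handling for zeros: equal counts still map to 0
  expect_equal(log2_ratio(0, 0), 0)
  expect_equal(log2_ratio(0, 10), log2(0.5 / 10.5))
  expect_error(log2_ratio(-1, 10), class = "myoslice_domain_error")
})

test_that("the OLS trend equals the closed-form least-squares solution", {
  days <- c(8, 14, 24, 35)
  set.seed(42)
  for (i in 1:20) {
    y <- rnorm(4, 0, 3)
    tr <- ols_trend(days, y)
    ref <- lm(y ~ days)
    expect_equal(tr$intercept, unname(coef(ref)[1]), tolerance = 1e-12)
    expect_equal(tr$slope, unname(coef(ref)[2]), tolerance = 1e-12)
    expect_equal(tr$slope_x35, tr$slope * 35)
  }
  # constant ratios: intercept c, zero slope
  tr0 <- ols_trend(days, rep(1.7, 4))
  expect_equal(tr0$intercept, 1.7)
  expect_equal(tr0$slope_x35, 0)
  # shifting all ratios shifts only the intercept
  y <- c(-3.76, -1.52, -2.64, 0.60)
  shifted <- ols_trend(days, y + 2)
  base <- ols_trend(days, y)
  expect_equal(shifted$intercept, base$intercept + 2, tolerance = 1e-12)
  expect_equal(shifted$slope, base$slope, tolerance = 1e-12)

  expect_error(ols_trend(c(8, 8, 8), c(1, 2, 3)),
               class = "myoslice_domain_error")
  expect_error(ols_trend(c(8, 14), c(1, 2, 3)),
               class = "myoslice_domain_error")
})

test_that("worked gene examples reproduce the published regression cells", {
  myh7 <- ols_trend(c(8, 14, 24, 35), c(-3.76, -1.52, -2.64, 0.60))
  expect_equal(myh7$intercept, -4.46, tolerance = 0.01)
  expect_equal(myh7$slope_x35, 4.54, tolerance = 0.01)

  eln <- ols_trend(c(8, 14, 24, 35), c(-2.68, -1.10, -0.75, 2.12))
  expect_equal(eln$intercept, -3.88, tolerance = 0.01)
  expect_equal(eln$slope_x35, 5.67, tolerance = 0.01)

  ryr2 <- ols_trend(c(8, 14, 24, 35), c(-2.57, -1.63, -1.89, -0.73))
  expect_equal(ryr2$slope_x35, 1.98, tolerance = 0.01)
})

test_that("every row of both reference tables is reproduced within 0.02", {
  for (k in 1:2) {
    tab <- myoslice_gene_table(k)
    res <- trend_table(tab)
    res <- res[match(paste(tab$gene, tab$category),
                     paste(res$gene, res$category)), ]
    expect_true(all(abs(res$intercept - tab$intercept) <= 0.02),
                label = sprintf("table %d intercepts", k))
    expect_true(all(abs(res$slope_x35 - tab$slope_x35) <= 0.02),
                label = sprintf("table %d slopes", k))
  }
})

test_that("trend tables classify and sort by the 35-day trend", {
  tab <- trend_table(myoslice_gene_table(2))
  expect_true(!is.unsorted(rev(tab$slope_x35)))
  expect_true(all(tab$trend[tab$slope_x35 >= 1] == "positive"))
  expect_true(all(tab$trend[tab$slope_x35 <= -1] == "negative"))
  expect_true(all(tab$trend[abs(tab$slope_x35) < 1] == "flat"))
  # the strongest positive trend in table 2 is elastin
  expect_equal(tab$gene[1], "ELN")

  empty <- trend_table(myoslice_gene_table(1)[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("intercept", "slope_x35", "trend") %in% names(empty)))
})

test_that("gene tables survive a TSV round trip", {
  tab <- myoslice_gene_table(1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_table(tab, path)
  back <- read_gene_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  bad <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(x = 1, y = 2), bad, sep = "\t", row.names = FALSE)
  expect_error(read_gene_table(bad), class = "myoslice_format_error")
})
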