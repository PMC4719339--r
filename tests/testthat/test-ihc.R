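test_that("segmentation recovers painted surfaces bit-exactly", {
  fields <- simulate_slide_fields(1, stain_area_px = 2000,
                                  nuclei_area_px = 1000, seed = 2)
  fq <- segment_field(fields[[1]]$image)
  expect_identical(fq$S, 2000L)
  expect_identical(fq$N, 1000L)
  expect_equal(fq$ratio, 2.0)
  expect_true(fq$usable)
  # masks coincide with the generator's ground truth
  img <- fields[[1]]$image
  r <- img[, , 1]; b <- img[, , 3]
  lum <- 0.299 * r + 0.587 * img[, , 2] + 0.114 * b
  expect_identical(unname((r - b >= 50) & (lum <= 200)),
                   unname(fields[[1]]$stain_mask))
})

test_that("blank fields are unusable and zero stain means ratio zero", {
  blank <- simulate_slide_fields(1, 0, 0, seed = 1)[[1]]
  fq <- segment_field(blank$image)
  expect_identical(fq$S, 0L)
  expect_identical(fq$N, 0L)
  expect_true(is.na(fq$ratio))
  expect_false(fq$usable)
  nost <- simulate_slide_fields(1, 0, 500, seed = 1)[[1]]
  expect_equal(nost$truth$ratio, 0)
  expect_equal(segment_field(nost$image)$ratio, 0)
  expect_error(segment_field(matrix(0, 4, 4)), "RGB")
})

test_that("5 percent palette jitter keeps recovered surfaces within 10 percent", {
  fields <- simulate_slide_fields(3, 2000, 1000, seed = 6, jitter = 0.05)
  for (f in fields) {
    fq <- segment_field(f$image)
    expect_lt(abs(fq$S - f$truth$S) / f$truth$S, 0.10)
    expect_lt(abs(fq$N - f$truth$N) / f$truth$N, 0.10)
  }
})

test_that("S/N is scale-free under 2x upsampling", {
  f <- simulate_slide_fields(1, 1500, 600, seed = 4)[[1]]
  up <- f$image[rep(1:512, each = 2), rep(1:512, each = 2), ]
  fq <- segment_field(f$image); fq2 <- segment_field(up)
  expect_identical(fq2$S, 4L * fq$S)
  expect_identical(fq2$N, 4L * fq$N)
  expect_equal(fq2$ratio, fq$ratio)
})

test_that("area requests beyond canvas capacity are rejected", {
  expect_error(simulate_slide_fields(1, 512 * 256 + 1, 0, seed = 1),
               "capacity")
  expect_error(simulate_slide_fields(1, -5, 0, seed = 1), ">= 0")
})

test_that("slide aggregation averages usable fields and discards thin slides", {
  fields <- data.frame(S = c(100, 200, 300, 200, 100, 300),
                       N = 100, ratio = c(1, 2, 3, 2, 1, 3), usable = TRUE)
  sq <- quantify_slide(fields)
  expect_equal(sq$mean_ratio, 2.0)
  expect_equal(sq$status, "quantified")
  # all fields unusable: discarded, not an error
  bad <- transform(fields, usable = FALSE)
  expect_equal(quantify_slide(bad)$status, "discarded")
  expect_true(is.na(quantify_slide(bad)$mean_ratio))
  # mixed usability: mean over the usable subset only
  mix <- fields; mix$usable <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  expect_equal(quantify_slide(mix)$mean_ratio, mean(c(1, 2, 3)))
  expect_equal(quantify_slide(mix, min_fields = 4)$status, "discarded")
  expect_error(quantify_slide(fields[0, ]), "at least one")
})

test_that("Mann-Whitney exact p equals enumeration for separated toy groups", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.100)
  expect_equal(res$method, "exact enumeration")
  # base-R exact test agrees in the tie-free case
  expect_equal(res$p_value,
               wilcox.test(c(1, 2, 3), c(4, 5, 6), exact = TRUE)$p.value)
  # identical multisets: U at its null mean, p = 1
  res_id <- mann_whitney(c(2, 5, 9), c(2, 5, 9))
  expect_equal(res_id$statistic, 3^2 / 2)
  expect_equal(res_id$p_value, 1)
})

test_that("exact Mann-Whitney agrees with the rank-sum enumeration oracle, ties included", {
  set.seed(31)
  for (i in 1:12) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, TRUE); y <- sample(1:6, n2, TRUE)  # many ties
    got <- mann_whitney(x, y)
    orc <- mw_oracle(x, y)
    expect_equal(got$statistic, orc$U)
    expect_equal(got$p_value, orc$p, tolerance = 1e-12)
  }
})

test_that("large-sample Mann-Whitney matches a permutation oracle within MC error", {
  set.seed(17)
  x <- rnorm(8, 1); y <- rnorm(8)
  got <- mann_whitney(x, y)
  expect_match(got$method, "normal")
  # 1e5-resample permutation reference
  pooled <- c(x, y); mu <- 32
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  set.seed(18)
  devs <- replicate(1e5, {
    idx <- sample(16, 8)
    abs(u_of(pooled[idx], pooled[-idx]) - mu)
  })
  p_perm <- mean(devs >= abs(got$statistic - mu) - 1e-9)
  expect_lt(abs(got$p_value - p_perm),
            0.01 + 3 * sqrt(p_perm * (1 - p_perm) / 1e5))
  expect_error(mann_whitney(numeric(0), y), "non-empty")
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(23)
  x <- rlnorm(7); y <- rlnorm(9, 0.8)
  f <- function(v) exp(v) + v^3
  r1 <- mann_whitney(x, y); r2 <- mann_whitney(f(x), f(y))
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  g <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  k1 <- kruskal_wallis(g); k2 <- kruskal_wallis(lapply(g, f))
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-12)
})

test_that("Kruskal-Wallis matches the hand-ranked formula and handles degeneracy", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  got <- kruskal_wallis(g)
  # rank-sum formula by hand: ranks 1..6, no ties
  rs <- c(1 + 2, 3 + 4, 5 + 6)
  h <- 12 / (6 * 7) * sum(rs^2 / 2) - 3 * 7
  expect_equal(got$statistic, h, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(h, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # fully tied data: p = 1 by convention
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2), c(2, 2)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, 4:6)), "mann_whitney")
})

test_that("Kruskal-Wallis chi-square p matches a label-permutation oracle", {
  set.seed(41)
  g <- list(rnorm(8), rnorm(8, 0.9), rnorm(8, 0.3))
  got <- kruskal_wallis(g)
  p_perm <- kw_perm_oracle(g, n_perm = 1e4, seed = 42)
  expect_lt(abs(got$p_value - p_perm),
            0.02 + 3 * sqrt(p_perm * (1 - p_perm) / 1e4))
})

test_that("shifted responder groups are detected with high power", {
  rej <- vapply(1:25, function(s) {
    d <- simulate_slide_ratios(seed = s)
    mann_whitney(d$ratio[d$group == "poor"],
                 d$ratio[d$group == "good"])$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.8)
})

test_that("manifest-driven quantification reads fields from disk", {
  tmp <- withr::local_tempdir()
  fields <- simulate_slide_fields(4, 1200, 600, seed = 12)
  paths <- vapply(seq_along(fields), function(i) {
    p <- file.path(tmp, sprintf("f%d.png", i))
    png::writePNG(fields[[i]]$image / 255, p)
    p
  }, character(1))
  manifest <- data.frame(slide_id = c("A", "A", "B", "B"),
                         field_id = 1:4, path = paths,
                         group = "ra")
  out <- quantify_manifest(manifest, min_fields = 2)
  expect_equal(nrow(out), 2)
  expect_equal(out$status, c("quantified", "quantified"))
  expect_equal(out$mean_ratio, c(2, 2), tolerance = 1e-12)
})
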