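test_that("duplicate records resolve to the highest-concentration experiment", {
  rec <- data.frame(
    compound = c("c1", "c1"), cell_line = c("L1", "L1"),
    concentration = c(1, 2), value = c(5, 7)
  )
  expect_equal(unclass(resolve_duplicates(rec))["c1", "L1"], 7)

  # order of records must not matter
  expect_equal(unclass(resolve_duplicates(rec[2:1, ]))["c1", "L1"], 7)

  single <- data.frame(compound = "c1", cell_line = "L1", concentration = 1, value = 3)
  expect_equal(unclass(resolve_duplicates(single))["c1", "L1"], 3)

  # absent pairs are missing
  two <- data.frame(
    compound = c("c1", "c2"), cell_line = c("L1", "L2"),
    concentration = 1, value = c(1, 2)
  )
  m <- resolve_duplicates(two)
  expect_true(is.na(m["c1", "L2"]))

  bad <- data.frame(compound = "c1", cell_line = "L1", concentration = "x", value = 1)
  expect_error(resolve_duplicates(bad), "record 1")
})

test_that("concentration ties keep the last-read record with a warning", {
  tie <- data.frame(
    compound = "c1", cell_line = "L1",
    concentration = c(2, 2), value = c(5, 9)
  )
  expect_warning(m <- resolve_duplicates(tie), "tie")
  expect_equal(unclass(m)["c1", "L1"], 9)

  # equal values: either candidate yields the same downstream binary matrix
  eq <- data.frame(
    compound = "c1", cell_line = paste0("L", 1:10),
    concentration = 1, value = c(1, rep(0, 9))
  )
  dup <- rbind(eq, data.frame(
    compound = "c1", cell_line = "L1", concentration = 1, value = 1
  ))
  b1 <- binarize(zscore_rows(resolve_duplicates(eq)), t = 2)
  suppressWarnings(b2 <- binarize(zscore_rows(resolve_duplicates(dup)), t = 2))
  expect_identical(b1, b2)
})

test_that("row z-scores use the population SD over observed entries", {
  m <- response_matrix(matrix(c(1, rep(0, 9)), 1, 10,
    dimnames = list("c1", paste0("L", 1:10))
  ))
  z <- zscore_rows(m)
  # mean 0.1, population SD 0.3, (1 - 0.1) / 0.3 = 3
  expect_equal(unclass(z)["c1", "L1"], 3.0)
  expect_equal(unname(rowMeans(z)), 0, tolerance = 1e-12)

  # standardized rows are fixed points
  x <- c(-1.2, 0.3, 1.1, -0.5, 0.8)
  x <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zz <- zscore_rows(matrix(x, 1, 5, dimnames = list("r", paste0("L", 1:5))))
  expect_equal(unname(unclass(zz)[1, ]), x, tolerance = 1e-12)

  # degenerate rows become all-missing with a warning
  const <- matrix(2, 1, 4, dimnames = list("flat", paste0("L", 1:4)))
  expect_warning(zc <- zscore_rows(const), "zero variance|fewer than 2")
  expect_true(all(is.na(zc)))
  lone <- matrix(c(1, NA, NA), 1, 3, dimnames = list("lone", paste0("L", 1:3)))
  expect_warning(zl <- zscore_rows(lone), "fewer than 2")
  expect_true(all(is.na(zl)))

  # missing entries stay missing, others computed over observed only
  mm <- matrix(c(1, 0, 0, NA), 1, 4, dimnames = list("r", paste0("L", 1:4)))
  zm <- zscore_rows(mm)
  expect_true(is.na(unclass(zm)[1, 4]))
  expect_false(anyNA(unclass(zm)[1, 1:3]))
})

test_that("thresholding is strict by default, sends missing to 0, is monotone in t", {
  z <- matrix(c(3, 2, 1.9, NA), 1, 4, dimnames = list("r", paste0("L", 1:4)))
  expect_equal(unname(binarize(z, t = 2)[1, ]), c(1L, 0L, 0L, 0L))
  expect_equal(unname(binarize(z, t = 2, strict = FALSE)[1, ]), c(1L, 1L, 0L, 0L))
  for (s in 1:10) {
    zr <- multihit:::with_seed(s, matrix(stats::rnorm(40), 4, 10))
    dimnames(zr) <- list(paste0("r", 1:4), paste0("L", 1:10))
    b_lo <- binarize(zr, t = 1.5)
    b_hi <- binarize(zr, t = 2.5)
    expect_true(all(b_hi <= b_lo)) # raising t never adds a 1
  }
})

test_that("a single elevated value among n equal ones crosses t = 2 iff n >= t^2 + 1", {
  # population SD makes the outlier z equal sqrt(n - 1): enumeration over n
  for (n in 2:30) {
    m <- matrix(c(1, rep(0, n - 1)), 1, n,
      dimnames = list("r", paste0("L", seq_len(n)))
    )
    b <- suppressWarnings(binarize(zscore_rows(m), t = 2))
    expect_equal(sum(b), if (n >= 6) 1L else 0L, info = paste("n =", n))
  }
})

test_that("instances built from binary matrices follow the constraint spec", {
  b <- diag(3)
  dimnames(b) <- list(paste0("d", 1:3), paste0("L", 1:3))
  inst <- build_instance(b, constraint_spec(), k = 3)
  expect_identical(validate_instance(inst), character(0))
  expect_equal(inst$d, 1)
  orc <- brute_min_size(inst)
  expect_equal(orc$size, 3) # three singleton classes need all three drugs

  # all-zero column with alpha >= 1 is flagged, not dropped
  b2 <- b
  b2[, 2] <- 0
  inst2 <- build_instance(b2, constraint_spec(), k = 3)
  expect_match(validate_instance(inst2), "L2", all = FALSE)

  # beta = 0 classes are retained for the kernelization to handle
  spec <- constraint_spec(
    group_of = c(L1 = "target", L2 = "avoid", L3 = "target"),
    bounds = list(target = c(1, Inf), avoid = c(0, 0))
  )
  inst3 <- build_instance(b, spec, k = 2)
  expect_equal(inst3$classes[["L2"]]$beta, 0)
  kern <- kernelize(inst3)
  expect_equal(kern$status, "ok")
  expect_false("d2" %in% kern$instance$drugs) # forbidden member removed

  expect_error(
    build_instance(matrix(2, 1, 1, dimnames = list("a", "b")), constraint_spec(), k = 1),
    "binary"
  )
})

test_that("the thresholding pipeline is deterministic end to end", {
  sc <- screen_matrix(generator_config(seed = 11))
  build <- function() {
    b <- binarize(zscore_rows(resolve_duplicates(sc$records)), t = 2)
    inst <- build_instance(b, constraint_spec(default_bounds = c(0, Inf)), k = 3)
    paste(readLines(write_instance(inst, tempfile(fileext = ".json"))), collapse = "\n")
  }
  expect_identical(build(), build())
})
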