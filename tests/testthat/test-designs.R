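test_that("alternating period sequences interleave washouts as expected", {
  expect_identical(sequence_string(build_sequence(design_spec(4, 10, 10))),
                   "AWBWAWBWAWBWAWB")
  expect_identical(sequence_string(build_sequence(design_spec(1, 40, 0))), "AB")
  expect_identical(sequence_string(build_sequence(design_spec(8, 5, 0))),
                   "ABABABABABABABAB")
})

test_that("randomized sequences keep the label counts and washout placement", {
  spec <- design_spec(4, 10, 10, randomize = TRUE)
  s <- sequence_string(build_sequence(spec, seed = 5L))
  chars <- strsplit(s, "")[[1]]
  expect_equal(sum(chars == "A"), 4L)
  expect_equal(sum(chars == "B"), 4L)
  expect_equal(sum(chars == "W"), 7L)
  # strict alternation treatment / washout: no two adjacent treatments or washouts
  expect_identical(chars[seq(2, 14, by = 2)], rep("W", 7L))
  expect_true(all(chars[seq(1, 15, by = 2)] %in% c("A", "B")))
})

test_that("randomized period orders are uniform over permutations", {
  spec <- design_spec(2, 5, 0, randomize = TRUE)
  orders <- vapply(1:900, function(s)
    sequence_string(build_sequence(spec, seed = s)), "")
  tab <- table(orders)
  expect_equal(length(tab), choose(4, 2))  # all 6 AABB arrangements appear
  expect_gt(chisq.test(tab)$p.value, 1e-4)
})

test_that("trial assembly carves, labels and shifts measurements correctly", {
  x <- as.numeric(1:6)
  spec <- design_spec(1, 3, 0)
  tr <- assemble_trial(x, spec, start = 1L)
  expect_equal(tr$value, x)
  expect_equal(tr$dummy, rep(0:1, each = 3L))
  expect_equal(tr$arm, rep(c("A", "B"), each = 3L))

  spec$effect <- 0.3
  tr2 <- assemble_trial(x, spec, start = 1L)
  expect_equal(tr2$value, x + 0.3 * (1 - tr$dummy))
})

test_that("washout positions are consumed but excluded from the analyzed trial", {
  spec <- design_spec(2, 20, 100)
  expect_equal(required_span(spec), 4 * 20 + 3 * 100)  # 380
  x <- simulate_ar1(380L, 0, seed = 8L)
  tr <- assemble_trial(x, spec, start = 1L)
  expect_equal(nrow(tr), 80L)
  expect_true(all(diff(tr$time) > 0))
  # analyzed positions are exactly the four 20-long treatment blocks
  expected_times <- c(1:20, 121:140, 241:260, 361:380)
  expect_equal(tr$time, expected_times)
  expect_equal(tr$value, x[expected_times])
})

test_that("effect injection is additive on top of the zero-effect carve", {
  x <- simulate_ar1(500L, 0.6, seed = 13L)
  base <- design_spec(2, 20, 30)
  with_eff <- base; with_eff$effect <- 0.3
  t0 <- assemble_trial(x, base, seed = 21L)
  t1 <- assemble_trial(x, with_eff, seed = 21L)
  expect_equal(t1$time, t0$time)
  expect_equal(t1$value, t0$value + 0.3 * (1 - t0$dummy))
})

test_that("a series too short for the design is refused with the required length", {
  spec <- design_spec(2, 20, 100)
  expect_error(assemble_trial(rnorm(100), spec), "380")
})

test_that("trial data survive a CSV round trip", {
  x <- simulate_ar1(400L, 0.4, seed = 3L)
  tr <- assemble_trial(x, design_spec(2, 10, 5), seed = 4L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(tr, path)
  back <- read_trial_csv(path)
  expect_equal(back$time, tr$time)
  expect_equal(back$value, tr$value, tolerance = 1e-12)
  expect_identical(back$arm, tr$arm)
  expect_identical(back$dummy, tr$dummy)
})
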