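# Empirical mode decomposition: extrema, envelopes, sifting, decomposition.

test_that("find_extrema handles the canonical cases", {
  e <- find_extrema(c(0, 1, 0, -1, 0, 1, 0))
  expect_identical(e$maxima_indices, c(2L, 6L))
  expect_identical(e$minima_indices, 4L)

  e2 <- find_extrema(seq(0, 1, length.out = 50)) # monotone ramp
  expect_length(e2$maxima_indices, 0)
  expect_length(e2$minima_indices, 0)

  # plateau contributes its midpoint once (rounded down)
  e3 <- find_extrema(c(0, 1, 1, 0))
  expect_identical(e3$maxima_indices, 2L)
  e4 <- find_extrema(c(0, 1, 1, 1, 0))
  expect_identical(e4$maxima_indices, 3L)

  expect_error(find_extrema(c(1, 2)), "at least 3")
})

test_that("find_extrema agrees with the three-point oracle on noise", {
  set.seed(42)
  x <- rnorm(1000) # continuous noise: no plateaus a.s.
  e <- find_extrema(x)
  o <- extrema_oracle(x)
  expect_identical(e$maxima_indices, o$maxima)
  expect_identical(e$minima_indices, o$minima)
  # interleaving invariant
  all_idx <- sort(c(e$maxima_indices, e$minima_indices))
  kinds <- ifelse(all_idx %in% e$maxima_indices, "M", "m")
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("envelopes hug a sinusoid and interpolate the extrema", {
  fs <- 20; A <- 1.7
  x <- A * sin(2 * pi * 1.5 * seq_len(800) / fs)
  ext <- find_extrema(x)
  env <- envelopes(x, ext)
  interior <- 100:700
  expect_lt(max(abs(env$upper[interior] - A)) / A, 0.02)
  expect_lt(max(abs(env$lower[interior] + A)) / A, 0.02)
  expect_equal(env$upper[ext$maxima_indices], x[ext$maxima_indices],
               tolerance = 1e-12)

  # a single maximum cannot support an envelope: termination condition
  y <- c(dnorm(seq(-3, 3, length.out = 50)))
  expect_error(envelopes(y, find_extrema(y)), class = "emd_termination")
})

test_that("sift converges fast on near-IMFs and strips trends", {
  fs <- 20; t <- seq_len(1200) / fs
  s2 <- sin(2 * pi * 2 * t)
  r1 <- sift(s2)
  expect_gt(cor(r1$imf, s2), 0.99)
  expect_lte(r1$iterations, 5)

  r2 <- sift(s2 + 0.5 * t / max(t)) # linear trend absorbed into local mean
  expect_gt(cor(r2$imf, s2), 0.95)

  # an input with symmetric envelopes is a fixed point after one pass
  r3 <- sift(s2, criterion = "envelope_mean")
  expect_equal(r3$iterations, 1)
  expect_equal(r3$imf, s2, tolerance = 0.05)
})

test_that("decompose reconstructs, separates tones, and is deterministic", {
  fs <- 20; t <- seq_len(1200) / fs
  mix <- sin(2 * pi * 2 * t) + sin(2 * pi * 0.5 * t)
  d <- decompose(mix)
  expect_identical(d$n_imfs, 2L)
  recon <- Reduce(`+`, d$imfs) + d$residue
  expect_lt(max(abs(mix - recon)) / max(abs(mix)), 1e-9)
  expect_gt(cor(d$imfs[[1]], sin(2 * pi * 2 * t)), 0.95)
  expect_gt(cor(d$imfs[[2]] + d$residue, sin(2 * pi * 0.5 * t)), 0.95)

  expect_identical(d, decompose(mix)) # bit-for-bit pure function

  dc <- decompose(rep(3.2, 100))
  expect_identical(dc$n_imfs, 0L)
  expect_identical(dc$residue, rep(3.2, 100))

  expect_error(decompose(c(rnorm(50), NA)), "input error")
  expect_error(decompose(rnorm(5)), "at least 10")
})

test_that("is_imf accepts canonical IMFs and rejects offset oscillations", {
  fs <- 20; t <- seq_len(1200) / fs
  s <- sin(2 * pi * 1.5 * t)
  expect_true(is_imf(s))
  expect_false(is_imf(s + 10)) # many extrema, no zero-crossings
  # postcondition consistency: sift output satisfies the IMF conditions
  for (s in c(8, 21, 34)) {
    set.seed(s)
    expect_true(is_imf(sift(rnorm(1200))$imf))
  }
})

test_that("IMF1 is faster than IMF2 on synthetic EHG windows", {
  recs <- make_mini_records(3, 3, seed = 31)
  zc <- function(x) { s <- sign(x); s <- s[s != 0]; sum(s[-1] != s[-length(s)]) }
  ok <- 0; total <- 0
  for (rec in recs) {
    x <- preprocess_channel(rec, "CH1")
    for (w in segment_windows(x, rec$fs, 60)) {
      d <- decompose(w$samples)
      if (d$n_imfs == 2) {
        total <- total + 1
        if (zc(d$imfs[[1]]) >= zc(d$imfs[[2]])) ok <- ok + 1
      }
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("IMF dump round-trips through CSV", {
  d <- decompose(sin(seq_len(200) / 3) + rnorm(200, sd = 0.1))
  p <- withr::local_tempfile(fileext = ".csv")
  write_imf_csv(d, p)
  tab <- read.csv(p)
  expect_identical(nrow(tab), 200L)
  expect_equal(tab$IMF1, d$imfs[[1]], tolerance = 1e-12)
  expect_equal(tab$residue, d$residue, tolerance = 1e-12)
})
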