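# RMS, sample entropy, mean Teager-Kaiser energy, aggregation, normalization.

test_that("rms matches direct arithmetic and the summation oracle", {
  expect_equal(rms(rep(-2, 50)), 2.0)
  expect_equal(rms(c(3, -4)), sqrt(12.5))
  set.seed(5)
  x <- rnorm(1200)
  expect_equal(rms(x), sqrt(sum(x * x) / length(x)), tolerance = 1e-12)
  expect_error(rms(numeric(0)), "length error")
})

test_that("sample entropy equals the O(n^2) oracle exactly", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(100:400, 1)
    x <- rnorm(n)
    tol <- 0.15 * sd(x)
    o <- sampen_counts_oracle(x, 3, tol)
    got <- ehgemd:::.sampen_counts_cpp(x, 3L, tol)
    expect_identical(got, unname(o)) # identical counts A and B
    if (o["A"] > 0 && o["B"] > 0)
      expect_equal(sample_entropy(x), -log(o[["A"]] / o[["B"]]),
                   tolerance = 1e-15)
  }
})

test_that("sample entropy degenerate and periodic cases", {
  # constant window, absolute tolerance: every template matches, A/B = 1
  expect_equal(sample_entropy(rep(1.5, 50), r = 0.1, r_mode = "absolute"), 0)
  # constant window, SD-relative: zero variance short-circuits to 0
  expect_equal(sample_entropy(rep(2, 50)), 0)
  # strict period 2: every length-3 match extends to length 4
  expect_equal(sample_entropy(rep(c(1, -1), 50)), 0)
  # undefined entropy signals a typed condition, not a made-up number
  expect_error(sample_entropy(c(1, 5, -3, 40, 2, -17, 8, 0, 30, -9),
                              r = 1e-9, r_mode = "absolute"),
               class = "sampen_undefined")
  expect_error(sample_entropy(rnorm(4), m = 3), "length error")
})

test_that("sample entropy is exactly scale invariant with SD-relative r", {
  set.seed(23)
  x <- rnorm(300)
  for (a in c(-3, 0.001, 1e6))
    expect_identical(sample_entropy(a * x), sample_entropy(x))
})

test_that("mtke closed forms", {
  expect_identical(mtke(rep(3.7, 10)), 0)
  expect_identical(mtke(as.numeric(0:99)), 1) # n^2 - (n-1)(n+1) = 1
  A <- 2; w <- 0.5
  x <- A * sin(w * (0:999))
  expect_equal(mtke(x), A^2 * sin(w)^2, tolerance = 1e-6)
  expect_error(mtke(c(1, 2)), "length error")
})

test_that("feature scaling identities hold", {
  set.seed(31)
  x <- rnorm(500)
  a <- -2.5
  expect_equal(rms(a * x), abs(a) * rms(x), tolerance = 1e-12)
  expect_equal(mtke(a * x), a^2 * mtke(x), tolerance = 1e-12)
})

test_that("SampEn ranks noise above a sinusoid", {
  set.seed(77)
  noise <- rnorm(1200)
  tone <- sin(2 * pi * 1.5 * seq_len(1200) / 20)
  expect_gt(sample_entropy(noise), sample_entropy(tone))
})

test_that("a record of identical windows averages to the window features", {
  # period-120 signal, no filtering, no trimming: all 10 windows identical
  fs <- 20
  base <- sin(2 * pi * 2 * seq_len(120) / fs) +
    0.3 * sin(2 * pi * 0.5 * seq_len(120) / fs)
  x <- rep(base, 100) # 1200 samples later split into 6-s windows
  rec <- ehg_record("flat", list(x, x, x), fs,
                    gestation_week_delivery = 40, prefiltered = TRUE)
  fv <- extract_record_features(rec, "CH1", window_seconds = 6,
                                trim_seconds = 0)
  d <- decompose(base)
  one <- c(rms(d$imfs[[1]]), rms(d$imfs[[2]]),
           sample_entropy(d$imfs[[1]]), sample_entropy(d$imfs[[2]]),
           mtke(d$imfs[[1]]), mtke(d$imfs[[2]]))
  expect_equal(unname(fv$values), one[c(1, 2, 3, 4, 5, 6)], tolerance = 1e-12)
  expect_identical(fv$n_windows_averaged, 100L)
})

test_that("record features equal the hand-computed mean over windows", {
  set.seed(41)
  fs <- 20
  x <- rnorm(3 * 1200, sd = 0.05)
  rec <- ehg_record("w3", list(x, x, x), fs,
                    gestation_week_delivery = 33, prefiltered = TRUE)
  fv <- extract_record_features(rec, "CH1", trim_seconds = 0)
  per_win <- sapply(0:2, function(i) {
    w <- x[(i * 1200 + 1):((i + 1) * 1200)]
    d <- decompose(w)
    c(rms(d$imfs[[1]]), rms(d$imfs[[2]]),
      sample_entropy(d$imfs[[1]]), sample_entropy(d$imfs[[2]]),
      mtke(d$imfs[[1]]), mtke(d$imfs[[2]]))
  })
  expect_equal(unname(fv$values), unname(rowMeans(per_win)), tolerance = 1e-12)
  expect_identical(fv$label, "preterm")
})

test_that("preterm records show higher IMF1 Teager energy than term", {
  recs <- make_mini_records(10, 10, seed = 13)
  fm <- extract_dataset_features(recs, "CH1")
  m_pre <- mean(fm$MTKE_IMF1[fm$label == "preterm"])
  m_term <- mean(fm$MTKE_IMF1[fm$label == "term"])
  expect_gt(m_pre, m_term)
})

test_that("normalize_features z-scores columns and guards degeneracy", {
  fm <- make_toy_matrix()
  fm$RMS_IMF1 <- c(1, 2, 3, rep(2, nrow(fm) - 3)) # known small column
  nf <- normalize_features(fm)
  for (cn in c("RMS_IMF1", "MTKE_IMF2")) {
    expect_lt(abs(mean(nf[[cn]])), 1e-9)
    expect_lt(abs(sd(nf[[cn]]) - 1), 1e-9)
  }
  expect_true(attr(nf, "normalized"))

  m3 <- make_toy_matrix(n_term = 2, n_preterm = 1)
  m3$RMS_IMF1 <- c(1, 2, 3)
  expect_equal(normalize_features(m3)$RMS_IMF1, c(-1, 0, 1))

  bad <- make_toy_matrix()
  bad$SampEn_IMF2 <- 1
  expect_error(normalize_features(bad), "SampEn_IMF2")

  # train_only mode: statistics from the training subset only
  tr <- 1:30
  nt <- normalize_features(fm, mode = "train_only", train_idx = tr)
  expect_lt(abs(mean(nt$MTKE_IMF1[tr])), 1e-9)
  expect_lt(abs(sd(nt$MTKE_IMF1[tr]) - 1), 1e-9)
})

test_that("feature tables round-trip through CSV", {
  fm <- make_toy_matrix()
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(fm, p)
  back <- read_feature_table(p)
  expect_equal(back$MTKE_IMF1, fm$MTKE_IMF1, tolerance = 1e-12)
  expect_identical(back$label, fm$label)
  expect_s3_class(back, "feature_matrix")
})
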