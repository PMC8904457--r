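test_that("initial rates recover linear slopes within the window", {
  t <- 0:10
  # exact linear data trips summary.lm's perfect-fit warning; harmless here
  expect_equal(suppressWarnings(initialRate(t, 3.2 * t + 1))$slope, 3.2)
  expect_equal(suppressWarnings(initialRate(t, rep(7, 11)))$slope, 0)
  # only the first 5 minutes are used: later curvature is ignored
  s <- 2 * t; s[t > 5] <- s[t > 5] + 50
  expect_equal(suppressWarnings(initialRate(t, s, window = 5))$slope, 2)
  expect_error(initialRate(c(0, 6, 7), c(0, 1, 2), window = 5), "fewer than 3")
  # noisy recovery: with 6 points in the window the slope/SE ratio is t
  # distributed with 4 df, so the +/- 3 SE coverage is 2*pt(3, 4) - 1;
  # the observed coverage over 1000 seeded replicates must match it to
  # within binomial sampling error
  set.seed(30)
  hits <- vapply(1:1000, function(i) {
    y <- 2 * t + rnorm(11, 0, 0.3)
    fr <- initialRate(t, y)
    abs(fr$slope - 2) <= 3 * fr$se
  }, logical(1))
  coverage <- 2 * pt(3, df = 4) - 1
  expect_lt(abs(mean(hits) - coverage),
            3 * sqrt(coverage * (1 - coverage) / 1000))
})

test_that("noiseless kinetic fits recover the generating parameters exactly", {
  # zero-noise identifiability for all four models, 1e-6 relative
  for (KM in c(7.2, 1.1)) {
    k <- genKinetics(syntheticKineticsSpec(KM = KM, kcat = 0.3,
                                           enzymeConc = 10, noiseSigma = 0),
                     seed = 1)
    d <- averageReplicates(k$mm)
    fit <- fitMichaelisMenten(d$conc, d$rate, enzymeConc = 10)
    expect_equal(fit$KM, KM, tolerance = 1e-6)
    expect_equal(fit$kcat, 0.3, tolerance = 1e-6)
  }
  k <- genKinetics(syntheticKineticsSpec(noiseSigma = 0), seed = 1)
  dki <- averageReplicates(k$ki)
  fki <- fitCompetitiveKi(dki$conc, dki$rate, S = 1, KM = 7.2)
  expect_equal(fki$Ki, 2.0, tolerance = 1e-6)
  # the I = 0 point reproduces the uninhibited rate
  expect_equal(dki$rate[dki$conc == 0], k$truth$v1, tolerance = 1e-12)
  dkd <- averageReplicates(k$kd)
  fkd <- fitBindingKd(dkd$conc, dkd$rate)
  expect_equal(fkd$Kd, 0.09, tolerance = 1e-6)
  expect_equal(fkd$v0, k$truth$v1, tolerance = 1e-6)
  # T = 0 point is the baseline activity
  expect_equal(dkd$rate[dkd$conc == 0], k$truth$v1, tolerance = 1e-12)
})

test_that("flat inhibition series and absurd designs are rejected", {
  expect_error(fitCompetitiveKi(c(0, 1, 2, 4, 8), rep(5, 5), S = 1, KM = 7.2),
               "no inhibition signal")
  expect_error(fitMichaelisMenten(c(0, 1), c(0, 1)), "at least 5")
  expect_error(fitBindingKd(c(1, 2, 3, 4, 5), 1:5), "T = 0")
  # non-saturating titration attaches a warning
  k <- genKinetics(syntheticKineticsSpec(Kd = 50, noiseSigma = 0), seed = 2)
  d <- averageReplicates(k$kd)
  expect_warning(fitBindingKd(d$conc, d$rate), "saturation not approached")
})

test_that("parameter recovery at 2% noise: median relative error below 5%", {
  # 500 seeded replicates on the packaged designs (0-12.5 mM substrate,
  # 0-3 uM titrant, fixed 1 mM substrate for Ki)
  errs <- vapply(1:500, function(r) {
    k <- genKinetics(syntheticKineticsSpec(noiseSigma = 0.02), seed = 5000 + r)
    m <- averageReplicates(k$mm)
    i <- averageReplicates(k$ki)
    d <- averageReplicates(k$kd)
    fm <- fitMichaelisMenten(m$conc, m$rate)
    fi <- fitCompetitiveKi(i$conc, i$rate, S = 1, KM = fm$KM)
    fd <- suppressWarnings(fitBindingKd(d$conc, d$rate))
    c(abs(fm$KM - 7.2) / 7.2, abs(fi$Ki - 2.0) / 2.0,
      abs(fd$Kd - 0.09) / 0.09)
  }, numeric(3))
  med <- apply(errs, 1, median)
  expect_lt(med[1], 0.05)   # KM
  expect_lt(med[2], 0.05)   # Ki
  expect_lt(med[3], 0.05)   # Kd
})

test_that("generated kinetics are deterministic in the seed", {
  a <- genKinetics(syntheticKineticsSpec(), seed = 7)
  b <- genKinetics(syntheticKineticsSpec(), seed = 7)
  c <- genKinetics(syntheticKineticsSpec(), seed = 8)
  expect_identical(a$mm, b$mm)
  expect_identical(a$kd, b$kd)
  expect_false(identical(a$mm$rate, c$mm$rate))
  # zero noise: rates equal the model predictions exactly
  z <- genKinetics(syntheticKineticsSpec(noiseSigma = 0), seed = 1)
  v <- with(z$truth, Vmax * z$mm$conc / (KM + z$mm$conc))
  expect_equal(z$mm$rate, v, tolerance = 1e-12)
})

test_that("reference normalisation yields 100% rows and scale invariance", {
  tab <- data.frame(variant = c("WT", "1", "2"),
                    KM = c(7.2, 1.1, 14.4), kcat = c(0.3, 0.6, 0.3),
                    Ki = c(2, 0.05, 4), fx_rate = c(5, 10, 2.5))
  out <- normalizeToReference(tab)
  expect_equal(out$pct_kcat_over_KM[1], 100)
  expect_equal(out$pct_Ki[1], 100)
  expect_equal(out$pct_fx[1], 100)
  # variant 1: efficiency fold = (0.6/1.1)/(0.3/7.2) = 13.09..
  expect_equal(out$pct_kcat_over_KM[2], 100 * (0.6 / 1.1) / (0.3 / 7.2))
  expect_equal(out$pct_fx[2], 200)
  # a 12.8-fold efficiency gain reads as 1280%
  tab2 <- data.frame(variant = c("WT", "36"), KM = c(7.2, 7.2),
                     kcat = c(0.3, 0.3 * 12.8))
  expect_equal(normalizeToReference(tab2)$pct_kcat_over_KM[2], 1280)
  # multiplying all rates by a constant leaves percentages unchanged
  tabS <- tab; tabS$kcat <- tab$kcat * 3.7; tabS$fx_rate <- tab$fx_rate * 3.7
  outS <- normalizeToReference(tabS)
  expect_equal(outS$pct_kcat_over_KM, out$pct_kcat_over_KM)
  expect_equal(outS$pct_fx, out$pct_fx)
  # both Ki ratio directions are emitted and are reciprocal
  expect_equal(out$pct_Ki * out$pct_Ki_inv, rep(1e4, 3))
  expect_error(normalizeToReference(tab, reference = "nope"), "absent")
})

test_that("heatmap table joins, sorts by loop length, and round trips", {
  lib <- enumerateDeletions(fviiaLoopDefinition())
  v <- variants(lib)
  act <- data.frame(variant = c("WT", as.character(v$index)),
                    KM = c(7.2, rep(5, 39)), kcat = c(0.3, rep(0.4, 39)),
                    Ki = c(2, rep(1, 39)))
  act <- normalizeToReference(act)
  heat <- buildHeatmapTable(act, lib)
  expect_equal(nrow(heat$table), 39L)
  expect_true(all(diff(heat$table$loop_length) <= 0))
  # canonical index is preserved as a column
  expect_setequal(heat$table$index, 1:39)
  # single-variant input: 1 informative row, the rest blank with a message
  act1 <- normalizeToReference(act[act$variant %in% c("WT", "12"), ])
  expect_message(h1 <- buildHeatmapTable(act1, lib), "38")
  expect_equal(sum(!is.na(h1$table$KM)), 1L)
  # TSV round trip preserves the numbers
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(heat$table, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$pct_kcat_over_KM, heat$table$pct_kcat_over_KM)
})
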