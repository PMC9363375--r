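cfgFast <- associationConfig(nPermutations = 100, seed = 1)

test_that("MICe saturates on noiseless functional relationships", {
  x <- seq(0, 1, length.out = 300)
  expect_gte(miceStat(x, x, cfgFast), 0.99)
  expect_gte(miceStat(x, (x - 0.5)^2, cfgFast), 0.99)
})

test_that("MICe stays small under independence", {
  set.seed(10)
  x <- runif(300)
  y <- runif(300)
  expect_lt(miceStat(x, y, cfgFast), 0.2)
})

test_that("constant inputs score zero with a warning", {
  x <- rep(1, 50)
  y <- rnorm(50)
  expect_warning(m <- miceStat(x, y, cfgFast), "constant")
  expect_equal(m, 0)
  expect_warning(t <- ticeStat(x, y, cfgFast), "constant")
  expect_equal(t, 0)
})

test_that("TICe dominates MICe and both are symmetric", {
  set.seed(12)
  for (i in 1:20) {
    x <- rnorm(40)
    y <- 0.5 * x + rnorm(40, 0, runif(1, 0.2, 2))
    expect_gte(ticeStat(x, y, cfgFast), miceStat(x, y, cfgFast))
    expect_equal(miceStat(x, y, cfgFast), miceStat(y, x, cfgFast))
    expect_equal(ticeStat(x, y, cfgFast), ticeStat(y, x, cfgFast))
  }
})

test_that("MICe is invariant under strictly monotone transformations", {
  set.seed(14)
  x <- rnorm(80)
  y <- x^2 + rnorm(80, 0, 0.3)
  base <- miceStat(x, y, cfgFast)
  maps <- list(function(v) exp(v), function(v) v^3, function(v) atan(v),
               function(v) 5 * v - 2, function(v) -v)
  for (i in 1:50) {
    fx <- maps[[sample(length(maps), 1)]]
    fy <- maps[[sample(length(maps), 1)]]
    mono <- miceStat(fx(x), fy(y), cfgFast)
    # -v reverses order; rank-based grids make either direction equivalent
    expect_equal(mono, base, tolerance = 1e-10)
  }
})

test_that("the DP equals exhaustive partition enumeration on small samples", {
  cfgSmall <- associationConfig(maxClumpsFactor = 50, bMax = 6,
                                nPermutations = 100)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(10:15, 1)
    x <- runif(n)
    y <- if (i %% 3 == 0) runif(n) else 0.7 * x + 0.3 * runif(n)
    dp <- hdspeech:::.cpp_mine(x, y, cfgSmall$alphaExponent,
                               cfgSmall$maxClumpsFactor, cfgSmall$bMax)
    oracle <- mineOracle(x, y, 6)
    expect_equal(dp$mice, oracle$mice, tolerance = 1e-10)
    expect_equal(dp$tice, oracle$tice, tolerance = 1e-10)
  }
})

test_that("permutation p-values are approximately uniform under independence", {
  set.seed(23)
  n <- 40
  pvals <- vapply(1:300, function(i) {
    x <- rnorm(n)
    y <- rnorm(n)
    perms <- vapply(1:199, function(j) sample.int(n), integer(n))
    res <- hdspeech:::.cpp_mine_batch(matrix(x, ncol = 1), y, 0.6, 5, 0L,
                                      perms)
    (1 + sum(res$tice_perm[1, ] >= res$tice[1])) / 200
  }, numeric(1))
  d <- max(abs(sort(pvals) - seq_along(pvals) / length(pvals)))
  expect_lt(d, 0.1)
})

test_that("max-statistic correction reduces to the ordinary permutation p for one variable", {
  set.seed(4)
  obs <- c(a = 1.7)
  permMax <- rnorm(500, 1, 0.4)
  expect_equal(maxStatCorrection(obs, permMax)[["a"]],
               (1 + sum(permMax >= 1.7)) / 501)
  # duplicated variables receive identical adjusted p
  obs2 <- c(u = 1.2, v = 1.2)
  p2 <- maxStatCorrection(obs2, permMax)
  expect_equal(p2[["u"]], p2[["v"]])
  expect_error(maxStatCorrection(obs, permMax[1:50]), ">= 100")
})

test_that("striatal volume percentage is scale-invariant arithmetic", {
  expect_equal(striatalVolumePercent(7, 9, 1, 1500), 100 * 17 / 1500)
  expect_equal(striatalVolumePercent(14, 18, 2, 3000),
               striatalVolumePercent(7, 9, 1, 1500))
  expect_error(striatalVolumePercent(-1, 9, 1, 1500), "positive")
  expect_error(striatalVolumePercent(700, 900, 100, 1500), "exceed")
})

test_that("the striatal screen reports one sorted row per variable", {
  co <- defaultCohort()
  vols <- S4Vectors::metadata(co)$volumes
  cd <- as.data.frame(SummarizedExperiment::colData(co))
  first <- which(cd$visit_index == 1)
  idx <- first[match(vols$participant_id, cd$participant_id[first])]
  feats <- t(SummarizedExperiment::assay(co, "features"))[idx, ]
  clin <- cd[idx, c("cuhdrs", "tms", "tfc", "uhdrs_is", "sdmt", "vf",
                    "stroop_word", "stroop_color", "stroop_interference")]
  scr <- striatalScreen(feats, clin, vols$striatal_pct,
                        associationConfig(nPermutations = 199, seed = 2))
  expect_equal(nrow(scr), 60 + 9)
  expect_setequal(scr$variable, c(colnames(feats), colnames(clin)))
  expect_true(all(diff(scr$adjusted_p) >= 0))
  expect_true(all(scr$adjusted_p >= scr$tice_p - 1e-12))
  expect_true(all(scr$mice >= 0 & scr$mice <= 1))
  expect_true(all(abs(scr$pearson_r) <= 1, abs(scr$spearman_rho) <= 1))

  # severity-linked backward silence features reach the top significance tier
  top <- scr$variable[scr$family == "speech" & scr$significant]
  expect_true(all(c("backward__silence_dur_mean", "backward__silence_dur_sd")
                  %in% top))

  # insufficient overlap is an explicit error naming the count
  expect_error(striatalScreen(feats[1:5, ], clin[1:5, ],
                              vols$striatal_pct[1:5], cfgFast),
               "5 participants")
})

test_that("a global-null screen rarely passes any variable", {
  set.seed(77)
  hits <- 0
  for (i in 1:10) {
    X <- matrix(rnorm(20 * 25), 20, 25,
                dimnames = list(NULL, paste0("f", 1:25)))
    y <- rnorm(20)
    scr <- striatalScreen(X, NULL, y,
                          associationConfig(nPermutations = 199,
                                            seed = 100 + i))
    hits <- hits + any(scr$significant)
  }
  expect_lte(hits, 2)
})
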