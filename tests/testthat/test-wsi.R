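# Probability-map assembly, the 50-feature extraction, feature selection,
# and the two slide classifiers.

test_that("map assembly is order-invariant with ND fill and duplicate
           detection", {
  df <- data.frame(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
                   p_nd = c(0.2, 0.1, 0.3, 0.25),
                   p_luad = c(0.5, 0.8, 0.4, 0.25),
                   p_lusc = c(0.3, 0.1, 0.3, 0.5))
  maps <- assembleProbabilityMaps(df)
  expect_identical(dim(classMap(maps, "LUAD")), c(2L, 2L))
  s <- classMap(maps, "ND") + classMap(maps, "LUAD") + classMap(maps, "LUSC")
  expect_lt(max(abs(s - 1)), 1e-9)
  # permuted input order gives identical maps
  maps2 <- assembleProbabilityMaps(df[c(3, 1, 4, 2), ])
  expect_equal(maps, maps2)
  # a missing cell is pure ND
  maps3 <- assembleProbabilityMaps(df[-2, ])
  expect_equal(classMap(maps3, "ND")[1, 2], 1)
  expect_equal(classMap(maps3, "LUAD")[1, 2], 0)
  expect_error(assembleProbabilityMaps(rbind(df, df[1, ])), "duplicate")
})

test_that("feature extraction yields the declared 50-feature vector", {
  # all-zero LUAD and LUSC maps: stats 0, components 0, guarded ratios 1
  z <- ProbabilityMaps(matrix(1, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6))
  f <- extractFeatures(z)
  expect_length(f, 50L)
  expect_identical(names(f), featureNames())
  expect_true(all(f[grepl("^luad|^lusc", names(f))] == 0))
  expect_true(all(f[grepl("^ratio", names(f))] == 1))
  # a single 7-cell super-threshold region: top-5 sizes (7,0,0,0,0)
  luad <- matrix(0, 6, 6)
  luad[2:4, 2:3] <- 0.8; luad[5, 3] <- 0.8  # 7 cells, 8-connected
  maps <- ProbabilityMaps(1 - luad, luad, matrix(0, 6, 6))
  f2 <- extractFeatures(maps)
  expect_equal(unname(f2[sprintf("luad_cc%d_t50", 1:5)]), c(7, 0, 0, 0, 0))
  expect_equal(unname(f2["luad_pos_count_t50"]), 7)
  expect_equal(unname(f2["luad_mean"]), mean(luad))
  # extraction is deterministic
  expect_identical(f2, extractFeatures(maps))
})

test_that("feature selection ranks by Fisher score with stable ties", {
  set.seed(5)
  n <- 8L
  X <- matrix(rnorm(n * 50, sd = 0.1), n, 50,
              dimnames = list(NULL, featureNames()))
  labels <- rep(c("LUAD", "LUSC"), each = 4)
  # one perfectly separating feature (disjoint supports) must rank first
  X[, "ratio_mass"] <- ifelse(labels == "LUAD", 10, -10) + rnorm(n, sd = 0.01)
  # a feature identical across classes scores 0
  X[, "luad_mean"] <- 1
  sel <- selectFeatures(X, labels, k = 25L)
  expect_length(sel, 25L)
  expect_identical(sel[1], "ratio_mass")
  expect_false("luad_mean" %in% sel)
  expect_error(selectFeatures(X, rep("LUAD", n)), "class")
  # deterministic for fixed input
  expect_identical(sel, selectFeatures(X, labels, k = 25L))
})

test_that("max voting counts argmax patches with the stated tie-breaks", {
  mk <- function(nLuad, nLusc, nNd) {
    n <- nLuad + nLusc + nNd
    luad <- c(rep(0.8, nLuad), rep(0.1, nLusc), rep(0.2, nNd))
    lusc <- c(rep(0.1, nLuad), rep(0.8, nLusc), rep(0.2, nNd))
    nd <- 1 - luad - lusc
    ProbabilityMaps(matrix(nd, 1), matrix(luad, 1), matrix(lusc, 1))
  }
  expect_identical(maxVote(mk(40, 25, 0)), "LUAD")
  expect_identical(maxVote(mk(25, 40, 0)), "LUSC")
  # all cells ND argmax -> count tie -> probability-mass comparison
  allNd <- ProbabilityMaps(matrix(0.6, 2, 2),
                           matrix(0.15, 2, 2), matrix(0.25, 2, 2))
  expect_identical(maxVote(allNd), "LUSC")
  # symmetric swap of the two maps flips the decision
  m <- mk(10, 4, 2)
  swapped <- ProbabilityMaps(classMap(m, "ND"), classMap(m, "LUSC"),
                             classMap(m, "LUAD"))
  expect_identical(c(maxVote(m), maxVote(swapped)), c("LUAD", "LUSC"))
})

test_that("the regression forest obeys its construction and determinism
           contracts", {
  set.seed(6)
  n <- 12L
  X <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, featureNames()))
  labels <- rep(c("LUAD", "LUSC"), each = n / 2)
  X[, 1] <- ifelse(labels == "LUSC", 2, -2) + rnorm(n, sd = 0.2)
  rf <- trainRF(X, labels, seed = 3L)
  expect_identical(rf$forest$ntree, 10L)
  expect_identical(rf$forest$mtry, ceiling(50 / 3))
  # predictions on {0,1} targets stay in [0,1]
  preds <- predict(rf$forest, X)
  expect_true(all(preds >= 0 & preds <= 1))
  # training-set predictions track the labels on separable data
  expect_gt(cor(preds, ifelse(labels == "LUSC", 1, 0)), 0.5)
  # bit-for-bit determinism under the seed
  rf2 <- trainRF(X, labels, seed = 3L)
  expect_identical(predict(rf2$forest, X), preds)
  # threshold convention: >= threshold is LUSC
  fake <- rf
  expect_identical(rfClassify(rf, X[1, ], threshold = 0),
                   "LUSC")  # any output >= 0
  expect_error(trainRF(X[1:4, ], labels[c(1, 1, 1, 1)]), "class")
  expect_error(trainRF(X[1:4, ], labels[c(1, 2, 7, 8)]), "6 slides")
})

test_that("slide classification composes maps, features and models", {
  set.seed(9)
  rows <- do.call(rbind, lapply(sprintf("s%02d", 1:8), function(s) {
    luad <- if (as.integer(substring(s, 2)) %% 2) 0.7 else 0.15
    data.frame(slide = s, row = rep(0:2, each = 3), col = rep(0:2, 3),
               p_nd = 0.1, p_luad = luad + rnorm(9, sd = 0.02),
               p_lusc = 0.9 - luad - rnorm(9, sd = 0.02))
  }))
  rows$p_nd <- 1 - rows$p_luad - rows$p_lusc
  truth <- ifelse(seq_len(8) %% 2 == 1, "LUAD", "LUSC")
  mv <- classifySlides(rows, "maxvote")
  expect_identical(mv$label, truth)
  feats <- t(vapply(unique(rows$slide), function(s)
    extractFeatures(assembleProbabilityMaps(rows[rows$slide == s, ])),
    numeric(50)))
  rf <- trainRF(feats, truth, seed = 1L)
  out <- classifySlides(rows, "rf", model = rf)
  expect_identical(out$label, truth)
  expect_error(classifySlides(rows, "rf"), "model")
})
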