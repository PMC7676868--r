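test_that("the zero-corruption oracle labels blobs with their true composition", {
  cs <- colonyCase()
  gt <- groundTruth(cs$sim)
  for (v in seq_len(nTracklets(cs$graph))) {
    b <- trackletBlobs(cs$graph)[[v]]
    for (j in seq_len(nrow(b))) {
      mem <- gtMembers(cs$graph, gt, v, j)
      want <- if (length(mem) == 0) "unknown"
              else if (length(mem) > 1) "multi" else mem
      expect_identical(b$blobLabel[j], want)
    }
  }
})

test_that("tracklet aggregation follows the plurality rule with the stated confidence", {
  g <- motifAbstractGraph()
  # unanimous: 5 blobs "GO" at score 0.99
  g@blobs[[1]]$blobLabel <- rep("GO", 5)
  g@blobs[[1]]$blobScore <- rep(0.99, 5)
  # contradiction: 3 "GO" vs 2 "BG"
  g@blobs[[2]]$blobLabel <- c("GO", "GO", "GO", "BG", "BG")
  g@blobs[[2]]$blobScore <- rep(0.99, 5)
  # predominantly multi
  g@blobs[[3]]$blobLabel <- c("multi", "multi", "multi", "GO", "unknown")
  g@blobs[[3]]$blobScore <- rep(1, 5)
  # all unknown
  g@blobs[[4]]$blobLabel <- rep("unknown", 5)
  g@blobs[[4]]$blobScore <- rep(1, 5)
  # tie between two IDs: left unlabeled
  g@blobs[[5]]$blobLabel <- c("GO", "GO", "BG", "BG", "unknown")
  g@blobs[[5]]$blobScore <- rep(0.9, 5)
  g <- classifyTracklets(g)
  nd <- trackletNodes(g)
  expect_equal(nd$label[1], "GO")
  expect_equal(nd$confidence[1], 0.99)
  expect_equal(nd$label[2], "GO")
  expect_equal(nd$confidence[2], 0.99 * (3 - 2) / 5)
  expect_lt(nd$confidence[2], nd$confidence[1])
  expect_equal(nd$kind[3], "multi")
  expect_true(is.na(nd$label[3]))
  expect_equal(nd$kind[4], "unknown")
  expect_equal(nd$kind[5], "single")
  expect_true(is.na(nd$label[5]))
})

test_that("confidence rises with the fraction of agreeing blobs and ignores blob order", {
  conf <- function(labels) {
    g <- makeTrackletGraph(data.frame(start = 1, end = length(labels)))
    g@blobs[[1]]$blobLabel <- labels
    g@blobs[[1]]$blobScore <- rep(1, length(labels))
    trackletNodes(classifyTracklets(g))$confidence[1]
  }
  mix <- function(nA, nB) c(rep("GO", nA), rep("BG", nB))
  confs <- vapply(6:9, function(k) conf(mix(k, 10 - k)), numeric(1))
  expect_true(all(diff(confs) > 0))
  expect_equal(conf(c("BG", "GO", "GO", "BG", "GO")),
               conf(c("GO", "GO", "GO", "BG", "BG")))
})

test_that("the trainable classifier separates IDs, unknown and multi crops", {
  ag <- colonyAgents(8, colors = c("B", "G", "O", "P"), nTags = 2)
  ex <- renderExampleCrops(ag, nPerClass = 18, seed = 11)
  idx <- withr::with_seed(42, sample(nrow(ex)))
  ntr <- floor(0.75 * nrow(ex))
  model <- trainBlobClassifier(ex[idx[1:ntr], ], ids = ag$id, hidden = 20,
                               maxit = 600, seed = 5)
  test <- ex[idx[(ntr + 1):nrow(ex)], ]
  blobs <- data.frame(x = rep(0, nrow(test)), y = 0)
  blobs$crop <- test$crop
  pr <- predictBlobs(model, blobs)
  expect_equal(rowSums(pr), rep(1, nrow(pr)), tolerance = 1e-6)
  lab <- colnames(pr)[max.col(pr)]
  sing <- test$label %in% ag$id
  expect_gt(mean(lab[sing] == test$label[sing]), 0.9)
  expect_gt(mean(lab == test$label), 0.85)
  # deterministic retraining
  model2 <- trainBlobClassifier(ex[idx[1:ntr], ], ids = ag$id, hidden = 20,
                                maxit = 600, seed = 5)
  expect_equal(model$fit$wts, model2$fit$wts)
})

test_that("a missing class in the training set is reported", {
  ag <- colonyAgents(2)
  ex <- renderExampleCrops(ag, nPerClass = 2, seed = 1)
  expect_error(trainBlobClassifier(ex[ex$label != "multi", ], ids = ag$id),
               "missing classes.*multi")
})

test_that("a corrupted oracle has roughly its stated error rate", {
  cs <- colonyCase()
  model <- oracleClassifier(cs$sim, corruption = 0.3, seed = 2)
  gph <- classifyGraphBlobs(cs$graph, model)
  labs0 <- unlist(lapply(trackletBlobs(cs$graph), `[[`, "blobLabel"))
  labs1 <- unlist(lapply(trackletBlobs(gph), `[[`, "blobLabel"))
  ids <- agentTable(cs$sim)$id
  idRows <- labs0 %in% ids
  flipped <- mean(labs0[idRows] != labs1[idRows])
  expect_gt(flipped, 0.2); expect_lt(flipped, 0.4)
})
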