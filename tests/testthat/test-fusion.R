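test_that("weight enumeration matches nested-loop oracles at coarse steps", {
  oracle_enum <- function(step) {
    g <- seq(0L, 100L, by = step)
    out <- list()
    for (w1 in g) for (w2 in g) for (w3 in g) for (w4 in g) {
      if (w1 + w2 + w3 + w4 == 100L) {
        out[[length(out) + 1L]] <- c(w1, w2, w3, w4)
      }
    }
    do.call(rbind, out)
  }
  for (step in c(50L, 25L)) {
    got <- enumerate_weight_vectors(step)
    ref <- oracle_enum(step)
    expect_equal(nrow(got), nrow(ref))
    expect_equal(nrow(got), choose(100L / step + 3L, 3L))  # stars and bars
    got_m <- as.matrix(got)
    dimnames(got_m) <- NULL
    expect_equal(got_m[do.call(order, as.data.frame(got_m)), ],
                 ref[do.call(order, as.data.frame(ref)), ])
  }
  expect_equal(nrow(enumerate_weight_vectors(100L)), 4L)  # only the corners
  expect_true(all(rowSums(as.matrix(enumerate_weight_vectors(20L))) == 100L))
  expect_error(enumerate_weight_vectors(3L), "divisor")
  expect_error(enumerate_weight_vectors(0L), "divisor")
})

test_that("the weighted vote sums weight x confidence per species", {
  rec1 <- tibble::tibble(part = "head", species_id = 7L, confidence = 0.8)
  v <- weighted_vote(rec1, c(100, 0, 0, 0))
  expect_equal(v$species_id, 7L)
  expect_equal(v$score, 0.8)
  # head -> A at 0.9, tail -> B at 0.8, weights (50,0,0,50): A wins 0.45 > 0.40
  rec2 <- tibble::tibble(part = c("head", "tail"), species_id = c(1L, 2L),
                         confidence = c(0.9, 0.8))
  v2 <- weighted_vote(rec2, c(50, 0, 0, 50))
  expect_equal(v2$species_id, 1L)
  expect_equal(v2$score, 0.45)
  # exact tie -> lower species id
  rec3 <- tibble::tibble(part = c("head", "tail"), species_id = c(9L, 3L),
                         confidence = c(0.6, 0.6))
  expect_equal(weighted_vote(rec3, c(50, 0, 0, 50))$species_id, 3L)
  # zero total weight on present parts -> abstention
  expect_true(is.na(weighted_vote(rec1, c(0, 100, 0, 0))$species_id))
  expect_true(is.na(weighted_vote(rec1[0, ], c(25, 25, 25, 25))$species_id))
})

test_that("the vote is order-invariant and scale-invariant in the weights", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    rec <- tibble::tibble(part = sample(part_types(), n),
                          species_id = sample.int(10, n, replace = TRUE),
                          confidence = runif(n))
    w <- runif(4, 0, 100)
    a <- weighted_vote(rec, w)
    b <- weighted_vote(rec[sample.int(n), ], w)
    expect_equal(a$species_id, b$species_id)
    expect_equal(a$score, b$score)
    c_ <- weighted_vote(rec, w * 3)
    expect_equal(a$species_id, c_$species_id)
  }
})

test_that("classification accuracy counts abstentions as errors", {
  truth <- tibble::tibble(image_id = c("a", "b", "c", "d"),
                          species_id = c(1L, 2L, 3L, 4L))
  preds <- tibble::tibble(image_id = c("a", "b", "c", "d"),
                          species_id = c(1L, 2L, 3L, 9L))
  expect_equal(classification_accuracy(preds, truth), 0.75)
  all_na <- dplyr::mutate(preds, species_id = NA_integer_)
  expect_equal(classification_accuracy(all_na, truth), 0)
  expect_equal(classification_accuracy(truth, truth), 1)
  expect_error(
    classification_accuracy(dplyr::mutate(preds, image_id = c("a", "b", "c", "z")),
                            truth),
    "same image set")
})

test_that("grid search maximises accuracy over the enumerated vectors", {
  # one image, one correct record: perfect accuracy
  tab <- tibble::tibble(image_id = "a", part = "head", species_id = 5L,
                        confidence = 0.7)
  truth <- tibble::tibble(image_id = "a", species_id = 5L)
  fr <- grid_search_weights(tab, truth, step_hundredths = 20L)
  expect_equal(fr$best_accuracy, 1)
  expect_equal(fr$n_evaluated, choose(5L + 3L, 3L))
  expect_error(grid_search_weights(tab, truth[0, ], 20L), "empty")

  # planted structure: only heads are ever correct, tails anti-informative
  set.seed(33)
  tbl <- generate_detection_table(150, n_species = 25,
                                  p_part = c(1, 0, 0, 0), dropout = 0,
                                  seed = 77L)
  fr2 <- grid_search_weights(tbl$records, tbl$truth, step_hundredths = 10L)
  head_only <- predict_species(tbl$records, c(100, 0, 0, 0),
                               image_ids = tbl$truth$image_id)
  acc_head <- classification_accuracy(head_only, tbl$truth)
  expect_equal(fr2$best_accuracy, acc_head)
  # argmax property: best is at least as good as any spot-checked vector
  for (w in list(c(25, 25, 25, 25), c(0, 50, 50, 0), c(10, 20, 30, 40))) {
    acc_w <- classification_accuracy(
      predict_species(tbl$records, w, image_ids = tbl$truth$image_id),
      tbl$truth)
    expect_gte(fr2$best_accuracy, acc_w)
  }
  # reported predictions reproduce the reported accuracy
  expect_equal(classification_accuracy(fr2$predictions, tbl$truth),
               fr2$best_accuracy)
})

test_that("fusion results expose tidy/glance summaries", {
  tab <- tibble::tibble(image_id = c("a", "b"), part = c("head", "tail"),
                        species_id = c(1L, 2L), confidence = c(0.9, 0.8))
  truth <- tibble::tibble(image_id = c("a", "b"), species_id = c(1L, 2L))
  fr <- grid_search_weights(tab, truth, step_hundredths = 25L)
  td <- tidy(fr)
  expect_equal(td$part, part_types())
  expect_equal(sum(td$weight), 1)
  gl <- glance(fr)
  expect_equal(gl$best_accuracy, fr$best_accuracy)
  expect_s3_class(autoplot(fr), "ggplot")
})
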