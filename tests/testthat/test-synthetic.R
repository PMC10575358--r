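test_that("scene generation is deterministic and respects cardinality", {
  s1 <- generate_scenes(6, n_species = 4, canvas_size = 128, seed = 11)
  s2 <- generate_scenes(6, n_species = 4, canvas_size = 128, seed = 11)
  expect_identical(s1$images, s2$images)
  expect_identical(as.data.frame(s1$annotations), as.data.frame(s2$annotations))
  s3 <- generate_scenes(6, n_species = 4, canvas_size = 128, seed = 12)
  expect_false(identical(s1$images, s3$images))

  s40 <- generate_scenes(40, n_species = 4, canvas_size = 128, seed = 21)
  counts <- table(s40$annotations$image_id)
  expect_true(all(counts <= 4))
  expect_length(s40$images, 40L)
  expect_equal(nrow(s40$truth), 40L)
})

test_that("generated annotations satisfy the box invariants and round-trip", {
  sc <- generate_scenes(8, n_species = 6, canvas_size = 128, seed = 31)
  a <- sc$annotations
  expect_true(all(a$xmin < a$xmax & a$ymin < a$ymax))
  expect_true(all(a$xmin >= 0 & a$ymin >= 0 &
                    a$xmax <= 128 & a$ymax <= 128))
  expect_equal(a$class_id, encode_class(a$species_id, a$part, n_species = 6))

  dir <- withr::local_tempdir()
  write_scenes(sc, dir)
  back <- read_scenes(dir, n_species = 6)
  cols <- c("image_id", "part", "species_id", "class_id",
            "xmin", "ymin", "xmax", "ymax")
  a_sorted <- dplyr::arrange(a[cols], image_id, part)
  b_sorted <- dplyr::arrange(back$annotations[cols], image_id, part)
  expect_equal(as.data.frame(a_sorted), as.data.frame(b_sorted))
  # images survive the PNG round trip to within quantisation
  expect_lt(max(abs(back$images[[1]] - sc$images[[names(back$images)[1]]])), 0.51)
})

test_that("scene XML output is byte-identical across runs with one seed", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  write_scenes(generate_scenes(4, n_species = 3, canvas_size = 128, seed = 5), dir1)
  write_scenes(generate_scenes(4, n_species = 3, canvas_size = 128, seed = 5), dir2)
  for (f in list.files(file.path(dir1, "Annotations"))) {
    expect_identical(readLines(file.path(dir1, "Annotations", f)),
                     readLines(file.path(dir2, "Annotations", f)))
  }
})

test_that("species are recoverable from glyph crops by construction", {
  sc <- generate_scenes(25, n_species = 8, canvas_size = 160, seed = 41)
  a <- sc$annotations
  hits <- vapply(seq_len(nrow(a)), function(i) {
    sp <- nearest_template_species(
      sc$images[[a$image_id[i]]],
      c(a$xmin[i], a$ymin[i], a$xmax[i], a$ymax[i]),
      n_species = 8)
    sp == a$species_id[i]
  }, logical(1))
  expect_true(all(hits))  # 100% separability by construction
})

test_that("a too-small canvas is rejected", {
  expect_error(generate_scenes(2, n_species = 2, canvas_size = 64),
               "canvas too small")
})

test_that("planted detection tables hit their per-part correctness rates", {
  tab <- generate_detection_table(2500, n_species = 50,
                                  p_part = c(0.9, 0.6, 0.4, 0.2),
                                  dropout = 0, seed = 13)
  expect_gte(nrow(tab$records), 10000L)
  stats <- dplyr::summarise(dplyr::group_by(tab$records, part),
                            rate = mean(correct), n = dplyr::n(),
                            .groups = "drop")
  stats <- stats[match(part_types(), stats$part), ]
  p <- c(0.9, 0.6, 0.4, 0.2)
  se <- sqrt(p * (1 - p) / stats$n)
  expect_true(all(abs(stats$rate - p) <= 3 * se))
  # at most one record per (image, part)
  expect_false(any(duplicated(tab$records[c("image_id", "part")])))
})

test_that("fully correct tables give perfect fused accuracy; planted-head tables
           make the head weight optimal", {
  tab <- generate_detection_table(120, n_species = 10, p_part = c(1, 1, 1, 1),
                                  dropout = 0, seed = 17)
  preds <- predict_species(tab$records, c(25, 25, 25, 25),
                           image_ids = tab$truth$image_id)
  expect_equal(classification_accuracy(preds, tab$truth), 1)

  tab2 <- generate_detection_table(200, n_species = 10, p_part = c(1, 0, 0, 0),
                                   dropout = 0, seed = 19)
  fr <- grid_search_weights(tab2$records, tab2$truth, step_hundredths = 10L)
  head_only <- classification_accuracy(
    predict_species(tab2$records, c(100, 0, 0, 0),
                    image_ids = tab2$truth$image_id),
    tab2$truth)
  expect_equal(fr$best_accuracy, head_only)
  expect_equal(head_only, 1)
})

test_that("confidence distributions separate correct from incorrect records", {
  tab <- generate_detection_table(1500, n_species = 30, dropout = 0, seed = 23)
  m <- dplyr::summarise(dplyr::group_by(tab$records, correct),
                        conf = mean(confidence), .groups = "drop")
  # Beta(8,2) mean 0.8 vs Beta(2,4) mean 1/3
  expect_gt(m$conf[m$correct], 0.75)
  expect_lt(m$conf[!m$correct], 0.4)
})
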