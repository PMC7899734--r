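write_fix_file <- function(df) {
  tmp <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, tmp, progress = FALSE)
  tmp
}

test_that("fixation reading filters by threshold, sorts, and validates", {
  f <- write_fix_file(fx(c(0, 1, 2), c(120, 80, 150), 1:3, 1:3))
  expect_silent(got <- suppressMessages(read_fixations(f, threshold_ms = 100)))
  expect_equal(nrow(got), 2)
  expect_equal(got$duration_ms, c(120, 150))

  f2 <- write_fix_file(fx(c(5, 1, 3), c(200, 200, 200), 1:3, 1:3))
  expect_equal(read_fixations(f2)$onset_s, c(1, 3, 5))

  f3 <- write_fix_file(fx(numeric(), numeric(), numeric(), numeric()))
  expect_warning(empty <- read_fixations(f3), "no data rows")
  expect_equal(nrow(empty), 0)

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset_s,duration_ms,x_px", "0,100,1"), f4)
  expect_error(read_fixations(f4), "missing column")

  f5 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("onset_s,duration_ms,x_px,y_px", "0,100,1,2", "1,oops,3,4"), f5)
  expect_error(read_fixations(f5), "row 2")
})

test_that("trajectory reading groups by label and enforces integrity", {
  tr <- static_tracks(c("A", "B"), t_end = 10)
  tr <- dplyr::bind_rows(tr, dplyr::mutate(tr[tr$time_s == 0, ], time_s = 5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_target_tracks(tr, tmp)
  got <- read_target_tracks(tmp)
  expect_equal(nrow(got), 6)
  expect_equal(unique(got$label), c("A", "B"))
  expect_true(all(diff(got$time_s[got$label == "A"]) > 0))

  dup <- dplyr::bind_rows(tr, tr[1, ])
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_target_tracks(dup, tmp2)
  expect_error(read_target_tracks(tmp2), "Duplicate")

  neg <- dplyr::mutate(tr, block_w = -1)
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  write_target_tracks(neg, tmp3)
  expect_error(read_target_tracks(tmp3), "Negative")
})

test_that("a target has regions only within its presence span", {
  tr <- dplyr::mutate(static_tracks("A", t_end = 300), time_s = time_s + 60)
  all_tr <- dplyr::bind_rows(tr, static_tracks("B", t_end = 1000))
  r_in <- aoi_regions_at(all_tr, 100)
  expect_setequal(r_in$label, c("A", "B"))
  r_out <- aoi_regions_at(all_tr, 30)
  expect_identical(r_out$label, "B")
})

test_that("AOI boxes span icon plus data block and inflate by the margin", {
  tr <- tibble::tibble(time_s = c(0, 10), label = "A",
                       icon_x = 100, icon_y = 100,
                       block_x = 130, block_y = 120, block_w = 50, block_h = 20)
  r0 <- aoi_regions_at(tr, 5, margin_px = 0)
  expect_equal(c(r0$xmin, r0$xmax, r0$ymin, r0$ymax), c(100, 180, 100, 140))
  r30 <- aoi_regions_at(tr, 5, margin_px = 30)
  expect_equal(c(r30$xmin, r30$xmax, r30$ymin, r30$ymax), c(70, 210, 70, 170))

  expect_warning(none <- aoi_regions_at(tr, 99), "outside the scenario span")
  expect_equal(nrow(none), 0)
})

test_that("overlapping targets yield intersecting regions and overlap hits", {
  tr <- dplyr::bind_rows(
    tibble::tibble(time_s = c(0, 10), label = "A", icon_x = 100, icon_y = 100,
                   block_x = 115, block_y = 115, block_w = 60, block_h = 30),
    tibble::tibble(time_s = c(0, 10), label = "B", icon_x = 140, icon_y = 110,
                   block_x = 155, block_y = 125, block_w = 60, block_h = 30)
  )
  r <- aoi_regions_at(tr, 5)
  a <- r[r$label == "A", ]; b <- r[r$label == "B", ]
  expect_true(a$xmax > b$xmin && a$ymax > b$ymin)

  expect_identical(hit_test(105, 105, r), "A")
  expect_identical(hit_test(150, 120, r), "(A;B)")
  expect_identical(hit_test(500, 500, r), NA_character_)
  # set semantics: region order is irrelevant
  expect_identical(hit_test(150, 120, r[2:1, ]), "(A;B)")
})

test_that("shrinking the margin never adds a hit", {
  tr <- static_tracks(c("A", "B", "C"), t_end = 100)
  withr::with_seed(11, {
    pts <- tibble::tibble(x = runif(80, 0, 1400), y = runif(80, 300, 700))
    for (m in list(c(0, 20), c(20, 60), c(5, 120))) {
      r_small <- aoi_regions_at(tr, 50, m[1])
      r_big <- aoi_regions_at(tr, 50, m[2])
      hit_small <- purrr::map_chr(seq_len(nrow(pts)),
                                  function(i) hit_test(pts$x[i], pts$y[i], r_small))
      hit_big <- purrr::map_chr(seq_len(nrow(pts)),
                                function(i) hit_test(pts$x[i], pts$y[i], r_big))
      expect_true(all(is.na(hit_small) | !is.na(hit_big)))
    }
  })
})

test_that("raw sequences keep time order, drop off-AOI hits, and conserve dwell", {
  tr <- static_tracks(c("A", "B", "C"), t_end = 100)
  regions <- aoi_regions_at(tr, 1)
  cx <- (regions$xmin + regions$xmax) / 2
  cy <- (regions$ymin + regions$ymax) / 2
  names(cx) <- names(cy) <- regions$label

  on_a <- fx(1:5, rep(150, 5), rep(cx["A"], 5), rep(cy["A"], 5))
  s1 <- build_raw_sequence(on_a, tr, list(start = 0, end = 100, index = 1))
  expect_identical(format_sequence(s1), "AAAAA")
  expect_equal(unname(s1$fix_counts["A"]), 5)

  labs <- c("A", "A", "B", "C", "C")
  mixed <- fx(1:5, c(120, 130, 140, 150, 160), cx[labs], cy[labs])
  s2 <- build_raw_sequence(mixed, tr, list(start = 0, end = 100, index = 1))
  expect_identical(format_sequence(s2), "AABCC")
  expect_equal(sum(s2$dwell_ms), sum(mixed$duration_ms))
  expect_identical(format_sequence(collapse_sequence(s2)), "ABC")

  # off-AOI fixations are dropped from the sequence but dwell of hits conserved
  with_miss <- dplyr::bind_rows(mixed, fx(2.5, 500, 5000, 5000))
  s3 <- suppressMessages(
    build_raw_sequence(with_miss, tr, list(start = 0, end = 100, index = 1))
  )
  expect_identical(format_sequence(s3), "AABCC")
  expect_equal(sum(s3$dwell_ms), sum(mixed$duration_ms))

  # interval membership is half-open on onset
  edge <- fx(c(1, 100), c(150, 150), rep(cx["A"], 2), rep(cy["A"], 2))
  s4 <- build_raw_sequence(edge, tr, list(start = 0, end = 100, index = 1))
  expect_identical(format_sequence(s4), "A")

  expect_warning(
    s5 <- build_raw_sequence(on_a, tr, list(start = 200, end = 300, index = 2)),
    "No fixations"
  )
  expect_length(s5, 0)
})
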