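master_multiples <- vs_master_sequence()
master_barcode <- translate_multiples(master_multiples)

test_that("the reference sequence translates to its 68-character barcode", {
  expect_equal(
    master_barcode,
    "10001001101001010110010010011000111100111010101001001010011001011011"
  )
  expect_equal(nchar(master_barcode), 68L)
  expect_equal(sum(strsplit(master_barcode, "")[[1]] == "1"), 33L)
  expect_equal(nchar(master_barcode), sum(master_multiples))
})

test_that("the multiple-to-barcode mapping follows 1, 10, 100, 1000", {
  expect_equal(translate_multiples(1L), "1")
  expect_equal(translate_multiples(c(2L, 2L)), "1010")
  expect_equal(translate_multiples(c(4L, 3L, 2L, 1L)), "1000100101")
  expect_error(translate_multiples(c(1L, 5L)), "1..4")
  expect_error(translate_multiples(integer()), "1..4")
})

test_that("barcode parsing inverts translation exactly", {
  withr::with_seed(41, {
    for (i in 1:25) {
      m <- sample(1:4, sample(3:40, 1), replace = TRUE)
      expect_identical(parse_barcode(translate_multiples(m)), as.integer(m))
    }
  })
  expect_error(parse_barcode("0101"), "starting")
})

test_that("window uniqueness validation agrees with a brute-force oracle", {
  expect_true(validate_multiples(master_multiples, 4))
  # 30 windows of length 4, all distinct
  expect_equal(length(master_multiples) - 4 + 1, 30)
  expect_false(validate_multiples(c(1, 1, 1, 1, 1), 2))
  expect_warning(v <- validate_multiples(c(1, 2), 4), "trivially")
  expect_true(v)
  withr::with_seed(42, {
    for (i in 1:40) {
      m <- sample(1:3, sample(5:15, 1), replace = TRUE)
      k <- sample(2:4, 1)
      expect_equal(as.logical(validate_multiples(m, k)),
                   windows_unique_oracle(m, k))
    }
  })
})

test_that("sequence design satisfies its own validator and constraints", {
  m <- design_multiples(33, k = 4, m_range = 1:4, max_total = 68, seed = 43)
  expect_length(m, 33L)
  expect_true(validate_multiples(m, 4))
  expect_lte(sum(m), 68)
  expect_true(all(m %in% 1:4))
  # trivially short sequence is valid
  m2 <- design_multiples(2, k = 4, seed = 1)
  expect_length(m2, 2L)
  expect_warning(expect_true(validate_multiples(m2, 4)), "trivially")
  # constant alphabet cannot satisfy uniqueness
  expect_error(design_multiples(300, k = 4, m_range = 1, seed = 1),
               "no valid sequence")
})

test_that("alignment accepts true windows and rejects foreign patterns", {
  # exact prefix aligns at offset 0 with distance 0
  a0 <- align_pattern("1000100110100", master_barcode)
  expect_equal(a0$offset, 0L)
  expect_equal(a0$distance, 0L)
  expect_true(a0$accepted)
  # one dropped detection still aligns (1 < 30% of 13)
  a1 <- align_pattern("0000100110100", master_barcode)
  expect_equal(a1$distance, 1L)
  expect_equal(a1$offset, 0L)
  expect_true(a1$accepted)
  # an all-ones pattern matches nowhere under the 30% rule
  a2 <- align_pattern(strrep("1", 13), master_barcode)
  expect_false(a2$accepted)
  # observed longer than the master cannot align
  a3 <- align_pattern(strrep("10", 40), master_barcode)
  expect_false(a3$accepted)
})

test_that("noiseless master windows with >= 5 detections always decode", {
  mas <- strsplit(master_barcode, "")[[1]]
  ones <- which(mas == "1") - 1L
  n_checked <- 0L
  for (s in ones) {
    for (L in 5:(nchar(master_barcode) - s)) {
      obs <- substr(master_barcode, s + 1, s + L)
      if (!endsWith(obs, "1")) next
      if (sum(strsplit(obs, "")[[1]] == "1") < 5) next
      a <- align_pattern(obs, master_barcode)
      expect_true(a$accepted)
      expect_equal(a$offset, s)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 400)
})

test_that("false acceptance of random patterns falls with observed length", {
  rate_at <- function(L, n = 300) {
    withr::with_seed(L, {
      mean(vapply(seq_len(n), function(i) {
        obs <- paste0("1", paste(sample(0:1, L - 2, replace = TRUE),
                                 collapse = ""), "1")
        align_pattern(obs, master_barcode)$accepted
      }, logical(1)))
    })
  }
  r20 <- rate_at(20)
  r35 <- rate_at(35)
  r50 <- rate_at(50)
  expect_gt(r20, r35)
  expect_gt(r35, r50)
  expect_lt(r50, 0.05)
})

test_that("absolute positions are recovered for a stationary VS emitter", {
  cfg <- acq_preset("er-vs")
  y0 <- 10; x0 <- 100   # the full 68-slot streak must stay on the chip
  slots_before <- c(0L, cumsum(master_multiples))[1:33]
  locs <- tibble::tibble(
    frame = 1L,
    x_px = x0,
    y_px = y0 + 15 * slots_before,
    photons = 300, background = 0.5, sigma_px = 1, precision_nm = 25
  )
  lp <- link_params(10, 500, mode = "vs")
  tr <- link_trails(locs, lp)
  expect_equal(dplyr::n_distinct(tr$trail_id), 1L)
  al <- align_trails(tr, master_barcode)
  expect_true(al$accepted)
  expect_equal(al$offset, 0L)
  traj <- recover_absolute(tr, al, master_multiples, cfg)
  expect_equal(nrow(traj), 33L)
  expect_equal(traj$timepoint, 1:33)
  expect_equal(traj$y_nm, rep(y0 * cfg$pixel_nm, 33))
  expect_equal(traj$x_nm, rep(x0 * cfg$pixel_nm, 33))

  # the same streak truncated to a window aligns at its true offset
  win <- locs[10:20, ]
  tr2 <- link_trails(win, lp)
  al2 <- align_trails(tr2, master_barcode)
  expect_true(al2$accepted)
  expect_equal(al2$offset, slots_before[10])
  traj2 <- recover_absolute(tr2, al2, master_multiples, cfg)
  expect_equal(unique(traj2$y_nm[!traj2$skipped]), y0 * cfg$pixel_nm)
  expect_equal(traj2$timepoint[!traj2$skipped], 10:20)
})
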