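make_frags <- function(n, seed) {
  set.seed(seed)
  rand_intervals(n, chroms = "chr1", max_pos = 2000, max_len = 40)
}

test_that("fragment filtering applies the three steps in order", {
  peaks <- gi("chr1", c(100, 500), c(200, 600))
  plasmid <- gi("chr1", c(110, 510, 800), c(150, 560, 850))
  negatives <- gi("chr1", 110, 150)

  # in negatives -> removed even though in plasmid and on a peak
  screen <- gi("chr1", 110, 150)
  out <- filter_fragments(screen, negatives, plasmid, peaks)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "removed")[["negative_control"]], 1)

  # in plasmid, not negative, overlapping a peak -> retained
  screen <- gi("chr1", 510, 560)
  out <- filter_fragments(screen, negatives, plasmid, peaks)
  expect_equal(nrow(out), 1)

  # in plasmid but off-peak -> removed at the ATAC step
  screen <- gi("chr1", 800, 850)
  out <- filter_fragments(screen, negatives, plasmid, peaks)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "removed")[["no_atac_peak"]], 1)

  expect_error(filter_fragments(screen, negatives,
                                gi(character(0), integer(0), integer(0)),
                                peaks),
               "empty plasmid")
})

test_that("filtering equals the set-algebra oracle on random instances", {
  set.seed(99)
  for (rep in 1:20) {
    screen <- rand_intervals(50, chroms = "chr1", max_pos = 500, max_len = 20)
    plasmid <- rbind(screen[sample(50, 30), ],
                     rand_intervals(20, chroms = "chr1", max_pos = 500,
                                    max_len = 20))
    negatives <- screen[sample(50, 5), ]
    peaks <- rand_intervals(10, chroms = "chr1", max_pos = 500, max_len = 60)
    got <- filter_fragments(screen, negatives, plasmid, peaks)
    want <- bf_filter_fragments(screen, negatives, plasmid, peaks)
    expect_equal(paste(got$chrom, got$start, got$end),
                 paste(want$chrom, want$start, want$end))
  }
})

test_that("filtering is monotone in negatives/plasmid and idempotent", {
  set.seed(5)
  screen <- rand_intervals(80, chroms = "chr1", max_pos = 800, max_len = 30)
  plasmid <- screen[1:60, ]
  negatives <- screen[1:10, ]
  peaks <- rand_intervals(15, chroms = "chr1", max_pos = 800, max_len = 80)
  base <- filter_fragments(screen, negatives, plasmid, peaks)
  more_neg <- filter_fragments(screen, rbind(negatives, screen[11:20, ]),
                               plasmid, peaks)
  expect_lte(nrow(more_neg), nrow(base))
  more_plasmid <- filter_fragments(screen, negatives,
                                   rbind(plasmid, screen[61:80, ]), peaks)
  expect_gte(nrow(more_plasmid), nrow(base))
  again <- filter_fragments(base, negatives, plasmid, peaks)
  expect_equal(nrow(again), nrow(base))
})

test_that("enhancer positivity needs at least one overlapping fragment", {
  peaks <- gi("chr1", c(100, 500, 900), c(200, 600, 1000),
              peak_id = c("p1", "p2", "p3"))
  frags <- gi("chr1", 150, 160)   # exactly one fragment, on p1 only
  pos <- call_enhancer_positive(peaks, frags)
  expect_identical(unname(pos), c(TRUE, FALSE, FALSE))
  expect_named(pos, c("p1", "p2", "p3"))

  set.seed(21)
  peaks <- rand_intervals(60, chroms = "chr1", max_pos = 1000, max_len = 50)
  frags <- rand_intervals(40, chroms = "chr1", max_pos = 1000, max_len = 20)
  want <- vapply(seq_len(60), function(i)
    any(vapply(seq_len(40), function(j)
      bf_overlaps(peaks[i, ], frags[j, ]), logical(1))), logical(1))
  expect_identical(unname(call_enhancer_positive(peaks, frags)), want)
})

test_that("activity states follow the normalized high/low ratio with ties Low", {
  peak <- gi("chr1", 100, 200, peak_id = "pk")
  lowf <- gi("chr1", c(110, 130, 150), c(120, 140, 160))
  call <- assign_activity_state(peak, lowf[0, ], lowf, 1000, 1000)
  expect_equal(call$state, "Low")
  expect_true(call$positive)

  # 10 of 1e6 vs 10 of 2e6 -> norm 10 vs 5 -> High
  high10 <- gi("chr1", 300 + 0:9, 320 + 0:9)
  low10 <- gi("chr1", 300 + 0:9, 320 + 0:9)
  peak2 <- gi("chr1", 300, 340, peak_id = "pk2")
  call <- assign_activity_state(peak2, high10, low10, 1e6, 2e6)
  expect_equal(call$norm_high, 10)
  expect_equal(call$norm_low, 5)
  expect_equal(call$state, "High")

  # equal counts, equal totals -> exact tie -> Low
  call <- assign_activity_state(peak2, high10, low10, 1e6, 1e6)
  expect_equal(call$state, "Low")

  # no fragments at all -> NotPositive
  call <- assign_activity_state(peak, lowf[0, ], lowf[0, ], 10, 10)
  expect_false(call$positive)
  expect_equal(call$state, "NotPositive")

  expect_error(assign_activity_state(peak, lowf, lowf, 0, 10), "positive")
})
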