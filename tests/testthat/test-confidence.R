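test_that("confidence scores are reciprocal frequency ratios", {
  cf <- confidence_from_freqs(5, 5)
  expect_equal(cf$confidence_exposed, 1)
  expect_equal(cf$confidence_buried, 1)
  cf2 <- confidence_from_freqs(c(6.24, 4), c(7.56, 0))
  expect_equal(cf2$confidence_exposed[1L] * cf2$confidence_buried[1L], 1,
               tolerance = 1e-12)
  expect_equal(cf2$confidence_exposed[2L], Inf)
  expect_true(all(is.na(confidence_from_freqs(0, 0))))
  expect_error(confidence_from_freqs(-1, 2), "non-negative")
})

test_that("bin tables tabulate per-state relative frequencies", {
  one_bin <- build_bin_table(rep("40 to 50", 6),
                             rep(c("exposed", "buried"), 3))
  expect_equal(one_bin$rel_freq_exposed[one_bin$bin == "40 to 50"], 100)
  expect_equal(one_bin$rel_freq_buried[one_bin$bin == "40 to 50"], 100)
  expect_equal(sum(one_bin$rel_freq_exposed), 100)

  set.seed(23)
  bins <- sample(bin_levels(), 200, replace = TRUE)
  states <- sample(c("buried", "exposed"), 200, replace = TRUE)
  tb <- build_bin_table(bins, states)
  # direct-counting oracle per bin
  for (b in bin_levels()) {
    expect_equal(tb$rel_freq_exposed[tb$bin == b],
                 100 * sum(bins == b & states == "exposed") /
                   sum(states == "exposed"))
  }
  expect_equal(sum(tb$rel_freq_exposed), 100, tolerance = 1e-9)
  expect_equal(sum(tb$rel_freq_buried), 100, tolerance = 1e-9)
  ok <- is.finite(tb$confidence_exposed) & tb$confidence_exposed > 0
  expect_equal(tb$confidence_exposed[ok] * tb$confidence_buried[ok],
               rep(1, sum(ok)), tolerance = 1e-9)
  expect_error(build_bin_table(bins, rep("buried", 200)), "no exposed")
})

test_that("bin tables round-trip through TSV unchanged", {
  tb <- reference_bin_table()
  path <- tempfile(fileext = ".tsv")
  write_bin_table(tb, path)
  expect_equal(read_bin_table(path), tb, tolerance = 1e-9)
  # confidences are recomputed when a file carries only frequencies
  write_bin_table(tb[, 1:3], path)
  expect_equal(read_bin_table(path), tb, tolerance = 1e-9)
})

test_that("state calls follow the strictly-above-threshold rule", {
  tb <- reference_bin_table()
  prof <- data.frame(position = 1:3, residue_name = c("L", "V", "K"),
                     bin_label = c("0 to 10", "90 to 100", "0 to 10"),
                     stringsAsFactors = FALSE)
  pred <- predict_state(prof, tb)
  expect_equal(nrow(pred), 2L)       # K is outside the prediction set
  expect_equal(pred$predicted_state, c("exposed", "buried"))
  # a confidence of exactly the threshold is called buried
  tie <- data.frame(bin = "50 to 60", rel_freq_exposed = 2.07,
                    rel_freq_buried = 1, confidence_exposed = 2.07,
                    confidence_buried = 1 / 2.07, stringsAsFactors = FALSE)
  p <- predict_state(data.frame(position = 1, residue_name = "L",
                                bin_label = "50 to 60"), tie)
  expect_equal(p$predicted_state, "buried")
})

test_that("prediction is deterministic and permutation-equivariant", {
  set.seed(41)
  prof <- data.frame(position = 1:50,
                     residue_name = sample(c("V", "I", "L", "M", "F"), 50, TRUE),
                     bin_label = sample(bin_levels(), 50, TRUE),
                     stringsAsFactors = FALSE)
  tb <- reference_bin_table()
  p1 <- predict_state(prof, tb)
  perm <- sample(nrow(prof))
  p2 <- predict_state(prof[perm, ], tb)
  expect_equal(p2[order(p2$position), ], p1[order(p1$position), ],
               ignore_attr = TRUE)
})

test_that("flanking index follows the weight scheme", {
  # neighbours L, A (left) and S, D (right): (1 + 0.75 + 0.35 + 0.15) / 4
  expect_equal(flanking_index("LAKSD", 3), 0.5625)
  expect_equal(flanking_index("FIVLM", 3), 1)
  # terminal position: only two neighbours exist
  expect_equal(flanking_index("KLF", 1), mean(c(1, 1)))
  expect_error(flanking_index("K", 1), "no flanking")
})

test_that("refinement flips only near-threshold calls in extreme windows", {
  tb <- reference_bin_table()
  seqs <- "KLFILVKDDLDDKK"
  #        12345678901234
  prof <- data.frame(position = c(3, 10), residue_name = c("F", "L"),
                     bin_label = c("40 to 50", "40 to 50"),
                     stringsAsFactors = FALSE)
  pred <- predict_state(prof, tb)   # 40-50 confidence 4.29 -> exposed
  expect_equal(pred$predicted_state, c("exposed", "exposed"))
  # margin 0 disables refinement entirely
  r0 <- refine_predictions(pred, seqs, margin = 0)
  expect_equal(r0$refined_state, r0$predicted_state)
  # wide margin: the F at 3 sits in an all-hydrophobic window -> buried;
  # the L at 10 is surrounded by D/K -> call stands
  r1 <- suppressMessages(refine_predictions(pred, seqs, margin = 3))
  expect_equal(r1$refined_state, c("buried", "exposed"))
  expect_equal(nrow(attr(r1, "flips")), 1L)
})

test_that("raising flank_high never increases the number of flips", {
  set.seed(53)
  tb <- reference_bin_table()
  seqs <- paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
                       80, replace = TRUE), collapse = "")
  prof <- data.frame(position = 3:78,
                     residue_name = strsplit(seqs, "")[[1L]][3:78],
                     bin_label = sample(bin_levels(), 76, replace = TRUE),
                     stringsAsFactors = FALSE)
  pred <- predict_state(prof, tb, hydrophobic_set = strsplit(seqs, "")[[1L]])
  flips <- vapply(c(0.5, 0.75, 0.9, 1.0), function(fh) {
    nrow(attr(suppressMessages(
      refine_predictions(pred, seqs, flank_high = fh, margin = 2)), "flips"))
  }, 0L)
  expect_true(all(diff(flips) <= 0L))
})

test_that("accuracy is the correct-call fraction and scales out", {
  expect_equal(accuracy(list(tp = 3, tn = 5, fp = 1, fn = 1)), 0.8)
  expect_equal(accuracy(list(tp = 10, tn = 10, fp = 0, fn = 0)), 1)
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
  expect_equal(accuracy(list(tp = 30, tn = 50, fp = 10, fn = 10)), 0.8)
  cc <- confusion_counts(c("exposed", "buried", "buried", "exposed"),
                         c("exposed", "exposed", "buried", "buried"))
  expect_equal(cc, list(tp = 1L, tn = 1L, fp = 1L, fn = 1L))
})
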