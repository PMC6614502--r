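test_that("wide write/read round trip preserves all matrices bit-exactly", {
  set.seed(11)
  area <- matrix(10^runif(15, 2, 6), 3, 5)
  pt <- make_pt(area, "QQSSB",
                rt = matrix(runif(15, 0.5, 7), 3),
                width = matrix(runif(15, 0.05, 0.3), 3),
                detected = matrix(c(rep(TRUE, 14), FALSE), 3))
  d <- withr::local_tempdir()
  write_peak_table(pt, file.path(d, "pt.tsv"), file.path(d, "seq.tsv"),
                   file.path(d, "det.tsv"))
  back <- read_peak_table(file.path(d, "pt.tsv"), file.path(d, "seq.tsv"),
                          file.path(d, "det.tsv"))
  expect_identical(back$area, pt$area)
  expect_identical(back$rt, pt$rt)
  expect_identical(back$width, pt$width)
  expect_identical(back$detected, pt$detected)
  expect_equal(back$injections, pt$injections)
  expect_equal(back$features$mz, pt$features$mz)
})

test_that("long-format peak tables are reshaped into matching matrices", {
  d <- withr::local_tempdir()
  long <- expand.grid(feature_id = c("a", "b", "c"), run_order = 1:5,
                      stringsAsFactors = FALSE)
  long$mz <- c(101, 202, 303)[match(long$feature_id, c("a", "b", "c"))]
  long$rt_median <- c(1, 2, 3)[match(long$feature_id, c("a", "b", "c"))]
  long$area <- seq_len(nrow(long)) * 10
  long$rt <- long$rt_median + 0.01
  long$width <- 0.1
  write.table(long, file.path(d, "long.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(run_order = 1:5,
                         sample_class = c("QC", "QC", "sample", "sample",
                                          "blank")),
              file.path(d, "seq.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pt <- read_peak_table(file.path(d, "long.tsv"), file.path(d, "seq.tsv"))
  expect_equal(dim(pt$area), c(3, 5))
  expect_equal(pt$area["b", "4"], long$area[long$feature_id == "b" &
                                              long$run_order == 4])
})

test_that("validation names the offending cell or row", {
  area <- matrix(100, 2, 3)
  expect_silent(make_pt(area, "QSB"))
  bad <- area; bad[2, 3] <- -1
  expect_error(make_pt(bad, "QSB"), "F002.*run_order 3")
  f <- data.frame(feature_id = c("x", "x"), mz = c(1, 2),
                  rt_median = c(1, 2))
  expect_error(
    peak_table(f, data.frame(run_order = 1:3,
                             sample_class = c("QC", "sample", "blank")),
               area, area, area),
    "duplicate feature_id")
  expect_error(
    peak_table(data.frame(feature_id = c("x", "y"), mz = 1:2,
                          rt_median = 1:2),
               data.frame(run_order = 1:3,
                          sample_class = c("QC", "mystery", "blank")),
               area, area, area),
    "unknown sample_class 'mystery'")
})

test_that("without a detection file, detection is thresholded area", {
  area <- matrix(100, 2, 4)
  area[1, 2] <- 0
  pt <- make_pt(area, "QSSB")
  expect_false(pt$detected[1, 2])
  expect_equal(sum(!pt$detected), 1)
})

test_that("annotate_sequence infers cycles, blank groups and positions", {
  # leading QCs, one mild cycle
  ann <- annotate_sequence(c(rep("QC", 10), rep("sample", 8), "blank",
                             rep("sample", 8)))
  expect_equal(unique(ann$cycle_id[1:18]), 0L)
  s2 <- ann[ann$cycle_id == 1 & ann$sample_class == "sample", ]
  expect_equal(s2$position_after_blank, 1:8)
  expect_equal(unique(s2$blank_group_size), 1L)
  # intense cycle opened by three consecutive blanks
  ann3 <- annotate_sequence(c(rep("sample", 8), rep("blank", 3),
                              rep("sample", 8)))
  tail_s <- ann3[ann3$cycle_id == 1 & ann3$sample_class == "sample", ]
  expect_equal(tail_s$position_after_blank, 1:8)
  expect_equal(unique(tail_s$blank_group_size), 3L)
  expect_equal(ann3$position_after_blank[9:11], 1:3)
  # degenerate: blanks only
  ann0 <- annotate_sequence(c("blank", "blank"))
  expect_equal(sum(ann0$sample_class == "sample"), 0)
  expect_equal(ann0$blank_group_size, c(2L, 2L))
})

test_that("annotation warns on layouts beyond the supported design", {
  expect_warning(annotate_sequence(c(rep("blank", 4), rep("sample", 2))),
                 "more than 3 consecutive blanks")
  expect_warning(annotate_sequence(c("blank", rep("sample", 9))),
                 "more than 8 samples")
  # positions keep counting past the cap
  ann <- suppressWarnings(annotate_sequence(c("blank", rep("sample", 9))))
  expect_equal(max(ann$position_after_blank[ann$sample_class == "sample"]),
               9L)
})

test_that("annotation is idempotent and partitions the sequence", {
  set.seed(5)
  for (i in 1:10) {
    cls <- sample(c("QC", "sample", "blank"), 40, replace = TRUE,
                  prob = c(0.1, 0.7, 0.2))
    a1 <- suppressWarnings(annotate_sequence(cls))
    a2 <- suppressWarnings(annotate_sequence(
      a1[, c("run_order", "sample_class")]))
    expect_identical(a1, a2)
    # every injection is in the leading block (cycle 0) or exactly one cycle
    expect_true(all(a1$cycle_id >= 0))
    expect_true(all(!is.na(a1$position_after_blank[
      a1$sample_class == "blank"])))
    in_lead <- a1$cycle_id == 0
    in_cycle <- a1$cycle_id > 0
    expect_true(all(xor(in_lead, in_cycle)))
  }
})

test_that("write_results emits stable, rerunnable TSVs with metadata", {
  d <- withr::local_tempdir()
  cls <- data.frame(feature_id = sprintf("F%d", 1:6),
                    label = c(rep("informative", 3), "contaminant",
                              "carryover+1", "excluded"))
  p1 <- write_results(list(classification = cls), file.path(d, "a"),
                      config = list(x = 1), seed = 42)
  got <- read.delim(p1, comment.char = "#")
  expect_equal(nrow(got), 6)
  expect_true("label" %in% names(got))
  hdr <- readLines(p1, n = 3)
  expect_match(hdr[3], "seed: 42")
  # empty result set -> header-only file
  p2 <- write_results(list(empty = cls[0, ]), file.path(d, "b"))
  expect_equal(nrow(read.delim(p2, comment.char = "#")), 0)
  # rerun with same config/seed -> byte-identical
  p3 <- write_results(list(classification = cls), file.path(d, "c"),
                      config = list(x = 1), seed = 42)
  expect_identical(readLines(p1), readLines(p3))
})

test_that("reference injections are the leading QCs plus pre-blank samples", {
  area <- matrix(100, 1, 22)
  pt <- make_pt(area, paste0(strrep("Q", 3), strrep("S", 8), "B",
                             strrep("S", 8), "BB"))
  ref <- reference_injections(pt, j = 1)
  # QCs 1:3 and the samples immediately before each blank group
  expect_equal(ref, c(1, 2, 3, 11, 20))
  ref2 <- reference_injections(pt, j = 2)
  expect_equal(ref2, c(1, 2, 3, 10, 11, 19, 20))
})
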