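test_that("export -> import -> export is a textual fixpoint with exact timing", {
  for (fam in c("flash", "se_epi_diffusion")) {
    seq <- build_sequence(fam, toy_protocol(fam))
    blocks <- stream_collect(seq)
    txt1 <- format_pulseq(export_pulseq(blocks))
    imp <- import_pulseq(parse_pulseq(txt1))
    expect_length(imp$blocks, length(blocks))
    txt2 <- format_pulseq(export_pulseq(imp$blocks))
    strip <- function(x) x[!grepl("^#", x)]
    expect_identical(strip(txt2), strip(txt1))
    # per-block (start, duration, event kinds) tuples identical
    tup <- function(bs) lapply(bs, function(b)
      list(b$start_ns, b$duration_ns, !is.null(b$rf),
           sort(unique(vapply(b$gradients, function(g) g$axis, character(1)))),
           if (!is.null(b$adc)) c(b$adc$start_ns, b$adc$n, b$adc$dwell_ns)))
    expect_identical(tup(imp$blocks), tup(blocks))
  }
})

test_that("block census matches and an empty sequence exports header-only", {
  seq <- build_sequence("flash",
    mr_protocol(TR_ms = 12, TE_ms = 5, flip_deg = 10, fov_mm = c(128, 128, 64),
                matrix_size = c(8L, 8L, 8L)))
  blocks <- stream_collect(seq)
  doc <- export_pulseq(blocks)
  expect_equal(nrow(doc$blocks), length(blocks))
  expect_equal(sum(doc$blocks[, "adc"] > 0), 64)
  doc0 <- export_pulseq(list())
  txt0 <- format_pulseq(doc0)
  expect_true(any(grepl("\\[VERSION\\]", txt0)))
  expect_false(any(grepl("\\[BLOCKS\\]", txt0) &
                     grepl("^[0-9]", txt0[which(txt0 == "[BLOCKS]") + 1])))
})

test_that("identical RF envelopes deduplicate to one shape entry", {
  rf <- make_rf("hann_sinc", 1, 10)
  b1 <- execution_block(0, rf = rf)
  rf2 <- rf; rf2$start_ns <- 0
  b2 <- execution_block(b1$duration_ns, rf = rf2)
  doc <- export_pulseq(list(b1, b2))
  # one magnitude + one phase shape, one RF table entry
  expect_length(doc$shapes, 2)
  expect_length(doc$rf, 1)
})

test_that("a hand-written three-block file imports with stated durations", {
  txt <- c("[VERSION]", "major 1", "minor 4", "revision 1", "",
           "[DEFINITIONS]", "BlockDurationRaster 1e-05", "",
           "[BLOCKS]",
           "1 100 0 0 0 0 0 0",
           "2 50 0 1 0 0 0 0",
           "3 200 0 0 0 0 1 0",
           "[TRAP]", "1 42577 100 300 100 0",
           "[ADC]", "1 64 10000 0 0 0")
  imp <- import_pulseq(parse_pulseq(txt))
  expect_length(imp$blocks, 3)
  expect_equal(vapply(imp$blocks, function(b) b$duration_ns, numeric(1)),
               c(100, 50, 200) * 1e4)
  expect_equal(imp$blocks[[2]]$gradients[[1]]$flat_ns, 3e5)
  expect_equal(imp$blocks[[3]]$adc$n, 64)
  # chronology reproduced
  expect_equal(imp$blocks[[3]]$start_ns, 150 * 1e4)
})

test_that("unknown sections and malformed content raise parse errors", {
  expect_error(parse_pulseq(c("[VERSION]", "major 1", "minor 4", "revision 1",
                              "[WAT]")), "unknown Pulseq section.*line 5")
  expect_error(parse_pulseq(c("stray")), "before first section")
  expect_error(parse_pulseq(c("[BLOCKS]", "1 2 3")), "bad block line")
})

test_that("acquisition counters survive the sidecar roundtrip", {
  seq <- build_sequence("flash", toy_protocol("flash"))
  blocks <- stream_collect(seq)
  f <- file.path(tempdir(), "toy.seq")
  export_pulseq(blocks, file = f)
  expect_true(file.exists(f))
  side <- file.path(tempdir(), "toy.labels.json")
  expect_true(file.exists(side))
  imp <- import_pulseq(f, labels = side)
  h1 <- lapply(adc_blocks(blocks), function(b) b$adc$header[c("line", "partition")])
  h2 <- lapply(adc_blocks(imp$blocks), function(b) b$adc$header[c("line", "partition")])
  expect_equal(h2, h1)
  unlink(c(f, side))
})

test_that("exported document passes internal consistency checks", {
  seq <- build_sequence("rare", toy_protocol("rare"))
  doc <- export_pulseq(stream_collect(seq))
  ids_used <- unique(c(doc$blocks[, "gx"], doc$blocks[, "gy"], doc$blocks[, "gz"]))
  ids_used <- ids_used[ids_used > 0]
  for (id in ids_used)
    expect_true((length(doc$trap) >= id && !is.null(doc$trap[[id]])) ||
                  (length(doc$grad) >= id && !is.null(doc$grad[[id]])))
  for (e in doc$rf) {
    expect_lte(e[["mag_id"]], length(doc$shapes))
    expect_lte(e[["phase_id"]], length(doc$shapes))
    expect_equal(length(doc$shapes[[e[["mag_id"]]]]),
                 length(doc$shapes[[e[["phase_id"]]]]))
  }
})
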