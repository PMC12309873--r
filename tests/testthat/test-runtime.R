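test_that("buffered streaming equals eager traversal for any window", {
  seq <- build_sequence("flash", toy_protocol("flash"))
  eager <- stream_collect(seq)
  for (w in c(30, 300)) {
    st <- stream_blocks(seq, runtime_config(buffer_ms = w))
    expect_identical(st$blocks, eager)
  }
  # empty sequence -> empty stream
  reg <- bp_registry()
  bp_register(reg, blueprint("solo"))
  empty <- assemble(reg, "solo", mr_protocol(TR_ms = 10, TE_ms = 5))
  st0 <- stream_blocks(empty, runtime_config())
  expect_length(st0$blocks, 0)
  expect_length(st0$buffers, 0)
})

test_that("window range is validated and long blocks are logged, not split", {
  expect_error(runtime_config(buffer_ms = 10), "30-300")
  expect_silent(runtime_config(buffer_ms = 10, allow_any_window = TRUE))
  seq <- build_sequence("steam", toy_protocol("steam"))  # 1 s+ ADC block
  st <- stream_blocks(seq, runtime_config(buffer_ms = 30))
  expect_gt(length(st$long_blocks), 0)
  expect_identical(st$blocks, stream_collect(seq))
})

test_that("materialized blocks stay within a two-window census bound", {
  seq <- build_sequence("flash", toy_protocol("flash"))
  eager <- stream_collect(seq)
  st <- stream_blocks(seq, runtime_config(buffer_ms = 100))
  starts <- vapply(eager, function(b) b$start_ns, numeric(1))
  census <- max(vapply(starts, function(t0)
    sum(starts >= t0 & starts < t0 + 2e8), integer(1)))
  expect_lte(st$peak_materialized, census)
})

test_that("feedback updates apply at sync points and reach later blocks only", {
  seq <- build_sequence("flash", toy_protocol("flash"))
  state <- feedback_state(exposed = list(slice_offset_mm = "protocol.slice_offset_mm"))
  # update arrives at t = 0.05 s of the 0.192 s scan
  fb_schedule(state, 0.05e9, "slice_offset_mm", 10)
  st <- stream_blocks(seq, runtime_config(buffer_ms = 30), feedback = state)
  rfb <- Filter(function(b) !is.null(b$rf), st$blocks)
  freqs <- vapply(rfb, function(b) b$rf$freq_hz, numeric(1))
  starts <- vapply(rfb, function(b) b$start_ns, numeric(1))
  changed <- which(freqs != 0)
  expect_gt(length(changed), 0)
  # causality: nothing before the arrival reflects it; first reflecting
  # block starts within one in-flight window plus one window
  expect_true(all(starts[setdiff(seq_along(freqs), changed)] < 0.05e9 + 6e7))
  expect_true(all(starts[changed] >= 0.05e9))
  expect_lte(min(starts[changed]), 0.05e9 + 2 * 3e7)
  # applied value matches gamma G dz for the 10 mm offset
  expect_gt(min(abs(freqs[changed])), 100)
})

test_that("without feedback sources the stream is unchanged", {
  seq1 <- build_sequence("flash", toy_protocol("flash"))
  seq2 <- build_sequence("flash", toy_protocol("flash"))
  state <- feedback_state(exposed = list(slice_offset_mm = "protocol.slice_offset_mm"))
  st <- stream_blocks(seq1, runtime_config(buffer_ms = 100), feedback = state)
  expect_identical(st$blocks, stream_collect(seq2))
  expect_true(all(fb_log_df(state)$event != "applied"))
})

test_that("last writer wins between sync points; versions audit applies", {
  g <- param_graph()
  pg_source(g, "x", 0)
  state <- feedback_state(exposed = list(x = "x"))
  fb_set(state, "x", 1)
  fb_set(state, "x", 2)
  expect_equal(fb_get(state, "x")$version, 2)
  expect_null(fb_get(state, "x")$applied)
  applied <- apply_feedback(state, g)
  expect_equal(applied, "x")
  expect_equal(pg_eval(g, "x"), 2)
  expect_equal(fb_get(state, "x")$applied_version, 2)
  # zero pending -> zero invalidations
  expect_length(apply_feedback(state, g), 0)
})

test_that("many distinct updates all apply at the single next sync", {
  g <- param_graph()
  nm <- paste0("p", 1:100)
  for (n in nm) pg_source(g, n, 0)
  state <- feedback_state(exposed = as.list(stats::setNames(nm, nm)))
  for (i in seq_along(nm)) fb_set(state, nm[i], i)
  applied <- apply_feedback(state, g)
  expect_setequal(applied, nm)
  expect_equal(vapply(nm, function(n) pg_eval(g, n), numeric(1)),
               stats::setNames(as.numeric(1:100), nm))
})

test_that("unknown parameters are rejected with a log entry, stream continues", {
  state <- feedback_state(exposed = list(a = "a"))
  expect_false(fb_set(state, "nope", 1))
  log <- fb_log_df(state)
  expect_match(log$event[nrow(log)], "rejected")
  expect_error(fb_get(state, "nope"), "unknown")
  expect_equal(fb_list(state), "a")
})

test_that("the feedback service speaks the JSON message contract", {
  g <- param_graph(); pg_source(g, "node.z", 0)
  state <- feedback_state(exposed = list(slice_z = "node.z"))
  svc <- feedback_service(state)
  expect_equal(jsonlite::fromJSON(svc$handle('{"op":"list"}'))$names, "slice_z")
  ack <- jsonlite::fromJSON(svc$handle(
    '{"op":"set","name":"slice_z","value":4.5,"timestamp":12}'))
  expect_true(ack$ok)
  # pending visible before sync, applied version unchanged
  got <- jsonlite::fromJSON(svc$handle('{"op":"get","name":"slice_z"}'))
  expect_equal(got$pending, 4.5)
  expect_equal(got$applied_version, 0)
  apply_feedback(state, g)
  got2 <- jsonlite::fromJSON(svc$handle('{"op":"get","name":"slice_z"}'))
  expect_equal(got2$applied, 4.5)
  # malformed messages get an error reply and change nothing
  expect_match(svc$handle("{not json"), "malformed")
  expect_match(svc$handle('{"op":"set","name":"missing_value"}'), "error")
  expect_match(svc$handle('{"op":"get","name":"ghost"}'), "unknown")
  expect_equal(jsonlite::fromJSON(svc$handle('{"op":"get","name":"slice_z"}'))$applied,
               4.5)
})

test_that("marked-atomic sync policy applies feedback before slice excitation", {
  seq <- build_sequence("flash", toy_protocol("flash"))
  state <- feedback_state(exposed = list(slice_offset_mm = "protocol.slice_offset_mm"))
  fb_schedule(state, 0.05e9, "slice_offset_mm", 7)
  st <- stream_blocks(seq, runtime_config(buffer_ms = 300,
                                          sync_policy = "at_marked_atomics"),
                      feedback = state)
  rfb <- Filter(function(b) !is.null(b$rf), st$blocks)
  starts <- vapply(rfb, function(b) b$start_ns, numeric(1))
  freqs <- vapply(rfb, function(b) b$rf$freq_hz, numeric(1))
  first_after <- min(which(starts >= 0.05e9))
  # the very first excitation after arrival already reflects the update
  expect_true(freqs[first_after] != 0)
})
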