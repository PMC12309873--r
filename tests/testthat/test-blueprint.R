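empty_protocol <- function() mr_protocol(TR_ms = 10, TE_ms = 5)

test_that("assembling a childless blueprint yields one element and no rules", {
  reg <- bp_registry()
  bp_register(reg, blueprint("solo"))
  seq <- assemble(reg, "solo", empty_protocol())
  expect_equal(seq$tree$kind, "module")
  expect_length(seq$tree$children, 0)
  # graph holds only protocol sources
  expect_true(all(grepl("^protocol\\.", pg_ids(seq$graph))))
  expect_length(stream_collect(seq), 0)  # empty stream
})

test_that("nested loops visit the atomic line x partition times", {
  reg <- bp_registry()
  bp_register(reg, blueprint("readout", atomic = TRUE, rules = list(
    raw = rule(character(), function() list(duration_ns = 1e4)))))
  bp_register(reg, blueprint("line_loop", loop = list(counter = "line", count = 96),
                             children = "readout"))
  bp_register(reg, blueprint("part_loop",
                             loop = list(counter = "partition", count = 120),
                             children = "line_loop"))
  bp_register(reg, blueprint("root", children = "part_loop"))
  seq <- assemble(reg, "root", empty_protocol())
  n <- 0
  it <- block_iterator(seq)
  while (!is.null(it())) n <- n + 1
  expect_equal(n, 96 * 120)  # 11 520 atomic visits
})

test_that("assembly errors: unknown blueprint, cycle, bad loop count", {
  reg <- bp_registry()
  bp_register(reg, blueprint("root", children = "ghost"))
  expect_error(assemble(reg, "root", empty_protocol()), "unknown blueprint.*ghost")

  reg2 <- bp_registry()
  bp_register(reg2, blueprint("root", rules = list(
    a = rule("b", function(x) x),
    b = rule("c", function(x) x),
    c = rule("a", function(x) x))))
  err <- tryCatch(assemble(reg2, "root", empty_protocol()),
                  error = function(e) conditionMessage(e))
  expect_match(err, "cyclic")
  expect_match(err, "root.a"); expect_match(err, "root.b"); expect_match(err, "root.c")

  reg3 <- bp_registry()
  bp_register(reg3, blueprint("a", atomic = TRUE, rules = list(
    raw = rule(character(), function() list(duration_ns = 1e4)))))
  bp_register(reg3, blueprint("loopn", loop = list(counter = "i", count = "n_bad"),
                              children = "a"))
  bp_register(reg3, blueprint("root", rules = list(
    n_bad = rule(character(), function() -3)), children = "loopn"))
  seq3 <- assemble(reg3, "root", empty_protocol())
  expect_error(stream_collect(seq3), "nonnegative integer")
})

test_that("two assemblies of the same definitions stream identically", {
  s1 <- build_sequence("flash", toy_protocol("flash"))
  s2 <- build_sequence("flash", toy_protocol("flash"))
  expect_identical(stream_collect(s1), stream_collect(s2))
})

test_that("check_protocol reports infeasible TE with the computed minimum", {
  p <- toy_protocol("flash"); p$TE_ms <- 0.1
  seq <- suppressWarnings(build_sequence("flash", p))
  rep <- check_protocol(seq, max_blocks = 8)
  expect_true(any(rep$kind == "TE"))
  expect_match(rep$message[rep$kind == "TE"], "minimum [0-9.]+ ms")
  # generous timing: empty report
  expect_equal(nrow(check_protocol(build_sequence("flash", toy_protocol("flash")),
                                   max_blocks = 20)), 0)
  # requested gradient above Gmax surfaces as a hardware violation
  tight <- hardware_limits(g_max_mT_m = 5)
  seq2 <- build_sequence("flash", toy_protocol("flash"))
  blk <- stream_collect(seq2, max_blocks = 4)
  viol <- unlist(lapply(blk, validate_block, limits = tight))
  expect_match(viol, "exceeds Gmax", all = FALSE)
})

test_that("an infeasible TR is extended to the minimum with a warning", {
  p <- toy_protocol("flash"); p$TR_ms <- 1
  expect_warning(seq <- build_sequence("flash", p), "extended")
  expect_gte(seq$protocol$TR_ms, pg_eval(seq$graph, seq$meta$min_tr_node) - 1e-9)
  expect_equal(nrow(check_protocol(seq, max_blocks = 20)), 0)
})

test_that("Pulseq imports embed as children of a native hierarchy", {
  s <- build_sequence("flash", toy_protocol("flash"))
  doc <- export_pulseq(stream_collect(s, max_blocks = 4))
  imp <- import_pulseq(doc)
  reg <- bp_registry()
  register_static_blocks(reg, "imported", imp$blocks)
  bp_register(reg, blueprint("rep_loop", loop = list(counter = "repetition",
                                                     count = 3),
                             children = "imported"))
  bp_register(reg, blueprint("root", children = "rep_loop"))
  seq <- assemble(reg, "root", empty_protocol())
  blocks <- stream_collect(seq)
  expect_length(blocks, 3 * length(imp$blocks))
  # embedded copies replay the imported timings
  durs <- vapply(blocks, function(b) b$duration_ns, numeric(1))
  expect_equal(durs, rep(vapply(imp$blocks, function(b) b$duration_ns,
                                numeric(1)), 3))
})
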