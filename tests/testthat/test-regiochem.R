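test_that("categorical calls reproduce the documented pose setups", {
  # arachidonate control: head out, open channel -> entrance-side carbon
  expect_equal(call_lox_type_categorical(10, 20, "HEAD_EXTERNAL", "OPEN")$oxidation, 8L)
  # same pose with an occluded channel oxidizes on the deep side
  expect_equal(call_lox_type_categorical(10, 20, "HEAD_EXTERNAL", "CLOSED")$oxidation, 12L)
  # head-in pose with a closed gate: deep side is now the head side
  call <- call_lox_type_categorical(11, 16, "HEAD_INTERNAL", "CLOSED")
  expect_equal(call$oxidation, 9L)
  expect_equal(call$lox_type, "LOX9")
})

test_that("out-of-range candidates fall back and are flagged", {
  call <- call_lox_type_categorical(2, 20, "HEAD_EXTERNAL", "OPEN")
  expect_equal(call$oxidation, 4L)
  expect_true("single_candidate" %in% call$flags)
  # deep side off the end with the gate closed
  call2 <- call_lox_type_categorical(19, 20, "HEAD_EXTERNAL", "CLOSED")
  expect_equal(call2$oxidation, 17L)
  expect_true("single_candidate" %in% call2$flags)
  expect_error(call_lox_type_categorical(1, 2, "HEAD_EXTERNAL", "OPEN"),
               "outside the chain")
  expect_error(call_lox_type_categorical(25, 20, "HEAD_EXTERNAL", "OPEN"),
               "outside")
})

test_that("flipping the gate flips the candidate; offsets are always two", {
  for (len in c(16L, 20L, 22L)) {
    for (n in 3:(len - 2L)) {
      for (o in c("HEAD_EXTERNAL", "HEAD_INTERNAL")) {
        open <- call_lox_type_categorical(n, len, o, "OPEN")
        closed <- call_lox_type_categorical(n, len, o, "CLOSED")
        expect_equal(abs(open$oxidation - n), 2L)
        expect_equal(abs(closed$oxidation - n), 2L)
        expect_false(open$oxidation == closed$oxidation)
      }
    }
  }
})

test_that("geometric calls read the delivery side off the pose", {
  fx_open <- make_pocket_fixture(20, 10, "HEAD_EXTERNAL", "GLY", seed = 5)
  at <- load_structure(fx_open$path)
  facts <- pose_facts(at)
  expect_equal(facts$oxidation, 8L)
  fx_closed <- make_pocket_fixture(20, 10, "HEAD_EXTERNAL", "ALA", seed = 5)
  expect_equal(pose_facts(load_structure(fx_closed$path))$oxidation, 12L)
  # boundary: candidate below C1 falls back to the deep side
  fx_edge <- make_pocket_fixture(20, 2, "HEAD_EXTERNAL", "GLY", seed = 5)
  at_edge <- load_structure(fx_edge$path)
  chain <- ligand_chain(at_edge, "LIG")
  frame <- pocket_frame(at_edge, "A:427", c("A:589", "A:620"))
  call <- call_lox_type_geometric(chain, frame, "OPEN")
  expect_equal(call$oxidation, 4L)
  expect_true("single_candidate" %in% call$flags)
})

test_that("pose reports bundle the call with contacts and shell", {
  fx <- make_pocket_fixture(16, 11, "HEAD_INTERNAL", "ALA", seed = 9)
  json <- withr::local_tempfile(fileext = ".json")
  rep <- pose_report(fx$path, "LIG", "A:427", c("A:589", "A:620"),
                     json = json)
  expect_equal(rep$lox_type, "LOX9")
  expect_equal(rep$orientation, "HEAD_INTERNAL")
  expect_equal(rep$gate$state, "CLOSED")
  expect_true(file.exists(json))
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$lox_type, "LOX9")
})
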