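test_that("rules parse to the expected ASTs", {
  m <- parse_model(c("downreg_cell = 2",
                     "NFkB = TLR2 | NOD2 | TLR4",
                     "TLR2 = NFkB", "NOD2 = NFkB", "TLR4 = NFkB",
                     "IL10 = NFkB",
                     "DC = NFkB & !(ANY(IL10, downreg_cell) & DC)"))
  expect_true(expr_equal(m$rules$NFkB$expr,
                         bn_or(bn_atom("TLR2"), bn_atom("NOD2"),
                               bn_atom("TLR4"))))
  expect_true(expr_equal(
    m$rules$DC$expr,
    bn_and(bn_atom("NFkB"),
           bn_not(bn_and(bn_any("IL10", "downreg_cell"), bn_atom("DC"))))))
  expect_identical(m$parameters[["downreg_cell"]], 2L)
})

test_that("precedence is NOT > AND > OR and parentheses override it", {
  m <- parse_model(c("A = B | C & !D", "B = A", "C = A", "D = A",
                     "E = (B | C) & D"))
  expect_true(expr_equal(m$rules$A$expr,
                         bn_or(bn_atom("B"),
                               bn_and(bn_atom("C"), bn_not(bn_atom("D"))))))
  expect_true(expr_equal(m$rules$E$expr,
                         bn_and(bn_or(bn_atom("B"), bn_atom("C")),
                                bn_atom("D"))))
})

test_that("malformed and inconsistent documents raise informative errors", {
  expect_error(parse_model("A = &! B"), "syntax error at line 1")
  expect_error(parse_model(c("A = B", "B = A", "A = !B")), "duplicate rule")
  expect_error(parse_model("A = B"), "undefined node")
  expect_error(parse_model("A = ALL(A, width)"), "unresolved parameter")
  expect_error(parse_model("A = ALL(A, 0)"), "width")
  expect_error(parse_model("w = 0"), "positive")
  expect_error(parse_model("A = (B | C"), "syntax error")
})

test_that("serialization round-trips structurally, including windows", {
  docs <- list(
    character(0),                                    # empty model
    c("A = !B", "B = A"),                            # toy 2-node
    c("w = 3", "A = ALL(B, w) | ANY(B, 2)", "B = !(A & B) | !B")
  )
  for (doc in docs) {
    m <- parse_model(c("# header comment", doc))
    expect_true(model_equal(m, parse_model(serialize_model(m))))
  }
  ibd <- build_ibd_model()
  expect_true(model_equal(ibd, parse_model(serialize_model(ibd))))
})

test_that("serializing a toy model yields its statements and parameters", {
  m <- parse_model(c("w = 2", "A = ALL(B, w)", "B = !A"))
  txt <- serialize_model(m)
  expect_setequal(txt, c("w = 2", "A = ALL(B, w)", "B = !A"))
  expect_identical(serialize_model(parse_model("# empty")), character(0))
})

test_that("interaction extraction follows NOT-parity and de-duplicates", {
  m <- parse_model(c("TLR2 = PGN", "PGN = !TLR2"))
  ia <- extract_interactions(m)
  expect_identical(ia$regulator, c("TLR2", "PGN"))
  expect_identical(ia$sign, c("inhibitory", "activating"))

  m2 <- parse_model(c("A = !B & !(C | !D) & ANY(B, 2)",
                      "B = A", "C = A", "D = A"))
  ia2 <- extract_interactions(m2)
  a <- ia2[ia2$target == "A", ]
  # B appears negated (atom) and un-negated (window): both parities kept
  expect_identical(a$sign[a$regulator == "B"],
                   c("activating", "inhibitory"))
  expect_identical(a$sign[a$regulator == "C"], "inhibitory")
  expect_identical(a$sign[a$regulator == "D"], "activating")
})

test_that("interaction extraction is invariant under child reordering", {
  m1 <- parse_model(c("A = B | !C & D", "B = A", "C = A", "D = A"))
  m2 <- parse_model(c("A = D & !C | B", "B = A", "C = A", "D = A"))
  expect_identical(extract_interactions(m1), extract_interactions(m2))
})

test_that("interaction lists round-trip through TSV", {
  ia <- extract_interactions(build_ibd_model())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(ia, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back, ia)
})
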