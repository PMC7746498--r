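# Tokenization and BRAT / CoNLL round-trip behaviour.

test_that("tokenizer reproduces the clinical example offsets", {
  sents <- ns_tokenize("no masas ni megalias")
  expect_length(sents, 1L)
  tk <- sents[[1]]$tokens
  expect_equal(tk$text, c("no", "masas", "ni", "megalias"))
  expect_equal(tk$start, c(0L, 3L, 9L, 12L))
  expect_equal(tk$end, c(2L, 8L, 11L, 20L))

  full <- ns_tokenize(ref_text)[[1]]$tokens
  expect_equal(nrow(full), 13L)
  expect_equal(full$start[6], 28L)   # "no"
  expect_equal(full$end[6], 30L)
  expect_equal(full$start[12], 53L)  # "doloroso"
  expect_equal(full$end[12], 61L)
})

test_that("token offsets always reconstruct the original substrings", {
  texts <- c(ref_text, "A. B.", "  spaced   out,text! ",
             "uno dos. tres? Cuatro! Si.")
  for (tx in texts) {
    for (s in ns_tokenize(tx)) {
      got <- mapply(function(a, b) slice_text(tx, a, b),
                    s$tokens$start, s$tokens$end)
      expect_equal(unname(got), s$tokens$text)
    }
  }
})

test_that("sentence splitting follows the punctuation + uppercase rule", {
  expect_length(ns_tokenize(""), 0L)
  ss <- ns_tokenize("A. B.")
  expect_length(ss, 2L)
  expect_equal(vapply(ss, function(s) nrow(s$tokens), 1L), c(2L, 2L))
  # lowercase after the period: no break
  expect_length(ns_tokenize("a. b."), 1L)
})

test_that("read_brat parses T lines, discontinuous spans and warns on A/R/E", {
  tf <- tempfile(fileext = ".txt"); af <- tempfile(fileext = ".ann")
  writeLines(ref_text, tf, sep = "", useBytes = TRUE)
  writeLines(c("T1\tNegMarker 28 30\tno",
               "T2\tNegPolIten 28 30;37 39\tno ni",
               "A1\tNegated T1"), af, useBytes = TRUE)
  expect_warning(doc <- read_brat(tf, af), "non-entity")
  ms <- doc$sentences[[1]]$mentions
  expect_length(ms, 2L)
  expect_equal(ms[[1]]$label, "NegMarker")
  expect_equal(unname(ms[[1]]$fragments[1, ]), c(28L, 30L))
  # discontinuous mention has two fragments; label spelling is normalized
  expect_equal(nrow(ms[[2]]$fragments), 2L)
  expect_equal(ms[[2]]$label, "NegPolItem")
  expect_equal(unname(ms[[2]]$fragments[2, ]), c(37L, 39L))
})

test_that("read_brat flags malformed lines, bad offsets and surface drift", {
  tf <- tempfile(fileext = ".txt"); af <- tempfile(fileext = ".ann")
  writeLines("no masas", tf, sep = "", useBytes = TRUE)
  writeLines("T1 NegMarker", af, useBytes = TRUE)       # no tabs
  expect_error(read_brat(tf, af), "line 1")
  writeLines("T1\tNegMarker 0 99\tno", af, useBytes = TRUE)
  expect_error(read_brat(tf, af), "outside")
  writeLines("T1\tNegMarker 0 2\tXX", af, useBytes = TRUE)
  expect_warning(read_brat(tf, af), "does not match")
  writeLines(character(0), af, useBytes = TRUE)          # empty .ann
  doc <- read_brat(tf, af)
  expect_length(doc$sentences[[1]]$mentions, 0L)
})

test_that("BRAT round-trip preserves mentions exactly (ids renumbered)", {
  doc <- ref_document()
  b <- write_brat(doc)
  expect_length(b$ann_lines, 7L)
  stem <- tempfile()
  write_brat_files(doc, stem)
  doc2 <- read_brat(paste0(stem, ".txt"), paste0(stem, ".ann"))
  expect_equal(keyset(negscope:::doc_mentions(doc2)),
               keyset(negscope:::doc_mentions(doc)))

  # property: random generated documents round-trip exactly
  docs <- generate_corpus(gen_config(seed = 21, n_sentences = 100))
  for (d in docs) {
    stem <- tempfile()
    write_brat_files(d, stem)
    d2 <- read_brat(paste0(stem, ".txt"), paste0(stem, ".ann"), id = d$id)
    expect_equal(keyset(negscope:::doc_mentions(d2)),
                 keyset(negscope:::doc_mentions(d)))
  }
})

test_that("CoNLL output matches the reference column layout and round-trips", {
  doc <- ref_document()
  lines <- write_conll(doc)
  expect_equal(lines[6],
    "no\tnegation_iac_3_corr\t28\t30\tW-NegMarker\tW-NegMarker")
  expect_equal(lines[7],
    "masas\tnegation_iac_3_corr\t31\t36\tV-Phrase\tW-DISO")
  # 13 token rows + 1 blank separator
  expect_length(lines, 14L)

  back <- read_conll(lines)
  expect_length(back, 1L)
  s <- back[[1]]$sentences[[1]]
  expect_equal(s$tokens$text, doc$sentences[[1]]$tokens$text)
  expect_equal(s$tags$outer, ref_outer)
  expect_equal(s$tags$inner, ref_inner)
  expect_identical(write_conll(back[[1]]), lines)

  # all-O tag columns decode to zero mentions
  plain <- ns_tokenize("sin datos de interes")[[1]]
  pd <- structure(list(id = "d1", text = "sin datos de interes",
                       sentences = list(plain)), class = "ns_document")
  lines0 <- write_conll(pd)
  expect_true(all(grepl("\tO\tO$", lines0[nzchar(lines0)])))
  expect_length(negscope:::doc_mentions(read_conll(lines0)[[1]]), 0L)
})

test_that("CoNLL round-trip is identity on generated corpora", {
  docs <- generate_corpus(gen_config(seed = 22, n_sentences = 100))
  for (d in docs) {
    lines <- write_conll(d)
    back <- read_conll(lines)[[1]]
    expect_identical(write_conll(back), lines)
    expect_equal(keyset(negscope:::doc_mentions(back)),
                 keyset(split_discontinuous(negscope:::doc_mentions(d))))
  }
})

test_that("ragged CoNLL input is rejected with a line number", {
  lines <- c("a\td\t0\t1\tO\tO", "b\td\t2\t3\tO")
  expect_error(read_conll(lines), "line 2")
})
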