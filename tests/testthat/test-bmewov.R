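# BMEWO-V codec: encoding, decoding, repair, joint vocabulary.

test_that("encoding the worked clinical sentence yields both tag columns", {
  tags <- bmewov_encode(ref_sentence())
  expect_equal(tags$outer, ref_outer)
  expect_equal(tags$inner, ref_inner)
  expect_equal(tags$joint[7], "V-Phrase|W-DISO")
  expect_equal(tags$joint[6], "W-NegMarker")   # inner copy collapses
})

test_that("decoding the worked tag columns recovers all 7 mentions", {
  s <- ref_sentence()
  dec <- bmewov_decode(list(outer = ref_outer, inner = ref_inner),
                       s$tokens)
  expect_length(dec, 7L)
  expect_equal(keyset(dec), keyset(ref_mentions()))
  # spot-check printed offsets
  km <- keyset(dec)
  expect_true("NegMarker#28,30" %in% km)
  expect_true("DISO#53,61" %in% km)
})

test_that("simple shapes: all-O, single multi-token mention", {
  s <- ns_tokenize("sin mas datos hoy")[[1]]
  s$mentions <- list()
  t0 <- bmewov_encode(s)
  expect_true(all(t0$outer == "O") && all(t0$inner == "O"))
  expect_length(bmewov_decode(t0, s$tokens), 0L)

  s$mentions <- list(mention("DISO", 4, 13))   # "mas datos": 2 tokens? no: 4..13 covers mas,datos
  t1 <- bmewov_encode(s)
  expect_equal(t1$outer[2:3], c("B-DISO", "E-DISO"))
  s$mentions <- list(mention("DISO", 4, 17))   # 3 tokens
  t2 <- bmewov_encode(s)
  expect_equal(t2$outer[2:4], c("B-DISO", "M-DISO", "E-DISO"))
  expect_equal(t2$inner[2:4], t2$outer[2:4])   # copies in the inner layer
})

test_that("invalid nesting is rejected with informative errors", {
  s <- ns_tokenize("uno dos tres cuatro cinco")[[1]]
  # depth-3 nesting
  s$mentions <- list(mention("A", 0, 25), mention("B", 0, 12),
                     mention("C", 0, 3))
  expect_error(bmewov_encode(s), "deeper")
  # partial (non-nested) overlap
  s$mentions <- list(mention("A", 0, 12), mention("B", 4, 18))
  expect_error(bmewov_encode(s), "overlapping")
  # two inner mentions on one token
  s$mentions <- list(mention("A", 0, 25), mention("B", 0, 3),
                     mention("C", 0, 3))
  expect_error(bmewov_encode(s))
})

test_that("repair follows the stated reinterpretation rules", {
  expect_equal(bmewov_repair("M-DISO"), "W-DISO")
  expect_equal(bmewov_repair(c("B-DISO", "B-DISO")), c("W-DISO", "W-DISO"))
  expect_equal(bmewov_repair(c("B-DISO", "M-DISO", "O")),
               c("B-DISO", "E-DISO", "O"))
  expect_equal(bmewov_repair(c("E-DISO", "O")), c("W-DISO", "O"))
  expect_equal(bmewov_repair(c("B-DISO", "M-PROC", "E-PROC")),
               c("W-DISO", "B-PROC", "E-PROC"))
  # valid sequences are unchanged
  valid <- c("O", "B-X", "M-X", "E-X", "W-Y", "O", "V-X|W-Y")
  expect_equal(bmewov_repair(valid), valid)
})

test_that("repair is idempotent, length-preserving and always valid", {
  set.seed(99)
  shapes <- c("B", "M", "E", "W", "V")
  labs <- c("X", "Y")
  pool <- c("O", as.vector(outer(shapes, labs, function(s, l)
    paste0(s, "-", l))))
  for (rep_i in 1:200) {
    n <- sample(1:12, 1)
    raw <- paste0(sample(pool, n, TRUE), "|", sample(pool, n, TRUE))
    raw <- sub("^O\\|O$", "O", raw)
    fixed <- bmewov_repair(raw)
    expect_length(fixed, n)
    expect_true(joint_is_valid(fixed))
    expect_equal(bmewov_repair(fixed), fixed)
  }
})

test_that("decode(encode(s)) is the identity on generated nested layouts", {
  docs <- generate_corpus(gen_config(seed = 31, n_sentences = 1000,
                                     p_discontinuous = 0.15,
                                     p_double_negation = 0.2))
  n_checked <- 0L
  for (d in docs) for (s in d$sentences) {
    tags <- bmewov_encode(s)
    dec <- bmewov_decode(tags, s$tokens)
    expect_equal(keyset(dec), keyset(split_discontinuous(s$mentions)))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 1000L)
})

test_that("joint vocabulary sizing and observed pairs", {
  expect_length(joint_vocabulary("cue"), 6L)
  expect_error(joint_vocabulary(character(0)), "non-empty")
  iula_labels <- c("NegMarker", "NegPolItem", "NegPredMarker", "PROC",
                   "DISO", "Phrase", "BODY", "SUBS")
  voc <- joint_vocabulary(iula_labels, corpus = list(ref_document()))
  expect_true("V-Phrase|W-DISO" %in% voc)
  expect_true("V-Phrase|W-NegPolItem" %in% voc)
  expect_equal(voc[1], "O")
  expect_false(anyDuplicated(voc) > 0)
})
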