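test_that("tokenization keeps united systems whole and round-trips", {
  expect_identical(tokenizeSmiles("ClCCl"), c("Cl", "C", "Cl"))
  expect_identical(tokenizeSmiles("c1ccccc1"),
                   c("c", "1", "c", "c", "c", "c", "c", "1"))
  expect_identical(tokenizeSmiles("C%11"), c("C", "%11"))
  expect_identical(tokenizeSmiles("C@@H"), c("C", "@@", "H"))
  expect_identical(tokenizeSmiles("[nH]c"), c("[nH]", "c"))
  expect_identical(tokenizeSmiles("BrC(=O)N"),
                   c("Br", "C", "(", "=", "O", ")", "N"))

  # lossless round trip over a battery of strings
  cases <- c("ClCCl", "c1ccccc1", "C%11CC%11", "CC(=O)Oc1ccccc1C(=O)O",
             "[C@@H](N)C(=O)O", "O=[N+]([O-])c1ccccc1", "C@@[Si]Cl")
  for (s in cases) {
    expect_identical(paste(tokenizeSmiles(s), collapse = ""), s)
  }
})

test_that("tokenization rejects malformed input with typed errors", {
  expect_cwqsar_error(tokenizeSmiles(""), "invalid_input")
  expect_cwqsar_error(tokenizeSmiles("C[NH"), "malformed_smiles")
  expect_cwqsar_error(tokenizeSmiles("C%1"), "malformed_smiles")
  expect_cwqsar_error(tokenizeSmiles("C%a1"), "malformed_smiles")
})

test_that("pair and triple keys are canonical and reversal-invariant", {
  b <- extractAttributes("ClCCl",
                         attrConfig(sk = FALSE, fls = FALSE, app = FALSE))
  expect_equal(unname(b["SS:C|Cl"]), 2L)
  expect_equal(unname(b["SSS:Cl|C|Cl"]), 1L)

  # reversal invariance on random token sequences
  set.seed(11)
  alphabet <- c("C", "c", "N", "O", "Cl", "(", ")", "1", "=")
  for (i in 1:25) {
    toks <- sample(alphabet, sample(2:12, 1), replace = TRUE)
    s <- paste(toks, collapse = "")
    r <- paste(rev(tokenizeSmiles(s)), collapse = "")
    cfg <- attrConfig(sk = FALSE, fls = FALSE, app = FALSE)
    expect_identical(sort(names(extractAttributes(s, cfg))),
                     sort(names(extractAttributes(r, cfg))))
    expect_identical(as.integer(extractAttributes(s, cfg)[
                       sort(names(extractAttributes(s, cfg)))]),
                     as.integer(extractAttributes(r, cfg)[
                       sort(names(extractAttributes(r, cfg)))]))
  }
})

test_that("single tokens are emitted once per occurrence", {
  b <- extractAttributes("ClCCl", attrConfig(ssk = FALSE, sssk = FALSE,
                                             fls = FALSE, app = FALSE))
  expect_equal(unname(b["S:Cl"]), 2L)
  expect_equal(unname(b["S:C"]), 1L)
  expect_equal(sum(b), length(tokenizeSmiles("ClCCl")))
})

test_that("FLS windows match the brute-force substring oracle", {
  expect_identical(detectFls(c("O", "C", "O")), "[xyx0]")
  expect_identical(detectFls(c("O", "C", "C", "O")), "[xyyx0]")
  expect_identical(detectFls(c("C", "C", "C")), character(0))
  # the inner CNC window is itself an XYX fragment
  expect_identical(sort(detectFls(c("O", "C", "N", "C", "O"))),
                   c("[xyx0]", "[xyzyx0]"))
  # Y != Z required for XYZYX
  expect_false("[xyzyx0]" %in% detectFls(c("O", "C", "C", "C", "O")))

  fls_oracle <- function(tokens) {
    out <- character()
    n <- length(tokens)
    for (len in 3:5) {
      if (n < len) next
      for (i in seq_len(n - len + 1L)) {
        w <- tokens[i:(i + len - 1L)]
        if (len == 3L && w[1] == w[3] && w[1] != w[2]) out <- c(out, "[xyx0]")
        if (len == 4L && w[1] == w[4] && w[2] == w[3] && w[1] != w[2])
          out <- c(out, "[xyyx0]")
        if (len == 5L && w[1] == w[5] && w[2] == w[4] && w[1] != w[2] &&
            w[2] != w[3]) out <- c(out, "[xyzyx0]")
      }
    }
    out
  }
  set.seed(5)
  for (i in 1:40) {
    toks <- sample(c("C", "c", "N", "O", "1", "("),
                   sample(3:14, 1), replace = TRUE)
    expect_identical(sort(detectFls(toks)), sort(fls_oracle(toks)),
                     info = paste(toks, collapse = ""))
  }
})

test_that("APP keys discretize the element count ratio", {
  expect_identical(extractApp(tokenizeSmiles("ClCCl")), "APP(C,Cl,5)")
  expect_identical(extractApp(tokenizeSmiles("CC")), character(0))
  expect_identical(extractApp(tokenizeSmiles("CN")), "APP(C,N,10)")
  expect_cwqsar_error(extractApp(c("C"), vocab = character(0)),
                      "config_error")
})

test_that("attribute extraction honours family switches", {
  b <- extractAttributes("ClCCl", attrConfig(ssk = FALSE, sssk = FALSE,
                                             fls = FALSE, app = FALSE))
  expect_setequal(names(b), c("S:C", "S:Cl"))
  empty <- extractAttributes("ClCCl",
                             attrConfig(sk = FALSE, ssk = FALSE,
                                        sssk = FALSE, fls = FALSE,
                                        app = FALSE))
  expect_length(empty, 0L)
  expect_cwqsar_error(extractAttributes(""), "invalid_input")
  fams <- attributeFamilies(extractAttributes("ClCCl"))
  expect_setequal(unique(unname(fams)),
                  c("Sk", "SSk", "SSSk", "FLS", "APP"))
})

test_that("extraction is deterministic and pure", {
  s <- "CC(=O)Oc1ccccc1C(=O)O"
  b1 <- extractAttributes(s)
  b2 <- extractAttributes(s)
  expect_identical(b1, b2)
})
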