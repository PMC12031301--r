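#' Attribute extraction configuration
#'
#' Controls which attribute families are extracted from a tokenized SMILES
#' and how they are keyed. The families are: single tokens (`Sk`), adjacent
#' token pairs (`SSk`), adjacent triples (`SSSk`), fragments of local
#' symmetry (`FLS`: token windows of shape XYX, XYYX or XYZYX with X != Y
#' and, for XYZYX, Y != Z), and atom-pair proportions (`APP`: a discretized
#' ratio of the counts of two element tokens).
#'
#' @param sk,ssk,sssk,fls,app logical switches for the five families.
#' @param flsContent if `TRUE`, FLS keys carry the matched tokens
#'   (e.g. `"[xyx:O|C]"`); by default keys are class-level (`"[xyx0]"`,
#'   `"[xyyx0]"`, `"[xyzyx0]"`) so all fragments of one shape share a weight.
#' @param appVocab character vector of element tokens counted for the APP
#'   family.
#' @return A list of class `attrConfig`.
#' @examples
#' cfg <- attrConfig(fls = FALSE)
#' extractAttributes("ClCCl", cfg)
#' @export
attrConfig <- function(sk = TRUE, ssk = TRUE, sssk = TRUE,
                       fls = TRUE, app = TRUE, flsContent = FALSE,
                       appVocab = c("C", "c", "N", "n", "O", "o", "S", "s",
                                    "P", "F", "Cl", "Br", "I")) {
  if (app && length(appVocab) == 0L) {
    stop_typed("config_error", "APP vocabulary must be non-empty")
  }
  structure(list(sk = sk, ssk = ssk, sssk = sssk, fls = fls, app = app,
                 flsContent = flsContent, appVocab = appVocab),
            class = "attrConfig")
}

# Canonical keys: "|" never occurs inside a token, so it is a safe separator;
# pair/triple end tokens are ordered so the key is direction-independent.
# Byte-order token ranks (radix = C locale), so canonical keys do not depend
# on the session collation.
token_rank <- function(a, b) {
  u <- sort(unique(c(a, b)), method = "radix")
  list(a = match(a, u), b = match(b, u))
}

extract_pairs <- function(tokens) {
  n <- length(tokens)
  if (n < 2L) return(character())
  a <- tokens[-n]; b <- tokens[-1L]
  r <- token_rank(a, b)
  swap <- r$a > r$b
  lo <- ifelse(swap, b, a); hi <- ifelse(swap, a, b)
  paste0("SS:", lo, "|", hi)
}

extract_triples <- function(tokens) {
  n <- length(tokens)
  if (n < 3L) return(character())
  a <- tokens[seq_len(n - 2L)]
  m <- tokens[seq.int(2L, n - 1L)]
  b <- tokens[seq.int(3L, n)]
  r <- token_rank(a, b)
  swap <- r$a > r$b
  lo <- ifelse(swap, b, a); hi <- ifelse(swap, a, b)
  paste0("SSS:", lo, "|", m, "|", hi)
}

#' Fragments of local symmetry in a token sequence
#'
#' Scans all windows of length 3, 4 and 5 for the palindromic shapes XYX
#' (`t1 == t3`, `t1 != t2`), XYYX (`t1 == t4`, `t2 == t3`, `t1 != t2`) and
#' XYZYX (`t1 == t5`, `t2 == t4`, `t1 != t2`, `t2 != t3`).
#'
#' @param tokens character vector of SMILES tokens.
#' @param content if `TRUE`, keys record the matched tokens; otherwise one
#'   class-level key per shape.
#' @return Character vector of FLS keys, one per matching window.
#' @examples
#' detectFls(c("O", "C", "O"))
#' detectFls(c("C", "C", "C"))   # X != Y fails: no fragment
#' @export
detectFls <- function(tokens, content = FALSE) {
  n <- length(tokens)
  keys <- character()
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      w <- tokens[i:(i + 2L)]
      if (w[1L] == w[3L] && w[1L] != w[2L]) {
        keys <- c(keys, if (content) paste0("[xyx:", w[1L], "|", w[2L], "]")
                        else "[xyx0]")
      }
    }
  }
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      w <- tokens[i:(i + 3L)]
      if (w[1L] == w[4L] && w[2L] == w[3L] && w[1L] != w[2L]) {
        keys <- c(keys, if (content) paste0("[xyyx:", w[1L], "|", w[2L], "]")
                        else "[xyyx0]")
      }
    }
  }
  if (n >= 5L) {
    for (i in seq_len(n - 4L)) {
      w <- tokens[i:(i + 4L)]
      if (w[1L] == w[5L] && w[2L] == w[4L] && w[1L] != w[2L] &&
          w[2L] != w[3L]) {
        keys <- c(keys, if (content)
                    paste0("[xyzyx:", w[1L], "|", w[2L], "|", w[3L], "]")
                  else "[xyzyx0]")
      }
    }
  }
  keys
}

#' Atom-pair proportion attributes
#'
#' For every unordered pair of vocabulary elements both present in the
#' molecule, emits one key `APP(X,Y,r)` where
#' `r = round(10 * min(nX, nY) / max(nX, nY))`, clamped to a minimum of 1,
#' i.e. a ten-level discretization of the count ratio.
#'
#' @param tokens character vector of SMILES tokens.
#' @param vocab element tokens to count (exact token match).
#' @return Character vector of APP keys.
#' @examples
#' extractApp(tokenizeSmiles("ClCCl"))  # "APP(C,Cl,5)"
#' @export
extractApp <- function(tokens, vocab = attrConfig()$appVocab) {
  if (length(vocab) == 0L) {
    stop_typed("config_error", "APP vocabulary must be non-empty")
  }
  cnt <- vapply(vocab, function(v) sum(tokens == v), integer(1L))
  present <- vocab[cnt > 0L]
  if (length(present) < 2L) return(character())
  keys <- character()
  for (i in seq_len(length(present) - 1L)) {
    for (j in seq.int(i + 1L, length(present))) {
      x <- present[i]; y <- present[j]
      pr <- sort(c(x, y), method = "radix")
      r <- max(1L, as.integer(round(10 * min(cnt[x], cnt[y]) /
                                      max(cnt[x], cnt[y]))))
      keys <- c(keys, paste0("APP(", pr[1L], ",", pr[2L], ",", r, ")"))
    }
  }
  keys
}

bag_from_keys <- function(keys, families) {
  if (length(keys) == 0L) {
    return(structure(integer(), names = character(),
                     family = character(), class = "attrBag"))
  }
  o <- order(keys, method = "radix")
  keys <- keys[o]; families <- families[o]
  tab <- rle(keys)
  fam <- families[cumsum(tab$lengths)]
  structure(as.integer(tab$lengths), names = tab$values,
            family = fam, class = "attrBag")
}

#' Extract the attribute multiset of a SMILES string
#'
#' Tokenizes the SMILES and extracts every enabled attribute family. The
#' result is the multiset of attribute keys whose correlation weights are
#' summed by [dcw()].
#'
#' @param smiles one SMILES string, or a character vector (a list of bags is
#'   returned, named by the input).
#' @param config an [attrConfig()].
#' @return For a single string, an `attrBag`: a named integer vector of key
#'   multiplicities with a `family` attribute (`Sk`, `SSk`, `SSSk`, `FLS`,
#'   `APP`) aligned with the names. For a vector input, a list of bags.
#' @examples
#' extractAttributes("ClCCl", attrConfig(ssk = FALSE, sssk = FALSE,
#'                                       fls = FALSE, app = FALSE))
#' @export
extractAttributes <- function(smiles, config = attrConfig()) {
  if (length(smiles) > 1L) {
    out <- lapply(smiles, extractAttributes, config = config)
    names(out) <- smiles
    return(out)
  }
  tokens <- tokenizeSmiles(smiles)
  keys <- character(); fams <- character()
  add <- function(k, f) {
    if (length(k)) {
      keys <<- c(keys, k)
      fams <<- c(fams, rep(f, length(k)))
    }
  }
  if (config$sk) add(paste0("S:", tokens), "Sk")
  if (config$ssk) add(extract_pairs(tokens), "SSk")
  if (config$sssk) add(extract_triples(tokens), "SSSk")
  if (config$fls) add(detectFls(tokens, content = config$flsContent), "FLS")
  if (config$app) add(extractApp(tokens, vocab = config$appVocab), "APP")
  bag_from_keys(keys, fams)
}

#' @describeIn extractAttributes family tags of a bag's keys.
#' @param bag an `attrBag`.
#' @export
attributeFamilies <- function(bag) {
  structure(attr(bag, "family"), names = names(bag))
}
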