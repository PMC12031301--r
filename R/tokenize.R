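#' Tokenize a SMILES string
#'
#' Splits a SMILES string into the atomic units the correlation-weight
#' descriptor operates on. The method works on the character sequence, not
#' the molecular graph: no aromaticity perception or chemical validation is
#' performed. Multi-character units that must never be split are the
#' two-letter halogens `Cl` and `Br`, the chirality marker `@@`, ring
#' closures `%NN` (percent sign plus two digits), and bracket atom
#' expressions `[...]` (one token from `[` to the matching `]`). Every other
#' character — including ring-closure digits, branch parentheses and bond
#' symbols — is its own token.
#'
#' @param smiles a single non-empty SMILES string.
#' @return Character vector of tokens; concatenating them reproduces the
#'   input exactly.
#' @examples
#' tokenizeSmiles("ClCCl")     # "Cl" "C" "Cl"
#' tokenizeSmiles("c1ccccc1")
#' tokenizeSmiles("C%11")      # "C" "%11"
#' @export
tokenizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles)) {
    stop_typed("invalid_input", "smiles must be a single character string")
  }
  if (!nzchar(smiles)) {
    stop_typed("invalid_input", "empty SMILES string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(n)
  nt <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop_typed("malformed_smiles", "unclosed '[' at position %d", i)
      }
      tok <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("^[0-9]$", chars[(i + 1L):(i + 2L)]))) {
        stop_typed("malformed_smiles",
                   "'%%' at position %d not followed by two digits", i)
      }
      tok <- paste(chars[i:(i + 2L)], collapse = "")
      i <- i + 3L
    } else if (i < n &&
               ((ch == "C" && chars[i + 1L] == "l") ||
                (ch == "B" && chars[i + 1L] == "r") ||
                (ch == "@" && chars[i + 1L] == "@"))) {
      tok <- paste0(ch, chars[i + 1L])
      i <- i + 2L
    } else {
      tok <- ch
      i <- i + 1L
    }
    nt <- nt + 1L
    tokens[nt] <- tok
  }
  tokens[seq_len(nt)]
}
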