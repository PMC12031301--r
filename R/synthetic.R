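#' Default ground-truth token weights of the synthetic generator
#'
#' One fixed choice of per-token effects on the endpoint, on a pIC50-like
#' scale: aromatic carbon and nitrogens raise the endpoint, oxygen and
#' chlorine lower it. Tokens absent from this table (ring digits, branch
#' parentheses) carry no effect, so pair/triple/FLS/APP attributes act as
#' nuisance families for the optimizer.
#'
#' @return Named numeric vector of token weights.
#' @export
defaultTrueWeights <- function() {
  c(C = 0.08, c = 0.25, N = 0.12, n = 0.18,
    O = -0.10, S = 0.05, Cl = -0.18, F = -0.05)
}

#' Default fragment library of the synthetic generator
#'
#' Drug-like molecules are combinations of a modest set of recurring
#' substructures, which keeps the SMILES-attribute vocabulary of a real
#' dataset compact and heavily shared between random subsets. The
#' generator therefore concatenates fragments from this fixed library
#' (aromatic rings, alkyl runs, heteroatom links) rather than sampling
#' tokens independently.
#'
#' @return Named numeric vector: fragment string -> sampling weight.
#' @export
defaultMotifs <- function() {
  c("c1ccccc1" = 0.16, "c1ccncc1" = 0.06, "n1ccccc1" = 0.04,
    "CC" = 0.10, "CCC" = 0.09, "CCCC" = 0.05,
    "CO" = 0.07, "OC" = 0.05, "CN" = 0.07, "NC" = 0.05,
    "CCO" = 0.05, "NCC" = 0.04,
    "C(C)C" = 0.05, "C(C)O" = 0.03, "C(N)C" = 0.03,
    "C(Cl)C" = 0.02, "CS" = 0.02, "CF" = 0.03, "CCl" = 0.03,
    "OCC" = 0.04, "Fc1ccccc1" = 0.02)
}

count_atoms <- function(s) nchar(gsub("[^A-Za-z]", "", s))

gen_one_smiles <- function(motifs, motifProbs, branchProb, maxLength) {
  budget <- sample(6:maxLength, 1L)
  out <- character(0)
  natoms <- 0L
  first <- TRUE
  while (natoms < budget) {
    m <- sample(names(motifs), 1L, prob = motifProbs)
    if (!first && stats::runif(1) < branchProb) m <- paste0("(", m, ")")
    out <- c(out, m)
    natoms <- natoms + count_atoms(m)
    first <- FALSE
  }
  paste(out, collapse = "")
}

gen_one_chain <- function(vocab, vocabProbs, persistence, maxLength,
                          ringProb, branchProb) {
  L <- sample(4:maxLength, 1L)
  draw <- function(prev) {
    if (!is.null(prev) && stats::runif(1) < persistence) return(prev)
    sample(vocab, 1L, prob = vocabProbs)
  }
  out <- character(0)
  prev <- NULL
  i <- 0L
  while (i < L) {
    prev <- draw(prev)
    out <- c(out, prev)
    i <- i + 1L
    if (i < L && stats::runif(1) < branchProb) {
      blen <- sample.int(min(3L, L - i), 1L)
      bprev <- prev
      for (k in seq_len(blen)) bprev[k + 1L] <- draw(bprev[k])
      out <- c(out, "(", bprev[-1L], ")")
      i <- i + blen
    }
  }
  if (stats::runif(1) < ringProb && length(out) >= 3L) {
    out <- c(out[1L], "1", out[-1L], "1")
  }
  paste(out, collapse = "")
}

#' Generate grammar-constrained random SMILES strings
#'
#' By default each molecule is a concatenation of fragments from a fixed
#' organic library ([defaultMotifs()]), optionally wrapped in branch
#' parentheses, up to an atom budget — emulating the compact, heavily
#' shared attribute vocabulary of real compound collections. Passing
#' `motifs = NULL` switches to a token-chain process over `vocab` with
#' optional persistence, ring closures and branches. All strings tokenize
#' losslessly with [tokenizeSmiles()]; no chemical realism beyond the
#' string statistics is claimed.
#'
#' @param n number of strings.
#' @param motifs named numeric vector (fragment -> sampling weight), or
#'   `NULL` for the token-chain process.
#' @param vocab atom tokens for the chain process.
#' @param vocabProbs sampling probabilities for `vocab`.
#' @param persistence chain process: probability of repeating the previous
#'   atom.
#' @param maxLength atom budget per molecule (`>= 4`).
#' @param ringProb chain process: probability of a ring closure pair.
#' @param branchProb probability of branching (wrapping a fragment, or
#'   opening a short side chain).
#' @param seed integer RNG seed.
#' @return Character vector of length `n`; deterministic per seed.
#' @export
generateSmiles <- function(n, motifs = defaultMotifs(),
                           vocab = names(defaultTrueWeights()),
                           vocabProbs = NULL, persistence = 0.5,
                           maxLength = 20L, ringProb = 0.2,
                           branchProb = 0.2, seed = 1L) {
  if (maxLength < 4L) {
    stop_typed("config_error", "maxLength must be at least 4")
  }
  if (is.null(motifs)) {
    if (length(vocab) == 0L) stop_typed("config_error", "empty vocabulary")
    if (is.null(vocabProbs) || length(vocabProbs) != length(vocab)) {
      vocabProbs <- rep(1 / length(vocab), length(vocab))
    }
    return(with_seed(seed, vapply(seq_len(n), function(i) {
      gen_one_chain(vocab, vocabProbs, persistence, maxLength, ringProb,
                    branchProb)
    }, character(1L))))
  }
  if (length(motifs) == 0L) stop_typed("config_error", "empty motif set")
  with_seed(seed, vapply(seq_len(n), function(i) {
    gen_one_smiles(motifs, unname(motifs), branchProb, maxLength)
  }, character(1L)))
}

#' Generate endpoints linear in token counts
#'
#' The latent endpoint of each molecule is
#' `intercept + sum(trueWeights * token count) + Gaussian(0, noiseSd)`.
#' For regression the latent value is returned directly (a pIC50-like
#' scale); for classification each molecule is labelled 1 iff its latent
#' value reaches the median, which keeps the classes balanced regardless of
#' the weights.
#'
#' @param smiles character vector of SMILES.
#' @param trueWeights named numeric token weights.
#' @param noiseSd Gaussian noise standard deviation (`>= 0`).
#' @param task `"regression"` or `"classification"`.
#' @param intercept baseline endpoint value.
#' @param seed integer RNG seed.
#' @return Numeric endpoint vector (0/1 for classification).
#' @export
generateEndpoint <- function(smiles, trueWeights = defaultTrueWeights(),
                             noiseSd = 0.3,
                             task = c("regression", "classification"),
                             intercept = 4, seed = 1L) {
  task <- match.arg(task)
  if (noiseSd < 0) stop_typed("config_error", "noiseSd must be >= 0")
  base <- vapply(smiles, function(s) {
    tok <- tokenizeSmiles(s)
    sum(trueWeights[tok], na.rm = TRUE)
  }, numeric(1L))
  latent <- intercept + base +
    with_seed(seed, stats::rnorm(length(smiles), sd = noiseSd))
  if (task == "regression") unname(latent)
  else as.numeric(latent >= stats::median(latent))
}

#' Synthetic benchmark dataset with known ground truth
#'
#' Convenience wrapper combining [generateSmiles()] and
#' [generateEndpoint()] into a [SmilesSet-class]. The generating model —
#' an endpoint linear in single-token counts — lies inside the descriptor
#' family, so with zero noise the correlation-weight optimizer can in
#' principle represent it exactly.
#'
#' @inheritParams generateSmiles
#' @inheritParams generateEndpoint
#' @return A [SmilesSet-class]; the generator settings and true weights are
#'   attached as attribute `"groundTruth"`.
#' @examples
#' ds <- syntheticDataset(n = 50, seed = 1)
#' ds
#' @export
syntheticDataset <- function(n = 200L, motifs = defaultMotifs(),
                             trueWeights = defaultTrueWeights(),
                             vocab = names(defaultTrueWeights()),
                             vocabProbs = NULL, persistence = 0.5,
                             maxLength = 20L, ringProb = 0.2,
                             branchProb = 0.2, noiseSd = 0.3,
                             task = c("regression", "classification"),
                             intercept = 4, seed = 1L) {
  task <- match.arg(task)
  smiles <- generateSmiles(n, motifs = motifs, vocab = vocab,
                           vocabProbs = vocabProbs,
                           persistence = persistence,
                           maxLength = maxLength, ringProb = ringProb,
                           branchProb = branchProb, seed = seed)
  y <- generateEndpoint(smiles, trueWeights, noiseSd, task,
                        intercept = intercept,
                        seed = derive_seed(seed, 1L))
  ds <- SmilesSet(smiles = smiles, endpoint = y, task = task)
  attr(ds, "groundTruth") <- list(
    motifs = motifs, trueWeights = trueWeights, maxLength = maxLength,
    ringProb = ringProb, branchProb = branchProb, noiseSd = noiseSd,
    intercept = intercept, task = task, seed = as.integer(seed))
  ds
}
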