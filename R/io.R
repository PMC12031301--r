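#' Read a compound dataset from CSV, TSV or .smi
#'
#' CSV/TSV files must carry columns `id`, `smiles`, `endpoint` and may
#' carry `split` (labels in `A/P/C/V`); `.smi` files are tab-separated
#' `SMILES<TAB>id<TAB>endpoint` with no header. Identifiers must be unique;
#' endpoints must be numeric (all 0/1 for classification). Exact duplicate
#' SMILES strings are detected and reported via the `"duplicates"`
#' attribute of the result; `dropDuplicates = TRUE` keeps the first
#' occurrence of each duplicated string.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"smi"`.
#' @param task `"regression"` or `"classification"`.
#' @param dropDuplicates drop all but the first record of each duplicated
#'   SMILES string.
#' @return A [SmilesSet-class]; attribute `"duplicates"` holds a data.frame
#'   of duplicated records (line number, id, smiles), empty when there are
#'   none.
#' @export
readDataset <- function(path, format = c("auto", "csv", "tsv", "smi"),
                        task = c("regression", "classification"),
                        dropDuplicates = FALSE) {
  format <- match.arg(format)
  task <- match.arg(task)
  if (!file.exists(path)) {
    stop_typed("parse_error", "file not found: %s", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", smi = "smi",
                     stop_typed("parse_error",
                                "cannot infer format from extension '%s'",
                                ext))
  }
  if (format == "smi") {
    raw <- utils::read.delim(path, header = FALSE,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 3L) {
      stop_typed("parse_error", ".smi needs SMILES<TAB>id<TAB>endpoint")
    }
    df <- data.frame(id = raw[[2L]], smiles = raw[[1L]],
                     endpoint = raw[[3L]], stringsAsFactors = FALSE)
  } else {
    df <- if (format == "csv") {
      utils::read.csv(path, colClasses = "character",
                      stringsAsFactors = FALSE)
    } else {
      utils::read.delim(path, colClasses = "character",
                        stringsAsFactors = FALSE)
    }
    need <- c("id", "smiles", "endpoint")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop_typed("parse_error", "missing column(s): %s",
                 paste(miss, collapse = ", "))
    }
  }
  line_no <- seq_len(nrow(df)) + if (format == "smi") 0L else 1L
  y <- suppressWarnings(as.numeric(df$endpoint))
  if (anyNA(y)) {
    stop_typed("parse_error", "non-numeric endpoint at line %d",
               line_no[which(is.na(y))[1L]])
  }
  if (task == "classification" && !all(y %in% c(0, 1))) {
    stop_typed("parse_error",
               "classification endpoint not 0/1 at line %d",
               line_no[which(!(y %in% c(0, 1)))[1L]])
  }
  if (anyDuplicated(df$id)) {
    stop_typed("parse_error", "duplicate id at line %d",
               line_no[which(duplicated(df$id))[1L]])
  }
  dup_idx <- which(df$smiles %in% df$smiles[duplicated(df$smiles)])
  duplicates <- data.frame(line = line_no[dup_idx], id = df$id[dup_idx],
                           smiles = df$smiles[dup_idx],
                           stringsAsFactors = FALSE)
  keep <- seq_len(nrow(df))
  if (dropDuplicates) keep <- which(!duplicated(df$smiles))
  split <- if ("split" %in% names(df)) df$split[keep] else NULL
  ds <- SmilesSet(smiles = df$smiles[keep], endpoint = y[keep],
                  ids = df$id[keep], split = split, task = task)
  attr(ds, "duplicates") <- duplicates
  ds
}

#' Write a dataset (and split labels) as CSV
#'
#' @param dataset a [SmilesSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeDataset <- function(dataset, path) {
  df <- data.frame(id = compoundIds(dataset),
                   smiles = smilesStrings(dataset),
                   endpoint = endpoints(dataset),
                   split = as.character(splitLabels(dataset)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeDataset two-column split file (id, label).
#' @param split named factor/character of `A/P/C/V` labels.
#' @export
writeSplit <- function(split, path) {
  df <- data.frame(id = names(split), label = as.character(split),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn writeDataset read a two-column split file back.
#' @export
readSplit <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  structure(factor(df$label, levels = c("A", "P", "C", "V")),
            names = df$id)
}

# Polynomial hash of a deparsed object; used to stamp artifacts with the
# configuration they came from.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
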