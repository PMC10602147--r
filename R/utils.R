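# Internal helpers shared across modules.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' Canonical 96-context labels
#'
#' Pyrimidine-centred trinucleotide labels of the form \code{X[R>A]Y}, ordered
#' by substitution class (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank, then
#' 3' flank -- the conventional layout of a 96-context mutation catalog.
#'
#' @return Character vector of length 96.
#' @export
contextLabels96 <- function() {
  unlist(lapply(SUBSTITUTION_CLASSES, function(cls) {
    as.vector(t(outer(BASES, BASES, function(f5, f3)
      paste0(f5, "[", cls, "]", f3))))
  }), use.names = FALSE)
}

# reverse complement of a vector of base strings (single bases or k-mers)
revComp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(comp[b])), collapse = ""), character(1))
}

# run `expr` under a fixed RNG seed without disturbing global state;
# seed = NULL uses the current RNG stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# tab-separated dialect used by every reader/writer: '#' comments, no quoting
readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stopf("%s is missing required column(s): %s", what,
          paste(missing, collapse = ", "))
  invisible(TRUE)
}
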