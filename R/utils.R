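# Internal helpers shared across modules: seeded evaluation, deterministic
# seed derivation, and small sequence utilities.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded operations do not
#' perturb the global random number stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

#' Derive a reproducible child seed from components
#'
#' Polynomial rolling hash of the string representation of the components,
#' reduced modulo 2^31 - 1 so the result is a valid 32-bit R seed. Used to
#' give each pair/stage/replicate its own deterministic stream.
#'
#' @param ... atomic components (coerced to character).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)), collapse = "|")
  bytes <- utf8ToInt(s)
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% m
  as.integer(h %% (m - 2L) + 1L)
}

dna_alphabet <- c("A", "C", "G", "T")

#' Random DNA string(s)
#' @keywords internal
random_dna <- function(n_char, n = 1L) {
  vapply(seq_len(n), function(i)
    paste(sample(dna_alphabet, n_char, replace = TRUE), collapse = ""),
    character(1))
}

#' Reverse complement of character sequences
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Hamming distance between two equal-length strings
#' @keywords internal
hamming <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  if (length(ia) != length(ib)) stop("hamming(): unequal lengths")
  sum(ia != ib)
}

#' Inject uniform substitution errors into a DNA string
#' @keywords internal
mutate_bases <- function(seq, n_sub) {
  if (n_sub == 0L) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample.int(length(chars), min(n_sub, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(dna_alphabet, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
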