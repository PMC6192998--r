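# Internal helpers shared across modules.

#' @importFrom stats rnbinom rlnorm rnorm runif sd ks.test t.test cor pt
#' @importFrom utils write.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## seed = NULL runs in the ambient RNG stream (no save/restore), so callers
## can nest seeded operations deterministically.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(code)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

## Uppercase and coerce to the DNA alphabet (U -> T).
.asDnaChar <- function(x) chartr("U", "T", toupper(x))

## Uppercase and coerce to the RNA alphabet (T -> U).
.asRnaChar <- function(x) chartr("T", "U", toupper(x))

.checkAlphabet <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTUN]", toupper(x))
  if (any(bad))
    stop(what, " contains letters outside {A,C,G,T,U,N}: ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  invisible(TRUE)
}

## Reverse complement of an RNA string (character in/out).
.revCompRna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGUT", "UGCAA", toupper(s)), "")[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## One uniform draw of an integer in 0:(k-1) per element of k (vectorized).
.runifInt0 <- function(k) {
  out <- floor(runif(length(k)) * k)
  pmin(out, k - 1)
}
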