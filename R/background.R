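#' Canonical amino-acid alphabet
#'
#' The 20 canonical amino acids in alphabetical one-letter order.  All
#' sequences and substrate windows handled by the package are restricted to
#' this alphabet; ambiguity codes are rejected.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Human proteome amino-acid background frequencies
#'
#' Amino-acid frequencies of the human proteome (reviewed UniProt entries,
#' rounded), normalised to sum exactly to one.  Used as the default
#' background distribution when turning cleavage-site counts into log-odds
#' scores; any other 20-element frequency vector named by [AA_ALPHABET] can
#' be supplied instead.
#'
#' @format Named numeric vector of length 20 summing to 1.
#' @seealso [build_pssm()]
#' @export
human_aa_freq <- local({
  f <- c(A = 0.0702, C = 0.0230, D = 0.0473, E = 0.0710, F = 0.0365,
         G = 0.0657, H = 0.0263, I = 0.0433, K = 0.0573, L = 0.0996,
         M = 0.0213, N = 0.0359, P = 0.0631, Q = 0.0477, R = 0.0564,
         S = 0.0833, T = 0.0535, V = 0.0597, W = 0.0122, Y = 0.0267)
  f / sum(f)
})

## -- shared validation helpers -------------------------------------------

check_background <- function(background) {
  if (!is.numeric(background) || length(background) != 20L)
    stop("'background' must be a numeric vector of length 20", call. = FALSE)
  if (is.null(names(background))) {
    names(background) <- AA_ALPHABET
  } else if (!setequal(names(background), AA_ALPHABET)) {
    stop("'background' names must be the 20 canonical amino acids",
         call. = FALSE)
  }
  background <- background[AA_ALPHABET]
  if (any(background < 0))
    stop("'background' frequencies must be nonnegative", call. = FALSE)
  if (abs(sum(background) - 1) > 1e-9)
    stop("'background' frequencies must sum to 1 (within 1e-9)",
         call. = FALSE)
  background
}

check_sequence <- function(sequence, arg = "sequence") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop(sprintf("'%s' must be a single character string", arg),
         call. = FALSE)
  sequence <- toupper(sequence)
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop(sprintf("'%s' contains non-canonical residues: %s", arg,
                 paste(bad, collapse = ", ")), call. = FALSE)
  sequence
}

## set.seed only when the caller supplied a seed; generators are otherwise
## plain consumers of the session RNG stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("'seed' must be a single integer", call. = FALSE)
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
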