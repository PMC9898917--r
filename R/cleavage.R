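## Protease specificity PSSMs, per-residue cleavage profiles, proximal
## regions around observed fragment termini, and the edge-enrichment test.
##
## Conventions: an 8-residue substrate window covers positions
## P4,P3,P2,P1,P1',P2',P3',P4' (window positions 1..8).  A cleavage site
## between residues i and i+1 of a parent sequence is indexed by i (the P1
## residue, 1-based), so its window spans residues i-3 .. i+4 and scores are
## defined for i in 4 .. L-4.  All log-odds are natural-log.

#' Build a protease-specificity position-specific scoring matrix
#'
#' Turns a set of aligned 8-residue substrate windows (P4--P4') into a
#' log-odds PSSM against a background amino-acid distribution.  Counts are
#' regularised with an additive pseudocount per matrix cell before
#' normalisation:
#' `p(a, j) = (count(a, j) + pseudocount) / (N + 20 * pseudocount)` and
#' `log_odds(a, j) = log(p(a, j) / background(a))`.
#'
#' @param windows Character vector of 8-residue substrate windows (or a
#'   data frame with a `window` column, as written by
#'   [gen_cleavage_dataset()]).
#' @param pseudocount Additive count added to every cell before
#'   normalisation.  Must be > 0 for a fully finite matrix; default 5.
#' @param background Named 20-element amino-acid frequency vector summing
#'   to 1; default [human_aa_freq].  All entries must be positive.
#' @param protease_id Optional label stored with the matrix.
#' @return An object of class `"pssm"`: a list with elements `log_odds`
#'   (8 x 20 matrix, rows P4..P4', columns [AA_ALPHABET], natural-log
#'   units), `pseudocount`, `background`, `n_windows` and `protease_id`.
#' @examples
#' pssm <- build_pssm(c("AAAKLGGS", "TPGKVVRS"), protease_id = "demo")
#' pssm$log_odds["P1", "K"]
#' @export
build_pssm <- function(windows, pseudocount = 5, background = human_aa_freq,
                       protease_id = NULL) {
  if (is.data.frame(windows)) {
    if (is.null(windows$window))
      stop("data-frame input must have a 'window' column", call. = FALSE)
    if (is.null(protease_id) && !is.null(windows$protease))
      protease_id <- as.character(windows$protease[1L])
    windows <- as.character(windows$window)
  }
  if (length(windows) < 1L)
    stop("at least one substrate window is required", call. = FALSE)
  windows <- toupper(windows)
  if (any(nchar(windows) != 8L))
    stop("all substrate windows must be exactly 8 residues long",
         call. = FALSE)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount < 0)
    stop("'pseudocount' must be a single nonnegative number", call. = FALSE)
  background <- check_background(background)
  if (any(background == 0))
    stop("'background' must be strictly positive for log-odds scoring",
         call. = FALSE)

  chars <- matrix(unlist(strsplit(windows, ""), use.names = FALSE),
                  nrow = length(windows), ncol = 8L, byrow = TRUE)
  bad <- setdiff(unique(as.vector(chars)), AA_ALPHABET)
  if (length(bad))
    stop("windows contain non-canonical residues: ",
         paste(bad, collapse = ", "), call. = FALSE)

  counts <- vapply(seq_len(8L), function(j)
    table(factor(chars[, j], levels = AA_ALPHABET)),
    numeric(20L))                       # 20 x 8
  n <- length(windows)
  p <- (counts + pseudocount) / (n + 20 * pseudocount)
  log_odds <- t(log(p / background))    # 8 x 20
  dimnames(log_odds) <- list(
    c("P4", "P3", "P2", "P1", "P1'", "P2'", "P3'", "P4'"), AA_ALPHABET)

  structure(list(log_odds = log_odds, pseudocount = pseudocount,
                 background = background, n_windows = n,
                 protease_id = protease_id),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("Protease cleavage PSSM",
      if (!is.null(x$protease_id)) paste0("(", x$protease_id, ")"), "\n")
  cat("  trained on", x$n_windows, "substrate windows, pseudocount",
      x$pseudocount, "\n")
  cat("  log-odds range:",
      sprintf("%.3f .. %.3f", min(x$log_odds), max(x$log_odds)), "\n")
  invisible(x)
}

#' Score every cleavable position of a sequence
#'
#' Slides the 8-residue window across the sequence and, at every position
#' with a complete window, sums the PSSM log-odds over the 8 window
#' positions.  With several PSSMs (e.g. cathepsin B and cathepsin D) the
#' per-position cleavage score is the largest of the per-matrix scores.
#'
#' @param sequence Protein sequence (single string, canonical residues).
#' @param pssms A `"pssm"` object or a list of them.
#' @param parent_id Optional sequence label.
#' @return An object of class `"cleavage_profile"`: a list with a
#'   data frame `scores` (columns `position`, `score`, `probability` --
#'   the logistic conversion of the score -- and one `score_<id>` column
#'   per input matrix), a logical `valid_mask` over all residues (TRUE at
#'   positions 4 .. L-4), `parent_id` and `seq_len`.
#' @seealso [score_to_probability()], [edge_enrichment_test()]
#' @export
score_sequence <- function(sequence, pssms, parent_id = NULL) {
  sequence <- check_sequence(sequence)
  if (inherits(pssms, "pssm")) pssms <- list(pssms)
  if (!length(pssms) || !all(vapply(pssms, inherits, logical(1L), "pssm")))
    stop("'pssms' must be a pssm object or a list of pssm objects",
         call. = FALSE)
  L <- nchar(sequence)
  valid <- rep(FALSE, L)
  if (L < 8L) {
    warning("sequence shorter than 8 residues: no scoreable positions")
    return(structure(list(
      scores = data.frame(position = integer(), score = numeric(),
                          probability = numeric()),
      valid_mask = valid, parent_id = parent_id, seq_len = L),
      class = "cleavage_profile"))
  }
  pos <- 4:(L - 4L)
  valid[pos] <- TRUE
  aa <- strsplit(sequence, "")[[1L]]
  aa_idx <- match(aa, AA_ALPHABET)

  per_pssm <- vapply(pssms, function(p) {
    s <- numeric(length(pos))
    for (j in 1:8) s <- s + p$log_odds[j, aa_idx[pos - 4L + j]]
    s
  }, numeric(length(pos)))
  per_pssm <- matrix(per_pssm, nrow = length(pos))
  score <- apply(per_pssm, 1L, max)

  ids <- vapply(seq_along(pssms), function(i) {
    id <- pssms[[i]]$protease_id
    if (is.null(id)) paste0("pssm", i) else id
  }, character(1L))
  scores <- data.frame(position = pos, score = score,
                       probability = score_to_probability(score))
  for (i in seq_along(ids)) scores[[paste0("score_", ids[i])]] <- per_pssm[, i]

  structure(list(scores = scores, valid_mask = valid,
                 parent_id = parent_id, seq_len = L),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat("Cleavage profile", if (!is.null(x$parent_id)) x$parent_id,
      "\n  ", x$seq_len, "residues,", sum(x$valid_mask),
      "scoreable positions\n")
  if (nrow(x$scores))
    cat("  score range:",
        sprintf("%.3f .. %.3f", min(x$scores$score), max(x$scores$score)),
        "\n")
  invisible(x)
}

#' Convert a cleavage log-odds score to a cleavage probability
#'
#' Logistic transform `p = exp(s) / (1 + exp(s))` of a natural-log odds
#' score; a score of 1.5 corresponds to a probability of about 0.817.
#' Numerically stable for large `|s|` and vectorised.
#'
#' @param score Numeric vector of natural-log odds scores.
#' @return Probabilities in `(0, 1)`.
#' @examples
#' score_to_probability(1.5)  # ~0.817
#' @export
score_to_probability <- function(score) {
  if (!is.numeric(score)) stop("'score' must be numeric", call. = FALSE)
  stats::plogis(score)
}

#' Proximal (edge) region around observed peptide fragments
#'
#' Marks the residues near the termini of observed peptide fragments where
#' a proteolytic cleavage must have occurred.  For a fragment
#' `[start, end]` the proximal set is
#' `{start-2 .. start+1}` union `{end-1 .. end+2}`, clipped to
#' `[1, seq_len]`; the allowance of a couple of residues on either side of
#' each terminus absorbs exopeptidase trimming.  Contributions from
#' overlapping fragments are merged.
#'
#' @param fragments Data frame with 1-based inclusive `start` and `end`
#'   columns (one row per observed fragment).  May be empty.
#' @param seq_len Length of the parent sequence.
#' @return Logical vector of length `seq_len`, TRUE on proximal residues.
#' @export
proximal_mask <- function(fragments, seq_len) {
  if (!is.numeric(seq_len) || length(seq_len) != 1L || seq_len < 1)
    stop("'seq_len' must be a positive integer", call. = FALSE)
  seq_len <- as.integer(seq_len)
  mask <- rep(FALSE, seq_len)
  if (is.null(fragments) || nrow(fragments) == 0L) return(mask)
  if (is.null(fragments$start) || is.null(fragments$end))
    stop("'fragments' must have 'start' and 'end' columns", call. = FALSE)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i]; e <- fragments$end[i]
    if (is.na(s) || is.na(e) || s < 1 || e > seq_len || s > e)
      stop(sprintf("fragment %d [%s, %s] is out of bounds for seq_len %d",
                   i, s, e, seq_len), call. = FALSE)
    idx <- c(seq(s - 2L, s + 1L), seq(e - 1L, e + 2L))
    idx <- idx[idx >= 1L & idx <= seq_len]
    mask[idx] <- TRUE
  }
  mask
}

#' One-tailed Mann-Whitney test for cleavage-score enrichment at fragment
#' edges
#'
#' Compares the cleavage scores at proximal (edge) positions with the
#' scores at all other scoreable positions, testing the alternative that
#' proximal scores are stochastically greater.  For small problems
#' (`n_edge + n_nonedge <= exact_max_n`) the null distribution of the U
#' statistic is obtained by complete enumeration of all group assignments
#' (ties handled exactly); otherwise the normal approximation with midrank
#' tie correction and continuity correction is used.
#'
#' @param profile A `"cleavage_profile"` from [score_sequence()].
#' @param mask Logical proximal mask over residues, from [proximal_mask()].
#' @param exact_max_n Largest combined group size for the exact
#'   enumeration path (default 12).
#' @param alpha Significance level used only to set the `significant`
#'   flag in the result (default 0.05).
#' @return An object of class `"edge_test"`: list with `U` (number of
#'   (proximal, distal) pairs won by the proximal score, ties counting
#'   one half), one-tailed `p_value`, `n_edge`, `n_nonedge`, `method`
#'   (`"exact"` or `"normal"`), `alternative` (`"proximal greater"`),
#'   `alpha` and `significant`.
#' @export
edge_enrichment_test <- function(profile, mask, exact_max_n = 12L,
                                 alpha = 0.05) {
  if (!inherits(profile, "cleavage_profile"))
    stop("'profile' must be a cleavage_profile", call. = FALSE)
  if (!is.logical(mask) || length(mask) != profile$seq_len)
    stop("'mask' must be a logical vector over all residues of the parent",
         call. = FALSE)
  pos <- profile$scores$position
  edge <- profile$scores$score[mask[pos]]
  dist <- profile$scores$score[!mask[pos]]
  if (!length(edge) || !length(dist))
    stop(paste("both proximal and distal score groups must be non-empty;",
               "use a longer sequence or more fragments"), call. = FALSE)
  res <- mann_whitney_greater(edge, dist, exact_max_n = exact_max_n)
  structure(c(res, list(alternative = "proximal greater", alpha = alpha,
                        significant = res$p_value < alpha)),
            class = "edge_test")
}

#' @export
print.edge_test <- function(x, ...) {
  cat("One-tailed Mann-Whitney edge-enrichment test (proximal greater)\n")
  cat(sprintf("  U = %.1f (n_edge = %d, n_nonedge = %d, %s)\n",
              x$U, x$n_edge, x$n_nonedge, x$method))
  cat(sprintf("  p = %.4g%s\n", x$p_value,
              if (x$significant) paste0(" (< ", x$alpha, ")") else ""))
  invisible(x)
}

## U statistic via midranks: U = sum of ranks of x in the pooled sample
## minus nx(nx+1)/2; equals #(x > y) + 0.5 #(x == y) pairs.
u_statistic <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

mann_whitney_greater <- function(x, y, exact_max_n = 12L) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  U <- u_statistic(x, y)
  if (n <= exact_max_n) {
    pooled <- c(x, y)
    idx <- utils::combn(n, nx)
    ustats <- apply(idx, 2L, function(i)
      u_statistic(pooled[i], pooled[-i]))
    p <- mean(ustats >= U - 1e-9)
    method <- "exact"
  } else {
    ties <- table(c(x, y))
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {                   # all values tied
      p <- 1
    } else {
      z <- (U - mu - 0.5) / sqrt(sigma2) # continuity correction
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
    method <- "normal"
  }
  list(U = U, p_value = min(max(p, .Machine$double.xmin), 1),
       n_edge = nx, n_nonedge = ny, method = method)
}
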