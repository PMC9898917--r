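## Shared fixture builders; everything is generated in code at test time.

## 20 windows containing every residue exactly once at each position:
## each window repeats one residue eight times.
uniform_windows <- function() {
  vapply(AA_ALPHABET, function(a) paste(rep(a, 8L), collapse = ""),
         character(1L))
}

uniform_background <- function() {
  stats::setNames(rep(0.05, 20L), AA_ALPHABET)
}

random_windows <- function(n, background = thagg::human_aa_freq) {
  vapply(seq_len(n), function(i)
    paste(sample(thagg::AA_ALPHABET, 8L, replace = TRUE,
                 prob = background), collapse = ""), character(1L))
}

random_sequence <- function(len, background = thagg::human_aa_freq) {
  paste(sample(thagg::AA_ALPHABET, len, replace = TRUE,
               prob = background), collapse = "")
}

## independent brute-force PSSM construction + scoring oracle: nested
## loops over windows, positions and residues, no shared code with the
## implementation
oracle_pssm_logodds <- function(windows, pseudocount, background) {
  lo <- matrix(NA_real_, 8L, 20L,
               dimnames = list(NULL, thagg::AA_ALPHABET))
  for (j in 1:8) {
    for (a in thagg::AA_ALPHABET) {
      cnt <- 0
      for (w in windows) if (substr(w, j, j) == a) cnt <- cnt + 1
      p <- (cnt + pseudocount) / (length(windows) + 20 * pseudocount)
      lo[j, a] <- log(p / background[[a]])
    }
  }
  lo
}

oracle_profile <- function(sequence, logodds_list) {
  L <- nchar(sequence)
  out <- rep(NA_real_, L)
  for (i in 4:(L - 4)) {
    best <- -Inf
    for (lo in logodds_list) {
      s <- 0
      for (j in 1:8) {
        a <- substr(sequence, i - 4 + j, i - 4 + j)
        s <- s + lo[j, a]
      }
      best <- max(best, s)
    }
    out[i] <- best
  }
  out
}

## complete-enumeration Mann-Whitney oracle via the rank-sum formula
oracle_mw_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - nx * (nx + 1) / 2
  }
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  sets <- utils::combn(length(pooled), nx)
  us <- apply(sets, 2L, function(idx) {
    rr <- rank(pooled)
    sum(rr[idx]) - nx * (nx + 1) / 2
  })
  list(U = u_obs, p = mean(us >= u_obs - 1e-9))
}

tht_truth <- function(t50 = 12, k = 1) {
  list(y_i = 10, m_i = 0.05, y_f = 90, m_f = 0.1, t50 = t50, k = k)
}
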