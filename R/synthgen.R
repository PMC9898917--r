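## Seeded generators for every input the pipeline consumes, with ground
## truth attached.  The generators are the forward models of the analysis
## modules: their noiseless output is reproduced exactly by the
## corresponding model evaluation, so parameter-recovery tests have a known
## answer.  Noise is i.i.d. Gaussian throughout.

#' Configuration for the synthetic cleavage-data generator
#'
#' Describes planted protease specificity motifs over a proteome-like
#' background.  A motif is a named list mapping window positions (1..8,
#' i.e. P4..P4') to a named probability vector: at that position a window
#' carries the named residue with the given probability and a background
#' draw otherwise.  An empty motif (`list()`) yields pure-background
#' windows (the null case).
#'
#' @param seed Integer seed; every generator call with the same config and
#'   seed is bit-identical.
#' @param n_substrates Substrate windows generated per protease
#'   (default 1000, the scale of curated peptidase-database substrate
#'   collections for the lysosomal cathepsins).  Training-set size also
#'   controls a subtle property of downstream log-odds profiles: the flat
#'   pseudocount imprints a sequence-composition component on every
#'   window score that shrinks as 1/N, and with it the spatial
#'   autocorrelation of the cleavage profile.
#' @param motifs Named list of per-protease motifs.  The default plants a
#'   cathepsin-B-like preference (Arg at P1) and a cathepsin-D-like
#'   preference (Phe at P1'), each with probability 0.9.
#' @param background 20-element amino-acid frequency vector (default
#'   [human_aa_freq]).
#' @param noise_sd_fluor Gaussian noise SD for fluorescence intensities
#'   (signal units; default 10, calibrated so that repeated melting-scan
#'   analyses reproduce Tm within the 0.1-0.2 degC technical
#'   repeatability of microcapillary DSF instruments).
#' @param noise_sd_radius Gaussian noise SD for DLS radii (nm; default
#'   0.2).
#' @param noise_sd_tht Gaussian noise SD for ThT intensities (a.u.;
#'   default 2).
#' @return Object of class `"synth_config"`.
#' @export
synth_config <- function(seed = NULL,
                         n_substrates = 1000L,
                         motifs = list(cathB = list("4" = c(R = 0.9)),
                                       cathD = list("5" = c(F = 0.9))),
                         background = human_aa_freq,
                         noise_sd_fluor = 10,
                         noise_sd_radius = 0.2,
                         noise_sd_tht = 2) {
  background <- check_background(background)
  if (n_substrates < 1L)
    stop("'n_substrates' must be at least 1", call. = FALSE)
  if (!is.list(motifs))
    stop("'motifs' must be a named list of per-protease motifs",
         call. = FALSE)
  for (pr in names(motifs)) {
    mot <- motifs[[pr]]
    if (!length(mot)) next
    pos <- suppressWarnings(as.integer(names(mot)))
    if (any(is.na(pos)) || any(pos < 1L | pos > 8L))
      stop(sprintf("motif positions for '%s' must be within 1..8 (P4..P4')",
                   pr), call. = FALSE)
    for (p in mot) {
      if (is.null(names(p)) || !all(names(p) %in% AA_ALPHABET))
        stop("motif residues must be canonical amino acids", call. = FALSE)
      if (any(p <= 0) || sum(p) > 1 + 1e-12)
        stop("motif probabilities must be in (0, 1] and sum to at most 1",
             call. = FALSE)
    }
  }
  if (noise_sd_fluor < 0 || noise_sd_radius < 0 || noise_sd_tht < 0)
    stop("noise standard deviations must be nonnegative", call. = FALSE)
  structure(list(seed = seed, n_substrates = as.integer(n_substrates),
                 motifs = motifs, background = background,
                 noise_sd_fluor = noise_sd_fluor,
                 noise_sd_radius = noise_sd_radius,
                 noise_sd_tht = noise_sd_tht),
            class = "synth_config")
}

sample_aa <- function(n, background) {
  sample(AA_ALPHABET, n, replace = TRUE, prob = background)
}

sample_motif_windows <- function(n, motif, background) {
  mat <- matrix(sample_aa(n * 8L, background), nrow = n, ncol = 8L)
  for (pos in names(motif)) {
    j <- as.integer(pos)
    p <- motif[[pos]]
    opts <- c(names(p), NA_character_)
    draw <- sample.int(length(p) + 1L, n, replace = TRUE,
                       prob = c(p, 1 - sum(p)))
    forced <- opts[draw]
    keep <- is.na(forced)
    mat[!keep, j] <- forced[!keep]
  }
  apply(mat, 1L, paste, collapse = "")
}

## deterministic motif match: all listed residues at their positions
motif_match_positions <- function(aa, motif) {
  L <- length(aa)
  if (L < 8L) return(integer())
  cand <- 4:(L - 4L)
  ok <- rep(TRUE, length(cand))
  for (pos in names(motif)) {
    j <- as.integer(pos)
    ok <- ok & aa[cand - 4L + j] %in% names(motif[[pos]])
  }
  cand[ok]
}

#' Generate a synthetic protease-cleavage dataset
#'
#' Draws per-protease substrate windows from the planted motifs, samples a
#' proteome-like parent sequence from the background distribution, and
#' derives observed peptide fragments by cutting the parent at every
#' position whose local 8-residue window matches a planted motif (exact
#' residue match at all motif positions).  Fragments are the digestion
#' products between consecutive cuts; interior fragments (both termini at
#' cut sites) are preferred when subsampling.  When all motifs are empty,
#' windows are pure background and fragments are cut at uniformly random
#' positions, giving a null dataset with no true edge enrichment.
#'
#' Dense fragment coverage (the default asks for more fragments than a
#' typical digest yields, so every digestion product is reported) mirrors
#' a fully sampled proteomics experiment and leaves the distal group free
#' of undetected cleavage sites.
#'
#' @param cfg A [synth_config()].
#' @param seq_len Parent sequence length (>= 20, default 400).
#' @param n_fragments Number of fragments to report (default 25; 0 gives
#'   an empty fragment table).
#' @param min_fragment_len Shortest fragment kept (default 4 residues).
#' @return List with `windows` (data frame: `protease`, `window`,
#'   `parent_id`, `site_index`), `sequence` (parent as a string),
#'   `fragments` (data frame: `parent_id`, `start`, `end`, 1-based
#'   inclusive) and `truth` (list: `cut_sites`, `motifs`).
#' @export
gen_cleavage_dataset <- function(cfg, seq_len = 400L, n_fragments = 25L,
                                 min_fragment_len = 4L) {
  stopifnot(inherits(cfg, "synth_config"))
  if (seq_len < 20L) stop("'seq_len' must be >= 20", call. = FALSE)
  if (n_fragments < 0L) stop("'n_fragments' must be >= 0", call. = FALSE)
  with_seed(cfg$seed, {
    windows <- do.call(rbind, lapply(names(cfg$motifs), function(pr) {
      data.frame(protease = pr,
                 window = sample_motif_windows(cfg$n_substrates,
                                               cfg$motifs[[pr]],
                                               cfg$background),
                 parent_id = NA_character_,
                 site_index = seq_len(cfg$n_substrates))
    }))
    aa <- sample_aa(seq_len, cfg$background)
    sequence <- paste(aa, collapse = "")

    planted <- Filter(length, cfg$motifs)
    if (length(planted)) {
      cuts <- sort(unique(unlist(lapply(planted, motif_match_positions,
                                        aa = aa))))
    } else {
      cuts <- sort(sample(4:(seq_len - 4L),
                          min(n_fragments + 1L, seq_len - 7L)))
    }

    fragments <- data.frame(parent_id = character(), start = integer(),
                            end = integer())
    if (n_fragments > 0L && length(cuts) >= 1L) {
      starts <- c(1L, cuts + 1L)
      ends <- c(cuts, seq_len)
      cand <- data.frame(start = starts, end = ends)
      cand$interior <- cand$start > 1L & cand$end < seq_len
      cand <- cand[cand$end - cand$start + 1L >= min_fragment_len, ]
      if (nrow(cand)) {
        ord <- order(!cand$interior, runif(nrow(cand)))
        take <- cand[ord[seq_len(min(n_fragments, nrow(cand)))], ]
        fragments <- data.frame(parent_id = "synthetic_parent",
                                start = take$start, end = take$end)
        fragments <- fragments[order(fragments$start), ]
        rownames(fragments) <- NULL
      }
    }
    list(windows = windows, sequence = sequence, fragments = fragments,
         truth = list(cut_sites = cuts, motifs = cfg$motifs))
  })
}

#' Generate synthetic melt curves from known two-state truth
#'
#' Forward-evaluates the two-state [signal_model()] at both emission
#' wavelengths for every urea concentration and capillary replicate and
#' adds i.i.d. Gaussian noise.  Each (urea, replicate) pair is one
#' physical microcapillary and gets its own `capillary_id`, which is the
#' resampling unit of [bootstrap_ci()].
#'
#' @param truth A `"stability_params"` object (see
#'   [default_stability_truth()]).
#' @param urea_grid Urea concentrations in M (default: the 9-step
#'   0--5.36 M protocol grid).
#' @param T_grid Temperature grid in degC, strictly increasing (default
#'   20--70 in 1 degC steps).
#' @param noise_sd Gaussian noise SD in signal units (default 10).
#' @param n_capillaries Replicate capillaries per urea value (default 1).
#' @param seed Optional integer seed.
#' @param conc Protein concentration metadata (uM, default 20).
#' @param sample_id Sample label.
#' @return List of [melt_curve()] objects (one per urea x capillary) with
#'   the generating `truth` attached as an attribute.
#' @export
gen_melt_curves <- function(truth,
                            urea_grid = seq(0, 5.36, length.out = 9L),
                            T_grid = seq(20, 70, by = 1),
                            noise_sd = 10, n_capillaries = 1L,
                            seed = NULL, conc = 20, sample_id = "S1") {
  stopifnot(inherits(truth, "stability_params"))
  if (any(diff(T_grid) <= 0))
    stop("'T_grid' must be strictly increasing", call. = FALSE)
  if (any(urea_grid < 0))
    stop("'urea_grid' must be nonnegative", call. = FALSE)
  with_seed(seed, {
    curves <- list()
    for (ui in seq_along(urea_grid)) {
      for (cap in seq_len(n_capillaries)) {
        i330 <- signal_model(truth, T_grid, urea_grid[ui], 330) +
          stats::rnorm(length(T_grid), 0, noise_sd)
        i350 <- signal_model(truth, T_grid, urea_grid[ui], 350) +
          stats::rnorm(length(T_grid), 0, noise_sd)
        curves[[length(curves) + 1L]] <- melt_curve(
          T_C = T_grid, I330 = i330, I350 = i350, conc = conc,
          urea = urea_grid[ui],
          capillary_id = sprintf("U%02dR%d", ui, cap),
          sample_id = sample_id)
      }
    }
    attr(curves, "truth") <- truth
    curves
  })
}

#' Default two-state truth used throughout the synthetic studies
#'
#' A light-chain-like parameter set: `Tm` = 52 degC, `dHm` = 500 kJ/mol,
#' `dCp` = 8 kJ/mol/K, m-value = 7.1 kJ/mol/M, giving
#' `dG(37 degC) ~ 20.3 kJ/mol`, with realistic tryptophan-fluorescence
#' baselines (the 350/330 ratio rises from ~0.7 folded to ~1.2 unfolded).
#'
#' @param Tm,dHm,dCp,m_value Override any thermodynamic parameter.
#' @return A `"stability_params"` object.
#' @export
default_stability_truth <- function(Tm = 52, dHm = 500, dCp = 8,
                                    m_value = 7.1) {
  stability_params(
    Tm = Tm, dHm = dHm, dCp = dCp, m_value = m_value,
    baselines = list("330" = c(19000, -30, 14000, -20),
                     "350" = c(13000, -20, 16000, -10)))
}

#' Generate a synthetic DLS cumulant-radius trace
#'
#' Cumulant radius modelled as a gently sloped linear baseline plus
#' sigmoidal aggregation growth.  When `Tagg_true` is given, the sigmoid
#' centre is placed so that the growth contribution first exceeds the
#' onset-detection criterion (relative divergence `onset_threshold` from
#' the baseline) exactly at `Tagg_true`; the generated ground truth is
#' therefore the onset under the same 0.5% rule that [find_tagg()]
#' applies.
#'
#' @param T_grid Temperature grid in degC (default 25--70 by 0.5).
#' @param baseline_radius Native hydrodynamic radius (nm, > 0; default 3,
#'   a monomer/dimer-scale light-chain radius).
#' @param Tagg_true Aggregation-onset temperature (degC), or `NULL` with
#'   `growth_amplitude = 0` for a flat trace.
#' @param growth_amplitude Radius growth amplitude (nm; default 1000,
#'   micron-scale aggregates).
#' @param growth_width Sigmoid width (degC; default 1).
#' @param baseline_slope Baseline slope (nm/degC; default 0.01).
#' @param noise_sd Gaussian noise SD (nm; default 0.2).
#' @param onset_threshold Relative divergence defining the planted onset
#'   (default 0.005, matching [find_tagg()]).
#' @param seed Optional integer seed.
#' @param conc,sample_id Metadata.
#' @return A [dls_trace()] with attribute `truth` (list with
#'   `Tagg_true`, `centre`, `growth_amplitude`, `growth_width`).
#' @export
gen_dls_trace <- function(T_grid = seq(25, 70, by = 0.5),
                          baseline_radius = 3, Tagg_true = 55,
                          growth_amplitude = 1000, growth_width = 1,
                          baseline_slope = 0.01, noise_sd = 0.2,
                          onset_threshold = 0.005, seed = NULL,
                          conc = NA_real_, sample_id = "S1") {
  if (baseline_radius <= 0)
    stop("'baseline_radius' must be positive", call. = FALSE)
  base <- baseline_radius + baseline_slope * (T_grid - T_grid[1])
  if (growth_amplitude > 0) {
    if (is.null(Tagg_true))
      stop("'Tagg_true' is required when growth_amplitude > 0",
           call. = FALSE)
    rb_on <- baseline_radius + baseline_slope * (Tagg_true - T_grid[1])
    ratio <- growth_amplitude / (onset_threshold * rb_on)
    if (ratio <= 1)
      stop("growth amplitude too small to ever cross the onset threshold",
           call. = FALSE)
    centre <- Tagg_true + growth_width * log(ratio - 1)
    growth <- growth_amplitude /
      (1 + exp(-(T_grid - centre) / growth_width))
  } else {
    centre <- NA_real_
    growth <- 0
  }
  with_seed(seed, {
    radius <- base + growth + stats::rnorm(length(T_grid), 0, noise_sd)
    radius <- pmax(radius, 1e-3)        # physical positivity
    tr <- dls_trace(T_C = T_grid, radius = radius, conc = conc,
                    sample_id = sample_id)
    attr(tr, "truth") <- list(Tagg_true = if (growth_amplitude > 0)
      Tagg_true else NA_real_, centre = centre,
      growth_amplitude = growth_amplitude, growth_width = growth_width)
    tr
  })
}

#' Generate a synthetic ThT kinetics trace
#'
#' Forward evaluation of the sigmoid-plus-sloped-baselines kinetics model
#' (see [fit_sigmoid()]) plus Gaussian noise.
#'
#' @param truth Named list or vector with `y_i`, `m_i`, `y_f`, `m_f`,
#'   `t50`, `k` (`k` > 0).
#' @param t_grid Time grid in hours (default 0--50 h every 5 min).
#' @param noise_sd Gaussian noise SD (a.u.; default 2).
#' @param seed Optional integer seed.
#' @param sample_id,conc,pH,replicate_id Metadata.
#' @return A [tht_trace()] with attribute `truth`.
#' @export
gen_tht_trace <- function(truth = list(y_i = 10, m_i = 0.05, y_f = 90,
                                       m_f = 0.1, t50 = 12, k = 1),
                          t_grid = seq(0, 50, by = 1 / 12),
                          noise_sd = 2, seed = NULL, sample_id = "S1",
                          conc = 35, pH = 3, replicate_id = 1L) {
  truth <- as.list(truth)
  need <- c("y_i", "m_i", "y_f", "m_f", "t50", "k")
  if (!all(need %in% names(truth)))
    stop("'truth' must provide y_i, m_i, y_f, m_f, t50, k", call. = FALSE)
  if (truth$k <= 0) stop("'k' must be positive", call. = FALSE)
  p <- unlist(truth[need])
  with_seed(seed, {
    y <- sigmoid_model(p, t_grid) + stats::rnorm(length(t_grid), 0,
                                                 noise_sd)
    tr <- tht_trace(t = t_grid, intensity = y, sample_id = sample_id,
                    conc = conc, pH = pH, replicate_id = replicate_id)
    attr(tr, "truth") <- truth
    tr
  })
}

#' Generate a synthetic turbidity (Bence-Jones test) trace
#'
#' Gaussian-bump turbidity with optional incomplete clearing, emulating a
#' 25--90 degC back-reflection scan: turbidity rises to a maximum at
#' `peak_T` and partially clears on further heating.
#'
#' @param T_grid Temperature grid (degC, default 25--90 by 0.5).
#' @param peak_T Temperature of maximal turbidity (degC); `NA` gives a
#'   flat (no-turbidity) trace.
#' @param amplitude Peak turbidity above baseline (default 100).
#' @param width Bump width (degC, default 8).
#' @param clearing Fraction of the rise that clears by scan end is
#'   controlled by the bump shape; an asymmetry factor > 1 slows the
#'   decline (default 1).
#' @param baseline Baseline turbidity (default 10).
#' @param noise_sd Gaussian noise SD (default 0.5).
#' @param seed Optional integer seed.
#' @param conc,pH,sample_id Metadata.
#' @return A [turbidity_trace()] with attribute `truth`.
#' @export
gen_turbidity_trace <- function(T_grid = seq(25, 90, by = 0.5),
                                peak_T = 66, amplitude = 100, width = 8,
                                clearing = 1, baseline = 10,
                                noise_sd = 0.5, seed = NULL,
                                conc = 27, pH = 5, sample_id = "S1") {
  if (is.na(peak_T) || amplitude == 0) {
    bump <- 0
  } else {
    w <- ifelse(T_grid <= peak_T, width, width * clearing)
    bump <- amplitude * exp(-((T_grid - peak_T)^2) / (2 * w^2))
  }
  with_seed(seed, {
    y <- baseline + bump + stats::rnorm(length(T_grid), 0, noise_sd)
    tr <- turbidity_trace(T_C = T_grid, turbidity = y, conc = conc,
                          pH = pH, sample_id = sample_id)
    attr(tr, "truth") <- list(peak_T = peak_T, amplitude = amplitude)
    tr
  })
}
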