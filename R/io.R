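## Plain-text interchange: FASTA for sequences, TSV for substrate windows
## and fragment coordinates, long-format CSV for instrument traces, JSON
## sidecars for ground truth.  The schemas written here are the ones the
## readers accept, so synthetic and real exports are interchangeable.

#' Write protein sequences to FASTA
#'
#' @param sequences Named character vector of sequences.
#' @param path Output file.
#' @export
write_sequences_fasta <- function(sequences, path) {
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  seqinr::write.fasta(as.list(sequences), names = names(sequences),
                      file.out = path, as.string = TRUE, nbchar = 60)
  invisible(path)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_sequences_fasta <- function(path) {
  x <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  stats::setNames(toupper(vapply(x, `[[`, character(1L), 1L)), names(x))
}

#' Write / read substrate-window tables
#'
#' TSV with columns `protease`, `window`, `parent_id`, `site_index` --
#' the schema produced by [gen_cleavage_dataset()] and accepted by
#' [build_pssm()]; identical tables can be exported from real
#' peptidase-database records.
#'
#' @param windows Data frame of windows.
#' @param path File path.
#' @export
write_windows_tsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_windows_tsv
#' @export
read_windows_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read fragment-coordinate tables
#'
#' TSV with columns `parent_id`, `start`, `end` (1-based inclusive).
#'
#' @param fragments Data frame of fragments.
#' @param path File path.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments_tsv
#' @export
read_fragments_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

## one trace -> long-format rows
trace_to_df <- function(x) {
  if (inherits(x, "melt_curve")) {
    data.frame(sample_id = x$sample_id, capillary_id = x$capillary_id,
               urea_M = x$urea, conc_uM = x$conc,
               T_or_t = rep(x$T_C, 2L),
               channel = rep(c("I330", "I350"), each = length(x$T_C)),
               value = c(x$I330, x$I350))
  } else if (inherits(x, "dls_trace")) {
    data.frame(sample_id = x$sample_id, capillary_id = NA_character_,
               urea_M = NA_real_, conc_uM = x$conc, T_or_t = x$T_C,
               channel = "radius_nm", value = x$radius)
  } else if (inherits(x, "turbidity_trace")) {
    data.frame(sample_id = x$sample_id, capillary_id = NA_character_,
               urea_M = NA_real_, conc_uM = x$conc, T_or_t = x$T_C,
               channel = "turbidity", value = x$turbidity)
  } else if (inherits(x, "tht_trace")) {
    data.frame(sample_id = x$sample_id,
               capillary_id = as.character(x$replicate_id),
               urea_M = NA_real_, conc_uM = x$conc, T_or_t = x$t,
               channel = "tht", value = x$intensity)
  } else stop("unsupported trace class", call. = FALSE)
}

#' Write instrument traces to a long-format CSV
#'
#' Columns: `sample_id`, `capillary_id`, `urea_M`, `conc_uM`, `T_or_t`
#' (degC for temperature scans, hours for kinetics), `channel` (`I330`,
#' `I350`, `radius_nm`, `turbidity` or `tht`) and `value`.
#'
#' @param traces A trace object or list of trace objects
#'   ([melt_curve()], [dls_trace()], [turbidity_trace()],
#'   [tht_trace()]).
#' @param path Output CSV.
#' @export
write_traces_csv <- function(traces, path) {
  if (!is.list(traces) || inherits(traces, c("melt_curve", "dls_trace",
                                             "turbidity_trace",
                                             "tht_trace")))
    traces <- list(traces)
  df <- do.call(rbind, lapply(traces, trace_to_df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read melt curves from a long-format trace CSV
#'
#' @param path CSV written by [write_traces_csv()].
#' @return List of [melt_curve()] objects (one per sample x capillary).
#' @export
read_melt_curves_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$channel %in% c("I330", "I350"), ]
  keys <- unique(df[c("sample_id", "capillary_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$sample_id == keys$sample_id[i] &
              df$capillary_id == keys$capillary_id[i], ]
    d330 <- d[d$channel == "I330", ]
    d350 <- d[d$channel == "I350", ]
    o <- order(d330$T_or_t)
    melt_curve(T_C = d330$T_or_t[o], I330 = d330$value[o],
               I350 = d350$value[order(d350$T_or_t)],
               conc = d330$conc_uM[1], urea = d330$urea_M[1],
               capillary_id = keys$capillary_id[i],
               sample_id = keys$sample_id[i])
  })
}

#' Read DLS or ThT traces from a long-format trace CSV
#'
#' @param path CSV written by [write_traces_csv()].
#' @return List of [dls_trace()] / [tht_trace()] objects.
#' @export
read_dls_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$channel == "radius_nm", ]
  lapply(unique(df$sample_id), function(id) {
    d <- df[df$sample_id == id, ]
    o <- order(d$T_or_t)
    dls_trace(T_C = d$T_or_t[o], radius = d$value[o],
              conc = d$conc_uM[1], sample_id = id)
  })
}

#' @rdname read_dls_traces_csv
#' @export
read_tht_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$channel == "tht", ]
  keys <- unique(df[c("sample_id", "capillary_id")])
  lapply(seq_len(nrow(keys)), function(i) {
    d <- df[df$sample_id == keys$sample_id[i] &
              df$capillary_id == keys$capillary_id[i], ]
    o <- order(d$T_or_t)
    tht_trace(t = d$T_or_t[o], intensity = d$value[o],
              sample_id = keys$sample_id[i], conc = d$conc_uM[1],
              replicate_id = keys$capillary_id[i])
  })
}

#' Write / read a ground-truth JSON sidecar
#'
#' @param truth List of ground-truth values (as attached by the
#'   generators).
#' @param path JSON file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
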