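# Candidate-sequence curation rules: N-terminal cysteine-motif
# classification (chemokine nomenclature), transmembrane-domain-count
# filtering of receptor candidates, and advisory length /
# signal-peptide flags. Transmembrane counts and signal-peptide calls
# are consumed from external predictor tables; only the decision rules
# live here.

#' Classify the N-terminal cysteine motif of a protein sequence
#'
#' Scans `sequence[offset+1 .. offset+window]` for the first two
#' cysteines and applies the standard chemokine spacing nomenclature:
#' gap 0 -> CC, gap 1 -> CXC, gap 3 -> CX3C; exactly one cysteine in
#' the window -> XC; no cysteine or a gap of 2 or >= 4 -> none. "X" in
#' the sequence is tolerated but never counted as cysteine.
#'
#' @param sequence Amino-acid string (one-letter code).
#' @param window Scan width in residues (default 60).
#' @param offset Residues skipped before the window (e.g. a cleaved
#'   signal peptide), default 0.
#' @return List of class `motif_call`: `class` (one of CC, CXC, CX3C,
#'   XC, none), `positions` (1-based positions of the classifying
#'   cysteines in the full sequence), `window` actually scanned.
#' @export
scan_cysteine_motif <- function(sequence, window = 60, offset = 0) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  from <- offset + 1L
  to <- min(length(chars), offset + window)
  region <- if (from <= to) chars[from:to] else character(0)
  cys <- which(region == "C") + offset
  cls <- "none"; pos <- integer(0)
  if (length(cys) == 1L) {
    cls <- "XC"; pos <- cys
  } else if (length(cys) >= 2L) {
    gap <- cys[2] - cys[1] - 1L
    cls <- switch(as.character(gap), "0" = "CC", "1" = "CXC",
                  "3" = "CX3C", "none")
    pos <- cys[1:2]
  }
  structure(list(class = cls, positions = pos, window = c(from, to)),
            class = "motif_call")
}

#' @export
print.motif_call <- function(x, ...) {
  cat("<motif_call:", x$class,
      if (length(x$positions)) paste0("(C at ",
                                      paste(x$positions, collapse = ","), ")"),
      ">\n")
  invisible(x)
}

#' Count cysteines in a sequence region
#'
#' @param sequence Amino-acid string.
#' @param window Optional region width from `offset`; NULL scans the
#'   full sequence.
#' @param offset Residues skipped before the region.
#' @return Integer count of 'C' residues.
#' @export
count_cysteines <- function(sequence, window = NULL, offset = 0) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  from <- offset + 1L
  to <- if (is.null(window)) length(chars) else
    min(length(chars), offset + window)
  if (from > to) return(0L)
  sum(chars[from:to] == "C")
}

#' Transmembrane-domain-count filter for receptor candidates
#'
#' Keeps candidates whose predicted transmembrane helix count lies in
#' [min_tm, max_tm]; the 5-8 default is the GPCR-candidate window
#' (7TM receptors allowing for missed or split helices). Missing
#' predictions are rejected with reason "no-prediction".
#'
#' @param tm_count Integer vector of predicted TM-domain counts (NA =
#'   no prediction).
#' @param min_tm,max_tm Inclusive bounds (defaults 5 and 8).
#' @return Data frame: tm_count, verdict ("keep"/"reject"), reason.
#' @export
tm_filter <- function(tm_count, min_tm = 5, max_tm = 8) {
  stopifnot(min_tm <= max_tm)
  keep <- !is.na(tm_count) & tm_count >= min_tm & tm_count <= max_tm
  reason <- ifelse(is.na(tm_count), "no-prediction",
                   ifelse(keep, "", "tm-count-out-of-range"))
  data.frame(tm_count = tm_count,
             verdict = ifelse(keep, "keep", "reject"),
             reason = reason, stringsAsFactors = FALSE)
}

#' Advisory flags for candidate sequences
#'
#' Flags, per record, (i) length outliers (robust |z| > cut against the
#' record's annotation group, or the whole set when no group column is
#' present) and (ii) missing signal peptides when one is required. The
#' report is purely advisory: no record is dropped.
#'
#' The z-score is robust -- (length - median) / (1.4826 * MAD) -- so a
#' single grossly long sequence among a handful of normal ones is
#' flagged; a classical mean/SD z-score is bounded by (n-1)/sqrt(n) and
#' can never flag an outlier in small groups. When the MAD is zero the
#' SD is used; when both are zero all z are 0.
#'
#' @param records Data frame with columns `id`, `length`, optional
#'   `signal_peptide` (logical), optional `group`.
#' @param length_zscore_cut Robust |z| threshold for the length flag
#'   (default 2.5).
#' @param require_signal_peptide Mark records lacking a signal peptide
#'   as suspect.
#' @return `records` with added columns `length_z`, `length_flag`,
#'   `signal_flag`, `verdict` ("keep"/"suspect").
#' @export
flag_candidates <- function(records, length_zscore_cut = 2.5,
                            require_signal_peptide = FALSE) {
  stopifnot(all(c("id", "length") %in% names(records)))
  records <- as.data.frame(records)
  grp <- if ("group" %in% names(records)) records$group else
    rep("all", nrow(records))
  z <- rep(NA_real_, nrow(records))
  for (g in unique(grp)) {
    at <- which(grp == g)
    if (length(at) < 3L) {
      warning("group '", g, "' has fewer than 3 records; ",
              "length flags skipped")
      next
    }
    ctr <- stats::median(records$length[at])
    scl <- stats::mad(records$length[at])
    if (scl == 0) scl <- stats::sd(records$length[at])
    z[at] <- if (scl > 0) (records$length[at] - ctr) / scl else 0
  }
  records$length_z <- z
  records$length_flag <- !is.na(z) & abs(z) > length_zscore_cut
  sigp <- if ("signal_peptide" %in% names(records))
    records$signal_peptide else rep(NA, nrow(records))
  records$signal_flag <- require_signal_peptide & !is.na(sigp) & !sigp
  records$verdict <- ifelse(records$length_flag | records$signal_flag,
                            "suspect", "keep")
  records
}

#' Full candidate report: motif class, cysteine counts, TM verdict
#'
#' @param sequences Named character vector of amino-acid sequences (or
#'   an `AAStringSet`).
#' @param annotations Data frame with `id` plus optional `tm_count`,
#'   `signal_peptide`, `top_hit`, `group` columns.
#' @param window,offset Motif-scan parameters.
#' @param min_tm,max_tm TM-filter bounds.
#' @param length_zscore_cut,require_signal_peptide Flag parameters.
#' @return Data frame: id, length, motif class, cysteine counts, TM
#'   verdict and advisory flags.
#' @export
candidate_report <- function(sequences, annotations = NULL, window = 60,
                             offset = 0, min_tm = 5, max_tm = 8,
                             length_zscore_cut = 2.5,
                             require_signal_peptide = FALSE) {
  if (inherits(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named")
  motif <- vapply(sequences, function(s)
    scan_cysteine_motif(s, window, offset)$class, character(1))
  rep0 <- data.frame(id = ids, length = nchar(sequences),
                     motif_class = motif,
                     n_cys_window = vapply(sequences, count_cysteines,
                                           0L, window = window,
                                           offset = offset),
                     n_cys_total = vapply(sequences, count_cysteines, 0L),
                     stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(annotations)) {
    rep0 <- merge(rep0, annotations, by = "id", all.x = TRUE, sort = TRUE)
  }
  if ("tm_count" %in% names(rep0)) {
    tm <- tm_filter(rep0$tm_count, min_tm, max_tm)
    rep0$tm_verdict <- tm$verdict
    rep0$tm_reason <- tm$reason
  }
  flag_candidates(rep0, length_zscore_cut, require_signal_peptide)
}

#' Read a FASTA file of protein sequences
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  # keep only the first whitespace-delimited token of each header
  nm <- vapply(strsplit(names(x), "\\s+"), `[[`, "", 1L)
  stats::setNames(as.character(x), nm)
}
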