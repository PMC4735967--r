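#' Parameters for ambiguous base-call refinement
#'
#' @param ratio_threshold Fraction in `(0, 1]`; a secondary channel competes
#'   with the strongest channel when its signal at the peak position is at
#'   least `ratio_threshold` times the primary signal. Default 0.5.
#' @param recall_scope `"n_only"` (default) re-examines only positions the
#'   base caller left as N; `"all_positions"` re-examines every base.
#' @return An `ambiguity_params` list.
#' @export
ambiguity_params <- function(ratio_threshold = 0.5,
                             recall_scope = c("n_only", "all_positions")) {
  recall_scope <- match.arg(recall_scope)
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1 ||
      ratio_threshold <= 0 || ratio_threshold > 1) {
    stop("ratio_threshold must be a single number in (0, 1]")
  }
  structure(list(ratio_threshold = ratio_threshold,
                 recall_scope = recall_scope),
            class = "ambiguity_params")
}

#' Refine ambiguous Sanger base calls from trace signals
#'
#' Sanger base callers report an unclear signal as N even when the traces
#' narrow the call down to two or three nucleotides (A-or-G should be R,
#' C-or-T should be Y, and so on). For each position in scope this reads the
#' four channel signals at the base's peak position; every channel whose
#' signal is at least `ratio_threshold` times the strongest signal joins the
#' competing set, and the position is re-called as the IUPAC code of that
#' set (one base gives that base, two give R/Y/S/W/K/M, three give B/D/H/V,
#' four -- or an all-zero peak -- stays N). Qualities and read length are
#' preserved; positions outside scope are untouched.
#'
#' @param chrom A [chromatogram_record()].
#' @param params An [ambiguity_params()] object.
#' @return A [seq_record()] with refined base calls.
#' @export
refine_ambiguous_calls <- function(chrom, params = ambiguity_params()) {
  if (!inherits(chrom, "chromatogram_record")) {
    stop("refine_ambiguous_calls needs a chromatogram_record")
  }
  if (is.null(chrom$traces) || is.null(chrom$peak_index)) {
    stop("chromatogram lacks traces or peak positions; skip refinement")
  }
  b <- strsplit(chrom$bases, "")[[1]]
  scope <- if (params$recall_scope == "n_only") {
    which(b == "N")
  } else {
    seq_along(b)
  }
  channels <- strsplit(chrom$channel_order, "")[[1]]
  for (i in scope) {
    p <- chrom$peak_index[i]
    sig <- vapply(chrom$traces, function(tr) as.numeric(tr[p]), numeric(1))
    names(sig) <- channels
    s1 <- max(sig)
    if (s1 <= 0) {
      b[i] <- "N"
      next
    }
    competing <- names(sig)[sig >= params$ratio_threshold * s1]
    b[i] <- iupac_code(competing)
  }
  seq_record(chrom$read_id, paste(b, collapse = ""), chrom$quals,
             chrom$pair_role)
}
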