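check_ct <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals)))
    stop("Ct values must be finite numbers", call. = FALSE)
  invisible(vals)
}

#' ChIP enrichment relative to total H3
#'
#' ChIP qPCR signal for an antibody normalized to the total-H3 positive
#' control: \code{2^-(Ct_ab - Ct_h3)}. One cycle later than H3 means half
#' the recovered material.
#'
#' @param ct_ab Threshold cycle of the antibody of interest.
#' @param ct_h3 Threshold cycle of the anti-H3 control on the same extract.
#' @return Enrichment ratio (1 when the Cts are equal).
#' @export
chip_enrichment <- function(ct_ab, ct_h3) {
  check_ct(ct_ab, ct_h3)
  2^-(ct_ab - ct_h3)
}

#' Normalize an enrichment value to a reference site
#'
#' Division by the enrichment at a reference locus (e.g. a hypersensitive
#' site), allowing comparison between extracts.
#'
#' @param value Enrichment value.
#' @param ref_value Enrichment at the reference site; must be positive.
#' @return \code{value / ref_value}.
#' @export
normalize_to_reference <- function(value, ref_value) {
  if (any(!is.finite(ref_value)) || any(ref_value <= 0))
    stop("'ref_value' must be positive and finite", call. = FALSE)
  value / ref_value
}

#' Expression fold change by the delta-delta-Ct method
#'
#' \code{2^-[(Ct_target_test - Ct_ref_test) - (Ct_target_ctrl - Ct_ref_ctrl)]}
#' at amplification efficiency \code{efficiency} (default 1, i.e. one cycle
#' corresponds to a 2-fold template difference; efficiency E uses base
#' \code{1 + E}).
#'
#' @param ct_target_test,ct_ref_test Target and reference-gene Cts in the
#'   test sample.
#' @param ct_target_ctrl,ct_ref_ctrl The same in the control sample.
#' @param efficiency Amplification efficiency in \code{(0, 1]}.
#' @return Fold change of the target in test relative to control.
#' @export
expression_fold_change <- function(ct_target_test, ct_ref_test,
                                   ct_target_ctrl, ct_ref_ctrl,
                                   efficiency = 1) {
  check_ct(ct_target_test, ct_ref_test, ct_target_ctrl, ct_ref_ctrl)
  if (length(efficiency) != 1L || !is.finite(efficiency) ||
      efficiency <= 0 || efficiency > 1)
    stop("'efficiency' must be in (0, 1]", call. = FALSE)
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  (1 + efficiency)^-ddct
}

#' CpG methylation fraction from HpaII/BamHI qPCR
#'
#' HpaII cleavage is blocked by CpG methylation, so template surviving
#' HpaII digestion measures the methylated fraction. Amplification after
#' HpaII digestion is normalized to BamHI-digested DNA (no BamHI site in
#' the amplicon) to control for input: \code{2^-(Ct_hpaii - Ct_bamhi)}.
#' Values above 1 (HpaII amplifying earlier than BamHI) are clamped to 1
#' with a warning, as they can only arise from measurement noise.
#'
#' @param ct_hpaii Threshold cycle after HpaII digestion.
#' @param ct_bamhi Threshold cycle after BamHI digestion.
#' @return Methylated fraction in \code{[0, 1]}.
#' @export
methylation_fraction <- function(ct_hpaii, ct_bamhi) {
  check_ct(ct_hpaii, ct_bamhi)
  frac <- 2^-(ct_hpaii - ct_bamhi)
  if (any(frac > 1)) {
    warning("methylation fraction > 1 clamped to 1 (HpaII Ct earlier than BamHI)",
            call. = FALSE)
    frac <- pmin(frac, 1)
  }
  frac
}

#' HpaII/MspI digestion control check
#'
#' HpaII and MspI are isoschizomers; at an unmethylated control site both
#' should cut completely and amplify with indistinguishable Cts. Returns a
#' QC flag: \code{TRUE} when the two Cts agree within \code{tol_cycles}.
#'
#' @param ct_hpaii,ct_mspi Threshold cycles at the control site.
#' @param tol_cycles Allowed absolute Ct difference (default 1 cycle).
#' @return Logical QC pass flag.
#' @export
hpaii_mspi_qc <- function(ct_hpaii, ct_mspi, tol_cycles = 1) {
  check_ct(ct_hpaii, ct_mspi)
  abs(ct_hpaii - ct_mspi) <= tol_cycles
}

#' Read a Ct table and average duplicate wells
#'
#' Reads a tab-separated table with columns \code{sample}, \code{target}
#' and \code{ct}, and averages replicate readings of the same
#' sample/target pair (reactions are typically run in duplicate) before
#' any ratio is formed.
#'
#' @param path Path to a TSV file with a header line.
#' @return Data frame with one row per sample/target and the mean
#'   \code{ct}, plus \code{n_wells}.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "target", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns sample, target, ct", call. = FALSE)
  if (any(!is.finite(tab$ct)) || any(tab$ct <= 0))
    stop("all Ct values must be positive finite numbers", call. = FALSE)
  agg <- stats::aggregate(ct ~ sample + target, data = tab, FUN = mean)
  n <- stats::aggregate(ct ~ sample + target, data = tab, FUN = length)
  agg$n_wells <- n$ct
  agg[order(agg$sample, agg$target), , drop = FALSE]
}
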