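#' Tissue-specificity index (tau)
#'
#' The tau index of a per-tissue expression profile:
#' `tau = sum(1 - v_i / max(v)) / (n - 1)`.  Tau is 0 for a flat positive
#' profile (ubiquitous expression), 1 when exactly one tissue is
#' expressed, and scale-invariant (multiplying the profile by a positive
#' constant leaves it unchanged).  When `tau >= threshold` the argmax
#' tissue is reported as the specific tissue.
#'
#' @param values Non-negative expression values, one per tissue (named or
#'   not); at least 2 tissues, not all zero.
#' @param threshold Tau value at or above which the profile is called
#'   tissue-specific (default 0.8).
#' @return List with `tau` and `specific_tissue` (tissue name or index,
#'   or `NA` when below threshold).
#' @export
#' @examples
#' tau_specificity(c(leaf = 0, root = 0, stem = 5, seed = 0))  # tau 1, stem
tau_specificity <- function(values, threshold = 0.8) {
  if (length(values) < 2L) stop("tau needs at least 2 tissues")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (all(values == 0)) stop("undefined tissue profile: all values zero")
  vmax <- max(values)
  tau <- sum(1 - values / vmax) / (length(values) - 1L)
  specific <- NA
  if (tau >= threshold) {
    i <- which.max(values)
    specific <- if (!is.null(names(values))) names(values)[i] else i
  }
  list(tau = tau, specific_tissue = specific)
}

#' Tau scores for a whole tissue expression matrix
#'
#' @param mat Numeric matrix, rows = transcripts, columns = tissues.
#' @param threshold Passed to [tau_specificity()].
#' @return Data frame: `id`, `tau`, `specific_tissue` (`NA` when not
#'   specific).  Rows that are all zero get `tau = NA`.
#' @export
tissue_specificity <- function(mat, threshold = 0.8) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2L)
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  res <- lapply(seq_len(nrow(mat)), function(i) {
    v <- mat[i, ]
    if (all(v == 0)) {
      return(data.frame(id = ids[i], tau = NA_real_,
                        specific_tissue = NA_character_,
                        stringsAsFactors = FALSE))
    }
    t <- tau_specificity(v, threshold)
    data.frame(id = ids[i], tau = t$tau,
               specific_tissue = as.character(t$specific_tissue),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Pfaffl efficiency-corrected relative quantification
#'
#' `ratio = E_target ^ dCp_target / E_ref ^ dCp_ref`, with amplification
#' efficiencies `E >= 1` (2 = perfect doubling per cycle) and delta-Cp
#' values taken as control minus treatment for both the target and the
#' reference gene.  Under this orientation a target upregulated by the
#' treatment (treatment Cp lower than control Cp) gives a positive
#' `dCp_target` and hence ratio > 1; set `flip = TRUE` to use the
#' treatment-minus-control convention instead.
#'
#' @param e_target,e_ref Amplification efficiencies (>= 1).
#' @param dcp_target,dcp_ref Cp differences (control - treatment).
#' @param flip Reverse the sign convention on both delta-Cp values.
#' @return Numeric expression ratio(s).
#' @export
#' @examples
#' pfaffl_ratio(2, 3, 2, 1)  # 4
pfaffl_ratio <- function(e_target, dcp_target, e_ref, dcp_ref, flip = FALSE) {
  if (any(e_target < 1) || any(e_ref < 1)) {
    stop("amplification efficiencies must be >= 1")
  }
  if (flip) {
    dcp_target <- -dcp_target
    dcp_ref <- -dcp_ref
  }
  e_target^dcp_target / e_ref^dcp_ref
}
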