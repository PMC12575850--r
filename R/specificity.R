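#' Expression breadth under the 10%-of-max rule
#'
#' The number of cell types whose TPM strictly exceeds `frac` (default
#' 10%) of the gene's maximum TPM across all cell types. An all-zero row
#' has breadth 0.
#'
#' @param tpm_row Non-negative TPM values across cell types.
#' @param frac Fraction of the maximum used as threshold, default 0.10.
#' @return Integer breadth in `[0, length(tpm_row)]`.
#' @examples
#' expression_breadth(c(100, 9, 5, 0))  # threshold 10 -> 1
#' @export
expression_breadth <- function(tpm_row, frac = 0.10) {
  assert_that(is.numeric(tpm_row) && !anyNA(tpm_row) && all(tpm_row >= 0),
              "TPM values must be non-negative")
  assert_that(is_scalar_number(frac) && frac > 0 && frac < 1,
              "frac must be in (0, 1)")
  if (all(tpm_row == 0)) return(0L)
  sum(tpm_row > frac * max(tpm_row))
}

#' Rank of T-cell expression among all cell types
#'
#' Rank of the T-cell TPM within the row, with 1 = highest TPM
#' (descending); ties take the minimum (best) rank.
#'
#' @param tpm_row TPM values across cell types.
#' @param tcell_index Index (or column name) of the T-cell entry.
#' @return Integer rank in `[1, length(tpm_row)]`.
#' @export
tcell_rank <- function(tpm_row, tcell_index) {
  if (is.character(tcell_index)) {
    tcell_index <- match(tcell_index, names(tpm_row))
  }
  assert_that(is_count(tcell_index) && tcell_index >= 1 &&
                tcell_index <= length(tpm_row),
              "tcell_index must identify an entry of the row")
  as.integer(rank(-tpm_row, ties.method = "min")[tcell_index])
}

#' Ratio of T-cell TPM to the median TPM of other cell types
#'
#' `TPM_Tcell / median(TPM of the other cell types)`. A positive numerator
#' over a zero median returns `Inf`; 0/0 returns 0 (flagged via the
#' `zero_over_zero` attribute).
#'
#' @param tpm_row TPM values across cell types (length >= 2).
#' @param tcell_index Index or name of the T-cell entry.
#' @param eps Optional pseudocount added to the denominator, default 0.
#' @return Non-negative ratio, possibly `Inf`.
#' @export
tcell_ratio <- function(tpm_row, tcell_index, eps = 0) {
  assert_that(length(tpm_row) >= 2, "row must have at least two cell types")
  if (is.character(tcell_index)) {
    tcell_index <- match(tcell_index, names(tpm_row))
  }
  assert_that(is_count(tcell_index) && tcell_index >= 1 &&
                tcell_index <= length(tpm_row),
              "tcell_index must identify an entry of the row")
  num <- tpm_row[[tcell_index]]
  den <- stats::median(tpm_row[-tcell_index]) + eps
  if (den == 0) {
    if (num == 0) return(structure(0, zero_over_zero = TRUE))
    return(Inf)
  }
  num / den
}

#' Specificity profile over a cell-type TPM table
#'
#' Applies [expression_breadth()], [tcell_rank()] and [tcell_ratio()] to
#' every gene of a genes-x-cell-types TPM matrix.
#'
#' @param tpm Genes-x-cell-types numeric matrix with column names.
#' @param tcell_column Name (or index) of the T-cell column; defaults to
#'   the matrix's `tcell_column` attribute when present.
#' @param frac Breadth threshold fraction, default 0.10.
#' @return A `SpecificityProfile` data.frame: gene_id, breadth,
#'   tcell_rank, tcell_ratio.
#' @export
specificity_profile <- function(tpm, tcell_column = attr(tpm, "tcell_column"),
                                frac = 0.10) {
  assert_that(is.matrix(tpm) && is.numeric(tpm), "tpm must be a numeric matrix")
  assert_that(!is.null(tcell_column), "tcell_column must be given")
  if (is.character(tcell_column)) {
    tcell_column <- match(tcell_column, colnames(tpm))
    assert_that(!is.na(tcell_column), "tcell_column not found among columns")
  }
  out <- data.frame(
    gene_id = rownames(tpm) %||% sprintf("gene_%d", seq_len(nrow(tpm))),
    breadth = apply(tpm, 1, expression_breadth, frac = frac),
    tcell_rank = apply(tpm, 1, tcell_rank, tcell_index = tcell_column),
    tcell_ratio = apply(tpm, 1, function(r) as.numeric(tcell_ratio(r, tcell_column))),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("SpecificityProfile", "data.frame")
  out
}
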