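#' @include AllClasses.R
NULL

#' Assign binary sensitivity labels from a per-drug IC50 vector
#'
#' The per-drug median IC50 is the data-driven threshold: a cell line is
#' \code{sensitive} when its IC50 is strictly below the threshold and
#' \code{non_sensitive} when it is equal to or above it. For even sample
#' sizes the interpolated median (mean of the two middle values) is used.
#' An external threshold can be supplied instead of the median.
#'
#' @param ic50 complete named numeric vector of IC50 values (names are
#'   cell-line ids), length at least 2.
#' @param drug drug identifier recorded in the result.
#' @param threshold optional externally fixed threshold; default is the
#'   median of \code{ic50}.
#' @return a \linkS4class{LabelVector}.
#' @examples
#' assignLabels(setNames(1:5, paste0("c", 1:5)), "drugA")
#' @export
assignLabels <- function(ic50, drug = "drug", threshold = NULL) {
  if (anyNA(ic50)) stop("IC50 vector must be complete (impute first)",
                        call. = FALSE)
  if (length(ic50) < 2L) stop("need at least 2 cell lines", call. = FALSE)
  if (is.null(names(ic50))) stop("ic50 must be named by cell line",
                                 call. = FALSE)
  thr <- if (is.null(threshold)) median(ic50) else threshold
  lab <- factor(ifelse(ic50 < thr, "sensitive", "non_sensitive"),
                levels = .LABEL_LEVELS)
  names(lab) <- names(ic50)
  if (length(unique(lab)) < 2L)
    stop("drug '", drug, "' yields a single class and is unusable",
         call. = FALSE)
  new("LabelVector", drug = drug, labels = lab, threshold = thr)
}

#' Imbalance ratio of a label vector
#'
#' IR = |non-sensitive| / |sensitive|. The non-sensitive class is treated
#' as the majority by definition; if the sensitive class actually
#' dominates, IR falls below 1 and the EasyEnsemble wrapper (triggered at
#' IR > 2) is simply bypassed.
#'
#' @param labels a \linkS4class{LabelVector} or a factor with levels
#'   \code{non_sensitive}, \code{sensitive}.
#' @return a nonnegative number.
#' @examples
#' lv <- assignLabels(setNames(c(1, 2, 3, 4, 5), paste0("c", 1:5)), "d")
#' imbalanceRatio(lv)
#' @export
imbalanceRatio <- function(labels) {
  lab <- if (is(labels, "LabelVector")) labelValues(labels) else labels
  n_sens <- sum(lab == "sensitive")
  n_non <- sum(lab == "non_sensitive")
  if (n_sens == 0L) stop("empty sensitive (minority) class", call. = FALSE)
  n_non / n_sens
}
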