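#' Ordered developmental stages of hematopoietic specification
#'
#' The pipeline works on six sequential stages of in vitro hematopoietic
#' specification and differentiation: embryonic stem cells (ESC), mesoderm
#' (MES), hemangioblast (HB), hemogenic endothelium (HE), hematopoietic
#' progenitors (HP) and macrophages (MAC). The order is total; transition
#' \code{Tk} joins stage \code{k} to stage \code{k + 1} (T1 = ESC to MES,
#' ..., T5 = HP to MAC). Every stage-indexed object in the package (peak
#' sets, expression columns, binary DHS codes, stage networks) uses this
#' order.
#'
#' @return Character vector of the six stage names, in developmental order.
#' @examples
#' hemo_stages()
#' @export
hemo_stages <- function() {
  c("ESC", "MES", "HB", "HE", "HP", "MAC")
}

#' Position of a stage in the developmental order
#'
#' @param stage Character vector of stage names (subset of
#'   \code{hemo_stages()}).
#' @return Integer vector of 1-based stage indices (ESC = 1, ..., MAC = 6).
#' @examples
#' stage_index(c("HB", "MAC"))
#' @export
stage_index <- function(stage) {
  i <- match(stage, hemo_stages())
  if (anyNA(i)) {
    stop("unknown stage(s): ", paste(stage[is.na(i)], collapse = ", "),
         "; expected one of ", paste(hemo_stages(), collapse = ", "))
  }
  i
}

#' Names of the five stage transitions
#'
#' @return Character vector \code{c("T1", ..., "T5")}; \code{Tk} joins
#'   stage \code{k} to stage \code{k + 1}.
#' @export
hemo_transitions <- function() {
  paste0("T", 1:5)
}
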