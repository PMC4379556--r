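#' Compare cell and virion abundance profiles
#'
#' Per element, the virion/cell relative-abundance ratio and a packaging
#' category. Loci undetected in one sample are floored at \code{floor}
#' percent for the ratio (and flagged \code{cell_only}/\code{virion_only});
#' when both are detected the raw values are used. Categories:
#' \code{increased} when the ratio exceeds the similar band, \code{decreased}
#' below it, \code{similar} within it. The human-readable fold is truncated
#' to an integer at 10-fold and above (so 25.32\% in cells against 0.38\% in
#' virions reads "66-fold decrease") and given to one decimal below 10-fold.
#'
#' @param cell,virion [computeExpression()] data.frames (or any frames with
#'   \code{element_id} and \code{abundance} columns) for the two samples.
#' @param floor detection floor in percent (default 0.01).
#' @param similar_band numeric length 2: ratio band treated as similar
#'   abundance.
#' @return data.frame: \code{element_id}, \code{a_cell}, \code{a_virion},
#'   \code{ratio}, \code{category}, \code{fold_text}, \code{detected_cell},
#'   \code{detected_virion}.
#' @export
compareProfiles <- function(cell, virion, floor = 0.01,
                            similar_band = c(0.5, 2.0)) {
  ce <- cell[!is.na(cell$abundance), c("element_id", "abundance")]
  vi <- virion[!is.na(virion$abundance), c("element_id", "abundance")]
  ids <- union(ce$element_id, vi$element_id)
  a_cell <- setNames(rep(0, length(ids)), ids)
  a_vir <- a_cell
  a_cell[ce$element_id] <- ce$abundance
  a_vir[vi$element_id] <- vi$abundance
  det_c <- a_cell > 0
  det_v <- a_vir > 0
  keep <- det_c | det_v
  ids <- ids[keep]
  a_cell <- a_cell[keep]; a_vir <- a_vir[keep]
  det_c <- det_c[keep]; det_v <- det_v[keep]
  r <- pmax(a_vir, floor) / pmax(a_cell, floor)
  category <- ifelse(!det_v, "cell_only",
              ifelse(!det_c, "virion_only",
              ifelse(r > similar_band[2], "increased",
              ifelse(r < similar_band[1], "decreased", "similar"))))
  fold <- pmax(r, 1 / r)
  fold_txt <- ifelse(fold >= 10, sprintf("%d", as.integer(trunc(fold))),
                     sprintf("%.1f", fold))
  dir <- ifelse(r >= 1, "increase", "decrease")
  fold_text <- ifelse(abs(r - 1) < 1e-12, "no change",
                      paste0(fold_txt, "-fold ", dir))
  data.frame(element_id = ids, a_cell = unname(a_cell),
             a_virion = unname(a_vir), ratio = unname(r),
             category = unname(category), fold_text = unname(fold_text),
             detected_cell = unname(det_c), detected_virion = unname(det_v),
             stringsAsFactors = FALSE, row.names = NULL)
}
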