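#' Significance-screen one parameter class against a trait vector
#'
#' Correlates every parameter column of the requested class with the target
#' and keeps those whose two-sided Pearson p value is below `alpha`, ordered
#' by descending |r|. This is the per-class building block of the four
#' screening strategies.
#'
#' @param params a [parameter_matrix()] (with the `param_class` attribute).
#' @param target numeric trait vector aligned with the rows of `params`.
#' @param class_tag one of `"empirical"`, `"trilateral"`, `"dualband"`.
#' @param alpha significance level (default 0.05, no multiplicity
#'   correction, matching the screening protocol being emulated).
#' @param p_adjust `"none"` (the protocol default) or `"BH"` for a
#'   Benjamini-Hochberg false-discovery-rate correction within the class.
#' @return data.frame with columns `member`, `r`, `p`, `n`, possibly empty
#'   (a warning is logged when nothing passes the gate). `p` is the
#'   (possibly adjusted) value the gate was applied to.
#' @export
screen_class <- function(params, target, class_tag, alpha = 0.05,
                         p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  tags <- attr(params, "param_class")
  if (is.null(tags)) stop("params lacks the 'param_class' attribute")
  class_tag <- match.arg(class_tag, c("empirical", "trilateral", "dualband"))
  cols <- names(tags)[tags == class_tag]
  stats_list <- lapply(cols, function(cn) pearson_r_with_p(params[, cn], target))
  out <- data.frame(member = cols,
                    r = vapply(stats_list, `[[`, numeric(1), "r"),
                    p = vapply(stats_list, `[[`, numeric(1), "p"),
                    n = vapply(stats_list, `[[`, integer(1), "n"),
                    stringsAsFactors = FALSE)
  if (p_adjust == "BH") out$p <- stats::p.adjust(out$p, method = "BH")
  out <- out[!is.na(out$p) & out$p < alpha, , drop = FALSE]
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) {
    warning(sprintf("no %s parameter passed the p < %g gate", class_tag, alpha))
  }
  out
}

#' Build the four screened feature combinations for every leaf layer
#'
#' For each leaf layer, screens the three parameter classes independently at
#' `alpha` and forms the four input combinations: `empirical`
#' ("Combination 1"), `dualband` ("Combination 2"), `trilateral`
#' ("Combination 3"), and `mixed` ("Combination 4", the union of the other
#' three preserving class order).
#'
#' @param params_by_layer named list (by layer) of [parameter_matrix()]
#'   objects, typically with layer-specific dual-band pairs; a single matrix
#'   is recycled for all layers (shared-pair mode).
#' @param lnc tidy LNC table (`sample_id`, `layer`, `lnc`).
#' @param alpha significance level.
#' @param layers layers to process (default `CL`, `LL`, `RL`).
#' @return nested list `combos[[layer]][[combination]]`: data.frames as
#'   returned by [screen_class()]; each combination carries its display
#'   label in the `"label"` attribute.
#' @export
build_combinations <- function(params_by_layer, lnc,
                               alpha = 0.05, layers = c("CL", "LL", "RL")) {
  if (is.matrix(params_by_layer)) {
    params_by_layer <- stats::setNames(rep(list(params_by_layer), length(layers)), layers)
  }
  labels <- c(empirical = "Combination 1", dualband = "Combination 2",
              trilateral = "Combination 3", mixed = "Combination 4")
  out <- lapply(layers, function(ly) {
    params <- params_by_layer[[ly]]
    if (is.null(params)) stop(sprintf("no parameter matrix supplied for layer %s", ly))
    target <- layer_target(lnc, ly, rownames(params))
    per_class <- lapply(c("empirical", "dualband", "trilateral"),
                        function(tg) screen_class(params, target, tg, alpha))
    names(per_class) <- c("empirical", "dualband", "trilateral")
    mixed <- do.call(rbind, per_class[c("empirical", "dualband", "trilateral")])
    rownames(mixed) <- NULL
    combos <- c(per_class, list(mixed = mixed))
    for (nm in names(combos)) attr(combos[[nm]], "label") <- labels[[nm]]
    combos
  })
  stats::setNames(out, layers)
}

#' Extract one layer's trait vector aligned to a sample ordering
#'
#' @param lnc tidy LNC table.
#' @param layer layer code (`"CL"`, `"LL"`, `"RL"`).
#' @param ids sample ids defining the output order.
#' @return numeric vector of LNC values.
#' @export
layer_target <- function(lnc, layer, ids) {
  sub <- lnc[lnc$layer == layer, , drop = FALSE]
  idx <- match(ids, sub$sample_id)
  if (anyNA(idx)) stop(sprintf("layer %s missing for sample '%s'", layer, ids[which(is.na(idx))[1]]))
  sub$lnc[idx]
}
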