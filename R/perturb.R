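#' In-silico interventions: clamping nodes of a logical network
#'
#' A perturbation is a set of nodes held at fixed values for the whole
#' network evolution, the discrete analogue of a pharmacological block or a
#' constitutively active channel. A clamped node ignores its regulators from
#' the first update onwards; its value at time 0 is whatever the initial
#' condition says (so basin statistics stay comparable across scenarios).
#'
#' @param ... named clamp values, e.g. `perturbation(HCN = 0, CaKC = 1)`.
#' @param label scenario identifier; derived from the clamps when omitted.
#' @return a tibble of class `perturbation` with columns `node`, `value`.
#' @export
perturbation <- function(..., label = NULL) {
  cl <- c(...)
  if (length(cl) == 0) {
    out <- tibble::tibble(node = character(), value = integer())
    attr(out, "label") <- label %||% "WT"
    class(out) <- c("perturbation", class(out))
    return(out)
  }
  if (is.null(names(cl)) || any(!nzchar(names(cl)))) {
    stop("clamps must be named, e.g. perturbation(HCN = 0)", call. = FALSE)
  }
  if (anyDuplicated(names(cl))) stop("a node appears more than once", call. = FALSE)
  out <- tibble::tibble(node = names(cl), value = as.integer(cl))
  attr(out, "label") <- label %||% clamp_signature(out)
  class(out) <- c("perturbation", class(out))
  out
}

clamp_signature <- function(spec) {
  if (nrow(spec) == 0) return("WT")
  paste0(spec$node, ifelse(spec$value == 0, "-", paste0("+", spec$value)),
         collapse = " ") |>
    gsub(pattern = "\\+1\\b", replacement = "+")
}

#' @export
print.perturbation <- function(x, ...) {
  cat(sprintf("<perturbation> %s\n", attr(x, "label")))
  NextMethod()
}

#' @rdname perturbation
#' @param spec a `perturbation`.
#' @export
perturbation_label <- function(spec) attr(spec, "label")

#' Knockout: clamp channels closed
#'
#' Models channel block (the niflumic-acid deletion semantics): every listed
#' node is held at 0 for the whole evolution, so the channel stays closed
#' even when its regulators are active.
#'
#' @param nodes character vector of node names.
#' @param label optional scenario label.
#' @return a [perturbation()].
#' @export
knockout <- function(nodes, label = NULL) {
  v <- stats::setNames(rep(0L, length(nodes)), nodes)
  perturbation(v, label = label)
}

#' Constitutive activation: clamp a binary channel open
#'
#' Holds every listed node at 1 for the whole evolution (permanently open
#' channel).
#'
#' @inheritParams knockout
#' @return a [perturbation()].
#' @export
constitutive_activation <- function(nodes, label = NULL) {
  v <- stats::setNames(rep(1L, length(nodes)), nodes)
  perturbation(v, label = label)
}

#' Merge perturbations
#'
#' Clamping commutes and is idempotent, so specs can be combined in any
#' order; a node may not receive two different clamp values.
#'
#' @param ... `perturbation` objects.
#' @param label optional label for the combination.
#' @return a [perturbation()].
#' @export
combine_perturbations <- function(..., label = NULL) {
  specs <- list(...)
  all <- dplyr::distinct(dplyr::bind_rows(lapply(specs, function(s) s[, c("node", "value")])))
  if (anyDuplicated(all$node)) {
    stop("conflicting clamp values for node(s): ",
         paste(unique(all$node[duplicated(all$node)]), collapse = ", "), call. = FALSE)
  }
  perturbation(stats::setNames(all$value, all$node), label = label)
}

#' The 12-scenario niflumic-acid intervention suite
#'
#' Enumerates the wild type and every studied combination of the three
#' NFA-sensitive channels: single knockouts of HCN, CaCC and CaKC plus the
#' constitutive activation of CaKC; the three pairwise knockouts and the two
#' pairs with CaKC activated; and the two triple interventions — scenario 1
#' (all three channels clamped closed) and scenario 2 (HCN and CaCC closed,
#' CaKC open). CaKC-activated scenarios carry `scenario = 2`.
#'
#' @return a named list of 12 [perturbation()] objects, `WT` first.
#' @export
scenario_suite <- function() {
  specs <- list(
    perturbation(label = "WT"),
    knockout("HCN"),
    knockout("CaCC"),
    knockout("CaKC"),
    constitutive_activation("CaKC"),
    knockout(c("HCN", "CaCC")),
    knockout(c("HCN", "CaKC")),
    knockout(c("CaCC", "CaKC")),
    combine_perturbations(knockout("HCN"), constitutive_activation("CaKC")),
    combine_perturbations(knockout("CaCC"), constitutive_activation("CaKC")),
    knockout(c("HCN", "CaCC", "CaKC"), label = "HCN- CaCC- CaKC- (scenario 1)"),
    combine_perturbations(knockout(c("HCN", "CaCC")), constitutive_activation("CaKC"),
                          label = "HCN- CaCC- CaKC+ (scenario 2)")
  )
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    attr(specs[[i]], "scenario") <-
      if (nrow(s) > 0 && any(s$node == "CaKC" & s$value == 1L)) 2L else 1L
  }
  names(specs) <- vapply(specs, perturbation_label, character(1))
  specs
}

`%||%` <- function(x, y) if (is.null(x)) y else x
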