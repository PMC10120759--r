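#' Expand variants into per-(variant, group) copies
#'
#' The bilevel prior treats a variant that belongs to several annotation
#' groups separately in each group: shrinkage parameters and posterior
#' effects live on (variant, group) *copies*, and the per-variant effect is
#' the sum over its copies. For a non-overlapping map the expansion is the
#' identity (`m_prime = M`). Copy order is deterministic: variant order of
#' `ss`, then group order of the map within each variant.
#'
#' @param am An [annotation_map()]; variants of `ss` not covered get the
#'   sentinel group.
#' @param ss Summary-statistics tibble (defines variant order).
#' @return An object of class `expanded_design`: a tibble with columns
#'   `copy` (index), `variant_id`, `variant_index`, `group`, `group_index`,
#'   with attributes `m_prime`, `groups`, `group_sizes` (copies per group,
#'   named) and `m_variants`.
#' @export
expand_overlap <- function(am, ss) {
  am <- complete_annotations(am, ss$variant_id)
  sets <- am$assignment[ss$variant_id]
  ord <- lapply(sets, function(g) sort(match(g, am$groups)))
  n_copies <- lengths(ord)
  design <- tibble::tibble(
    copy = seq_len(sum(n_copies)),
    variant_id = rep(ss$variant_id, n_copies),
    variant_index = rep(seq_len(nrow(ss)), n_copies),
    group_index = unlist(ord, use.names = FALSE)
  )
  design$group <- am$groups[design$group_index]
  design <- design[, c("copy", "variant_id", "variant_index", "group", "group_index")]
  gs <- tabulate(design$group_index, nbins = length(am$groups))
  names(gs) <- am$groups
  structure(design,
            class = c("expanded_design", class(design)),
            m_prime = nrow(design),
            groups = am$groups,
            group_sizes = gs,
            m_variants = nrow(ss))
}

design_m_prime <- function(design) attr(design, "m_prime")
design_groups <- function(design) attr(design, "groups")
design_group_sizes <- function(design) attr(design, "group_sizes")

#' @export
print.expanded_design <- function(x, ...) {
  cat("<expanded_design> ", attr(x, "m_variants"), " variants -> ",
      attr(x, "m_prime"), " copies in ", length(attr(x, "groups")),
      " group(s)\n", sep = "")
  NextMethod()
}
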