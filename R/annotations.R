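#' Annotation maps
#'
#' An annotation map assigns each variant a non-empty set of annotation-group
#' labels (gene-based categories, pathways, ...). Groups may overlap: a
#' variant mapped to several pathways carries all of their labels. Variants
#' without any annotation are assigned the sentinel group `"__none__"`.
#'
#' @param assignment Named list: variant id -> character vector of labels,
#'   or a long tibble with columns `variant_id`, `group`.
#' @param groups Optional ordered character vector of group labels; defaults
#'   to the sorted distinct labels observed.
#' @return An object of class `annotation_map` with fields `groups` (ordered
#'   labels) and `assignment` (named list of label sets).
#' @export
annotation_map <- function(assignment, groups = NULL) {
  if (is.data.frame(assignment)) {
    stopifnot(all(c("variant_id", "group") %in% names(assignment)))
    assignment <- split(as.character(assignment$group),
                        factor(assignment$variant_id,
                               levels = unique(assignment$variant_id)))
  }
  assignment <- lapply(assignment, function(g) unique(as.character(g)))
  if (any(lengths(assignment) == 0)) abort("every variant needs at least one label")
  observed <- unique(unlist(assignment, use.names = FALSE))
  if (is.null(groups)) groups <- sort(observed)
  if (!all(observed %in% groups)) {
    abort(paste0("labels not in groups: ",
                 paste(setdiff(observed, groups), collapse = ", ")))
  }
  structure(list(groups = groups, assignment = assignment),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat("<annotation_map> ", length(x$assignment), " variants, K = ",
      length(x$groups), " groups\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.annotation_map <- function(x, ...) {
  tibble::tibble(
    variant_id = rep(names(x$assignment), lengths(x$assignment)),
    group = unlist(x$assignment, use.names = FALSE)
  )
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

none_label <- function() "__none__"

#' Look up the label sets for a set of variants
#'
#' Variants absent from the map (or mapped to an empty label) receive the
#' sentinel group `"__none__"`, mirroring the convention of keeping a
#' separate group for variants with no annotations.
#'
#' @param am An [annotation_map()].
#' @param variant_ids Character vector of variant ids to query.
#' @return An `annotation_map` covering exactly `variant_ids`; the sentinel
#'   label is appended to `groups` when needed.
#' @export
complete_annotations <- function(am, variant_ids) {
  sets <- am$assignment[variant_ids]
  names(sets) <- variant_ids
  missing <- lengths(sets) == 0 | vapply(sets, is.null, logical(1))
  sets[missing] <- list(none_label())
  groups <- am$groups
  if (any(missing) && !(none_label() %in% groups)) {
    groups <- c(groups, none_label())
  }
  annotation_map(sets, groups = groups)
}

#' Read a variant-to-annotation mapping
#'
#' Expects a TSV with two columns: variant id and a comma-separated list of
#' group labels. Multi-label rows are preserved (overlapping groups); rows
#' with an empty label field get the sentinel `"__none__"` group.
#'
#' @param path Path to the annotation TSV (no header).
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) abort(paste0("annotation file not found: ", path))
  raw <- readr::read_tsv(path, col_names = c("variant_id", "labels"),
                         col_types = "cc", progress = FALSE)
  if (nrow(raw) == 0) abort("annotation file is empty")
  sets <- strsplit(ifelse(is.na(raw$labels) | raw$labels == "",
                          none_label(), raw$labels), ",", fixed = TRUE)
  sets <- lapply(sets, trimws)
  names(sets) <- raw$variant_id
  annotation_map(sets)
}

#' Intersection-over-union of two annotation groups
#'
#' @param am An [annotation_map()].
#' @param g1,g2 Group labels.
#' @return IOU in `[0, 1]`: shared variants / variants in either group.
#' @export
iou <- function(am, g1, g2) {
  if (!all(c(g1, g2) %in% am$groups)) abort("both groups must exist in the map")
  tab <- as_tibble(am)
  s1 <- tab$variant_id[tab$group == g1]
  s2 <- tab$variant_id[tab$group == g2]
  u <- union(s1, s2)
  if (length(u) == 0) abort("both groups are empty; IOU undefined")
  length(intersect(s1, s2)) / length(u)
}

#' Construct annotation assignments with controlled overlap
#'
#' Builds a K-group map over `variant_ids` with the group sizes of a
#' partition given by `sizes`, then (for the overlap patterns) adds the
#' second label to a subset of variants so that the intersection-over-union
#' between one designated pair of groups reaches `target_iou`. Pattern
#' `"overlap_I"` overlaps the two low-heritability groups (indices 1, 2);
#' `"overlap_II"` overlaps the two high-heritability groups (indices 3, 4);
#' all other pairs remain disjoint. `"none"` returns the plain partition.
#'
#' @param variant_ids Character vector of variants (length `sum(sizes)`).
#' @param sizes Partition sizes M_k (length K).
#' @param pattern `"none"`, `"overlap_I"` or `"overlap_II"` (the latter two
#'   require K = 4).
#' @param target_iou Target IOU for the overlapped pair (default 0.5).
#' @param seed Integer seed controlling which variants gain the extra label.
#' @param group_labels Optional labels; default `g1..gK`.
#' @return An [annotation_map()].
#' @export
make_overlap_assignment <- function(variant_ids, sizes,
                                    pattern = c("none", "overlap_I", "overlap_II"),
                                    target_iou = 0.5, seed = 1,
                                    group_labels = NULL) {
  pattern <- match.arg(pattern)
  K <- length(sizes)
  if (sum(sizes) != length(variant_ids)) {
    abort("sum(sizes) must equal length(variant_ids)")
  }
  if (pattern != "none" && K != 4) abort("overlap patterns require K = 4")
  if (is.null(group_labels)) group_labels <- paste0("g", seq_len(K))
  grp <- rep(group_labels, times = sizes)
  sets <- as.list(grp)
  names(sets) <- variant_ids

  if (pattern != "none") {
    pair <- if (pattern == "overlap_I") c(1L, 2L) else c(3L, 4L)
    m1 <- sizes[pair[1]]; m2 <- sizes[pair[2]]
    # adding the other label to s_i members of partition cell i gives
    # IOU = (s1 + s2) / (m1 + m2)
    s1 <- round(target_iou * m1); s2 <- round(target_iou * m2)
    if (s1 > m1 || s2 > m2 || target_iou < 0 || target_iou > 1) {
      abort("target_iou infeasible for the given sizes")
    }
    withr_seed(seed, {
      idx1 <- which(grp == group_labels[pair[1]])
      idx2 <- which(grp == group_labels[pair[2]])
      pick1 <- sample(idx1, s1)
      pick2 <- sample(idx2, s2)
      for (i in pick1) sets[[i]] <- c(sets[[i]], group_labels[pair[2]])
      for (i in pick2) sets[[i]] <- c(sets[[i]], group_labels[pair[1]])
    })
  }
  annotation_map(sets, groups = group_labels)
}

# evaluate expr under a temporary seed, restoring RNG state afterwards
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval.parent(substitute(expr))
}
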