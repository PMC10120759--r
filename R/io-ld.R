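#' Construct and validate an LD block
#'
#' An LD block holds an ordered set of variant ids and the corresponding
#' symmetric, unit-diagonal correlation matrix `D` estimated from a reference
#' panel. Validation enforces symmetry (1e-10), unit diagonal and positive
#' semi-definiteness up to an eigenvalue tolerance of -1e-8.
#'
#' @param variant_ids Character vector of variant ids, in matrix order.
#' @param D Square correlation matrix.
#' @param ridge Optional ridge value added to the diagonal (then rescaled to
#'   unit diagonal) to repair near-singular blocks; `0` disables.
#' @return An object of class `ld_block`.
#' @export
ld_block <- function(variant_ids, D, ridge = 0) {
  D <- as.matrix(D)
  m <- length(variant_ids)
  if (!all(dim(D) == c(m, m))) abort("D must be square and match variant_ids")
  if (max(abs(D - t(D))) > 1e-10) abort("LD matrix is not symmetric")
  if (ridge > 0) {
    D <- (D + diag(ridge, m)) / (1 + ridge)
  }
  if (max(abs(diag(D) - 1)) > 1e-8) abort("LD matrix diagonal must be 1")
  ev_min <- min(eigen(D, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8) {
    abort("LD matrix is not positive semi-definite; consider ridge repair (ridge = 1e-6)")
  }
  structure(list(variant_ids = as.character(variant_ids), D = unname(D)),
            class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat("<ld_block> ", length(x$variant_ids), " variants\n", sep = "")
  invisible(x)
}

block_variant_ids <- function(blocks) {
  unlist(lapply(blocks, function(b) b$variant_ids), use.names = FALSE)
}

#' Compute LD blocks from a genotype matrix
#'
#' Standardizes dosages column-wise and computes the sample correlation
#' within each block. Monomorphic variants are dropped with a message.
#'
#' @param genotypes n x m dosage matrix with variant ids as column names.
#' @param block_table Tibble with columns `start`, `end` giving half-open
#'   `[start, end)` 1-based column index ranges (optionally `chrom`,
#'   `start`/`end` interpreted on `pos` when a `bim` is supplied).
#' @param bim Optional bim tibble; when given, `block_table` boundaries are
#'   base-pair positions rather than column indices.
#' @param ridge Ridge repair value passed to [ld_block()] (0 = off).
#' @return List of `ld_block` objects.
#' @export
ld_blocks_from_genotypes <- function(genotypes, block_table, bim = NULL, ridge = 0) {
  m <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) abort("genotype matrix must have variant ids as column names")
  sds <- apply(genotypes, 2, sd)
  mono <- !is.finite(sds) | sds == 0
  if (any(mono)) {
    inform(paste0("dropped ", sum(mono), " monomorphic variant(s) from LD reference"))
  }
  blocks <- list()
  for (i in seq_len(nrow(block_table))) {
    if (!is.null(bim)) {
      in_blk <- bim$pos >= block_table$start[i] & bim$pos < block_table$end[i]
      if ("chrom" %in% names(block_table) && "chrom" %in% names(bim)) {
        in_blk <- in_blk & bim$chrom == block_table$chrom[i]
      }
      cols <- match(bim$variant_id[in_blk], ids)
      cols <- cols[!is.na(cols)]
    } else {
      cols <- seq(block_table$start[i], min(block_table$end[i] - 1, m))
    }
    cols <- cols[!mono[cols]]
    if (length(cols) == 0) next
    D <- cor(genotypes[, cols, drop = FALSE])
    blocks[[length(blocks) + 1]] <- ld_block(ids[cols], D, ridge = ridge)
  }
  blocks
}

#' Read an LD reference
#'
#' Accepts either a PLINK triplet prefix (genotypes are read, standardized
#' and correlated within blocks) or a directory of precomputed per-block
#' correlation matrices stored as TSV files (`ld_block_*.tsv`, header row =
#' variant ids). Variants listed in `block_table` but absent from the panel
#' are dropped with a warning.
#'
#' @param path PLINK prefix or directory of precomputed blocks.
#' @param block_table Block boundary table (see [ld_blocks_from_genotypes()]);
#'   ignored for precomputed directories.
#' @param ridge Ridge repair value (0 = off).
#' @return List of `ld_block` objects.
#' @export
read_ld_reference <- function(path, block_table = NULL, ridge = 0) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "^ld_block_.*\\.tsv$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("no ld_block_*.tsv files in ", path))
    return(lapply(files, function(f) {
      tab <- readr::read_tsv(f, col_types = readr::cols(.default = "d"),
                             progress = FALSE)
      ld_block(names(tab), as.matrix(tab), ridge = ridge)
    }))
  }
  if (is.null(block_table)) abort("block_table is required for a PLINK reference")
  pk <- read_plink(path)
  want <- NULL
  if ("variant_id" %in% names(block_table)) {
    want <- block_table$variant_id
    missing_ids <- setdiff(want, pk$bim$variant_id)
    if (length(missing_ids) > 0) {
      warn(paste0(length(missing_ids), " variant(s) in block table absent from panel; dropped"))
    }
  }
  ld_blocks_from_genotypes(pk$genotypes, block_table, bim = pk$bim, ridge = ridge)
}

#' Extract the panel allele table from a PLINK triplet or bim tibble
#'
#' @param bim A bim tibble (from [read_plink()]).
#' @return Tibble with `variant_id`, `a1`, `a2`.
#' @export
panel_alleles <- function(bim) {
  tibble::tibble(variant_id = bim$variant_id,
                 a1 = toupper(bim$a1), a2 = toupper(bim$a2))
}
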