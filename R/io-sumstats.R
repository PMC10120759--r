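#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited summary-statistics file into the
#' standardized per-variant table used throughout the package. Two dialects
#' are supported: `"prscs"` expects the columns `SNP A1 A2 BETA` (or `OR`)
#' `P`, the layout used by continuous-shrinkage PRS tools; `"generic"` takes
#' an explicit column map. Odds ratios are log-transformed at read time so
#' downstream code only ever sees additive effects on the standardized scale.
#'
#' @param path Path to the summary-statistics file (header required).
#' @param dialect `"prscs"` or `"generic"`.
#' @param n_gwas GWAS sample size. Required for the `"prscs"` dialect (the
#'   format carries no N column). For `"generic"`, used as a fallback when
#'   `col_map` names no `n` column. If a per-variant N column is present, the
#'   median N is used for all variants, with a warning.
#' @param col_map Named character vector for the `"generic"` dialect mapping
#'   canonical names (`variant_id`, `a1`, `a2`, `beta` or `or`, and
#'   optionally `chrom`, `pos`, `se`, `n`) to file column names.
#'
#' @return A tibble with columns `variant_id`, `chrom`, `pos`, `a1`, `a2`,
#'   `beta_hat`, `n_gwas`. Rows with missing effects (or zero/missing SE when
#'   an SE column is mapped) are dropped with a message.
#' @export
read_sumstats <- function(path, dialect = c("prscs", "generic"),
                          n_gwas = NULL, col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("summary-statistics file not found: ", path))
  raw <- readr::read_table(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (nrow(raw) == 0) abort("summary-statistics file is empty")

  if (dialect == "prscs") {
    need <- c("SNP", "A1", "A2")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("summary-statistics file missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    if (!any(c("BETA", "OR") %in% names(raw))) {
      abort("summary-statistics file missing required column(s): BETA (or OR)")
    }
    if (is.null(n_gwas)) abort("`n_gwas` is required for the prscs dialect")
    eff <- if ("BETA" %in% names(raw)) as.numeric(raw$BETA) else log(as.numeric(raw$OR))
    out <- tibble::tibble(
      variant_id = raw$SNP,
      chrom = if ("CHR" %in% names(raw)) raw$CHR else NA_character_,
      pos = if ("BP" %in% names(raw)) as.integer(raw$BP) else NA_integer_,
      a1 = toupper(raw$A1), a2 = toupper(raw$A2),
      beta_hat = eff,
      n_gwas = as.integer(round(n_gwas))
    )
    se <- if ("SE" %in% names(raw)) as.numeric(raw$SE) else NULL
  } else {
    if (is.null(col_map)) abort("`col_map` is required for the generic dialect")
    for (canon in c("variant_id", "a1", "a2")) {
      if (!canon %in% names(col_map)) {
        abort(paste0("col_map must name a column for: ", canon))
      }
    }
    if (!any(c("beta", "or") %in% names(col_map))) {
      abort("col_map must name a column for: beta (or or)")
    }
    missing_cols <- setdiff(unname(col_map), names(raw))
    if (length(missing_cols) > 0) {
      abort(paste0("summary-statistics file missing required column(s): ",
                   paste(missing_cols, collapse = ", ")))
    }
    get <- function(canon) if (canon %in% names(col_map)) raw[[col_map[[canon]]]] else NULL
    eff <- if ("beta" %in% names(col_map)) as.numeric(get("beta")) else log(as.numeric(get("or")))
    nvec <- get("n")
    if (!is.null(nvec)) {
      nvec <- as.numeric(nvec)
      if (length(unique(nvec[is.finite(nvec)])) > 1L) {
        warn("per-variant N column found; using the median N for all variants")
      }
      n_use <- as.integer(round(median(nvec, na.rm = TRUE)))
    } else {
      if (is.null(n_gwas)) abort("no N column mapped and `n_gwas` not supplied")
      n_use <- as.integer(round(n_gwas))
    }
    out <- tibble::tibble(
      variant_id = as.character(get("variant_id")),
      chrom = as.character(get("chrom") %||% NA_character_),
      pos = as.integer(get("pos") %||% NA_integer_),
      a1 = toupper(as.character(get("a1"))),
      a2 = toupper(as.character(get("a2"))),
      beta_hat = eff,
      n_gwas = n_use
    )
    se <- if ("se" %in% names(col_map)) as.numeric(get("se")) else NULL
  }

  bad <- !is.finite(out$beta_hat)
  if (!is.null(se)) bad <- bad | !is.finite(se) | se <= 0
  if (any(bad)) {
    inform(paste0("dropped ", sum(bad), " variant(s) with missing effect or zero/missing SE"))
    out <- out[!bad, , drop = FALSE]
  }
  if (nrow(out) == 0) abort("no usable variants after dropping missing effects")
  dup <- out$variant_id[duplicated(out$variant_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate variant_id in summary statistics: ", dup[[1]]))
  }
  if (any(out$a1 == out$a2)) {
    abort("a1 and a2 must differ for every variant")
  }
  out
}

#' Align summary-statistics alleles to an LD reference panel
#'
#' Restricts summary statistics to the variants present in the panel (in the
#' panel's block order) and harmonises effect alleles: where summary `a1`/`a2`
#' are swapped relative to the panel, the sign of `beta_hat` is flipped.
#' Variants whose alleles cannot be reconciled are dropped with a message.
#' The operation is idempotent: aligning an already aligned table is a no-op.
#'
#' @param ss Summary-statistics tibble from [read_sumstats()].
#' @param panel_alleles Tibble with columns `variant_id`, `a1`, `a2` giving
#'   the panel's allele coding, in the order of the LD blocks.
#' @param remove_ambiguous Drop strand-ambiguous (A/T, C/G) variants.
#'
#' @return The aligned summary-statistics tibble, one row per panel variant
#'   retained, ordered as `panel_alleles`.
#' @export
align_alleles <- function(ss, panel_alleles, remove_ambiguous = FALSE) {
  stopifnot(all(c("variant_id", "a1", "a2", "beta_hat") %in% names(ss)))
  pa <- panel_alleles
  pa$a1 <- toupper(pa$a1); pa$a2 <- toupper(pa$a2)
  keep <- pa[pa$variant_id %in% ss$variant_id, , drop = FALSE]
  if (nrow(keep) == 0) abort("no shared variants between summary statistics and panel")
  idx <- match(keep$variant_id, ss$variant_id)
  out <- ss[idx, , drop = FALSE]

  same <- out$a1 == keep$a1 & out$a2 == keep$a2
  swapped <- out$a1 == keep$a2 & out$a2 == keep$a1
  ambiguous <- is_strand_ambiguous(out$a1, out$a2)

  drop <- !(same | swapped)
  if (remove_ambiguous) drop <- drop | ambiguous
  out$beta_hat[swapped] <- -out$beta_hat[swapped]
  out$a1[swapped] <- keep$a1[swapped]
  out$a2[swapped] <- keep$a2[swapped]
  if (any(drop)) {
    inform(paste0("dropped ", sum(drop), " variant(s) during allele alignment"))
    out <- out[!drop, , drop = FALSE]
  }
  if (nrow(out) == 0) abort("no shared variants after allele alignment")
  out
}

is_strand_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Write and read posterior effect-size tables
#'
#' The per-copy table has one row per (variant, group) copy with columns
#' `variant_id chrom pos a1 beta_tilde group`; the aggregated table has one
#' row per variant with the summed effect over its copies. Values round-trip
#' through the text format at full double precision.
#'
#' @param effects Tibble of posterior effects (per-copy or per-variant).
#' @param path Output TSV path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_posterior_effects <- function(effects, path) {
  readr::write_tsv(effects, path)
  invisible(path)
}

#' @rdname write_posterior_effects
#' @export
read_posterior_effects <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    variant_id = "c",
    chrom = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
}
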