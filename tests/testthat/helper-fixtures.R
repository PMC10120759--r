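# in-code fixtures used across test files

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_ss <- function(beta_hat, n_gwas = 200L, ids = NULL) {
  m <- length(beta_hat)
  ids <- ids %||% paste0("rs", seq_len(m))
  tibble::tibble(variant_id = ids, chrom = "1", pos = seq_len(m),
                 a1 = "A", a2 = "G", beta_hat = beta_hat,
                 n_gwas = as.integer(n_gwas))
}

toy_identity_blocks <- function(ids, block_size = length(ids)) {
  starts <- seq(1, length(ids), by = block_size)
  lapply(starts, function(s) {
    sel <- ids[s:min(s + block_size - 1, length(ids))]
    ld_block(sel, diag(length(sel)))
  })
}

one_group_map <- function(ids, label = "g1") {
  annotation_map(setNames(as.list(rep(label, length(ids))), ids),
                 groups = label)
}

write_sumstats_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
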