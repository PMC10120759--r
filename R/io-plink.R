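#' Read a PLINK .bed/.bim/.fam genotype triplet
#'
#' Minimal reader for SNP-major PLINK 1 binary genotypes. Dosages count
#' copies of the A1 allele in the .bim file; missing genotypes become `NA`.
#'
#' @param prefix Path prefix; `prefix.bed`, `prefix.bim`, `prefix.fam` must
#'   exist.
#' @return A list with `genotypes` (n x m dosage matrix, columns named by
#'   variant id), `bim` (tibble: chrom, variant_id, cm, pos, a1, a2) and
#'   `fam` (tibble: fid, iid, pat, mat, sex, pheno).
#' @export
read_plink <- function(prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(paste0("PLINK file not found: ", p))
  }
  bim <- readr::read_tsv(bim_path,
    col_names = c("chrom", "variant_id", "cm", "pos", "a1", "a2"),
    col_types = "ccdicc", progress = FALSE)
  fam <- readr::read_table(fam_path,
    col_names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
    col_types = "cccccd", progress = FALSE)
  n <- nrow(fam); m <- nrow(bim)

  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L))) {
    abort("not a SNP-major PLINK .bed file")
  }
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * m)
  if (length(raw) < bytes_per_snp * m) abort(".bed file truncated")
  # 2-bit codes per individual: 00=hom A1 (dosage 2), 10=het, 11=hom A2, 01=missing
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = m)
  ints <- as.integer(raw)
  dim(ints) <- c(bytes_per_snp, m)
  lookup <- bed_code_lookup()
  for (shift in 0:3) {
    codes[seq(shift + 1, 4 * bytes_per_snp, by = 4), ] <-
      lookup[bitwAnd(bitwShiftR(ints, 2L * shift), 3L) + 1L]
  }
  G <- codes[seq_len(n), , drop = FALSE]
  storage.mode(G) <- "double"
  G[G == -1] <- NA_real_
  colnames(G) <- bim$variant_id
  rownames(G) <- fam$iid
  list(genotypes = G, bim = bim, fam = fam)
}

# map 2-bit code -> A1 dosage (-1 = missing)
bed_code_lookup <- function() c(2L, -1L, 1L, 0L)

#' Write a PLINK .bed/.bim/.fam genotype triplet
#'
#' @param genotypes n x m matrix of A1-allele dosages (0/1/2, `NA` missing),
#'   columns named by variant id.
#' @param bim Tibble with columns chrom, variant_id, cm, pos, a1, a2.
#' @param fam Optional fam tibble; generated ids are used when absent.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(genotypes, bim, prefix, fam = NULL) {
  n <- nrow(genotypes); m <- ncol(genotypes)
  stopifnot(nrow(bim) == m)
  if (is.null(fam)) {
    fam <- tibble::tibble(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
                          pat = "0", mat = "0", sex = "0", pheno = -9)
  }
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE)
  readr::write_tsv(fam, paste0(prefix, ".fam"), col_names = FALSE)

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  bytes_per_snp <- ceiling(n / 4)
  # dosage -> 2-bit code: 2->00, 1->10, 0->11, NA->01
  code_of <- function(g) {
    out <- integer(length(g))
    out[is.na(g)] <- 1L
    out[!is.na(g) & g == 2] <- 0L
    out[!is.na(g) & g == 1] <- 2L
    out[!is.na(g) & g == 0] <- 3L
    out
  }
  pad <- 4 * bytes_per_snp - n
  for (j in seq_len(m)) {
    cj <- c(code_of(genotypes[, j]), integer(pad))
    dim(cj) <- c(4, bytes_per_snp)
    byte <- cj[1, ] + bitwShiftL(cj[2, ], 2L) + bitwShiftL(cj[3, ], 4L) +
      bitwShiftL(cj[4, ], 6L)
    writeBin(as.raw(byte), con)
  }
  invisible(prefix)
}
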