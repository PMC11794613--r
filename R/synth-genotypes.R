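#' Generate a block-LD genotype dosage matrix
#'
#' Haplotypes are drawn blockwise from a shared-pool model: within a block
#' every SNP shares one minor-allele frequency and each haplotype copies a
#' single block-wide founder allele with probability `r`, otherwise draws
#' alleles independently. This yields pairwise dosage correlation equal to
#' `r` within a block and independence across blocks. Males on chromosome X
#' carry a single haplotype whose dosage is doubled (hemizygotes coded as
#' homozygotes), so male chrX dosages lie in \{0, 2\}.
#'
#' @param n number of individuals.
#' @param block_spec data frame with one row per block: `n_snp`, `r`
#'   (within-block dosage correlation in [0,1)), optional `chrom`
#'   (defaults to "1", use "X" for the X chromosome) and optional `maf`
#'   (default drawn Uniform(0.05, 0.5)).
#' @param sex optional integer vector (1 = male, 0 = female), required when
#'   any block is on chrX.
#' @param seed integer seed.
#' @param bp_spacing base pairs between adjacent SNPs (default 10 kb).
#' @return An object of class `genotype_matrix`: `dosages` (n x SNPs),
#'   `snp_meta` (chrom, pos, id, ref, alt, maf, block) and `blocks`.
#' @export
generate_genotypes <- function(n, block_spec, sex = NULL, seed = 1,
                               bp_spacing = 10000) {
  stopifnot(is.data.frame(block_spec), all(c("n_snp", "r") %in%
                                             names(block_spec)))
  if (is.null(block_spec$chrom)) block_spec$chrom <- "1"
  restore <- scoped_seed(seed)
  on.exit(restore(), add = TRUE)
  if (is.null(block_spec$maf)) {
    block_spec$maf <- rep(NA_real_, nrow(block_spec))
  }
  draw <- is.na(block_spec$maf)
  block_spec$maf[draw] <- stats::runif(sum(draw), 0.05, 0.5)
  any_x <- any(block_spec$chrom == "X")
  if (any_x && is.null(sex)) stop("sex required when chrX blocks requested")

  total <- sum(block_spec$n_snp)
  dos <- matrix(0L, n, total)
  meta <- data.frame(chrom = character(total), pos = integer(total),
                     id = character(total), ref = "A", alt = "G",
                     maf = numeric(total), block = integer(total),
                     stringsAsFactors = FALSE)
  pos_counter <- new.env()
  col <- 0L
  for (b in seq_len(nrow(block_spec))) {
    m <- block_spec$n_snp[b]
    r <- block_spec$r[b]
    p <- block_spec$maf[b]
    chrom <- as.character(block_spec$chrom[b])
    x_linked <- chrom == "X"
    draw_hap <- function() {
      # one block-wide founder allele per haplotype; the whole haplotype
      # copies it with probability r, giving pairwise dosage correlation r
      founder <- stats::rbinom(n, 1, p)
      copy <- stats::rbinom(n, 1, r)
      indep <- matrix(stats::rbinom(n * m, 1, p), n, m)
      copy * matrix(founder, n, m) + (1 - copy) * indep
    }
    h1 <- draw_hap()
    h2 <- draw_hap()
    g <- h1 + h2
    if (x_linked) g[sex == 1, ] <- 2L * h1[sex == 1, ]
    idx <- col + seq_len(m)
    dos[, idx] <- g
    prev <- if (exists(chrom, envir = pos_counter)) {
      get(chrom, envir = pos_counter)
    } else 0L
    meta$chrom[idx] <- chrom
    meta$pos[idx] <- prev + seq_len(m) * bp_spacing
    assign(chrom, prev + m * bp_spacing + 500000L, envir = pos_counter)
    meta$maf[idx] <- p
    meta$block[idx] <- b
    col <- col + m
  }
  meta$id <- paste0("rs", seq_len(total))
  colnames(dos) <- meta$id
  structure(list(dosages = dos, snp_meta = meta,
                 blocks = block_spec, sex = sex),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs in %d blocks\n",
              nrow(x$dosages), ncol(x$dosages), nrow(x$blocks)))
  invisible(x)
}

#' Write a genotype matrix as minimal VCF 4.2
#'
#' Emits one sample column per individual with a GT field; dosage 0 ->
#' "0/0", 1 -> "0/1", 2 -> "1/1".
#'
#' @param geno a `genotype_matrix`.
#' @param path output file.
#' @export
write_vcf <- function(geno, path) {
  m <- geno$snp_meta
  n <- nrow(geno$dosages)
  gt <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", seq_len(n))),
                     collapse = "\t")), con)
  body <- vapply(seq_len(nrow(m)), function(j) {
    paste(c(m$chrom[j], m$pos[j], m$id[j], m$ref[j], m$alt[j], ".", "PASS",
            ".", "GT", gt[geno$dosages[, j] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

#' Read a minimal GT-only VCF back into dosages
#'
#' @param path VCF file written by [write_vcf()] (or any VCF whose first
#'   FORMAT field is GT with diploid calls).
#' @return A `genotype_matrix` (blocks unknown; maf recomputed from data).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  recs <- strsplit(body[-1], "\t")
  n_sample <- length(hdr) - 9L
  parse_gt <- function(fields) {
    g <- sub(":.*", "", fields[-(1:9)])
    as.integer(substr(g, 1, 1) != "0") + as.integer(substr(g, 3, 3) != "0")
  }
  dos <- vapply(recs, parse_gt, integer(n_sample))
  if (is.null(dim(dos))) dos <- matrix(dos, nrow = n_sample)
  meta <- data.frame(
    chrom = vapply(recs, `[`, "", 1), pos = as.integer(vapply(recs, `[`, "", 2)),
    id = vapply(recs, `[`, "", 3), ref = vapply(recs, `[`, "", 4),
    alt = vapply(recs, `[`, "", 5), stringsAsFactors = FALSE)
  meta$maf <- pmin(colMeans(dos) / 2, 1 - colMeans(dos) / 2)
  meta$block <- NA_integer_
  colnames(dos) <- meta$id
  structure(list(dosages = dos, snp_meta = meta, blocks = NULL, sex = NULL),
            class = "genotype_matrix")
}
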