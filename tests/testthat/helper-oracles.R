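# Independent oracle implementations used to cross-check package
# algorithms. These are written in a deliberately different style from the
# package code (explicit enumeration / plain data-frame loops) and must
# stay independent of the functions they check.

# exhaustive minimum-cost left-to-right path: enumerate every admissible
# row sequence (|row step| <= max_jump), cost = sum of (max - intensity)
# plus lambda per unit row change
oracle_min_path <- function(img, max_jump = 3, lambda_frac = 0.1) {
  n_row <- nrow(img); n_col <- ncol(img)
  lambda <- lambda_frac * (max(img) - min(img))
  cellcost <- max(img) - img
  best <- Inf
  best_path <- NULL
  recurse <- function(path, acc) {
    cc <- length(path)
    if (acc >= best) return()
    if (cc == n_col) {
      if (acc < best) {
        best <<- acc
        best_path <<- path
      }
      return()
    }
    last <- path[cc]
    for (r in max(1, last - max_jump):min(n_row, last + max_jump)) {
      recurse(c(path, r),
              acc + cellcost[r, cc + 1] + lambda * abs(r - last))
    }
  }
  for (r0 in seq_len(n_row)) recurse(r0, cellcost[r0, 1])
  list(cost = best, path = best_path)
}

# Benjamini-Hochberg step-up from first principles: find the largest k
# with p_(k) <= k/m * q by checking every k, then adjusted p by the
# textbook monotone construction
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p of the i-th smallest: min over j >= i of m * p_(j) / j
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    adj[o[i]] <- min(1, min(vals))
  }
  adj
}

# hypergeometric upper tail by explicit enumeration of the pmf
oracle_hyper_tail <- function(k, K, N, n) {
  kk <- max(0, n - (N - K)):min(n, K)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# independent re-implementation of the printed loci-consolidation loop,
# in plain data-frame style. Interpretations (shared with the package, as
# documented): allocation removes (locus SNP x allocated phenotype)
# pairs; supporting SNPs are the full clump membership; the non-index
# branch removes the clump's pairs for the current phenotype only.
oracle_consolidate <- function(tab, clumps, snp_meta, p_iter = 5e-8,
                               p_support = 5e-5, min_snps = 5,
                               p_report = p_iter) {
  df <- tab[tab$p < p_support, c("snp", "phenotype", "p")]
  df$chrom <- snp_meta$chrom[match(df$snp, snp_meta$id)]
  df$pos <- snp_meta$pos[match(df$snp, snp_meta$id)]
  df <- df[order(df$p, df$chrom, df$pos, df$phenotype), ]
  loci <- list()
  sentinels <- character(0)
  while (TRUE) {
    sig <- df[df$p < p_iter, ]
    if (nrow(sig) == 0) break
    s <- sig$snp[1]; q <- sig$phenotype[1]; pv <- sig$p[1]
    cl_q <- clumps[[q]]
    is_index <- FALSE
    members <- character(0)
    for (cl in cl_q) {
      if (cl$index == s) {
        is_index <- TRUE
        members <- union(members, cl$members)
      }
    }
    if (is_index) {
      members <- union(s, members)
      phenos <- unique(df$phenotype[df$snp %in% members])
      loci[[length(loci) + 1]] <- list(sentinel = s, top_phenotype = q,
                                       sentinel_p = pv,
                                       supporting = setdiff(members, s),
                                       phenotypes = phenos,
                                       n_snps = length(members))
      sentinels <- c(sentinels, s)
      df <- df[!(df$snp %in% members & df$phenotype %in% phenos), ]
    } else {
      hold <- Filter(function(cl) s %in% cl$members, cl_q)
      if (length(hold) == 0) stop("oracle: orphan SNP")
      hold <- Filter(function(cl) cl$index %in% sentinels, hold)
      if (length(hold) == 0) stop("oracle: index without locus")
      members <- unique(unlist(lapply(hold, function(cl) cl$members)))
      df <- df[!(df$phenotype == q & df$snp %in% members), ]
    }
  }
  Filter(function(l) l$n_snps >= min_snps && l$sentinel_p < p_report, loci)
}

# canonical form for comparing locus lists
locus_canon <- function(loci) {
  out <- lapply(loci, function(l) {
    list(sentinel = l$sentinel, top = l$top_phenotype,
         supporting = sort(l$supporting),
         phenotypes = sort(l$phenotypes), n_snps = l$n_snps)
  })
  out[order(vapply(out, `[[`, "", "sentinel"))]
}
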