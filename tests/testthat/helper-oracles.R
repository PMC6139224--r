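# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

# BH step-up: p * n / rank with right-to-left cumulative minimum
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exact two-sided rank-sum p by full enumeration of group assignments
ranksum_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled)
  m <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)])
  ws <- apply(utils::combn(N, m), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# upper-tail hypergeometric p by enumerating every possible query draw
hyper_oracle <- function(background, set, query) {
  q <- length(query)
  k_obs <- length(intersect(set, query))
  draws <- utils::combn(background, q, simplify = FALSE)
  mean(vapply(draws, function(d) length(intersect(d, set)) >= k_obs,
              logical(1)))
}

# nearest-TSS mapping by all-pairs scan with the same tie rule
nearest_tss_oracle <- function(probes, genes, max_dist = 10000) {
  res <- lapply(seq_len(nrow(probes)), function(i) {
    g <- genes[genes$chrom == probes$chrom[i], ]
    if (nrow(g) == 0) return(list(gene = NA_character_, d = NA_real_))
    d <- abs(g$tss - probes$pos[i])
    dm <- min(d)
    if (dm >= max_dist) return(list(gene = NA_character_, d = NA_real_))
    cand <- sort(g$gene_id[d == dm])
    list(gene = cand[1], d = dm)
  })
  tibble::tibble(
    probe_id = probes$probe_id,
    gene_id = vapply(res, function(z) z$gene, character(1)),
    tss_distance = vapply(res, function(z) z$d, numeric(1))
  )
}

# max-|r| pair by exhaustive scan with the pairing tie rules
pairing_oracle <- function(em, mm, expr_probes, meth_probes) {
  grid <- expand.grid(e = sort(expr_probes), m = sort(meth_probes),
                      stringsAsFactors = FALSE)
  grid$r <- mapply(function(e, m) cor(em[e, ], mm[m, ]), grid$e, grid$m)
  grid <- grid[order(-abs(grid$r), grid$r, grid$e, grid$m), ]
  grid[1, ]
}

# average-linkage agglomeration by hand for small n: returns the merge
# heights in order
avg_linkage_merge_heights <- function(d) {
  n <- attr(d, "Size")
  dm <- as.matrix(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dij <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dij < bd) { bd <- dij; best <- c(j, i) }
      }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
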