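# Genomic annotation of CpG probes: nearest-TSS gene mapping, gene-region
# category and CpG-island context. All coordinates are 0-based; intervals
# are half-open [start, end), following the BED convention.

#' Map probes to the gene with the nearest transcription start site
#'
#' Each probe is assigned to the gene whose TSS is closest in absolute
#' distance, provided that distance is strictly below `max_dist`; otherwise
#' no gene is assigned. Equidistant TSSs are resolved by lexicographically
#' smallest `gene_id`. Chromosomes are matched by name; probes on
#' chromosomes without genes map to none.
#'
#' @param probes Probe annotation tibble with `probe_id`, `chrom`, `pos`.
#' @param genes Gene models tibble with `gene_id`, `chrom`, `tss`.
#' @param max_dist Maximum TSS distance in bp (default 10000, strict `<`).
#' @return Tibble `probe_id`, `gene_id` (NA when unmapped), `tss_distance`.
#' @export
map_probes_to_genes <- function(probes, genes, max_dist = 10000) {
  out <- tibble(probe_id = probes$probe_id,
                gene_id = NA_character_,
                tss_distance = NA_real_)
  for (ch in unique(probes$chrom)) {
    g <- genes[genes$chrom == ch, ]
    pi <- which(probes$chrom == ch)
    if (nrow(g) == 0 || length(pi) == 0) next
    # one row per distinct TSS position, keeping the lexicographically
    # smallest gene_id at that position (within-position tie rule)
    tsspos <- g |>
      arrange(.data$tss, .data$gene_id) |>
      distinct(.data$tss, .keep_all = TRUE)
    tv <- tsspos$tss
    p <- probes$pos[pi]
    right <- findInterval(p, tv) + 1L       # first TSS >= p (or beyond end)
    left <- right - 1L
    # findInterval gives rightmost tv <= p as `left`
    left_ok <- left >= 1L
    right_ok <- right <= length(tv)
    dl <- ifelse(left_ok, p - tv[pmax(left, 1L)], Inf)
    dr <- ifelse(right_ok, tv[pmin(right, length(tv))] - p, Inf)
    d <- pmin(dl, dr)
    gene_left <- ifelse(left_ok, tsspos$gene_id[pmax(left, 1L)], NA)
    gene_right <- ifelse(right_ok, tsspos$gene_id[pmin(right, length(tv))], NA)
    pick <- ifelse(
      dl < dr, gene_left,
      ifelse(dr < dl, gene_right,
             pmin(gene_left, gene_right))   # equidistant: lexicographic
    )
    hit <- d < max_dist
    out$gene_id[pi[hit]] <- pick[hit]
    out$tss_distance[pi[hit]] <- d[hit]
  }
  out
}

region_levels <- c("TSS200", "TSS1500", "5'UTR", "1stExon", "Body",
                   "3'UTR", "IGR")

#' Classify a probe position into a gene-region category
#'
#' Strand-aware classification with precedence
#' `TSS200 > TSS1500 > 5'UTR > 1stExon > 3'UTR > Body` among overlapping
#' definitions (the 450K annotation convention). On the plus strand:
#' TSS200 is the 200 bp immediately upstream of the TSS, TSS1500 the
#' 201-1500 bp band, the 5'UTR spans `[tx_start, cds_start)`, the first exon
#' `[tss, first_exon_end)`, the 3'UTR `[cds_end, tx_end)`, and the remaining
#' transcribed span is Body; positions outside all features are IGR.
#' Minus-strand genes are mirrored (`first_exon_end` is then the genomic
#' start of the first exon, which spans `[first_exon_end, tss]`).
#'
#' @param pos Probe position(s), 0-based.
#' @param gene A single-row gene model (tibble or list) with `strand`,
#'   `tss`, `tx_start`, `tx_end`, `cds_start`, `cds_end`, `first_exon_end`.
#' @return Character vector of region categories.
#' @export
classify_region <- function(pos, gene) {
  if (gene$cds_start < gene$tx_start || gene$cds_end > gene$tx_end ||
      gene$cds_start >= gene$cds_end) {
    abort(sprintf("Malformed gene model for %s: CDS outside transcript.",
                  gene$gene_id %||% "<unnamed>"))
  }
  plus <- gene$strand == "+"
  updist <- if (plus) gene$tss - pos else pos - gene$tss
  in_tx <- pos >= gene$tx_start & pos < gene$tx_end
  in_utr5 <- if (plus) {
    pos >= gene$tx_start & pos < gene$cds_start
  } else {
    pos >= gene$cds_end & pos < gene$tx_end
  }
  in_exon1 <- if (plus) {
    pos >= gene$tss & pos < gene$first_exon_end
  } else {
    pos >= gene$first_exon_end & pos <= gene$tss
  }
  in_utr3 <- if (plus) {
    pos >= gene$cds_end & pos < gene$tx_end
  } else {
    pos >= gene$tx_start & pos < gene$cds_start
  }
  case_when(
    updist >= 1 & updist <= 200 ~ "TSS200",
    updist >= 201 & updist <= 1500 ~ "TSS1500",
    in_utr5 ~ "5'UTR",
    in_exon1 ~ "1stExon",
    in_utr3 ~ "3'UTR",
    in_tx ~ "Body",
    .default = "IGR"
  )
}

#' Classify probe positions by CpG-island context
#'
#' A probe inside an island interval is `island`; within 2 kb of the nearest
#' island boundary, `shore`; within 4 kb, `shelf`; otherwise `open_sea`
#' (the platform's standard distance bands).
#'
#' @param pos Probe position(s), 0-based, on a single chromosome.
#' @param islands Tibble of island intervals (`start`, `end`, 0-based
#'   half-open) on that chromosome; may be empty.
#' @return Character vector of contexts.
#' @export
classify_cpg_context <- function(pos, islands) {
  if (nrow(islands) == 0) return(rep("open_sea", length(pos)))
  starts <- sort(islands$start)
  ends <- islands$end[order(islands$start)]
  vapply(pos, function(p) {
    inside <- any(p >= starts & p < ends)
    if (inside) return("island")
    d <- min(pmax(starts - p, p - ends + 1))
    if (d <= 2000) "shore" else if (d <= 4000) "shelf" else "open_sea"
  }, character(1))
}

#' Annotate all methylation probes
#'
#' Runs nearest-TSS gene mapping, gene-region classification and CpG-island
#' context for every probe, producing the per-probe context table used by
#' the integration stage. A probe mapped to a gene by TSS distance can
#' still be classified IGR when it lies outside all of that gene's defined
#' features.
#'
#' @param probes Probe annotation (`probe_id`, `chrom`, `pos`).
#' @param genes Gene models (see [classify_region()] for fields).
#' @param islands CpG island intervals (`chrom`, `start`, `end`).
#' @param max_dist Maximum TSS mapping distance (default 10000).
#' @return Tibble `probe_id`, `chrom`, `pos`, `gene_id`, `tss_distance`,
#'   `region`, `cpg_context`.
#' @export
annotate_probes <- function(probes, genes, islands, max_dist = 10000) {
  mapped <- map_probes_to_genes(probes, genes, max_dist = max_dist)
  out <- probes |>
    select("probe_id", "chrom", "pos") |>
    left_join(mapped, by = "probe_id")
  region <- rep("IGR", nrow(out))
  hit <- which(!is.na(out$gene_id))
  if (length(hit) > 0) {
    genes_df <- as.data.frame(genes)
    by_gene <- split(hit, out$gene_id[hit])
    gidx <- match(names(by_gene), genes_df$gene_id)
    for (i in seq_along(by_gene)) {
      rows <- by_gene[[i]]
      region[rows] <- classify_region(out$pos[rows], genes_df[gidx[i], ])
    }
  }
  out$region <- region
  out$cpg_context <- rep("open_sea", nrow(out))
  for (ch in unique(out$chrom)) {
    sel <- out$chrom == ch
    out$cpg_context[sel] <- classify_cpg_context(
      out$pos[sel], islands[islands$chrom == ch, , drop = FALSE]
    )
  }
  out
}

#' Genomic distribution of called DMPs
#'
#' Tabulates counts and integer-rounded percentages of DMPs per CpG-island
#' context and per gene-region category.
#'
#' @param contexts Per-probe context table from [annotate_probes()].
#' @param dmps A `dmp_stats` tibble with `is_dmp` (only called DMPs are
#'   summarised), or NULL to summarise every probe in `contexts`.
#' @return Tibble `dimension` (`"cpg_context"` or `"region"`), `category`,
#'   `n`, `percent`. Empty when no DMPs are called.
#' @export
summarize_genomic_distribution <- function(contexts, dmps = NULL) {
  if (!is.null(dmps)) {
    keep <- dmps$probe_id[dmps$is_dmp]
    contexts <- filter(contexts, .data$probe_id %in% keep)
  }
  if (nrow(contexts) == 0) {
    return(tibble(dimension = character(), category = character(),
                  n = integer(), percent = numeric()))
  }
  one <- function(col) {
    contexts |>
      count(category = .data[[col]], name = "n") |>
      mutate(dimension = col, percent = round(100 * .data$n / sum(.data$n)))
  }
  bind_rows(one("cpg_context"), one("region")) |>
    relocate("dimension") |>
    arrange(.data$dimension, desc(.data$n))
}
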