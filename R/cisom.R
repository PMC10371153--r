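#' Detect cis-overlapping motifs (CisOMs)
#'
#' A CisOM is the smallest genomic interval covering a P53 full site and a
#' cMYC site that overlap each other by at least 1 bp. The overlap predicate
#' uses the P53 full-site span including the spacer, and one CisOM is
#' reported per overlapping site pair — duplicate intervals arising from
#' distinct pairs are retained, since they carry distinct site identities.
#'
#' @param p53_full_sites Tibble of full sites from [pair_p53_half_sites()] /
#'   [call_sites()] on a [p53_model()].
#' @param cmyc_sites Tibble of simple sites from [scan_sites()].
#' @param regions Optional co-occupied regions from [intersect_peaks()];
#'   when given, each CisOM must overlap a region interval by at least
#'   `min_region_overlap` bp and is labelled with its `region_id`.
#' @param min_region_overlap Minimum bp of the CisOM inside the co-occupied
#'   overlap segment (default 1).
#' @return Tibble of CisOMs sorted by `start`: `cisom_id`, `chrom`, `start`,
#'   `end` (minimal cover), the P53 site columns (`p53_*`, spacer and half
#'   coordinates), the cMYC site columns (`cmyc_*`), and `region_id`.
#' @export
detect_cisoms <- function(p53_full_sites, cmyc_sites, regions = NULL,
                          min_region_overlap = 1L) {
  empty <- tibble(
    cisom_id = character(), chrom = character(), start = integer(),
    end = integer(),
    p53_start = integer(), p53_end = integer(), p53_lr = double(),
    p53_spacer = integer(),
    half_a_start = integer(), half_a_end = integer(), half_a_strand = character(),
    half_b_start = integer(), half_b_end = integer(), half_b_strand = character(),
    cmyc_start = integer(), cmyc_end = integer(), cmyc_strand = character(),
    cmyc_lr = double(), region_id = character()
  )
  if (nrow(p53_full_sites) == 0 || nrow(cmyc_sites) == 0) return(empty)
  p <- p53_full_sites |>
    select(chrom, p53_start = start, p53_end = end, p53_lr = lr,
           p53_spacer = spacer, half_a_start, half_a_end, half_a_strand,
           half_b_start, half_b_end, half_b_strand)
  m <- cmyc_sites |>
    select(chrom, cmyc_start = start, cmyc_end = end, cmyc_strand = strand,
           cmyc_lr = lr)
  out <- inner_join(p, m, by = "chrom", relationship = "many-to-many") |>
    filter(pmin(.data$p53_end, .data$cmyc_end) -
             pmax(.data$p53_start, .data$cmyc_start) >= 1L) |>
    mutate(start = pmin(.data$p53_start, .data$cmyc_start),
           end = pmax(.data$p53_end, .data$cmyc_end))
  if (!nrow(out)) return(empty)
  if (!is.null(regions) && nrow(regions) > 0) {
    r <- regions |> select(region_id, chrom, r_start = start, r_end = end)
    out <- inner_join(out, r, by = "chrom", relationship = "many-to-many") |>
      filter(pmin(.data$end, .data$r_end) - pmax(.data$start, .data$r_start) >=
               min_region_overlap) |>
      select(-r_start, -r_end)
  } else {
    out$region_id <- NA_character_
  }
  out |>
    arrange(.data$chrom, .data$start, .data$end, .data$cmyc_start) |>
    mutate(cisom_id = sprintf("cisom_%05d", row_number())) |>
    select(all_of(names(empty)))
}

#' Count CisOMs per co-occupied region
#'
#' @param cisoms Tibble from [detect_cisoms()] (with `region_id`).
#' @param regions Tibble from [intersect_peaks()]; regions without CisOMs
#'   are reported with zero.
#' @return Tibble `region_id`, `n_cisoms`, one row per region plus a final
#'   `total` row.
#' @export
count_cisoms_per_region <- function(cisoms, regions) {
  counts <- regions |>
    select(region_id) |>
    left_join(count(cisoms, .data$region_id, name = "n_cisoms"),
              by = "region_id") |>
    mutate(n_cisoms = if_else(is.na(.data$n_cisoms), 0L, .data$n_cisoms))
  bind_rows(counts,
            tibble(region_id = "total", n_cisoms = sum(counts$n_cisoms)))
}

#' Map variants onto CisOMs with an expression context window
#'
#' Each variant is annotated with every CisOM containing it (start
#' inclusive, end exclusive) and with its context window of
#' `pos - context_radius` to `pos + context_radius` inclusive (the window
#' used to relate a SNP to the surrounding co-occupied element). Variants
#' inside no CisOM keep an `NA` annotation.
#'
#' @param variants Variant tibble (`chrom`, `pos` 0-based, `ref`, `alt`,
#'   `id`).
#' @param cisoms Tibble from [detect_cisoms()].
#' @param context_radius Context half-width in bp around the SNP
#'   (default 500).
#' @return Tibble of annotations: variant columns, `cisom_id` (NA when
#'   outside all CisOMs), `region_id`, `context_start`, `context_end`.
#' @export
map_variants_to_cisoms <- function(variants, cisoms, context_radius = 500L) {
  ctx <- variants |>
    mutate(context_start = pmax(0L, .data$pos - as.integer(context_radius)),
           context_end = .data$pos + as.integer(context_radius) + 1L)
  if (nrow(cisoms) == 0 || nrow(variants) == 0) {
    return(ctx |> mutate(cisom_id = NA_character_, region_id = NA_character_))
  }
  hit <- inner_join(
    ctx,
    cisoms |> select(chrom, cisom_start = start, cisom_end = end,
                     cisom_id, region_id),
    by = "chrom", relationship = "many-to-many"
  ) |>
    filter(.data$pos >= .data$cisom_start, .data$pos < .data$cisom_end) |>
    select(-cisom_start, -cisom_end)
  miss <- ctx |>
    filter(!.data$id %in% hit$id) |>
    mutate(cisom_id = NA_character_, region_id = NA_character_)
  bind_rows(hit, miss) |> arrange(.data$chrom, .data$pos, .data$cisom_id)
}

#' Assign the nearest TSS as a putative target gene
#'
#' A deliberately simple nearest-transcription-start-site assignment (by
#' distance from the variant or interval midpoint to the TSS position),
#' reported as `putative_gene`. More elaborate regulatory-domain models are
#' out of scope.
#'
#' @param x Tibble with `chrom` and either `pos` or `start`/`end`.
#' @param tss Tibble with `chrom`, `start` (TSS position, 0-based) and
#'   `name` (gene).
#' @return `x` with `putative_gene` and `tss_distance` columns.
#' @export
annotate_nearest_tss <- function(x, tss) {
  mid <- if ("pos" %in% names(x)) x$pos else (x$start + x$end) %/% 2L
  gene <- rep(NA_character_, nrow(x))
  dist <- rep(NA_integer_, nrow(x))
  for (ch in unique(x$chrom)) {
    ti <- which(tss$chrom == ch)
    xi <- which(x$chrom == ch)
    if (!length(ti) || !length(xi)) next
    d <- abs(outer(mid[xi], tss$start[ti], "-"))
    j <- apply(d, 1, which.min)
    gene[xi] <- tss$name[ti][j]
    dist[xi] <- d[cbind(seq_along(xi), j)]
  }
  x |> mutate(putative_gene = gene, tss_distance = dist)
}
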