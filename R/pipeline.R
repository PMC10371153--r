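#' Run the full CisOM pipeline
#'
#' Reads a genome and two ChIP peak sets, computes co-occupied regions,
#' calls P53 full sites and cMYC sites in each region, detects CisOMs,
#' saturates every CisOM with all single-nucleotide variants and scores
#' their delta-binding for both TFs, optionally annotates observed SNPs
#' and correlates their delta-binding with delta-expression, and writes
#' every result as TSV (plus BED companions) with a JSON run manifest.
#'
#' Inputs may be file paths or already-loaded objects (named genome vector,
#' interval tibbles, variant tibble, expression tibble). Region sequences
#' are extracted with enough flanking genome that delta-binding windows are
#' not truncated at region edges.
#'
#' @param out_dir Output directory (created if needed); pass `NULL` to skip
#'   writing and just return the results.
#' @param fasta Genome FASTA path or [read_genome()] vector.
#' @param peaks_p53,peaks_cmyc BED paths or interval tibbles.
#' @param variants Optional VCF/TSV path or variant tibble of observed SNPs.
#' @param expression Optional TSV path or expression tibble
#'   (`variant_id`, `expr_common`, `expr_alt`).
#' @param tss Optional TSS BED path or tibble for putative-gene assignment.
#' @param p53_half_pwm,cmyc_pwm Motif file paths or [pwm()] objects
#'   (defaults: bundled toys).
#' @param threshold Site-calling threshold in bits (default: half of each
#'   motif's maximum score, see [default_threshold()]).
#' @param min_spacer,max_spacer P53 spacer bounds (defaults 2, 15).
#' @param window_bp Delta-binding window (default 100).
#' @param context_radius SNP context half-width (default 500).
#' @param min_overlap,merge Passed to [intersect_peaks()].
#' @param include_zero_delta Passed to [correlate_deltas()].
#' @param bg Background model.
#' @return (Invisibly) a list with `regions`, `sites`, `cisoms`,
#'   `cisom_counts`, `saturation`, `snp_annotations`, `snp_deltas`,
#'   `correlations` (tibble of [glance()] rows), `burden` and `manifest`.
#' @export
run_cisom_pipeline <- function(out_dir,
                               fasta, peaks_p53, peaks_cmyc,
                               variants = NULL, expression = NULL, tss = NULL,
                               p53_half_pwm = toy_pwm("p53_half"),
                               cmyc_pwm = toy_pwm("cmyc"),
                               threshold = NULL,
                               min_spacer = 2L, max_spacer = 15L,
                               window_bp = 100L, context_radius = 500L,
                               min_overlap = 1L, merge = FALSE,
                               include_zero_delta = TRUE,
                               bg = background_model()) {
  input_paths <- c(
    fasta = if (is.character(fasta) && length(fasta) == 1) fasta,
    peaks_p53 = if (is.character(peaks_p53)) peaks_p53,
    peaks_cmyc = if (is.character(peaks_cmyc)) peaks_cmyc,
    variants = if (is.character(variants)) variants,
    expression = if (is.character(expression)) expression,
    tss = if (is.character(tss)) tss)
  genome <- if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    read_genome(fasta) else fasta
  if (is.character(fasta) && length(fasta) == 1 && !file.exists(fasta)) {
    abort(sprintf("FASTA file not found: %s", fasta),
          class = "cisomr_missing_file")
  }
  pk_a <- if (is.character(peaks_p53)) read_bed(peaks_p53) else peaks_p53
  pk_b <- if (is.character(peaks_cmyc)) read_bed(peaks_cmyc) else peaks_cmyc
  if (is.character(p53_half_pwm)) p53_half_pwm <- read_pwm(p53_half_pwm)
  if (is.character(cmyc_pwm)) cmyc_pwm <- read_pwm(cmyc_pwm)
  p53 <- p53_model(p53_half_pwm, min_spacer, max_spacer)
  obs <- if (is.character(variants)) {
    if (grepl("\\.vcf$", variants)) read_vcf_min(variants)
    else read_variants_tsv(variants)
  } else variants
  expr <- if (is.character(expression)) {
    e <- read_tsv(expression, comment = "#", show_col_types = FALSE)
    if ("genotype_class" %in% names(e)) read_expression_tsv(expression) else e
  } else expression
  tss_tbl <- if (is.character(tss)) read_bed(tss) else tss

  regions <- intersect_peaks(pk_a, pk_b, min_overlap = min_overlap,
                             merge = merge)

  pad <- as.integer(window_bp) + model_span(p53)
  sites <- list(); cisoms <- list(); saturation <- list()
  for (k in seq_len(nrow(regions))) {
    r <- regions[k, ]
    L <- nchar(genome[[r$chrom]])
    rseq <- extract_sequence(genome, tibble(
      chrom = r$chrom, start = max(0L, r$start - pad), end = min(L, r$end + pad)))
    p53_sites <- call_sites(p53, rseq, threshold = threshold, bg = bg)
    cmyc_sites <- call_sites(cmyc_pwm, rseq, threshold = threshold, bg = bg)
    sites[[k]] <- bind_rows(
      p53_sites |> select(chrom, start, end, strand, tf, lr, kind),
      cmyc_sites) |> mutate(region_id = r$region_id)
    cm <- detect_cisoms(p53_sites, cmyc_sites, regions = r)
    if (nrow(cm)) {
      cisoms[[k]] <- cm
      sat <- bind_rows(lapply(seq_len(nrow(cm)), function(j) {
        vs <- saturate_cisom(cm[j, ], rseq)
        bind_rows(
          delta_binding(vs, rseq, p53, bg = bg, threshold = threshold,
                        window_bp = window_bp),
          delta_binding(vs, rseq, cmyc_pwm, bg = bg, threshold = threshold,
                        window_bp = window_bp))
      }))
      saturation[[k]] <- sat |> mutate(region_id = r$region_id)
    }
  }
  sites <- bind_rows(sites)
  cisoms <- bind_rows(cisoms)
  if (nrow(cisoms)) {
    # re-id across regions so ids are unique genome-wide
    cisoms <- cisoms |>
      arrange(.data$chrom, .data$start, .data$end, .data$cmyc_start) |>
      mutate(new_id = sprintf("cisom_%05d", row_number()))
    if (length(saturation)) {
      remap <- cisoms |> select(region_id, old = cisom_id, new = new_id)
      saturation <- bind_rows(saturation) |>
        left_join(remap, by = c("region_id", cisom_id = "old")) |>
        mutate(cisom_id = .data$new) |> select(-new)
    } else saturation <- bind_rows(saturation)
    cisoms <- cisoms |> mutate(cisom_id = .data$new_id) |> select(-new_id)
  } else {
    saturation <- bind_rows(saturation)
  }
  counts <- count_cisoms_per_region(cisoms, regions)

  if (!is.null(tss_tbl) && nrow(cisoms)) {
    cisoms <- annotate_nearest_tss(cisoms, tss_tbl)
    if (nrow(saturation)) {
      saturation <- saturation |>
        left_join(cisoms |> select(cisom_id, putative_gene), by = "cisom_id")
    }
  }

  snp_ann <- NULL; snp_deltas <- NULL; correlations <- NULL
  if (!is.null(obs) && nrow(obs)) {
    snp_ann <- map_variants_to_cisoms(obs, cisoms,
                                      context_radius = context_radius)
    in_cisom <- snp_ann |> filter(!is.na(.data$cisom_id)) |>
      distinct(.data$chrom, .data$pos, .data$ref, .data$alt, .data$id)
    if (nrow(in_cisom)) {
      gseq <- purrr::map(setNames(unique(in_cisom$chrom), unique(in_cisom$chrom)),
                         ~dna_seq(genome[[.x]], chrom = .x, offset = 0L))
      snp_deltas <- bind_rows(lapply(unique(in_cisom$chrom), function(ch) {
        v <- filter(in_cisom, .data$chrom == ch)
        bind_rows(
          delta_binding(v, gseq[[ch]], p53, bg = bg, threshold = threshold,
                        window_bp = window_bp),
          delta_binding(v, gseq[[ch]], cmyc_pwm, bg = bg,
                        threshold = threshold, window_bp = window_bp))
      }))
      if (!is.null(expr)) {
        correlations <- bind_rows(lapply(unique(snp_deltas$tf), function(tf) {
          res <- tryCatch(
            correlate_deltas(snp_deltas, expr, tf = tf,
                             include_zero_delta = include_zero_delta),
            cisomr_insufficient_data = function(e) NULL)
          if (is.null(res)) NULL else glance(res)
        }))
      }
    }
  }

  burden_input <- if (!is.null(snp_ann)) {
    snp_ann |> filter(!is.na(.data$cisom_id))
  } else saturation
  if (!is.null(burden_input) && nrow(burden_input) &&
      !is.null(tss_tbl) && !"putative_gene" %in% names(burden_input)) {
    burden_input <- annotate_nearest_tss(burden_input, tss_tbl)
  }
  burden <- if (!is.null(burden_input)) burden_summary(burden_input)
            else burden_summary(tibble(chrom = character()))

  params <- list(threshold = threshold %||% "0.5*max_score",
                 min_spacer = min_spacer, max_spacer = max_spacer,
                 window_bp = window_bp, context_radius = context_radius,
                 min_overlap = min_overlap, merge = merge,
                 include_zero_delta = include_zero_delta)
  results <- list(regions = regions, sites = sites, cisoms = cisoms,
                  cisom_counts = counts, saturation = saturation,
                  snp_annotations = snp_ann, snp_deltas = snp_deltas,
                  correlations = correlations, burden = burden)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    results$manifest <- write_pipeline_outputs(results, out_dir, params,
                                               input_paths)
  }
  invisible(results)
}

write_pipeline_outputs <- function(results, out_dir, params, input_paths) {
  input_paths <- input_paths %||% character(0)
  tsv <- function(x, name) {
    if (is.null(x)) return(NULL)
    path <- file.path(out_dir, name)
    writeLines(output_header(params), path)
    write_tsv(x, path, append = TRUE, col_names = TRUE)
    path
  }
  written <- c(
    tsv(results$regions, "regions.tsv"),
    tsv(results$sites, "sites.tsv"),
    tsv(results$cisoms, "cisoms.tsv"),
    tsv(results$cisom_counts, "cisom_counts.tsv"),
    tsv(results$saturation, "saturation.tsv"),
    tsv(results$snp_annotations, "snp_annotations.tsv"),
    tsv(results$snp_deltas, "snp_deltas.tsv"),
    tsv(results$correlations, "correlations.tsv"),
    tsv(results$burden, "burden.tsv"))
  if (!is.null(results$regions) && nrow(results$regions)) {
    written <- c(written, write_bed(
      results$regions |> rename(name = region_id),
      file.path(out_dir, "regions.bed"), params = params))
  }
  if (!is.null(results$cisoms) && nrow(results$cisoms)) {
    written <- c(written, write_bed(
      results$cisoms |> select(chrom, start, end, name = cisom_id),
      file.path(out_dir, "cisoms.bed"), params = params))
  }
  manifest <- list(
    tool = "cisomr", version = as.character(packageVersion("cisomr")),
    parameters = params,
    inputs = as.list(input_paths[!is.na(input_paths) & nzchar(input_paths)]),
    input_md5 = as.list(md5sum(input_paths[file.exists(input_paths)])),
    outputs = as.list(setNames(md5sum(written), basename(written))),
    counts = list(
      regions = nrow(results$regions),
      sites = nrow(results$sites %||% tibble()),
      cisoms = nrow(results$cisoms %||% tibble()),
      saturation_variants = nrow(results$saturation %||% tibble()) ,
      observed_snps = nrow(results$snp_annotations %||% tibble())),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
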