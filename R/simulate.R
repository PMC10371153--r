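#' Configuration for the synthetic CisOM genome generator
#'
#' Collects every knob of the simulation in one validated object so a seed
#' plus a config fully determines the generated data. Defaults emulate the
#' statistical structure the downstream analysis assumes: a random
#' background at realistic human GC content, co-occupied loci carrying a
#' consensus P53 half-site pair whose spacer hosts a consensus cMYC E-box
#' (so both motifs overlap within the P53 full-site span and form a planted
#' CisOM), ChIP-like peaks with jittered boundaries around each locus, SNPs
#' inside and outside CisOMs, and expression linearly linked to
#' delta-binding plus Gaussian noise.
#'
#' @param seed Integer RNG seed; identical configs give byte-identical data.
#' @param genome_length Genome size in bp (default 50000).
#' @param gc_content Background G+C fraction in (0, 1) (default 0.41, about
#'   the human genome average).
#' @param n_cooccupied Number of planted co-occupied loci (default 20).
#' @param p53_half_pwm,cmyc_pwm Motif models planted and later recovered
#'   (defaults: the bundled toy matrices).
#' @param planted_spacers Spacer lengths to draw from; each must be at
#'   least the cMYC width so the E-box fits inside the spacer (default
#'   `8:15`).
#' @param expression_slope Linear link between delta-binding and
#'   delta-expression (default 1).
#' @param noise_sd Gaussian noise on delta-expression (default 0.5).
#' @param n_snps Number of simulated SNPs (default 30).
#' @param frac_snps_outside Fraction of SNPs placed outside all CisOMs
#'   (default 0.2).
#' @param peak_pad Range (bp) of random padding added on each side of a
#'   planted locus when drawing peaks, giving peak widths of roughly
#'   200-600 bp (default `c(85, 280)`).
#' @param baseline_expression Common-allele expression baseline
#'   (default 10).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 50000L, gc_content = 0.41,
                       n_cooccupied = 20L,
                       p53_half_pwm = toy_pwm("p53_half"),
                       cmyc_pwm = toy_pwm("cmyc"),
                       planted_spacers = 8:15,
                       expression_slope = 1, noise_sd = 0.5,
                       n_snps = 30L, frac_snps_outside = 0.2,
                       peak_pad = c(85L, 280L),
                       baseline_expression = 10) {
  stopifnot(gc_content > 0, gc_content < 1, noise_sd >= 0,
            n_cooccupied >= 0, n_snps >= 0,
            inherits(p53_half_pwm, "pwm"), inherits(cmyc_pwm, "pwm"))
  if (any(planted_spacers < cmyc_pwm$width)) {
    abort("Every planted spacer must be at least the cMYC motif width, so the E-box fits inside the spacer.")
  }
  cluster <- 2L * p53_half_pwm$width + max(planted_spacers)
  need <- cluster + 2L * max(peak_pad) + 40L
  if (n_cooccupied > 0 && genome_length %/% n_cooccupied < need) {
    abort(sprintf(
      "Infeasible packing: %d loci need at least %d bp each but only %d are available.",
      n_cooccupied, need, genome_length %/% n_cooccupied),
      class = "cisomr_config_error")
  }
  structure(
    list(seed = as.integer(seed), genome_length = as.integer(genome_length),
         gc_content = gc_content, n_cooccupied = as.integer(n_cooccupied),
         p53_half_pwm = p53_half_pwm, cmyc_pwm = cmyc_pwm,
         planted_spacers = as.integer(planted_spacers),
         expression_slope = expression_slope, noise_sd = noise_sd,
         n_snps = as.integer(n_snps), frac_snps_outside = frac_snps_outside,
         peak_pad = as.integer(peak_pad),
         baseline_expression = baseline_expression),
    class = "sim_config"
  )
}

#' Simulate a genome with planted CisOMs, peaks, SNPs and truth
#'
#' Draws an i.i.d. background at the configured GC content, embeds at each
#' co-occupied locus a consensus P53 half-site pair with a spacer drawn
#' from `planted_spacers` and a consensus cMYC E-box inside that spacer,
#' draws jittered 200-600 bp ChIP peaks around each locus for both factors,
#' places SNPs inside (and a fraction outside) the planted CisOMs, and
#' computes each SNP's true delta-binding for both TFs with
#' [delta_binding()] at the default threshold.
#'
#' @param config A [sim_config()].
#' @return A `cisom_sim` list: `genome` (named character, one chromosome
#'   `chrSim`), `peaks_p53`, `peaks_cmyc`, `tss` (one gene per locus),
#'   `snps` (with `in_cisom`, `locus`, `gene`, `delta_p53`, `delta_cmyc`),
#'   `truth` (per-locus planted coordinates), and the `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  hw <- config$p53_half_pwm$width
  mw <- config$cmyc_pwm$width
  half_cons <- pwm_consensus(config$p53_half_pwm)
  cmyc_cons <- pwm_consensus(config$cmyc_pwm)
  chrom <- "chrSim"

  with_seed(config$seed, {
    base_p <- gc_background(config$gc_content)
    genome_chars <- sample(DNA_BASES, config$genome_length, replace = TRUE,
                           prob = base_p)
    n <- config$n_cooccupied
    truth <- tibble(locus = integer(), gene = character(),
                    half_a_start = integer(), half_a_end = integer(),
                    spacer = integer(),
                    half_b_start = integer(), half_b_end = integer(),
                    cmyc_start = integer(), cmyc_end = integer(),
                    cisom_start = integer(), cisom_end = integer(),
                    tss = integer())
    peaks_p53 <- peaks_cmyc <- tibble(chrom = character(), start = integer(),
                                      end = integer(), name = character())
    if (n > 0) {
      block <- config$genome_length %/% n
      for (i in seq_len(n)) {
        spacer <- draw1(config$planted_spacers)
        cluster <- 2L * hw + spacer
        lo <- (i - 1L) * block
        jit_max <- max(0L, (block - cluster - 2L * max(config$peak_pad) - 20L) %/% 2L)
        centre <- lo + block %/% 2L + draw1(seq.int(-jit_max, jit_max))
        a_start <- centre - cluster %/% 2L
        a_end <- a_start + hw
        b_start <- a_end + spacer
        b_end <- b_start + hw
        m_start <- a_end + draw1(seq.int(0L, spacer - mw))
        m_end <- m_start + mw
        genome_chars[(a_start + 1):a_end] <- strsplit(half_cons, "")[[1]]
        genome_chars[(b_start + 1):b_end] <- strsplit(half_cons, "")[[1]]
        genome_chars[(m_start + 1):m_end] <- strsplit(cmyc_cons, "")[[1]]
        pads <- sample(seq.int(config$peak_pad[1], config$peak_pad[2]), 4,
                       replace = TRUE)
        peaks_p53 <- bind_rows(peaks_p53, tibble(
          chrom = chrom, start = max(0L, a_start - pads[1]),
          end = min(config$genome_length, b_end + pads[2]),
          name = sprintf("p53_pk_%02d", i)))
        peaks_cmyc <- bind_rows(peaks_cmyc, tibble(
          chrom = chrom, start = max(0L, a_start - pads[3]),
          end = min(config$genome_length, b_end + pads[4]),
          name = sprintf("cmyc_pk_%02d", i)))
        truth <- bind_rows(truth, tibble(
          locus = i, gene = sprintf("gene_%02d", i),
          half_a_start = a_start, half_a_end = a_end, spacer = spacer,
          half_b_start = b_start, half_b_end = b_end,
          cmyc_start = m_start, cmyc_end = m_end,
          cisom_start = a_start, cisom_end = b_end,
          tss = min(config$genome_length - 1L, b_end + 150L)))
      }
    }
    genome <- setNames(paste(genome_chars, collapse = ""), chrom)

    snps <- simulate_snps(config, genome, truth, chrom)

    structure(
      list(genome = genome, peaks_p53 = peaks_p53, peaks_cmyc = peaks_cmyc,
           tss = if (nrow(truth)) tibble(chrom = chrom, start = truth$tss,
                                         end = truth$tss + 1L,
                                         name = truth$gene)
                 else tibble(chrom = character(), start = integer(),
                             end = integer(), name = character()),
           snps = snps, truth = truth, config = config),
      class = "cisom_sim")
  })
}

# sample(x, 1) that never falls into sample.int() surprise behaviour when
# x has length 1
draw1 <- function(x) x[sample.int(length(x), 1L)]

simulate_snps <- function(config, genome, truth, chrom) {
  empty <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), id = character(), in_cisom = logical(),
                  locus = integer(), gene = character(),
                  delta_p53 = double(), delta_cmyc = double())
  if (config$n_snps == 0) return(empty)
  n_out <- round(config$n_snps * config$frac_snps_outside)
  n_in <- config$n_snps - n_out
  inside_pool <- if (nrow(truth)) {
    unlist(purrr::map2(truth$cisom_start, truth$cisom_end,
                       function(s, e) s:(e - 1L)))
  } else integer(0)
  if (n_in > length(inside_pool)) {
    abort("Not enough CisOM positions for the requested number of inside SNPs.",
          class = "cisomr_config_error")
  }
  pos_in <- if (n_in > 0) sort(sample(inside_pool, n_in)) else integer(0)
  outside_pool <- setdiff(seq(0L, config$genome_length - 1L), inside_pool)
  pos_out <- if (n_out > 0) sort(sample(outside_pool, n_out)) else integer(0)
  pos <- c(pos_in, pos_out)
  refs <- substring(genome[[chrom]], pos + 1L, pos + 1L)
  alts <- vapply(refs, function(b) sample(setdiff(DNA_BASES, b), 1), "")
  locus <- vapply(pos, function(p) {
    hit <- which(truth$cisom_start <= p & p < truth$cisom_end)
    if (length(hit)) hit[1] else NA_integer_
  }, 1L)
  snps <- tibble(
    chrom = chrom, pos = pos, ref = refs, alt = alts,
    id = sprintf("snp_%03d", seq_along(pos)),
    in_cisom = c(rep(TRUE, n_in), rep(FALSE, n_out)),
    locus = locus,
    gene = if_else(is.na(locus), NA_character_, truth$gene[locus])
  )
  seq <- dna_seq(genome[[chrom]], chrom = chrom, offset = 0L)
  d53 <- delta_binding(snps, seq, p53_model(config$p53_half_pwm))
  dmyc <- delta_binding(snps, seq, config$cmyc_pwm)
  snps$delta_p53 <- d53$delta
  snps$delta_cmyc <- dmyc$delta
  snps
}

#' Simulate allelic expression linearly linked to delta-binding
#'
#' `expr_common` is a constant baseline; `expr_alt` adds
#' `slope * delta + N(0, noise_sd)`, so with zero noise delta-expression
#' equals `slope * delta` exactly and with `slope = 0` the link is null.
#'
#' @param delta_records Tibble with `id` and `delta` columns (e.g. from
#'   [delta_binding()], or the simulated SNP table with the chosen TF's
#'   delta renamed to `delta`).
#' @param slope Linear coefficient (default 1).
#' @param noise_sd Gaussian noise standard deviation (default 0.5).
#' @param seed RNG seed.
#' @param baseline Common-allele expression level (default 10).
#' @return Expression tibble: `variant_id`, `gene` (if present in the
#'   input), `expr_common`, `expr_alt`, `source = "synthetic"`.
#' @export
simulate_expression <- function(delta_records, slope = 1, noise_sd = 0.5,
                                seed = 1L, baseline = 10) {
  stopifnot(noise_sd >= 0)
  with_seed(as.integer(seed), {
    tibble(
      variant_id = delta_records$id,
      gene = if ("gene" %in% names(delta_records)) delta_records$gene
             else NA_character_,
      expr_common = baseline,
      expr_alt = baseline + slope * delta_records$delta +
        rnorm(nrow(delta_records), 0, noise_sd),
      source = "synthetic"
    )
  })
}

#' Write a simulation to files accepted by the pipeline and CLI
#'
#' Emits `genome.fa`, `p53_peaks.bed`, `cmyc_peaks.bed`, `tss.bed`,
#' `snps.vcf`, `expression.tsv` (simulated from the P53 delta-binding with
#' the configured slope and noise) and `truth.json`.
#'
#' @param sim A `cisom_sim` from [simulate_genome()].
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cisom_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    p53_peaks = file.path(dir, "p53_peaks.bed"),
    cmyc_peaks = file.path(dir, "cmyc_peaks.bed"),
    tss = file.path(dir, "tss.bed"),
    snps = file.path(dir, "snps.vcf"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json")
  )
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$genome), paths[["genome"]])
  write_bed(sim$peaks_p53, paths[["p53_peaks"]],
            params = list(seed = sim$config$seed))
  write_bed(sim$peaks_cmyc, paths[["cmyc_peaks"]],
            params = list(seed = sim$config$seed))
  write_bed(sim$tss, paths[["tss"]], params = list(seed = sim$config$seed))
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                   sim$snps$chrom, sim$snps$pos + 1L, sim$snps$id,
                   sim$snps$ref, sim$snps$alt))
  writeLines(vcf, paths[["snps"]])
  expr <- simulate_expression(
    sim$snps |> rename(delta = all_of("delta_p53")),
    slope = sim$config$expression_slope, noise_sd = sim$config$noise_sd,
    seed = sim$config$seed, baseline = sim$config$baseline_expression)
  write_tsv(expr, paths[["expression"]])
  write_json(
    list(config = sim$config[setdiff(names(sim$config),
                                     c("p53_half_pwm", "cmyc_pwm"))],
         truth = sim$truth, snps = sim$snps),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
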