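#' In-silico saturation mutagenesis of a CisOM
#'
#' Enumerates every possible single-nucleotide substitution inside the CisOM
#' interval: all three alternative bases at each position, giving exactly
#' `3 * L` variants for an interval of length `L`.
#'
#' @param cisom One-row tibble (or list) with `chrom`, `start`, `end` and
#'   optionally `cisom_id`.
#' @param seq A [dna_seq()] covering the CisOM interval.
#' @return Variant tibble ordered by position then alternative base
#'   (A < C < G < T): `chrom`, `pos` (0-based), `ref`, `alt`, `id`,
#'   `cisom_id`.
#' @export
saturate_cisom <- function(cisom, seq) {
  seq <- as_dna_seq(seq)
  start <- as.integer(cisom$start[[1]])
  end <- as.integer(cisom$end[[1]])
  off <- seq_offset(seq)
  if (start < off || end > off + nchar(seq)) {
    abort("`seq` does not cover the CisOM interval.", class = "cisomr_range_error")
  }
  refs <- strsplit(substr(unclass(seq), start - off + 1L, end - off),
                   "", fixed = TRUE)[[1]]
  if (!all(refs %in% DNA_BASES)) {
    bad <- which(!refs %in% DNA_BASES)[1]
    abort(sprintf("Reference base '%s' at position %d is not A/C/G/T.",
                  refs[bad], start + bad - 1L),
          class = "cisomr_invalid_sequence")
  }
  pos <- rep(start:(end - 1L), each = 3L)
  ref <- rep(refs, each = 3L)
  alt <- unlist(lapply(refs, function(b) setdiff(DNA_BASES, b)), use.names = FALSE)
  tibble(
    chrom = seq_chrom(seq), pos = pos, ref = ref, alt = alt,
    id = variant_id(seq_chrom(seq), pos, ref, alt),
    cisom_id = if ("cisom_id" %in% names(cisom)) cisom$cisom_id[[1]] else NA_character_
  )
}

#' Apply a single-nucleotide variant to a sequence
#'
#' @param seq A [dna_seq()] (or character string).
#' @param variant One-row tibble/list with `chrom`, `pos` (0-based), `ref`,
#'   `alt`.
#' @return A [dna_seq()] of the same length and origin with the base
#'   substituted; errors if the stated reference base does not match the
#'   sequence.
#' @export
apply_variant <- function(seq, variant) {
  seq <- as_dna_seq(seq)
  pos <- as.integer(variant$pos[[1]])
  i <- pos - seq_offset(seq) + 1L
  s <- unclass(seq)
  if (i < 1L || i > nchar(s)) {
    abort(sprintf("Variant position %d lies outside the sequence.", pos),
          class = "cisomr_range_error")
  }
  have <- substr(s, i, i)
  if (have != toupper(variant$ref[[1]])) {
    abort(sprintf(
      "Reference mismatch at %s:%d: variant states '%s' but the sequence has '%s'.",
      seq_chrom(seq), pos, variant$ref[[1]], have),
      class = "cisomr_ref_mismatch")
  }
  substr(s, i, i) <- toupper(variant$alt[[1]])
  dna_seq(s, chrom = seq_chrom(seq), offset = seq_offset(seq))
}

#' Delta-binding score of variants over a fixed window
#'
#' For each variant, all sites of the model are called (same threshold for
#' both alleles) on the reference and on the variant sequence, sites whose
#' span touches the window `[pos - window_bp/2, pos + window_bp/2)` are
#' aggregated, and the change `delta = s_alt - s_ref` is reported. Sites are
#' recalled from scratch on each allele, so a variant can create or destroy
#' sites across the calling threshold — that discontinuity is the intended
#' call-then-sum behaviour.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, `id`, and
#'   any extra columns, which are carried through).
#' @param seq A [dna_seq()] covering the variants (windows truncated at the
#'   sequence ends are flagged in `truncated`).
#' @param model A [pwm()] (simple sites, e.g. cMYC) or [p53_model()] (full
#'   sites via half-site pairing).
#' @param bg Background model.
#' @param threshold Site-calling threshold in bits
#'   (default [default_threshold()]).
#' @param window_bp Window width centred on the variant (default 100).
#' @param site_window_rule `"overlap"` (site span shares >= 1 bp with the
#'   window, default) or `"contained"` (site span inside the window).
#' @param agg `"sum"` (default: summed score of all retained sites) or
#'   `"max"`.
#' @return Tibble of delta records: the variant columns plus `tf`, `s_ref`,
#'   `s_alt`, `delta`, `window_start`, `window_end`, `truncated`.
#' @export
delta_binding <- function(variants, seq, model, bg = background_model(),
                          threshold = NULL, window_bp = 100L,
                          site_window_rule = c("overlap", "contained"),
                          agg = c("sum", "max")) {
  site_window_rule <- match.arg(site_window_rule)
  agg <- match.arg(agg)
  seq <- as_dna_seq(seq)
  threshold <- threshold %||%
    default_threshold(model, bg = bg)
  off <- seq_offset(seq)
  L <- nchar(seq)
  half <- as.integer(window_bp) %/% 2L
  nv <- nrow(variants)
  s_ref <- s_alt <- numeric(nv)
  ws <- we <- integer(nv)
  trunc <- logical(nv)
  for (k in seq_len(nv)) {
    pos <- variants$pos[k]
    w0 <- pos - half
    w1 <- w0 + as.integer(window_bp)
    ws[k] <- max(w0, off)
    we[k] <- min(w1, off + L)
    if (we[k] <= ws[k]) {
      abort(sprintf("Window around position %d lies entirely outside the sequence.",
                    pos), class = "cisomr_range_error")
    }
    trunc[k] <- (ws[k] > w0) | (we[k] < w1)
    s_ref[k] <- binding_score(seq, model, ws[k], we[k], bg, threshold,
                              site_window_rule, agg)
    s_alt[k] <- binding_score(apply_variant(seq, variants[k, ]), model,
                              ws[k], we[k], bg, threshold,
                              site_window_rule, agg)
  }
  variants |>
    mutate(tf = model_tf(model), s_ref = s_ref, s_alt = s_alt,
           delta = s_alt - s_ref, window_start = ws, window_end = we,
           truncated = trunc)
}

# summed (or max) score of called sites whose span satisfies the window rule;
# only the window plus one maximal site span of margin needs scanning
binding_score <- function(seq, model, w_start, w_end, bg, threshold,
                          site_window_rule, agg) {
  off <- seq_offset(seq)
  L <- nchar(seq)
  margin <- model_span(model)
  s0 <- max(off, w_start - margin)
  s1 <- min(off + L, w_end + margin)
  sub <- dna_seq(substr(unclass(seq), s0 - off + 1L, s1 - off),
                 chrom = seq_chrom(seq), offset = s0)
  sites <- call_sites(model, sub, threshold = threshold, bg = bg)
  keep <- if (site_window_rule == "overlap") {
    sites$start < w_end & sites$end > w_start
  } else {
    sites$start >= w_start & sites$end <= w_end
  }
  lr <- sites$lr[keep]
  if (!length(lr)) return(0)
  if (agg == "sum") sum(lr) else max(lr)
}
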