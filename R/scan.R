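#' DNA sequence with a genomic origin
#'
#' Attaches a chromosome name and a 0-based offset to a plain DNA string so
#' that sites found by scanning can be reported in genomic coordinates.
#'
#' @param seq Character scalar over A/C/G/T (soft-masked lowercase is
#'   uppercased).
#' @param chrom Chromosome / sequence label.
#' @param offset 0-based genomic position of the first base of `seq`.
#' @return A `dna_seq` object.
#' @export
dna_seq <- function(seq, chrom = "seq", offset = 0L) {
  stopifnot(is.character(seq), length(seq) == 1)
  structure(toupper(seq), chrom = chrom, offset = as.integer(offset),
            class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  s <- unclass(x)
  shown <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(sprintf("<dna_seq> %s:%d-%d  %s\n", seq_chrom(x), seq_offset(x),
              seq_offset(x) + nchar(s), shown))
  invisible(x)
}

seq_chrom <- function(seq) attr(seq, "chrom") %||% "seq"
seq_offset <- function(seq) as.integer(attr(seq, "offset") %||% 0L)
as_dna_seq <- function(seq) {
  if (inherits(seq, "dna_seq")) seq else dna_seq(seq)
}

EMPTY_SITES <- tibble::new_tibble(list(
  chrom = character(), start = integer(), end = integer(),
  strand = character(), tf = character(), lr = double(),
  kind = character()), nrow = 0L)

empty_sites <- function() EMPTY_SITES

EMPTY_FULL_SITES <- tibble::new_tibble(list(
  chrom = character(), start = integer(), end = integer(),
  strand = character(), tf = character(), lr = double(), kind = character(),
  spacer = integer(),
  half_a_start = integer(), half_a_end = integer(),
  half_a_strand = character(), half_a_lr = double(),
  half_b_start = integer(), half_b_end = integer(),
  half_b_strand = character(), half_b_lr = double()), nrow = 0L)

#' Scan a sequence for PWM matches above a threshold
#'
#' Slides the PWM along the sequence and reports every window whose log2
#' likelihood-ratio score reaches `threshold`. Minus-strand windows are scored
#' on the reverse complement but reported in plus-strand coordinates
#' (0-based half-open, shifted by the sequence origin).
#'
#' @param seq A [dna_seq()] or plain character DNA string.
#' @param pwm A [pwm()] object.
#' @param bg Background model.
#' @param threshold Minimum score in bits to call a site; default
#'   [default_threshold()] of the PWM (half its maximum achievable score).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param kind Site kind recorded in the output (`"simple"` for ordinary
#'   motifs, `"half"` when scanning P53 half-sites).
#' @return Tibble of sites: `chrom`, `start`, `end`, `strand`, `tf`, `lr`,
#'   `kind`, sorted by `start` then `strand`.
#' @examples
#' p <- toy_pwm("cmyc")
#' scan_sites(dna_seq("TTTTCACGTGTCTTTT"), p, threshold = 5)
#' @export
scan_sites <- function(seq, pwm, bg = background_model(), threshold = NULL,
                       strands = c("both", "+", "-"), kind = "simple") {
  strands <- match.arg(strands)
  stopifnot(inherits(pwm, "pwm"))
  threshold <- threshold %||% default_threshold(pwm, bg = bg)
  if (!is.finite(threshold)) abort("`threshold` must be finite.")
  seq <- as_dna_seq(seq)
  s <- unclass(seq)
  L <- nchar(s)
  w <- pwm$width
  if (L < w) return(empty_sites())
  ints <- encode_bases(s)
  lodds <- log_odds(pwm, bg)
  off <- seq_offset(seq)

  starts <- integer(0); strand <- character(0); lr <- numeric(0)
  if (strands %in% c("both", "+")) {
    sc <- slide_scores(ints, lodds)
    hit <- which(sc >= threshold)
    starts <- c(starts, off + hit - 1L)
    strand <- c(strand, rep("+", length(hit)))
    lr <- c(lr, sc[hit])
  }
  if (strands %in% c("both", "-")) {
    sc <- slide_scores(revcomp_ints(ints), lodds)
    hit <- which(sc >= threshold)
    # window k (1-based) on the reverse complement covers plus-strand
    # bases [L - k - w + 1, L - k + 1) in 0-based coordinates
    starts <- c(starts, off + L - hit - w + 1L)
    strand <- c(strand, rep("-", length(hit)))
    lr <- c(lr, sc[hit])
  }
  if (!length(starts)) return(empty_sites())
  o <- order(starts, strand)
  nh <- length(starts)
  tibble::new_tibble(list(
    chrom = rep(seq_chrom(seq), nh), start = starts[o], end = starts[o] + w,
    strand = strand[o], tf = rep(pwm$tf_name, nh), lr = lr[o],
    kind = rep(kind, nh)), nrow = nh)
}

# scores of all windows; O(L * width) with vectorised position lookups
slide_scores <- function(ints, lodds) {
  w <- ncol(lodds)
  n <- length(ints) - w + 1L
  if (n <= 0) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    sc <- sc + lodds[cbind(ints[j:(j + n - 1L)], j)]
  }
  sc
}

#' P53 dimer model: paired half-sites with a bounded spacer
#'
#' P53 binds as a tetramer on two decameric half-sites. A full site is a pair
#' of half-site matches separated by a spacer (gap in bp between the end of
#' the first and the start of the second half-site) inside
#' `[min_spacer, max_spacer]`; its score is the sum of the two half-site
#' log2 scores.
#'
#' @param half_pwm Half-site [pwm()].
#' @param min_spacer,max_spacer Inclusive spacer bounds in bp (defaults 2
#'   and 15).
#' @param require_same_strand If `TRUE`, only tandem (same-strand) half-site
#'   pairs form full sites; by default head-to-head, tail-to-tail and tandem
#'   arrangements are all allowed.
#' @return A `p53_model` object usable with [call_sites()] and
#'   [delta_binding()].
#' @export
p53_model <- function(half_pwm, min_spacer = 2L, max_spacer = 15L,
                      require_same_strand = FALSE) {
  stopifnot(inherits(half_pwm, "pwm"), min_spacer <= max_spacer)
  structure(
    list(half_pwm = half_pwm, tf_name = sub("_half.*$", "", half_pwm$tf_name),
         min_spacer = as.integer(min_spacer),
         max_spacer = as.integer(max_spacer),
         require_same_strand = require_same_strand),
    class = "p53_model"
  )
}

#' @export
print.p53_model <- function(x, ...) {
  cat(sprintf("<p53_model> %s: half-site width %d, spacer [%d, %d]%s\n",
              x$tf_name, x$half_pwm$width, x$min_spacer, x$max_spacer,
              if (x$require_same_strand) ", tandem only" else ""))
  invisible(x)
}

#' Pair P53 half-sites into full sites under the spacer constraint
#'
#' Forms every ordered pair `(a, b)` of half-sites with `a$start < b$start`,
#' no overlap, and spacer `b$start - a$end` inside the configured bounds.
#' The combined score is exactly `a$lr + b$lr`; a half-site may take part in
#' several full sites.
#'
#' @param half_sites Tibble of half-sites from [scan_sites()]; all rows must
#'   share one chromosome.
#' @param min_spacer,max_spacer Inclusive spacer bounds in bp.
#' @param require_same_strand Restrict to tandem pairs.
#' @return Tibble of full sites with the span coordinates in
#'   `start`/`end`, `lr` = combined score, `spacer`, and the four half-site
#'   coordinate/score columns; `kind` is `"full"`.
#' @export
pair_p53_half_sites <- function(half_sites, min_spacer = 2L, max_spacer = 15L,
                                require_same_strand = FALSE) {
  if (nrow(half_sites) > 0 && length(unique(half_sites$chrom)) > 1) {
    abort("All half-sites must lie on one chromosome.")
  }
  empty <- EMPTY_FULL_SITES
  if (nrow(half_sites) < 2) return(empty)
  # all ordered index pairs, base-vectorised: this sits in the inner loop of
  # delta-binding rescans, so no data-frame machinery here
  n <- nrow(half_sites)
  ai <- rep(seq_len(n), each = n)
  bi <- rep(seq_len(n), times = n)
  st <- half_sites$start; en <- half_sites$end
  spacer <- st[bi] - en[ai]
  keep <- st[ai] < st[bi] & spacer >= 0L &  # overlapping half-sites never pair
    spacer >= min_spacer & spacer <= max_spacer
  if (require_same_strand) {
    keep <- keep & half_sites$strand[ai] == half_sites$strand[bi]
  }
  if (!any(keep)) return(empty)
  ai <- ai[keep]; bi <- bi[keep]; spacer <- spacer[keep]
  sa <- half_sites$strand[ai]; sb <- half_sites$strand[bi]
  out <- tibble::new_tibble(list(
    chrom = half_sites$chrom[ai], start = st[ai], end = en[bi],
    strand = ifelse(sa == sb, sa, "+"),
    tf = half_sites$tf[ai],
    lr = half_sites$lr[ai] + half_sites$lr[bi],
    kind = rep("full", length(ai)),
    spacer = as.integer(spacer),
    half_a_start = st[ai], half_a_end = en[ai],
    half_a_strand = sa, half_a_lr = half_sites$lr[ai],
    half_b_start = st[bi], half_b_end = en[bi],
    half_b_strand = sb, half_b_lr = half_sites$lr[bi]), nrow = length(ai))
  out[order(out$start, out$end), ]
}

#' Call binding sites for a motif model on a sequence
#'
#' Generic over plain PWMs (simple sites) and the [p53_model()] (half-site
#' scan followed by spacer-constrained pairing; `threshold` applies to each
#' half-site).
#'
#' @param model A `pwm` or `p53_model`.
#' @param seq A [dna_seq()] or character string.
#' @param threshold Bits; default half the maximum achievable score of the
#'   scanned motif (the half-site motif for the P53 model).
#' @param bg Background model.
#' @param strands Strand selection passed to [scan_sites()].
#' @return Tibble of called sites (full sites for the P53 model).
#' @export
call_sites <- function(model, seq, threshold = NULL, bg = background_model(),
                       strands = "both") {
  UseMethod("call_sites")
}

#' @export
call_sites.pwm <- function(model, seq, threshold = NULL,
                           bg = background_model(), strands = "both") {
  scan_sites(seq, model, bg = bg, threshold = threshold, strands = strands,
             kind = "simple")
}

#' @export
call_sites.p53_model <- function(model, seq, threshold = NULL,
                                 bg = background_model(), strands = "both") {
  halves <- scan_sites(seq, model$half_pwm, bg = bg, threshold = threshold,
                       strands = strands, kind = "half")
  pair_p53_half_sites(halves, model$min_spacer, model$max_spacer,
                      model$require_same_strand)
}

model_tf <- function(model) {
  if (inherits(model, "p53_model")) model$tf_name else model$tf_name
}

# widest genomic footprint a single called site can have under the model
model_span <- function(model) {
  if (inherits(model, "p53_model")) {
    2L * model$half_pwm$width + model$max_spacer
  } else {
    model$width
  }
}
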