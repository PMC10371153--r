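#' Position weight matrix for a transcription-factor motif
#'
#' Builds a PWM object from a matrix of per-position base probabilities or
#' counts over the alphabet A, C, G, T. Counts (or raw probabilities) are
#' augmented with a pseudocount and renormalised so every entry is strictly
#' positive; the pseudocount used is recorded on the object. Binding sites are
#' scored against a PWM as a log2 likelihood ratio (in bits) relative to a
#' background base-composition model, so scores of independent sites are
#' additive.
#'
#' @param mat Numeric matrix, either 4 x width (rows A, C, G, T) or width x 4.
#'   Values may be counts or probabilities; columns (positions) are
#'   renormalised after pseudocount addition.
#' @param tf_name Label for the transcription factor (e.g. `"P53_half"`).
#' @param pseudocount Non-negative value added to every entry, scaled by the
#'   column total for count matrices, before renormalisation. The default
#'   0.001 guarantees finite log scores with negligible distortion.
#'
#' @return An object of class `pwm` with fields `tf_name`, `width`, `probs`
#'   (4 x width probability matrix, rows A/C/G/T) and `pseudocount`.
#' @seealso [lr_score()], [scan_sites()], [read_pwm()]
#' @examples
#' m <- matrix(c(0.7, 0.1, 0.1, 0.1,
#'               0.1, 0.7, 0.1, 0.1), nrow = 4)
#' pwm(m, "toy")
#' @export
pwm <- function(mat, tf_name = "TF", pseudocount = 0.001) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    abort("`mat` must be a numeric matrix.")
  }
  if (nrow(mat) != 4 && ncol(mat) == 4) mat <- t(mat)
  if (nrow(mat) != 4) {
    abort("PWM matrix must have 4 rows (or 4 columns) for bases A, C, G, T.")
  }
  if (pseudocount < 0) abort("`pseudocount` must be non-negative.")
  if (any(mat < 0) || any(!is.finite(mat))) {
    abort("PWM entries must be finite and non-negative.")
  }
  if (ncol(mat) < 1) abort("PWM must have at least one position.")
  totals <- colSums(mat)
  if (any(totals <= 0)) abort("Every PWM position needs a positive total.")
  # pseudocount is interpreted per unit of column mass so that count matrices
  # and probability matrices are treated alike
  probs <- sweep(mat, 2, totals, "/") + pseudocount
  probs <- sweep(probs, 2, colSums(probs), "/")
  rownames(probs) <- DNA_BASES
  stopifnot(all(abs(colSums(probs) - 1) < 1e-9), all(probs > 0))
  structure(
    list(tf_name = tf_name, width = ncol(probs), probs = probs,
         pseudocount = pseudocount),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$tf_name, ": width ", x$width,
      ", consensus ", pwm_consensus(x),
      ", max score ", format(pwm_max_score(x), digits = 4), " bits\n",
      sep = "")
  invisible(x)
}

#' Background base-composition model
#'
#' @param freqs Named (A, C, G, T) or positional vector of 4 base
#'   frequencies; must be strictly positive and sum to 1 (tolerance 1e-9).
#' @return Named numeric vector of length 4.
#' @export
background_model <- function(freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (length(freqs) != 4) abort("Background needs 4 base frequencies.")
  if (is.null(names(freqs))) names(freqs) <- DNA_BASES
  freqs <- freqs[DNA_BASES]
  if (any(is.na(freqs)) || any(freqs <= 0)) {
    abort("Background frequencies must be strictly positive for A, C, G, T.")
  }
  if (abs(sum(freqs) - 1) > 1e-9) abort("Background frequencies must sum to 1.")
  freqs
}

#' GC-content parameterised background
#'
#' @param gc Fraction of G+C in (0, 1).
#' @return Named base-frequency vector.
#' @export
gc_background <- function(gc = 0.5) {
  stopifnot(gc > 0, gc < 1)
  background_model(c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2))
}

# log2 odds matrix, 4 x width
log_odds <- function(pwm, bg) {
  log2(pwm$probs / bg)
}

#' Maximum achievable score and consensus sequence of a PWM
#'
#' @param pwm A [pwm()] object.
#' @param bg Background model (for `pwm_max_score`).
#' @return `pwm_max_score`: the best attainable log2 likelihood-ratio score
#'   in bits; `pwm_consensus`: the highest-probability base at each position.
#' @export
pwm_max_score <- function(pwm, bg = background_model()) {
  sum(apply(log_odds(pwm, bg), 2, max))
}

#' @rdname pwm_max_score
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Default site-calling threshold
#'
#' The threshold below which a scored window is not called a site. Neither
#' published PWM scanners nor the CisOM analysis fix a universal cutoff, so
#' the default is a fraction of the best attainable score of the motif,
#' recorded in output headers. For the P53 dimer model the threshold applies
#' to each half-site before pairing.
#'
#' @param model A `pwm` or [p53_model()] object.
#' @param fraction Fraction of the maximum achievable log2 score (default 0.5).
#' @param bg Background model.
#' @return Threshold in bits.
#' @export
default_threshold <- function(model, fraction = 0.5, bg = background_model()) {
  if (inherits(model, "p53_model")) model <- model$half_pwm
  fraction * pwm_max_score(model, bg)
}

#' Log2 likelihood-ratio score of one window
#'
#' Scores a sequence window of exactly the PWM width as
#' `sum over positions of log2(probs[base, i] / bg[base])`, the per-site
#' binding score used throughout the CisOM analysis.
#'
#' @param pwm A [pwm()] object.
#' @param window Character scalar of length `pwm$width`, bases A/C/G/T only
#'   (case-insensitive; ambiguity codes are rejected).
#' @param bg Background model from [background_model()].
#' @return Score in bits (0 when the PWM equals the background).
#' @examples
#' p <- pwm(matrix(c(7, 1, 1, 1, 1, 7, 1, 1), nrow = 4), "toy")
#' lr_score(p, "AC")
#' @export
lr_score <- function(pwm, window, bg = background_model()) {
  stopifnot(inherits(pwm, "pwm"))
  if (!is.character(window) || length(window) != 1) {
    abort("`window` must be a single character string.")
  }
  if (nchar(window) != pwm$width) {
    abort(sprintf("`window` has %d bases but the PWM width is %d.",
                  nchar(window), pwm$width))
  }
  ints <- encode_bases(window)
  sum(log_odds(pwm, bg)[cbind(ints, seq_len(pwm$width))])
}

# A,C,G,T -> 1..4; errors name the first offending position
encode_bases <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  ints <- match(chars, DNA_BASES)
  if (anyNA(ints)) {
    bad <- which(is.na(ints))[1]
    abort(
      sprintf("Invalid base '%s' at position %d: only A, C, G, T are allowed.",
              chars[bad], bad),
      class = "cisomr_invalid_sequence"
    )
  }
  ints
}

decode_bases <- function(ints) paste(DNA_BASES[ints], collapse = "")

# reverse complement on the integer encoding (A<->T is 1<->4, C<->G is 2<->3)
revcomp_ints <- function(ints) rev(5L - ints)

#' Reverse complement of a DNA string
#' @param seq Character scalar over A/C/G/T.
#' @return Reverse-complemented string.
#' @export
revcomp <- function(seq) decode_bases(revcomp_ints(encode_bases(seq)))
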