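`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles. These deliberately re-derive every result
# by a different route than the package (per-window probability products,
# explicit double loops) so agreement is informative.

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# log2 of the product of per-position probability ratios
oracle_window_score <- function(win, probs, bg) {
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  r <- 1
  for (k in seq_along(ch)) r <- r * probs[ch[k], k] / bg[[ch[k]]]
  log2(r)
}

# exhaustive scan of every window on the requested strands
oracle_scan <- function(seq, pwm, bg = background_model(), threshold,
                        strands = c("+", "-")) {
  probs <- pwm$probs
  w <- pwm$width
  L <- nchar(seq)
  out <- list()
  for (st in strands) {
    sq <- if (st == "+") seq else oracle_revcomp(seq)
    chars <- strsplit(sq, "", fixed = TRUE)[[1]]
    n <- L - w + 1
    if (n < 1) next
    for (i in seq_len(n)) {
      ch <- chars[i:(i + w - 1)]
      r <- 1
      for (k in seq_len(w)) r <- r * probs[ch[k], k] / bg[[ch[k]]]
      sc <- log2(r)
      if (sc >= threshold) {
        start <- if (st == "+") i - 1L else L - (i - 1L) - w
        out[[length(out) + 1]] <- data.frame(start = start, strand = st,
                                             lr = sc)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), strand = character(), lr = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), , drop = FALSE]
}

# all ordered half-site pairs satisfying the spacer predicate, double loop
oracle_pair <- function(half_sites, min_spacer, max_spacer) {
  out <- list()
  n <- nrow(half_sites)
  if (n >= 2) {
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- half_sites[i, ]; b <- half_sites[j, ]
      spacer <- b$start - a$end
      if (a$start < b$start && spacer >= 0 &&
          spacer >= min_spacer && spacer <= max_spacer) {
        out[[length(out) + 1]] <- data.frame(
          start = a$start, end = b$end, spacer = spacer, lr = a$lr + b$lr)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), spacer = integer(),
                      lr = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$spacer), , drop = FALSE]
}

# quadratic all-pairs interval intersection
oracle_intersect <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
    if (e - s >= 1) {
      out[[length(out) + 1]] <- data.frame(chrom = a$chrom[i], start = s,
                                           end = e)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# full-site calling by oracle: scan half-sites then pair
oracle_call_p53 <- function(seq_str, half_pwm, bg, threshold, min_spacer,
                            max_spacer) {
  halves <- oracle_scan(seq_str, half_pwm, bg, threshold)
  halves$end <- halves$start + half_pwm$width
  oracle_pair(halves, min_spacer, max_spacer)
}

# independent full-rescan delta: score both alleles from scratch over the
# whole sequence, filter sites touching the window, sum
oracle_delta <- function(variant, seq_str, off, model, bg, threshold,
                         window_bp = 100) {
  score_allele <- function(s, w0, w1) {
    if (inherits(model, "p53_model")) {
      sites <- oracle_call_p53(s, model$half_pwm, bg, threshold,
                               model$min_spacer, model$max_spacer)
    } else {
      sites <- oracle_scan(s, model, bg, threshold)
      sites$end <- sites$start + model$width
    }
    if (!nrow(sites)) return(0)
    keep <- (sites$start + off) < w1 & (sites$end + off) > w0
    sum(sites$lr[keep])
  }
  half <- window_bp %/% 2
  w0 <- max(variant$pos - half, off)
  w1 <- min(variant$pos - half + window_bp, off + nchar(seq_str))
  i <- variant$pos - off + 1
  stopifnot(substr(seq_str, i, i) == variant$ref)
  alt_str <- seq_str
  substr(alt_str, i, i) <- variant$alt
  score_allele(alt_str, w0, w1) - score_allele(seq_str, w0, w1)
}

# exhaustive permutation p-value for Spearman's rho, via cor() per permutation
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_perms(n - 1L)
  out <- list()
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (p in smaller) out[[length(out) + 1]] <- c(i, rest[p])
  }
  out
}

oracle_spearman_p <- function(x, y) {
  obs <- abs(cor(x, y, method = "spearman"))
  rhos <- vapply(oracle_perms(length(y)),
                 function(p) cor(x, y[p], method = "spearman"), 0)
  mean(abs(rhos) >= obs - 1e-12)
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a full-site row in the shape pair_p53_half_sites() emits, for constructing
# detect_cisoms() fixtures directly
make_full_site <- function(chrom, start, end, lr = 20, spacer = 5,
                           half_w = 10) {
  tibble::tibble(
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    strand = "+", tf = "P53", lr = lr, kind = "full",
    spacer = as.integer(spacer),
    half_a_start = as.integer(start), half_a_end = as.integer(start + half_w),
    half_a_strand = "+", half_a_lr = lr / 2,
    half_b_start = as.integer(end - half_w), half_b_end = as.integer(end),
    half_b_strand = "+", half_b_lr = lr / 2)
}

make_simple_site <- function(chrom, start, end, lr = 10, tf = "cMYC",
                             strand = "+") {
  tibble::tibble(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), strand = strand, tf = tf, lr = lr,
                 kind = "simple")
}
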