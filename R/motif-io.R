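#' Read a motif matrix from a JASPAR or MEME file
#'
#' `read_pwm()` sniffs the format (a `MEME version` line marks MEME minimal
#' format, a `>` header marks JASPAR raw/pfm format) and dispatches to the
#' matching parser. JASPAR matrices are usually counts; MEME matrices are
#' letter probabilities; both are pseudocounted and renormalised by [pwm()].
#'
#' @param path Path to the motif file.
#' @param tf_name Optional override for the motif name found in the file.
#' @param pseudocount Passed to [pwm()].
#' @return A [pwm()] object (the first motif in the file).
#' @export
read_pwm <- function(path, tf_name = NULL, pseudocount = 0.001) {
  if (!file.exists(path)) {
    abort(sprintf("Motif file not found: %s", path), class = "cisomr_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MEME version", lines))) {
    read_meme(path, tf_name = tf_name, pseudocount = pseudocount)
  } else {
    read_jaspar(path, tf_name = tf_name, pseudocount = pseudocount)
  }
}

#' @rdname read_pwm
#' @export
read_jaspar <- function(path, tf_name = NULL, pseudocount = 0.001) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  name <- if (length(hdr)) sub("^>\\s*\\S*\\s*", "", lines[hdr[1]]) else "motif"
  if (length(hdr) && !nzchar(name)) name <- sub("^>\\s*", "", lines[hdr[1]])
  rows <- grep("^[ACGT]\\s*\\[?", lines, value = TRUE)
  rows <- rows[substr(rows, 1, 1) %in% DNA_BASES]
  if (length(rows) == 4) {
    base <- substr(rows, 1, 1)
    vals <- lapply(rows, function(r) parse_numbers(sub("^[ACGT]", "", r)))
  } else {
    # headerless 4-row numeric layout (rows in A, C, G, T order)
    vals <- lapply(setdiff(lines, lines[hdr]), parse_numbers)
    base <- DNA_BASES
    if (length(vals) != 4) abort("Cannot locate the 4 base rows of a JASPAR matrix.")
  }
  if (length(unique(lengths(vals))) != 1) {
    abort(sprintf("Ragged JASPAR matrix in %s", path))
  }
  mat <- do.call(rbind, vals)[match(DNA_BASES, base), , drop = FALSE]
  if (anyNA(mat) || any(!is.finite(mat))) {
    abort(sprintf("Malformed JASPAR matrix in %s", path))
  }
  pwm(mat, tf_name = tf_name %||% name, pseudocount = pseudocount)
}

parse_numbers <- function(x) {
  x <- gsub("[][]", " ", x)
  as.numeric(strsplit(trimws(x), "\\s+")[[1]])
}

#' @rdname read_pwm
#' @export
read_meme <- function(path, tf_name = NULL, pseudocount = 0.001) {
  lines <- readLines(path, warn = FALSE)
  mi <- grep("^MOTIF\\b", lines)
  if (!length(mi)) abort(sprintf("No MOTIF block in MEME file %s", path))
  name <- strsplit(trimws(lines[mi[1]]), "\\s+")[[1]][2]
  li <- grep("^letter-probability matrix", lines)
  li <- li[li > mi[1]][1]
  if (is.na(li)) abort(sprintf("No letter-probability matrix in %s", path))
  w <- suppressWarnings(as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[li])))
  body <- character(0)
  i <- li + 1
  while (i <= length(lines) && grepl("^\\s*[0-9.eE+-]", lines[i])) {
    body <- c(body, lines[i]); i <- i + 1
  }
  if (!is.na(w)) body <- head(body, w)
  mat <- t(do.call(rbind, lapply(body, parse_numbers)))  # 4 x width
  pwm(mat, tf_name = tf_name %||% name, pseudocount = pseudocount)
}

#' Bundled toy motifs for P53 half-sites and the cMYC E-box
#'
#' The package ships small synthetic JASPAR-format matrices: a 10 bp P53
#' half-site (consensus `GGGCAAGTCC`, an RRRCWWGYYY-pattern decamer) and an
#' 8 bp E-box-like cMYC motif (consensus `CACGTGTC`). They stand in for real
#' JASPAR matrices, which can be substituted via any [read_pwm()] file.
#'
#' @param which `"p53_half"` or `"cmyc"`.
#' @return A [pwm()] object.
#' @export
toy_pwm <- function(which = c("p53_half", "cmyc")) {
  which <- match.arg(which)
  f <- c(p53_half = "p53_half_toy.jaspar", cmyc = "cmyc_ebox_toy.jaspar")[[which]]
  read_pwm(system.file("extdata", f, package = "cisomr", mustWork = TRUE))
}
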