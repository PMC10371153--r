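#' Read genomic intervals from a BED file
#'
#' BED coordinates are taken verbatim as 0-based half-open. Lines starting
#' with `#`, `track` or `browser` are ignored; at least 3 columns are
#' required and a 4th, if present, becomes the interval name.
#'
#' @param path Path to a BED (>= 3 column) file.
#' @return Tibble with `chrom`, `start`, `end`, `name` (NA when absent), in
#'   file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("BED file not found: %s", path), class = "cisomr_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  if (!length(lines)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("Malformed BED line %d in %s: fewer than 3 columns.",
                  which(nf < 3)[1], path), class = "cisomr_parse_error")
  }
  out <- tibble(
    chrom = vapply(fields, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(fields, `[`, "", 2))),
    end   = suppressWarnings(as.integer(vapply(fields, `[`, "", 3))),
    name  = vapply(fields, function(f) if (length(f) >= 4) f[4] else NA_character_, "")
  )
  if (anyNA(out$start) || anyNA(out$end)) {
    bad <- which(is.na(out$start) | is.na(out$end))[1]
    abort(sprintf("Malformed BED line %d in %s: non-numeric coordinates.",
                  bad, path), class = "cisomr_parse_error")
  }
  bad <- which(out$start >= out$end | out$start < 0)
  if (length(bad)) {
    abort(sprintf("Invalid interval on BED line %d in %s: start %d, end %d.",
                  bad[1], path, out$start[bad[1]], out$end[bad[1]]),
          class = "cisomr_validation_error")
  }
  out
}

#' Write intervals (or sites) to a BED file
#'
#' Emits BED6 when `lr` and `strand` columns are present (name = `tf:kind`,
#' score = `lr * 100` rounded, as a lossy display companion to the full
#' precision TSVs), otherwise BED3/4. A comment header records the package
#' version and any supplied parameters.
#'
#' @param x Tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `strand`, `lr`, `tf`, `kind`.
#' @param path Output path.
#' @param params Named list recorded in the `#` header.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, params = list()) {
  hdr <- output_header(params)
  if (all(c("lr", "strand", "tf", "kind") %in% names(x))) {
    body <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", x$chrom, x$start, x$end,
                    paste0(x$tf, ":", x$kind), round(x$lr * 100), x$strand)
  } else {
    nm <- if ("name" %in% names(x)) if_else(is.na(x$name), ".", x$name) else NULL
    body <- if (is.null(nm)) sprintf("%s\t%d\t%d", x$chrom, x$start, x$end)
            else sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, nm)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

output_header <- function(params = list()) {
  ver <- as.character(packageVersion("cisomr"))
  p <- if (length(params)) {
    paste0("; ", paste(names(params), unlist(params), sep = "=", collapse = "; "))
  } else ""
  sprintf("# cisomr %s%s", ver, p)
}

#' Co-occupied regions: intersection of two ChIP peak sets
#'
#' Reports one co-occupied region per overlapping peak pair, with interval
#' `[max(starts), min(ends))` — overlapping output segments are not merged
#' unless `merge = TRUE`, in which case overlapping segments are unioned
#' (the two conventions can give different region counts; both are exposed).
#'
#' @param peaks_a,peaks_b Interval tibbles (`chrom`, `start`, `end`,
#'   optional `name`), e.g. from [read_bed()].
#' @param min_overlap Minimum shared bp to call co-occupancy (default 1).
#' @param merge Union overlapping output segments instead of reporting each
#'   a x b pair.
#' @return Tibble of co-occupied regions: `region_id`, `chrom`, `start`,
#'   `end`, `source_a`, `source_b` (sources are `NA` in merged mode), sorted
#'   by chrom then start.
#' @export
intersect_peaks <- function(peaks_a, peaks_b, min_overlap = 1L, merge = FALSE) {
  empty <- tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(),
                  source_a = character(), source_b = character())
  if (nrow(peaks_a) == 0 || nrow(peaks_b) == 0) return(empty)
  ga <- as_granges(peaks_a)
  gb <- as_granges(peaks_b)
  hits <- GenomicRanges::findOverlaps(ga, gb, minoverlap = min_overlap)
  if (!length(hits)) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- tibble(
    chrom = peaks_a$chrom[qi],
    start = pmax(peaks_a$start[qi], peaks_b$start[si]),
    end = pmin(peaks_a$end[qi], peaks_b$end[si]),
    source_a = interval_label(peaks_a, qi),
    source_b = interval_label(peaks_b, si)
  )
  if (merge) {
    red <- GenomicRanges::reduce(as_granges(out))
    out <- tibble(
      chrom = as.character(GenomicRanges::seqnames(red)),
      start = BiocGenerics::start(red) - 1L,
      end = BiocGenerics::end(red),
      source_a = NA_character_, source_b = NA_character_
    )
  }
  out |>
    arrange(.data$chrom, .data$start, .data$end) |>
    mutate(region_id = sprintf("region_%04d", row_number()), .before = 1)
}

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end))
}

interval_label <- function(x, i) {
  nm <- if ("name" %in% names(x)) x$name[i] else rep(NA_character_, length(i))
  if_else(is.na(nm) | !nzchar(nm),
          sprintf("%s:%d-%d", x$chrom[i], x$start[i], x$end[i]), nm)
}

#' Load a FASTA genome
#'
#' @param path FASTA file.
#' @return Named character vector of uppercased chromosome sequences.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTA file not found: %s", path), class = "cisomr_missing_file")
  }
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Extract the sequence of an interval from a genome
#'
#' @param genome Named character vector from [read_genome()] (or a
#'   `DNAStringSet`).
#' @param interval One-row tibble (or list) with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return A [dna_seq()] carrying the interval's origin; soft-masked
#'   lowercase bases are uppercased.
#' @export
extract_sequence <- function(genome, interval) {
  if (is(genome, "DNAStringSet")) genome <- setNames(as.character(genome), names(genome))
  chrom <- interval$chrom[[1]]
  start <- as.integer(interval$start[[1]])
  end <- as.integer(interval$end[[1]])
  if (!chrom %in% names(genome)) {
    abort(sprintf("Sequence '%s' not present in the genome.", chrom),
          class = "cisomr_missing_sequence")
  }
  L <- nchar(genome[[chrom]])
  if (start < 0 || end > L || start >= end) {
    abort(sprintf("Interval %s:%d-%d is outside the sequence bounds [0, %d).",
                  chrom, start, end, L), class = "cisomr_range_error")
  }
  dna_seq(substr(genome[[chrom]], start + 1L, end), chrom = chrom, offset = start)
}

#' Read variants from a minimal VCF or a TSV dialect
#'
#' `read_vcf_min()` parses the CHROM/POS/ID/REF/ALT columns of a VCF
#' (1-based positions converted to the package's 0-based convention);
#' `read_variants_tsv()` reads a `chrom, pos1based, rsid, ref, alt` table.
#' Only single-nucleotide A/C/G/T variants with `ref != alt` are valid.
#'
#' @param path Input file.
#' @return Tibble with `chrom`, `pos` (0-based), `ref`, `alt`, `id`.
#' @export
read_vcf_min <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("VCF file not found: %s", path), class = "cisomr_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(validate_variants(tibble(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), id = character())))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 5)) {
    abort(sprintf("Malformed VCF line %d: fewer than 5 columns.",
                  which(lengths(f) < 5)[1]), class = "cisomr_parse_error")
  }
  validate_variants(tibble(
    chrom = vapply(f, `[`, "", 1),
    pos = as.integer(vapply(f, `[`, "", 2)) - 1L,
    ref = toupper(vapply(f, `[`, "", 4)),
    alt = toupper(vapply(f, `[`, "", 5)),
    id = dplyr::na_if(vapply(f, `[`, "", 3), ".")
  ))
}

#' @rdname read_vcf_min
#' @export
read_variants_tsv <- function(path) {
  x <- read_tsv(path, comment = "#", show_col_types = FALSE)
  validate_variants(tibble(
    chrom = as.character(x$chrom), pos = as.integer(x$pos1based) - 1L,
    ref = toupper(x$ref), alt = toupper(x$alt),
    id = as.character(x$rsid)
  ))
}

validate_variants <- function(v) {
  ok <- v$ref %in% DNA_BASES & v$alt %in% DNA_BASES & v$ref != v$alt &
    !is.na(v$pos) & v$pos >= 0
  if (any(!ok)) {
    abort(sprintf(
      "Variant %d is not a valid single-nucleotide substitution (ref %s, alt %s).",
      which(!ok)[1], v$ref[which(!ok)[1]], v$alt[which(!ok)[1]]),
      class = "cisomr_validation_error")
  }
  v |> mutate(id = if_else(is.na(.data$id) | !nzchar(.data$id),
                           variant_id(.data$chrom, .data$pos, .data$ref, .data$alt),
                           .data$id))
}

# display ids are 1-based, matching the TSV/VCF convention
variant_id <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", chrom, pos + 1L, ref, alt)
}
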