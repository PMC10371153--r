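#' Delta-expression: alternative minus common allele
#'
#' Adds `delta_expr = expr_alt - expr_common` to an expression table: the
#' change in readout (luciferase activity or median normalised expression)
#' attributable to the alternative allele.
#'
#' @param expr Tibble with numeric `expr_common` and `expr_alt` columns.
#' @return `expr` with a `delta_expr` column.
#' @export
delta_expression <- function(expr) {
  if (!all(c("expr_common", "expr_alt") %in% names(expr))) {
    abort("`expr` needs `expr_common` and `expr_alt` columns.")
  }
  if (nrow(expr) && any(!is.finite(expr$expr_common) | !is.finite(expr$expr_alt))) {
    abort("Expression values must be finite.", class = "cisomr_validation_error")
  }
  mutate(expr, delta_expr = .data$expr_alt - .data$expr_common)
}

#' Spearman rank correlation with an exact small-sample p-value
#'
#' Computes rho on average ranks (ties allowed) and a two-sided p-value: by
#' exact enumeration of all `n!` rank permutations when `n <= exact_limit`
#' (counting permutations with `|rho| >=` the observed value), and by the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2`
#' degrees of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither may be
#'   constant.
#' @param exact_limit Largest `n` for exact enumeration (default 9; `9!`
#'   permutations are still enumerable in well under a second).
#' @return A `cisom_correlation` object with fields `n`, `estimate` (rho),
#'   `p.value` and `method` (`"exact_permutation"` or
#'   `"t_approximation"`). Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' spearman_test(1:6, c(2, 1, 4, 3, 6, 5))
#' @export
spearman_test <- function(x, y, exact_limit = 9L) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  n <- length(x)
  if (n < 3) abort("Need at least 3 pairs.", class = "cisomr_insufficient_data")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "cisomr_validation_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Spearman's rho is undefined for a constant vector.",
          class = "cisomr_degenerate_input")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- cor(rx, ry)
  if (n <= exact_limit) {
    perms <- all_permutations(n)
    # ranks are permuted as a set, so only the cross-product term varies
    s_obs <- sum(rx * ry)
    s_perm <- as.vector(matrix(ry[perms], nrow = nrow(perms)) %*% rx)
    # |rho| >= |rho_obs|  <=>  |s - n*mean^2 terms| compared on s directly
    center <- n * mean(rx) * mean(ry)
    p <- mean(abs(s_perm - center) >= abs(s_obs - center) - 1e-9)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
    method <- "t_approximation"
  }
  new_cisom_correlation(n = n, estimate = rho, p.value = p, method = method)
}

new_cisom_correlation <- function(n, estimate, p.value, method, tf = NA_character_,
                                  data = NULL, include_zero_delta = NA) {
  structure(
    list(n = n, estimate = estimate, p.value = p.value, method = method,
         tf = tf, include_zero_delta = include_zero_delta, data = data),
    class = "cisom_correlation"
  )
}

# permutation matrices cached per n (9! x 9 is ~13 MB of integers)
perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_cache[[key]])) return(perm_cache[[key]])
  res <- if (n == 1L) {
    matrix(1L, 1, 1)
  } else {
    sub <- all_permutations(n - 1L)
    blocks <- lapply(seq_len(n), function(i) {
      rest <- seq_len(n)[-i]
      cbind(rep(i, nrow(sub)), matrix(rest[sub], nrow(sub)))
    })
    do.call(rbind, blocks)
  }
  if (n <= 9L) perm_cache[[key]] <- res
  res
}

#' @export
print.cisom_correlation <- function(x, ...) {
  cat(sprintf(
    "<cisom_correlation>%s n = %d, rho = %.4f, p = %.4g (%s)\n",
    if (!is.na(x$tf)) paste0(" ", x$tf, ":") else "",
    x$n, x$estimate, x$p.value, x$method))
  invisible(x)
}

#' @method tidy cisom_correlation
#' @export
tidy.cisom_correlation <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p.value, method = x$method,
         alternative = "two.sided", tf = x$tf)
}

#' @method glance cisom_correlation
#' @export
glance.cisom_correlation <- function(x, ...) {
  tibble(n = x$n, rho = x$estimate, p.value = x$p.value, method = x$method,
         tf = x$tf, include_zero_delta = x$include_zero_delta)
}

#' Correlate delta-binding with delta-expression
#'
#' Inner-joins per-variant delta-binding records with per-variant expression
#' records, computes delta-expression (alternative minus common), and runs
#' [spearman_test()] on the paired vectors. A variant annotated to several
#' CisOMs contributes one pair per TF, keeping the CisOM with the largest
#' `|delta|`.
#'
#' @param delta_records Tibble from [delta_binding()] (columns `id`, `tf`,
#'   `delta`).
#' @param expr Expression tibble with `variant_id`, `expr_common`,
#'   `expr_alt` (see [read_expression_tsv()] or [simulate_expression()]).
#' @param tf Optional TF name to restrict `delta_records` to.
#' @param include_zero_delta Keep pairs whose delta-binding is exactly zero
#'   (default `TRUE`); toggling this changes only the pair count, never any
#'   sign convention.
#' @param join_key Column of `expr` holding the variant identifier.
#' @return A `cisom_correlation` object whose `data` field is the paired
#'   `(delta, delta_expr)` table used.
#' @export
correlate_deltas <- function(delta_records, expr, tf = NULL,
                             include_zero_delta = TRUE,
                             join_key = "variant_id") {
  d <- delta_records
  if (!is.null(tf)) d <- filter(d, .data$tf == !!tf)
  d <- d |>
    group_by(.data$id, .data$tf) |>
    slice_max(abs(.data$delta), n = 1, with_ties = FALSE) |>
    ungroup()
  e <- delta_expression(expr) |> rename(id = all_of(join_key))
  paired <- inner_join(d |> select(id, tf, delta),
                       e |> select(id, delta_expr),
                       by = "id")
  if (!include_zero_delta) paired <- filter(paired, .data$delta != 0)
  if (nrow(paired) < 3) {
    abort(sprintf(
      paste0("Insufficient data: %d joinable pair(s) after filtering ",
             "(%d delta record(s), %d expression record(s), ",
             "include_zero_delta = %s)."),
      nrow(paired), nrow(d), nrow(e), include_zero_delta),
      class = "cisomr_insufficient_data")
  }
  res <- spearman_test(paired$delta, paired$delta_expr)
  res$tf <- if (is.null(tf)) paste(unique(paired$tf), collapse = "+") else tf
  res$include_zero_delta <- include_zero_delta
  res$data <- paired
  res
}

#' Read a GTEx-style expression export
#'
#' Expects a long table with columns `variant_id`, `gene`,
#' `genotype_class` (`common_hom`, `het`, `alt_hom`), `median_expression`
#' and optional `tissue`, and reshapes it into one row per variant with
#' `expr_common` and `expr_alt`. The alternative readout defaults to the
#' heterozygous median, since homozygous-alternative medians are frequently
#' unavailable; several tissues per variant are combined by the chosen
#' policy.
#'
#' @param path TSV path.
#' @param alt_genotype `"het"` (default) or `"hom"`.
#' @param tissue_policy `"median"` across tissues (default) or the name of a
#'   single tissue to keep.
#' @return Tibble `variant_id`, `gene`, `expr_common`, `expr_alt`, `source`.
#' @export
read_expression_tsv <- function(path, alt_genotype = c("het", "hom"),
                                tissue_policy = "median") {
  alt_genotype <- match.arg(alt_genotype)
  x <- read_tsv(path, comment = "#", show_col_types = FALSE)
  alt_class <- c(het = "het", hom = "alt_hom")[[alt_genotype]]
  if (!"tissue" %in% names(x)) x$tissue <- "all"
  if (!identical(tissue_policy, "median")) {
    x <- filter(x, .data$tissue == tissue_policy)
  }
  x |>
    filter(.data$genotype_class %in% c("common_hom", alt_class)) |>
    group_by(.data$variant_id, .data$gene, .data$genotype_class) |>
    summarise(expr = median(.data$median_expression), .groups = "drop") |>
    pivot_wider(names_from = "genotype_class", values_from = "expr") |>
    rename(expr_common = all_of("common_hom"), expr_alt = all_of(alt_class)) |>
    filter(is.finite(.data$expr_common), is.finite(.data$expr_alt)) |>
    mutate(source = "gtex")
}

#' Per-gene and per-chromosome variant burden
#'
#' Counts putative variants by gene and by chromosome, the summary used to
#' rank genes and chromosomes by their load of CisOM-disrupting variants.
#'
#' @param variants Tibble with `chrom` and (optionally) `putative_gene` or
#'   `gene`.
#' @return Tibble `group` (`"gene"`/`"chromosome"`), `name`, `n_variants`,
#'   sorted by descending count within each group.
#' @export
burden_summary <- function(variants) {
  empty <- tibble(group = character(), name = character(), n_variants = integer())
  if (nrow(variants) == 0) return(empty)
  gene_col <- intersect(c("putative_gene", "gene"), names(variants))[1]
  out <- list()
  if (!is.na(gene_col)) {
    out$gene <- variants |>
      filter(!is.na(.data[[gene_col]])) |>
      count(name = "n_variants", .data[[gene_col]]) |>
      rename(name = all_of(gene_col)) |>
      mutate(group = "gene")
  }
  out$chrom <- variants |>
    count(.data$chrom, name = "n_variants") |>
    rename(name = chrom) |>
    mutate(group = "chromosome")
  bind_rows(out) |>
    select(group, name, n_variants) |>
    arrange(.data$group, desc(.data$n_variants), .data$name)
}
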