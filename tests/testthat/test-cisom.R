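test_that("a CisOM is the minimal cover of an overlapping site pair", {
  p53 <- make_full_site("chr1", 100, 120)
  cmyc <- make_simple_site("chr1", 115, 125)
  cm <- detect_cisoms(p53, cmyc)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$start, 100L)
  expect_equal(cm$end, 125L)
  expect_equal(cm$p53_start, 100L)
  expect_equal(cm$cmyc_start, 115L)
})

test_that("abutting sites with no shared base form no CisOM", {
  p53 <- make_full_site("chr1", 100, 120)
  expect_equal(nrow(detect_cisoms(p53, make_simple_site("chr1", 120, 130))), 0)
  # one shared base suffices
  expect_equal(nrow(detect_cisoms(p53, make_simple_site("chr1", 119, 129))), 1)
  # different chromosomes never overlap
  expect_equal(nrow(detect_cisoms(p53, make_simple_site("chr2", 110, 118))), 0)
})

test_that("detection equals the all-pairs overlap oracle, order-invariantly", {
  set.seed(31)
  for (rep in 1:6) {
    np <- sample(3:8, 1); nm <- sample(3:10, 1)
    ps <- sample(0:500, np)
    p53 <- dplyr::bind_rows(lapply(ps, function(s)
      make_full_site("chr1", s, s + sample(22:35, 1))))
    ms <- sample(0:500, nm)
    cmyc <- dplyr::bind_rows(lapply(ms, function(s)
      make_simple_site("chr1", s, s + 8)))
    got <- detect_cisoms(p53, cmyc)
    # brute force over every (full site, cmyc site) pair
    want <- 0L
    for (i in seq_len(np)) for (j in seq_len(nm)) {
      ov <- min(p53$end[i], cmyc$end[j]) - max(p53$start[i], cmyc$start[j])
      if (ov >= 1) {
        want <- want + 1L
        expect_true(any(
          got$start == min(p53$start[i], cmyc$start[j]) &
            got$end == max(p53$end[i], cmyc$end[j]) &
            got$p53_start == p53$start[i] & got$cmyc_start == cmyc$start[j]))
      }
    }
    expect_equal(nrow(got), want)
    shuf <- detect_cisoms(p53[sample(np), ], cmyc[sample(nm), ])
    expect_equal(shuf |> dplyr::select(-cisom_id),
                 got |> dplyr::select(-cisom_id))
    # interval-length bounds relative to the two site widths
    if (nrow(got)) {
      p53_len <- got$p53_end - got$p53_start
      cmyc_len <- got$cmyc_end - got$cmyc_start
      len <- got$end - got$start
      expect_true(all(len <= p53_len + cmyc_len - 1))
      expect_true(all(len >= pmax(p53_len, cmyc_len)))
    }
  }
})

test_that("region filtering keeps CisOMs touching the co-occupied segment", {
  p53 <- make_full_site("chr1", 100, 130)
  cmyc <- make_simple_site("chr1", 110, 118)
  region_in <- tibble::tibble(region_id = "region_0001", chrom = "chr1",
                              start = 90L, end = 200L)
  region_out <- tibble::tibble(region_id = "region_0002", chrom = "chr1",
                               start = 400L, end = 500L)
  expect_equal(detect_cisoms(p53, cmyc, regions = region_in)$region_id,
               "region_0001")
  expect_equal(nrow(detect_cisoms(p53, cmyc, regions = region_out)), 0)
})

test_that("per-region counts include zeros and a totals row", {
  regions <- tibble::tibble(region_id = c("r1", "r2", "r3"), chrom = "chr1",
                            start = c(0L, 100L, 200L), end = c(50L, 150L, 250L))
  none <- count_cisoms_per_region(
    detect_cisoms(make_full_site("chr1", 0, 30)[0, ], make_simple_site("chr1", 1, 9)),
    regions)
  expect_equal(none$n_cisoms, c(0L, 0L, 0L, 0L))
  cisoms <- tibble::tibble(region_id = c("r1", "r1", "r2", "r2", "r3", "r3"))
  counts <- count_cisoms_per_region(cisoms, regions)
  expect_equal(counts$n_cisoms, c(2L, 2L, 2L, 6L))
  expect_equal(counts$region_id[4], "total")
  per_region <- counts$n_cisoms[counts$region_id != "total"]
  expect_equal(mean(per_region), 2)
})

test_that("variant-to-CisOM mapping respects half-open boundaries", {
  cisoms <- detect_cisoms(make_full_site("chr1", 100, 130),
                          make_simple_site("chr1", 110, 118))
  mkv <- function(pos) tibble::tibble(chrom = "chr1", pos = as.integer(pos),
                                      ref = "A", alt = "C",
                                      id = paste0("v", pos))
  at_start <- map_variants_to_cisoms(mkv(100), cisoms)
  expect_false(is.na(at_start$cisom_id))
  at_end <- map_variants_to_cisoms(mkv(130), cisoms)
  expect_true(is.na(at_end$cisom_id))
  inside <- map_variants_to_cisoms(mkv(129), cisoms, context_radius = 500)
  expect_equal(inside$context_start, 0L)  # clamped at the chromosome start
  expect_equal(inside$context_end, 129L + 501L)
})

test_that("membership matches a brute-force oracle for random variants", {
  set.seed(32)
  starts <- sample(0:2000, 20)
  cisoms <- detect_cisoms(
    dplyr::bind_rows(lapply(starts, function(s) make_full_site("chr1", s, s + 28))),
    dplyr::bind_rows(lapply(starts, function(s) make_simple_site("chr1", s + 10, s + 18))))
  pos <- sample(0:2100, 100)
  variants <- tibble::tibble(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                             id = paste0("v", seq_along(pos)))
  ann <- map_variants_to_cisoms(variants, cisoms)
  for (k in seq_len(nrow(variants))) {
    inside <- cisoms$cisom_id[cisoms$start <= pos[k] & pos[k] < cisoms$end]
    hits <- ann$cisom_id[ann$id == variants$id[k]]
    if (length(inside)) {
      expect_setequal(hits, inside)
    } else {
      expect_true(is.na(hits))
    }
  }
})

test_that("nearest-TSS assignment picks the closest gene", {
  tss <- tibble::tibble(chrom = "chr1", start = c(100L, 1000L),
                        name = c("geneA", "geneB"))
  x <- tibble::tibble(chrom = "chr1", pos = c(90L, 800L, 549L))
  ann <- annotate_nearest_tss(x, tss)
  expect_equal(ann$putative_gene, c("geneA", "geneB", "geneA"))
  expect_equal(ann$tss_distance, c(10L, 200L, 449L))
})
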