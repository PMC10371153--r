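p53h <- toy_pwm("p53_half")
cmyc <- toy_pwm("cmyc")
p53m <- p53_model(p53h)

test_that("saturation emits exactly 3L ordered variants per CisOM", {
  set.seed(51)
  s <- dna_seq(random_dna(60), "chr1", offset = 200L)
  cisom <- tibble::tibble(chrom = "chr1", start = 210L, end = 220L,
                          cisom_id = "cisom_00001")
  vs <- saturate_cisom(cisom, s)
  expect_equal(nrow(vs), 3 * 10)
  expect_true(all(vs$ref != vs$alt))
  # reference bases equal the genome and ordering is pos then alt (A<C<G<T)
  expect_equal(vs$ref, rep(strsplit(substr(unclass(s), 11, 20), "")[[1]], each = 3))
  expect_equal(vs$pos, rep(210:219, each = 3))
  expect_true(all(tapply(vs$alt, vs$pos, function(a) !is.unsorted(a))))
  # (pos, alt) pairs are the Cartesian product minus the reference pairs
  all_pairs <- expand.grid(pos = 210:219, alt = c("A", "C", "G", "T"),
                           stringsAsFactors = FALSE)
  ref_at <- setNames(vs$ref[!duplicated(vs$pos)], unique(vs$pos))
  keep <- all_pairs$alt != ref_at[as.character(all_pairs$pos)]
  expect_setequal(paste(vs$pos, vs$alt), paste(all_pairs$pos, all_pairs$alt)[keep])
  expect_equal(vs$cisom_id, rep("cisom_00001", 30))
})

test_that("saturation rejects intervals not covered by the sequence", {
  s <- dna_seq("ACGTACGTAC", "chr1", offset = 0L)
  expect_error(saturate_cisom(tibble::tibble(chrom = "chr1", start = 5L, end = 15L), s),
               class = "cisomr_range_error")
})

test_that("apply_variant substitutes, checks the reference and inverts", {
  s <- dna_seq("ACGTACGTAC", "chr1", offset = 100L)
  v <- tibble::tibble(chrom = "chr1", pos = 103L, ref = "T", alt = "G")
  s2 <- apply_variant(s, v)
  expect_equal(unclass(s2), "ACGGACGTAC", ignore_attr = TRUE)
  expect_equal(nchar(s2), nchar(s))
  inv <- tibble::tibble(chrom = "chr1", pos = 103L, ref = "G", alt = "T")
  expect_equal(unclass(apply_variant(s2, inv)), unclass(s))
  # boundary positions work
  expect_equal(substr(unclass(apply_variant(s, tibble::tibble(
    pos = 100L, ref = "A", alt = "T"))), 1, 1), "T", ignore_attr = TRUE)
  expect_equal(substr(unclass(apply_variant(s, tibble::tibble(
    pos = 109L, ref = "C", alt = "A"))), 10, 10), "A", ignore_attr = TRUE)
  err <- tryCatch(apply_variant(s, tibble::tibble(pos = 103L, ref = "A", alt = "G")),
                  error = function(e) e)
  expect_s3_class(err, "cisomr_ref_mismatch")
  expect_match(conditionMessage(err), "'A'")
  expect_match(conditionMessage(err), "'T'")
  expect_error(apply_variant(s, tibble::tibble(pos = 500L, ref = "A", alt = "G")),
               class = "cisomr_range_error")
})

test_that("a variant destroying the only called site has delta = -s_ref", {
  set.seed(52)
  flank <- strrep("T", 60)
  s <- dna_seq(paste0(flank, pwm_consensus(cmyc), flank), "chr1", 0L)
  # one mismatch costs ~4 bits, so a threshold of 12 bits makes the single
  # consensus site disappear on mutation while still being called on reference
  v <- tibble::tibble(chrom = "chr1", pos = 63L, ref = "G", alt = "T",
                      id = "kill")
  d <- delta_binding(v, s, cmyc, threshold = 12)
  expect_gt(d$s_ref, 0)
  expect_equal(d$s_alt, 0)
  expect_equal(d$delta, -d$s_ref)
  expect_equal(d$tf, "cMYC")
  expect_equal(d$window_start, 13L)
  expect_equal(d$window_end, 113L)
  expect_false(d$truncated)
})

test_that("variants far from any possible site have delta zero", {
  s <- dna_seq(strrep("T", 300), "chr1", 0L)
  v <- tibble::tibble(chrom = "chr1", pos = 150L, ref = "T", alt = "G",
                      id = "null")
  expect_equal(delta_binding(v, s, cmyc)$delta, 0)
  expect_equal(delta_binding(v, s, p53m)$delta, 0)
})

test_that("delta is antisymmetric under variant inversion, bit for bit", {
  set.seed(53)
  sim <- simulate_genome(sim_config(seed = 53, n_cooccupied = 2,
                                    genome_length = 6000, n_snps = 0))
  s <- dna_seq(sim$genome[[1]], "chrSim", 0L)
  for (k in 1:20) {
    pos <- sample(sim$truth$cisom_start[1]:(sim$truth$cisom_end[1] - 1L), 1)
    ref <- substr(unclass(s), pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- tibble::tibble(chrom = "chrSim", pos = pos, ref = ref, alt = alt,
                        id = "x")
    model <- if (k %% 2 == 0) p53m else cmyc
    d <- delta_binding(v, s, model)
    s_mut <- apply_variant(s, v)
    v_inv <- tibble::tibble(chrom = "chrSim", pos = pos, ref = "x",
                            alt = "x", id = "x")
    v_inv$ref <- alt; v_inv$alt <- ref
    d_inv <- delta_binding(v_inv, s_mut, model)
    expect_true(d_inv$delta == -d$delta)
    expect_true(d_inv$s_ref == d$s_alt)
  }
})

test_that("delta matches an independent full-rescan oracle", {
  set.seed(54)
  bg <- background_model()
  for (k in 1:25) {
    # embed a consensus or near-consensus site so scores straddle threshold
    core <- if (k %% 2 == 0) pwm_consensus(cmyc)
            else paste0(pwm_consensus(p53h), random_dna(sample(2:12, 1)),
                        pwm_consensus(p53h))
    s_str <- paste0(random_dna(80), core, random_dna(80))
    off <- sample(0:1000, 1)
    s <- dna_seq(s_str, "chr1", off)
    pos <- off + sample(seq_len(nchar(s_str)), 1) - 1L
    ref <- substr(s_str, pos - off + 1, pos - off + 1)
    v <- tibble::tibble(chrom = "chr1", pos = pos, ref = ref,
                        alt = sample(setdiff(c("A", "C", "G", "T"), ref), 1),
                        id = "x")
    model <- if (k %% 2 == 0) cmyc else p53m
    thr <- default_threshold(model)
    got <- delta_binding(v, s, model, threshold = thr)$delta
    want <- oracle_delta(v, s_str, off, model, bg, thr)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the contained site-window rule is stricter than overlap", {
  s <- dna_seq(paste0(strrep("T", 49), pwm_consensus(cmyc), strrep("T", 60)),
               "chr1", 0L)
  # variant placed so the site pokes out of a narrow window
  v <- tibble::tibble(chrom = "chr1", pos = 50L, ref = "A", alt = "C",
                      id = "edge")
  ov <- delta_binding(v, s, cmyc, window_bp = 10L, threshold = 12,
                      site_window_rule = "overlap")
  ct <- delta_binding(v, s, cmyc, window_bp = 10L, threshold = 12,
                      site_window_rule = "contained")
  expect_lt(ov$delta, 0)  # destroying the site is seen under overlap
  expect_equal(ct$s_ref, 0)  # but the site is not contained in 10 bp
})
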