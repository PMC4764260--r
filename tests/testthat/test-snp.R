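test_that("category rules follow the log-odds threshold and sign flip", {
  # delta 3.5 with a sign flip -> switch
  expect_equal(classify_category(1.0, -2.5), "switch")
  # below threshold -> footprint
  expect_equal(classify_category(2.0, 1.0), "footprint")
  # delta 3 both negative -> effect, not switch
  expect_equal(classify_category(-1.0, -4.0), "effect")
  # boundary: exactly 3 counts as effect (>= rule)
  expect_equal(classify_category(3, 0), "switch")   # 0 belongs to both signs
  expect_equal(classify_category(4, 1), "effect")
  expect_equal(classify_category(2.999, 0), "footprint")
  # vectorised
  expect_equal(classify_category(c(1, 2, -1), c(-2.5, 1, -4)),
               c("switch", "footprint", "effect"))
})

test_that("the log-odds threshold of 3 is the printed >= 20-fold rule", {
  expect_gte(exp(3), 20)
  expect_equal(exp(3), 20.0855, tolerance = 1e-4)
  # a SNP at exactly 20-fold prior-odds change is an effect-SNP
  expect_equal(classify_category(log(20.09), 0), "switch")
})

test_that("category and delta are invariant under allele swap", {
  set.seed(31)
  a <- rnorm(200, sd = 3)
  b <- rnorm(200, sd = 3)
  expect_equal(classify_category(a, b), classify_category(b, a))
  expect_equal(abs(a - b), abs(b - a))
})

# A small annotated fixture shared by the annotation tests.
make_annotation_fixture <- function(seed = 32, n_sites = 600) {
  g <- simulate_genome(3e4, n_sites = n_sites, seed = seed)
  sm <- pwm_log_odds(g$pwm)
  sim <- simulate_cut_matrix(g$sites$score, flank = 20, seed = seed + 1)
  fit <- fit_centipede(sim$cuts, g$sites$score, min_sites = 500)
  matches <- dplyr::mutate(g$sites, site_id = fit$site_ids)
  list(genome = g, sm = sm, fit = fit, matches = matches)
}

test_that("annotation computes per-allele prior log odds and categories", {
  fx <- make_annotation_fixture()
  sm <- fx$sm
  m <- fx$matches[1, ]
  # variant at the first motif position
  pos0 <- m$start
  ref <- if (m$strand == "+") substr(m$sequence, 1, 1) else
    chartr("ACGT", "TGCA", substr(m$sequence, 10, 10))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  v <- tibble::tibble(chrom = m$chrom, pos0 = pos0, ref = ref, alt = alt)
  ann <- annotate_snps(v, fx$matches, sm, fit = fx$fit, sample_id = "s1")
  expect_equal(nrow(ann), 1)
  b <- fx$fit$beta
  expect_equal(ann$ell_ref, b[1] + b[2] * ann$score_ref, tolerance = 1e-12)
  expect_equal(ann$ell_alt, b[1] + b[2] * ann$score_alt, tolerance = 1e-12)
  expect_equal(ann$delta, abs(ann$log_ratio))
  expect_equal(ann$score_ref, m$score, tolerance = 1e-12)
  # allele swap flips the sign of log_ratio, keeps delta and category
  v2 <- tibble::tibble(chrom = m$chrom, pos0 = pos0)
  v2$ref <- alt
  v2$alt <- ref
  ann2 <- annotate_snps(v2, fx$matches, sm, fit = fx$fit, sample_id = "s1")
  expect_equal(ann2$log_ratio, -ann$log_ratio, tolerance = 1e-12)
  expect_equal(ann2$delta, ann$delta, tolerance = 1e-12)
  expect_equal(ann2$category, ann$category)
})

test_that("known score differences map to the documented categories", {
  # beta1 = 1.5, score difference 2 -> delta 3 -> effect
  sm <- pwm_log_odds(toy_pwm())
  shift <- unname(sm$scores["A", 1] - sm$scores["C", 1])
  beta <- c(-1, 2 * 3 / (2 * shift))  # engineered so delta = 3 for A->C...
  m <- tibble::tibble(chrom = "c", start = 0L, end = 4L, strand = "+",
                      score = score_sequence(sm, "ACGT"), sequence = "ACGT",
                      motif_id = "TOY", site_id = "s1")
  v <- tibble::tibble(chrom = "c", pos0 = 0L, ref = "A", alt = "C")
  ann <- annotate_snps(v, m, sm, beta = c(0, 3 / shift))
  expect_equal(ann$delta, 3, tolerance = 1e-9)
  expect_match(ann$category, "effect|switch")
  # zero-information column: substitute at a uniform column -> delta 0
  uni <- new_pwm(matrix(25, 4, 4), pseudocount = 0)
  smu <- pwm_log_odds(uni)
  mu_ <- dplyr::mutate(m, score = 0, sequence = "ACGT", motif_id = "UNI")
  annu <- annotate_snps(v, mu_, smu, beta = c(0, 1.5))
  expect_equal(annu$delta, 0)
  expect_equal(annu$category, "footprint")
})

test_that("overlap resolution keeps the largest likelihood ratio deterministically", {
  base <- tibble::tibble(
    chrom = "chr1", pos0 = 100L, ref = "A", alt = "G", sample_id = "s",
    motif_id = c("M_b", "M_a"), site_id = c("x", "y"),
    score_ref = 1, score_alt = 0, ell_ref = 1, ell_alt = 0,
    delta = 1, log_ratio = 1, category = "footprint",
    lik_ratio = c(log(10), log(100)), posterior = 0.5
  )
  kept <- resolve_overlaps(base)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$motif_id, "M_a")          # ln 100 wins
  expect_equal(resolve_overlaps(base[1, ])$motif_id, "M_b")  # singleton

  # exact tie: smaller motif_id wins, stable under input shuffles
  tie <- dplyr::mutate(base, lik_ratio = log(10))
  for (i in 1:5) {
    shuffled <- tie[sample(nrow(tie)), ]
    expect_equal(resolve_overlaps(shuffled)$motif_id, "M_a")
  }
  expect_error(resolve_overlaps(base[0, ]), class = "footvar_input")
})

test_that("the catalog round-trips through its 8-column format", {
  ann <- tibble::tibble(
    chrom = "chr1", pos0 = 713977L, ref = "A", alt = "G",
    motif_id = "M00001", sample_id = "fLung",
    ell_ref = 1.234567, ell_alt = -2.345678,
    log_ratio = 1.234567 - (-2.345678), delta = abs(1.234567 + 2.345678),
    category = "switch", score_ref = 1, score_alt = 0, site_id = "s",
    lik_ratio = 1, posterior = 0.999
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(ann, path)
  lines <- readLines(path)
  expect_true(any(grepl("0-based half-open", lines)))
  row <- strsplit(lines[!startsWith(lines, "#")][1], "\t")[[1]]
  expect_equal(row[1:4], c("chr1", "713977", "713978", "M00001"))
  expect_equal(as.numeric(row[5]), ann$log_ratio, tolerance = 1e-6)
  expect_equal(row[8], "fLung")

  back <- read_catalog(path)
  expect_equal(back$pos0, ann$pos0)
  expect_equal(back$ell_ref, round(ann$ell_ref, 6))
  expect_equal(back$ell_alt, round(ann$ell_alt, 6))
  expect_equal(back$log_ratio, round(ann$log_ratio, 6))

  # empty catalog: header-only file, zero-row read-back
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(ann[0, ], p2)
  expect_equal(nrow(read_catalog(p2)), 0)
})

test_that("nested categories respect the containment funnel", {
  snps <- tibble::tibble(
    chrom = "chr1",
    pos0 = c(10L, 110L, 210L, 310L, 410L),
    category = c(NA, "footprint", "effect", "switch", NA)
  )
  footprints <- tibble::tibble(chrom = "chr1", start = c(100L, 200L, 300L),
                               end = c(120L, 220L, 320L))
  dhs <- tibble::tibble(chrom = "chr1", start = 0L, end = 350L)
  nested <- nest_categories(snps, footprints, dhs)
  expect_equal(nested$nested_category,
               c("dhs", "footprint", "effect", "switch", "none"))
  counts <- category_funnel(nested)
  n <- setNames(counts$n, counts$category)
  expect_lte(n[["switch"]], n[["effect"]])
  expect_lte(n[["effect"]], n[["footprint"]])
  expect_lte(n[["footprint"]], n[["dhs"]])

  # footprint SNP outside all DHS regions: kept with a warning
  dhs_small <- tibble::tibble(chrom = "chr1", start = 0L, end = 150L)
  expect_warning(n2 <- nest_categories(snps, footprints, dhs_small),
                 "outside every DHS")
  expect_equal(n2$nested_category[3], "effect")
})
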