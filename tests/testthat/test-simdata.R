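test_that("element_spec validates mismatch budget and canonical windows", {
  expect_s3_class(element_spec("TATA", -31L), "element_spec")
  expect_error(element_spec("TATA", -15L), "canonical window")
  expect_error(element_spec("PAUSE", 38L), "canonical window")  # runs past +40
  expect_error(element_spec("INR", -2L, planted_mismatches = 2L), "0 or 1")
  expect_error(element_spec("TATA", -31L, consensus_id = "XXX"), "unknown")
})

test_that("planted elements are emitted with the requested mismatch count", {
  set.seed(51)
  cons <- element_consensi()
  for (i in 1:200) {
    kind <- sample(c("TATA", "INR", "PAUSE"), 1)
    mm <- sample(0:1, 1)
    spec <- switch(kind,
      TATA = element_spec("TATA", sample(-40:-28, 1), planted_mismatches = mm),
      INR = element_spec("INR", -2L, planted_mismatches = mm),
      PAUSE = element_spec("PAUSE", sample(15:33, 1),
                           consensus_id = "CSARCSSA", planted_mismatches = mm))
    pr <- make_promoter(list(spec), 201L, 100L, gc = 0.5)
    o <- bio_to_offset(spec$planted_offset, 100L)
    sub <- substr(pr$sequence, o + 1, o + nchar(spec$consensus))
    expect_identical(iupac_mismatches(sub, spec$consensus), mm)
  }
})

test_that("a forced +2 base overrides the initiator instance", {
  pr <- make_promoter(list(element_spec("INR", -2L, force_plus2 = "G")),
                      seed = 1)
  tssi <- 100L
  expect_identical(substr(pr$sequence, tssi + 1, tssi + 1), "A")  # +1
  expect_identical(substr(pr$sequence, tssi + 2, tssi + 2), "G")  # +2
  # forcing a base outside the code set without a mismatch budget fails
  expect_error(make_promoter(list(element_spec("INR", -2L, force_plus2 = "A")),
                             seed = 1), "conflicts")
  # with one mismatch allowed the forced base consumes the budget
  pr2 <- make_promoter(list(element_spec("INR", -2L, planted_mismatches = 1L,
                                         force_plus2 = "A")), seed = 2)
  inr <- substr(pr2$sequence, 99, 104)
  expect_identical(iupac_mismatches(inr, "TCAKTY"), 1L)
  expect_identical(substr(pr2$sequence, 102, 102), "A")
})

test_that("planting is rejected on overlap or out-of-bounds windows", {
  expect_error(make_promoter(list(element_spec("INR", -2L),
                                  element_spec("INR", -2L)), seed = 1),
               "overlap")
  expect_error(make_promoter(list(element_spec("TATA", -40L)),
                             length = 130L, tss_index = 20L, seed = 1),
               "out of bounds")
  expect_error(make_promoter(list(), length = 100L), ">= 120")
})

test_that("promoter generation is reproducible and respects GC content", {
  a <- make_promoter(list(element_spec("TATA", -31L)), seed = 7)
  b <- make_promoter(list(element_spec("TATA", -31L)), seed = 7)
  expect_identical(a$sequence, b$sequence)
  rich <- make_promoter(list(), 5001L, 2500L, gc = 0.8, seed = 8)
  gc_frac <- mean(strsplit(rich$sequence, "")[[1]] %in% c("G", "C"))
  expect_equal(gc_frac, 0.8, tolerance = 0.03)
})

test_that("empty-spec promoters rarely contain background elements", {
  set.seed(52)
  hits <- 0L
  for (i in 1:200) {
    pr <- make_promoter(list(), 201L, 100L, gc = 0.5)
    ann <- annotate_promoter("bg", pr$sequence, 100L)
    hits <- hits + (ann$has_tata || ann$has_inr || ann$has_pause)
  }
  expect_lt(hits / 200, 0.5)  # background matches exist but are a minority
})

test_that("half-life draws are log-normal with the stated median", {
  expect_equal(sample_halflife("Inr-G", dispersion = 0), 44)
  expect_equal(sample_halflife("Inr-nonG", dispersion = 0), 14)
  draws <- sample_halflife("Inr-G", dispersion = 0.5, seed = 3, n = 10000)
  expect_equal(median(draws), 44, tolerance = 0.05)
  expect_true(all(draws > 0))
  expect_error(sample_halflife("mystery"), "no median")
})

test_that("simulated read counts follow the decay law in expectation", {
  tr <- sim_truth("c", list(), 60, treat_min = 60)
  params <- sim_read_params(n_pause_reads = 10000, n_init_reads = 0,
                            duplicate_rate = 0)
  counts <- vapply(1:50, function(s) {
    nrow(simulate_nexus_reads(tr, params, "triptolide", 60, seed = s)$reads)
  }, numeric(1))
  expect_equal(mean(counts), 5000, tolerance = 0.02)
  ctl <- simulate_nexus_reads(tr, params, "control", 0, seed = 1)
  expect_equal(nrow(ctl$reads), 10000, tolerance = 0.05)
  expect_error(simulate_nexus_reads(tr, params, "triptolide", -5), ">= 0")
  expect_error(simulate_nexus_reads(tr, params, "control", 10), "treat_min = 0")
})

test_that("footprint geometry straddles the pause site by strand", {
  tr <- sim_truth("c", list(), 60, treat_min = 60)
  params <- sim_read_params(n_pause_reads = 3000, n_init_reads = 0,
                            duplicate_rate = 0, footprint_halfwidth = 10L)
  lib <- simulate_nexus_reads(tr, params, "control", 0, seed = 9)
  bio <- offset_to_bio(lib$reads$five_prime_pos, params$tss_index)
  plus <- bio[lib$reads$strand == "+"]
  minus <- bio[lib$reads$strand == "-"]
  # plus-strand stops sit ~10 bp upstream, minus-strand ~10 bp downstream
  expect_true(all(plus >= 30 - 10 & plus <= 50 - 10))
  expect_true(all(minus >= 30 + 10 & minus <= 50 + 10))
  expect_equal(length(plus) / nrow(lib$reads), 0.5, tolerance = 0.05)
})

test_that("duplicates share the full read key and vanish at rate zero", {
  tr <- sim_truth("c", list(), 60, treat_min = 60)
  p0 <- sim_read_params(n_pause_reads = 200, n_init_reads = 0,
                        duplicate_rate = 0)
  lib0 <- simulate_nexus_reads(tr, p0, "control", 0, seed = 10)
  expect_identical(nrow(dedup_reads(lib0$reads)), nrow(lib0$reads))
  p1 <- sim_read_params(n_pause_reads = 2000, n_init_reads = 0,
                        duplicate_rate = 0.3)
  lib1 <- simulate_nexus_reads(tr, p1, "control", 0, seed = 10)
  expect_gt(nrow(lib1$reads), nrow(dedup_reads(lib1$reads)))
})

test_that("library simulation is byte-identical under a fixed seed", {
  tr <- sim_truth("c", list(), 45, treat_min = 30)
  params <- sim_read_params(n_pause_reads = 500)
  a <- simulate_nexus_reads(tr, params, "triptolide", 30, seed = 12)
  b <- simulate_nexus_reads(tr, params, "triptolide", 30, seed = 12)
  expect_identical(a, b)
})

test_that("cohort planting round-trips through annotation exactly", {
  co <- simulate_cohort(15, c("Inr-G", "Inr-nonG"), seed = 11)
  anns <- lapply(names(co$sequences), function(id) {
    annotate_promoter(id, co$sequences[[id]], co$tss_index)
  })
  groups <- group_by_combination(anns, co$halflives, "exclusive")
  sizes <- setNames(vapply(groups, `[[`, integer(1), "n"),
                    vapply(groups, `[[`, character(1), "label"))
  expect_identical(unname(sizes["Inr-G"]), 15L)
  expect_identical(unname(sizes["Inr-nonG"]), 15L)
  expect_identical(sum(sizes), 30L)
  expect_error(simulate_cohort(0, "Inr-G"), ">= 1")
})

test_that("cohort outputs round-trip through the file formats", {
  co <- simulate_cohort(3, c("TATA", "pause"), seed = 12)
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_fasta(co$sequences, fa)
  write_halflife_table(co$halflives, tsv)
  expect_identical(read_fasta(fa), co$sequences)
  expect_equal(read_halflife_table(tsv), co$halflives)  # text round-trip: 15 sig digits
})

test_that("qPCR simulation encodes the printed Ct arithmetic", {
  q <- simulate_qpcr(1.0, copy_number_ratio = 10, noise_sd_ct = 0, seed = 1)
  expect_equal(qpcr_relative_expression(q), rep(1.0, 3))
  # copy number cancels: a 50-fold plasmid excess leaves the estimate at 2
  q2 <- simulate_qpcr(2.0, copy_number_ratio = 50, noise_sd_ct = 0, seed = 1)
  expect_equal(qpcr_relative_expression(q2), rep(2.0, 3))
  expect_error(simulate_qpcr(0), "> 0")
  expect_error(simulate_qpcr(1, copy_number_ratio = -1), "> 0")
})

test_that("noisy qPCR recovers the truth in geometric-mean expectation", {
  ests <- vapply(1:500, function(s) {
    q <- simulate_qpcr(2.0, noise_sd_ct = 0.2, seed = s, n_replicates = 1)
    qpcr_relative_expression(q)
  }, numeric(1))
  expect_equal(exp(mean(log(ests))), 2.0, tolerance = 0.1)
})
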