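mk_group <- function(label, hl) {
  structure(list(label = label, elements = strsplit(label, "+", fixed = TRUE)[[1]],
                 mode = "exclusive", member_ids = paste0(label, seq_along(hl)),
                 halflives_min = hl,
                 median_min = if (length(hl)) median(hl) else NA_real_,
                 n = length(hl)), class = "combination_group")
}

test_that("stratify reports order-statistic medians sorted descending", {
  tab <- stratify(list(mk_group("a", c(10, 20, 30)),
                       mk_group("b", c(10, 20, 30, 40)),
                       mk_group("c", numeric(0))))
  expect_equal(tab$median_min[tab$label == "a"], 20)
  expect_equal(tab$median_min[tab$label == "b"], 25)  # mean of middle two
  expect_true(is.na(tab$median_min[tab$label == "c"]))
  expect_identical(tab$n[tab$label == "c"], 0L)
  expect_identical(tab$label, c("b", "a", "c"))  # descending, NA last
  expect_error(stratify(list()), "no groups")
})

test_that("rank-sum test: degenerate ties, exact small-sample enumeration", {
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)  # 2/20 arrangements as extreme
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum p equals exhaustive permutation enumeration with ties", {
  set.seed(41)
  for (i in 1:60) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    a <- sample(1:4, m, replace = TRUE)  # heavy ties
    b <- sample(1:4, n, replace = TRUE)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_ranksum_p(a, b),
                 tolerance = 1e-12,
                 label = paste("a:", toString(a), "b:", toString(b)))
  }
})

test_that("rank-sum agrees with wilcox.test where both are defined", {
  set.seed(42)
  # exact, tie-free small samples
  for (i in 1:20) {
    a <- sample(seq(1, 199, 2), 5); b <- sample(seq(2, 200, 2), 6)
    expect_equal(wilcoxon_rank_sum(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-10)
  }
  # large samples: normal approximation with continuity and tie correction
  a <- rnorm(60); b <- rnorm(70, 0.4)
  expect_equal(wilcoxon_rank_sum(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
  at <- round(rnorm(50), 1); bt <- round(rnorm(55, 0.3), 1)  # with ties
  expect_equal(wilcoxon_rank_sum(at, bt)$p_value,
               wilcox.test(at, bt, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("promoter classes follow the TATA/stable half-life thresholds", {
  tab <- data.frame(
    promoter_id = paste0("p", 1:5),
    has_tata = c(TRUE, FALSE, TRUE, FALSE, FALSE),
    has_inr = FALSE, inr_variant = "absent", base_plus2 = "A",
    has_pause = FALSE, n_in_window = FALSE, stringsAsFactors = FALSE
  )
  hl <- data.frame(promoter_id = paste0("p", 1:5),
                   halflife_min = c(25, 65, 45, 30, 70))
  cls <- define_classes(tab, hl)
  expect_identical(cls$tata_class, "p1")     # TATA and < 30 min
  expect_identical(cls$stable_class, c("p2", "p5"))  # no TATA, >= 60 min
  expect_length(intersect(cls$tata_class, cls$stable_class), 0L)
})

test_that("class partition is always disjoint on random inputs", {
  set.seed(43)
  for (i in 1:25) {
    n <- 40
    tab <- data.frame(promoter_id = paste0("p", 1:n),
                      has_tata = sample(c(TRUE, FALSE), n, TRUE),
                      has_inr = FALSE, inr_variant = "absent",
                      base_plus2 = "A", has_pause = FALSE,
                      n_in_window = FALSE, stringsAsFactors = FALSE)
    hl <- data.frame(promoter_id = tab$promoter_id,
                     halflife_min = rlnorm(n, log(30), 1))
    cls <- define_classes(tab, hl)
    expect_length(intersect(cls$tata_class, cls$stable_class), 0L)
  }
})

test_that("PFM columns count bases and IC spans the entropy bounds", {
  seqs <- c("AAAA", "AACC", "AAGG", "AATT")
  pfm <- pfm_and_logo(seqs, tss_indices = 2L, window_bio = c(-2, 2))
  # column at -2 (offset 0): all A -> counts (4,0,0,0), IC = 2 bits
  expect_identical(unname(pfm$counts[, "-2"]), c(4L, 0L, 0L, 0L))
  expect_equal(unname(pfm$info_content["-2"]), 2)
  # column at +2 (offset 3): one of each base -> IC = 0 bits
  expect_identical(unname(pfm$counts[, "2"]), c(1L, 1L, 1L, 1L))
  expect_equal(unname(pfm$info_content["2"]), 0)
  # column (2,1,1,0): entropy 1.5 bits -> IC = 0.5
  seqs2 <- c("A", "A", "C", "G")
  pfm2 <- pfm_and_logo(seqs2, tss_indices = 0L, window_bio = c(1, 1))
  expect_equal(unname(pfm2$info_content), 0.5)
})

test_that("PFM conserves columns and bounds IC on random inputs", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    seqs <- vapply(seq_len(n), function(j) random_dna(40), character(1))
    pfm <- pfm_and_logo(seqs, tss_indices = 20L, window_bio = c(-10, 10))
    expect_true(all(colSums(pfm$counts) == n))
    expect_true(all(pfm$info_content >= 0 & pfm$info_content <= 2))
  }
})

test_that("short sequences are excluded from the PFM with a warning", {
  expect_warning(
    pfm <- pfm_and_logo(c("ACGTACGTAC", "ACG"), tss_indices = c(5L, 1L),
                        window_bio = c(-2, 2)),
    "excluded")
  expect_identical(pfm$n_sequences, 1L)
  expect_error(suppressWarnings(
    pfm_and_logo("ACG", tss_indices = 1L, window_bio = c(-2, 2))))
})

test_that("G-at-+2 comparison uses the literal base and Fisher's exact test", {
  mk <- function(base2, n) {
    vapply(seq_len(n), function(i) {
      s <- strsplit(random_dna(10), "")[[1]]
      s[6] <- base2  # tss_index 4 -> +2 at offset 5
      paste(s, collapse = "")
    }, character(1))
  }
  set.seed(45)
  # identical composition -> p = 1
  a <- c(mk("G", 50), mk("A", 50))
  b <- c(mk("G", 50), mk("A", 50))
  res <- g2_frequency_test(a, b, 4L, 4L)
  expect_equal(res$prop_a, 0.5)
  expect_equal(res$prop_b, 0.5)
  expect_equal(res$p_value, 1)
  # 9/1 vs 1/9 against the hypergeometric enumeration oracle
  res2 <- g2_frequency_test(c(mk("G", 9), mk("T", 1)),
                            c(mk("G", 1), mk("T", 9)), 4L, 4L)
  expect_equal(res2$p_value, oracle_fisher_p(9, 1, 1, 9), tolerance = 1e-9)
  expect_equal(res2$p_value, 0.0011, tolerance = 0.05)
  expect_error(g2_frequency_test(character(0), b, 4L, 4L), "non-empty")
})
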