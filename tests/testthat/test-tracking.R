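pair_fixture <- function(vat_seqs, vat_counts, pb_seqs, pb_counts,
                         id = "P1", group = "LC") {
  list(pb = make_rep(pb_counts, cdr3 = pb_seqs, individual_id = id,
                     group = group, compartment = "PB"),
       vat = make_rep(vat_counts, cdr3 = vat_seqs, individual_id = id,
                      group = group, compartment = "VAT"))
}

test_that("disjoint PB and VAT repertoires share nothing", {
  fx <- pair_fixture(seq_pool(5), rep(1, 5), seq_pool(10)[6:10], rep(1, 5))
  rc <- recirculating_clones(fx$pb, fx$vat)
  expect_length(rc$shared_keys, 0)
  expect_equal(rc$frac_recirc_vat, 0)
  expect_equal(rc$frac_recirc_pb, 0)
})

test_that("recirculation fractions count shared unique clones per compartment", {
  vat <- seq_pool(100)
  pb <- c(vat[1:5], seq_pool(100, prefix = "CASR")[1:45])
  fx <- pair_fixture(vat, rep(1, 100), pb, rep(1, 50))
  rc <- recirculating_clones(fx$pb, fx$vat)
  expect_setequal(rc$shared_keys, vat[1:5])
  expect_equal(rc$frac_recirc_vat, 0.05)
  expect_equal(rc$frac_recirc_pb, 0.1)
})

test_that("direction classification follows the frequency comparison", {
  expect_equal(classify_direction(0.02, 0.01), "VAT")
  expect_equal(classify_direction(0.01, 0.02), "PB")
  expect_equal(classify_direction(0.01, 0.01), "TIED")
  expect_equal(classify_direction(c(0.3, 0.1, 0.2), c(0.1, 0.3, 0.2)),
               c("VAT", "PB", "TIED"))
})

test_that("mismatched individual or subset is rejected", {
  fx <- pair_fixture(seq_pool(3), rep(1, 3), seq_pool(3), rep(1, 3))
  fx$pb$individual_id <- "OTHER"
  expect_error(recirculating_clones(fx$pb, fx$vat),
               class = "tcrtrack_scope_error")
  expect_error(recirculating_clones(fx$vat, fx$vat),
               class = "tcrtrack_scope_error")
})

test_that("shared keys are symmetric between the two compartments", {
  set.seed(31)
  for (i in 1:5) {
    n_shared <- sample(0:10, 1)
    vat <- seq_pool(30)
    pb <- c(sample(vat, n_shared), seq_pool(40, prefix = "CASR")[1:20])
    fx <- pair_fixture(vat, sample(1:9, 30, TRUE), pb,
                       sample(1:9, n_shared + 20, TRUE))
    rc <- recirculating_clones(fx$pb, fx$vat)
    expect_setequal(rc$shared_keys,
                    intersect(fx$pb$clonotypes$cdr3_aa,
                              fx$vat$clonotypes$cdr3_aa))
    expect_equal(length(rc$shared_keys), n_shared)
  }
})

test_that("direction calls match a brute-force re-scan on synthetic individuals", {
  sim <- generate_cohort(group_scenario("OB-Dys", 3,
                                        clones_per_repertoire = 150,
                                        recirc_fraction = 0.1,
                                        pb_expansion_bias = 0.5),
                         seed = 17, subsets = "PD1pos")
  tr <- track_cohort(sim$cohort)
  for (rc in tr$reports) {
    pb <- filter_functional(cohort_select(sim$cohort, "PB",
                                          individual_id = rc$individual_id)[[1]])
    vat <- filter_functional(cohort_select(sim$cohort, "VAT",
                                           individual_id = rc$individual_id)[[1]])
    for (j in seq_len(nrow(rc$per_clone))) {
      k <- rc$per_clone$key[j]
      fv <- vat$clonotypes$frequency[vat$clonotypes$cdr3_aa == k]
      fp <- pb$clonotypes$frequency[pb$clonotypes$cdr3_aa == k]
      want <- if (fv > fp) "VAT" else if (fp > fv) "PB" else "TIED"
      expect_equal(rc$per_clone$direction[j], want)
    }
    # and against the planted ground truth
    truth <- sim$truth$recirc[sim$truth$recirc$individual_id ==
                                rc$individual_id, ]
    m <- match(rc$per_clone$key, truth$cdr3_aa)
    expect_false(anyNA(m))
    expect_equal(rc$per_clone$direction, truth$direction[m])
  }
})

test_that("group summary pools directions and is order-invariant", {
  fx1 <- pair_fixture(seq_pool(4), c(5, 5, 1, 1),
                      c(seq_pool(4)[1:2], seq_pool(6, "CASR")[1:2]),
                      c(1, 1, 10, 10), id = "A")
  rc1 <- recirculating_clones(fx1$pb, fx1$vat)
  s1 <- group_summary(list(rc1))
  expect_equal(s1$frac_clones_vat_expanded, 1)
  expect_equal(s1$frac_clones_pb_expanded, 0)

  fx2 <- pair_fixture(seq_pool(8), rep(c(4, 1), 4),
                      c(seq_pool(8)[c(1, 3)], seq_pool(9, "CASR")[1:2]),
                      c(20, 1, 5, 6), id = "B")
  rc2 <- recirculating_clones(fx2$pb, fx2$vat)
  s12 <- group_summary(list(rc1, rc2))
  s21 <- group_summary(list(rc2, rc1))
  expect_equal(s12$median_frac_recirc, s21$median_frac_recirc)
  expect_equal(s12$frac_clones_vat_expanded, s21$frac_clones_vat_expanded)
  expect_equal(s12$frac_clones_vat_expanded +
                 s12$frac_clones_pb_expanded + s12$frac_clones_tied, 1,
               tolerance = 1e-9)
})

test_that("identical group distributions give a high Kruskal-Wallis p", {
  tab <- tibble::tibble(
    individual_id = paste0("P", 1:12),
    group = rep(c("LC", "OB-ND", "OB-Dys"), each = 4),
    subset = "PD1pos", n_shared = 5L,
    frac_recirc_vat = rep(c(0.05, 0.08, 0.1, 0.12), 3),
    frac_recirc_pb = rep(c(0.05, 0.08, 0.1, 0.12), 3))
  res <- compare_recirculation(list(table = tab, summaries = list()))
  expect_gte(res$kruskal$p_value, 0.05)
})

test_that("one-sided Wilcoxon p is minimal when every pair favors PB", {
  for (n in c(5, 8)) {
    fv <- seq(0.01, 0.01 * n, by = 0.01)
    fp <- fv + 0.01 + 0.001 * seq_len(n)   # distinct, all-positive differences
    p <- stats::wilcox.test(fp, fv, paired = TRUE, alternative = "greater",
                            exact = TRUE)$p.value
    expect_equal(p, 1 / 2^n, tolerance = 1e-12)
    expect_equal(p, wilcoxon_signed_oracle(fp, fv, "greater"),
                 tolerance = 1e-12)
  }
})

test_that("a planted location shift is detected by Kruskal-Wallis", {
  set.seed(19)
  hits <- 0
  for (i in 1:100) {
    tab <- tibble::tibble(
      individual_id = paste0("P", 1:60),
      group = rep(c("LC", "OB-ND", "OB-Dys"), each = 20),
      subset = "PD1pos", n_shared = 5L,
      frac_recirc_vat = c(rbeta(20, 5, 95), rbeta(20, 8, 92),
                          rbeta(20, 12, 88)),
      frac_recirc_pb = 0.1)
    res <- compare_recirculation(list(table = tab, summaries = list()))
    if (res$kruskal$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
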