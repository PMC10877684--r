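test_that("central-region k-mers trim three residues at each flank", {
  expect_setequal(extract_motifs("CASSLGQAYEQYF", k = 3),
                  c("SLG", "LGQ", "GQA", "QAY", "AYE"))
  expect_setequal(extract_motifs("CASSLGQAYEQYF", k = 4),
                  c("SLGQ", "LGQA", "GQAY", "QAYE"))
  # central region shorter than k
  expect_length(extract_motifs("CASSAYF", k = 3), 0)
  expect_length(extract_motifs("CASSLGAYF", k = 4), 0)

  set.seed(41)
  for (i in 1:20) {
    s <- paste0("C", paste(sample(LETTERS[1:20], sample(10:16, 1), TRUE),
                           collapse = ""), "F")
    for (k in c(3, 4)) {
      for (m in extract_motifs(s, k)) {
        expect_equal(nchar(m), k)
        expect_true(grepl(m, substr(s, 4, nchar(s) - 3), fixed = TRUE))
      }
    }
  }
})

test_that("motif at equal rates is not called enriched", {
  samp <- c(paste0("CAS", strrep("A", 3), "QQQ", strrep("B", 3), "FF"),
            seq_pool(9))
  refr <- c(samp[1], seq_pool(90, prefix = "CASR"))
  enr <- motif_enrichment(samp, refr, k = 3)
  qqq <- enr[enr$motif == "QQQ", ]
  expect_equal(qqq$fold, (1 / 10) / (1 / 91), tolerance = 1e-9)
  # identical sample and reference: no over-representation anywhere
  null_like <- motif_enrichment(seq_pool(20), seq_pool(20), k = 3)
  expect_true(all(null_like$fold == 1))
  expect_true(all(null_like$fisher_score > 0.45))
})

test_that("a spiked motif reaches significance at n >= 200", {
  set.seed(43)
  spike <- "WWW"
  n_s <- 200
  samp <- seq_pool(n_s)
  idx <- sample(n_s, 20)                      # 10% of the sample
  substr(samp[idx], 6, 8) <- spike
  refr <- seq_pool(676, prefix = "CASR")[1:500] # ~0% carries it
  enr <- motif_enrichment(samp, refr, k = 3)
  expect_lte(enr$fisher_score[enr$motif == spike], 0.05)
})

test_that("one-sided motif Fisher scores equal exhaustive enumeration", {
  for (a in 0:5) for (b in 0:5) for (cc in 0:5) for (d in 0:5) {
    if ((a + cc) == 0) next
    p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2),
                            alternative = "greater")$p.value
    expect_equal(p, fisher_greater_oracle(a, b, cc, d), tolerance = 1e-10)
  }
})

test_that("build_patterns clusters exactly the sequences carrying the motif", {
  spike <- "YWY"
  members <- paste0("CASS", c("A", "C", "D", "E", "G"), spike, "TEQYF")
  others <- seq_pool(20)
  rep <- make_rep(rep(1, 25), cdr3 = c(members, others))
  refr <- seq_pool(400, prefix = "CASR")
  pat <- build_patterns(list(rep), refr, k = 3)
  hit <- pat[pat$motif == spike, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$n_unique_cdr3, 5)
  expect_setequal(hit$members[[1]]$cdr3_aa, members)
  expect_true(all(grepl(spike, hit$members[[1]]$cdr3_aa)))
})

test_that("no patterns are built from an empty or motif-free scope", {
  rep <- make_rep(c(1, 1), cdr3 = c("CASSAYF", "CASSGYF"))
  pat <- build_patterns(list(rep), seq_pool(50), k = 3)
  expect_equal(nrow(pat), 0)
})

test_that("a spiked specificity cluster survives the full pattern pipeline", {
  sc <- group_scenario("OB-Dys", 3, clones_per_repertoire = 120,
                       recirc_fraction = 0.1,
                       motif_spikes = list(list(motif = "WQW", rate = 0.08)))
  sim <- generate_cohort(sc, seed = 149, subsets = "PD1pos")
  set.seed(151)
  refr <- replicate(400, paste0(
    "C", paste(sample(LETTERS[1:20], sample(10:16, 1), TRUE),
               collapse = ""), "F"))
  pats <- build_patterns(cohort_select(sim$cohort, subset = "PD1pos"),
                         refr, k = 3, min_members = 3)
  kept <- filter_patterns(pats)
  expect_true("WQW" %in% kept$motif)
  hit <- kept[kept$motif == "WQW", ]
  expect_gte(hit$n_unique_cdr3, 3)
  expect_true(all(sim$truth$spiked_motifs$cdr3_aa %in%
                    hit$members[[1]]$cdr3_aa))
})

test_that("the retention filter keeps exactly the patterns meeting all four inclusive criteria", {
  fixture <- tibble::tibble(
    motif = sprintf("M%02d", 1:10),
    n_unique_cdr3 = c(3, 2, 3, 3, 3, 5, 10, 3, 4, 2),
    fisher_score = c(0.05, 0.001, 0.051, 0.001, 0.02, 0.05, 0.0001,
                      0.03, 0.05, 0.06),
    v_enrichment_p = c(0.05, 0.001, 0.01, 0.06, 0.02, 0.05, 0.001,
                        0.03, 0.07, 0.01),
    length_p = c(0.05, 0.001, 0.01, 0.01, 0.051, 0.05, 0.001, 0.02,
                  0.01, 0.2))
  kept <- filter_patterns(fixture)
  expect_setequal(kept$motif, c("M01", "M06", "M07", "M08"))

  # idempotent and order-invariant
  expect_equal(filter_patterns(kept), kept)
  shuffled <- fixture[sample.int(10), ]
  expect_setequal(filter_patterns(shuffled)$motif, kept$motif)

  # missing statistics are an error naming the pattern
  broken <- fixture
  broken$length_p[3] <- NA
  expect_error(filter_patterns(broken), "M03",
               class = "tcrtrack_format_error")
})

test_that("imported GLIPH2 tables pass through the retention filter", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    pattern = c("SLG", "QAY", "AYE"),
    number_unique_cdr3 = c(5, 2, 4),
    Fisher_score = c(0.01, 0.01, 0.2),
    vb_score = c(0.02, 0.02, 0.02),
    length_score = c(0.03, 0.03, 0.03),
    final_score = c(1e-8, 1e-5, 1e-3)), path)
  pat <- read_gliph2(path)
  expect_equal(filter_patterns(pat)$motif, "SLG")
})

test_that("pattern recirculation requires members in both compartments of an individual", {
  mk <- function(cdr3s, comp) tibble::tibble(
    cdr3_aa = cdr3s, v_gene = "TRBV19", individual_id = "P1",
    compartment = comp)
  vat_only <- tibble::tibble(
    motif = "AAA", members = list(mk(c("CASSAAAXEQYF"), "VAT")))
  both <- tibble::tibble(
    motif = "WWW", members = list(dplyr::bind_rows(
      mk("CASSWWWXEQYF", "VAT"), mk("CASSGWWWEQYF", "PB"))))
  res <- pattern_recirculation(dplyr::bind_rows(vat_only, both))
  expect_equal(res$overall_frac, 0.5)
  expect_equal(res$per_individual$n_recirculating, 1)

  # planted rate on constructed pattern sets
  set.seed(47)
  for (rate in c(0.2, 0.5)) {
    n_pat <- 40
    recirc <- runif(n_pat) < rate
    pats <- purrr::map_dfr(seq_len(n_pat), function(i) {
      mem <- mk(sprintf("CASSM%02dXEQYF", i), "VAT")
      if (recirc[i]) mem <- dplyr::bind_rows(mem,
        mk(sprintf("CASSN%02dXEQYF", i), "PB"))
      tibble::tibble(motif = sprintf("P%02d", i), members = list(mem))
    })
    res <- pattern_recirculation(pats)
    expect_equal(res$overall_frac, mean(recirc))
  }
})
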