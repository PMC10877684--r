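test_that("the generator is deterministic given a seed", {
  sc <- default_scenarios(clones_per_repertoire = 60, public_pool_size = 5)
  a <- generate_cohort(sc, seed = 77, subsets = "PD1pos")
  b <- generate_cohort(sc, seed = 77, subsets = "PD1pos")
  expect_identical(lapply(a$cohort$repertoires, `[[`, "clonotypes"),
                   lapply(b$cohort$repertoires, `[[`, "clonotypes"))
  expect_identical(a$truth$recirc, b$truth$recirc)
  c_ <- generate_cohort(sc, seed = 78, subsets = "PD1pos")
  expect_false(identical(a$cohort$repertoires[[1]]$clonotypes,
                         c_$cohort$repertoires[[1]]$clonotypes))
})

test_that("zero recirculation fraction yields disjoint compartments", {
  sim <- generate_cohort(group_scenario("LC", 3, clones_per_repertoire = 80,
                                        recirc_fraction = 0),
                         seed = 79, subsets = "PD1pos")
  tr <- track_cohort(sim$cohort)
  expect_true(all(tr$table$n_shared == 0))
  expect_equal(nrow(sim$truth$recirc), 0)
})

test_that("ground truth is re-derivable by brute-force scan of the repertoires", {
  sim <- generate_cohort(default_scenarios(clones_per_repertoire = 100,
                                           public_pool_size = 10),
                         seed = 83, subsets = "PD1pos")
  truth <- sim$truth$recirc
  for (id in unique(truth$individual_id)) {
    pb <- filter_functional(cohort_select(sim$cohort, "PB",
                                          individual_id = id)[[1]])
    vat <- filter_functional(cohort_select(sim$cohort, "VAT",
                                           individual_id = id)[[1]])
    shared <- intersect(pb$clonotypes$cdr3_aa, vat$clonotypes$cdr3_aa)
    want <- truth$cdr3_aa[truth$individual_id == id]
    expect_setequal(shared, want)
    for (k in shared) {
      fv <- vat$clonotypes$frequency[vat$clonotypes$cdr3_aa == k]
      fp <- pb$clonotypes$frequency[pb$clonotypes$cdr3_aa == k]
      planted <- truth$direction[truth$individual_id == id &
                                   truth$cdr3_aa == k]
      rescanned <- if (fv > fp) "VAT" else if (fp > fv) "PB" else "TIED"
      expect_equal(rescanned, planted)
    }
  }
})

test_that("motif spikes are embedded in the central region at the planted rate", {
  sc <- group_scenario("OB-Dys", 2, clones_per_repertoire = 100,
                       motif_spikes = list(list(motif = "WQW", rate = 0.1)))
  sim <- generate_cohort(sc, seed = 89, subsets = "PD1pos")
  spk <- sim$truth$spiked_motifs
  expect_equal(nrow(spk), 2 * 10)
  for (i in seq_len(nrow(spk))) {
    s <- spk$cdr3_aa[i]
    expect_true(grepl("WQW", substr(s, 4, nchar(s) - 3), fixed = TRUE))
    expect_equal(nchar(s), 14)  # cluster-like shared length
  }
  vat <- cohort_select(sim$cohort, "VAT",
                       individual_id = spk$individual_id[1])[[1]]
  mine <- spk$cdr3_aa[spk$individual_id == vat$individual_id]
  expect_true(all(mine %in% vat$clonotypes$cdr3_aa))
  # spiked sequences share the cluster V gene
  expect_true(all(vat$clonotypes$v_gene[match(mine, vat$clonotypes$cdr3_aa)] ==
                    "TRBV19"))
})

test_that("ties are only generated when requested", {
  no_tie <- generate_cohort(group_scenario("LC", 2,
                                           clones_per_repertoire = 100,
                                           recirc_fraction = 0.1),
                            seed = 97, subsets = "PD1pos")
  expect_false(any(no_tie$truth$recirc$direction == "TIED"))
  tied <- generate_cohort(group_scenario("LC", 2, clones_per_repertoire = 100,
                                         recirc_fraction = 0.1,
                                         tie_rate = 1),
                          seed = 97, subsets = "PD1pos")
  expect_true(all(tied$truth$recirc$direction == "TIED"))
  tr <- track_cohort(tied$cohort)
  expect_true(all(unlist(lapply(tr$reports,
                                function(r) r$per_clone$direction)) == "TIED"))
})

test_that("infeasible scenarios are rejected", {
  expect_error(generate_cohort(group_scenario("LC", 1,
                                              clones_per_repertoire = 50,
                                              recirc_fraction = 1),
                               seed = 1, subsets = "PD1pos"),
               class = "tcrtrack_value_error")
})

test_that("written cohorts round-trip through the manifest reader", {
  dir <- withr::local_tempdir()
  sim <- generate_cohort(group_scenario("LC", 2, clones_per_repertoire = 40,
                                        public_pool_size = 0),
                         seed = 101, subsets = "PD1pos", dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  ch <- read_cohort(file.path(dir, "manifest.yaml"))
  expect_equal(length(ch$repertoires), length(sim$cohort$repertoires))
  expect_equal(ch$clinical$homa_ir, sim$cohort$clinical$homa_ir)
  for (nm in names(sim$cohort$repertoires)) {
    a <- dplyr::arrange(sim$cohort$repertoires[[nm]]$clonotypes, cdr3_aa)
    b <- dplyr::arrange(ch$repertoires[[nm]]$clonotypes, cdr3_aa)
    expect_equal(b$count, a$count)
    expect_equal(b$frequency, a$frequency)
  }
})

test_that("synthetic clinical records classify into their cohort group", {
  sim <- generate_cohort(default_scenarios(clones_per_repertoire = 40),
                         seed = 103, subsets = "PD1pos")
  clin <- sim$cohort$clinical
  meta <- cohort_metadata(sim$cohort)
  grp <- meta$group[match(clin$individual_id, meta$individual_id)]
  cls <- classify_glycemia(clin)
  expect_true(all(cls[grp %in% c("LC", "OB-ND")] == "ND"))
  expect_true(all(cls[grp == "OB-Dys"] %in% c("PreD", "D")))
})

test_that("group ordering of recirculation medians reflects the planted fractions", {
  ok <- 0
  for (s in 1:5) {
    sim <- generate_cohort(default_scenarios(clones_per_repertoire = 100,
                                             public_pool_size = 0),
                           seed = 200 + s, subsets = "PD1pos")
    tr <- track_cohort(sim$cohort)
    med <- vapply(tr$summaries, `[[`, numeric(1), "median_frac_recirc")
    if (med[["OB-Dys"]] > med[["LC"]]) ok <- ok + 1
  }
  expect_gte(ok, 5 * 0.95 - 1)
})
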